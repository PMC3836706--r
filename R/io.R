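#' Write a choice table to CSV with provenance header
#'
#' Canonical tabular interchange for choice sets, schedules and simulated
#' datasets: plain CSV preceded by `#`-prefixed comment lines recording the
#' generator seed and any extra metadata.
#'
#' @param x data frame (choice pairs, schedule, or dataset).
#' @param path output file.
#' @param seed seed to record; defaults to the table's `seed` attribute.
#' @param meta optional named character vector of extra header fields.
#' @export
write_choice_csv <- function(x, path, seed = attr(x, "seed"), meta = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(seed)) writeLines(sprintf("# seed: %d", as.integer(seed)), con)
  for (nm in names(meta)) writeLines(sprintf("# %s: %s", nm, meta[[nm]]), con)
  write.table(as.data.frame(x), con, sep = ",", row.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' Read a choice table written by [write_choice_csv()]
#'
#' @param path CSV file; `#` comment lines are skipped (the seed header is
#'   returned as the `seed` attribute when present).
#' @return data frame.
#' @export
read_choice_csv <- function(path) {
  hdr <- readLines(path, n = 10)
  seed_line <- grep("^# seed:", hdr, value = TRUE)
  out <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if ("choice" %in% names(out) && !all(out$choice %in% c(0, 1, "sooner", "later")))
    stop("malformed choice column: values must be 0/1 or sooner/later; ",
         "offending rows: ",
         paste(head(which(!(out$choice %in% c(0, 1, "sooner", "later"))), 5),
               collapse = ", "))
  if (length(seed_line))
    attr(out, "seed") <- as.integer(sub("^# seed:\\s*", "", seed_line[1]))
  out
}

#' Flatten fit results to a summary data frame
#'
#' One row per subject x model fit, suitable for CSV export: estimates,
#' log-likelihood, BIC, convergence and at-bound flags.
#'
#' @param per_subject_fits named list: subject -> named list: model ->
#'   `dread_fit`.
#' @return data frame.
#' @export
fit_summary_table <- function(per_subject_fits) {
  rows <- list()
  for (s in names(per_subject_fits)) {
    for (m in names(per_subject_fits[[s]])) {
      f <- per_subject_fits[[s]][[m]]
      k <- length(f$spec$free)
      row <- data.frame(subject = s, model = m, logLik = f$logLik,
                        k = k, n = f$n_obs,
                        BIC = bic(f$logLik, k, f$n_obs),
                        converged = f$converged,
                        any_at_bound = any(f$at_bound))
      for (nm in names(f$params)) row[[nm]] <- f$params[[nm]]
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
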