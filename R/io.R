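# Plain-text readers/writers for cohort artifacts: long-format signal CSV
# (sample, lead, microvolts), covariate/label tables, and JSON configs.

#' Write a recording as a long-format CSV
#'
#' Columns: sample (1-based index), lead, uV. Sampling metadata is carried in
#' a `# fs=<Hz>` comment line at the top of the file.
#'
#' @param rec an `ecg_recording`.
#' @param path output file path.
#' @export
write_recording_csv <- function(rec, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%g subject_id=%s", rec$fs, rec$subject_id), con)
  long <- data.frame(
    sample = rep(seq_len(nrow(rec$samples)), times = ncol(rec$samples)),
    lead = rep(rec$leads, each = nrow(rec$samples)),
    uV = as.vector(rec$samples))
  utils::write.csv(long, con, row.names = FALSE)
  invisible(path)
}

#' Read a long-format recording CSV written by [write_recording_csv()]
#'
#' @param path input file path.
#' @return an `ecg_recording`.
#' @export
read_recording_csv <- function(path) {
  hdr <- readLines(path, n = 1)
  fs <- as.numeric(sub(".*fs=([0-9.]+).*", "\\1", hdr))
  sid <- sub(".*subject_id=(\\S+).*", "\\1", hdr)
  long <- utils::read.csv(path, comment.char = "#")
  leads <- unique(long$lead)
  M <- vapply(leads, function(l) long$uV[long$lead == l],
              numeric(sum(long$lead == leads[1])))
  colnames(M) <- leads
  ecg_recording(M, fs = fs, leads = leads, subject_id = sid)
}

#' Write cohort tables (covariates, ground-truth labels, generation config)
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @param signals also write one long CSV per subject under `dir/signals/`
#'   (default FALSE; recordings are reproducible from the config seed).
#' @return the directory, invisibly.
#' @export
write_cohort <- function(cohort, dir, signals = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cohort$covariates, file.path(dir, "covariates.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$labels, file.path(dir, "labels.csv"),
                   row.names = FALSE)
  cfg <- list(seed = cohort$seed, jitter = cohort$jitter,
              duration_s = cohort$duration_s, fs = cohort$fs,
              noise = unclass(cohort$noise),
              group_sizes = as.list(table(cohort$labels$group_label)))
  jsonlite::write_json(cfg, file.path(dir, "config.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  if (signals) {
    sdir <- file.path(dir, "signals")
    dir.create(sdir, showWarnings = FALSE)
    for (rec in cohort$subjects)
      write_recording_csv(rec, file.path(sdir, paste0(rec$subject_id, ".csv")))
  }
  invisible(dir)
}
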