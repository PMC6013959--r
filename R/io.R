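# Plain-text serialization of cohorts: one CSV per data type, note sections
# as JSON lines, and a JSON sidecar carrying the generator config.

#' Write a synthetic cohort to a directory of plain-text files
#'
#' Writes one CSV per data type (admissions, demographics, diagnoses, labs,
#' medications, procedures), note sections as a JSON-lines file with the
#' token stream split into an array, and `config.json` recording the
#' generator configuration (including the seed) so the cohort can be
#' regenerated or audited.
#'
#' @param cohort An `emr_cohort` from [generate_cohort()].
#' @param dir Output directory; created if missing.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "emr_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (tab in c("admissions", "demographics", "diagnoses", "labs",
                "medications", "procedures", "covariates", "truth")) {
    utils::write.csv(cohort[[tab]], file.path(dir, paste0(tab, ".csv")),
                     row.names = FALSE)
  }
  notes <- cohort$notes
  con <- file(file.path(dir, "notes.jsonl"), open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(notes))) {
    rec <- list(admission_id = notes$admission_id[i],
                note_type = notes$note_type[i],
                note_date = notes$note_date[i],
                section = notes$section[i],
                tokens = strsplit(notes$text[i], " ", fixed = TRUE)[[1]])
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con)
  }
  cfg <- unclass(cohort$config)
  cfg$nonlinear_pairs <- apply(cohort$config$nonlinear_pairs, 1, as.numeric,
                               simplify = FALSE)
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory previously produced by [write_cohort()].
#' @return An `emr_cohort` object.
#' @export
read_cohort <- function(dir) {
  out <- list()
  for (tab in c("admissions", "demographics", "diagnoses", "labs",
                "medications", "procedures", "covariates", "truth")) {
    out[[tab]] <- utils::read.csv(file.path(dir, paste0(tab, ".csv")),
                                  stringsAsFactors = FALSE)
  }
  lines <- readLines(file.path(dir, "notes.jsonl"))
  recs <- lapply(lines, jsonlite::fromJSON)
  out$notes <- data.frame(
    admission_id = vapply(recs, `[[`, character(1), "admission_id"),
    note_type = vapply(recs, `[[`, character(1), "note_type"),
    note_date = vapply(recs, `[[`, numeric(1), "note_date"),
    section = vapply(recs, `[[`, character(1), "section"),
    text = vapply(recs, function(r) paste(r$tokens, collapse = " "),
                  character(1)),
    stringsAsFactors = FALSE
  )
  cfg <- jsonlite::fromJSON(file.path(dir, "config.json"))
  np <- cfg$nonlinear_pairs
  cfg$nonlinear_pairs <- if (is.null(np) || length(np) == 0) {
    matrix(numeric(0), ncol = 3)
  } else if (is.matrix(np)) {
    np
  } else {
    matrix(as.numeric(unlist(np)), ncol = 3, byrow = TRUE)
  }
  out$config <- do.call(cohort_config, cfg)
  structure(out, class = "emr_cohort")
}
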