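#' Write a per-arm study report
#'
#' Collects the outputs of any subset of pipeline stages into one
#' human-readable delimited table (one row per arm; combination-level
#' quantities sit on the combination arm's row) and a machine-readable JSON
#' sidecar at `paste0(path, ".json")` holding every supplied component at
#' full precision. [read_study_report()] restores the sidecar, so write
#' followed by read is an identity on the stored values.
#'
#' @param results A named list with any of:
#'   * `growth`: per-arm summary from [summarize_groups()]
#'   * `gri`: a tibble of tidied [gri()] results (or a single `gri_result`)
#'   * `synergy`: a tidied [synergy_score()] result (or `synergy_result`)
#'   * `bwl`: output of [max_body_weight_loss()]
#'   * `cr`: output of [complete_responders()]
#'   * `survival`: output of `median_survival` columns (`group`,
#'     `median_survival`), e.g. via [km_estimate()] summaries
#'   At least one component must be supplied.
#' @param path Output path for the delimited (CSV) summary.
#' @return Invisibly, the per-arm summary tibble that was written.
#' @export
write_study_report <- function(results, path) {
  if (!is.list(results) || length(results) == 0 ||
      is.null(names(results)) || all(names(results) == "")) {
    abort("write_study_report(): supply a named list with >= 1 stage output.",
          class = "tumorgri_validation_error")
  }
  known <- c("growth", "gri", "synergy", "bwl", "cr", "survival")
  unknown <- setdiff(names(results), known)
  if (length(unknown) > 0) {
    abort(paste0("write_study_report(): unknown component(s): ",
                 paste(unknown, collapse = ", "), ". Known: ",
                 paste(known, collapse = ", ")),
          class = "tumorgri_validation_error")
  }
  if (inherits(results$gri, "gri_result")) results$gri <- tidy(results$gri)
  if (inherits(results$synergy, "synergy_result")) {
    results$synergy <- tidy(results$synergy)
  }

  arms <- unique(c(
    if (!is.null(results$growth)) results$growth$group,
    if (!is.null(results$gri)) c(results$gri$treatment, results$gri$control),
    if (!is.null(results$synergy)) results$synergy$ab,
    if (!is.null(results$bwl)) results$bwl$group,
    if (!is.null(results$cr)) results$cr$group,
    if (!is.null(results$survival)) results$survival$group
  ))
  report <- tibble(group = arms)
  if (!is.null(results$growth)) {
    report <- dplyr::left_join(
      report,
      dplyr::select(results$growth, "group", "n", "mean_rate", "se"),
      by = "group"
    )
  }
  if (!is.null(results$gri)) {
    report <- dplyr::left_join(
      report,
      dplyr::select(results$gri, group = "treatment", "gri_percent",
                    gri_p_value = "p_value"),
      by = "group"
    )
  }
  if (!is.null(results$synergy)) {
    report <- dplyr::left_join(
      report,
      dplyr::select(results$synergy, group = "ab",
                    synergy_score_percent = "score_percent",
                    synergy_p_value = "p_value", classification = "label"),
      by = "group"
    )
  }
  if (!is.null(results$cr)) {
    report <- dplyr::left_join(
      report,
      dplyr::select(results$cr, "group", "cr_count"),
      by = "group"
    )
  }
  if (!is.null(results$bwl)) {
    report <- dplyr::left_join(
      report,
      dplyr::select(results$bwl, "group", "max_mean_bwl_percent"),
      by = "group"
    )
  }
  if (!is.null(results$survival)) {
    report <- dplyr::left_join(
      report,
      dplyr::select(results$survival, "group", "median_survival"),
      by = "group"
    )
  }

  readr::write_csv(report, path)
  sidecar <- lapply(results, function(x) {
    if (inherits(x, "data.frame")) {
      # list columns (e.g. cr_animals, rates) serialize as JSON arrays
      as.data.frame(x)
    } else {
      x
    }
  })
  jsonlite::write_json(sidecar, paste0(path, ".json"), digits = NA,
                       dataframe = "columns", na = "null")
  invisible(report)
}

#' Read back a study-report JSON sidecar
#'
#' @param path The path given to [write_study_report()] (the `.json`
#'   sidecar is read from `paste0(path, ".json")`).
#' @return A named list of tibbles, one per stored component.
#' @export
read_study_report <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) {
    abort(paste0("read_study_report(): sidecar not found: ", sidecar),
          class = "tumorgri_io_error")
  }
  parsed <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  lapply(parsed, function(x) {
    if (is.list(x) && !is.null(names(x))) as_tibble(as.data.frame(
      lapply(x, function(col) if (is.list(col)) I(col) else col),
      stringsAsFactors = FALSE
    )) else x
  })
}
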