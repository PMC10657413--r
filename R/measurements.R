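#' Read a long-format caliper measurement table
#'
#' Reads a delimited text file with one row per animal-day, the common
#' currency of every downstream stage. The file must have a header and must
#' provide, after applying `schema`, the columns `animal_id`, `group` and
#' `day`, plus either `volume` (mm^3) or both `length` and `width` (mm);
#' `body_weight` (g) is optional. Missing numeric cells are empty strings,
#' never sentinel numbers. Where `volume` is absent on a row but `length` and
#' `width` are present, the volume is filled in with [caliper_volume()].
#'
#' The parsed table is validated with [validate_measurements()]; any
#' violation is an error. Rows with unparsable numeric cells are reported
#' with their file line number.
#'
#' @param path Path to a delimited text file (comma-separated by default).
#' @param schema Optional named character vector mapping canonical column
#'   names to the names used in the file, e.g.
#'   `c(animal_id = "Mouse", day = "StudyDay")`. Canonical names:
#'   `animal_id`, `group`, `day`, `length`, `width`, `volume`, `body_weight`.
#' @param delim Field delimiter, default `","`.
#'
#' @return A tibble with columns `animal_id`, `group`, `day`, `length`,
#'   `width`, `volume`, `body_weight`, ordered by animal then day.
#' @seealso [validate_measurements()], [caliper_volume()]
#' @export
read_measurements <- function(path, schema = NULL, delim = ",") {
  if (!file.exists(path)) {
    abort(paste0("read_measurements(): file not found: ", path),
          class = "tumorgri_io_error")
  }
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_character()
  ), na = character(), trim_ws = TRUE)

  canonical <- c("animal_id", "group", "day", "length", "width", "volume",
                 "body_weight")
  if (!is.null(schema)) {
    bad <- setdiff(names(schema), canonical)
    if (length(bad) > 0) {
      abort(paste0("read_measurements(): unknown schema field(s): ",
                   paste(bad, collapse = ", ")),
            class = "tumorgri_schema_error")
    }
    missing_src <- setdiff(unname(schema), names(raw))
    if (length(missing_src) > 0) {
      abort(paste0("read_measurements(): schema maps to column(s) absent ",
                   "from the file: ", paste(missing_src, collapse = ", ")),
            class = "tumorgri_schema_error")
    }
    raw <- dplyr::rename(raw, !!!setNames(schema, names(schema)))
  }

  required <- c("animal_id", "group", "day")
  missing_req <- setdiff(required, names(raw))
  if (length(missing_req) > 0) {
    abort(paste0("read_measurements(): required column(s) missing: ",
                 paste(missing_req, collapse = ", ")),
          class = "tumorgri_schema_error")
  }
  if (!("volume" %in% names(raw)) &&
      !all(c("length", "width") %in% names(raw))) {
    abort(paste0("read_measurements(): need a volume column or both ",
                 "length and width columns."),
          class = "tumorgri_schema_error")
  }

  # header is line 1, so data row i sits on file line i + 1
  parse_num <- function(x, col) {
    x[x == ""] <- NA_character_
    out <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(out))
    if (length(bad) > 0) {
      abort(paste0(
        "read_measurements(): unparsable numeric value(s) in column '", col,
        "' at file line(s) ", paste(bad + 1, collapse = ", "), ": ",
        paste(unique(x[head(bad, 5)]), collapse = ", ")
      ), class = "tumorgri_parse_error")
    }
    out
  }

  tbl <- tibble(
    animal_id = as.character(raw$animal_id),
    group = as.character(raw$group),
    day = parse_num(raw$day, "day"),
    length = if ("length" %in% names(raw)) parse_num(raw$length, "length") else NA_real_,
    width = if ("width" %in% names(raw)) parse_num(raw$width, "width") else NA_real_,
    volume = if ("volume" %in% names(raw)) parse_num(raw$volume, "volume") else NA_real_,
    body_weight = if ("body_weight" %in% names(raw)) {
      parse_num(raw$body_weight, "body_weight")
    } else {
      NA_real_
    }
  )
  as_measurement_table(tbl)
}

#' Coerce and validate an in-memory measurement table
#'
#' Fills volumes from caliper length/width where absent, orders rows by
#' animal and day, and errors on any invariant violation found by
#' [validate_measurements()].
#'
#' @param data A data frame with at least `animal_id`, `group`, `day`, and
#'   `volume` or `length` + `width`.
#' @return A validated tibble ordered by `animal_id`, `day`.
#' @export
as_measurement_table <- function(data) {
  tbl <- as_tibble(data)
  for (col in c("length", "width", "volume", "body_weight")) {
    if (!(col %in% names(tbl))) tbl[[col]] <- NA_real_
  }
  tbl <- dplyr::mutate(
    tbl,
    animal_id = as.character(.data$animal_id),
    group = as.character(.data$group),
    volume = dplyr::if_else(
      is.na(.data$volume) & !is.na(.data$length) & !is.na(.data$width),
      caliper_volume(.data$length, .data$width),
      .data$volume
    )
  )
  tbl <- dplyr::arrange(tbl, .data$animal_id, .data$day)
  tbl <- dplyr::select(tbl, "animal_id", "group", "day", "length", "width",
                       "volume", "body_weight")
  issues <- validate_measurements(tbl)
  if (nrow(issues) > 0) {
    abort(paste0(
      "Measurement table failed validation (", nrow(issues), " issue(s)):\n",
      paste(utils::head(issues$message, 10), collapse = "\n")
    ), class = "tumorgri_validation_error")
  }
  tbl
}

#' Check measurement-table invariants
#'
#' Reports (never errors) every violation of the measurement-table
#' invariants: each row must resolve a nonnegative volume; study days must be
#' nonnegative and unique within an animal; each animal must belong to
#' exactly one arm. A recorded volume of exactly 0 is legal and means "no
#' palpable tumor".
#'
#' @param data A measurement data frame (see [as_measurement_table()]).
#' @return A tibble with columns `rule`, `animal_id`, `day`, `message`;
#'   zero rows iff the table satisfies all invariants.
#' @export
validate_measurements <- function(data) {
  tbl <- as_tibble(data)
  issues <- list()
  add <- function(rule, animal_id, day, message) {
    tibble(rule = rule, animal_id = as.character(animal_id),
           day = as.numeric(day), message = message)
  }

  miss <- tbl[is.na(tbl$volume), ]
  if (nrow(miss) > 0) {
    issues <- c(issues, list(add(
      "missing_volume", miss$animal_id, miss$day,
      paste0("animal ", miss$animal_id, " day ", miss$day,
             ": no volume and no length/width to derive one")
    )))
  }
  neg <- tbl[!is.na(tbl$volume) & tbl$volume < 0, ]
  if (nrow(neg) > 0) {
    issues <- c(issues, list(add(
      "negative_volume", neg$animal_id, neg$day,
      paste0("animal ", neg$animal_id, " day ", neg$day,
             ": negative volume ", neg$volume)
    )))
  }
  negd <- tbl[is.na(tbl$day) | tbl$day < 0, ]
  if (nrow(negd) > 0) {
    issues <- c(issues, list(add(
      "invalid_day", negd$animal_id, negd$day,
      paste0("animal ", negd$animal_id,
             ": day must be a nonnegative number, got ", negd$day)
    )))
  }
  dup <- tbl %>%
    dplyr::filter(!is.na(.data$day)) %>%
    dplyr::count(.data$animal_id, .data$day) %>%
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    issues <- c(issues, list(add(
      "duplicate_day", dup$animal_id, dup$day,
      paste0("animal ", dup$animal_id, " day ", dup$day, ": ",
             dup$n, " rows for the same animal-day")
    )))
  }
  multi <- tbl %>%
    dplyr::distinct(.data$animal_id, .data$group) %>%
    dplyr::count(.data$animal_id) %>%
    dplyr::filter(.data$n > 1)
  if (nrow(multi) > 0) {
    issues <- c(issues, list(add(
      "multiple_arms", multi$animal_id, NA,
      paste0("animal ", multi$animal_id, " appears in ", multi$n,
             " different arms")
    )))
  }
  if (length(issues) == 0) {
    return(tibble(rule = character(), animal_id = character(),
                  day = numeric(), message = character()))
  }
  dplyr::bind_rows(issues)
}
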