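# small in-code fixtures shared across test files

# well-formed two-animal table over three days
fixture_table <- function() {
  tibble::tibble(
    animal_id = rep(c("m1", "m2"), each = 3),
    group = rep(c("vehicle", "treated"), each = 3),
    day = rep(c(0, 3, 7), 2),
    length = NA_real_,
    width = NA_real_,
    volume = c(30, 60, 150, 30, 40, 55),
    body_weight = c(20, 20.5, 21, 20, 19.5, 19.8)
  )
}

write_fixture_csv <- function(tbl, path = withr::local_tempfile(
                                fileext = ".csv",
                                .local_envir = parent.frame())) {
  readr::write_csv(tbl, path, na = "")
  path
}

# exact exponential series for one animal
exp_series <- function(id, group, days, v0, rate) {
  tibble::tibble(animal_id = id, group = group, day = days,
                 volume = v0 * exp(rate * days))
}

# per-animal fits tibble straight from rate vectors
fits_from_rates <- function(...) {
  rates <- list(...)
  dplyr::bind_rows(lapply(names(rates), function(g) {
    tibble::tibble(
      animal_id = paste0(g, "-", seq_along(rates[[g]])),
      group = g, rate = rates[[g]]
    )
  }))
}
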