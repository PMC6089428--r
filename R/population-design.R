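#' Describe a temporally sampled population
#'
#' A population design bundles what the Wright-Fisher test needs to know about
#' one population: its (diploid) effective size `Ne` and the ordered sampling
#' events, each with the calendar year(s) of collection and the number of
#' diploid individuals sampled. Generation offsets are derived from the years:
#' the first event sits at offset 0 and each later event at
#' `floor((year - year0) / generation_time)` complete generations, using the
#' earliest calendar year when an event pools collections from several years.
#'
#' @param name Population label.
#' @param Ne Effective population size in diploid individuals (integer >= 2).
#' @param years Collection years, one element per sampling event. An event that
#'   pools several collection years is given as a vector inside a list, e.g.
#'   `list(1999, c(2012, 2013))`.
#' @param n_diploid Integer vector, diploid individuals per event (all >= 1).
#' @param generation_time Years per generation; default 2.
#'
#' @return An object of class `population_design`: a list with `name`, `Ne`,
#'   `generation_time` and an `events` tibble (`event`, `year_label`, `years`
#'   list-column, `n_diploid`, `gen_offset`).
#'
#' @examples
#' # Two samples 13 calendar years apart: 6 complete generations at 2 y/gen
#' fn <- population_design("FN", Ne = 34, years = list(1999, c(2012, 2013)),
#'                         n_diploid = c(29, 20))
#' fn$events$gen_offset
#' @export
population_design <- function(name, Ne, years, n_diploid, generation_time = 2) {
  if (!is.numeric(Ne) || length(Ne) != 1L || Ne < 2 || Ne != round(Ne)) {
    abort("`Ne` must be a single integer >= 2.")
  }
  if (!is.list(years)) years <- as.list(years)
  n_events <- length(years)
  if (n_events < 1L) abort("`years` must contain at least one sampling event.")
  if (length(n_diploid) != n_events) {
    abort("`n_diploid` must have one entry per sampling event.")
  }
  if (any(n_diploid < 1) || any(n_diploid != round(n_diploid))) {
    abort("all sample sizes must be integers >= 1.")
  }
  first_year <- vapply(years, min, numeric(1))
  gen_offset <- floor((first_year - first_year[1]) / generation_time)
  if (any(diff(gen_offset) <= 0)) {
    abort("sampling events must be strictly increasing in generation offset; pool same-generation collections into one event.")
  }
  events <- tibble(
    event = seq_len(n_events),
    year_label = vapply(years, function(y) paste(y, collapse = "-"), character(1)),
    years = years,
    n_diploid = as.integer(n_diploid),
    gen_offset = as.integer(gen_offset)
  )
  structure(
    list(name = name, Ne = as.integer(Ne),
         generation_time = generation_time, events = events),
    class = "population_design"
  )
}

#' @export
print.population_design <- function(x, ...) {
  cat("<population_design> ", x$name,
      "  (Ne = ", x$Ne, ", generation time = ", x$generation_time, " y)\n",
      sep = "")
  print(x$events[c("event", "year_label", "n_diploid", "gen_offset")])
  invisible(x)
}

#' Study designs of the three Tasmanian devil populations
#'
#' The three genomic time-series used in the devil DFTD selection scan:
#' Freycinet (FN, Ne = 34, samples of 29 and 20 diploids spanning 6
#' generations), Narawntapu (NP, Ne = 37, three samples of 26/26/27 spanning 5
#' generations) and West Pencil Pine (WP, Ne = 26, samples of 21 and 43
#' spanning 3 generations), at a generation time of 2 years.
#'
#' @return Named list of three [population_design] objects (`FN`, `NP`, `WP`).
#' @examples
#' devil_designs()$NP
#' @export
devil_designs <- function() {
  list(
    FN = population_design("FN", Ne = 34,
                           years = list(1999, c(2012, 2013)),
                           n_diploid = c(29, 20)),
    NP = population_design("NP", Ne = 37,
                           years = list(1999, 2004, 2009),
                           n_diploid = c(26, 26, 27)),
    WP = population_design("WP", Ne = 26,
                           years = list(2006, c(2013, 2014)),
                           n_diploid = c(21, 43))
  )
}
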