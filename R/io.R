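# Cohort CSV io: header x1,x2,y plus a JSON metadata sidecar.

#' Write a cohort to CSV with a metadata sidecar
#'
#' The CSV has columns `x1,x2,y`, one row per individual. A sidecar JSON at
#' `<path>.meta.json` records the population id, the seed and the realized
#' prevalence.
#'
#' @param cohort A `cohort`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort"))
  utils::write.csv(
    data.frame(x1 = cohort$x[, 1], x2 = cohort$x[, 2], y = cohort$y),
    path, row.names = FALSE)
  jsonlite::write_json(
    list(population_id = cohort$population_id, seed = cohort$seed,
         realized_prevalence = cohort$prevalence),
    paste0(path, ".meta.json"), auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Read a cohort written by [write_cohort_csv()]
#'
#' @param path CSV path; the `<path>.meta.json` sidecar is read when present
#'   (otherwise the population id is taken from the file name and the seed
#'   recorded as NA).
#' @return A `cohort`.
#' @export
read_cohort_csv <- function(path) {
  tab <- utils::read.csv(path)
  stopifnot(all(c("x1", "x2", "y") %in% names(tab)))
  meta_path <- paste0(path, ".meta.json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    pid <- meta$population_id
    seed <- meta$seed
  } else {
    pid <- sub("\\.csv$", "", basename(path))
    seed <- NA_integer_
  }
  new_cohort(pid, cbind(x1 = tab$x1, x2 = tab$x2), tab$y, seed)
}
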