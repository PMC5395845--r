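# Simulated cohorts: two predictor columns and a binary outcome per subject.

new_cohort <- function(population_id, x, y, seed) {
  stopifnot(is.matrix(x), ncol(x) == 2L, length(y) == nrow(x))
  if (!all(y %in% c(0L, 1L))) stop("outcomes must be 0/1", call. = FALSE)
  colnames(x) <- c("x1", "x2")
  structure(
    list(population_id = population_id, x = x, y = as.integer(y),
         seed = as.integer(seed), prevalence = mean(y)),
    class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf(
    "Cohort '%s': %d individuals, %d cases (realized prevalence %.4f), seed %d\n",
    x$population_id, length(x$y), sum(x$y), x$prevalence, x$seed))
  invisible(x)
}

#' Number of individuals in a cohort
#'
#' @param cohort A `cohort` object.
#' @return Integer cohort size.
#' @export
cohort_size <- function(cohort) length(cohort$y)

# Accepts a cohort or a bare n x 2 matrix and returns the predictor matrix.
predictor_matrix <- function(x) {
  if (inherits(x, "cohort")) return(x$x)
  if (is.data.frame(x)) x <- as.matrix(x)
  stopifnot(is.matrix(x), ncol(x) == 2L, is.numeric(x))
  x
}

check_two_classes <- function(y, what = "cohort") {
  if (sum(y == 1L) == 0L || sum(y == 0L) == 0L) {
    stop(sprintf("%s must contain both cases and controls", what),
         call. = FALSE)
  }
  invisible(TRUE)
}
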