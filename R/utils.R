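#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the random number generator seeded at `seed`, then restores
#' the caller's RNG state so that library-internal randomness never perturbs a
#' user's stream. All randomised operations in the package funnel through this.
#'
#' @param seed single integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# stop() with sprintf formatting and no call in the condition
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Significance stars for a p-value
#'
#' Maps p-values to the conventional star annotation: `***` for p < 0.001,
#' `**` for p < 0.01, `*` for p < 0.05, empty otherwise. `NA` maps to `NA`.
#'
#' @param p numeric vector of p-values.
#' @return character vector of stars.
#' @examples
#' p_stars(c(0.2, 0.03, 0.004, 2e-5))
#' @export
p_stars <- function(p) {
  out <- ifelse(is.na(p), NA_character_,
         ifelse(p < 0.001, "***",
         ifelse(p < 0.01, "**",
         ifelse(p < 0.05, "*", ""))))
  out
}
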