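#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; the printed comparison-table
#' convention in this package is half away from zero (so 1.75 -> 1.8 and
#' 49.55 -> 49.6, at 1 decimal). Used everywhere a ratio, percent or
#' predicted time is reported at a fixed precision.
#'
#' @param x Numeric vector.
#' @param digits Integer, number of decimal places (default 0).
#' @return Numeric vector rounded half away from zero.
#' @examples
#' round_half_up(c(1.75, -1.75, 2.5), 1)
#' round_half_up(101.1948)
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  # nudge by a few ulps so values that are exactly .5 before binary
  # representation error do not fall on the wrong side
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# shared id sanity check: opaque, non-empty, no whitespace
check_concept_ids <- function(ids, what = "concept_id") {
  bad <- is.na(ids) | !nzchar(ids) | grepl("\\s", ids)
  if (any(bad)) {
    abort(
      sprintf(
        "%s values must be non-empty strings without whitespace (%d offending)",
        what, sum(bad)
      ),
      class = "phenovset_invalid_id"
    )
  }
  invisible(ids)
}

# run code with a temporary RNG state seeded from `seed`, restoring
# the caller's .Random.seed afterwards (generators stay pure functions
# of their seed without clobbering the session stream)
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}
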