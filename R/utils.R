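#' Round half away from zero
#'
#' Rounds to `digits` decimals with halves going up (0.05 -> 0.1), the
#' convention used for displayed percentages throughout the resource's
#' evaluation tables.  Base R's `round()` rounds halves to even, which would
#' turn e.g. 71.25 into 71.2.
#'
#' @param x numeric vector
#' @param digits number of decimal places
#' @return rounded numeric vector
#' @export
#' @examples
#' round_half_up(0.15, 1)   # 0.2
#' round_half_up(71.25, 1)  # 71.3
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Run code with a temporarily seeded RNG, restoring prior state afterwards.
# Keeps generator functions deterministic without clobbering the caller's RNG.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Trim leading/trailing whitespace and collapse internal runs to one space.
normalize_whitespace <- function(x) {
  gsub("[[:space:]]+", " ", trimws(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Build a zero-row or n-row character data.frame with the given columns.
chr_frame <- function(cols, n = 0L) {
  out <- as.data.frame(
    stats::setNames(replicate(length(cols), character(n), simplify = FALSE), cols),
    stringsAsFactors = FALSE
  )
  out
}

stopifnot_scalar_chr <- function(x, name) {
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("`%s` must be a single string", name), call. = FALSE)
  }
}
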