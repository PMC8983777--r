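#' Run code with a temporary RNG seed
#'
#' Evaluates `expr` with the RNG seeded at `seed`, then restores the caller's
#' RNG state, so seeded helpers do not perturb an enclosing simulation.
#'
#' @param seed Integer seed, or `NULL` to leave the RNG stream untouched.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a per-stage RNG seed from a global seed
#'
#' Stage streams are decoupled by offsetting the global seed with a small
#' integer hash of the stage name: `(seed + 7919 * (sum of UTF-8 codes of
#' `stage`))  mod  (2^31 - 1)`. The derivation is deterministic and keeps the
#' result inside the 32-bit integer range.
#'
#' @param seed Global integer seed.
#' @param stage Character stage name, e.g. `"synthetic"`.
#' @return An integer seed.
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- sum(utf8ToInt(stage))
  as.integer((as.numeric(seed) + 7919 * h) %% (2^31 - 1))
}

# circular difference wrapped to (-180, 180]
wrap_angle <- function(x) {
  y <- (x + 180) %% 360 - 180
  y[y == -180] <- 180
  y
}

# map a direction label to the target-motion angle in degrees
direction_angle <- function(direction) {
  if (is.numeric(direction)) return(direction)
  ang <- c(right = 0, left = 180)[as.character(direction)]
  if (anyNA(ang)) stop("unknown direction label; use 'right', 'left' or an angle in degrees")
  unname(ang)
}
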