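#' Wrap angles to (-pi, pi]
#'
#' @param x numeric vector/matrix of angles in radians.
#' @return object of the same shape with every value wrapped to (-pi, pi].
#' @export
wrap_pi <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  # %% maps exact pi to -pi; restore the half-open convention (-pi, pi]
  y[y == -pi] <- pi
  y
}

#' Wrap orientation angles (degrees) to [-90, 90)
#' @param x numeric, degrees.
#' @return wrapped degrees in [-90, 90).
#' @export
wrap_axis_deg <- function(x) ((x + 90) %% 180) - 90

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Circular mean of angles
#'
#' Mean direction of a set of angles; used on doubled angles when the
#' underlying quantity is degenerate modulo pi (retardation folds, optic
#' axes).
#'
#' @param x angles in radians (vector).
#' @param w optional non-negative weights.
#' @return mean angle in (-pi, pi].
#' @export
circ_mean <- function(x, w = NULL) {
  if (is.null(w)) w <- rep(1, length(x))
  atan2(sum(w * sin(x)), sum(w * cos(x)))
}

# Row-wise circular mean across a list of matrices of identical shape,
# returning atan2(sum sin, sum cos) elementwise.
circ_mean_mats <- function(mats) {
  s <- 0; c <- 0
  for (m in mats) { s <- s + sin(m); c <- c + cos(m) }
  atan2(s, c)
}

# seeded RNG scope helper: run expr with a local seed, restoring RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_field <- function(field, msg) {
  stop(sprintf("[%s] %s", field, msg), call. = FALSE)
}
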