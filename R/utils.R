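# Internal helpers shared across modules.

#' Wrap an angle to the half-open interval (-pi, pi]
#'
#' @param x numeric vector of angles in radians.
#' @return angles mapped into (-pi, pi].
#' @keywords internal
wrap_angle <- function(x) {
  w <- atan2(sin(x), cos(x))
  # atan2 may return -pi for arguments numerically on the branch cut
  w[w <= -pi + 1e-12] <- w[w <= -pi + 1e-12] + 2 * pi
  w
}

# Smallest absolute angular difference between two angles.
circ_dist <- function(a, b) {
  d <- wrap_angle(a - b)
  abs(d)
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(expr)
}

stop_validation <- function(...) {
  stop(errorCondition(paste0(...), class = c("ssvephase_validation_error", "error")))
}

stop_io <- function(...) {
  stop(errorCondition(paste0(...), class = c("ssvephase_io_error", "error")))
}

stop_degenerate <- function(...) {
  stop(errorCondition(paste0(...), class = c("ssvephase_degenerate_error", "error")))
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}
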