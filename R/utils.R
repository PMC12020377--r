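#' @keywords internal
"_PACKAGE"

## Run code with a temporary RNG state so generators are pure in their seed.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

#' Round half away from zero
#'
#' Decimal rounding with ties going away from zero, the convention used when
#' free energies and populations are reported to one decimal place.
#' `base::round()` rounds half to even, which would disagree on exact ties.
#'
#' @param x numeric vector.
#' @param digits number of decimal digits (default 1).
#' @return rounded numeric vector.
#' @examples
#' round_half_up(0.25, 1)   # 0.3
#' round_half_up(-0.25, 1)  # -0.3
#' @export
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

## Rotation matrix for angle `theta` (radians) about unit axis `u` (Rodrigues).
rotation_matrix <- function(u, theta) {
  u <- u / sqrt(sum(u^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

## Normalize angles in degrees onto (-180, 180].
normalize_angle <- function(theta) {
  out <- theta %% 360
  out[out > 180] <- out[out > 180] - 360
  out
}

## Any unit vector orthogonal to v.
perp_vector <- function(v) {
  v <- v / sqrt(sum(v^2))
  ref <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  w <- ref - sum(ref * v) * v
  w / sqrt(sum(w^2))
}
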