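# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' Derive a substream seed from a master seed and a stage tag
#'
#' One run seed drives all stochastic stages through independent derived
#' streams; no stage reads global RNG state. The same (seed, stage) pair
#' always yields the same substream seed (a 31-bit integer).
#'
#' @param seed master seed (integer).
#' @param stage character tag of the consuming stage.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(as.character(stage)) * seq_along(utf8ToInt(as.character(stage))))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483647)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

vec_norm <- function(v) sqrt(sum(v^2))

unit <- function(v) {
  n <- vec_norm(v)
  if (n == 0) stop("cannot normalise a zero vector")
  v / n
}

# Angle between two vectors, degrees.
angle_deg <- function(a, b) {
  ca <- sum(unit(a) * unit(b))
  acos(clamp(ca, -1, 1)) * 180 / pi
}

# Any unit vector orthogonal to v.
orthogonal_unit <- function(v) {
  v <- unit(v)
  ref <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  unit(pracma_cross(v, ref))
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Rotate vector v by `deg` degrees about unit axis k (Rodrigues).
rotate_about <- function(v, k, deg) {
  k <- unit(k)
  th <- deg * pi / 180
  v * cos(th) + pracma_cross(k, v) * sin(th) + k * sum(k * v) * (1 - cos(th))
}

# Running mean with edge-shrinking window (odd w).
running_mean <- function(x, w) {
  n <- length(x)
  if (n == 0 || w <= 1) return(x)
  r <- w %/% 2
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - r, 1)
  hi <- pmin(seq_len(n) + r, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
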