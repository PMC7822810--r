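# Internal helpers: seeding, small vector geometry.

#' Derive a child seed from a master seed
#'
#' All randomness in corpus construction flows from one master seed; children
#' (one per model, per draw site) are produced by a fixed multiplicative rule
#' so any model can be regenerated in isolation.
#'
#' @param master Integer master seed.
#' @param index Non-negative integer stream index.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, index) {
  m <- 2147483647 # 2^31 - 1, Mersenne prime; products stay exact in doubles
  s <- ((master %% m) * 48271 + (index %% m) * 16807 + 1) %% m
  as.integer(s + (s == 0))
}

# Evaluate `expr` under `seed` without disturbing the caller's RNG stream.
local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

vnorm <- function(v) sqrt(sum(v^2))

unit <- function(v) {
  n <- vnorm(v)
  if (n == 0) abort("cannot normalize a zero vector")
  v / n
}

# Deterministic orthonormal basis of the plane normal to unit vector d.
perp_basis <- function(d) {
  ref <- if (abs(d[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- unit(ref - sum(ref * d) * d)
  e2 <- c(
    d[2] * e1[3] - d[3] * e1[2],
    d[3] * e1[1] - d[1] * e1[3],
    d[1] * e1[2] - d[2] * e1[1]
  )
  list(e1 = e1, e2 = e2)
}

# Rodrigues rotation of v about unit axis k by angle (radians).
rotate_about <- function(v, k, angle) {
  k <- unit(k)
  kxv <- c(
    k[2] * v[3] - k[3] * v[2],
    k[3] * v[1] - k[1] * v[3],
    k[1] * v[2] - k[2] * v[1]
  )
  v * cos(angle) + kxv * sin(angle) + k * sum(k * v) * (1 - cos(angle))
}

row_norms <- function(m) {
  if (is.null(dim(m))) abs(m) else sqrt(rowSums(m^2))
}

as_coord_matrix <- function(x, what = "coordinates") {
  if (is.data.frame(x)) {
    if (!all(c("x", "y", "z") %in% names(x))) {
      abort(sprintf("%s must have columns x, y, z", what))
    }
    m <- cbind(x$x, x$y, x$z)
  } else {
    m <- as.matrix(x)
  }
  if (ncol(m) != 3 || !is.numeric(m)) abort(sprintf("%s must be N x 3 numeric", what))
  if (!all(is.finite(m))) abort(sprintf("%s must be finite", what))
  unname(m)
}
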