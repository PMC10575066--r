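# Internal helpers shared across modules.

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards.  A NULL seed leaves the global stream alone.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed from a base seed and a stream label, staying inside
# the 32-bit integer range set.seed() accepts.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + 1000003 * as.numeric(offset)) %% 2147483647L)
}

is_count <- function(x, min = 0) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x >= min && x == round(x)
}

stop_input <- function(...) stop(..., call. = FALSE)

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# Separable Gaussian blur of a matrix with edge replication.  sigma = 0 is
# the identity.  Used by the scene generator (soil mottling) and by the
# pixel-level augmentations.
gauss_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  H <- nrow(m); W <- ncol(m)
  out <- matrix(0, H, W)
  for (t in -r:r) {          # along rows
    idx <- pmin(pmax(seq_len(H) + t, 1L), H)
    out <- out + k[t + r + 1L] * m[idx, , drop = FALSE]
  }
  m2 <- matrix(0, H, W)
  for (t in -r:r) {          # along columns
    idx <- pmin(pmax(seq_len(W) + t, 1L), W)
    m2 <- m2 + k[t + r + 1L] * out[, idx, drop = FALSE]
  }
  m2
}
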