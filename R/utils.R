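#' @keywords internal
"_PACKAGE"

# Run `expr` under a local RNG stream seeded with `seed`, restoring the global
# .Random.seed afterwards so package functions never disturb user RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

# Derive a child seed from a parent seed and a stream index, staying inside
# the 32-bit signed integer range R requires for set.seed().
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(stream) * 104729) %% 2147483629)
}

# Slice a 3D array along one axis with an index vector, keeping dimensions.
index_axis <- function(a, axis, idx) {
  switch(axis,
    a[idx, , , drop = FALSE],
    a[, idx, , drop = FALSE],
    a[, , idx, drop = FALSE]
  )
}

# Separable 1D convolution of a 3D array along `axis` with taps `h`, whose
# origin is at position `center`; boundaries handled by edge replication so
# constant inputs are mapped exactly.
axis_convolve <- function(a, h, axis, center) {
  n <- dim(a)[axis]
  out <- array(0, dim(a))
  base <- seq_len(n)
  for (k in seq_along(h)) {
    if (h[k] == 0) next
    idx <- base + (k - center)
    idx[idx < 1L] <- 1L
    idx[idx > n] <- n
    out <- out + h[k] * index_axis(a, axis, idx)
  }
  out
}

# Gaussian smoothing of a 3D array; sigma given per axis in voxels.
gaussian_smooth <- function(a, sigma_vox) {
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    x <- (-r):r
    k <- exp(-x^2 / (2 * s^2))
    k <- k / sum(k)
    a <- axis_convolve(a, k, ax, r + 1L)
  }
  a
}

stopifnot_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("`%s` must be a single positive finite number", name), call. = FALSE)
  }
  invisible(x)
}
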