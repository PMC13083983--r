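# Shared tiny fixtures, built in code at test time.

tiny_case <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_case(phantom_spec(), label = 1, site_id = 1, seed = 42)
    }
    cache
  }
})

dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# Solid metric ball on an isotropic-or-not grid (1-based centre voxel).
test_ball <- function(dims, spacing, centre, r) {
  dx2 <- ((seq_len(dims[1]) - centre[1]) * spacing[1])^2
  dy2 <- ((seq_len(dims[2]) - centre[2]) * spacing[2])^2
  dz2 <- ((seq_len(dims[3]) - centre[3]) * spacing[3])^2
  array(outer(outer(dx2, dy2, "+"), dz2, "+") <= r^2, dims)
}

# Menger-sponge approximation: `iter` subdivision rounds on a 3^iter cube.
menger_sponge <- function(iter = 3L) {
  n <- 3^iter
  keep_digit <- function(idx) {
    # TRUE unless, at any scale, >= 2 of the 3 coordinates hit the middle third
    m <- matrix(TRUE, length(idx), 1)
    idx
  }
  coords <- as.matrix(expand.grid(x = 0:(n - 1), y = 0:(n - 1), z = 0:(n - 1)))
  keep <- rep(TRUE, nrow(coords))
  for (k in seq_len(iter)) {
    digit <- (coords %/% 3^(k - 1)) %% 3
    keep <- keep & rowSums(digit == 1) < 2
  }
  a <- array(FALSE, c(n, n, n))
  a[coords[keep, , drop = FALSE] + 1] <- TRUE
  a
}
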