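# Shared fixtures and independent brute-force oracles. Everything is
# generated in code; no binary data.

# A small, fast phantom case. Noise/blur switchable so exactness tests can
# use the clean limit.
tinyCase <- function(type = "osteoblastic", seed = 7L, shape = c(48, 48, 32),
                     noiseless = FALSE, breach = FALSE, id = "tiny") {
  les <- lesionSpec(type, center = round(shape / 2) + c(0, 0, -2),
                    radiusMm = 6, corticalBreach = breach)
  spec <- phantomSpec(shape = shape, lesions = list(les),
                      boneOuterRadiusMm = 12, corticalThicknessMm = 3,
                      ctNoise = !noiseless,
                      ctBlurSigmaMm = if (noiseless) 0 else 0.8,
                      mrBlurSigmaMm = if (noiseless) 0 else 0.8,
                      trabecularTexture = if (noiseless) 0 else 0.7,
                      seed = seed)
  acq <- acquisitionParams(noiseSd = if (noiseless) 0 else 0.02)
  simulateCase(spec, id, acq)
}

# Smooth Gaussian blob on an isotropic grid; amplitude 1.
gaussBlob <- function(n = 32, sigma = 5, center = (n + 1) / 2) {
  g <- (seq_len(n) - center)^2
  blob <- exp(-outer(outer(g, g, "+"), g, "+") / (2 * sigma^2))
  array(blob, c(n, n, n))
}

# Brute-force directed surface RMSD: all-pairs nearest distances between
# boundary voxel centers (6-connectivity, out-of-volume counts as outside).
bfBoundary <- function(mask) {
  d <- dim(mask)
  at <- function(i, j, k) {
    if (i < 1 || i > d[1] || j < 1 || j > d[2] || k < 1 || k > d[3])
      return(FALSE)
    mask[i, j, k]
  }
  idx <- which(mask, arr.ind = TRUE)
  keep <- apply(idx, 1, function(v) {
    i <- v[1]; j <- v[2]; k <- v[3]
    !(at(i - 1, j, k) && at(i + 1, j, k) && at(i, j - 1, k) &&
        at(i, j + 1, k) && at(i, j, k - 1) && at(i, j, k + 1))
  })
  idx[keep, , drop = FALSE]
}

bfSurfaceRMSD <- function(a, b, spacing) {
  pa <- sweep(bfBoundary(a) - 1, 2, spacing, "*")
  pb <- sweep(bfBoundary(b) - 1, 2, spacing, "*")
  d2 <- vapply(seq_len(nrow(pa)), function(i)
    min(colSums((t(pb) - pa[i, ])^2)), numeric(1))
  sqrt(mean(d2))
}

# Brute-force physical-space dilation by distance enumeration.
bfDilate <- function(mask, margin, spacing) {
  d <- dim(mask)
  src <- sweep(which(mask, arr.ind = TRUE) - 1, 2, spacing, "*")
  out <- array(FALSE, d)
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    p <- (c(i, j, k) - 1) * spacing
    if (min(colSums((t(src) - p)^2)) <= margin^2 + 1e-12)
      out[i, j, k] <- TRUE
  }
  out
}

# Random small mask with at least one voxel.
randomMask <- function(dims, pOn = 0.2) {
  m <- array(runif(prod(dims)) < pOn, dims)
  if (!any(m)) m[ceiling(dims[1] / 2), 1, 1] <- TRUE
  m
}

# Desk-scale network/training configs used across model tests.
deskNet <- function() networkConfig(baseFilters = 8L)
tinyNet <- function() networkConfig(baseFilters = 2L, levels = 2L,
                                    patchSize = 8L)
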