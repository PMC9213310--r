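# 3D patch-based UNet-like regression network, written directly on the
# package's GEMM convolution kernels: an encoder-decoder with skip
# connections, two input channels (the two MR echoes), one linear output
# channel on the normalized CT scale. Blocks are conv(3^3)+ReLU pairs;
# down by 2^3 max pooling, up by 2^3 transposed convolution. The backward
# pass is hand-derived and verified against finite differences in the test
# suite.

#' Network architecture configuration
#'
#' @param inChannels input channels; 2 (the two MR echoes) by design.
#' @param outChannels output channels; 1 (normalized CT).
#' @param levels resolution levels (default 3: two poolings).
#' @param baseFilters filters at the top level; doubled per level.
#'   32 is the full-size default; 8 is the desk-scale setting used for CPU
#'   experiments.
#' @param patchSize cubic patch edge in voxels; must be divisible by
#'   `2^(levels - 1)`.
#' @return Named list of class `"networkConfig"`.
#' @export
networkConfig <- function(inChannels = 2L, outChannels = 1L, levels = 3L,
                          baseFilters = 32L, patchSize = 24L) {
  stopifnot(inChannels >= 1, outChannels == 1L, levels >= 2, baseFilters >= 1)
  if (patchSize %% 2^(levels - 1) != 0)
    stop(sprintf("patchSize %d not divisible by 2^(levels-1) = %d",
                 patchSize, 2^(levels - 1)))
  structure(list(inChannels = as.integer(inChannels),
                 outChannels = as.integer(outChannels),
                 levels = as.integer(levels),
                 baseFilters = as.integer(baseFilters),
                 patchSize = as.integer(patchSize)),
            class = "networkConfig")
}

convLayer <- function(cin, cout, gain = 2) {
  list(w = matrix(rnorm(27 * cin * cout, sd = sqrt(gain / (27 * cin))),
                  27 * cin, cout),
       b = numeric(cout))
}
upLayer <- function(cin, cout) {
  # transposed conv, kernel 2 stride 2: fan-in per output voxel is cin
  list(w = matrix(rnorm(8 * cin * cout, sd = sqrt(2 / cin)), 8 * cin, cout),
       b = numeric(cout))
}

#' Build (initialize) a network
#'
#' He-style Gaussian initialization, fully seeded. The nominal receptive
#' field of the default 3-level architecture (~57 voxels across) exceeds
#' the 24-voxel patch, so in practice the patch footprint is what caps the
#' context any output voxel sees -- the locality that keeps a patch-based
#' model generalizable from few subjects.
#'
#' @param cfg a [networkConfig()].
#' @param seed integer seed for the weight draw.
#' @return A [TrainedModel-class] with empty training history (an
#'   "untrained model" usable as a baseline).
#' @export
buildNetwork <- function(cfg = networkConfig(), seed = 1L) {
  stopifnot(inherits(cfg, "networkConfig"))
  L <- cfg$levels
  f <- cfg$baseFilters * 2^(seq_len(L) - 1)
  weights <- withSeed(seed, {
    enc <- vector("list", L)
    for (l in seq_len(L)) {
      cin <- if (l == 1) cfg$inChannels else f[l - 1]
      enc[[l]] <- list(a = convLayer(cin, f[l]), b = convLayer(f[l], f[l]))
    }
    up <- vector("list", L - 1)
    dec <- vector("list", L - 1)
    for (l in seq_len(L - 1)) {
      up[[l]] <- upLayer(f[l + 1], f[l])
      dec[[l]] <- list(a = convLayer(2 * f[l], f[l]),
                       b = convLayer(f[l], f[l]))
    }
    head <- list(w = matrix(rnorm(f[1], sd = sqrt(1 / f[1])), f[1], 1),
                 b = 0)
    list(enc = enc, up = up, dec = dec, head = head)
  })
  new("TrainedModel", weights = weights, netConfig = unclass(cfg),
      trainConfig = list(), normMeta = list(huMin = .CT_HU_MIN,
                                            huMax = .CT_HU_MAX,
                                            mrPercentile = 95),
      history = data.frame())
}

#' Number of trainable parameters
#' @param model a [TrainedModel-class].
#' @return Integer parameter count.
#' @export
parameterCount <- function(model) {
  sum(unlist(rapply(model@weights, length, how = "unlist")))
}

relu <- function(x) pmax(x, 0)

upconvForward <- function(x, layer) {
  d <- dim(x)
  cin <- d[4]; cout <- ncol(layer$w)
  N <- prod(d[1:3])
  xm <- matrix(x, N, cin)
  y <- array(0, c(2 * d[1], 2 * d[2], 2 * d[3], cout))
  for (o in 0:7) {
    di <- o %% 2; dj <- (o %/% 2) %% 2; dk <- o %/% 4
    wo <- layer$w[o + 1 + 8 * (seq_len(cin) - 1), , drop = FALSE]
    y[seq(1, 2 * d[1], 2) + di, seq(1, 2 * d[2], 2) + dj,
      seq(1, 2 * d[3], 2) + dk, ] <- array(xm %*% wo, c(d[1:3], cout))
  }
  sweep(y, 4, layer$b, "+")
}

upconvBackward <- function(x, layer, gy) {
  d <- dim(x)
  cin <- d[4]; cout <- ncol(layer$w)
  N <- prod(d[1:3])
  xm <- matrix(x, N, cin)
  gw <- matrix(0, 8 * cin, cout)
  gxm <- matrix(0, N, cin)
  for (o in 0:7) {
    di <- o %% 2; dj <- (o %/% 2) %% 2; dk <- o %/% 4
    rows <- o + 1 + 8 * (seq_len(cin) - 1)
    gyo <- matrix(gy[seq(1, 2 * d[1], 2) + di, seq(1, 2 * d[2], 2) + dj,
                     seq(1, 2 * d[3], 2) + dk, , drop = FALSE], N, cout)
    gw[rows, ] <- crossprod(xm, gyo)
    gxm <- gxm + gyo %*% t(layer$w[rows, , drop = FALSE])
  }
  list(gx = array(gxm, d), gw = gw, gb = apply(gy, 4, sum))
}

concat4 <- function(a, b) {
  array(c(a, b), c(dim(a)[1:3], dim(a)[4] + dim(b)[4]))
}

# Forward pass; with cache = TRUE all intermediates needed by
# netBackward() are retained.
netForward <- function(weights, cfg, x, cache = FALSE) {
  L <- cfg$levels
  encIn <- vector("list", L); encA1 <- vector("list", L)
  encA2 <- vector("list", L); poolIdx <- vector("list", L)
  cur <- x
  for (l in seq_len(L)) {
    encIn[[l]] <- cur
    a1 <- relu(cpp_conv3_forward(cur, weights$enc[[l]]$a$w,
                                 weights$enc[[l]]$a$b, dim(cur)))
    a2 <- relu(cpp_conv3_forward(a1, weights$enc[[l]]$b$w,
                                 weights$enc[[l]]$b$b, dim(a1)))
    encA1[[l]] <- a1; encA2[[l]] <- a2
    if (l < L) {
      pl <- cpp_maxpool2_forward(a2, dim(a2))
      poolIdx[[l]] <- pl$idx
      cur <- pl$y
    }
  }
  decIn <- vector("list", L - 1); decU <- vector("list", L - 1)
  decCat <- vector("list", L - 1); decA1 <- vector("list", L - 1)
  d <- encA2[[L]]
  for (l in rev(seq_len(L - 1))) {
    decIn[[l]] <- d
    u <- relu(upconvForward(d, weights$up[[l]]))
    ct <- concat4(u, encA2[[l]])
    a1 <- relu(cpp_conv3_forward(ct, weights$dec[[l]]$a$w,
                                 weights$dec[[l]]$a$b, dim(ct)))
    d <- relu(cpp_conv3_forward(a1, weights$dec[[l]]$b$w,
                                weights$dec[[l]]$b$b, dim(a1)))
    decU[[l]] <- u; decCat[[l]] <- ct; decA1[[l]] <- a1
  }
  dd <- dim(d)
  N <- prod(dd[1:3])
  out <- array(matrix(d, N, dd[4]) %*% weights$head$w + weights$head$b,
               dd[1:3])
  if (!cache) return(list(out = out))
  list(out = out,
       cache = list(x = x, encIn = encIn, encA1 = encA1, encA2 = encA2,
                    poolIdx = poolIdx, decIn = decIn, decU = decU,
                    decCat = decCat, decA1 = decA1, headIn = d))
}

# Backward pass: returns gradients with the same structure as the weights.
netBackward <- function(weights, cfg, cache, gOut) {
  L <- cfg$levels
  g <- list(enc = vector("list", L), up = vector("list", L - 1),
            dec = vector("list", L - 1), head = NULL)

  hd <- cache$headIn
  dd <- dim(hd)
  N <- prod(dd[1:3])
  hm <- matrix(hd, N, dd[4])
  gOutM <- matrix(gOut, N, 1)
  g$head <- list(gw = crossprod(hm, gOutM), gb = sum(gOutM))
  gd <- array(gOutM %*% t(weights$head$w), dd)

  gSkip <- vector("list", L)  # gradient flowing into encA2[[l]] via skips
  for (l in seq_len(L - 1)) {
    # decoder level l backward (decoder ran l = L-1 .. 1; backprop ascends)
    gpreB <- gd * netReluMask(cache, l)
    bb <- cpp_conv3_backward(cache$decA1[[l]], weights$dec[[l]]$b$w, gpreB,
                             dim(cache$decA1[[l]]))
    gpreA <- bb$gx * (cache$decA1[[l]] > 0)
    ba <- cpp_conv3_backward(cache$decCat[[l]], weights$dec[[l]]$a$w, gpreA,
                             dim(cache$decCat[[l]]))
    g$dec[[l]] <- list(a = list(gw = ba$gw, gb = ba$gb),
                       b = list(gw = bb$gw, gb = bb$gb))
    cu <- dim(cache$decU[[l]])[4]
    gcat <- ba$gx
    gu <- gcat[, , , seq_len(cu), drop = FALSE]
    gSkip[[l]] <- gcat[, , , cu + seq_len(dim(gcat)[4] - cu), drop = FALSE]
    gpreU <- gu * (cache$decU[[l]] > 0)
    ub <- upconvBackward(cache$decIn[[l]], weights$up[[l]], gpreU)
    g$up[[l]] <- list(gw = ub$gw, gb = ub$gb)
    gd <- ub$gx
  }
  # gd now reaches encA2[[L]] (bottleneck output)
  gUp <- gd
  for (l in rev(seq_len(L))) {
    gA2 <- if (l == L) gUp
    else cpp_maxpool2_backward(gUp, cache$poolIdx[[l]],
                               dim(cache$encA2[[l]])) + gSkip[[l]]
    gpreB <- gA2 * (cache$encA2[[l]] > 0)
    bb <- cpp_conv3_backward(cache$encA1[[l]], weights$enc[[l]]$b$w, gpreB,
                             dim(cache$encA1[[l]]))
    gpreA <- bb$gx * (cache$encA1[[l]] > 0)
    ba <- cpp_conv3_backward(cache$encIn[[l]], weights$enc[[l]]$a$w, gpreA,
                             dim(cache$encIn[[l]]), need_gx = l > 1L)
    g$enc[[l]] <- list(a = list(gw = ba$gw, gb = ba$gb),
                       b = list(gw = bb$gw, gb = bb$gb))
    gUp <- ba$gx
  }
  g
}

# ReLU mask of decoder level l's output: that tensor is decIn[[l-1]] for
# l > 1 and the head input for l = 1.
netReluMask <- function(cache, l) {
  v <- if (l == 1) cache$headIn else cache$decIn[[l - 1]]
  v > 0
}

# Flatten weights / grads to aligned lists of numeric vectors for Adam.
flattenParams <- function(w) {
  out <- list()
  walk <- function(x, path) {
    if (is.list(x)) {
      for (nm in seq_along(x)) {
        key <- if (!is.null(names(x)) && nzchar(names(x)[nm]))
          names(x)[nm] else as.character(nm)
        walk(x[[nm]], c(path, key))
      }
    } else out[[paste(path, collapse = ".")]] <<- x
  }
  walk(w, character(0))
  out
}

assignFlat <- function(w, flat, path = character(0)) {
  if (!is.list(w)) return(flat[[paste(path, collapse = ".")]])
  for (i in seq_along(w)) {
    key <- if (!is.null(names(w)) && nzchar(names(w)[i]))
      names(w)[i] else as.character(i)
    w[[i]] <- assignFlat(w[[i]], flat, c(path, key))
  }
  w
}

# One Adam update; state carries first/second moments and the step count.
adamStep <- function(flatW, flatG, state, lr, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  if (is.null(state))
    state <- list(m = lapply(flatW, function(x) x * 0),
                  v = lapply(flatW, function(x) x * 0), t = 0)
  state$t <- state$t + 1
  for (k in names(flatW)) {
    gk <- flatG[[k]]
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * gk
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * gk^2
    mhat <- state$m[[k]] / (1 - beta1^state$t)
    vhat <- state$v[[k]] / (1 - beta2^state$t)
    flatW[[k]] <- flatW[[k]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(w = flatW, state = state)
}

# Map gradient structure (gw/gb leaves) onto the weight structure (w/b).
gradAsWeights <- function(g) {
  rename <- function(x) {
    if (is.list(x)) {
      if (!is.null(x$gw)) return(list(w = x$gw, b = x$gb))
      lapply(x, rename)
    } else x
  }
  rename(g)
}
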