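# Small convolutional feature extractor with hand-derived backpropagation.
#
# Layout per extractor (one independent extractor per modality):
#   repeat for each entry of `channels`: 3x3 same-pad convolution -> ReLU ->
#   2x2 max-pool (ceiling division on odd dims), then a 1x1 "add-on"
#   convolution to the shared prototype channel count C followed by a
#   logistic squashing so latent features live in (0, 1) — the same range the
#   prototypes are uniformly initialised on.
#
# Convolution and pooling kernels (im2col + BLAS matmul and their exact
# adjoints) are compiled code (src/convnet.cpp); this file holds the layer
# bookkeeping and the chain rule.

#' Feature extractor configuration
#'
#' Describes the shared architecture of the per-modality feature extractors.
#' The spatial downsampling factor is `2 ^ length(channels)` (one 2x2 pooling
#' per convolution block), so a `h x w` input yields a
#' `ceiling(h / downsample) x ceiling(w / downsample) x C` feature map.
#'
#' @param channels integer vector, output channels of each 3x3 convolution
#'   block. Its length sets the number of blocks and hence the downsampling.
#'   The default three-block stack (downsample 8) keeps desk-scale training
#'   cheap; a deeper/wider stack is selected by passing a longer vector.
#' @param C number of latent channels shared with the prototypes (the add-on
#'   1x1 convolution maps the last block to `C`).
#' @param in_channels input image channels (3 for RGB).
#' @return an object of class `backbone_config`.
#' @export
backbone_config <- function(channels = c(8L, 16L, 32L), C = 128L, in_channels = 3L) {
  stopifnot(length(channels) >= 1L, all(channels >= 1L), is_count(C),
            is_count(in_channels))
  structure(list(channels = as.integer(channels), C = as.integer(C),
                 in_channels = as.integer(in_channels),
                 downsample = 2L^length(channels), kernel = 3L),
            class = "backbone_config")
}

# He-normal initialisation of one extractor's parameters (list of conv
# matrices (k*k*cin) x cout plus biases, and the 1x1 add-on).
init_extractor <- function(cfg, modality_index = 1L) {
  k <- cfg$kernel
  cin <- cfg$in_channels
  conv <- vector("list", length(cfg$channels))
  for (l in seq_along(cfg$channels)) {
    cout <- cfg$channels[l]
    fan <- k * k * cin
    conv[[l]] <- list(W = matrix(stats::rnorm(fan * cout, 0, sqrt(2 / fan)), fan, cout),
                      b = numeric(cout))
    cin <- cout
  }
  addon <- list(W = matrix(stats::rnorm(cin * cfg$C, 0, sqrt(2 / cin)), cin, cfg$C),
                b = numeric(cfg$C))
  structure(list(conv = conv, addon = addon, config = cfg,
                 modality_index = as.integer(modality_index)),
            class = "feature_extractor")
}

conv_forward <- function(x, layer) {
  out <- conv3_forward_cpp(x, layer$W, layer$b)
  list(y = out$y, xcol = out$xcol, in_dim = dim(x))
}

conv_backward <- function(gy, cache, layer) {
  d <- cache$in_dim
  conv3_backward_cpp(matrix(gy, d[1L] * d[2L]), cache$xcol, layer$W,
                     d[1L], d[2L], d[3L])
}

maxpool_forward <- function(x) {
  out <- maxpool2_forward_cpp(x)
  list(y = out$y, argmax = out$argmax, in_dim = dim(x))
}

maxpool_backward <- function(gy, cache) {
  maxpool2_backward_cpp(as.vector(gy), cache$argmax, cache$in_dim[1L],
                        cache$in_dim[2L], cache$in_dim[3L])
}

# ---- full extractor forward / backward -------------------------------------

extractor_forward <- function(x, ext, keep_cache = FALSE) {
  cfg <- ext$config
  caches <- if (keep_cache) vector("list", length(ext$conv)) else NULL
  for (l in seq_along(ext$conv)) {
    cv <- conv_forward(x, ext$conv[[l]])
    pre <- cv$y
    act <- pre * (pre > 0)
    pl <- maxpool_forward(act)
    if (keep_cache) caches[[l]] <- list(conv = cv, relu_mask = pre > 0, pool = pl)
    x <- pl$y
  }
  d <- dim(x)
  xmat <- matrix(x, nrow = d[1L] * d[2L])
  a <- sweep(xmat %*% ext$addon$W, 2L, ext$addon$b, `+`)
  z <- 1 / (1 + exp(-a))
  fmap <- array(z, dim = c(d[1L], d[2L], cfg$C))
  if (keep_cache) {
    list(fmap = fmap, caches = caches, addon_in = xmat, z = z, last_dim = d)
  } else {
    list(fmap = fmap)
  }
}

# gz: gradient w.r.t. the fmap (array Hf x Wf x C). Returns gradient lists
# matching ext$conv / ext$addon.
extractor_backward <- function(gz, fw, ext) {
  d <- fw$last_dim
  gz <- matrix(gz, nrow = d[1L] * d[2L])
  ga <- gz * fw$z * (1 - fw$z)
  g_addon <- list(W = crossprod(fw$addon_in, ga), b = colSums(ga))
  gx <- array(ga %*% t(ext$addon$W), dim = d)
  g_conv <- vector("list", length(ext$conv))
  for (l in rev(seq_along(ext$conv))) {
    cc <- fw$caches[[l]]
    g_act <- maxpool_backward(gx, cc$pool)
    g_pre <- g_act * cc$relu_mask
    bk <- conv_backward(g_pre, cc$conv, ext$conv[[l]])
    g_conv[[l]] <- list(W = bk$gW, b = bk$gb)
    gx <- bk$gx
  }
  list(conv = g_conv, addon = g_addon)
}
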