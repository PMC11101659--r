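# Raster image helpers. Images are numeric arrays H x W x 3 with values in
# [0, 1]; grayscale files are replicated across channels on load.

as_rgb_array <- function(x) {
  if (is.matrix(x)) x <- array(rep(x, 3L), dim = c(dim(x), 3L))
  if (length(dim(x)) != 3L) stopf("image must be a 2-D or 3-D array")
  if (dim(x)[3L] == 4L) x <- x[, , 1:3, drop = FALSE]     # drop alpha
  if (dim(x)[3L] == 1L) x <- array(rep(x, 3L), dim = c(dim(x)[1:2], 3L))
  if (dim(x)[3L] != 3L) stopf("image must have 1, 3 or 4 channels")
  storage.mode(x) <- "double"
  clip01(x)
}

read_image <- function(path) {
  if (!file.exists(path)) stopf("image file not found: %s", path)
  as_rgb_array(png::readPNG(path))
}

write_image <- function(img, path) {
  png::writePNG(clip01(img), target = path)
  invisible(path)
}

img_gray <- function(img) {
  0.299 * img[, , 1L] + 0.587 * img[, , 2L] + 0.114 * img[, , 3L]
}

# Horizontal flip (mirror columns), all channels.
flip_horizontal <- function(img) img[, rev(seq_len(dim(img)[2L])), , drop = FALSE]

# Rotate about the image centre by `angle` degrees (bilinear inverse warp,
# zero fill outside), output size kept.
rotate_image <- function(img, angle) {
  if (angle == 0) return(img)
  h <- dim(img)[1L]; w <- dim(img)[2L]
  th <- angle * pi / 180
  cr <- (h - 1) / 2; cc <- (w - 1) / 2
  # inverse mapping: sample input at R(-th) (out - centre) + centre
  a11 <- cos(th); a12 <- sin(th); a21 <- -sin(th); a22 <- cos(th)
  warp_bilinear_cpp(img, h, w, a11, a12, a21, a22,
                    cr - a11 * cr - a12 * cc, cc - a21 * cr - a22 * cc, 0L)
}

# Central crop of a fraction of each dimension, resized back to original dims.
crop_resize <- function(img, fraction) {
  if (fraction >= 1) return(img)
  h <- dim(img)[1L]; w <- dim(img)[2L]
  ch <- max(2, h * fraction); cw <- max(2, w * fraction)
  r0 <- (h - ch) / 2; c0 <- (w - cw) / 2
  warp_bilinear_cpp(img, h, w, ch / h, 0, 0, cw / w,
                    r0 + ch / h / 2 - 0.5, c0 + cw / w / 2 - 0.5, 1L)
}

resize_image <- function(img, h, w) {
  was_mat <- is.matrix(img)
  if (was_mat) img <- array(img, dim = c(dim(img), 1L))
  hi <- dim(img)[1L]; wi <- dim(img)[2L]
  out <- warp_bilinear_cpp(img, h, w, hi / h, 0, 0, wi / w,
                           hi / h / 2 - 0.5, wi / w / 2 - 0.5, 1L)
  if (was_mat) out[, , 1L] else out
}

gaussian_blur <- function(img, sigma = 1) {
  # cap the kernel so it fits small images; below a 3-pixel brush the blur
  # is a no-op
  mx <- min(dim(img)[1:2])
  radius <- min(2L * ceiling(3 * sigma) + 1L, mx - (1L - mx %% 2L))
  if (radius < 3L) return(img)
  out <- EBImage::gblur(EBImage::Image(aperm(img, c(2L, 1L, 3L)), colormode = "Color"),
                        sigma = sigma, radius = radius)
  aperm(EBImage::imageData(out), c(2L, 1L, 3L))
}

adjust_brightness <- function(img, factor) clip01(img * factor)

# Contrast scale about mid-gray.
adjust_contrast <- function(img, factor) clip01((img - 0.5) * factor + 0.5)
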