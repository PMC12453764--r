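#' Preprocessing configuration
#'
#' @param target_size integer (rows, cols) after resampling; default
#'   c(256, 256).
#' @param sanlm_h smoothing bandwidth h > 0 of the adaptive non-local-means
#'   filter, on \code{[0,1]} intensities; default 0.1.
#' @param sanlm_patch_radius similarity-patch radius (1 = 3x3); 0 compares
#'   single pixels.
#' @param sanlm_search_radius search-window radius (2 = 5x5 window).
#' @param otsu_weights RGB-to-grayscale weights used before Otsu thresholding;
#'   default luma (0.299, 0.587, 0.114).
#' @param resample_mode "nearest" (default, index remapping) or "bilinear".
#' @param normalize_epsilon reserved guard for near-constant images.
#' @return config list of class \code{preprocessConfig}.
#' @export
preprocessConfig <- function(target_size = c(256L, 256L), sanlm_h = 0.1,
                             sanlm_patch_radius = 1L, sanlm_search_radius = 2L,
                             otsu_weights = c(0.299, 0.587, 0.114),
                             resample_mode = c("nearest", "bilinear"),
                             normalize_epsilon = 1e-12) {
  target_size <- as.integer(target_size)
  if (any(target_size < 1L)) stop("target_size must be >= 1 in both dimensions")
  if (sanlm_h <= 0) stop("sanlm_h must be > 0")
  if (sanlm_patch_radius < 0L || sanlm_search_radius < 1L)
    stop("sanlm radii invalid: patch >= 0, search >= 1")
  structure(list(target_size = target_size, sanlm_h = sanlm_h,
                 sanlm_patch_radius = as.integer(sanlm_patch_radius),
                 sanlm_search_radius = as.integer(sanlm_search_radius),
                 otsu_weights = otsu_weights,
                 resample_mode = match.arg(resample_mode),
                 normalize_epsilon = normalize_epsilon),
            class = "preprocessConfig")
}

.as_image3 <- function(image) {
  if (is.matrix(image)) image <- array(image, dim = c(dim(image), 1L))
  if (length(dim(image)) != 3L) stop("image must be H x W or H x W x C")
  if (!all(is.finite(image))) stop("image values must be finite")
  image
}

#' Resample an image to a target size
#'
#' Default mode is nearest-index remapping: output pixel (x, y) takes input
#' pixel (floor(x*H/H'), floor(y*W/W')) in 0-based coordinates, so output
#' intensities are a subset of input intensities. A bilinear mode is
#' available for smoother downstream appearance.
#'
#' @param image H x W x C numeric array (or H x W matrix).
#' @param target integer (H', W').
#' @param mode "nearest" or "bilinear".
#' @return resampled H' x W' x C array.
#' @export
resampleImage <- function(image, target, mode = c("nearest", "bilinear")) {
  mode <- match.arg(mode)
  image <- .as_image3(image)
  target <- as.integer(target)
  if (length(target) != 2L || any(target < 1L))
    stop("target dimensions must be positive")
  H <- dim(image)[1]; W <- dim(image)[2]; C <- dim(image)[3]
  Hp <- target[1]; Wp <- target[2]
  if (mode == "nearest") {
    ri <- floor((seq_len(Hp) - 1) * H / Hp) + 1
    ci <- floor((seq_len(Wp) - 1) * W / Wp) + 1
    out <- image[ri, ci, , drop = FALSE]
  } else {
    # align source/target pixel centers: src = (t + 0.5) * H/H' - 0.5
    rs <- pmin(pmax((seq_len(Hp) - 0.5) * H / Hp - 0.5, 0), H - 1)
    cs <- pmin(pmax((seq_len(Wp) - 0.5) * W / Wp - 0.5, 0), W - 1)
    r0 <- floor(rs); c0 <- floor(cs)
    r1 <- pmin(r0 + 1, H - 1); c1 <- pmin(c0 + 1, W - 1)
    fr <- rs - r0; fc <- cs - c0
    out <- array(0, dim = c(Hp, Wp, C))
    for (ch in seq_len(C)) {
      pl <- image[, , ch]
      a <- pl[cbind(rep(r0 + 1, Wp), rep(c0 + 1, each = Hp))]
      b <- pl[cbind(rep(r0 + 1, Wp), rep(c1 + 1, each = Hp))]
      d <- pl[cbind(rep(r1 + 1, Wp), rep(c0 + 1, each = Hp))]
      e <- pl[cbind(rep(r1 + 1, Wp), rep(c1 + 1, each = Hp))]
      wfr <- rep(fr, Wp); wfc <- rep(fc, each = Hp)
      out[, , ch] <- matrix((1 - wfr) * (1 - wfc) * a + (1 - wfr) * wfc * b +
                            wfr * (1 - wfc) * d + wfr * wfc * e, Hp, Wp)
    }
  }
  out
}

#' Adaptive non-local-means denoising
#'
#' Each output pixel is the similarity-weighted average over its search
#' window, with weights \code{exp(-d2/h^2)} where d2 is the (similarity-patch
#' averaged) squared intensity distance; the Euclidean norm runs over
#' channels and weights are shared across channels. Being a convex
#' combination, the output range never exceeds the input range.
#'
#' @param image H x W x C numeric array.
#' @param config a \code{\link{preprocessConfig}} (uses sanlm_h and radii).
#' @return denoised array of the same shape.
#' @export
sanlmDenoise <- function(image, config = preprocessConfig()) {
  image <- .as_image3(image)
  if (config$sanlm_h <= 0) stop("sanlm_h must be > 0")
  d <- dim(image)
  out <- cpp_sanlm(as.numeric(image), d[1], d[2], d[3],
                   config$sanlm_patch_radius, config$sanlm_search_radius,
                   config$sanlm_h)
  array(out, dim = d)
}

#' Otsu threshold of a 256-bin histogram
#'
#' Returns the bin index T (0-based, i.e. on the 0..255 gray scale) that
#' maximises between-class variance -- equivalently minimises within-class
#' variance -- with the smallest optimum chosen on ties. A pixel belongs to
#' the foreground when its gray level exceeds T.
#'
#' @param counts numeric vector of 256 non-negative bin counts.
#' @return integer threshold in 0..254.
#' @export
otsuThreshold <- function(counts) {
  if (length(counts) != 256L || any(counts < 0))
    stop("counts must be 256 non-negative values")
  if (sum(counts > 0) < 2L)
    stop("degenerate histogram: all mass in one bin")
  n <- sum(counts)
  levels <- 0:255
  w <- cumsum(counts) / n                  # class-0 mass for T = 0..255
  mu <- cumsum(counts * levels) / n
  muT <- mu[256]
  # candidate thresholds T = 0..254; class 0 = bins <= T, class 1 = bins > T
  w0 <- w[1:255]; mu0 <- mu[1:255]
  valid <- w0 > 0 & w0 < 1
  sigma_b <- rep(-Inf, 255)
  sigma_b[valid] <- (muT * w0[valid] - mu0[valid])^2 / (w0[valid] * (1 - w0[valid]))
  best <- which(sigma_b == max(sigma_b))[1]
  as.integer(best - 1L)
}

#' Otsu-based skin mask and segmentation
#'
#' Converts the image to grayscale (luma weights by default), builds a
#' 256-bin histogram over the image's own intensity range, thresholds by
#' Otsu's method, and returns the binary mask (1 where the gray level exceeds
#' the threshold) together with the element-wise masked image.
#'
#' @param image H x W x C numeric array.
#' @param config a \code{\link{preprocessConfig}}.
#' @param threshold optional externally forced threshold on the grayscale
#'   intensity scale (bypasses Otsu).
#' @return list with \code{mask} (H x W 0/1 matrix), \code{threshold}
#'   (grayscale intensity), and \code{segmented} (image * mask).
#' @export
skinMask <- function(image, config = preprocessConfig(), threshold = NULL) {
  image <- .as_image3(image)
  d <- dim(image)
  wts <- config$otsu_weights
  if (d[3] == 1L) gray <- image[, , 1]
  else gray <- wts[1] * image[, , 1] + wts[2] * image[, , 2] + wts[3] * image[, , 3]
  if (is.null(threshold)) {
    gmin <- min(gray); gmax <- max(gray)
    if (gmax - gmin <= 0)
      stop("degenerate (constant) image: Otsu threshold undefined")
    bins <- pmin(floor((gray - gmin) / (gmax - gmin) * 256), 255)
    counts <- tabulate(bins + 1L, nbins = 256L)
    t_bin <- otsuThreshold(counts)
    threshold <- gmin + (t_bin + 1) / 256 * (gmax - gmin)  # upper edge of bin T
  }
  mask <- (gray > threshold) + 0
  segmented <- image * array(rep(mask, d[3]), dim = d)
  list(mask = mask, threshold = threshold, segmented = segmented)
}

#' Min-max intensity normalisation
#'
#' Rescales an image linearly so its minimum maps to 0 and maximum to 1,
#' recording the original extremes. A constant image yields all zeros with
#' \code{degenerate = TRUE} rather than dividing by zero.
#'
#' @param image numeric array.
#' @return list with \code{pixels}, \code{i_min}, \code{i_max},
#'   \code{degenerate}.
#' @export
minmaxNormalize <- function(image) {
  image <- .as_image3(image)
  i_min <- min(image); i_max <- max(image)
  if (i_max - i_min <= 0)
    return(list(pixels = array(0, dim = dim(image)), i_min = i_min,
                i_max = i_max, degenerate = TRUE))
  list(pixels = (image - i_min) / (i_max - i_min), i_min = i_min,
       i_max = i_max, degenerate = FALSE)
}

#' Geometric and photometric augmentation
#'
#' \describe{
#'   \item{rotate}{rotation by \code{angle} degrees about the image center,
#'     nearest-neighbour sampling, out-of-canvas pixels set to 0.}
#'   \item{hflip / vflip}{mirror columns / rows.}
#'   \item{crop}{window \code{c(row, col, height, width)} in 0-based
#'     coordinates; must lie inside the image.}
#'   \item{brightness}{multiply by \code{factor} > 0 and clip to [0,1].}
#' }
#'
#' @param image H x W x C numeric array in \code{[0,1]}.
#' @param op one of "rotate", "hflip", "vflip", "crop", "brightness".
#' @param angle rotation angle in degrees (for "rotate").
#' @param window crop window (for "crop").
#' @param factor brightness factor (for "brightness").
#' @return transformed array.
#' @export
augmentImage <- function(image, op = c("rotate", "hflip", "vflip", "crop", "brightness"),
                         angle = 0, window = NULL, factor = 1) {
  op <- match.arg(op)
  image <- .as_image3(image)
  d <- dim(image)
  H <- d[1]; W <- d[2]
  switch(op,
    rotate = {
      th <- angle * pi / 180
      ctr <- c((H - 1) / 2, (W - 1) / 2)
      out <- array(0, dim = d)
      xr <- rep(seq_len(H) - 1, W) - ctr[1]
      yr <- rep(seq_len(W) - 1, each = H) - ctr[2]
      # inverse rotation of the sampling grid about the image center
      sr <- round(xr * cos(th) + yr * sin(th) + ctr[1])
      sc <- round(-xr * sin(th) + yr * cos(th) + ctr[2])
      ok <- sr >= 0 & sr < H & sc >= 0 & sc < W
      for (ch in seq_len(d[3])) {
        pl <- matrix(0, H, W)
        pl[ok] <- image[, , ch][cbind(sr[ok] + 1, sc[ok] + 1)]
        out[, , ch] <- pl
      }
      out
    },
    hflip = image[, W:1, , drop = FALSE],
    vflip = image[H:1, , , drop = FALSE],
    crop = {
      if (is.null(window) || length(window) != 4L)
        stop("crop requires window = c(row, col, height, width)")
      w <- as.integer(window)
      if (w[1] < 0 || w[2] < 0 || w[1] + w[3] > H || w[2] + w[4] > W)
        stop("crop window outside image bounds")
      image[w[1] + seq_len(w[3]), w[2] + seq_len(w[4]), , drop = FALSE]
    },
    brightness = {
      if (factor <= 0) stop("brightness factor must be > 0")
      pmin(pmax(image * factor, 0), 1)
    })
}

#' Full preprocessing pipeline
#'
#' Applies, in order: resample to target size, adaptive non-local-means
#' denoising, Otsu skin masking (element-wise multiplication), and min-max
#' normalisation. Augmentation is a train-time concern and is not part of
#' this deterministic pipeline.
#'
#' @param image H x W x C array.
#' @param config a \code{\link{preprocessConfig}}.
#' @param mask apply the Otsu skin mask (default TRUE); synthetic cohorts
#'   whose full frame is skin may disable it.
#' @return list with \code{pixels} (clean image), \code{mask},
#'   \code{threshold}, \code{i_min}, \code{i_max}, \code{degenerate},
#'   \code{steps} (provenance).
#' @export
preprocessImage <- function(image, config = preprocessConfig(), mask = TRUE) {
  steps <- character(0)
  img <- resampleImage(image, config$target_size, config$resample_mode)
  steps <- c(steps, sprintf("resample(%dx%d,%s)", config$target_size[1],
                            config$target_size[2], config$resample_mode))
  img <- sanlmDenoise(img, config)
  steps <- c(steps, sprintf("sanlm(h=%g,patch=%d,search=%d)", config$sanlm_h,
                            config$sanlm_patch_radius, config$sanlm_search_radius))
  msk <- NULL; thr <- NA_real_
  if (mask) {
    sm <- skinMask(img, config)
    img <- sm$segmented; msk <- sm$mask; thr <- sm$threshold
    steps <- c(steps, sprintf("otsu_mask(T=%.4f)", thr))
  }
  nz <- minmaxNormalize(img)
  steps <- c(steps, "minmax_normalize")
  list(pixels = nz$pixels, mask = msk, threshold = thr, i_min = nz$i_min,
       i_max = nz$i_max, degenerate = nz$degenerate, steps = steps)
}
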