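#' Aggregate patch probabilities into a disease probability map
#'
#' Each patch's scalar diseased probability is broadcast over its footprint
#' and the map takes, at every pixel, the maximum over all patches containing
#' it. Pixels covered by no patch get probability 0 (and coverage 0).
#'
#' @param grid a \linkS4class{PatchGrid}.
#' @param predictions numeric vector of per-patch diseased probabilities in
#'   \code{[0,1]}, one per patch, in grid order.
#' @return a \linkS4class{ProbMap}.
#' @export
aggregateMap <- function(grid, predictions) {
  stopifnot(is(grid, "PatchGrid"))
  n <- nPatches(grid)
  if (length(predictions) != n)
    stop(sprintf("expected %d predictions, got %d", n, length(predictions)))
  if (any(predictions < 0 | predictions > 1))
    stop("predictions must lie in [0,1]")
  H <- grid@imageDim[1]; W <- grid@imageDim[2]; p <- grid@patchSize
  vals <- matrix(0, H, W)
  cov <- matrix(0L, H, W)
  for (k in seq_len(n)) {
    o <- grid@origins[k, ]
    ri <- o[1] + seq_len(p); ci <- o[2] + seq_len(p)
    vals[ri, ci] <- pmax(vals[ri, ci], predictions[k])
    cov[ri, ci] <- cov[ri, ci] + 1L
  }
  vals[cov == 0L] <- 0
  methods::new("ProbMap", values = vals, coverage = cov, stride = grid@stride)
}

#' Threshold a probability map into high-risk pixels
#'
#' Returns exactly the pixels whose map value is >= T.
#'
#' @param map a \linkS4class{ProbMap}.
#' @param threshold probability threshold T in \code{[0,1]}.
#' @return list with \code{mask} (logical H x W) and \code{values} (numeric
#'   vector of retained map values).
#' @export
thresholdRegions <- function(map, threshold = 0.5) {
  stopifnot(is(map, "ProbMap"))
  if (threshold < 0 || threshold > 1) stop("threshold must lie in [0,1]")
  keep <- map@values >= threshold
  list(mask = keep, values = map@values[keep])
}

#' Top high-risk windows of a probability map
#'
#' Slides a \code{windowSize} x \code{windowSize} window at stride
#' \code{windowSize} (disjoint windows), keeps windows whose mean intensity
#' is >= \code{threshold}, ranks them by mean intensity descending (ties by
#' ascending row then column origin) and returns the first
#' \code{min(n, available)}.
#'
#' @param map a \linkS4class{ProbMap}.
#' @param n maximum number of regions, >= 1.
#' @param threshold minimum window mean retained; default 0 keeps all.
#' @param windowSize window side; default 32.
#' @return a \linkS4class{RiskRegionSet}.
#' @export
topRegions <- function(map, n = 8L, threshold = 0, windowSize = 32L) {
  stopifnot(is(map, "ProbMap"))
  if (n < 1L) stop("n must be >= 1")
  H <- nrow(map@values); W <- ncol(map@values)
  windowSize <- as.integer(windowSize)
  if (windowSize > H || windowSize > W)
    stop(sprintf("map %dx%d smaller than %dx%d window", H, W, windowSize, windowSize))
  rows <- seq(0L, H - windowSize, by = windowSize)
  cols <- seq(0L, W - windowSize, by = windowSize)
  origins <- cbind(row = rep(rows, each = length(cols)),
                   col = rep(cols, times = length(rows)))
  means <- vapply(seq_len(nrow(origins)), function(k) {
    o <- origins[k, ]
    mean(map@values[o[1] + seq_len(windowSize), o[2] + seq_len(windowSize)])
  }, numeric(1))
  keep <- which(means >= threshold)
  ord <- keep[order(-means[keep], origins[keep, 1], origins[keep, 2])]
  ord <- ord[seq_len(min(n, length(ord)))]
  methods::new("RiskRegionSet",
               origins = matrix(as.integer(origins[ord, , drop = FALSE]), ncol = 2,
                                dimnames = list(NULL, c("row", "col"))),
               means = means[ord],
               values = lapply(ord, function(k) {
                 o <- origins[k, ]
                 map@values[o[1] + seq_len(windowSize), o[2] + seq_len(windowSize)]
               }),
               windowSize = windowSize)
}

#' Reduce high-risk regions to the fusion input tensor
#'
#' Each window is reduced column-wise to a length-\code{windowSize} mean
#' profile (preserving a 1-D spatial signature at the tensor's printed
#' width); profiles stack into an (N, 1, L) tensor. When fewer than
#' \code{n_slots} regions are available the tensor is zero-padded. A
#' \code{flat} mode concatenating the full window row-major (length L*L) is
#' available.
#'
#' @param regions a \linkS4class{RiskRegionSet}.
#' @param n_slots fixed tensor row count N; default 8.
#' @param reduce "colmean" (default) or "flat".
#' @return a \linkS4class{RegionTensor}.
#' @export
regionsToTensor <- function(regions, n_slots = 8L, reduce = c("colmean", "flat")) {
  stopifnot(is(regions, "RiskRegionSet"))
  reduce <- match.arg(reduce)
  k <- length(regions@means)
  if (k < 1L) stop("at least one region required")
  L <- if (reduce == "colmean") regions@windowSize
       else regions@windowSize^2
  dat <- array(0, dim = c(n_slots, 1L, L))
  for (i in seq_len(min(k, n_slots))) {
    v <- regions@values[[i]]
    dat[i, 1, ] <- if (reduce == "colmean") colMeans(v) else as.numeric(t(v))
  }
  methods::new("RegionTensor", data = dat, nRegions = as.integer(min(k, n_slots)))
}

#' Render a probability-map overlay
#'
#' Alpha-blends the map (red heat colour) over the image and writes a PNG.
#' Pure visualisation; no analysis effect.
#'
#' @param map a \linkS4class{ProbMap}.
#' @param image H x W x 3 array in \code{[0,1]} with matching dimensions.
#' @param file output PNG path.
#' @param alpha maximum blend weight at map value 1; default 0.6.
#' @return invisibly, the blended H x W x 3 array.
#' @export
renderOverlay <- function(map, image, file = NULL, alpha = 0.6) {
  stopifnot(is(map, "ProbMap"))
  image <- .as_image3(image)
  if (!identical(dim(image)[1:2], dim(map@values)))
    stop(sprintf("dimension mismatch: map %dx%d vs image %dx%d",
                 nrow(map@values), ncol(map@values), dim(image)[1], dim(image)[2]))
  heat <- c(1, 0, 0)
  a <- map@values * alpha
  out <- image
  for (ch in 1:3) out[, , ch] <- (1 - a) * image[, , ch] + a * heat[ch]
  if (!is.null(file)) png::writePNG(out, target = file)
  invisible(out)
}
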