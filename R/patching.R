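#' Extract a patch grid from an image
#'
#' Tiles an image into p x p patches at stride s. Origins are all 0-based
#' (a*s, b*s) with a*s + p <= H and b*s + p <= W, ordered row-major. With
#' s = p the tiling is disjoint and the count equals
#' \code{floor(H/p) * floor(W/p)}; remainder rows/columns that cannot host a
#' full patch are left uncovered. Overlapping grids (s < p) are used for
#' probability-map aggregation.
#'
#' @param image H x W x C numeric array (or H x W matrix).
#' @param p patch side, 1 <= p <= min(H, W).
#' @param stride stride s >= 1; defaults to p (non-overlapping).
#' @return a \linkS4class{PatchGrid}.
#' @examples
#' img <- array(stats::runif(64 * 64 * 3), dim = c(64, 64, 3))
#' grid <- extractPatches(img, p = 32, stride = 16)
#' nPatches(grid)  # 9
#' @export
extractPatches <- function(image, p, stride = p) {
  image <- .as_image3(image)
  d <- dim(image)
  H <- d[1]; W <- d[2]; C <- d[3]
  p <- as.integer(p); stride <- as.integer(stride)
  if (p < 1L || p > H || p > W)
    stop(sprintf("patch size %d exceeds image bounds %dx%d", p, H, W))
  if (stride < 1L) stop("stride must be >= 1")
  rows <- seq(0L, H - p, by = stride)
  cols <- seq(0L, W - p, by = stride)
  origins <- cbind(row = rep(rows, each = length(cols)),
                   col = rep(cols, times = length(rows)))
  n <- nrow(origins)
  pixels <- array(0, dim = c(p, p, C, n))
  for (k in seq_len(n))
    pixels[, , , k] <- image[origins[k, 1] + seq_len(p),
                             origins[k, 2] + seq_len(p), , drop = FALSE]
  methods::new("PatchGrid", pixels = pixels,
               origins = matrix(as.integer(origins), ncol = 2,
                                dimnames = list(NULL, c("row", "col"))),
               patchSize = p, stride = stride, imageDim = c(H, W))
}

#' Per-pixel patch coverage counts
#'
#' @param grid a \linkS4class{PatchGrid}.
#' @return integer H x W matrix; entry (x, y) counts the patches containing
#'   that pixel. With stride = p counts are 0 or 1.
#' @export
patchCoverage <- function(grid) {
  stopifnot(is(grid, "PatchGrid"))
  H <- grid@imageDim[1]; W <- grid@imageDim[2]; p <- grid@patchSize
  cov <- matrix(0L, H, W)
  for (k in seq_len(nPatches(grid))) {
    o <- grid@origins[k, ]
    ri <- o[1] + seq_len(p); ci <- o[2] + seq_len(p)
    cov[ri, ci] <- cov[ri, ci] + 1L
  }
  cov
}

#' Stitch a disjoint patch grid back into an image
#'
#' Reassembles the covered sub-image from a stride = p grid; uncovered
#' remainder pixels are 0. Inverse of \code{\link{extractPatches}} on the
#' covered block.
#'
#' @param grid a \linkS4class{PatchGrid} with stride equal to patch size.
#' @return H x W x C numeric array.
#' @export
stitchPatches <- function(grid) {
  stopifnot(is(grid, "PatchGrid"))
  if (grid@stride != grid@patchSize)
    stop("stitching requires a disjoint grid (stride = patch size)")
  H <- grid@imageDim[1]; W <- grid@imageDim[2]
  C <- dim(grid@pixels)[3]; p <- grid@patchSize
  out <- array(0, dim = c(H, W, C))
  for (k in seq_len(nPatches(grid))) {
    o <- grid@origins[k, ]
    out[o[1] + seq_len(p), o[2] + seq_len(p), ] <- grid@pixels[, , , k]
  }
  out
}

#' Label patches against a pixel-level lesion mask
#'
#' A patch is labelled diseased (1) when at least \code{frac} of its pixels
#' fall inside the ground-truth lesion mask; with no mask available, every
#' patch inherits the image label.
#'
#' @param grid a \linkS4class{PatchGrid}.
#' @param mask H x W 0/1 matrix, or NULL.
#' @param image_label 0/1 image label used when \code{mask} is NULL.
#' @param frac lesion-coverage fraction required; default 0.5.
#' @return integer 0/1 vector, one label per patch.
#' @export
labelPatches <- function(grid, mask, image_label = NA_integer_, frac = 0.5) {
  stopifnot(is(grid, "PatchGrid"))
  n <- nPatches(grid); p <- grid@patchSize
  if (is.null(mask)) {
    if (is.na(image_label)) stop("image_label required when mask is NULL")
    return(rep(as.integer(image_label), n))
  }
  labs <- integer(n)
  for (k in seq_len(n)) {
    o <- grid@origins[k, ]
    labs[k] <- as.integer(mean(mask[o[1] + seq_len(p), o[2] + seq_len(p)]) >= frac)
  }
  labs
}
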