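# Intensity-correlation colocalization: per-pixel product of the
# differences from the mean (PDM) on background-subtracted projections of
# two-channel confocal stacks.

#' Morphological background subtraction
#'
#' Estimates a smooth per-slice background by grayscale opening with a disc
#' structuring element of the given radius (the morphological counterpart
#' of rolling-ball background estimation) and subtracts it. Structures
#' narrower than the disc survive; broad smooth background is removed. The
#' result is clipped at zero.
#'
#' @param stack A 2-D matrix, a 3-D array (x, y, slice), or a list of
#'   matrices.
#' @param radius Disc radius in pixels (default 50); must be positive and
#'   smaller than both image dimensions.
#' @return Same shape as the input.
#' @export
subtract_background <- function(stack, radius = 50) {
  slices <- as_slice_list(stack)
  d <- dim(slices[[1]])
  if (radius <= 0) stop("radius must be positive")
  if (2 * radius + 1 > min(d))
    stop("radius must be smaller than the image extent")
  brush <- EBImage::makeBrush(2 * as.integer(radius) + 1L, shape = "disc")
  out <- lapply(slices, function(sl) {
    # grayscale morphology operates on [0, 1] intensities; flat-element
    # erosion/dilation commute with positive scaling, so rescaling is exact
    top <- max(sl)
    if (top <= 0) return(sl * 0)
    bg <- EBImage::opening(sl / top, brush) * top
    pmax(sl - bg, 0)
  })
  restore_slices(out, stack)
}

#' Z-projection of a confocal stack
#'
#' Per-pixel sum or maximum across the selected slices.
#'
#' @param stack 3-D array (x, y, slice) or list of matrices.
#' @param method `"sum"` or `"max"`.
#' @param slice_range Integer vector of slice indices (default all).
#' @return A 2-D matrix.
#' @export
z_project <- function(stack, method = c("sum", "max"), slice_range = NULL) {
  method <- match.arg(method)
  slices <- as_slice_list(stack)
  if (is.null(slice_range)) slice_range <- seq_along(slices)
  if (length(slice_range) == 0L) stop("empty slice range")
  if (any(slice_range < 1L | slice_range > length(slices)))
    stop("slice_range outside the stack")
  slices <- slices[slice_range]
  out <- slices[[1]]
  if (length(slices) > 1L) {
    for (i in 2:length(slices)) {
      out <- if (method == "sum") out + slices[[i]]
             else pmax(out, slices[[i]])
    }
  }
  out
}

as_slice_list <- function(stack) {
  if (is.list(stack)) {
    stopifnot(all(vapply(stack, is.matrix, logical(1))))
    return(stack)
  }
  if (is.matrix(stack)) return(list(stack))
  if (is.array(stack) && length(dim(stack)) == 3L)
    return(lapply(seq_len(dim(stack)[3]), function(i) stack[, , i]))
  stop("stack must be a matrix, 3-D array, or list of matrices")
}

restore_slices <- function(slices, template) {
  if (is.matrix(template)) return(slices[[1]])
  if (is.list(template)) return(slices)
  array(unlist(slices, use.names = FALSE),
        dim = c(dim(slices[[1]]), length(slices)))
}

#' Per-pixel intensity-correlation (PDM) map
#'
#' For two aligned channels (conventionally red and green) the product of
#' the differences from the mean at each pixel is
#' `PDM = (R - mean(R)) * (G - mean(G))`, with means taken over the
#' analysis mask. `PDM > 0` marks pixels whose intensities covary
#' (colocalization); `PDM < 0` marks anticorrelated pixels. The mean PDM
#' over the mask equals the (population) covariance of the two channels.
#'
#' @param channel_r,channel_g Numeric matrices of identical shape
#'   (background-subtracted projections).
#' @param mask Optional logical matrix of the same shape selecting the
#'   analysed pixels (default: all pixels). Must cover at least 2 pixels.
#' @return Object of class `"pdm_map"`: list with `pdm` (matrix, `NA`
#'   outside the mask), `mean_r`, `mean_g`, `mask`, `constant` (`TRUE` when
#'   either channel is constant over the mask, in which case the map is all
#'   zero), and `summary` (list `mean_pdm`, `fraction_positive`, `min`,
#'   `max`).
#' @examples
#' r <- matrix(c(1, 1, 3, 3), 2)
#' g <- matrix(c(1, 3, 3, 1), 2)
#' compute_pdm(r, g)$pdm
#' @export
compute_pdm <- function(channel_r, channel_g, mask = NULL) {
  stopifnot(is.matrix(channel_r), is.matrix(channel_g),
            all(dim(channel_r) == dim(channel_g)))
  if (any(!is.finite(channel_r)) || any(!is.finite(channel_g)))
    stop("intensities must be finite")
  if (is.null(mask)) mask <- matrix(TRUE, nrow(channel_r), ncol(channel_r))
  stopifnot(is.logical(mask), all(dim(mask) == dim(channel_r)))
  npx <- sum(mask)
  if (npx < 2L) stop("mask must cover at least 2 pixels")
  mean_r <- mean(channel_r[mask])
  mean_g <- mean(channel_g[mask])
  constant <- length(unique(channel_r[mask])) == 1L ||
    length(unique(channel_g[mask])) == 1L
  pdm <- (channel_r - mean_r) * (channel_g - mean_g)
  pdm[!mask] <- NA_real_
  v <- pdm[mask]
  structure(list(pdm = pdm, mean_r = mean_r, mean_g = mean_g, mask = mask,
                 constant = constant,
                 summary = list(mean_pdm = mean(v),
                                fraction_positive = mean(v > 0),
                                min = min(v), max = max(v))),
            class = "pdm_map")
}

#' @export
print.pdm_map <- function(x, ...) {
  s <- x$summary
  cat(sprintf("pdm_map: %d x %d, %d masked px\n", nrow(x$pdm), ncol(x$pdm),
              sum(x$mask)))
  cat(sprintf("  mean PDM %.4g, fraction positive %.3f, range [%.4g, %.4g]\n",
              s$mean_pdm, s$fraction_positive, s$min, s$max))
  if (x$constant) cat("  note: a channel is constant over the mask\n")
  invisible(x)
}

#' Summarise and render a PDM map
#'
#' Returns the summary record and optionally writes a false-color rendering
#' with a diverging palette (purple for PDM < 0, orange for PDM > 0)
#' symmetric about zero, limits `+/- max(|PDM|)`.
#'
#' @param map A `"pdm_map"`.
#' @param png_path Optional path; when given, a PNG rendering is written.
#' @return Data frame with `mean_pdm`, `fraction_positive`, `min`, `max`,
#'   `n_pixels`.
#' @export
pdm_summary <- function(map, png_path = NULL) {
  stopifnot(inherits(map, "pdm_map"))
  if (!is.null(png_path)) {
    grDevices::png(png_path, width = 480, height = 480)
    on.exit(grDevices::dev.off())
    plot(map)
  }
  s <- map$summary
  data.frame(mean_pdm = s$mean_pdm, fraction_positive = s$fraction_positive,
             min = s$min, max = s$max, n_pixels = sum(map$mask))
}

#' @export
plot.pdm_map <- function(x, ...) {
  lim <- max(abs(x$pdm), na.rm = TRUE)
  if (lim == 0) lim <- 1
  pal <- grDevices::colorRampPalette(c("#6a00a8", "#b58cd4", "#f5f5f5",
                                       "#f5a154", "#d95f02"))(255)
  graphics::image(x$pdm, zlim = c(-lim, lim), col = pal, axes = FALSE,
                  asp = ncol(x$pdm) / nrow(x$pdm), ...)
  invisible(x)
}

#' Read a multi-page TIFF as a stack
#'
#' @param path Path to a TIFF file.
#' @param scale Multiply intensities by this factor (default 1; `tiff`
#'   returns intensities normalised to `[0, 1]` for integer files, so pass
#'   e.g. 255 or 65535 to recover raw values).
#' @return List of matrices, one per page.
#' @export
read_tiff_stack <- function(path, scale = 1) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]  # first plane of RGB pages
    p * scale
  })
}

#' Write a stack (or matrix) as a 32-bit float multi-page TIFF
#'
#' @param stack Matrix, 3-D array or list of matrices.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_tiff_stack <- function(stack, path) {
  slices <- as_slice_list(stack)
  tiff::writeTIFF(slices, path, bits.per.sample = 32L)
  invisible(path)
}
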