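# Synthetic two-channel confocal stacks: Gaussian blobs shared between
# channels (true colocalized structure), channel-private blobs, a smooth
# background gradient and pixel noise, with a per-pixel ground-truth label.

#' Parameters for a synthetic two-channel image pair
#'
#' @param shape Image shape in pixels, `c(rows, cols)`, at least 32 x 32
#'   (default `c(64, 64)`).
#' @param n_slices Number of confocal slices (default 4).
#' @param n_shared Number of blobs present in both channels (default 4).
#' @param n_private Number of channel-private blobs per channel
#'   (default 3).
#' @param amp_shared,amp_private Peak blob amplitudes (defaults 100).
#' @param sigma_px Blob Gaussian width in pixels (default 2.5).
#' @param gradient_amp Peak-to-trough amplitude of a smooth linear
#'   background gradient (default 20).
#' @param noise_sd Gaussian pixel noise SD (default 2).
#' @return List of class `"image_sim_params"`.
#' @export
image_sim_params <- function(shape = c(64L, 64L), n_slices = 4L,
                             n_shared = 4L, n_private = 3L,
                             amp_shared = 100, amp_private = 100,
                             sigma_px = 2.5, gradient_amp = 20,
                             noise_sd = 2) {
  stopifnot(length(shape) == 2L, all(shape >= 32L), n_slices >= 1L,
            amp_shared >= 0, amp_private >= 0, sigma_px > 0,
            gradient_amp >= 0, noise_sd >= 0)
  structure(list(shape = as.integer(shape), n_slices = as.integer(n_slices),
                 n_shared = as.integer(n_shared),
                 n_private = as.integer(n_private),
                 amp_shared = amp_shared, amp_private = amp_private,
                 sigma_px = sigma_px, gradient_amp = gradient_amp,
                 noise_sd = noise_sd),
            class = "image_sim_params")
}

#' Simulate a two-channel confocal stack pair
#'
#' Blob centers are drawn uniformly inside the image (a margin of
#' `3 * sigma_px` from the borders); each blob has a Gaussian z-profile
#' across slices. Ground truth labels every pixel as `"shared"`,
#' `"private_r"`, `"private_g"` or `"background"` by proximity (within
#' `2 * sigma_px`) to the blob centers, with shared taking precedence.
#'
#' @param params An [image_sim_params()].
#' @param seed Integer seed.
#' @return List of class `"image_sim"`: `r`, `g` (lists of slice
#'   matrices), `labels` (character matrix), `centers` (data frame of blob
#'   centers and kinds), `params`, `seed`.
#' @export
simulate_image_pair <- function(params, seed = 1L) {
  stopifnot(inherits(params, "image_sim_params"))
  set.seed(seed)
  nr <- params$shape[1]; nc <- params$shape[2]; nz <- params$n_slices
  margin <- ceiling(3 * params$sigma_px)
  draw_centers <- function(n, kind) {
    if (n == 0L) return(NULL)
    data.frame(row = runif(n, margin, nr - margin),
               col = runif(n, margin, nc - margin),
               z = runif(n, 1, nz),
               kind = kind, stringsAsFactors = FALSE)
  }
  centers <- rbind(draw_centers(params$n_shared, "shared"),
                   draw_centers(params$n_private, "private_r"),
                   draw_centers(params$n_private, "private_g"))
  rowg <- matrix(seq_len(nr), nr, nc)
  colg <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  blob_xy <- function(cen)
    exp(-((rowg - cen$row)^2 + (colg - cen$col)^2) / (2 * params$sigma_px^2))
  zprof <- function(cen, z) exp(-(z - cen$z)^2 / (2 * 1.0^2))
  gradient <- params$gradient_amp * (rowg / nr + colg / nc) / 2

  make_stack <- function(kinds, amps) {
    lapply(seq_len(nz), function(z) {
      img <- gradient
      if (!is.null(centers)) {
        for (i in seq_len(nrow(centers))) {
          j <- match(centers$kind[i], kinds)
          if (is.na(j)) next
          img <- img + amps[j] * zprof(centers[i, ], z) *
            blob_xy(centers[i, ])
        }
      }
      if (params$noise_sd > 0)
        img <- img + matrix(rnorm(nr * nc, 0, params$noise_sd), nr, nc)
      pmax(img, 0)
    })
  }
  r <- make_stack(c("shared", "private_r"),
                  c(params$amp_shared, params$amp_private))
  g <- make_stack(c("shared", "private_g"),
                  c(params$amp_shared, params$amp_private))

  labels <- matrix("background", nr, nc)
  if (!is.null(centers)) {
    # private first, shared wins conflicts
    for (kind in c("private_r", "private_g", "shared")) {
      sel <- centers[centers$kind == kind, , drop = FALSE]
      for (i in seq_len(nrow(sel))) {
        near <- (rowg - sel$row[i])^2 + (colg - sel$col[i])^2 <=
          (2 * params$sigma_px)^2
        labels[near] <- kind
      }
    }
  }
  structure(list(r = r, g = g, labels = labels, centers = centers,
                 params = params, seed = seed),
            class = "image_sim")
}
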