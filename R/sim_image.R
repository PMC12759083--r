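#' Configuration for a simulated multi-channel mitochondria image
#'
#' Objects are curvilinear "mitochondria": random-walk skeletons dilated to a
#' 3-5 px width, placed without mutual contact. Three channels are rendered:
#' `MTS` (a matrix-targeted marker, labelling every object), `MMP` (a
#' membrane-potential dye, labelling only high-MMP objects) and `PINK1`
#' (per-class configurable gain). Additive Gaussian noise (clipped at 0) is
#' applied to all channels.
#'
#' @param shape image height and width in pixels, `c(h, w)`.
#' @param n_mito number of objects (>= 0).
#' @param frac_low_mmp fraction of objects with collapsed membrane potential
#'   (no MMP-dye signal), in [0, 1]; the planted count is
#'   `round(frac_low_mmp * n_mito)`.
#' @param channel_gains list with numeric `MTS`, `MMP` and a named vector
#'   `PINK1 = c(high = ..., low = ...)` giving the per-class PINK1 intensity.
#' @param noise_sd additive Gaussian noise SD (>= 0; default 2).
#' @param walk_steps skeleton length in steps (default 40).
#' @param widths admissible object widths in px; each object samples one
#'   (odd values; default c(3, 5)).
#' @param seed integer seed; required.
#' @return an object of class `image_sim_config`.
#' @export
image_sim_config <- function(shape = c(256L, 256L), n_mito = 30L,
                             frac_low_mmp = 0,
                             channel_gains = list(MTS = 200, MMP = 200,
                                                  PINK1 = c(high = 100, low = 100)),
                             noise_sd = 2, walk_steps = 40L,
                             widths = c(3L, 5L), seed) {
  if (!is.numeric(shape) || length(shape) != 2L || any(shape < 16))
    stop_config("'shape' must be c(h, w) with both >= 16")
  n_mito <- check_count(n_mito, "n_mito", min = 0L)
  frac <- check_number(frac_low_mmp, "frac_low_mmp", lower = 0, upper = 1)
  if (!is.list(channel_gains) || !all(c("MTS", "MMP", "PINK1") %in% names(channel_gains)))
    stop_config("'channel_gains' must provide MTS, MMP and PINK1")
  pg <- channel_gains$PINK1
  if (!is.numeric(pg) || !all(c("high", "low") %in% names(pg)))
    stop_config("channel_gains$PINK1 must be c(high = ..., low = ...)")
  if (!is.numeric(widths) || !length(widths) || any(widths %% 2 != 1) || any(widths < 1))
    stop_config("'widths' must be odd positive pixel widths")
  structure(list(shape = as.integer(shape), n_mito = n_mito, frac_low_mmp = frac,
                 channel_gains = channel_gains,
                 noise_sd = check_number(noise_sd, "noise_sd", lower = 0),
                 walk_steps = check_count(walk_steps, "walk_steps", min = 2L),
                 widths = as.integer(widths), seed = check_seed(seed)),
            class = "image_sim_config")
}

#' A named multi-channel image stack on a common pixel grid
#'
#' @param channels named list of numeric matrices, all of identical dimension.
#' @param rois optional list of polygon ROIs (2-column `(x, y)` = (col, row)
#'   vertex matrices), all vertices inside the frame.
#' @return an object of class `image_stack`.
#' @export
image_stack <- function(channels, rois = NULL) {
  if (!is.list(channels) || !length(channels) || is.null(names(channels)))
    stop_input("'channels' must be a non-empty named list of matrices")
  dims <- unique(lapply(channels, dim))
  if (length(dims) != 1L || is.null(dims[[1]]))
    stop_input("all channels must be matrices of identical dimension")
  h <- dims[[1]][1]; w <- dims[[1]][2]
  if (!is.null(rois)) {
    for (p in rois) {
      p <- as.matrix(p)
      if (ncol(p) != 2L || any(p[, 1] < 1) || any(p[, 1] > w) ||
          any(p[, 2] < 1) || any(p[, 2] > h))
        stop_input("ROI polygon vertices must lie inside the frame")
    }
  }
  structure(list(channels = channels, rois = rois, dim = c(h, w)),
            class = "image_stack")
}

# Chebyshev-disk offsets for dilating a skeleton to width 2r+1.
dilate_offsets <- function(r) {
  g <- expand.grid(dr = -r:r, dc = -r:r)
  g
}

# Dilate a set of (row, col) pixels by radius r, clipped to the frame.
dilate_pixels <- function(rc, r, h, w) {
  off <- dilate_offsets(r)
  rows <- rep(rc[, 1], each = nrow(off)) + off$dr
  cols <- rep(rc[, 2], each = nrow(off)) + off$dc
  keep <- rows >= 1 & rows <= h & cols >= 1 & cols <= w
  unique(cbind(rows[keep], cols[keep]))
}

#' Simulate a multi-channel image of curvilinear mitochondria
#'
#' @param config an [image_sim_config()].
#' @return list with `stack` (an [image_stack()] with channels MTS, MMP,
#'   PINK1) and `truth` (per-object MMP class and pixel sets).
#' @details Raises a generation error if the requested objects cannot be
#'   placed without contact (frame capacity exceeded).
#' @export
simulate_cell_image <- function(config) {
  if (!inherits(config, "image_sim_config"))
    stop_config("'config' must be created by image_sim_config()")
  h <- config$shape[1]; w <- config$shape[2]
  r_max <- (max(config$widths) - 1) / 2
  approx_area <- config$walk_steps * max(config$widths)
  if (config$n_mito * approx_area > 0.4 * h * w)
    stop_generation("n_mito = %d exceeds the capacity of a %dx%d frame",
                    config$n_mito, h, w)

  n_low <- round(config$frac_low_mmp * config$n_mito)
  sim <- with_sim_seed(config$seed, {
    classes <- sample(rep(c("low", "high"),
                          c(n_low, config$n_mito - n_low)))
    occupied <- matrix(FALSE, h, w)   # objects dilated by +1 px, to keep
    pixel_sets <- vector("list", config$n_mito)  # objects 8-disconnected
    margin <- r_max + 2
    for (k in seq_len(config$n_mito)) {
      placed <- FALSE
      for (attempt in seq_len(60L)) {
        width <- sample(config$widths, 1L)
        r <- (width - 1) / 2
        pos <- c(stats::runif(1, margin, h - margin),
                 stats::runif(1, margin, w - margin))
        theta <- stats::runif(1, 0, 2 * pi)
        pts <- matrix(NA_real_, config$walk_steps, 2)
        for (s in seq_len(config$walk_steps)) {
          pts[s, ] <- pos
          theta <- theta + stats::rnorm(1, 0, 0.3)
          pos <- pos + c(sin(theta), cos(theta))
          pos <- pmin(pmax(pos, margin), c(h, w) - margin)
        }
        rc <- unique(cbind(round(pts[, 1]), round(pts[, 2])))
        body <- dilate_pixels(rc, r, h, w)
        buffer <- dilate_pixels(rc, r + 1, h, w)
        if (!any(occupied[buffer])) {
          occupied[buffer] <- TRUE
          pixel_sets[[k]] <- body[, 1] + (body[, 2] - 1) * h
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop_generation("could not place object %d without contact; frame too crowded", k)
    }
    noise <- function() matrix(stats::rnorm(h * w, 0, config$noise_sd), h, w)
    list(classes = classes, pixel_sets = pixel_sets,
         noise = if (config$noise_sd > 0)
           list(MTS = noise(), MMP = noise(), PINK1 = noise()) else NULL)
  })

  render <- function(gain_per_object) {
    img <- matrix(0, h, w)
    for (k in seq_len(config$n_mito))
      img[sim$pixel_sets[[k]]] <- gain_per_object[k]
    img
  }
  g <- config$channel_gains
  n_obj <- config$n_mito
  chans <- list(
    MTS = render(rep(g$MTS, length.out = max(n_obj, 1))[seq_len(n_obj)]),
    MMP = render(ifelse(sim$classes == "high", g$MMP, 0)),
    PINK1 = render(unname(g$PINK1[sim$classes]))
  )
  if (!is.null(sim$noise))
    chans <- Map(function(ch, nz) pmax(ch + nz, 0), chans, sim$noise)

  truth <- list(
    objects = data.frame(object_id = seq_len(n_obj),
                         mmp_class = if (n_obj) sim$classes else character(),
                         area_px = if (n_obj) lengths(sim$pixel_sets) else integer(),
                         stringsAsFactors = FALSE),
    pixel_sets = sim$pixel_sets,
    config = config
  )
  structure(list(stack = image_stack(chans), truth = truth),
            class = "image_sim")
}
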