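#' @title Mask-based per-mitochondrion quantification
#' @name image_quant
#' @description Fixed-threshold mask construction on 8-bit-rescaled channels,
#'   union/subtraction partition of the mitochondrial mask by membrane
#'   potential, per-ROI channel intensities over connected components, and
#'   the pixel-randomization colocalization statistic "R over background".
NULL

# Rasterize a polygon ROI to a logical pixel mask. Pixel (row i, col j) has
# center (x = j, y = i); NULL selects the whole frame.
roi_pixel_mask <- function(dim, roi) {
  h <- dim[1]; w <- dim[2]
  if (is.null(roi)) return(matrix(TRUE, h, w))
  roi <- as.matrix(roi)
  if (ncol(roi) != 2L || nrow(roi) < 3L || polygon_area(roi) <= 0)
    stop_input("ROI polygon is degenerate")
  xs <- rep(seq_len(w), each = h)
  ys <- rep(seq_len(h), times = w)
  matrix(points_in_polygon(xs, ys, roi), h, w)
}

# Linear min-max rescale to 8-bit integers (min -> 0, max -> 255);
# a constant image maps to all zeros.
to_eight_bit <- function(mat) {
  rng <- range(mat)
  if (rng[2] == rng[1]) return(matrix(0L, nrow(mat), ncol(mat)))
  matrix(as.integer(round((mat - rng[1]) / (rng[2] - rng[1]) * 255)),
         nrow(mat), ncol(mat))
}

#' Build the threshold masks and the membrane-potential partition
#'
#' Each requested channel is cropped to the cell ROI (outside set to 0),
#' linearly rescaled to 8 bits per channel, and thresholded inclusively at
#' `threshold` (default `c(80, 255)`). The partition follows the published
#' macro verbatim: `mito_mask` is the union of the MTS and MMP-dye masks,
#' `partition_a = mito_mask` minus the MMP-dye mask (the macro labels this
#' "high MMP"), and `partition_b` is the remainder (macro label "low MMP").
#' Note the dye marks polarized mitochondria, so under dye logic
#' `partition_a` holds the objects *without* membrane potential; the macro's
#' labels are kept as printed and recorded in the `labels` field.
#'
#' @param stack an [image_stack()] with the MTS and MMP channels.
#' @param cell_roi polygon ROI (2-column `(x, y)` matrix) or NULL for the
#'   whole frame.
#' @param threshold inclusive 8-bit mask window `c(lo, hi)` (default 80, 255).
#' @param mts_channel,mmp_channel channel names (defaults "MTS", "MMP").
#' @return object of class `mask_set` with logical masks `mts_mask`,
#'   `mmp_mask`, `mito_mask`, `partition_a`, `partition_b`, plus `roi` and
#'   `labels`.
#' @export
make_masks <- function(stack, cell_roi = NULL, threshold = c(80, 255),
                       mts_channel = "MTS", mmp_channel = "MMP") {
  if (!inherits(stack, "image_stack")) stop_input("'stack' must be an image_stack")
  for (ch in c(mts_channel, mmp_channel))
    if (!ch %in% names(stack$channels)) stop_input("missing channel '%s'", ch)
  if (!is.numeric(threshold) || length(threshold) != 2L ||
      threshold[1] > threshold[2] || threshold[1] < 0 || threshold[2] > 255)
    stop_input("'threshold' must be c(lo, hi) within [0, 255]")
  roi <- roi_pixel_mask(stack$dim, cell_roi)
  if (!any(roi)) stop_input("ROI selects no pixels")
  channel_mask <- function(ch) {
    v <- stack$channels[[ch]]
    v[!roi] <- 0
    q <- to_eight_bit(v)
    q >= threshold[1] & q <= threshold[2] & roi
  }
  mts <- channel_mask(mts_channel)
  mmp <- channel_mask(mmp_channel)
  mito <- mts | mmp
  part_a <- mito & !mmp
  part_b <- mito & !part_a
  structure(list(mts_mask = mts, mmp_mask = mmp, mito_mask = mito,
                 partition_a = part_a, partition_b = part_b,
                 roi = roi, threshold = threshold,
                 labels = c(partition_a = "high_mmp", partition_b = "low_mmp")),
            class = "mask_set")
}

#' Label connected components (8-connectivity)
#'
#' Iterative minimum-label propagation over the 8-neighborhood; labels are
#' relabelled consecutively from 1 in first-pixel order.
#'
#' @param mask logical matrix.
#' @return integer matrix of component labels (0 = background).
#' @export
label_components <- function(mask) {
  if (!is.logical(mask) || !is.matrix(mask)) stop_input("'mask' must be a logical matrix")
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(Inf, h, w)
  lab[mask] <- seq_len(sum(mask))
  if (!any(mask)) return(matrix(0L, h, w))
  shift <- function(m, dr, dc) {
    out <- matrix(Inf, h, w)
    rs <- max(1, 1 + dr):min(h, h + dr)
    cs <- max(1, 1 + dc):min(w, w + dc)
    out[rs, cs] <- m[rs - dr, cs - dc, drop = FALSE]
    out
  }
  repeat {
    nb <- lab
    for (dr in -1:1) for (dc in -1:1)
      if (dr || dc) nb <- pmin(nb, shift(lab, dr, dc))
    nb[!mask] <- Inf
    new <- pmin(lab, nb)
    if (identical(new, lab)) break
    lab <- new
  }
  out <- matrix(0L, h, w)
  ids <- lab[mask]
  # consecutive relabel in order of first appearance (column-major scan)
  out[mask] <- as.integer(match(ids, unique(ids)))
  out
}

#' Per-ROI channel intensities over the partition masks
#'
#' Connected components (8-connectivity) of each partition become ROIs; per
#' ROI, the mean *raw* (pre-quantization) intensity of every channel and the
#' pixel area are reported.
#'
#' @param stack the [image_stack()] the masks were derived from.
#' @param masks a [make_masks()] result.
#' @return data frame (`partition`, `roi_id`, `area_px`, one `mean_<channel>`
#'   column per channel); zero rows if both partitions are empty.
#' @export
roi_intensities <- function(stack, masks) {
  if (!inherits(stack, "image_stack")) stop_input("'stack' must be an image_stack")
  if (!inherits(masks, "mask_set")) stop_input("'masks' must be a mask_set")
  one_partition <- function(mask, label) {
    lab <- label_components(mask)
    n <- max(lab)
    if (n == 0L) return(NULL)
    idx <- split(which(lab > 0), lab[lab > 0])
    rows <- lapply(seq_len(n), function(k) {
      px <- idx[[as.character(k)]]
      means <- vapply(stack$channels, function(ch) mean(ch[px]), numeric(1))
      names(means) <- paste0("mean_", names(stack$channels))
      cbind(data.frame(partition = label, roi_id = k, area_px = length(px),
                       stringsAsFactors = FALSE),
            as.data.frame(as.list(means)))
    })
    do.call(rbind, rows)
  }
  out <- rbind(one_partition(masks$partition_a, "a"),
               one_partition(masks$partition_b, "b"))
  if (is.null(out)) {
    cols <- c(list(partition = character(), roi_id = integer(), area_px = integer()),
              stats::setNames(rep(list(numeric()), length(stack$channels)),
                              paste0("mean_", names(stack$channels))))
    out <- do.call(data.frame, c(cols, stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

# Shuffle square blocks of a matrix (Costes-style): the largest grid of
# full blocks is permuted; margin pixels keep their values.
shuffle_blocks <- function(mat, block) {
  h <- nrow(mat); w <- ncol(mat)
  bh <- h %/% block; bw <- w %/% block
  if (bh * bw < 2L) return(matrix(sample(mat), h, w))
  H <- bh * block; W <- bw * block
  i <- rep(seq_len(H), times = W); j <- rep(seq_len(W), each = H)
  br <- (i - 1L) %/% block; bc <- (j - 1L) %/% block
  oi <- (i - 1L) %% block; oj <- (j - 1L) %% block
  bid <- br + bh * bc + 1L
  perm <- sample.int(bh * bw)
  src_br <- (perm[bid] - 1L) %% bh
  src_bc <- (perm[bid] - 1L) %/% bh
  src <- (src_br * block + oi + 1L) + H * (src_bc * block + oj)
  out <- mat
  out[cbind(i, j)] <- mat[, seq_len(W), drop = FALSE][seq_len(H), , drop = FALSE][src]
  out
}

#' Pearson colocalization above a pixel-randomized background
#'
#' Computes the Pearson coefficient of two channels over the in-ROI pixels
#' (`r_obs`) and over `n_rand` control images in which the second channel is
#' randomized, and returns `r_obs` minus the mean control coefficient
#' ("R over background"). The default randomization transposes square pixel
#' blocks (block size = the estimated object width, default 5 px), preserving
#' local texture; `method = "pixel"` shuffles individual in-ROI pixels.
#'
#' @param stack an [image_stack()], or NULL if `ch1`/`ch2` are matrices.
#' @param ch1,ch2 channel names in `stack`, or numeric matrices.
#' @param cell_roi polygon ROI or NULL for the whole frame.
#' @param n_rand number of randomized controls (default 20).
#' @param block block size in pixels for the block shuffle (default 5).
#' @param method `"block"` (default) or `"pixel"`.
#' @param seed integer seed; required (the statistic is stochastic).
#' @return object of class `coloc_result`: `r_obs`, `r_rand_mean`,
#'   `r_over_background = r_obs - r_rand_mean`, `n_rand`, `method`, `seed`.
#' @export
coloc_r_over_background <- function(stack = NULL, ch1, ch2, cell_roi = NULL,
                                    n_rand = 20L, block = 5L,
                                    method = c("block", "pixel"), seed) {
  method <- match.arg(method)
  n_rand <- check_count(n_rand, "n_rand")
  block <- check_count(block, "block")
  seed <- check_seed(seed)
  get_channel <- function(ch, name) {
    if (is.matrix(ch)) return(ch)
    if (is.null(stack) || !inherits(stack, "image_stack"))
      stop_input("'%s' is a channel name but 'stack' is not an image_stack", name)
    if (!ch %in% names(stack$channels)) stop_input("missing channel '%s'", ch)
    stack$channels[[ch]]
  }
  m1 <- get_channel(ch1, "ch1"); m2 <- get_channel(ch2, "ch2")
  if (!identical(dim(m1), dim(m2))) stop_input("channels must share dimensions")
  roi <- roi_pixel_mask(dim(m1), cell_roi)
  x <- m1[roi]; y <- m2[roi]
  if (length(x) < 3L) stop_input("ROI selects fewer than 3 pixels")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_stat("constant channel inside the ROI; Pearson undefined")
  r_obs <- pearson_r(x, y)
  r_rand <- with_sim_seed(seed, vapply(seq_len(n_rand), function(i) {
    if (method == "pixel") {
      pearson_r(x, sample(y))
    } else {
      y_s <- shuffle_blocks(m2, block)
      pearson_r(x, y_s[roi])
    }
  }, numeric(1)))
  r_rand_mean <- mean(r_rand)
  structure(list(r_obs = r_obs, r_rand_mean = r_rand_mean,
                 r_over_background = r_obs - r_rand_mean,
                 n_rand = n_rand, method = method, block = block, seed = seed),
            class = "coloc_result")
}
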