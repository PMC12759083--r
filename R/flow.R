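#' @title Single-cell flow-cytometry statistics
#' @name flow_stats
#' @description Reporter statistics computed from event tables: MFN2-Halo
#'   degradation, control-normalized channel intensities, MitoLite
#'   membrane-potential normalization, mt-Keima mitophagy gating with
#'   spillover compensation, and the PINK1 x MMP quadrant analysis.
NULL

check_events <- function(events, channels, what = "events") {
  if (!is.data.frame(events)) stop_input("'%s' must be a data frame", what)
  missing_ch <- setdiff(channels, names(events))
  if (length(missing_ch))
    stop_input("'%s' lacks channel(s): %s", what, paste(missing_ch, collapse = ", "))
  for (ch in channels)
    if (!is.numeric(events[[ch]]) || !all(is.finite(events[[ch]])))
      stop_input("channel '%s' in '%s' must be finite numeric", ch, what)
  invisible(TRUE)
}

pop_stat <- function(x, stat = c("mean", "median")) {
  stat <- match.arg(stat)
  if (stat == "mean") mean(x) else stats::median(x)
}

#' Percent reporter degradation between marker-positive and -negative cells
#'
#' Implements, exactly as printed, the degradation statistic
#' \deqn{100 (normint^{+} - normint^{-}) / normint^{+}}
#' where `normint` is the population average of the reporter channel divided
#' by the corresponding control-guide average. Note the sign convention: when
#' the marker-positive (Parkin-expressing) population loses reporter signal,
#' the statistic is negative.
#'
#' @param parkin_pos,parkin_neg event tables for the marker-positive and
#'   -negative populations; both must be non-empty.
#' @param ctrl_pos_mean,ctrl_neg_mean average raw reporter intensity of the
#'   control-guide samples for each population (> 0).
#' @param channel reporter channel name (default "MFN2").
#' @param stat population average: "mean" (default, the raw-intensity
#'   average) or "median".
#' @return degradation in percent.
#' @export
mfn2_degradation <- function(parkin_pos, parkin_neg, ctrl_pos_mean, ctrl_neg_mean,
                             channel = "MFN2", stat = "mean") {
  check_events(parkin_pos, channel, "parkin_pos")
  check_events(parkin_neg, channel, "parkin_neg")
  if (nrow(parkin_pos) == 0L || nrow(parkin_neg) == 0L)
    stop_input("both event sets must be non-empty")
  if (!is.numeric(ctrl_pos_mean) || length(ctrl_pos_mean) != 1L || ctrl_pos_mean <= 0 ||
      !is.numeric(ctrl_neg_mean) || length(ctrl_neg_mean) != 1L || ctrl_neg_mean <= 0)
    stop_input("control means must be single positive numbers")
  ni_pos <- pop_stat(parkin_pos[[channel]], stat) / ctrl_pos_mean
  ni_neg <- pop_stat(parkin_neg[[channel]], stat) / ctrl_neg_mean
  100 * (ni_pos - ni_neg) / ni_pos
}

#' Control-normalized channel intensity
#'
#' The sample's average channel intensity divided by the average of the
#' control-replicate intensities (e.g. PINK1-YFP or MTS-mCherry normalized to
#' control guides, or TMRE normalized to the untreated condition).
#'
#' @param sample event table.
#' @param channel channel name.
#' @param ctrl_means numeric vector of control replicate averages (non-empty,
#'   positive mean).
#' @param stat population average: "mean" (default) or "median".
#' @return normalized intensity (control-relative, unitless).
#' @export
normalize_channel <- function(sample, channel, ctrl_means, stat = "mean") {
  check_events(sample, channel, "sample")
  if (nrow(sample) == 0L) stop_input("'sample' must be non-empty")
  if (!is.numeric(ctrl_means) || !length(ctrl_means) || mean(ctrl_means) <= 0)
    stop_input("'ctrl_means' must be non-empty with positive mean")
  pop_stat(sample[[channel]], stat) / mean(ctrl_means)
}

mitolite_within <- function(events, channel, positive_col, stat) {
  check_events(events, channel)
  if (!positive_col %in% names(events) || !is.logical(events[[positive_col]]))
    stop_input("events need a logical '%s' column", positive_col)
  pos <- events[[positive_col]]
  if (!any(pos) || !any(!pos))
    stop_input("both marker-positive and marker-negative events are required")
  pop_stat(events[[channel]][pos], stat) / pop_stat(events[[channel]][!pos], stat)
}

#' Two-step within-sample MitoLite membrane-potential normalization
#'
#' Step 1 divides the marker-positive population's average dye intensity by
#' the marker-negative population's (within-sample normalization, controlling
#' well-to-well staining variability); step 2 divides that ratio by the
#' average of the same ratio over the control-guide samples.
#'
#' @param sample event table with the dye channel and a logical marker column.
#' @param ctrl_samples list of control event tables with the same columns.
#' @param channel dye channel name (default "MitoLite").
#' @param positive_col logical column marking transduced cells
#'   (default "positive").
#' @param stat population average: "mean" (default) or "median".
#' @return control-relative normalized membrane-potential value.
#' @export
mitolite_normalize <- function(sample, ctrl_samples, channel = "MitoLite",
                               positive_col = "positive", stat = "mean") {
  if (!is.list(ctrl_samples) || !length(ctrl_samples))
    stop_input("'ctrl_samples' must be a non-empty list of event tables")
  within_sample <- mitolite_within(sample, channel, positive_col, stat)
  within_ctrl <- vapply(ctrl_samples, mitolite_within, numeric(1),
                        channel = channel, positive_col = positive_col, stat = stat)
  within_sample / mean(within_ctrl)
}

#' A flow-cytometry gate
#'
#' @param kind `"polygon"` (vertex list in channel units) or `"threshold"`
#'   (a single cut on one channel; events at or above the cut are inside).
#' @param channels channel name(s): two for a polygon (x then y), one for a
#'   threshold.
#' @param vertices 2-column matrix of polygon vertices (polygon kind); must
#'   enclose a positive area.
#' @param cut numeric threshold (threshold kind).
#' @return an object of class `gate_spec`.
#' @export
gate_spec <- function(kind = c("polygon", "threshold"), channels,
                      vertices = NULL, cut = NULL) {
  kind <- match.arg(kind)
  if (kind == "polygon") {
    if (length(channels) != 2L) stop_input("polygon gates need two channels (x, y)")
    vertices <- as.matrix(vertices)
    if (is.null(vertices) || ncol(vertices) != 2L || nrow(vertices) < 3L ||
        polygon_area(vertices) <= 0)
      stop_input("polygon gate is degenerate (area must be > 0)")
  } else {
    if (length(channels) != 1L || !is.numeric(cut) || length(cut) != 1L)
      stop_input("threshold gates need one channel and a single numeric cut")
  }
  structure(list(kind = kind, channels = channels, vertices = vertices, cut = cut),
            class = "gate_spec")
}

gate_contains <- function(gate, events) {
  if (gate$kind == "threshold")
    events[[gate$channels]] >= gate$cut
  else
    points_in_polygon(events[[gate$channels[1]]], events[[gate$channels[2]]],
                      gate$vertices)
}

#' mt-Keima mitophagy fraction with spillover compensation
#'
#' The neutral-mKeima channel (ex488-em611) is corrected for spillover from
#' the ex488-em528 channel: `corrected = ex488em611 - spillover * ex488em528`,
#' floored at 0 (default spillover 0.10). The mitophagy fraction is the
#' percentage of events inside the gate drawn on the (corrected neutral,
#' acidic) plane, where the acidic channel is ex561-em611.
#'
#' @param sample event table with channels `ex488em611`, `ex561em611`,
#'   `ex488em528` (names configurable via `channels`).
#' @param gate a polygon [gate_spec()] on channels `c("neutral", "acidic")`.
#' @param spillover spillover fraction in [0, 1) (default 0.10).
#' @param channels named vector mapping roles `neutral`, `acidic`, `yfp` to
#'   column names.
#' @return percent of events in the mitophagy gate, in [0, 100].
#' @export
keima_mitophagy_fraction <- function(sample, gate, spillover = 0.10,
                                     channels = c(neutral = "ex488em611",
                                                  acidic = "ex561em611",
                                                  yfp = "ex488em528")) {
  check_events(sample, unname(channels), "sample")
  if (nrow(sample) == 0L) stop_input("'sample' must be non-empty")
  spillover <- check_number(spillover, "spillover", lower = 0, upper = 1,
                            strict_upper = TRUE)
  if (!inherits(gate, "gate_spec") || gate$kind != "polygon")
    stop_input("'gate' must be a polygon gate_spec")
  corrected <- pmax(sample[[channels["neutral"]]] -
                      spillover * sample[[channels["yfp"]]], 0)
  plane <- data.frame(neutral = corrected, acidic = sample[[channels["acidic"]]])
  g <- gate
  g$channels <- c("neutral", "acidic")
  100 * mean(gate_contains(g, plane))
}

#' PINK1 x MMP quadrant analysis with guide-negative normalization
#'
#' The guide-negative reference population of each sample (events below both
#' the PINK1 cutoff and the BFP cutoff, i.e. non-transduced cells) yields a
#' per-sample "normalization factor": its mean MitoLite intensity divided by
#' the same quantity in the control sample. Every event's MitoLite value is
#' divided by that factor (PINK1 values are untouched) and events are then
#' partitioned by the fixed cutoffs; events exactly at a cutoff count as
#' "high".
#'
#' The PINK1 cutoff is in raw channel units. The MitoLite cutoff is in
#' control-relative units: 1.0 equals the control sample's guide-negative
#' reference mean (the normalized data's natural scale). This makes the
#' MMP split equal to `raw / sample_reference_mean >= cut` and therefore
#' invariant to any common rescaling of the MitoLite channel — fixed raw
#' cutoffs would silently depend on detector gain.
#'
#' @param sample,ctrl event tables containing the PINK1, MitoLite and BFP
#'   channels.
#' @param cutoffs numeric `c(pink1 = ..., mitolite = ...)` quadrant cutoffs
#'   (> 0), shared across samples; the MitoLite cut is control-relative (see
#'   above).
#' @param bfp_cut BFP cutoff defining guide-negative events.
#' @param channels named vector mapping roles `pink1`, `mitolite`, `bfp` to
#'   column names.
#' @return object of class `quadrant_result`: fractions `q_ll`, `q_lh`,
#'   `q_hl`, `q_hh` (PINK1 state first, MMP state second; they sum to 1),
#'   the cutoffs and the normalization factor applied.
#' @export
quadrant_analysis <- function(sample, ctrl, cutoffs, bfp_cut,
                              channels = c(pink1 = "PINK1_YFP",
                                           mitolite = "MitoLite",
                                           bfp = "BFP")) {
  check_events(sample, unname(channels), "sample")
  check_events(ctrl, unname(channels), "ctrl")
  if (!is.numeric(cutoffs) || length(cutoffs) != 2L || any(cutoffs <= 0))
    stop_input("'cutoffs' must be two positive numbers (pink1, mitolite)")
  pink1_cut <- unname(cutoffs[1]); mmp_cut <- unname(cutoffs[2])
  ref_mean <- function(ev, what) {
    ref <- ev[[channels["pink1"]]] < pink1_cut & ev[[channels["bfp"]]] < bfp_cut
    if (!any(ref))
      stop_input("empty guide-negative reference population in '%s' (PINK1 < %g & BFP < %g)",
                 what, pink1_cut, bfp_cut)
    mean(ev[[channels["mitolite"]]][ref])
  }
  ref_ctrl <- ref_mean(ctrl, "ctrl")
  norm_factor <- ref_mean(sample, "sample") / ref_ctrl
  mmp <- sample[[channels["mitolite"]]] / norm_factor
  pink1 <- sample[[channels["pink1"]]]
  hi_p <- pink1 >= pink1_cut          # boundary -> high
  hi_m <- mmp >= mmp_cut * ref_ctrl   # MitoLite cut is control-relative
  n <- nrow(sample)
  if (n == 0L) stop_input("'sample' must be non-empty")
  res <- list(q_ll = sum(!hi_p & !hi_m) / n,
              q_lh = sum(!hi_p & hi_m) / n,
              q_hl = sum(hi_p & !hi_m) / n,
              q_hh = sum(hi_p & hi_m) / n,
              cutoffs = c(pink1 = pink1_cut, mitolite = mmp_cut),
              bfp_cut = bfp_cut,
              norm_factor = norm_factor)
  structure(res, class = "quadrant_result")
}
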