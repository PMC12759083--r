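#' Configuration for a simulated flow-cytometry sample
#'
#' Events are drawn from a two-component mixture: a marker-positive
#' subpopulation (e.g. guide-transduced or Parkin-expressing cells) and a
#' marker-negative one. Each channel is lognormal within each subpopulation.
#'
#' `true_degradation_pct` plants a known value for the reporter-degradation
#' estimator: the marker-negative subpopulation's `degradation_channel` mean
#' is scaled by (1 - d/100), so that the degradation formula
#' 100 * (normint+ - normint-) / normint+ (see [mfn2_degradation()]) recovers
#' +d when the control sample is generated with d = 0. Note the printed
#' formula itself is signed: it returns negative values when the
#' marker-positive population loses reporter signal.
#'
#' @param n_events number of events (> 0).
#' @param channel_params named list, one entry per channel; each entry a list
#'   with `pos` and `neg` numeric vectors `c(meanlog, sdlog)` (natural-log
#'   scale, sdlog > 0) for the two subpopulations.
#' @param frac_guide_positive expected marker-positive fraction, in (0, 1).
#' @param true_degradation_pct planted degradation percentage (< 100).
#' @param degradation_channel channel the planted degradation applies to
#'   (default "MFN2"; ignored if absent from `channel_params`).
#' @param seed integer seed; required.
#' @return an object of class `flow_sim_config`.
#' @export
flow_sim_config <- function(n_events,
                            channel_params = list(
                              MFN2 = list(pos = c(meanlog = 6, sdlog = 0.5),
                                          neg = c(meanlog = 6, sdlog = 0.5))),
                            frac_guide_positive = 0.5,
                            true_degradation_pct = 0,
                            degradation_channel = "MFN2", seed) {
  n_events <- check_count(n_events, "n_events")
  frac <- check_number(frac_guide_positive, "frac_guide_positive",
                       lower = 0, upper = 1, strict_lower = TRUE, strict_upper = TRUE)
  d <- check_number(true_degradation_pct, "true_degradation_pct",
                    upper = 100, strict_upper = TRUE)
  if (!is.list(channel_params) || !length(channel_params) ||
      is.null(names(channel_params)) || any(!nzchar(names(channel_params))))
    stop_config("'channel_params' must be a non-empty named list of channels")
  for (ch in names(channel_params)) {
    p <- channel_params[[ch]]
    if (!is.list(p) || !all(c("pos", "neg") %in% names(p)))
      stop_config("channel '%s' must have 'pos' and 'neg' (meanlog, sdlog) entries", ch)
    for (side in c("pos", "neg")) {
      v <- p[[side]]
      if (!is.numeric(v) || length(v) != 2L || anyNA(v) || v[2] <= 0)
        stop_config("channel '%s' %s must be c(meanlog, sdlog) with sdlog > 0", ch, side)
    }
  }
  structure(list(n_events = n_events, channel_params = channel_params,
                 frac_guide_positive = frac, true_degradation_pct = d,
                 degradation_channel = degradation_channel,
                 seed = check_seed(seed)),
            class = "flow_sim_config")
}

#' Simulate a single-cell flow-cytometry event table with known ground truth
#'
#' @param config a [flow_sim_config()].
#' @return list with `events` (data frame: `event_id`, logical `positive`,
#'   one numeric column per channel) and `truth` (planted degradation
#'   percentage, expected positive fraction, per-event membership).
#' @export
simulate_flow_sample <- function(config) {
  if (!inherits(config, "flow_sim_config"))
    stop_config("'config' must be created by flow_sim_config()")
  n <- config$n_events
  out <- with_sim_seed(config$seed, {
    positive <- stats::runif(n) < config$frac_guide_positive
    cols <- lapply(names(config$channel_params), function(ch) {
      p <- config$channel_params[[ch]]
      ml <- ifelse(positive, p$pos[1], p$neg[1])
      sl <- ifelse(positive, p$pos[2], p$neg[2])
      if (identical(ch, config$degradation_channel) && config$true_degradation_pct != 0)
        ml[!positive] <- ml[!positive] + log(1 - config$true_degradation_pct / 100)
      stats::rlnorm(n, meanlog = ml, sdlog = sl)
    })
    names(cols) <- names(config$channel_params)
    list(positive = positive, cols = cols)
  })
  events <- data.frame(event_id = seq_len(n), positive = out$positive,
                       out$cols, stringsAsFactors = FALSE, check.names = FALSE)
  truth <- list(
    true_degradation_pct = config$true_degradation_pct,
    frac_guide_positive = config$frac_guide_positive,
    events = data.frame(event_id = seq_len(n), positive = out$positive),
    config = config
  )
  structure(list(events = events, truth = truth), class = "flow_sim")
}
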