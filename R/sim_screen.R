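#' Configuration for a simulated FACS-bin CRISPRi screen
#'
#' Defines the generative model for one screen (one cell line x treatment):
#' each cell carries one guide; its reporter value on the log2 scale is the
#' guide's knockdown effect plus lognormal cell-to-cell noise; the top and
#' bottom `sort_fraction` of the pooled reporter distribution are sorted into
#' the high and low bins; per-guide read counts in each bin follow a negative
#' binomial with variance mu + mu^2/dispersion.
#'
#' @param n_genes number of genes in the library.
#' @param guides_per_gene guides per gene (default 5). Guide potency within a
#'   gene is heterogeneous: multiplicative efficacies 1.0, 0.8, 0.6, ...
#'   (floored at 0.2).
#' @param n_replicates sorted replicates per bin (default 2).
#' @param baseline_mean expected reads per guide per bin under no effect.
#' @param dispersion negative-binomial size parameter (> 0); variance is
#'   mu + mu^2/dispersion.
#' @param effect_table named numeric vector, gene -> reporter log2 shift for
#'   this screen condition. Names must be genes of the simulated library
#'   (`gene_00001`, ...). Unnamed genes have shift 0.
#' @param sort_fraction fraction of cells sorted into each bin, in (0, 0.5]
#'   (default 0.30, i.e. top/bottom 30%).
#' @param reporter_sd cell-to-cell reporter noise SD in log2 units (default 1).
#' @param seed integer seed; required.
#' @return an object of class `screen_sim_config`.
#' @export
screen_sim_config <- function(n_genes, guides_per_gene = 5L, n_replicates = 2L,
                              baseline_mean = 500, dispersion = 10,
                              effect_table = numeric(), sort_fraction = 0.30,
                              reporter_sd = 1, seed) {
  cfg <- list(
    n_genes = check_count(n_genes, "n_genes"),
    guides_per_gene = check_count(guides_per_gene, "guides_per_gene"),
    n_replicates = check_count(n_replicates, "n_replicates"),
    baseline_mean = check_number(baseline_mean, "baseline_mean", lower = 0, strict_lower = TRUE),
    dispersion = check_number(dispersion, "dispersion", lower = 0, strict_lower = TRUE),
    sort_fraction = check_number(sort_fraction, "sort_fraction",
                                 lower = 0, upper = 0.5, strict_lower = TRUE),
    reporter_sd = check_number(reporter_sd, "reporter_sd", lower = 0, strict_lower = TRUE),
    seed = check_seed(seed)
  )
  if (length(effect_table)) {
    if (!is.numeric(effect_table) || is.null(names(effect_table)) ||
        any(!nzchar(names(effect_table))) || anyNA(effect_table))
      stop_config("'effect_table' must be a named numeric vector of gene -> log2 shift")
    genes <- screen_sim_gene_names(cfg$n_genes)
    bad <- setdiff(names(effect_table), genes)
    if (length(bad))
      stop_config("'effect_table' names not in the simulated library: %s",
                  paste(utils::head(bad, 3), collapse = ", "))
  }
  cfg$effect_table <- effect_table
  structure(cfg, class = "screen_sim_config")
}

screen_sim_gene_names <- function(n_genes) sprintf("gene_%05d", seq_len(n_genes))

#' Simulate one FACS-bin screen with planted ground truth
#'
#' Per-guide bin membership probabilities are computed from the pooled
#' reporter mixture: the high/low cutoffs are the (1 - f) and f quantiles of
#' the mixture of per-guide normal reporter distributions, and a guide's
#' expected read count in a bin is proportional to the probability mass of its
#' reporter distribution beyond the cutoff. Counts are then drawn negative
#' binomial per replicate. A gene with reporter shift s is depleted from the
#' high bin when s < 0, so the expected log2(high/low) is monotone in s.
#'
#' @param config a [screen_sim_config()].
#' @return list with elements `high` and `low` (data frames: `guide_id`,
#'   `gene`, one integer count column per replicate) and `truth` (planted
#'   per-gene shifts and per-guide efficacies/expected means).
#' @export
simulate_screen <- function(config) {
  if (!inherits(config, "screen_sim_config"))
    stop_config("'config' must be created by screen_sim_config()")
  genes <- screen_sim_gene_names(config$n_genes)
  gpg <- config$guides_per_gene
  efficacy <- pmax(0.2, 1 - 0.2 * (seq_len(gpg) - 1))
  gene_shift <- stats::setNames(numeric(config$n_genes), genes)
  gene_shift[names(config$effect_table)] <- config$effect_table

  guide_gene <- rep(genes, each = gpg)
  guide_id <- paste0(guide_gene, "_g", rep(seq_len(gpg), times = config$n_genes))
  guide_shift <- rep(gene_shift, each = gpg) * rep(efficacy, times = config$n_genes)

  sd <- config$reporter_sd
  f <- config$sort_fraction
  mix_cdf <- function(c) mean(stats::pnorm(c, mean = guide_shift, sd = sd))
  lo_rng <- range(guide_shift) + c(-8, 8) * sd
  c_lo <- stats::uniroot(function(c) mix_cdf(c) - f, lo_rng, tol = 1e-10)$root
  c_hi <- stats::uniroot(function(c) mix_cdf(c) - (1 - f), lo_rng, tol = 1e-10)$root

  p_hi <- stats::pnorm(c_hi, mean = guide_shift, sd = sd, lower.tail = FALSE)
  p_lo <- stats::pnorm(c_lo, mean = guide_shift, sd = sd)
  mu_hi <- config$baseline_mean * p_hi / mean(p_hi)
  mu_lo <- config$baseline_mean * p_lo / mean(p_lo)

  n_guides <- length(guide_id)
  draw_bin <- function(mu) {
    m <- vapply(seq_len(config$n_replicates), function(i)
      stats::rnbinom(n_guides, mu = mu, size = config$dispersion), numeric(n_guides))
    storage.mode(m) <- "integer"
    colnames(m) <- paste0("rep_", seq_len(config$n_replicates))
    m
  }
  counts <- with_sim_seed(config$seed, list(high = draw_bin(mu_hi), low = draw_bin(mu_lo)))

  as_table <- function(m)
    data.frame(guide_id = guide_id, gene = guide_gene, m,
               stringsAsFactors = FALSE, check.names = FALSE)
  truth <- list(
    genes = data.frame(gene = genes, shift = unname(gene_shift),
                       planted = gene_shift != 0, stringsAsFactors = FALSE),
    guides = data.frame(guide_id = guide_id, gene = guide_gene,
                        efficacy = rep(efficacy, times = config$n_genes),
                        guide_shift = guide_shift,
                        mu_high = mu_hi, mu_low = mu_lo,
                        stringsAsFactors = FALSE),
    cutoffs = c(low = c_lo, high = c_hi),
    config = config
  )
  structure(list(high = as_table(counts$high), low = as_table(counts$low),
                 truth = truth), class = "screen_sim")
}
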