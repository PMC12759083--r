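#' @title FACS-bin screen scoring
#' @name screen_scoring
#' @description Turn per-screen guide count tables (high vs low sorted bins)
#'   into guide statistics, gene scores, and six-screen hit calls for the
#'   PINK1-Parkin reporter screens.
NULL

# The six screen conditions (cell line x treatment) a full hit classification
# requires. NT = not treated; AO = oligomycin + antimycin (CCCP for HEK293).
#' Canonical screen condition keys
#' @return character vector of the six screen keys.
#' @export
screen_keys <- function() c("HeLa_Parkin_NT", "HeLa_Parkin_AO",
                            "HeLa_noParkin_NT", "HeLa_noParkin_AO",
                            "HEK293_NT", "HEK293_AO")

count_matrix <- function(table, what) {
  cols <- setdiff(names(table), c("guide_id", "gene"))
  if (!length(cols)) stop_input("%s table has no count columns", what)
  m <- as.matrix(table[cols])
  if (nrow(m) == 0L) storage.mode(m) <- "integer"
  if (!is.numeric(m) || anyNA(m) || any(m < 0) || any(m != floor(m)))
    stop_input("%s table counts must be non-negative integers", what)
  rownames(m) <- table$guide_id
  m
}

check_guide_tables <- function(high, low) {
  for (tb in list(high, low))
    if (!is.data.frame(tb) || !all(c("guide_id", "gene") %in% names(tb)))
      stop_input("count tables need 'guide_id' and 'gene' columns")
  if (anyDuplicated(high$guide_id) || anyDuplicated(low$guide_id))
    stop_input("guide_id must be unique within a table")
  if (!identical(high$guide_id, low$guide_id) || !identical(high$gene, low$gene))
    stop_input("high and low tables must share an identical guide universe")
  invisible(TRUE)
}

#' Drop guides with a zero read count in any replicate of either bin
#'
#' A guide is kept only if its count is strictly positive in every replicate
#' of both the high and the low bin; row order is preserved.
#'
#' @param high,low guide count tables (`guide_id`, `gene`, one column per
#'   replicate) for the high and low sorted bins.
#' @return list with the filtered `high` and `low` tables.
#' @export
filter_zero_count_guides <- function(high, low) {
  check_guide_tables(high, low)
  keep <- rowSums(count_matrix(high, "high") == 0) == 0 &
    rowSums(count_matrix(low, "low") == 0) == 0
  list(high = high[keep, , drop = FALSE], low = low[keep, , drop = FALSE])
}

# Median-of-ratios size factors across all count columns (high and low bins
# jointly). Guides with any zero are excluded from the geometric-mean
# reference, as usual.
median_ratio_size_factors <- function(m) {
  pos <- rowSums(m == 0) == 0
  if (!any(pos)) stop_input("no guide has all-positive counts; cannot normalize")
  loggeo <- rowMeans(log(m[pos, , drop = FALSE]))
  # median taken in log space (the DESeq convention)
  apply(m[pos, , drop = FALSE], 2,
        function(col) exp(stats::median(log(col) - loggeo)))
}

#' Guide-level differential abundance between sorted bins
#'
#' A transparent stand-in for an external guide-ranking pipeline: counts are
#' size-normalized per replicate by median-of-ratios across guides; the
#' log2 fold change is `log2((mean normalized high + pc) / (mean normalized
#' low + pc))` with pseudocount `pc = 0.5`; the two-sided p-value tests the
#' replicate-level normalized log2 ratios against zero. With >= 2 replicates
#' the default test standardizes each guide's mean log-ratio by the variance
#' pooled across all guides (approximately normal under the null; a per-guide
#' Student t is available via `test = "t"`). With a single replicate, an
#' empirical two-sided p is computed against the distribution of all guides'
#' log-ratios (a guide-label permutation null).
#'
#' @param high,low filtered count tables sharing the same guide universe.
#' @param pseudocount added to normalized means before the log ratio
#'   (default 0.5).
#' @param norm `"median_ratio"` (default) or `"none"`.
#' @param test `"pooled_z"` (default), `"t"`, or `"permutation"`; single-
#'   replicate input always uses the permutation null.
#' @param bonferroni_mode passed to [bonferroni_correct()] for the `p_adj`
#'   column (`m` = number of guides tested).
#' @return data frame (`guide_id`, `gene`, `log2fc`, `p_raw`, `p_adj`,
#'   `score`) where `score = (-log10 p_adj) * log2fc`.
#' @export
guide_differential <- function(high, low, pseudocount = 0.5,
                               norm = c("median_ratio", "none"),
                               test = c("pooled_z", "t", "permutation"),
                               bonferroni_mode = c("standard", "as_printed")) {
  check_guide_tables(high, low)
  norm <- match.arg(norm)
  test <- match.arg(test)
  mh <- count_matrix(high, "high"); ml <- count_matrix(low, "low")
  if (ncol(mh) != ncol(ml)) stop_input("high and low bins must have the same replicate count")
  k <- ncol(mh)
  if (k < 1L) stop_input("at least one replicate per bin is required")
  if (nrow(mh) == 0L)
    return(data.frame(guide_id = character(), gene = character(),
                      log2fc = numeric(), p_raw = numeric(),
                      p_adj = numeric(), score = numeric()))

  if (norm == "median_ratio") {
    sf <- median_ratio_size_factors(cbind(mh, ml))
    nh <- sweep(mh, 2, sf[seq_len(k)], "/")
    nl <- sweep(ml, 2, sf[k + seq_len(k)], "/")
  } else {
    nh <- mh; nl <- ml
  }
  pc <- pseudocount
  log2fc <- log2((rowMeans(nh) + pc) / (rowMeans(nl) + pc))
  ratios <- log2((nh + pc) / (nl + pc))        # replicate-level log2 ratios

  if (k == 1L || test == "permutation") {
    r <- rowMeans(ratios)
    dev <- abs(r - stats::median(r))
    p_raw <- vapply(dev, function(d) mean(dev >= d), numeric(1))
  } else if (test == "t") {
    m <- rowMeans(ratios)
    s <- sqrt(apply(ratios, 1, stats::var) / k)
    tt <- ifelse(s > 0, m / s, 0)
    p_raw <- 2 * stats::pt(-abs(tt), df = k - 1)
  } else {
    m <- rowMeans(ratios)
    s2_pool <- mean(apply(ratios, 1, stats::var))
    if (s2_pool == 0) {
      # degenerate noiseless input: no evidence against zero where m == 0
      p_raw <- as.numeric(m != 0) * .Machine$double.xmin + as.numeric(m == 0)
    } else {
      z <- m / sqrt(s2_pool / k)
      p_raw <- 2 * stats::pnorm(-abs(z))
    }
  }
  p_adj <- bonferroni_correct(p_raw, m = length(p_raw), mode = bonferroni_mode)
  data.frame(guide_id = high$guide_id, gene = high$gene,
             log2fc = unname(log2fc), p_raw = unname(p_raw),
             p_adj = unname(p_adj),
             score = gene_score(unname(p_adj), unname(log2fc)),
             stringsAsFactors = FALSE)
}

#' Bonferroni correction over m tests
#'
#' `mode = "standard"` is the usual correction, `min(1, p * m)`.
#' `mode = "as_printed"` divides p by m instead — the direction some reports
#' describe verbatim; it makes p smaller and is exposed only for exact
#' reproduction of such a pipeline, never as a default.
#'
#' @param p_raw numeric vector of p-values in [0, 1].
#' @param m number of tests (>= 1).
#' @param mode `"standard"` (default) or `"as_printed"`.
#' @return corrected p-values.
#' @export
bonferroni_correct <- function(p_raw, m, mode = c("standard", "as_printed")) {
  mode <- match.arg(mode)
  if (!is.numeric(m) || length(m) != 1L || is.na(m) || m < 1 || m != floor(m))
    stop_input("'m' must be a single integer >= 1")
  if (!is.numeric(p_raw) || anyNA(p_raw) || any(p_raw < 0 | p_raw > 1))
    stop_input("'p_raw' must be probabilities in [0, 1]")
  if (mode == "standard") pmin(1, p_raw * m) else p_raw / m
}

#' Signed gene score: (-log10 adjusted p) x log2 fold change
#'
#' @param p_adj adjusted p-value(s) in (0, 1]; exact zeros are clamped to the
#'   smallest representable positive double with a warning.
#' @param log2fc log2 fold change(s).
#' @return numeric score(s); the sign equals the sign of `log2fc`.
#' @export
gene_score <- function(p_adj, log2fc) {
  if (!is.numeric(p_adj) || anyNA(p_adj) || any(p_adj < 0 | p_adj > 1))
    stop_input("'p_adj' must be probabilities in [0, 1]")
  if (any(p_adj == 0)) {
    warning("p_adj of 0 clamped to .Machine$double.xmin before -log10")
    p_adj <- pmax(p_adj, .Machine$double.xmin)
  }
  (-log10(p_adj)) * log2fc
}

#' Aggregate guide statistics to gene level
#'
#' `method = "best_guide_pair"` (default): the gene's sign is taken from the
#' guide with the largest absolute score (ties broken by lexicographic
#' `guide_id`); the gene log2fc is the mean of the (up to) two largest-|score|
#' guides of that sign, and the gene adjusted p is the max (most conservative)
#' of those guides' `p_adj`. `method = "mean"` takes plain means of `log2fc`
#' and `p_adj`. In both cases the gene score is recomputed as
#' `(-log10 p_adj) * log2fc` and `significant = p_adj < alpha`.
#'
#' @param stats guide statistics from [guide_differential()].
#' @param method `"best_guide_pair"` (default) or `"mean"`.
#' @param alpha gene-level significance cut (default 0.05).
#' @return data frame (`gene`, `log2fc`, `p_adj`, `score`, `significant`,
#'   `n_guides`), one row per gene with surviving guides.
#' @export
aggregate_guides_to_gene <- function(stats, method = c("best_guide_pair", "mean"),
                                     alpha = 0.05) {
  method <- match.arg(method)
  need <- c("guide_id", "gene", "log2fc", "p_adj", "score")
  if (!is.data.frame(stats) || !all(need %in% names(stats)))
    stop_input("'stats' must have columns %s", paste(need, collapse = ", "))
  split_idx <- split(seq_len(nrow(stats)), stats$gene)
  rows <- lapply(split_idx, function(idx) {
    g <- stats[idx, , drop = FALSE]
    if (method == "mean") {
      lfc <- mean(g$log2fc); padj <- mean(g$p_adj)
    } else {
      ord <- order(-abs(g$score), g$guide_id)
      g <- g[ord, , drop = FALSE]
      dom <- sign(g$score[1])
      sel <- if (dom == 0) utils::head(seq_len(nrow(g)), 2)
             else utils::head(which(sign(g$score) == dom), 2)
      lfc <- mean(g$log2fc[sel]); padj <- max(g$p_adj[sel])
    }
    data.frame(gene = g$gene[1], log2fc = lfc, p_adj = padj,
               score = gene_score(padj, lfc),
               significant = padj < alpha, n_guides = length(idx),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$gene), , drop = FALSE]
}

#' Score one screen end to end
#'
#' Convenience pipeline: zero-count filtering, guide differential with
#' Bonferroni correction over surviving guides, and guide-to-gene
#' aggregation. Genes whose guides were all filtered out are omitted and
#' their count reported via `message()`.
#'
#' @param high,low raw guide count tables for the screen's two bins.
#' @param ... passed to [guide_differential()].
#' @param method,alpha passed to [aggregate_guides_to_gene()].
#' @return gene-level score table (see [aggregate_guides_to_gene()]).
#' @export
score_screen <- function(high, low, ..., method = "best_guide_pair", alpha = 0.05) {
  filt <- filter_zero_count_guides(high, low)
  stats <- guide_differential(filt$high, filt$low, ...)
  genes_in <- unique(high$gene)
  lost <- setdiff(genes_in, unique(stats$gene))
  if (length(lost))
    message(length(lost), " gene(s) lost all guides to the zero-count filter")
  aggregate_guides_to_gene(stats, method = method, alpha = alpha)
}

#' Classify genes across the six screens
#'
#' Applies the category rules, in order of precedence:
#' \itemize{
#'   \item Parkin activator: significant in the untreated HeLa + Parkin screen,
#'     log2fc there < -1, and the difference to the untreated HeLa without
#'     Parkin log2fc is < -1.25.
#'   \item Parkin facilitator: significant in the treated HeLa + Parkin screen,
#'     log2fc there > 1, and that log2fc exceeds both the untreated
#'     HeLa + Parkin and the treated HeLa without Parkin log2fc by more than 1.
#'   \item MFN2 downregulator: significant with log2fc < -1 in both the HEK293
#'     untreated and HeLa without Parkin untreated screens, and not an
#'     activator.
#'   \item MFN2 upregulator: the symmetric rule with log2fc > 1, and not a
#'     facilitator.
#' }
#' Missing gene-level values in a screen make the corresponding condition
#' false.
#'
#' @param scores named list of gene score tables (from [score_screen()] or
#'   [aggregate_guides_to_gene()]), with names covering [screen_keys()].
#' @return data frame (`gene`, `category`) where `category` is one of
#'   `parkin_activator`, `parkin_facilitator`, `mfn2_downregulator`,
#'   `mfn2_upregulator`, `none`.
#' @export
classify_hits <- function(scores) {
  keys <- screen_keys()
  missing_keys <- setdiff(keys, names(scores))
  if (length(missing_keys))
    stop_input("missing screen key(s): %s", paste(missing_keys, collapse = ", "))
  genes <- sort(unique(unlist(lapply(scores[keys], function(s) s$gene))))
  pull <- function(key, col) {
    s <- scores[[key]]
    out <- s[[col]][match(genes, s$gene)]
    out
  }
  lfc <- do.call(cbind, lapply(keys, pull, col = "log2fc"))
  sig <- do.call(cbind, lapply(keys, pull, col = "significant"))
  colnames(lfc) <- colnames(sig) <- keys
  tf <- function(x) !is.na(x) & x   # NA -> condition not met

  act <- tf(sig[, "HeLa_Parkin_NT"]) & tf(lfc[, "HeLa_Parkin_NT"] < -1) &
    tf((lfc[, "HeLa_Parkin_NT"] - lfc[, "HeLa_noParkin_NT"]) < -1.25)
  fac <- tf(sig[, "HeLa_Parkin_AO"]) & tf(lfc[, "HeLa_Parkin_AO"] > 1) &
    tf((lfc[, "HeLa_Parkin_AO"] - lfc[, "HeLa_Parkin_NT"]) > 1) &
    tf((lfc[, "HeLa_Parkin_AO"] - lfc[, "HeLa_noParkin_AO"]) > 1)
  down <- tf(sig[, "HEK293_NT"]) & tf(sig[, "HeLa_noParkin_NT"]) &
    tf(lfc[, "HEK293_NT"] < -1) & tf(lfc[, "HeLa_noParkin_NT"] < -1) & !act
  up <- tf(sig[, "HEK293_NT"]) & tf(sig[, "HeLa_noParkin_NT"]) &
    tf(lfc[, "HEK293_NT"] > 1) & tf(lfc[, "HeLa_noParkin_NT"] > 1) & !fac

  category <- rep("none", length(genes))
  category[up] <- "mfn2_upregulator"
  category[down] <- "mfn2_downregulator"
  category[fac] <- "parkin_facilitator"
  category[act] <- "parkin_activator"
  data.frame(gene = genes, category = category, stringsAsFactors = FALSE)
}

#' Harmonize gene symbols and annotate mitochondrial localization
#'
#' Applies the fixed symbol remapping (TIMM23B -> TIMM23, HSPE1-MOB4 -> HSPE1,
#' PARK2 -> PRKN) before looking genes up in a MitoCarta-style annotation
#' table. Genes absent from the annotation get `is_mitochondrial = FALSE`;
#' their count is reported via `message()`.
#'
#' @param calls hit-call table with a `gene` column (e.g. [classify_hits()]).
#' @param mitocarta data frame with a `gene` column and optionally a logical
#'   `is_mitochondrial` column (absent means every listed gene is
#'   mitochondrial).
#' @param renames named character vector, old symbol -> new symbol.
#' @return `calls` with harmonized `gene` and an `is_mitochondrial` column.
#' @export
harmonize_and_annotate <- function(calls, mitocarta,
                                   renames = c("TIMM23B" = "TIMM23",
                                               "HSPE1-MOB4" = "HSPE1",
                                               "PARK2" = "PRKN")) {
  if (!is.data.frame(calls) || !"gene" %in% names(calls))
    stop_input("'calls' must have a 'gene' column")
  if (!is.data.frame(mitocarta) || !"gene" %in% names(mitocarta))
    stop_input("'mitocarta' must be a data frame with a 'gene' column")
  gene <- calls$gene
  hit <- gene %in% names(renames)
  gene[hit] <- unname(renames[gene[hit]])
  idx <- match(gene, mitocarta$gene)
  is_mito <- if ("is_mitochondrial" %in% names(mitocarta)) {
    v <- mitocarta$is_mitochondrial[idx]
    if (!is.logical(v)) stop_input("'is_mitochondrial' must be logical")
    !is.na(v) & v
  } else !is.na(idx)
  n_unknown <- sum(is.na(idx))
  if (n_unknown) message(n_unknown, " gene(s) absent from the annotation; set to FALSE")
  calls$gene <- gene
  calls$is_mitochondrial <- is_mito
  calls
}
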