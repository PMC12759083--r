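# Screen scoring: filtering, guide differential, correction, aggregation,
# six-screen classification and annotation.

test_that("zero-count filter keeps exactly the all-positive guides, order preserved", {
  tb <- toy_guide_tables(
    counts_high = rbind(c(10, 12), c(5, 0), c(8, 9), c(3, 3), c(1, 1), c(7, 2)),
    counts_low  = rbind(c(4, 4),  c(6, 6), c(0, 2), c(9, 1), c(2, 5), c(8, 8)))
  filt <- filter_zero_count_guides(tb$high, tb$low)
  expect_identical(filt$high$guide_id, c("g01", "g04", "g05", "g06"))
  expect_identical(filt$low$guide_id, filt$high$guide_id)
  # all-positive input is passed through unchanged
  clean <- toy_guide_tables(matrix(5, 4, 2), matrix(7, 4, 2))
  expect_identical(filter_zero_count_guides(clean$high, clean$low)$high, clean$high)
  # empty input is an empty output, not an error
  empty <- toy_guide_tables(matrix(0, 0, 2), matrix(0, 0, 2), genes = character())
  expect_identical(nrow(filter_zero_count_guides(empty$high, empty$low)$high), 0L)
})

test_that("log2fc matches brute-force median-of-ratios recomputation to 1e-9", {
  set.seed(31)
  for (rep in 1:5) {
    n <- sample(6:20, 1)
    tb <- toy_guide_tables(matrix(rpois(n * 2, 200) + 1, n, 2),
                           matrix(rpois(n * 2, 150) + 1, n, 2))
    gd <- guide_differential(tb$high, tb$low)
    expect_equal(gd$log2fc, brute_force_log2fc(tb$high, tb$low), tolerance = 1e-9)
  }
})

test_that("median-of-ratios size factors agree with the DESeq2 reference", {
  skip_if_not_installed("DESeq2")
  set.seed(8)
  m <- matrix(rpois(200, 300) + 1, 50, 4)
  ours <- mitosense:::median_ratio_size_factors(m)
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  expect_equal(unname(ours), unname(ref), tolerance = 1e-9)
})

test_that("identical high and low tables give zero log2fc everywhere", {
  tb <- toy_guide_tables(matrix(rpois(20, 500) + 1, 10, 2),
                         matrix(0, 10, 2))
  gd <- guide_differential(tb$high, tb$high)
  expect_equal(gd$log2fc, rep(0, 10))
})

test_that("a doubled subset recovers log2fc near 1; global doubling is exact without normalization", {
  set.seed(12)
  base <- matrix(rpois(40, 400) + 100, 20, 2)
  high <- base; high[1:3, ] <- 2 * base[1:3, ]           # minority doubled
  tb <- toy_guide_tables(high, base)
  # extreme z-scores underflow p to 0 here; the documented clamp warns
  gd <- suppressWarnings(guide_differential(tb$high, tb$low))
  expect_true(all(abs(gd$log2fc[1:3] - 1) < 0.1))
  # with equal library sizes asserted (norm = "none"), 2x everywhere is ~1
  tb2 <- toy_guide_tables(2 * base, base)
  gd2 <- suppressWarnings(guide_differential(tb2$high, tb2$low, norm = "none"))
  expect_true(all(abs(gd2$log2fc - 1) < 0.1))
})

test_that("guide universe mismatch is an input error", {
  tb <- toy_guide_tables(matrix(5, 4, 2), matrix(7, 4, 2))
  swapped <- tb$low[c(2, 1, 3, 4), ]
  expect_error(guide_differential(tb$high, swapped), class = "mitosense_input_error")
})

test_that("bonferroni arithmetic, clipping and printed-direction mode", {
  expect_identical(bonferroni_correct(0.5, m = 1), 0.5)
  expect_equal(bonferroni_correct(1e-6, m = 1e4), 0.01)
  expect_identical(bonferroni_correct(0.1, m = 100), 1)
  expect_equal(bonferroni_correct(0.1, m = 100, mode = "as_printed"), 0.001)
  expect_error(bonferroni_correct(0.1, m = 0), class = "mitosense_input_error")
  expect_error(bonferroni_correct(1.2, m = 10), class = "mitosense_input_error")
})

test_that("gene score arithmetic, sign and zero clamping", {
  expect_identical(gene_score(1, 5), 0)
  expect_identical(gene_score(0.5, 0), 0)
  expect_equal(gene_score(0.01, -2), -4)
  expect_equal(sign(gene_score(0.001, 3)), 1)
  expect_warning(v <- gene_score(0, 1), "clamped")
  expect_true(is.finite(v) && v > 0)
})

test_that("best-guide-pair aggregation follows the sign-agreement rule", {
  st <- data.frame(
    guide_id = paste0("g", 1:5), gene = "X",
    log2fc = c(-2, -1.5, 0.05, 0, 0),
    p_adj = c(1e-4, 1e-3, 0.9, 1, 1),
    score = c(-4, -3, 0.1, 0, 0), stringsAsFactors = FALSE)
  agg <- aggregate_guides_to_gene(st)
  expect_equal(agg$log2fc, mean(c(-2, -1.5)))
  expect_equal(agg$p_adj, 1e-3)
  expect_true(agg$significant)
  # single guide passes through
  one <- st[2, ]
  agg1 <- aggregate_guides_to_gene(one)
  expect_equal(agg1$log2fc, -1.5)
  expect_equal(agg1$p_adj, 1e-3)
  # "mean" method takes plain means
  aggm <- aggregate_guides_to_gene(st, method = "mean")
  expect_equal(aggm$log2fc, mean(st$log2fc))
})

make_scores <- function(gene, lfc, sig) {
  keys <- screen_keys()
  out <- lapply(keys, function(k)
    data.frame(gene = gene, log2fc = lfc[[k]],
               p_adj = ifelse(sig[[k]], 0.01, 0.5),
               score = 0, significant = sig[[k]], stringsAsFactors = FALSE))
  names(out) <- keys
  out
}

test_that("six-screen classification applies the printed thresholds", {
  base_lfc <- setNames(as.list(rep(0, 6)), screen_keys())
  base_sig <- setNames(as.list(rep(FALSE, 6)), screen_keys())
  # activator: significant, lfc(HeLa+P, NT) = -1.5, no-Parkin lfc 0 (diff -1.5)
  l <- base_lfc; s <- base_sig
  l$HeLa_Parkin_NT <- -1.5; s$HeLa_Parkin_NT <- TRUE
  expect_identical(classify_hits(make_scores("A", l, s))$category, "parkin_activator")
  # same but no-Parkin lfc -1.0 (diff -0.5): threshold -1.25 not met
  l$HeLa_noParkin_NT <- -1.0
  expect_identical(classify_hits(make_scores("A", l, s))$category, "none")
  # facilitator: AO+P lfc 2.0, NT+P 0.5, AO-P 0.3, significant in AO+P
  l <- base_lfc; s <- base_sig
  l$HeLa_Parkin_AO <- 2.0; l$HeLa_Parkin_NT <- 0.5; l$HeLa_noParkin_AO <- 0.3
  s$HeLa_Parkin_AO <- TRUE
  expect_identical(classify_hits(make_scores("F", l, s))$category, "parkin_facilitator")
  # downregulator: lfc < -1 in HEK293-NT and HeLa-noParkin-NT, both significant
  l <- base_lfc; s <- base_sig
  l$HEK293_NT <- -1.4; l$HeLa_noParkin_NT <- -1.2
  s$HEK293_NT <- TRUE; s$HeLa_noParkin_NT <- TRUE
  expect_identical(classify_hits(make_scores("D", l, s))$category, "mfn2_downregulator")
  # a gene meeting both activator and downregulator rules is an activator
  l$HeLa_Parkin_NT <- -3; s$HeLa_Parkin_NT <- TRUE   # diff vs -1.2 is -1.8 < -1.25
  expect_identical(classify_hits(make_scores("AD", l, s))$category, "parkin_activator")
  # upregulator, symmetric
  l <- base_lfc; s <- base_sig
  l$HEK293_NT <- 1.4; l$HeLa_noParkin_NT <- 1.2
  s$HEK293_NT <- TRUE; s$HeLa_noParkin_NT <- TRUE
  expect_identical(classify_hits(make_scores("U", l, s))$category, "mfn2_upregulator")
})

test_that("a missing screen key is an input error naming the key", {
  sc <- make_scores("A", setNames(as.list(rep(0, 6)), screen_keys()),
                    setNames(as.list(rep(FALSE, 6)), screen_keys()))
  sc$HEK293_AO <- NULL
  expect_error(classify_hits(sc), "HEK293_AO", class = "mitosense_input_error")
})

test_that("symbol harmonization precedes mitochondrial annotation", {
  calls <- data.frame(gene = c("TIMM23B", "HSPE1-MOB4", "PARK2", "ACTB", "XYZ"),
                      category = "none", stringsAsFactors = FALSE)
  carta <- data.frame(gene = c("TIMM23", "HSPE1", "PRKN"), stringsAsFactors = FALSE)
  out <- suppressMessages(harmonize_and_annotate(calls, carta))
  expect_identical(out$gene, c("TIMM23", "HSPE1", "PRKN", "ACTB", "XYZ"))
  expect_identical(out$is_mitochondrial, c(TRUE, TRUE, TRUE, FALSE, FALSE))
  # no renames: symbols untouched
  out2 <- suppressMessages(harmonize_and_annotate(calls, carta, renames = character()))
  expect_identical(out2$gene, calls$gene)
})
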