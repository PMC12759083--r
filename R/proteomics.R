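#' @title Proteomics post-processing and annotation
#' @name proteomics_annot
#' @description Downstream label-free proteomics statistics: differential
#'   abundance with BH FDR and the joint FDR/fold-change significance flag,
#'   per-sample normalization to the non-mitochondrial median, and the
#'   strong-presequence annotation rule.
NULL

#' Differential protein abundance with BH FDR
#'
#' Per protein: `log2fc = log2(mean(a) / mean(b))` of the linear condition
#' means, a two-sided t-test on the log2-transformed abundances (classical
#' equal-variance by default; `welch = TRUE` for the Welch correction), and a
#' Benjamini-Hochberg FDR over all tested proteins. A protein is flagged
#' significant when `FDR < 0.05` and `|log2fc| > lfc_cut`. Proteins with
#' fewer than 2 observed replicates or more than 50% missing values in
#' either condition are excluded from testing; their count is reported via
#' `message()`.
#'
#' @param a,b numeric abundance matrices (proteins x replicates, linear
#'   scale, > 0 or NA) with matching rownames.
#' @param lfc_cut absolute log2 fold-change cut for the significance flag
#'   (1.0 for most experiments, 0.5 where so designed).
#' @param welch use Welch's unequal-variance t-test (default FALSE).
#' @param fdr_alpha FDR cut for the significance flag (default 0.05).
#' @return data frame (`protein`, `log2fc`, `p_value`, `fdr`, `significant`,
#'   `n_a`, `n_b`), one row per tested protein.
#' @export
differential_abundance <- function(a, b, lfc_cut = 1.0, welch = FALSE,
                                   fdr_alpha = 0.05) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (is.null(rownames(a)) || !identical(rownames(a), rownames(b)))
    stop_input("'a' and 'b' must have identical rownames (protein ids)")
  if (any(a <= 0, na.rm = TRUE) || any(b <= 0, na.rm = TRUE))
    stop_input("abundances must be positive (linear scale) or NA")
  lfc_cut <- check_number(lfc_cut, "lfc_cut", lower = 0)
  n_a <- rowSums(!is.na(a)); n_b <- rowSums(!is.na(b))
  testable <- n_a >= 2 & n_b >= 2 &
    n_a > ncol(a) / 2 & n_b > ncol(b) / 2
  if (!any(testable)) stop_input("no protein has enough replicates to test")
  n_excl <- sum(!testable)
  if (n_excl) message(n_excl, " protein(s) excluded for missing replicates")
  a <- a[testable, , drop = FALSE]; b <- b[testable, , drop = FALSE]

  log2fc <- log2(rowMeans(a, na.rm = TRUE) / rowMeans(b, na.rm = TRUE))
  la <- log2(a); lb <- log2(b)
  p <- vapply(seq_len(nrow(a)), function(i)
    stats::t.test(la[i, ], lb[i, ], var.equal = !welch)$p.value, numeric(1))
  fdr <- stats::p.adjust(p, method = "BH")
  data.frame(protein = rownames(a),
             log2fc = unname(log2fc), p_value = p, fdr = fdr,
             significant = fdr < fdr_alpha & abs(log2fc) > lfc_cut,
             n_a = unname(n_a[testable]), n_b = unname(n_b[testable]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Normalize each sample to its non-mitochondrial protein median
#'
#' Divides every abundance in a sample (column) by that sample's median over
#' the non-mitochondrial proteins, so that the non-mitochondrial median
#' equals 1 in every sample afterwards.
#'
#' @param abundance numeric matrix, proteins x samples (linear scale; NA
#'   allowed).
#' @param is_mitochondrial logical vector, one entry per protein row.
#' @return the normalized matrix.
#' @export
normalize_to_nonmito_median <- function(abundance, is_mitochondrial) {
  abundance <- as.matrix(abundance)
  if (!is.logical(is_mitochondrial) || length(is_mitochondrial) != nrow(abundance))
    stop_input("'is_mitochondrial' must be logical with one entry per protein")
  nonmito <- !is_mitochondrial
  if (!any(nonmito)) stop_input("no non-mitochondrial proteins to normalize to")
  med <- apply(abundance[nonmito, , drop = FALSE], 2, stats::median, na.rm = TRUE)
  if (any(!is.finite(med)) || any(med <= 0))
    stop_input("a sample has no positive non-mitochondrial abundances")
  sweep(abundance, 2, med, "/")
}

#' Flag proteins with a predicted strong N-terminal presequence
#'
#' A protein is flagged when it (1) localizes to mitochondria but not
#' primarily the outer mitochondrial membrane, (2) has a matrix-targeting-
#' sequence (MTS1) score >= 2, and (3) an MTS1 start position < 20 residues
#' from the N-terminus. Rows with any missing annotation get FALSE; their
#' count is reported via `message()`.
#'
#' @param table data frame with logical `is_mitochondrial`, `is_omm` and
#'   numeric `mts1_score`, `mts1_start` columns.
#' @return `table` with an added logical `strong_presequence` column.
#' @export
annotate_strong_presequence <- function(table) {
  need <- c("is_mitochondrial", "is_omm", "mts1_score", "mts1_start")
  if (!is.data.frame(table) || !all(need %in% names(table)))
    stop_input("'table' must have columns %s", paste(need, collapse = ", "))
  flag <- table$is_mitochondrial & !table$is_omm &
    table$mts1_score >= 2 & table$mts1_start < 20
  n_na <- sum(is.na(flag))
  if (n_na) message(n_na, " protein(s) with missing annotations; flag set to FALSE")
  table$strong_presequence <- !is.na(flag) & flag
  table
}
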