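# Small programmatic fixtures shared across tests.

toy_guide_tables <- function(counts_high, counts_low, genes = NULL) {
  n <- nrow(counts_high)
  genes <- genes %||% paste0("G", rep(seq_len(ceiling(n / 2)), each = 2)[seq_len(n)])
  mk <- function(m) {
    colnames(m) <- paste0("rep_", seq_len(ncol(m)))
    data.frame(guide_id = sprintf("g%02d", seq_len(n)), gene = genes, m,
               stringsAsFactors = FALSE)
  }
  list(high = mk(as.matrix(counts_high)), low = mk(as.matrix(counts_low)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force recomputation of guide_differential's log2fc from first
# principles (median-of-ratios + pseudocount), written with explicit loops
# so it shares no code path with the implementation.
brute_force_log2fc <- function(high, low, pc = 0.5) {
  cnt <- cbind(as.matrix(high[setdiff(names(high), c("guide_id", "gene"))]),
               as.matrix(low[setdiff(names(low), c("guide_id", "gene"))]))
  n <- nrow(cnt); k <- ncol(cnt) / 2
  geo <- numeric(n)
  for (i in seq_len(n)) geo[i] <- prod(cnt[i, ])^(1 / ncol(cnt))
  sf <- numeric(ncol(cnt))
  for (j in seq_len(ncol(cnt))) {
    lograt <- numeric(n)
    for (i in seq_len(n)) lograt[i] <- log(cnt[i, j]) - log(geo[i])
    sf[j] <- exp(median(lograt))
  }
  out <- numeric(n)
  for (i in seq_len(n)) {
    mh <- mean(cnt[i, 1:k] / sf[1:k])
    ml <- mean(cnt[i, k + (1:k)] / sf[k + (1:k)])
    out[i] <- log2((mh + pc) / (ml + pc))
  }
  out
}

# Brute-force BH step-up, independent of stats::p.adjust.
brute_force_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- Inf
  for (i in m:1) {
    running <- min(running, p[o[i]] * m / i)
    adj[o[i]] <- min(1, running)
  }
  adj
}

# A structured sparse test image: scattered bright blobs on black.
structured_image <- function(n = 96) {
  img <- matrix(0, n, n)
  withr::with_seed(1234, {
    for (k in 1:15) {
      i <- sample(2:(n - 2), 1); j <- sample(2:(n - 2), 1)
      img[i + 0:1, j + 0:1] <- 100
    }
  })
  img
}
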