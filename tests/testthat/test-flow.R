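# Flow-cytometry statistics: degradation formula, normalizations, keima
# gating, quadrant analysis.

events_of <- function(x) data.frame(MFN2 = x)

test_that("degradation formula reproduces printed arithmetic and symmetry", {
  # equal normalized intensities -> 0%
  expect_equal(mfn2_degradation(events_of(c(100, 300)), events_of(c(150, 250)),
                                ctrl_pos_mean = 200, ctrl_neg_mean = 200), 0)
  # raw means 100 vs 400, both CTRL means 400: normint 0.25 vs 1.0 -> -300%
  expect_equal(mfn2_degradation(events_of(100), events_of(400), 400, 400), -300)
  expect_error(mfn2_degradation(events_of(100), events_of(400), 0, 400),
               class = "mitosense_input_error")
  expect_error(mfn2_degradation(events_of(numeric()), events_of(400), 1, 1),
               class = "mitosense_input_error")
})

test_that("degradation is invariant to common rescaling of the reporter channel", {
  set.seed(4)
  pos <- events_of(rlnorm(500, 5, 0.4)); neg <- events_of(rlnorm(500, 5.3, 0.4))
  d1 <- mfn2_degradation(pos, neg, 120, 140)
  d2 <- mfn2_degradation(events_of(pos$MFN2 * 7), events_of(neg$MFN2 * 7),
                         120 * 7, 140 * 7)
  expect_equal(d1, d2, tolerance = 1e-12)
})

test_that("channel normalization divides by the mean of control replicates", {
  s <- data.frame(YFP = c(400, 600))
  expect_equal(normalize_channel(s, "YFP", ctrl_means = c(200, 300)), 2)
  expect_equal(normalize_channel(s, "YFP", ctrl_means = 500), 1)
  expect_error(normalize_channel(s, "YFP", ctrl_means = numeric()),
               class = "mitosense_input_error")
  expect_error(normalize_channel(s, "nope", ctrl_means = 1),
               class = "mitosense_input_error")
})

test_that("two-step MitoLite normalization and its scale invariance", {
  mk <- function(pos_mean, neg_mean, scale = 1)
    data.frame(MitoLite = c(rep(pos_mean, 50), rep(neg_mean, 50)) * scale,
               positive = rep(c(TRUE, FALSE), each = 50))
  ctrls <- list(mk(500, 500), mk(600, 600))      # within = 1 each
  expect_equal(mitolite_normalize(mk(300, 600), ctrls), 0.5)
  expect_equal(mitolite_normalize(mk(500, 500), ctrls), 1)
  # global rescale of every event in sample and CTRLs cancels
  c3 <- 3.7
  ctrls_s <- list(mk(500, 500, c3), mk(600, 600, c3))
  expect_equal(mitolite_normalize(mk(300, 600, c3), ctrls_s),
               mitolite_normalize(mk(300, 600), ctrls), tolerance = 1e-12)
  # missing subpopulation is an input error
  bad <- data.frame(MitoLite = rep(1, 10), positive = rep(TRUE, 10))
  expect_error(mitolite_normalize(bad, ctrls), class = "mitosense_input_error")
})

test_that("keima compensation floors at zero and the gate fraction is in range", {
  gate <- gate_spec("polygon", c("neutral", "acidic"),
                    vertices = rbind(c(-10, 50), c(50, 50), c(-10, 200)))
  # spillover 0.10: neutral 10 - 0.1 * 100 = 0, floored; (0, 100) is in-gate
  ev <- data.frame(ex488em611 = 10, ex561em611 = 100, ex488em528 = 100)
  expect_equal(keima_mitophagy_fraction(ev, gate, spillover = 0.10), 100)
  # all events at the gate centroid -> 100%
  cen <- colMeans(rbind(c(-10, 50), c(50, 50), c(-10, 200)))
  ev2 <- data.frame(ex488em611 = rep(cen[1], 20), ex561em611 = rep(cen[2], 20),
                    ex488em528 = 0)
  expect_equal(keima_mitophagy_fraction(ev2, gate, spillover = 0), 100)
  # events far outside -> 0%
  ev3 <- data.frame(ex488em611 = 1000, ex561em611 = 1, ex488em528 = 0)
  expect_equal(keima_mitophagy_fraction(ev3, gate), 0)
  # degenerate gate
  expect_error(gate_spec("polygon", c("neutral", "acidic"),
                         vertices = rbind(c(0, 0), c(1, 1), c(2, 2))),
               class = "mitosense_input_error")
})

test_that("keima fraction is monotone under gate growth", {
  set.seed(11)
  ev <- data.frame(ex488em611 = rlnorm(2000, 3, 1), ex561em611 = rlnorm(2000, 3, 1),
                   ex488em528 = rlnorm(2000, 2, 1))
  small <- gate_spec("polygon", c("neutral", "acidic"),
                     vertices = rbind(c(0, 0), c(30, 0), c(30, 30), c(0, 30)))
  big <- gate_spec("polygon", c("neutral", "acidic"),
                   vertices = rbind(c(0, 0), c(300, 0), c(300, 300), c(0, 300)))
  f_small <- keima_mitophagy_fraction(ev, small)
  f_big <- keima_mitophagy_fraction(ev, big)
  expect_true(f_small >= 0 && f_big <= 100)
  expect_lte(f_small, f_big)
})

quadrant_sample <- function(n, seed, scale = 1) {
  set.seed(seed)
  data.frame(PINK1_YFP = rlnorm(n, 4, 0.6),
             MitoLite = rlnorm(n, 5, 0.5) * scale,
             BFP = rlnorm(n, 3, 0.7))
}

test_that("quadrant fractions partition the events and normalize by the factor", {
  s <- quadrant_sample(5000, 1); ctrl <- quadrant_sample(5000, 2)
  q <- quadrant_analysis(s, ctrl, cutoffs = c(pink1 = 80, mitolite = 1.2), bfp_cut = 40)
  expect_equal(q$q_ll + q$q_lh + q$q_hl + q$q_hh, 1, tolerance = 1e-12)
  expect_true(all(c(q$q_ll, q$q_lh, q$q_hl, q$q_hh) > 0))  # all quadrants populated
  # all events below both cutoffs -> q_ll = 1
  low <- data.frame(PINK1_YFP = rep(1, 100), MitoLite = rep(1, 100), BFP = rep(1, 100))
  q2 <- quadrant_analysis(low, low, cutoffs = c(1000, 1000), bfp_cut = 1000)
  expect_identical(q2$q_ll, 1)
  # empty reference population is an input error with a diagnostic
  expect_error(quadrant_analysis(s, ctrl, cutoffs = c(80, 1.2), bfp_cut = 0),
               "reference", class = "mitosense_input_error")
})

test_that("rescaling MitoLite in sample and control cancels out of the quadrants", {
  s <- quadrant_sample(5000, 5); ctrl <- quadrant_sample(5000, 6)
  q1 <- quadrant_analysis(s, ctrl, cutoffs = c(80, 1.2), bfp_cut = 40)
  s3 <- s; s3$MitoLite <- s3$MitoLite * 3
  c3 <- ctrl; c3$MitoLite <- c3$MitoLite * 3
  q3 <- quadrant_analysis(s3, c3, cutoffs = c(80, 1.2), bfp_cut = 40)
  for (f in c("q_ll", "q_lh", "q_hl", "q_hh"))
    expect_lte(abs(q1[[f]] - q3[[f]]), 1e-12)
  # rescaling the sample alone also cancels (the factor's purpose)
  q4 <- quadrant_analysis(s3, ctrl, cutoffs = c(80, 1.2), bfp_cut = 40)
  for (f in c("q_ll", "q_lh", "q_hl", "q_hh"))
    expect_lte(abs(q1[[f]] - q4[[f]]), 1e-12)
})

test_that("boundary events are assigned to the high side", {
  # reference population is the second event alone: reference mean 150,
  # factor 1; MitoLite cut 2 control-relative units = normalized 300
  s <- data.frame(PINK1_YFP = c(80, 79.999), MitoLite = c(300, 150), BFP = c(1, 1))
  ctrl <- s
  q <- quadrant_analysis(s, ctrl, cutoffs = c(pink1 = 80, mitolite = 2), bfp_cut = 40)
  expect_equal(q$q_hh, 0.5)   # first event: both exactly at cutoff -> high/high
  expect_equal(q$q_ll, 0.5)
})
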