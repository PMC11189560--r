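toy_counts <- function(alt1 = c(10, 10), alt10 = c(18, 18), n = 20) {
  data.frame(marker = "m1", replicate = c("A", "B"),
             alt1 = alt1, ref1 = n - alt1,
             alt10 = alt10, ref10 = n - alt10,
             stringsAsFactors = FALSE)
}

test_that("the CMH statistic matches its hand evaluation", {
  # two identical strata [gen1: 10/10, gen10: 18/2]; by direct evaluation
  # E = 14, V = 28/13, statistic = 104/7
  res <- cmh_test(toy_counts(), cmh_options(drift_aware = FALSE))
  expect_equal(res$statistic, 104 / 7, tolerance = 1e-9)
  expect_equal(res$p_value, 1.159680678e-4, tolerance = 1e-6)

  # independent implementation: stats::mantelhaen.test without correction
  tab <- array(c(10, 18, 10, 2, 10, 18, 10, 2), dim = c(2, 2, 2))
  mt <- stats::mantelhaen.test(tab, correct = FALSE)
  expect_equal(res$statistic, unname(mt$statistic), tolerance = 1e-9)
  expect_equal(res$p_value, mt$p.value, tolerance = 1e-9)
})

test_that("no change means no signal, and degenerate strata are safe", {
  res <- cmh_test(toy_counts(alt10 = c(10, 10)),
                  cmh_options(drift_aware = FALSE))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  # monomorphic in all strata: statistic undefined, reported as null
  res0 <- cmh_test(toy_counts(alt1 = c(0, 0), alt10 = c(0, 0)))
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p_value, 1)

  expect_error(cmh_test(toy_counts(alt1 = c(-1, 10))), "negative")
})

test_that("the drift term vanishes as Ne grows and never adds power", {
  classical <- cmh_test(toy_counts(), cmh_options(drift_aware = FALSE))
  huge_ne <- cmh_test(toy_counts(), cmh_options(drift_aware = TRUE, ne = Inf))
  expect_equal(huge_ne$statistic, classical$statistic, tolerance = 1e-9)

  # variance inflation: drift-aware statistic never exceeds the classical one
  set.seed(12)
  for (i in 1:20) {
    cnt <- toy_counts(alt1 = rbinom(2, 20, 0.5), alt10 = rbinom(2, 20, 0.7))
    s_c <- cmh_test(cnt, cmh_options(drift_aware = FALSE))$statistic
    s_d <- cmh_test(cnt, cmh_options(drift_aware = TRUE, ne = 25))$statistic
    expect_lte(s_d, s_c + 1e-12)
  }
})

test_that("the statistic ignores stratum order and allele labels", {
  cnt <- toy_counts(alt1 = c(8, 12), alt10 = c(15, 17))
  perm <- cnt[2:1, ]
  swap <- cnt
  swap[, c("alt1", "ref1", "alt10", "ref10")] <-
    cnt[, c("ref1", "alt1", "ref10", "alt10")]
  s <- function(x) cmh_test(x, cmh_options(drift_aware = FALSE))$statistic
  expect_equal(s(cnt), s(perm), tolerance = 1e-12)
  expect_equal(s(cnt), s(swap), tolerance = 1e-12)
})

test_that("BH q-values reproduce the step-up rule", {
  expect_equal(fdr_bh(0.05), 0.05)
  expect_equal(fdr_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_bh(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(fdr_bh(numeric(0)), numeric(0))
  expect_error(fdr_bh(c(0.1, 0)), "p-values")

  # independent step-up oracle on random inputs
  step_up <- function(p) {
    m <- length(p); o <- order(p)
    q <- p[o] * m / seq_len(m)
    q <- rev(cummin(rev(q)))
    pmin(q, 1)[order(o)]
  }
  set.seed(5)
  for (i in 1:10) {
    p <- runif(50)^2
    expect_equal(fdr_bh(p), step_up(p), tolerance = 1e-12)
  }
})

test_that("window pruning keeps the best marker per 2-kb window", {
  map <- data.frame(marker = c("a", "b", "c"), chrom = "A01",
                    pos = c(100L, 1500L, 2500L), stringsAsFactors = FALSE)
  res <- data.frame(marker = c("a", "b", "c"),
                    statistic = c(1, 2, 3),
                    p_value = c(0.01, 0.001, 0.5), stringsAsFactors = FALSE)
  pr <- prune_windows(res, map, 2000L)
  expect_identical(pr$marker[pr$pruned_representative], c("b", "c"))

  # single marker represents itself
  pr1 <- prune_windows(res[1, ], map, 2000L)
  expect_true(pr1$pruned_representative)

  # tie on p: the smaller position wins
  res$p_value <- c(0.01, 0.01, 0.5)
  pr2 <- prune_windows(res, map, 2000L)
  expect_true(pr2$pruned_representative[pr2$marker == "a"])
  expect_false(pr2$pruned_representative[pr2$marker == "b"])
})

test_that("significance requires FDR, pruning and replicate agreement", {
  map <- data.frame(marker = c("m1", "m2", "m3"), chrom = "A01",
                    pos = c(100L, 5000L, 9000L), stringsAsFactors = FALSE)
  res <- data.frame(marker = map$marker, statistic = c(20, 20, 1),
                    p_value = c(1e-5, 1e-5, 0.4), stringsAsFactors = FALSE)
  af <- data.frame(
    marker = rep(map$marker, each = 2),
    replicate = rep(c("A", "B"), 3),
    delta = c(0.2, 0.3,    # consistent
              0.2, -0.3,   # sign conflict
              0.2, 0.3),
    stringsAsFactors = FALSE
  )
  sig <- significant_set(res, af, map, cmh_options(fdr_alpha = 0.05))
  expect_true(sig$significant[sig$marker == "m1"])
  expect_false(sig$significant[sig$marker == "m2"])  # replicates disagree
  expect_false(sig$significant[sig$marker == "m3"])  # q above threshold
  expect_true(all(sig$q_value[sig$pruned_representative] >=
                    sig$p_value[sig$pruned_representative]))
})

test_that("drift-aware testing controls the neutral false-positive rate", {
  # Wright-Fisher null at the design's scale; a reduced version of the
  # full calibration (which lives in the acceptance suite)
  panel <- simulate_drift_panel(1500, ne = 25, n_diploid = 49, t = 9,
                                seed = 77)
  p_drift <- cmh_test(panel, cmh_options(drift_aware = TRUE, ne = 25,
                                         t_generations = 9))$p_value
  p_class <- cmh_test(panel, cmh_options(drift_aware = FALSE))$p_value
  expect_lte(mean(p_drift < 0.05), 0.075)
  expect_gt(mean(p_class < 0.05), mean(p_drift < 0.05))
})
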