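test_that("the GxE model is calibrated under the null and powered under GxE", {
  # null: no local advantage, interaction should rarely be significant
  p_int <- vapply(1:100, function(i) {
    fit <- fit_gxe(gxe_data(50, local_shift = 0, seed = i))
    fit$terms$p_value[fit$terms$term == "soil_line:soil_grown"]
  }, numeric(1))
  expect_gte(mean(p_int > 0.05), 0.90)

  # a crossing local advantage of one residual sd is detected essentially
  # always at this size
  p_alt <- vapply(1:20, function(i) {
    fit <- fit_gxe(gxe_data(50, local_shift = 1, seed = 1000 + i))
    fit$terms$p_value[fit$terms$term == "soil_line:soil_grown"]
  }, numeric(1))
  expect_gte(mean(p_alt < 0.001), 0.95)
})

test_that("a generator without replicate effects yields a boundary fit", {
  fit <- fit_gxe(gxe_data(60, local_shift = 0, seed = 3, rep_effect = 0))
  expect_lte(fit$replicate_variance, 1e-6)
  # and with a real replicate shift the variance is picked up
  fit2 <- fit_gxe(gxe_data(120, local_shift = 0, seed = 3, rep_effect = 3))
  expect_gt(fit2$replicate_variance, 0.5)
})

test_that("cell requirements are enforced", {
  d <- gxe_data(5, seed = 1)
  d <- d[!(d$soil_line == "tuff" & d$soil_grown == "tuff"), ]
  expect_error(fit_gxe(d), "fewer than 2 observations")
  expect_error(fit_gxe(d[0, ]), "fewer than 2|missing column")
})

test_that("contrasts recover the cell-mean arithmetic", {
  # residuals constructed to sum to zero per cell: cell means are exact
  d <- gxe_data(40, local_shift = 0, sd = 0, seed = 2)
  d$open_flowers <- d$open_flowers +
    ifelse(d$soil_line == d$soil_grown, 30, 20) - 30 +
    rep(c(-0.5, 0.5), nrow(d) / 2)
  fit <- fit_gxe(d)
  ctr <- gxe_contrasts(fit)
  expect_equal(ctr$estimate[ctr$contrast == "local_vs_foreign"], 10,
               tolerance = 1e-6)
  expect_equal(ctr$estimate[ctr$contrast == "home_vs_away"], 10,
               tolerance = 1e-6)
  expect_true(all(ctr$p_value < 1e-6))

  # symmetric means: both contrasts vanish
  d2 <- gxe_data(40, local_shift = 0, sd = 0, seed = 2)
  d2$open_flowers <- d2$open_flowers + rep(c(-0.5, 0.5), nrow(d2) / 2)
  ctr2 <- gxe_contrasts(fit_gxe(d2))
  expect_lt(max(abs(ctr2$estimate)), 1e-8)
})

test_that("the local-adaptation verdict needs both tests and the right sign", {
  d <- gxe_data(75, local_shift = 0.5, sd = 1, seed = 11)
  fit <- fit_gxe(d)
  v <- assess_local_adaptation(fit, gxe_contrasts(fit))
  expect_true(v$adapted)
  expect_gt(v$contrast_estimate, 0)

  # foreign advantage: significant interaction but wrong direction
  d$open_flowers <- d$open_flowers -
    ifelse(d$soil_line == d$soil_grown, 1, 0)
  fit2 <- fit_gxe(d)
  v2 <- assess_local_adaptation(fit2, gxe_contrasts(fit2))
  expect_false(v2$adapted)

  # null: no verdict
  d0 <- gxe_data(75, local_shift = 0, seed = 12)
  fit0 <- fit_gxe(d0)
  expect_false(assess_local_adaptation(fit0, gxe_contrasts(fit0))$adapted)
})

test_that("fitness models are calibrated under the null", {
  reject <- matrix(NA, 400, 2)
  for (i in seq_len(nrow(reject))) {
    set.seed(i)
    ph <- data.frame(open_flowers = rnorm(120, 30, 6))
    ph <- simulate_fitness_components(ph, flower_effect = 0, seed = 5000 + i)
    fm <- fitness_proxy_models(ph)
    reject[i, ] <- c(fm$binary$p_value < 0.05, fm$truncated$p_value < 0.05)
  }
  expect_gte(mean(reject[, 1], na.rm = TRUE), 0.02)
  expect_lte(mean(reject[, 1], na.rm = TRUE), 0.08)
  expect_gte(mean(reject[, 2], na.rm = TRUE), 0.02)
  expect_lte(mean(reject[, 2], na.rm = TRUE), 0.08)
})

test_that("forced associations and degenerate cases are recognized", {
  set.seed(1)
  ph <- data.frame(open_flowers = rnorm(100, 30, 6),
                   replicate = rep(c("A", "B"), 50))
  # deterministic association: seed set grows with the trait
  ph$seed_set <- exp(scale(ph$open_flowers)[, 1])
  ph$visits <- rpois(100, 2 + 2 * (ph$seed_set > 1))
  ph$first_choices <- rpois(100, exp(0.5 * scale(ph$open_flowers)[, 1]))
  fm <- fitness_proxy_models(ph)
  expect_gt(fm$truncated$estimate, 0)
  expect_lt(fm$truncated$p_value, 1e-6)
  expect_lt(fm$poisson$p_value, 1e-3)
  # every plant produces seeds: the binary model is degenerate
  expect_true(fm$binary$degenerate)
  expect_gt(fm$visits_seeds$r, 0)

  # complete separation is flagged rather than reported as an estimate
  ph2 <- data.frame(open_flowers = c(rnorm(50, 10, 1), rnorm(50, 50, 1)))
  ph2$seed_set <- as.numeric(ph2$open_flowers > 30)
  fm2 <- fitness_proxy_models(ph2)
  expect_true(fm2$binary$degenerate)
})

test_that("trait evolution contrasts detect an evolved shift, local only", {
  make_gen_data <- function(shift, seed) {
    set.seed(seed)
    d <- expand.grid(treatment = c("LHB", "THB"),
                     replicate = c("A", "B"),
                     generation = c(1L, 10L),
                     plant = 1:40, stringsAsFactors = FALSE)
    d$soil_line <- ifelse(d$treatment == "LHB", "limestone", "tuff")
    d$soil_grown <- d$soil_line
    d$open_flowers <- rnorm(nrow(d), 30 + shift * (d$generation == 10L), 1)
    d
  }
  # a one-sd shift at n = 40 per group is essentially always significant
  hits <- vapply(1:20, function(i) {
    te <- trait_evolution(make_gen_data(1, i))
    all(te$p_value < 0.05) && all(te$estimate > 0)
  }, logical(1))
  expect_gte(mean(hits), 0.9)

  # no shift: the contrast stays near zero
  te0 <- trait_evolution(make_gen_data(0, 99))
  expect_lt(max(abs(te0$estimate)), 0.5)

  # foreign-grown plants are excluded with a message
  d <- make_gen_data(0, 5)
  d$soil_grown[1:10] <- ifelse(d$soil_line[1:10] == "limestone",
                               "tuff", "limestone")
  expect_message(trait_evolution(d), "excluding 10")
  d_one_gen <- d[d$generation == 1L, ]
  expect_error(suppressMessages(trait_evolution(d_one_gen)),
               "both generations")
})
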