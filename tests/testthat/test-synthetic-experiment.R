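test_that("founder draws follow the design and Hardy-Weinberg sampling", {
  cfg <- experiment_config(rng_seed = 11)
  f <- simulate_founders(cfg, default_architecture())
  expect_equal(nrow(f$samples), 8 * 2 * 49)
  expect_true(all(f$samples$generation == 1))
  expect_equal(length(unique(f$samples$treatment)), 8)
  # families: replicate A gets 1..49, replicate B 50..98
  expect_equal(sort(unique(f$samples$family[f$samples$replicate == "A"])), 1:49)
  expect_equal(sort(unique(f$samples$family[f$samples$replicate == "B"])), 50:98)

  # degenerate founder frequency pins the genotypes
  f2 <- simulate_founders(cfg, one_locus_arch(freq = 1 - 1e-12))
  expect_true(all(f2$genotypes == 2L))

  # realized frequency close to the nominal one for a large cohort
  cfg_big <- experiment_config(n_plants = 10000L, rng_seed = 3)
  f3 <- simulate_founders(cfg_big, one_locus_arch(freq = 0.5))
  p_hat <- mean(f3$genotypes) / 2
  expect_lt(abs(p_hat - 0.5), 0.02)
})

test_that("founder simulation rejects empty inputs", {
  cfg <- experiment_config()
  expect_error(genetic_architecture(data.frame()), "missing column")
  expect_error(simulate_founders(experiment_config(n_plants = 2L),
                                 one_locus_arch(freq = 1.2)),
               "founder_freq", ignore.case = TRUE)
})

test_that("phenotype model is additive with known variance partition", {
  cfg <- experiment_config(rng_seed = 5)
  arch <- one_locus_arch(freq = 0.5, trait_effect = 1)
  f <- simulate_founders(cfg, arch)
  f$samples$soil_grown <- f$samples$soil_line

  # all effects zero, no noise: trait equals the intercept
  tm0 <- trait_model(intercept = 12, soil_main = c(limestone = 0, tuff = 0),
                     gxe_effect = 0, fitness_coupling = 0, residual_sd = 0)
  arch0 <- one_locus_arch(freq = 0.5, trait_effect = 0)
  ph0 <- simulate_phenotype(f$genotypes, f$samples, arch0, tm0)
  expect_true(all(ph0$open_flowers == 12))

  # additivity: dosage 2 vs dosage 0 differ by twice the effect
  ph1 <- simulate_phenotype(f$genotypes, f$samples, arch, tm0)
  d2 <- ph1$open_flowers[f$genotypes[, 1] == 2][1]
  d0 <- ph1$open_flowers[f$genotypes[, 1] == 0][1]
  expect_equal(d2 - d0, 2)

  # heritability 0.5 is realized within Monte-Carlo tolerance at n = 2000
  m <- 40
  arch_poly <- genetic_architecture(data.frame(
    chrom = "A01", pos = 1000L + 5000L * (0:(m - 1)), founder_freq = 0.5,
    class = "NEUTRAL", s_limestone = 0, s_tuff = 0, trait_effect = 0.5,
    stringsAsFactors = FALSE))
  set.seed(8)
  G <- matrix(rbinom(2000 * m, 2L, 0.5), 2000, m,
              dimnames = list(NULL, arch_poly$marker))
  gval <- drop(G %*% arch_poly$trait_effect)
  sd_e <- sd(gval)  # residual matched to genetic sd gives h2 = 0.5
  samples <- data.frame(soil_grown = "tuff", soil_line = "tuff")
  samples <- samples[rep(1, 2000), ]
  tm <- trait_model(intercept = 0, soil_main = c(limestone = 0, tuff = 0),
                    gxe_effect = 0, fitness_coupling = 0, residual_sd = sd_e)
  ph <- simulate_phenotype(G, samples, arch_poly, tm, seed = 21)
  h2_hat <- var(gval) / var(ph$open_flowers)
  expect_gt(h2_hat, 0.42)
  expect_lt(h2_hat, 0.58)

  expect_error(simulate_phenotype(f$genotypes,
                                  transform(f$samples, soil_grown = NA),
                                  arch, tm0),
               "soil_grown")
})

test_that("seed contributions follow the replicate-normalized quota", {
  plan <- contributions(c(10, 88), 49)
  expect_equal(plan$contribution_quota[1], 5.0)
  expect_equal(sum(plan$contribution_quota), 49)
  expect_equal(sum(plan$offspring_count), 49L)

  # equal seed sets: largest remainder spreads the odd plant out
  plan3 <- contributions(c(1, 1, 1), 49)
  expect_equal(sort(plan3$offspring_count), c(16L, 16L, 17L))
  expect_equal(sum(plan3$offspring_count), 49L)

  # zero seed set never reproduces
  plan0 <- contributions(c(0, 5, 5), 10)
  expect_identical(plan0$offspring_count[1], 0L)

  # random seed sets always conserve the totals
  set.seed(99)
  for (i in 1:25) {
    s <- rexp(49) * rbinom(49, 1, 0.5)
    if (sum(s) == 0) next
    p <- contributions(s, 49)
    expect_equal(sum(p$contribution_quota), 49)
    expect_equal(sum(p$offspring_count), 49L)
    expect_true(all(p$offspring_count[p$seed_set == 0] == 0L))
  }

  expect_error(contributions(c(0, 0), 49), "extinction")
  expect_error(contributions(c(-1, 2), 49), "non-negative")
})

test_that("mating respects self-incompatibility and Mendelian drift", {
  cfg <- experiment_config(rng_seed = 2, hand_mothers = 49L)
  arch <- neutral_arch(1000)
  set.seed(4)
  G <- matrix(rbinom(49 * 1000, 2L, 0.5), 49, 1000,
              dimnames = list(NULL, arch$marker))

  off <- select_and_mate(G, "limestone", "hand", selective = FALSE,
                         arch = arch, config = cfg, seed = 7)
  parents <- attr(off, "parents")
  expect_true(all(parents$mother != parents$father))
  expect_true(all(off %in% 0:2))

  # neutral transmission: only binomial drift, mean |dp| small
  dp <- colMeans(off) / 2 - colMeans(G) / 2
  expect_lt(mean(abs(dp)), 0.05)
})

test_that("strong selection drives directional change, drift does not", {
  cfg <- experiment_config(rng_seed = 2)

  # effectively infinite selection: only dosage-2 plants attract and breed
  arch_fix <- one_locus_arch(freq = 0.5, s_a = 20, s_b = -20)
  G <- matrix(c(rep(2L, 30), rep(0L, 19)), ncol = 1,
              dimnames = list(NULL, arch_fix$marker))
  off <- select_and_mate(G, "limestone", "bee", selective = TRUE,
                         arch = arch_fix, config = cfg, ne = 22L, seed = 3)
  expect_equal(mean(off) / 2, 1)

  # an AP locus moves in opposite directions in the two soils
  arch_ap <- one_locus_arch(freq = 0.5, s_a = 0.3, s_b = -0.3)
  run_one <- function(soil, seed) {
    set.seed(seed)
    G <- matrix(rbinom(49, 2L, 0.5), ncol = 1,
                dimnames = list(NULL, arch_ap$marker))
    for (t in 1:9) {
      G <- select_and_mate(G, soil, if (t <= 8) "bee" else "hand",
                           selective = t <= 8, arch = arch_ap, config = cfg,
                           ne = 22L, seed = seed * 100 + t)
    }
    mean(G) / 2 - 0.5
  }
  dA <- vapply(1:200, function(i) run_one("limestone", i), numeric(1))
  dB <- vapply(1:200, function(i) run_one("tuff", 4000 + i), numeric(1))
  expect_gt(mean(dA), 0)
  expect_lt(mean(dB), 0)

  expect_error(select_and_mate(G[1, , drop = FALSE], "limestone", "hand",
                               FALSE, arch_ap, cfg), "extinction")
})

test_that("the full experiment conserves counts and is reproducible", {
  cfg <- experiment_config(rng_seed = 31)
  arch <- default_architecture(n_ap = 4L, n_cn = 4L, n_neutral = 12L)
  ex <- run_experiment(cfg, arch)

  expect_equal(length(ex$genotypes), 8)
  expect_true(all(vapply(ex$genotypes, length, 1L) == 2))
  expect_equal(sort(unique(ex$samples$generation)), c(1L, 10L))
  expect_true(all(ex$audit$offspring_sum == 49L))
  expect_true(all(abs(ex$audit$quota_sum - 49) < 1e-9))
  # 16 lines x 9 transmissions
  expect_equal(nrow(ex$audit), 16 * 9)

  # same root seed, bit-identical outputs
  ex2 <- run_experiment(cfg, arch)
  expect_identical(ex$genotypes, ex2$genotypes)
  expect_identical(ex$phenotypes, ex2$phenotypes)

  # no transmissions: the final generation is the founder generation
  cfg0 <- experiment_config(n_selection_generations = 0L,
                            n_neutral_generations = 0L, rng_seed = 31)
  ex0 <- run_experiment(cfg0, arch)
  g <- ex0$genotypes[["LHB"]][["A"]]
  expect_equal(unname(g$gen1), unname(g$gen_final))
})
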