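#' Draw founder genotypes for every treatment and replicate
#'
#' Founders are drawn from Hardy--Weinberg proportions at each locus's
#' founder frequency, independently across loci and plants. Every replicate
#' line receives an independent draw from the same founder distribution,
#' emulating the random assignment of full-sib families to replicates.
#'
#' @param config An \code{\link{experiment_config}}.
#' @param arch A \code{\link{genetic_architecture}}.
#' @return A list with \code{genotypes} (integer matrix, plants x markers,
#'   dosages 0/1/2, rownames = plant ids) and \code{samples} (data frame of
#'   per-plant metadata: plant_id, treatment, group, soil_line, herbivory,
#'   pollination, replicate, generation, family).
#' @export
#' @examples
#' cfg <- experiment_config()
#' f <- simulate_founders(cfg, default_architecture())
#' nrow(f$samples)  # 8 treatments x 2 replicates x 49 plants = 784
simulate_founders <- function(config, arch) {
  stopifnot(inherits(config, "experiment_config"),
            inherits(arch, "genetic_architecture"))
  m <- nrow(arch)
  if (m == 0L) stop("architecture has zero loci")
  if (config$n_plants == 0L) stop("configuration has zero plants")

  reps <- replicate_labels(config$n_replicates)
  blocks <- list(); meta <- list()
  for (i in seq_len(nrow(config$treatments))) {
    trt <- config$treatments[i, ]
    for (r in seq_along(reps)) {
      set.seed(derive_seed(config$rng_seed, "founders", trt$treatment, reps[r]))
      G <- matrix(stats::rbinom(config$n_plants * m, 2L,
                                rep(arch$founder_freq, each = config$n_plants)),
                  nrow = config$n_plants, ncol = m,
                  dimnames = list(NULL, arch$marker))
      ids <- sprintf("%s_%s_g01_p%02d", trt$treatment, reps[r],
                     seq_len(config$n_plants))
      rownames(G) <- ids
      blocks[[length(blocks) + 1L]] <- G
      meta[[length(meta) + 1L]] <- data.frame(
        plant_id = ids,
        treatment = trt$treatment,
        group = treatment_group(trt$treatment),
        soil_line = trt$soil,
        herbivory = trt$herbivory,
        pollination = trt$pollination,
        replicate = reps[r],
        generation = 1L,
        family = (r - 1L) * config$n_plants + seq_len(config$n_plants),
        stringsAsFactors = FALSE
      )
    }
  }
  list(genotypes = do.call(rbind, blocks), samples = do.call(rbind, meta))
}

# Pollination/herbivory group code: treatment minus the soil prefix
# (LHB and THB both belong to group HB, etc.).
treatment_group <- function(treatment) sub("^[LT]", "", treatment)

#' Simulate the fitness-proxy trait (number of open flowers)
#'
#' Applies the generative model of \code{\link{trait_model}} to a genotype
#' matrix: additive marker effects, a soil-of-growth main effect, a
#' fitness-coupling term through which adaptation to the growth soil raises
#' flower production, a local-advantage shift for lines grown in their
#' native soil, and Gaussian noise.
#'
#' @param genotypes Dosage matrix (plants x markers) matching \code{samples}
#'   row-for-row.
#' @param samples Sample table with columns \code{soil_grown} and
#'   \code{soil_line}.
#' @param arch The \code{\link{genetic_architecture}}.
#' @param trait A \code{\link{trait_model}}.
#' @param seed Integer seed (the draw is deterministic given it).
#' @return \code{samples} with an added \code{open_flowers} column.
#' @export
simulate_phenotype <- function(genotypes, samples, arch, trait, seed = 1L) {
  if (!("soil_grown" %in% names(samples)))
    stop("samples must carry a soil_grown column")
  if (any(is.na(samples$soil_grown)) ||
      !all(samples$soil_grown %in% names(trait$soil_main)))
    stop("soil_grown contains labels missing from the trait model")
  if (nrow(genotypes) != nrow(samples))
    stop("genotypes and samples must have matching rows")

  soils <- attr(arch, "soils")
  s_mat <- as.matrix(arch[, paste0("s_", soils)])
  colnames(s_mat) <- soils
  gval <- drop(genotypes %*% arch$trait_effect)
  adapt <- genotypes %*% s_mat            # adaptation score in either soil
  grown <- match(samples$soil_grown, soils)
  adapt_grown <- adapt[cbind(seq_len(nrow(samples)), grown)]

  set.seed(seed)
  y <- trait$intercept +
    unname(trait$soil_main[samples$soil_grown]) +
    gval +
    trait$fitness_coupling * adapt_grown +
    trait$gxe_effect * as.numeric(samples$soil_grown == samples$soil_line) +
    stats::rnorm(nrow(samples), 0, trait$residual_sd)
  samples$open_flowers <- y
  samples
}

#' Seed contributions to the next generation
#'
#' Each plant's contribution quota is its seed set divided by the replicate
#' total, scaled to the replicate size: quotas always sum exactly to
#' \code{n_plants}. Integer offspring counts are obtained by largest-remainder
#' rounding, so they also sum exactly to \code{n_plants} and a plant with
#' zero seed set never reproduces.
#'
#' @param seed_sets Non-negative numeric vector, one entry per plant.
#' @param n_plants Target number of offspring.
#' @return A data frame of class \code{"reproduction_plan"} with columns
#'   \code{seed_set}, \code{contribution_quota}, \code{offspring_count}.
#' @export
#' @examples
#' plan <- contributions(c(10, 88), 49)
#' plan$contribution_quota  # 5.0 and 44.0
contributions <- function(seed_sets, n_plants) {
  if (any(seed_sets < 0)) stop("seed sets must be non-negative")
  total <- sum(seed_sets)
  if (total <= 0)
    stop("extinction: all seed sets are zero, the replicate cannot continue")
  quota <- seed_sets / total * n_plants
  base <- floor(quota)
  need <- n_plants - as.integer(sum(base))
  counts <- as.integer(base)
  if (need > 0L) {
    top <- order(quota - base, decreasing = TRUE)[seq_len(need)]
    counts[top] <- counts[top] + 1L
  }
  structure(data.frame(seed_set = seed_sets,
                       contribution_quota = quota,
                       offspring_count = counts),
            class = c("reproduction_plan", "data.frame"))
}

#' Advance one replicate line by one generation
#'
#' Implements one transmission of the greenhouse design for a single
#' replicate. During selective generations, expected seed set is multiplied
#' by \code{exp(sum(dosage * s[soil]))} (fecundity selection). Under bee
#' pollination only a visitation-limited set of plants reproduces: the
#' plants most attractive to bees -- attractiveness being the simulated
#' flower phenotype, through which soil adaptation is visible to the bees --
#' are visited, serve as seed parents, and exchange pollen among themselves.
#' Under hand pollination a random set of mother plants of equal expected
#' seed set is crossed with pollen from random donors. During wash-out
#' generations selection is off and pollination is by hand. Offspring are
#' produced by Mendelian transmission with distinct mother and father
#' (self-incompatibility), loci unlinked.
#'
#' @param genotypes Dosage matrix for the current generation of one replicate.
#' @param soil Soil this line evolves in.
#' @param pollination \code{"bee"} or \code{"hand"}.
#' @param selective Logical: apply fecundity selection and bee choice?
#' @param arch,config,trait Architecture, design and trait model.
#' @param ne Number of bee-visited seed parents (defaults to the treatment
#'   Ne, capped by the pollen-limitation budget).
#' @param seed Integer seed.
#' @return Dosage matrix of the next generation (same dimensions), with the
#'   \code{\link{contributions}} plan attached as attribute \code{"plan"}.
#' @export
select_and_mate <- function(genotypes, soil, pollination, selective,
                            arch, config, trait = trait_model(),
                            ne = NULL, seed = 1L) {
  n <- nrow(genotypes)
  if (n < 2L) stop("extinction: fewer than two plants")
  soils <- attr(arch, "soils")
  if (!soil %in% soils) stop("unknown soil: ", soil)

  set.seed(seed)
  s_soil <- arch[[paste0("s_", soil)]]
  adapt <- if (selective) drop(genotypes %*% s_soil) else numeric(n)
  w <- exp(adapt)

  if (pollination == "bee" && selective) {
    if (is.null(ne)) {
      ne <- config$treatments$ne[config$treatments$soil == soil &
                                   config$treatments$pollination == "bee"][1]
    }
    k <- min(ne, config$pollen_limitation, n)
    attract <- trait$intercept +
      drop(genotypes %*% arch$trait_effect) +
      trait$fitness_coupling * adapt +
      stats::rnorm(n, 0, trait$residual_sd)
    visited <- order(attract, decreasing = TRUE)[seq_len(k)]
    mothers <- visited
    father_pool <- visited
  } else {
    mothers <- sample.int(n, min(config$hand_mothers, n))
    father_pool <- seq_len(n)
  }

  seed_set <- numeric(n)
  seed_set[mothers] <- w[mothers]
  if (sum(seed_set > 0) < 2L)
    stop("extinction: fewer than two plants with nonzero seed set")
  plan <- contributions(seed_set, n)

  moms <- rep(seq_len(n), plan$offspring_count)
  dads <- vapply(moms, function(mm) {
    pool <- father_pool[father_pool != mm]
    pool[sample.int(length(pool), 1L)]
  }, integer(1))

  Gm <- genotypes[moms, , drop = FALSE]
  Gd <- genotypes[dads, , drop = FALSE]
  offspring <- matrix(
    stats::rbinom(length(Gm), 1L, Gm / 2) + stats::rbinom(length(Gd), 1L, Gd / 2),
    nrow = n, ncol = ncol(genotypes),
    dimnames = list(NULL, colnames(genotypes))
  )
  attr(offspring, "plan") <- plan
  attr(offspring, "parents") <- data.frame(mother = moms, father = dads)
  offspring
}

#' Run the full replicated evolution experiment
#'
#' Evolves every treatment x replicate line from generation 1 to the final
#' sampled generation (selection generations under the treatment's
#' pollination regime, then insect-free wash-out), and phenotypes the final
#' generation reciprocally in both soils together with generation-1 plants
#' in their native soil.
#'
#' @param config An \code{\link{experiment_config}}.
#' @param arch A \code{\link{genetic_architecture}}.
#' @param trait A \code{\link{trait_model}}.
#' @return A list of class \code{"adaptscan_experiment"}:
#'   \describe{
#'     \item{genotypes}{nested list \code{[[treatment]][[replicate]]} with
#'       matrices \code{gen1} and \code{gen_final};}
#'     \item{samples}{per-plant metadata for both sampled generations;}
#'     \item{phenotypes}{reciprocal-transplant trait table (final generation
#'       in both soils, generation 1 in its native soil);}
#'     \item{audit}{per-transmission conservation record of contribution
#'       quotas and offspring counts;}
#'     \item{truth}{the architecture (ground-truth locus classes);}
#'     \item{config, trait}{the inputs.}
#'   }
#' @export
run_experiment <- function(config, arch, trait = trait_model()) {
  founders <- simulate_founders(config, arch)
  reps <- replicate_labels(config$n_replicates)
  n_trans <- n_transmissions(config)
  gen_final <- final_generation(config)

  genotypes <- list(); audit <- list(); samples <- list(); phenos <- list()
  for (i in seq_len(nrow(config$treatments))) {
    trt <- config$treatments[i, ]
    genotypes[[trt$treatment]] <- list()
    for (r in reps) {
      sel <- founders$samples$treatment == trt$treatment &
        founders$samples$replicate == r
      G1 <- founders$genotypes[sel, , drop = FALSE]
      G <- G1
      if (n_trans > 0L) {
        for (t in seq_len(n_trans)) {
          selective <- t <= config$n_selection_generations
          G <- select_and_mate(
            G, soil = trt$soil,
            pollination = if (selective) trt$pollination else "hand",
            selective = selective, arch = arch, config = config,
            trait = trait, ne = trt$ne,
            seed = derive_seed(config$rng_seed, "trans", trt$treatment, r, t)
          )
          plan <- attr(G, "plan")
          audit[[length(audit) + 1L]] <- data.frame(
            treatment = trt$treatment, replicate = r, transmission = t,
            quota_sum = sum(plan$contribution_quota),
            offspring_sum = sum(plan$offspring_count),
            stringsAsFactors = FALSE
          )
        }
      }
      rownames(G) <- sprintf("%s_%s_g%02d_p%02d", trt$treatment, r,
                             gen_final, seq_len(nrow(G)))
      genotypes[[trt$treatment]][[r]] <- list(gen1 = G1, gen_final = G)

      meta1 <- founders$samples[sel, , drop = FALSE]
      metaF <- meta1
      metaF$plant_id <- rownames(G)
      metaF$generation <- gen_final
      samples[[length(samples) + 1L]] <- rbind(meta1, metaF)

      # reciprocal transplant: final generation in both soils,
      # generation 1 in its native soil only
      for (soil_grown in config$soils) {
        ph <- metaF
        ph$soil_grown <- soil_grown
        phenos[[length(phenos) + 1L]] <- simulate_phenotype(
          G, ph, arch, trait,
          seed = derive_seed(config$rng_seed, "pheno", trt$treatment, r,
                             gen_final, soil_grown)
        )
      }
      ph1 <- meta1
      ph1$soil_grown <- trt$soil
      phenos[[length(phenos) + 1L]] <- simulate_phenotype(
        G1, ph1, arch, trait,
        seed = derive_seed(config$rng_seed, "pheno", trt$treatment, r, 1L,
                           trt$soil)
      )
    }
  }

  structure(list(
    config = config, trait = trait, truth = arch,
    genotypes = genotypes,
    samples = do.call(rbind, samples),
    phenotypes = do.call(rbind, phenos),
    audit = do.call(rbind, audit)
  ), class = "adaptscan_experiment")
}

#' @export
print.adaptscan_experiment <- function(x, ...) {
  cat("adaptscan experiment:",
      nrow(x$config$treatments), "treatments x",
      x$config$n_replicates, "replicates x",
      x$config$n_plants, "plants;",
      nrow(x$truth), "loci\n")
  cat("  sampled generations: 1 and", final_generation(x$config), "\n")
  invisible(x)
}

#' Attach simulated fitness components to a phenotype table
#'
#' Adds the fitness-related columns used by the trait-association models:
#' bumblebee visit counts and first choices (Poisson, log-linear in the
#' standardized flower count) and a zero-inflated seed set (roughly half of
#' the plants set no seed; positive seed sets are log-normal and increase
#' with flower count).
#'
#' @param pheno Phenotype table with an \code{open_flowers} column.
#' @param flower_effect Strength of the flowers-to-fitness association on
#'   the linear predictor scale; 0 gives the null of no association.
#' @param seed Integer seed.
#' @return \code{pheno} with columns \code{visits}, \code{first_choices},
#'   \code{seed_set} added.
#' @export
simulate_fitness_components <- function(pheno, flower_effect = 0.8,
                                        seed = 1L) {
  if (!("open_flowers" %in% names(pheno)))
    stop("pheno must carry open_flowers")
  set.seed(seed)
  z <- as.numeric(scale(pheno$open_flowers))
  n <- nrow(pheno)
  pheno$visits <- stats::rpois(n, exp(0.4 + 0.5 * flower_effect * z))
  pheno$first_choices <- stats::rpois(n, exp(-0.7 + 0.6 * flower_effect * z))
  produces <- stats::rbinom(n, 1L, stats::plogis(flower_effect * z))
  pheno$seed_set <- produces *
    exp(stats::rnorm(n, 2 + 0.5 * flower_effect * z, 0.4))
  pheno
}
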