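#' Linear mixed model for genotype-by-environment local adaptation
#'
#' Fits the reciprocal-transplant model for one treatment group: trait ~
#' soil line (the soil the plants evolved in) x soil (the soil they were
#' grown in) as fixed factors with a random intercept per replicate line.
#' Fixed terms are tested by 1-df Wald chi-squares on the REML fit (type
#' III, sum-to-zero contrasts); a replicate variance estimated at the
#' boundary (zero) is legitimate and reported as such. A significant
#' interaction is the genomic-background signature of local adaptation.
#'
#' @param pheno Phenotype table with columns \code{soil_line},
#'   \code{soil_grown}, \code{replicate} and the trait.
#' @param trait Name of the trait column.
#' @return Object of class \code{"gxe_fit"}: \code{terms} (term, chisq, df,
#'   p_value), \code{cells} (soil_line, soil_grown, mean, se),
#'   \code{vcov_cells}, \code{replicate_variance}, \code{residual_df},
#'   \code{n}, and the underlying \code{model}.
#' @export
fit_gxe <- function(pheno, trait = "open_flowers") {
  for (col in c("soil_line", "soil_grown", "replicate", trait)) {
    if (!col %in% names(pheno)) stop("pheno is missing column ", col)
  }
  d <- data.frame(
    y = pheno[[trait]],
    soil_line = factor(pheno$soil_line),
    soil_grown = factor(pheno$soil_grown),
    replicate = factor(pheno$replicate)
  )
  if (nrow(d) == 0L || nlevels(d$soil_line) < 2L ||
      nlevels(d$soil_grown) < 2L)
    stop("every soil_line x soil cell needs data; a cell has fewer than 2 observations")
  cell_n <- table(d$soil_line, d$soil_grown)
  if (any(cell_n < 2L)) {
    bad <- which(cell_n < 2L, arr.ind = TRUE)[1, ]
    stop(sprintf("cell %s x %s has fewer than 2 observations",
                 rownames(cell_n)[bad[1]], colnames(cell_n)[bad[2]]))
  }
  stats::contrasts(d$soil_line) <- stats::contr.sum(nlevels(d$soil_line))
  stats::contrasts(d$soil_grown) <- stats::contr.sum(nlevels(d$soil_grown))

  mod <- suppressMessages(lme4::lmer(
    y ~ soil_line * soil_grown + (1 | replicate), data = d, REML = TRUE,
    control = lme4::lmerControl(check.conv.singular = "ignore")
  ))
  an <- car::Anova(mod, type = "III", test.statistic = "Chisq")
  keep <- c("soil_line", "soil_grown", "soil_line:soil_grown")
  terms <- data.frame(term = rownames(an), chisq = an[, "Chisq"],
                      df = an[, "Df"], p_value = an[, "Pr(>Chisq)"],
                      stringsAsFactors = FALSE)
  terms <- terms[terms$term %in% keep, , drop = FALSE]
  rownames(terms) <- NULL

  nd <- expand.grid(soil_line = levels(d$soil_line),
                    soil_grown = levels(d$soil_grown),
                    KEEP.OUT.ATTRS = FALSE)
  mm <- stats::model.matrix(
    ~ soil_line * soil_grown, nd,
    contrasts.arg = list(
      soil_line = stats::contr.sum(nlevels(d$soil_line)),
      soil_grown = stats::contr.sum(nlevels(d$soil_grown)))
  )
  beta <- lme4::fixef(mod)
  Vb <- as.matrix(stats::vcov(mod))
  cells <- cbind(nd, mean = drop(mm %*% beta),
                 se = sqrt(diag(mm %*% Vb %*% t(mm))))
  vc <- as.data.frame(lme4::VarCorr(mod))

  structure(list(
    model = mod, terms = terms, cells = cells,
    vcov_cells = mm %*% Vb %*% t(mm),
    replicate_variance = vc$vcov[vc$grp == "replicate"],
    residual_df = nrow(d) - length(beta),
    n = nrow(d)
  ), class = "gxe_fit")
}

#' Local-versus-foreign and home-versus-away contrasts
#'
#' "Local" cells are lines grown in the soil they evolved in; "foreign"
#' compares them with the other line grown in the same soil, "away" with
#' the same line grown in the other soil. Estimates are pooled over the two
#' soils (resp. lines); a positive estimate means the local/home plants
#' outperform. With two soils and two lines both contrasts reduce to the
#' same combination of the four cell means, so they share an estimate; they
#' are reported separately because the two criteria are conceptually
#' distinct and generalize differently. Standard errors come from the fixed
#' -effect covariance of the mixed model; degrees of freedom are the
#' residual df.
#'
#' @param fit A \code{\link{fit_gxe}} result.
#' @return Data frame with rows \code{local_vs_foreign} and
#'   \code{home_vs_away}: estimate, se, t, df, p_value.
#' @export
gxe_contrasts <- function(fit) {
  cells <- fit$cells
  if (nrow(cells) != 4L) stop("expected four soil_line x soil cells")
  local <- cells$soil_line == cells$soil_grown
  w_lf <- ifelse(local, 0.5, -0.5)
  w_ha <- w_lf  # identical combination in the 2x2 design; see docs
  one <- function(w, label) {
    est <- sum(w * cells$mean)
    se <- sqrt(drop(t(w) %*% fit$vcov_cells %*% w))
    t <- est / se
    data.frame(contrast = label, estimate = est, se = se, t = t,
               df = fit$residual_df,
               p_value = 2 * stats::pt(-abs(t), fit$residual_df),
               stringsAsFactors = FALSE)
  }
  rbind(one(w_lf, "local_vs_foreign"), one(w_ha, "home_vs_away"))
}

#' Local-adaptation verdict
#'
#' Local adaptation is called when the soil-line x soil interaction is
#' significant and the local-versus-foreign contrast is significantly
#' positive (no multiple-testing correction across traits).
#'
#' @param fit A \code{\link{fit_gxe}} result.
#' @param contrasts A \code{\link{gxe_contrasts}} result.
#' @param alpha Significance threshold.
#' @return List: \code{adapted} (logical), \code{interaction_p},
#'   \code{contrast_p}, \code{contrast_estimate}.
#' @export
assess_local_adaptation <- function(fit, contrasts, alpha = 0.05) {
  ip <- fit$terms$p_value[fit$terms$term == "soil_line:soil_grown"]
  lf <- contrasts[contrasts$contrast == "local_vs_foreign", ]
  list(adapted = isTRUE(ip < alpha && lf$p_value < alpha && lf$estimate > 0),
       interaction_p = ip, contrast_p = lf$p_value,
       contrast_estimate = lf$estimate)
}

#' Trait-fitness association models
#'
#' Quantifies how a candidate fitness-proxy trait relates to realized
#' fitness components. Because seed set is zero-inflated (about half the
#' plants set no seed under pollen limitation), two models are used: a
#' binary response model on seeds/no-seeds and a linear model restricted to
#' the seed-producing plants ("truncated" model). Bumblebee first choices
#' are modelled with a Poisson log-linear model, and the visit--seed-set
#' correlation is reported.
#'
#' @param pheno Phenotype table (see
#'   \code{\link{simulate_fitness_components}}); replicate, if present with
#'   more than one level, enters the models as a covariate.
#' @param trait Trait column used as the predictor.
#' @return List of class \code{"fitness_proxy_models"}: \code{binary},
#'   \code{truncated}, \code{poisson} (each: estimate, se, statistic,
#'   p_value, degenerate flag) and \code{visits_seeds} (r, p_value, n).
#' @export
fitness_proxy_models <- function(pheno, trait = "open_flowers") {
  z <- as.numeric(scale(pheno[[trait]]))
  use_rep <- "replicate" %in% names(pheno) &&
    length(unique(pheno$replicate)) > 1L
  rhs <- if (use_rep) "z + replicate" else "z"
  coef_row <- function(fit, test = "z") {
    s <- summary(fit)$coefficients
    data.frame(estimate = s[test, 1], se = s[test, 2],
               statistic = s[test, 3], p_value = s[test, 4],
               degenerate = FALSE, stringsAsFactors = FALSE)
  }
  degenerate_row <- function() {
    data.frame(estimate = NA_real_, se = NA_real_, statistic = NA_real_,
               p_value = NA_real_, degenerate = TRUE)
  }

  out <- list()
  if ("seed_set" %in% names(pheno)) {
    produces <- as.integer(pheno$seed_set > 0)
    if (length(unique(produces)) < 2L) {
      out$binary <- degenerate_row()
    } else {
      separated <- FALSE
      fit <- withCallingHandlers(
        stats::glm(stats::as.formula(paste("produces ~", rhs)),
                   data = cbind(pheno, z = z, produces = produces),
                   family = stats::binomial()),
        warning = function(w) {
          if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
            separated <<- TRUE
          invokeRestart("muffleWarning")
        })
      out$binary <- if (separated) degenerate_row() else coef_row(fit)
    }
    pos <- pheno$seed_set > 0
    if (sum(pos) >= 3L && stats::var(pheno$seed_set[pos]) > 0) {
      fit <- stats::lm(stats::as.formula(paste("seed_set ~", rhs)),
                       data = cbind(pheno, z = z)[pos, , drop = FALSE])
      out$truncated <- coef_row(fit)
    } else {
      out$truncated <- degenerate_row()
    }
  }
  if ("first_choices" %in% names(pheno)) {
    fit <- stats::glm(stats::as.formula(paste("first_choices ~", rhs)),
                      data = cbind(pheno, z = z), family = stats::poisson())
    out$poisson <- coef_row(fit)
  }
  if (all(c("visits", "seed_set") %in% names(pheno))) {
    ct <- stats::cor.test(pheno$visits, pheno$seed_set)
    out$visits_seeds <- list(r = unname(ct$estimate),
                             p_value = ct$p.value, n = nrow(pheno))
  }
  structure(out, class = "fitness_proxy_models")
}

#' Trait change between the first and final generation
#'
#' Compares trait values of generation-1 and final-generation plants grown
#' in their native soil (foreign-grown plants are excluded with a message),
#' using a mixed model with generation x treatment fixed effects and a
#' replicate random intercept, followed by within-treatment generation
#' contrasts.
#'
#' @param pheno Phenotype table covering both generations.
#' @param trait Trait column.
#' @return Data frame per treatment: estimate (final minus first), se, t,
#'   df, p_value.
#' @export
trait_evolution <- function(pheno, trait = "open_flowers") {
  foreign <- pheno$soil_grown != pheno$soil_line
  if (any(foreign)) {
    message("excluding ", sum(foreign), " foreign-grown plants")
    pheno <- pheno[!foreign, , drop = FALSE]
  }
  gens <- sort(unique(pheno$generation))
  if (length(gens) < 2L) stop("both generations must be present")
  d <- data.frame(
    y = pheno[[trait]],
    generation = factor(pheno$generation, levels = gens,
                        labels = c("first", "final")[seq_along(gens)]),
    treatment = factor(pheno$treatment),
    replicate = factor(pheno$replicate)
  )
  mod <- suppressMessages(lme4::lmer(
    y ~ generation * treatment + (1 | replicate), data = d, REML = TRUE,
    control = lme4::lmerControl(check.conv.singular = "ignore")
  ))
  beta <- lme4::fixef(mod)
  Vb <- as.matrix(stats::vcov(mod))
  df <- nrow(d) - length(beta)

  out <- lapply(levels(d$treatment), function(tr) {
    nd <- data.frame(generation = factor(c("first", "final"),
                                         levels = levels(d$generation)),
                     treatment = factor(tr, levels = levels(d$treatment)))
    mm <- stats::model.matrix(~ generation * treatment, nd)
    w <- mm[2, ] - mm[1, ]
    est <- sum(w * beta)
    se <- sqrt(drop(t(w) %*% Vb %*% w))
    data.frame(treatment = tr, estimate = est, se = se, t = est / se,
               df = df, p_value = 2 * stats::pt(-abs(est / se), df),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
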