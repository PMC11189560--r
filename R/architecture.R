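#' Genetic architecture of the simulated loci
#'
#' A locus table with per-locus founder allele frequency, selection
#' coefficients in the two soils, an additive effect on the fitness-proxy
#' trait, and a ground-truth class label:
#' \describe{
#'   \item{AP}{antagonistic pleiotropy -- selection coefficients of opposite
#'     sign in the two soils;}
#'   \item{CN_<soil>}{conditional neutrality -- selected in the named soil,
#'     coefficient exactly zero in the other;}
#'   \item{NEUTRAL}{zero coefficient in both soils.}
#' }
#'
#' Selection coefficients are on the log-fecundity scale: a plant's expected
#' seed set is multiplied by \code{exp(dosage * s[soil])} per locus.
#'
#' @param loci Data frame with columns \code{chrom}, \code{pos},
#'   \code{founder_freq}, \code{class}, \code{s_<soilA>}, \code{s_<soilB>}
#'   (one selection-coefficient column per soil) and \code{trait_effect}.
#'   A \code{marker} column is added if absent (\code{chrom_pos}).
#' @param soils Character vector of the two soil labels; must match the
#'   selection-coefficient columns.
#'
#' @return The validated data frame with class \code{"genetic_architecture"}
#'   and attribute \code{soils}.
#' @export
genetic_architecture <- function(loci, soils = c("limestone", "tuff")) {
  s_cols <- paste0("s_", soils)
  needed <- c("chrom", "pos", "founder_freq", "class", s_cols, "trait_effect")
  miss <- setdiff(needed, names(loci))
  if (length(miss)) stop("loci is missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(loci) == 0L) stop("architecture must contain at least one locus")
  if (any(loci$founder_freq <= 0 | loci$founder_freq >= 1))
    stop("founder_freq must lie strictly inside (0, 1)")

  ok_class <- c("AP", paste0("CN_", soils), "NEUTRAL")
  if (!all(loci$class %in% ok_class))
    stop("class must be one of: ", paste(ok_class, collapse = ", "))

  sA <- loci[[s_cols[1]]]; sB <- loci[[s_cols[2]]]
  ap <- loci$class == "AP"
  if (any(ap & (sA * sB >= 0)))
    stop("AP loci need selection coefficients of opposite sign in the two soils")
  cnA <- loci$class == paste0("CN_", soils[1])
  cnB <- loci$class == paste0("CN_", soils[2])
  if (any(cnA & (sB != 0 | sA == 0)) || any(cnB & (sA != 0 | sB == 0)))
    stop("CN loci must be selected in their soil and have zero coefficient in the other")
  neu <- loci$class == "NEUTRAL"
  if (any(neu & (sA != 0 | sB != 0)))
    stop("NEUTRAL loci must have zero selection coefficients")

  ord <- order(loci$chrom, loci$pos)
  loci <- loci[ord, , drop = FALSE]
  dup <- unlist(tapply(loci$pos, loci$chrom, function(p) duplicated(p)))
  if (any(dup)) stop("positions must be strictly increasing within a chromosome")
  if (!("marker" %in% names(loci)))
    loci$marker <- paste(loci$chrom, loci$pos, sep = "_")
  rownames(loci) <- NULL

  structure(loci, soils = soils, class = c("genetic_architecture", "data.frame"))
}

#' Default locus panel for the simulated experiment
#'
#' A compact genome of two chromosomes carrying loci under antagonistic
#' pleiotropy (opposite-sign coefficients, founder frequency 0.5 so both
#' directions of change have room), conditionally neutral loci for each
#' soil, and a neutral background whose founder frequencies follow the
#' U-shaped Beta(0.5, 0.5) spectrum typical of drifting variants (clipped
#' away from the boundaries to respect a minor-allele-frequency floor).
#'
#' Loci are spaced 5 kb apart so each occupies its own 2-kb pruning window,
#' except for a small set of deliberate close pairs that exercise window
#' pruning.
#'
#' @param n_ap,n_cn,n_neutral Locus counts per class (\code{n_cn} is split
#'   evenly between the two soils).
#' @param s Selection-coefficient magnitude (log fecundity per allele copy).
#' @param trait_effect Additive effect of selected loci on the trait.
#' @param soils The two soil labels.
#' @param seed Seed for drawing neutral founder frequencies.
#' @return A \code{\link{genetic_architecture}}.
#' @export
#' @examples
#' arch <- default_architecture()
#' table(arch$class)
default_architecture <- function(n_ap = 20L, n_cn = 16L, n_neutral = 150L,
                                 s = 0.5, trait_effect = 0.5,
                                 soils = c("limestone", "tuff"),
                                 seed = 2025L) {
  m <- n_ap + n_cn + n_neutral
  set.seed(seed)
  chrom <- rep(c("A01", "A02"), length.out = m)
  idx <- stats::ave(seq_len(m), chrom, FUN = seq_along)
  pos <- 1000L + (idx - 1L) * 5000L
  # a few close pairs (500 bp apart) so 2-kb windows contain >1 marker
  close <- which(idx %% 10L == 0L)
  pos[close] <- pos[close] - 4500L

  half <- n_cn %/% 2L
  class <- c(rep("AP", n_ap),
             rep(paste0("CN_", soils[1]), half),
             rep(paste0("CN_", soils[2]), n_cn - half),
             rep("NEUTRAL", n_neutral))
  # alternate the favoured soil across AP loci
  ap_sign <- rep(c(1, -1), length.out = n_ap)
  sA <- c(ap_sign * s, rep(s, half), rep(0, n_cn - half), rep(0, n_neutral))
  sB <- c(-ap_sign * s, rep(0, half), rep(s, n_cn - half), rep(0, n_neutral))
  freq <- c(rep(0.5, n_ap + n_cn),
            pmin(pmax(stats::rbeta(n_neutral, 0.5, 0.5), 0.05), 0.95))
  eff <- c(rep(trait_effect, n_ap + n_cn), rep(0, n_neutral))

  loci <- data.frame(chrom = chrom, pos = pos, founder_freq = freq,
                     class = class, trait_effect = eff,
                     stringsAsFactors = FALSE)
  loci[[paste0("s_", soils[1])]] <- sA
  loci[[paste0("s_", soils[2])]] <- sB
  genetic_architecture(loci, soils = soils)
}

#' Generative model for the fitness-proxy trait
#'
#' The simulated trait is the number of open flowers on pollination day.
#' For a plant with genotype dosages \eqn{g}, grown in soil \eqn{E} and
#' descending from the line evolved in soil \eqn{L}:
#' \deqn{y = \mu + m_E + \sum_j g_j a_j + c \sum_j g_j s_j(E) +
#'       d\,[E = L] + \varepsilon,\quad \varepsilon \sim N(0, \sigma^2)}
#' where \eqn{a_j} are the additive trait effects, \eqn{s_j(E)} the
#' selection coefficients in the growth soil, \eqn{c} the fitness coupling
#' (flower production tracks how well a genotype is adapted to the soil it
#' grows in -- this is what makes the flower count a fitness proxy and what
#' lets bee visitation select on soil adaptation), and \eqn{d} a residual
#' local-advantage term for lines grown in their native soil.
#'
#' @param intercept Baseline flower count.
#' @param soil_main Named numeric: additive soil-of-growth effect per soil.
#' @param gxe_effect Local-advantage shift \eqn{d} (flowers) added when the
#'   growth soil equals the line's native soil.
#' @param fitness_coupling Flowers per unit of the log-fecundity adaptation
#'   score \eqn{c}.
#' @param residual_sd Environmental standard deviation (flowers).
#' @return An object of class \code{"trait_model"}.
#' @export
trait_model <- function(intercept = 30,
                        soil_main = c(limestone = -3, tuff = 0),
                        gxe_effect = 3,
                        fitness_coupling = 8,
                        residual_sd = 6) {
  if (residual_sd < 0) stop("residual_sd must be non-negative")
  structure(list(intercept = intercept, soil_main = soil_main,
                 gxe_effect = gxe_effect,
                 fitness_coupling = fitness_coupling,
                 residual_sd = residual_sd),
            class = "trait_model")
}
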