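#' Simulate a neutral Wright--Fisher marker panel for CMH calibration
#'
#' For each marker and replicate, a founder frequency is drawn, an ideal
#' Wright--Fisher population of size \code{ne} drifts for \code{t} binomial
#' transmissions, and cohorts of \code{n_diploid} individuals are sampled at
#' the first and last generation. The returned allele-count table is the
#' input format of \code{\link{cmh_test}}, so the panel provides an exact
#' null (drift and sampling only, no selection) for type-I-error studies.
#'
#' @param n_markers Number of independent neutral markers.
#' @param ne Effective population size governing drift.
#' @param n_diploid Diploid sample size per cohort.
#' @param t Number of transmissions between the two sampled generations.
#' @param n_replicates Independent replicate populations (CMH strata).
#' @param freq_range Founder frequencies are drawn uniformly in this range.
#' @param seed Integer seed.
#' @return Data frame with one row per marker x replicate: \code{marker},
#'   \code{replicate}, \code{alt1}, \code{ref1}, \code{alt10}, \code{ref10}.
#' @export
simulate_drift_panel <- function(n_markers, ne = 25L, n_diploid = 49L,
                                 t = 9L, n_replicates = 2L,
                                 freq_range = c(0.1, 0.9), seed = 1L) {
  set.seed(seed)
  rows <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    p0 <- stats::runif(n_markers, freq_range[1], freq_range[2])
    p <- p0
    for (g in seq_len(t)) p <- stats::rbinom(n_markers, 2L * ne, p) / (2L * ne)
    a1 <- stats::rbinom(n_markers, 2L * n_diploid, p0)
    a10 <- stats::rbinom(n_markers, 2L * n_diploid, p)
    rows[[r]] <- data.frame(
      marker = paste0("m", seq_len(n_markers)),
      replicate = replicate_labels(n_replicates)[r],
      alt1 = a1, ref1 = 2L * n_diploid - a1,
      alt10 = a10, ref10 = 2L * n_diploid - a10,
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, rows)
}

#' Simulate a genotype/trait panel for marker-effect recovery studies
#'
#' Generates the kind of data the ridge-BLUP module is meant for: a dense
#' marker panel organized in short linkage blocks (each block of adjacent
#' markers tags one underlying diplotype, with a small per-marker discordance
#' rate, as in resequencing data where nearby SNPs are strongly correlated)
#' and a polygenic trait with a prescribed narrow-sense heritability. True
#' per-marker effects spread each block's effect over its tag markers.
#'
#' @param n Individuals.
#' @param n_blocks Number of underlying haplotype blocks.
#' @param block_size Tag markers per block (total markers =
#'   \code{n_blocks * block_size}).
#' @param discordance Probability that a tag marker's genotype is re-drawn
#'   independently of its block diplotype.
#' @param h2 Narrow-sense heritability of the trait.
#' @param seed Integer seed.
#' @return List with \code{X} (coded -1/0/1 marker matrix), \code{y}
#'   (standardized trait values) and \code{effects} (true marker effects).
#' @export
simulate_blup_panel <- function(n = 150L, n_blocks = 40L, block_size = 5L,
                                discordance = 0.02, h2 = 0.5, seed = 1L) {
  set.seed(seed)
  m <- n_blocks * block_size
  Z <- matrix(stats::rbinom(n * n_blocks, 2L, 0.5), n, n_blocks)
  X <- matrix(0L, n, m)
  g <- numeric(m)
  b <- stats::rnorm(n_blocks)
  for (k in seq_len(n_blocks)) {
    for (j in seq_len(block_size)) {
      col <- (k - 1L) * block_size + j
      redraw <- stats::runif(n) < 2 * discordance
      X[, col] <- ifelse(redraw, stats::rbinom(n, 2L, 0.5), Z[, k])
      g[col] <- b[k] / block_size
    }
  }
  X <- X - 1L
  colnames(X) <- sprintf("blk%02d_t%d",
                         rep(seq_len(n_blocks), each = block_size),
                         rep(seq_len(block_size), n_blocks))
  gv <- drop(X %*% g)
  ve <- stats::var(gv) * (1 - h2) / h2
  y <- gv + stats::rnorm(n, 0, sqrt(ve))
  list(X = X, y = as.numeric(scale(y)), effects = g)
}
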