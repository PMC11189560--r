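#' Options for allele-frequency-change testing
#'
#' @param drift_aware Inflate the per-stratum variance by the binomial drift
#'   variance accumulated over \code{t_generations} Wright--Fisher
#'   transmissions at effective size \code{ne}, so that drift alone does not
#'   produce significance. The classical test (\code{FALSE}) treats the two
#'   cohorts as samples from a fixed population.
#' @param ne Effective population size used by the drift term; \code{Inf}
#'   recovers the classical statistic exactly.
#' @param t_generations Transmissions between the sampled generations
#'   (nine for generations 1 and 10).
#' @param fdr_alpha Benjamini--Hochberg threshold on q-values.
#' @param window_bp Width of the linkage-pruning windows.
#' @return List of class \code{"cmh_options"}.
#' @export
cmh_options <- function(drift_aware = TRUE, ne = 25, t_generations = 9L,
                        fdr_alpha = 0.05, window_bp = 2000L) {
  if (ne < 2) stop("ne must be at least 2")
  if (t_generations < 1L) stop("t_generations must be at least 1")
  if (fdr_alpha <= 0 || fdr_alpha >= 1) stop("fdr_alpha must lie in (0, 1)")
  if (window_bp < 1L) stop("window_bp must be positive")
  structure(list(drift_aware = drift_aware, ne = as.numeric(ne),
                 t_generations = as.integer(t_generations),
                 fdr_alpha = fdr_alpha, window_bp = as.integer(window_bp)),
            class = "cmh_options")
}

#' Cochran--Mantel--Haenszel test of allele-frequency change
#'
#' Tests, per marker, whether allele counts differ between the two sampled
#' generations consistently across replicate strata. Writing \eqn{a_k} for
#' the generation-1 alt count in stratum \eqn{k}, with \eqn{E_k} and
#' \eqn{V_k} its hypergeometric mean and variance under the null of no
#' change, the statistic is
#' \deqn{X^2 = \left(\sum_k (a_k - E_k)\right)^2 / \sum_k V_k}
#' referred to chi-square with 1 df (no continuity correction, so the
#' statistic is exactly invariant to swapping the allele labels).
#'
#' In drift-aware mode each \eqn{V_k} is inflated by the drift variance of
#' the final-generation allele count over \eqn{t} transmissions at
#' effective size \eqn{N_e}:
#' \deqn{V_k' = V_k + n_{10,k}^2\, \hat p_k (1 - \hat p_k)
#'       \left[1 - (1 - 1/(2N_e))^{t}\right]}
#' with \eqn{\hat p_k} the pooled stratum frequency and \eqn{n_{10,k}} the
#' final-generation allele count. As \eqn{N_e \to \infty} the classical
#' statistic is recovered.
#'
#' Strata with a zero margin are dropped; a marker monomorphic in all
#' strata gets statistic 0 and p-value 1.
#'
#' @param counts Count table as produced by \code{\link{build_count_tables}}
#'   or \code{\link{simulate_drift_panel}} (columns marker, replicate,
#'   alt1, ref1, alt10, ref10).
#' @param opts A \code{\link{cmh_options}}.
#' @return Data frame: marker, statistic, p_value.
#' @export
cmh_test <- function(counts, opts = cmh_options()) {
  if (any(counts$alt1 < 0 | counts$ref1 < 0 | counts$alt10 < 0 |
            counts$ref10 < 0))
    stop("negative cell counts")
  n1 <- counts$alt1 + counts$ref1
  n10 <- counts$alt10 + counts$ref10
  N <- n1 + n10
  c1 <- counts$alt1 + counts$alt10
  c2 <- counts$ref1 + counts$ref10
  ok <- n1 > 0 & n10 > 0 & c1 > 0 & c2 > 0 & N > 1
  E <- ifelse(ok, n1 * c1 / N, 0)
  V <- ifelse(ok, n1 * n10 * c1 * c2 / (N^2 * (N - 1)), 0)
  if (opts$drift_aware) {
    p_hat <- ifelse(ok, c1 / N, 0)
    drift <- 1 - (1 - 1 / (2 * opts$ne))^opts$t_generations
    V <- V + ifelse(ok, n10^2 * p_hat * (1 - p_hat) * drift, 0)
  }
  dev <- ifelse(ok, counts$alt1 - E, 0)

  num <- tapply(dev, counts$marker, sum)
  den <- tapply(V, counts$marker, sum)
  stat <- ifelse(den > 0, num^2 / den, 0)
  data.frame(marker = names(num),
             statistic = unname(stat),
             p_value = unname(ifelse(den > 0,
                                     stats::pchisq(stat, 1, lower.tail = FALSE),
                                     1)),
             stringsAsFactors = FALSE)
}

#' Benjamini--Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment (monotone in the sorted order,
#' capped at 1).
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @return q-values in the input order.
#' @export
fdr_bh <- function(p_values) {
  if (!length(p_values)) return(numeric(0))
  if (any(is.na(p_values)) || any(p_values <= 0 | p_values > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Prune markers to one representative per genomic window
#'
#' Windows are non-overlapping, half-open, anchored at coordinate 1 on each
#' chromosome (\code{[1, w+1), [w+1, 2w+1), ...}). Within each window the
#' marker with the smallest p-value is the representative; ties go to the
#' smallest position.
#'
#' @param results A \code{\link{cmh_test}} result.
#' @param map Marker map (marker, chrom, pos).
#' @param window_bp Window width in bp.
#' @return \code{results} with added columns \code{chrom}, \code{pos},
#'   \code{window_id} and \code{pruned_representative}.
#' @export
prune_windows <- function(results, map, window_bp = 2000L) {
  idx <- match(results$marker, map$marker)
  if (anyNA(idx)) stop("markers missing from the map")
  results$chrom <- map$chrom[idx]
  results$pos <- map$pos[idx]
  results$window_id <- paste0(results$chrom, ":",
                              (results$pos - 1L) %/% window_bp)
  results$pruned_representative <- FALSE
  if (nrow(results)) {
    split_idx <- split(seq_len(nrow(results)), results$window_id)
    for (ii in split_idx) {
      best <- ii[order(results$p_value[ii], results$pos[ii])][1]
      results$pruned_representative[best] <- TRUE
    }
  }
  results
}

#' Significant markers of one treatment
#'
#' Applies the full inference chain for one treatment: window pruning, BH
#' correction across the window representatives, the q-value threshold, and
#' the replicate-consistency requirement that the allele-frequency change
#' has the same (nonzero) direction in both replicates.
#'
#' @param results \code{\link{cmh_test}} output for one treatment.
#' @param af \code{\link{af_change}} table for the same treatment (both
#'   replicates).
#' @param map Marker map.
#' @param opts A \code{\link{cmh_options}}.
#' @return Data frame per marker with statistic, p, q, window columns,
#'   \code{consistent} (replicate direction agreement) and
#'   \code{significant}; only window representatives carry a q-value.
#' @export
significant_set <- function(results, af, map, opts = cmh_options()) {
  res <- prune_windows(results, map, opts$window_bp)
  res$q_value <- NA_real_
  rep_rows <- which(res$pruned_representative)
  res$q_value[rep_rows] <- fdr_bh(res$p_value[rep_rows])

  deltas <- split(af$delta, af$marker)
  cons <- vapply(deltas, function(d) {
    length(d) >= 2L && all(!is.na(d)) && (all(d > 0) || all(d < 0))
  }, logical(1))
  res$consistent <- unname(cons[res$marker])
  res$consistent[is.na(res$consistent)] <- FALSE
  res$significant <- res$pruned_representative &
    !is.na(res$q_value) & res$q_value < opts$fdr_alpha & res$consistent
  res
}
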