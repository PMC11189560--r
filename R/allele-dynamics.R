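#' Alt-allele frequencies from a dosage matrix
#'
#' Frequency per marker is the dosage sum over twice the number of
#' non-missing calls; markers with no non-missing call get \code{NA}.
#'
#' @param genotypes Samples x markers dosage matrix (0/1/2, NA missing).
#' @param sample_mask Optional logical or integer index selecting rows.
#' @return Named numeric vector of frequencies in [0, 1].
#' @export
#' @examples
#' allele_freq(rbind(c(0, 2), c(1, 2), c(2, 2)))  # 0.5, 1.0
allele_freq <- function(genotypes, sample_mask = NULL) {
  if (!is.null(sample_mask)) {
    genotypes <- genotypes[sample_mask, , drop = FALSE]
    if (nrow(genotypes) == 0L) stop("sample_mask selects no samples")
  }
  called <- colSums(!is.na(genotypes))
  p <- colSums(genotypes, na.rm = TRUE) / (2 * called)
  p[called == 0L] <- NA_real_
  p
}

#' Allele-frequency change between the two sampled generations
#'
#' One row per marker for a single treatment x replicate: frequencies at
#' generation 1 and the final generation, their difference (final minus
#' first, signed on the alt allele), and non-missing allele counts.
#'
#' @param geno_gen1,geno_final Dosage matrices for the two generations.
#' @param map Marker map (marker, chrom, pos).
#' @param treatment,replicate Labels recorded in the output.
#' @return Data frame: marker, chrom, pos, treatment, replicate, p_gen1,
#'   p_gen10, delta, n_gen1, n_gen10.
#' @export
af_change <- function(geno_gen1, geno_final, map, treatment = NA_character_,
                      replicate = NA_character_) {
  if (is.null(geno_gen1) || is.null(geno_final))
    stop("both generations are required for ", treatment, "/", replicate)
  p1 <- allele_freq(geno_gen1)
  pF <- allele_freq(geno_final)
  data.frame(
    marker = map$marker, chrom = map$chrom, pos = map$pos,
    treatment = treatment, replicate = replicate,
    p_gen1 = unname(p1), p_gen10 = unname(pF),
    delta = unname(pF - p1),
    n_gen1 = unname(2L * colSums(!is.na(geno_gen1))),
    n_gen10 = unname(2L * colSums(!is.na(geno_final))),
    stringsAsFactors = FALSE
  )
}

#' Allele-frequency change for every treatment x replicate of an experiment
#'
#' @param experiment An \code{\link{run_experiment}} result.
#' @return Row-bound \code{\link{af_change}} tables (16 with the default
#'   design: 8 treatments x 2 replicates).
#' @export
af_change_all <- function(experiment) {
  map <- experiment$truth[, c("marker", "chrom", "pos")]
  out <- list()
  for (trt in names(experiment$genotypes)) {
    for (r in names(experiment$genotypes[[trt]])) {
      g <- experiment$genotypes[[trt]][[r]]
      out[[length(out) + 1L]] <- af_change(g$gen1, g$gen_final, map, trt, r)
    }
  }
  do.call(rbind, out)
}

#' Mean allele-frequency change over replicates
#'
#' @param af An \code{\link{af_change}} table covering both replicates.
#' @return Data frame per marker x treatment: \code{mean_delta} (arithmetic
#'   mean over replicates), \code{n_replicates}, and \code{excluded} --
#'   markers observed in fewer than two replicates are flagged and must not
#'   be used downstream.
#' @export
mean_af_change <- function(af) {
  key <- interaction(af$marker, af$treatment, drop = TRUE)
  agg <- do.call(rbind, lapply(split(af, key), function(d) {
    data.frame(marker = d$marker[1], treatment = d$treatment[1],
               mean_delta = mean(d$delta), n_replicates = nrow(d),
               stringsAsFactors = FALSE)
  }))
  agg$excluded <- agg$n_replicates < 2L
  rownames(agg) <- NULL
  agg
}

#' Stratified 2x2 allele-count tables for the CMH test
#'
#' For each marker and replicate, counts non-missing alt and ref alleles in
#' the generation-1 and final-generation cohorts. The replicates are the
#' strata of the Cochran--Mantel--Haenszel test.
#'
#' @param geno_gen1_by_rep,geno_final_by_rep Named lists (replicate ->
#'   dosage matrix) for the two generations of one treatment.
#' @param map Marker map.
#' @return Data frame: marker, replicate, alt1, ref1, alt10, ref10.
#' @export
build_count_tables <- function(geno_gen1_by_rep, geno_final_by_rep, map) {
  reps <- names(geno_gen1_by_rep)
  if (!length(reps)) stop("at least one replicate is required")
  out <- lapply(reps, function(r) {
    g1 <- geno_gen1_by_rep[[r]]; gF <- geno_final_by_rep[[r]]
    n1 <- 2L * colSums(!is.na(g1)); nF <- 2L * colSums(!is.na(gF))
    a1 <- colSums(g1, na.rm = TRUE); aF <- colSums(gF, na.rm = TRUE)
    data.frame(marker = map$marker, replicate = r,
               alt1 = unname(a1), ref1 = unname(n1 - a1),
               alt10 = unname(aF), ref10 = unname(nF - aF),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
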