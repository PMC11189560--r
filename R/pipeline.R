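#' Full genomic local-adaptation scan of a simulated (or assembled) dataset
#'
#' Chains the genomic modules over an experiment bundle: allele-frequency
#' change per treatment x replicate, replicate-stratified CMH tests with
#' window pruning, FDR control and replicate-direction consistency,
#' ridge-BLUP marker effects for the fitness-proxy trait per treatment x
#' replicate (trait Z-transformed within each fit, 60\% training split),
#' cross-replicate retention, and AP/CN classification per
#' pollination-herbivory group across the two soils.
#'
#' Classification gating follows the discard rules: an AP call requires the
#' marker to be significant in both soils' treatments; a CN call requires
#' significance in the soil carrying the large change (both with
#' replicate-consistent direction). With \code{strict_cn = TRUE} the
#' one-soil discard rule is applied to CN as well, i.e. CN also requires
#' significance in both soils.
#'
#' @param experiment A \code{\link{run_experiment}} bundle.
#' @param opts A \code{\link{cmh_options}}; the treatment-specific Ne from
#'   the experiment config is substituted per treatment.
#' @param train_fraction Training fraction of the marker-effect fits.
#' @param genes Optional gene table (\code{\link{read_gff3}}) for
#'   annotating classified markers within \code{flank_bp}.
#' @param flank_bp Gene-annotation flank.
#' @param strict_cn Apply the both-soils significance rule to CN calls.
#' @param seed Seed for the training splits.
#' @return List of class \code{"adaptscan_scan"}:
#'   \describe{
#'     \item{af}{per treatment x replicate allele-frequency change table;}
#'     \item{cmh}{named list (treatment) of \code{\link{significant_set}}
#'       tables;}
#'     \item{blup}{named list (treatment) of per-replicate
#'       \code{\link{fit_ridge_blup}} models;}
#'     \item{retained}{named list (treatment) of cross-replicate retained
#'       markers;}
#'     \item{calls}{data frame of per-marker classifications per group;}
#'     \item{summary}{named list (group) of \code{\link{summarize_classes}}
#'       tables.}
#'   }
#' @export
classify_experiment <- function(experiment, opts = cmh_options(),
                                train_fraction = 0.6, genes = NULL,
                                flank_bp = 1000L, strict_cn = FALSE,
                                seed = 1L) {
  config <- experiment$config
  map <- experiment$truth[, c("marker", "chrom", "pos")]
  af <- af_change_all(experiment)

  cmh <- list(); blup <- list(); retained <- list()
  for (i in seq_len(nrow(config$treatments))) {
    trt <- config$treatments[i, ]
    g <- experiment$genotypes[[trt$treatment]]
    reps <- names(g)

    counts <- build_count_tables(
      lapply(g, function(x) x$gen1),
      lapply(g, function(x) x$gen_final), map)
    t_opts <- opts
    t_opts$ne <- trt$ne
    res <- cmh_test(counts, t_opts)
    af_t <- af[af$treatment == trt$treatment, , drop = FALSE]
    cmh[[trt$treatment]] <- significant_set(res, af_t, map, t_opts)

    models <- list()
    for (r in reps) {
      ph <- experiment$phenotypes
      ph <- ph[ph$treatment == trt$treatment & ph$replicate == r &
                 ph$generation > 1L, , drop = FALSE]
      geno <- g[[r]]$gen_final
      rows <- match(ph$plant_id, rownames(geno))
      prep <- prepare_matrix(geno[rows, , drop = FALSE])
      split <- train_split(seq_len(nrow(ph)), train_fraction,
                           seed = derive_seed(seed, "split", trt$treatment, r))
      y <- as.numeric(scale(ph$open_flowers[split$training]))
      models[[r]] <- fit_ridge_blup(prep$X[split$training, , drop = FALSE], y)
    }
    blup[[trt$treatment]] <- models
    retained[[trt$treatment]] <-
      if (length(models) >= 2L) {
        cross_replicate_retain(models[[1]], models[[2]])
      } else models[[1]]$markers
  }

  calls <- classify_groups(experiment, af, cmh, blup, retained, genes,
                           flank_bp, strict_cn)
  summaries <- lapply(split(calls, calls$group), function(d) {
    n_sig <- attr(calls, "n_significant")[[d$group[1]]]
    summarize_classes(d$class, n_sig, genes = d$genes)
  })

  structure(list(af = af, cmh = cmh, blup = blup, retained = retained,
                 calls = calls, summary = summaries),
            class = "adaptscan_scan")
}

# Classify candidate markers group by group (a group pairs the two soils'
# treatments for one pollination x herbivory combination).
classify_groups <- function(experiment, af, cmh, blup, retained, genes,
                            flank_bp, strict_cn) {
  config <- experiment$config
  soils <- config$soils
  map <- experiment$truth
  trts <- config$treatments
  groups <- unique(treatment_group(trts$treatment))

  out <- list(); n_sig <- list()
  for (grp in groups) {
    trtA <- trts$treatment[trts$soil == soils[1] &
                             treatment_group(trts$treatment) == grp]
    trtB <- trts$treatment[trts$soil == soils[2] &
                             treatment_group(trts$treatment) == grp]
    sigA <- cmh[[trtA]]$marker[cmh[[trtA]]$significant]
    sigB <- cmh[[trtB]]$marker[cmh[[trtB]]$significant]
    keepA <- retained[[trtA]]; keepB <- retained[[trtB]]
    n_sig[[grp]] <- length(union(sigA, sigB))

    cand <- intersect(intersect(keepA, keepB), union(sigA, sigB))
    if (!length(cand)) next

    afA <- af[af$treatment == trtA & af$marker %in% cand, ]
    afB <- af[af$treatment == trtB & af$marker %in% cand, ]
    dA <- split(afA$delta, afA$marker)
    dB <- split(afB$delta, afB$marker)
    effA <- rowMeans(cbind(blup[[trtA]][[1]]$effects[cand],
                           blup[[trtA]][[2]]$effects[cand]))
    effB <- rowMeans(cbind(blup[[trtB]][[1]]$effects[cand],
                           blup[[trtB]][[2]]$effects[cand]))

    rows <- lapply(cand, function(mk) {
      cls <- classify_ap_cn(dA[[mk]], dB[[mk]])
      in_a <- mk %in% sigA; in_b <- mk %in% sigB
      if (cls$class == "AP" && !(in_a && in_b)) cls$class <- "OTHER"
      if (cls$class == "CN") {
        need <- if (strict_cn) in_a && in_b
        else if (identical(cls$cn_soil, "A")) in_a else in_b
        if (!need) cls$class <- "OTHER"
      }
      mrow <- map[map$marker == mk, ]
      gene_ids <- if (!is.null(genes)) {
        paste(annotate_genes(mrow$chrom, mrow$pos, genes, flank_bp),
              collapse = ",")
      } else NA_character_
      data.frame(marker = mk, group = grp, class = cls$class,
                 cn_soil = ifelse(cls$class == "CN", cls$cn_soil,
                                  NA_character_),
                 delta_a1 = dA[[mk]][1], delta_a2 = dA[[mk]][2],
                 delta_b1 = dB[[mk]][1], delta_b2 = dB[[mk]][2],
                 mean_delta_a = mean(dA[[mk]]),
                 mean_delta_b = mean(dB[[mk]]),
                 sig_a = in_a, sig_b = in_b,
                 effect_a = unname(effA[mk]), effect_b = unname(effB[mk]),
                 genes = gene_ids, stringsAsFactors = FALSE)
    })
    out[[grp]] <- do.call(rbind, rows)
  }
  calls <- if (length(out)) do.call(rbind, out) else
    data.frame(marker = character(), group = character(),
               class = character(), stringsAsFactors = FALSE)
  rownames(calls) <- NULL
  attr(calls, "n_significant") <- n_sig
  calls
}

#' @export
print.adaptscan_scan <- function(x, ...) {
  cat("adaptscan genomic scan\n")
  for (grp in names(x$summary)) {
    s <- x$summary[[grp]]
    cat(sprintf("  %s: AP %d, CN %d, other %d\n", grp,
                s$count[s$class == "AP"], s$count[s$class == "CN"],
                s$count[s$class == "OTHER"]))
  }
  invisible(x)
}
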