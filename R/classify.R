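#' Classify a marker as antagonistic pleiotropy or conditional neutrality
#'
#' Applies the threshold rules to the per-replicate allele-frequency changes
#' observed in the two soils (all inequalities strict):
#' \describe{
#'   \item{AP}{change of magnitude > \code{ap_min} in every replicate of
#'     both soils, with consistent direction across replicates within each
#'     soil and opposite direction between the soils;}
#'   \item{CN}{change of magnitude > \code{cn_large} in both replicates of
#'     one soil (either direction) and magnitude < \code{cn_small} in both
#'     replicates of the other;}
#'   \item{OTHER}{anything else.}
#' }
#' Both replicates must satisfy the rule individually. AP and CN are
#' mutually exclusive because \code{cn_small <= ap_min}.
#'
#' @param delta_soil_a,delta_soil_b Numeric vectors of per-replicate deltas
#'   (length = number of replicates, usually 2) for the two soils.
#' @param ap_min,cn_large,cn_small Threshold magnitudes.
#' @return List with \code{class} ("AP", "CN" or "OTHER") and
#'   \code{cn_soil} ("A", "B" or NA).
#' @export
#' @examples
#' classify_ap_cn(c(0.15, 0.16), c(-0.12, -0.13))$class  # "AP"
#' classify_ap_cn(c(0.25, 0.22), c(0.05, 0.03))$class    # "CN"
classify_ap_cn <- function(delta_soil_a, delta_soil_b,
                           ap_min = 0.1, cn_large = 0.2, cn_small = 0.1) {
  dA <- delta_soil_a; dB <- delta_soil_b
  if (any(is.na(dA)) || any(is.na(dB)))
    stop("missing replicate delta")
  same_dir <- function(d) all(d > 0) || all(d < 0)
  ap <- all(abs(dA) > ap_min) && all(abs(dB) > ap_min) &&
    same_dir(dA) && same_dir(dB) && (dA[1] * dB[1] < 0)
  if (ap) return(list(class = "AP", cn_soil = NA_character_))
  if (all(abs(dA) > cn_large) && all(abs(dB) < cn_small))
    return(list(class = "CN", cn_soil = "A"))
  if (all(abs(dB) > cn_large) && all(abs(dA) < cn_small))
    return(list(class = "CN", cn_soil = "B"))
  list(class = "OTHER", cn_soil = NA_character_)
}

#' Genes within a flanking window of a marker
#'
#' Returns genes whose interval (1-based inclusive) intersects
#' \code{[pos - flank_bp, pos + flank_bp]}, strand-agnostic; a marker inside
#' a gene always matches.
#'
#' @param chrom,pos Marker coordinates.
#' @param genes Gene table from \code{\link{read_gff3}}.
#' @param flank_bp Flank width on each side.
#' @return Character vector of gene ids (empty, with a warning, for a
#'   chromosome absent from the gene table).
#' @export
annotate_genes <- function(chrom, pos, genes, flank_bp = 1000L) {
  on_chrom <- genes$chrom == chrom
  if (!any(on_chrom)) {
    warning("no genes annotated on chromosome ", chrom)
    return(character(0))
  }
  g <- genes[on_chrom, , drop = FALSE]
  hit <- g$start <= pos + flank_bp & g$end >= pos - flank_bp
  g$gene_id[hit]
}

#' Class counts and percentages among significant markers
#'
#' Percentages are relative to the number of significant markers in the
#' treatment group and rounded half-up to one decimal, matching the usual
#' reporting style (24 AP among 861 significant markers is 2.8\%).
#'
#' @param classes Character vector of classes ("AP"/"CN"/"OTHER") for the
#'   classified markers of one group.
#' @param n_significant Denominator: significant markers in the group.
#' @param genes Optional list (parallel to \code{classes}) of gene-id
#'   vectors; the number of distinct genes over AP markers is then reported.
#' @return Data frame with one row per class: count, percent; attribute
#'   \code{"ap_genes"} carries the distinct AP gene count when genes are
#'   supplied.
#' @export
summarize_classes <- function(classes, n_significant, genes = NULL) {
  counts <- table(factor(classes, levels = c("AP", "CN", "OTHER")))
  pct <- if (n_significant > 0) {
    round_half_up(100 * as.numeric(counts) / n_significant, 1)
  } else rep(NA_real_, length(counts))
  out <- data.frame(class = names(counts), count = as.integer(counts),
                    percent = pct, stringsAsFactors = FALSE)
  if (!is.null(genes)) {
    ap_genes <- unique(unlist(genes[classes == "AP"]))
    attr(out, "ap_genes") <- length(ap_genes)
  }
  out
}

round_half_up <- function(x, digits = 0) {
  s <- 10^digits
  floor(x * s + 0.5) / s
}

#' Compare the prevalence of a marker pattern between two treatments
#'
#' Tests equality of two proportions (e.g., the fraction of significant
#' markers showing antagonistic pleiotropy in two treatment groups) with a
#' binary generalized linear model: the 1-df likelihood-ratio (deviance)
#' statistic of the treatment factor. The Pearson chi-square of the
#' corresponding 2x2 table is reported alongside.
#'
#' @param count_a,total_a Pattern count and significant-marker total in
#'   group A.
#' @param count_b,total_b Same for group B.
#' @return List: \code{statistic} and \code{p_value} (likelihood ratio),
#'   \code{pearson_statistic} and \code{pearson_p}.
#' @export
compare_prevalence <- function(count_a, total_a, count_b, total_b) {
  if (count_a > total_a || count_b > total_b)
    stop("count exceeds total")
  if (total_a <= 0 || total_b <= 0) stop("totals must be positive")
  resp <- cbind(c(count_a, count_b),
                c(total_a - count_a, total_b - count_b))
  grp <- factor(c("A", "B"))
  fit <- stats::glm(resp ~ grp, family = stats::binomial())
  lrt <- fit$null.deviance - fit$deviance
  tab <- matrix(c(count_a, total_a - count_a,
                  count_b, total_b - count_b), nrow = 2, byrow = TRUE)
  pear <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(lrt),
       p_value = stats::pchisq(lrt, 1, lower.tail = FALSE),
       pearson_statistic = unname(pear$statistic),
       pearson_p = unname(pear$p.value))
}
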