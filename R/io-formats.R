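#' Variant-filtering rules
#'
#' Hard filters applied when reading a VCF: indels and multiallelic records
#' are always dropped; site quality must exceed \code{min_quality}
#' (strictly); genotype (or site mean) depth must lie inside
#' \code{[min_depth, max_depth]} (inclusive); minor allele frequency,
#' computed from non-missing calls, must be at least \code{min_maf}.
#'
#' @param biallelic_only Keep only biallelic SNPs (always recommended).
#' @param min_quality Strict lower bound on the QUAL field.
#' @param min_depth,max_depth Inclusive depth bounds.
#' @param min_maf Inclusive minor-allele-frequency floor.
#' @param depth_mode \code{"genotype"} sets individual genotypes with DP
#'   outside the bounds to missing; \code{"site"} drops whole sites whose
#'   mean depth falls outside the bounds.
#' @return A list of class \code{"variant_filter_spec"}.
#' @export
variant_filter_spec <- function(biallelic_only = TRUE, min_quality = 20,
                                min_depth = 6L, max_depth = 100L,
                                min_maf = 0.01,
                                depth_mode = c("genotype", "site")) {
  if (min_maf < 0 || min_maf >= 0.5) stop("min_maf must lie in [0, 0.5)")
  if (min_depth > max_depth) stop("min_depth must not exceed max_depth")
  structure(list(biallelic_only = biallelic_only,
                 min_quality = min_quality,
                 min_depth = as.integer(min_depth),
                 max_depth = as.integer(max_depth),
                 min_maf = min_maf,
                 depth_mode = match.arg(depth_mode)),
            class = "variant_filter_spec")
}

#' Read and filter a VCF into a dosage matrix
#'
#' Parses a VCF (via \pkg{vcfR}), applies the filters of a
#' \code{\link{variant_filter_spec}}, and encodes genotypes as alt-allele
#' dosages 0/1/2 with \code{NA} for missing calls.
#'
#' @param path Path to a VCF file.
#' @param filter A \code{\link{variant_filter_spec}}.
#' @return List with \code{genotypes} (samples x markers dosage matrix) and
#'   \code{map} (data frame: marker, chrom, pos, ref, alt).
#' @export
read_vcf <- function(path, filter = variant_filter_spec()) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  if (ncol(v@gt) < 2L) stop("VCF has no sample columns")
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  qual <- suppressWarnings(as.numeric(fix$QUAL))
  keep <- rep(TRUE, nrow(fix))
  if (filter$biallelic_only) {
    keep <- keep & !grepl(",", fix$ALT, fixed = TRUE)
    keep <- keep & nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
      fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  }
  keep <- keep & !is.na(qual) & qual > filter$min_quality
  if (!any(keep)) {
    return(list(genotypes = matrix(NA_integer_, ncol(v@gt) - 1L, 0L),
                map = empty_marker_map()))
  }

  gt <- vcfR::extract.gt(v, element = "GT")
  dose <- gt_to_dosage(gt)           # markers x samples
  has_dp <- any(grepl("DP", v@fix[, "INFO"], fixed = TRUE)) ||
    any(grepl("DP", v@gt[, 1], fixed = TRUE))
  if (has_dp) {
    dp <- suppressWarnings(
      matrix(as.numeric(vcfR::extract.gt(v, element = "DP")),
             nrow = nrow(gt), ncol = ncol(gt))
    )
    if (filter$depth_mode == "genotype") {
      bad <- !is.na(dp) & (dp < filter$min_depth | dp > filter$max_depth)
      dose[bad] <- NA_integer_
    } else {
      mean_dp <- rowMeans(dp, na.rm = TRUE)
      keep <- keep & !is.na(mean_dp) &
        mean_dp >= filter$min_depth & mean_dp <= filter$max_depth
    }
  }

  n_called <- rowSums(!is.na(dose))
  p <- rowSums(dose, na.rm = TRUE) / (2 * pmax(n_called, 1L))
  maf <- pmin(p, 1 - p)
  keep <- keep & n_called > 0L & maf >= filter$min_maf

  dose <- dose[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  map <- data.frame(
    marker = ifelse(is.na(fix$ID) | fix$ID == ".",
                    paste(fix$CHROM, fix$POS, sep = "_"), fix$ID),
    chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE
  )
  G <- t(dose)
  colnames(G) <- map$marker
  list(genotypes = G, map = map)
}

gt_to_dosage <- function(gt) {
  d <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  clean <- sub(":.*$", "", gt)
  d[clean %in% c("0/0", "0|0")] <- 0L
  d[clean %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  d[clean %in% c("1/1", "1|1")] <- 2L
  d
}

empty_marker_map <- function() {
  data.frame(marker = character(), chrom = character(), pos = integer(),
             ref = character(), alt = character(), stringsAsFactors = FALSE)
}

#' Write a dosage matrix as a minimal VCF
#'
#' Emits a VCF 4.2 file with GT fields (unphased) from a 0/1/2 dosage
#' matrix; missing dosages become \code{./.}.
#'
#' @param genotypes Samples x markers dosage matrix (rownames = sample ids).
#' @param map Marker map (marker, chrom, pos, ref, alt).
#' @param path Output path.
#' @param qual QUAL value written for every record.
#' @export
write_vcf <- function(genotypes, map, path, qual = 30) {
  gt_code <- c("0/0", "0/1", "1/1")
  samples <- rownames(genotypes)
  if (is.null(samples)) samples <- paste0("S", seq_len(nrow(genotypes)))
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  body <- vapply(seq_len(nrow(map)), function(j) {
    g <- genotypes[, j]
    calls <- ifelse(is.na(g), "./.", gt_code[g + 1L])
    paste(c(map$chrom[j], map$pos[j], map$marker[j], map$ref[j], map$alt[j],
            qual, "PASS", ".", "GT", calls), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read/write the 012 dosage-matrix dialect
#'
#' The 012 format stores one individual per row (first column a 0-based row
#' index, then one dosage per marker, \code{-1} for missing), with sidecar
#' files \code{<prefix>.012.indv} (sample ids) and \code{<prefix>.012.pos}
#' (chromosome and position per marker).
#'
#' @param prefix Path prefix; files \code{<prefix>.012[.indv|.pos]} are used.
#' @return For the reader: list with \code{genotypes} and \code{map}.
#' @export
read_dosage_012 <- function(prefix) {
  main <- paste0(prefix, ".012")
  body <- utils::read.table(main, header = FALSE, sep = "\t",
                            colClasses = "numeric")
  mat <- as.matrix(body[, -1, drop = FALSE])
  pos_file <- paste0(prefix, ".012.pos")
  if (length(readLines(pos_file)) == 0L) {
    indv <- readLines(paste0(prefix, ".012.indv"))
    mat <- matrix(integer(0), nrow = length(indv), ncol = 0,
                  dimnames = list(indv, NULL))
    return(list(genotypes = mat,
                map = empty_marker_map()[, c("marker", "chrom", "pos",
                                             "ref", "alt")]))
  }
  if (length(mat) && !all(mat %in% c(-1, 0, 1, 2)))
    stop("012 format error: values outside {-1, 0, 1, 2} in ", main)
  mat[mat == -1] <- NA
  storage.mode(mat) <- "integer"
  indv <- readLines(paste0(prefix, ".012.indv"))
  pos <- utils::read.table(paste0(prefix, ".012.pos"), header = FALSE,
                           sep = "\t", colClasses = c("character", "integer"))
  map <- data.frame(marker = paste(pos[[1]], pos[[2]], sep = "_"),
                    chrom = pos[[1]], pos = pos[[2]],
                    ref = NA_character_, alt = NA_character_,
                    stringsAsFactors = FALSE)
  dimnames(mat) <- list(indv, map$marker)
  list(genotypes = mat, map = map)
}

#' @rdname read_dosage_012
#' @param genotypes Samples x markers dosage matrix (NA = missing).
#' @param map Marker map with \code{chrom} and \code{pos}.
#' @export
write_dosage_012 <- function(genotypes, map, prefix) {
  mat <- genotypes
  mat[is.na(mat)] <- -1L
  out <- cbind(seq_len(nrow(mat)) - 1L, mat)
  utils::write.table(out, paste0(prefix, ".012"), sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  ids <- rownames(genotypes)
  if (is.null(ids)) ids <- paste0("S", seq_len(nrow(genotypes)))
  writeLines(ids, paste0(prefix, ".012.indv"))
  utils::write.table(map[, c("chrom", "pos")], paste0(prefix, ".012.pos"),
                     sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(prefix)
}

#' Read gene models from a GFF3 file
#'
#' Keeps only features of type \code{gene} (1-based inclusive coordinates)
#' and returns them sorted by chromosome and start.
#'
#' @param path Path to a GFF3 file.
#' @return Data frame: \code{gene_id}, \code{chrom}, \code{start},
#'   \code{end}, \code{strand}.
#' @export
read_gff3 <- function(path) {
  g <- ape::read.gff(path, na.strings = c(".", "?"), GFF3 = TRUE)
  g <- g[g$type == "gene", , drop = FALSE]
  if (nrow(g) == 0L) {
    return(data.frame(gene_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  if (any(g$end < g$start))
    stop("GFF3 format error: feature with end < start")
  id <- sub(".*(?:^|;)ID=([^;]+).*", "\\1", g$attributes)
  noid <- !grepl("ID=", g$attributes)
  id[noid] <- paste0("gene", seq_len(sum(noid)))
  out <- data.frame(gene_id = id, chrom = as.character(g$seqid),
                    start = as.integer(g$start), end = as.integer(g$end),
                    strand = as.character(g$strand),
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a minimal GFF3 of gene models
#'
#' @param genes Data frame with \code{gene_id}, \code{chrom}, \code{start},
#'   \code{end} and optionally \code{strand}.
#' @param path Output path.
#' @export
write_gff3 <- function(genes, path) {
  strand <- if ("strand" %in% names(genes)) genes$strand else "+"
  lines <- sprintf("%s\tadaptscan\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                   genes$chrom, genes$start, genes$end, strand,
                   genes$gene_id)
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}
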