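# Small architectures and toy files built in code for the tests.

one_locus_arch <- function(freq = 0.5, s_a = 0, s_b = 0, trait_effect = 0,
                           class = NULL) {
  if (is.null(class)) {
    class <- if (s_a == 0 && s_b == 0) "NEUTRAL"
    else if (s_a != 0 && s_b != 0) "AP"
    else if (s_a != 0) "CN_limestone" else "CN_tuff"
  }
  genetic_architecture(data.frame(
    chrom = "A01", pos = 1000L, founder_freq = freq, class = class,
    s_limestone = s_a, s_tuff = s_b, trait_effect = trait_effect,
    stringsAsFactors = FALSE
  ))
}

neutral_arch <- function(m, freq = 0.5) {
  genetic_architecture(data.frame(
    chrom = "A01", pos = 1000L + 5000L * (seq_len(m) - 1L),
    founder_freq = freq, class = "NEUTRAL",
    s_limestone = 0, s_tuff = 0, trait_effect = 0,
    stringsAsFactors = FALSE
  ))
}

# VCF with one clean biallelic SNP, one indel, one triallelic record,
# one low-quality SNP, and per-genotype DP values.
write_toy_vcf <- function(path, n_extra_samples = 0) {
  samples <- c("S1", "S2", "S3",
               if (n_extra_samples > 0) paste0("X", seq_len(n_extra_samples)))
  gt <- function(...) paste(c(...), collapse = "\t")
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", samples), collapse = "\t"),
    gt("A01", "100", "snp1", "A", "G", "30", "PASS", ".", "GT:DP",
       "0/0:40", "0/1:40", "1/1:40",
       rep("0/1:40", n_extra_samples)),
    gt("A01", "200", "indel1", "AT", "A", "50", "PASS", ".", "GT:DP",
       "0/0:40", "0/1:40", "1/1:40",
       rep("0/0:40", n_extra_samples)),
    gt("A01", "300", "tri1", "A", "G,T", "50", "PASS", ".", "GT:DP",
       "0/0:40", "0/1:40", "1/2:40",
       rep("0/0:40", n_extra_samples)),
    gt("A01", "400", "lowq", "C", "T", "20", "PASS", ".", "GT:DP",
       "0/0:40", "0/1:40", "1/1:40",
       rep("0/0:40", n_extra_samples)),
    gt("A01", "500", "lowdp", "G", "A", "30", "PASS", ".", "GT:DP",
       "0/1:5", "0/1:40", "1/1:101",
       rep("0/1:40", n_extra_samples))
  )
  writeLines(lines, path)
  path
}

toy_genes <- function() {
  data.frame(
    gene_id = c("geneA", "geneB", "geneC"),
    chrom = c("A01", "A01", "A02"),
    start = c(5900L, 6100L, 100L),
    end = c(6500L, 6500L, 900L),
    strand = c("+", "-", "+"),
    stringsAsFactors = FALSE
  )
}

# Balanced reciprocal-transplant phenotype table with prescribed cell means.
gxe_data <- function(n_per_cell, local_shift = 0, sd = 1, seed = 1,
                     rep_effect = 0) {
  set.seed(seed)
  cells <- expand.grid(soil_line = c("limestone", "tuff"),
                       soil_grown = c("limestone", "tuff"),
                       replicate = c("A", "B"),
                       stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    local <- cells$soil_line[i] == cells$soil_grown[i]
    mu <- 30 + local_shift * local +
      rep_effect * (cells$replicate[i] == "B")
    data.frame(cells[i, ], open_flowers = rnorm(n_per_cell, mu, sd),
               row.names = NULL)
  }))
  out
}
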