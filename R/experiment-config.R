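#' Experimental-evolution design configuration
#'
#' Describes the replicated factorial greenhouse design: two soil types
#' crossed with herbivory (aphids present or absent) and pollination mode
#' (bumblebee or hand), giving eight treatment groups, each evolved as two
#' independent replicate lines of 49 plants.
#'
#' Effective population sizes default to the seed-parent averages of the
#' original design (21--28 plants per replicate, depending on treatment).
#' Under bee pollination the number of seed parents per generation is capped
#' at the treatment's Ne; under hand pollination a fixed number of randomly
#' chosen mother plants (default 28) is pollinated.
#'
#' @param soils Character vector of length 2: the two soil environments.
#' @param n_replicates Number of replicate lines per treatment.
#' @param n_plants Plants per replicate per generation.
#' @param n_selection_generations Number of transmissions with selection and
#'   treatment-specific pollination.
#' @param n_neutral_generations Number of terminal wash-out generations grown
#'   without insects (hand pollination, no selection). The sampled final
#'   generation is the last of these; with the defaults (8 selection + 2
#'   wash-out) generations 1 and 10 are sampled and nine transmissions
#'   separate them.
#' @param ne Named integer vector: effective population size per treatment.
#'   Names must be the treatment codes (e.g. \code{"LHB"}: limestone,
#'   herbivory, bee pollination; \code{"TNHH"}: tuff, no herbivory, hand
#'   pollination).
#' @param hand_mothers Number of mother plants pollinated by hand.
#' @param pollen_limitation Upper bound on plants visited per replicate under
#'   bee pollination (seven bees times five visits).
#' @param rng_seed Integer root seed; all per-population streams are derived
#'   from it deterministically.
#'
#' @return An object of class \code{"experiment_config"}: a list with the
#'   fields above plus \code{treatments}, a data frame with one row per
#'   treatment (columns \code{treatment}, \code{soil}, \code{herbivory},
#'   \code{pollination}, \code{ne}).
#' @export
#' @examples
#' cfg <- experiment_config()
#' cfg$treatments
experiment_config <- function(soils = c("limestone", "tuff"),
                              n_replicates = 2L,
                              n_plants = 49L,
                              n_selection_generations = 8L,
                              n_neutral_generations = 2L,
                              ne = c(LNHH = 28L, LHH = 26L, LNHB = 22L,
                                     LHB = 22L, TNHH = 28L, THH = 27L,
                                     TNHB = 23L, THB = 21L),
                              hand_mothers = 28L,
                              pollen_limitation = 35L,
                              rng_seed = 1L) {
  if (length(soils) != 2L || anyDuplicated(soils))
    stop("exactly two distinct soils are required")
  if (n_plants < 2L) stop("n_plants must be at least 2")
  if (n_replicates < 1L) stop("n_replicates must be at least 1")
  if (n_selection_generations < 0L || n_neutral_generations < 0L)
    stop("generation counts must be non-negative")

  treatments <- expand.grid(
    pollination = c("hand", "bee"),
    herbivory   = c("none", "aphids"),
    soil        = soils,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  treatments$treatment <- paste0(
    toupper(substr(treatments$soil, 1, 1)),
    ifelse(treatments$herbivory == "aphids", "H", "NH"),
    ifelse(treatments$pollination == "bee", "B", "H")
  )
  treatments <- treatments[, c("treatment", "soil", "herbivory", "pollination")]

  missing_ne <- setdiff(treatments$treatment, names(ne))
  if (length(missing_ne))
    stop("ne missing for treatment(s): ", paste(missing_ne, collapse = ", "))
  treatments$ne <- as.integer(ne[treatments$treatment])
  if (any(treatments$ne < 2L)) stop("every Ne must be at least 2")

  structure(list(
    soils = soils,
    n_replicates = as.integer(n_replicates),
    n_plants = as.integer(n_plants),
    n_selection_generations = as.integer(n_selection_generations),
    n_neutral_generations = as.integer(n_neutral_generations),
    treatments = treatments,
    hand_mothers = as.integer(hand_mothers),
    pollen_limitation = as.integer(pollen_limitation),
    rng_seed = as.integer(rng_seed)
  ), class = "experiment_config")
}

#' @export
print.experiment_config <- function(x, ...) {
  cat("Experimental-evolution design\n")
  cat("  soils:", paste(x$soils, collapse = " / "), "\n")
  cat("  treatments:", nrow(x$treatments),
      " replicates:", x$n_replicates,
      " plants/replicate:", x$n_plants, "\n")
  cat("  transmissions:", n_transmissions(x),
      sprintf("(%d with selection)", x$n_selection_generations), "\n")
  cat("  plants per generation:",
      nrow(x$treatments) * x$n_replicates * x$n_plants, "\n")
  invisible(x)
}

# Number of meioses separating the first and the final sampled generation.
# The wash-out generations are grown without insects; only transmissions
# *within* the wash-out phase (n - 1 of n wash-out generations) are free of
# selection, since the last selective generation reproduces under its
# treatment to found the first wash-out generation.
n_transmissions <- function(config) {
  config$n_selection_generations +
    max(config$n_neutral_generations - 1L, 0L)
}

# Final sampled generation label (generation 1 + transmissions).
final_generation <- function(config) 1L + n_transmissions(config)

# Deterministic child seed for a named stream, bounded below 2^31.
derive_seed <- function(root, ...) {
  tokens <- paste(c(root, ...), collapse = "/")
  h <- 0
  for (v in utf8ToInt(tokens)) h <- (h * 131 + v) %% 2147480009
  as.integer(h + 1)
}

replicate_labels <- function(n) LETTERS[seq_len(n)]
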