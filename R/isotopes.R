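#' Per-atom isotope distribution under a labeling state
#'
#' Natural isotopic abundances for C, H, N, O, S; under the `"nitrogen15"`
#' state only nitrogen is replaced by the two-point distribution
#' \{14N: 1 - enrichment, 15N: enrichment\}, emulating growth on
#' 15N-enriched minimal medium.
#'
#' @param element One of `"C"`, `"H"`, `"N"`, `"O"`, `"S"`.
#' @param label `"natural"` or `"nitrogen15"`.
#' @param enrichment Fraction of nitrogen atoms that are 15N (only used for
#'   `label = "nitrogen15"`); default 0.995, typical of metabolic labeling.
#' @return Tibble with columns `mass`, `abundance` (zero-probability isotopes
#'   dropped), plus `offset`, the nominal mass above the element's lightest
#'   isotope.
#' @export
element_distribution <- function(element, label = c("natural", "nitrogen15"),
                                 enrichment = 0.995) {
  label <- match.arg(label)
  if (!element %in% ELEMENTS) stop("unknown element: ", element)
  stopifnot(enrichment >= 0, enrichment <= 1)
  d <- ISOTOPE_TABLE[[element]]
  abundance <- d$abundance
  if (element == "N" && label == "nitrogen15") {
    abundance <- c(1 - enrichment, enrichment)
  }
  out <- tibble::tibble(
    mass = d$mass,
    abundance = abundance,
    offset = as.integer(round(d$mass - d$mass[1]))
  )
  out[out$abundance > 0, ]
}

# Convolve two centroided distributions keyed by integer nominal-mass offset.
# Probabilities multiply and sum over pairs; the centroid mass of each output
# offset is the probability-weighted mean of the contributing pair masses.
# Distributions are plain lists (offset, abundance, mass) internally: this
# sits in the innermost loop and data-frame overhead would dominate.
convolve_offset_dist <- function(a, b, floor_rel = 1e-15) {
  key <- as.vector(outer(a$offset, b$offset, `+`))
  p <- as.vector(outer(a$abundance, b$abundance, `*`))
  m <- as.vector(outer(a$mass, b$mass, `+`))
  ps <- rowsum(p, key)
  ms <- rowsum(p * m, key) / ps
  keep <- ps > floor_rel * max(ps)
  off <- as.integer(rownames(ps))[keep]
  ord <- order(off)
  list(offset = off[ord],
       abundance = as.vector(ps)[keep][ord],
       mass = as.vector(ms)[keep][ord])
}

# distribution of n independent atoms, by binary exponentiation
atom_power_dist <- function(d, n) {
  stopifnot(n >= 1)
  result <- NULL
  base <- d
  while (n > 0) {
    if (n %% 2 == 1) {
      result <- if (is.null(result)) base else convolve_offset_dist(result, base)
    }
    n <- n %/% 2
    if (n > 0) base <- convolve_offset_dist(base, base)
  }
  result
}

#' Theoretical isotopologue distribution of a peptide
#'
#' Convolves the per-atom isotope distributions of every atom in the
#' composition, aggregating isotopologues that share a nominal mass offset
#' into a single centroid at the abundance-weighted mean mass (the
#' granularity of centroided TOF data).  Peaks below `prune` relative to the
#' base peak are dropped and the distribution renormalized to sum to one.
#'
#' @param composition Named count vector (see [peptide_composition()]).
#' @inheritParams element_distribution
#' @param prune Relative-abundance pruning threshold in `[0, 0.01)`;
#'   default 1e-4, below the dynamic range of the instrument class emulated.
#' @return Tibble with columns `mass` (neutral, Da, strictly increasing) and
#'   `abundance` (summing to 1), with attributes `label` and `enrichment`.
#' @examples
#' p <- isotope_pattern(peptide_composition("SAMPLER"))
#' sum(p$abundance)
#' @export
isotope_pattern <- function(composition, label = c("natural", "nitrogen15"),
                            enrichment = 0.995, prune = 1e-4) {
  label <- match.arg(label)
  stopifnot(prune >= 0, prune < 0.01)
  composition <- as_composition(composition)
  present <- names(composition)[composition > 0]
  if (length(present) == 0) stop("empty composition has no isotope pattern")
  dist <- NULL
  for (el in present) {
    d0 <- element_distribution(el, label = label, enrichment = enrichment)
    d <- list(offset = d0$offset, abundance = d0$abundance, mass = d0$mass)
    dn <- atom_power_dist(d, composition[[el]])
    dist <- if (is.null(dist)) dn else convolve_offset_dist(dist, dn)
  }
  keep <- dist$abundance > prune * max(dist$abundance)
  out <- tibble::tibble(
    mass = dist$mass[keep],
    abundance = dist$abundance[keep] / sum(dist$abundance[keep])
  )
  attr(out, "label") <- label
  attr(out, "enrichment") <- if (label == "nitrogen15") enrichment else NA_real_
  out
}

#' Project a neutral isotope pattern to m/z at a charge state
#'
#' `m/z = (neutral mass + charge * proton mass) / charge`; abundances are
#' unchanged.
#'
#' @param pattern Tibble from [isotope_pattern()].
#' @param charge Positive integer charge state.
#' @return Tibble with columns `mz`, `abundance`.
#' @export
pattern_to_mz <- function(pattern, charge) {
  if (length(charge) != 1 || charge < 1 || charge != round(charge)) {
    stop("charge must be a positive integer")
  }
  tibble::tibble(
    mz = (pattern$mass + charge * PROTON_MASS) / charge,
    abundance = pattern$abundance
  )
}
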