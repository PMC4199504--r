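#' Elemental composition of a peptide
#'
#' Sums residue compositions over a peptide sequence and adds one water for
#' the termini.  With `carbamidomethyl = TRUE` (the default, matching standard
#' iodoacetamide alkylation during sample preparation) every cysteine
#' additionally gains C2H3NO.
#'
#' @param sequence Peptide sequence, uppercase one-letter codes (canonical 20).
#' @param carbamidomethyl Apply the fixed carbamidomethyl-Cys modification?
#' @return Named integer vector with counts for C, H, N, O, S.
#' @examples
#' peptide_composition("G")  # glycine: C2 H5 N O2
#' @export
peptide_composition <- function(sequence, carbamidomethyl = TRUE) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  if (!nzchar(sequence)) {
    stop("peptide sequence must be non-empty")
  }
  residues <- strsplit(sequence, "")[[1]]
  bad <- which(!residues %in% CANONICAL_RESIDUES)
  if (length(bad) > 0) {
    stop(sprintf("non-canonical residue '%s' at position %d in '%s'",
                 residues[bad[1]], bad[1], sequence))
  }
  counts <- colSums(RESIDUE_COMPOSITIONS[residues, , drop = FALSE]) +
    WATER_COMPOSITION
  if (carbamidomethyl) {
    n_cys <- sum(residues == "C")
    counts <- counts + n_cys * CARBAMIDOMETHYL_COMPOSITION
  }
  storage.mode(counts) <- "integer"
  counts
}

#' Monoisotopic mass of an elemental composition
#'
#' Sum of atom counts times the mass of each element's lightest isotope.
#'
#' @param composition Named numeric vector of C, H, N, O, S counts
#'   (as returned by [peptide_composition()]).
#' @return Mass in Da.
#' @export
monoisotopic_mass <- function(composition) {
  composition <- as_composition(composition)
  sum(composition * MONO_MASS)
}

#' Molecular formula in Hill order
#'
#' @param composition Named numeric vector of element counts.
#' @return Formula string, e.g. `"C2H5NO2"`.
#' @export
composition_formula <- function(composition) {
  composition <- as_composition(composition)
  hill <- c("C", "H", "N", "O", "S")
  parts <- vapply(hill, function(el) {
    n <- composition[[el]]
    if (n == 0) "" else if (n == 1) el else paste0(el, n)
  }, character(1))
  paste(parts, collapse = "")
}

# Coerce and validate a composition vector: named, covers C/H/N/O/S,
# non-negative integer counts.
as_composition <- function(composition) {
  if (length(composition) == 0) {
    return(stats::setNames(numeric(length(ELEMENTS)), ELEMENTS))
  }
  if (is.null(names(composition))) {
    stop("composition must be a named vector of element counts")
  }
  unknown <- setdiff(names(composition), ELEMENTS)
  if (length(unknown) > 0) {
    stop("unknown element(s): ", paste(unknown, collapse = ", "))
  }
  full <- stats::setNames(numeric(length(ELEMENTS)), ELEMENTS)
  full[names(composition)] <- composition
  if (any(full < 0) || any(full != round(full))) {
    stop("element counts must be non-negative integers")
  }
  full
}
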