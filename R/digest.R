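#' Read a protein set from a FASTA file
#'
#' Wraps `Biostrings::readAAStringSet()` and validates the records: the header
#' token before the first whitespace becomes the protein id, sequences are
#' uppercased, ids must be unique, and every residue must be one of the 20
#' canonical amino acids.
#'
#' @param path Path to a (multi-record) FASTA file.
#' @return A tibble with columns `protein_id`, `sequence`.
#' @export
read_proteome <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(
    Biostrings::readAAStringSet(path),
    error = function(e) stop("malformed FASTA '", path, "': ", conditionMessage(e),
                             call. = FALSE)
  )
  if (length(set) == 0) {
    return(tibble::tibble(protein_id = character(), sequence = character()))
  }
  ids <- vapply(strsplit(names(set), "\\s+"), `[[`, character(1), 1)
  proteins <- tibble::tibble(
    protein_id = ids,
    sequence = unname(toupper(as.character(set)))
  )
  validate_proteome(proteins)
  proteins
}

#' Write a protein set to FASTA
#'
#' @param proteins Tibble with columns `protein_id`, `sequence`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_proteome <- function(proteins, path) {
  validate_proteome(proteins)
  set <- Biostrings::AAStringSet(stats::setNames(proteins$sequence,
                                                 proteins$protein_id))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

validate_proteome <- function(proteins) {
  stopifnot(is.data.frame(proteins),
            all(c("protein_id", "sequence") %in% names(proteins)))
  dup <- unique(proteins$protein_id[duplicated(proteins$protein_id)])
  if (length(dup) > 0) {
    stop("duplicate protein id(s): ", paste(dup, collapse = ", "))
  }
  for (i in seq_len(nrow(proteins))) {
    seq <- proteins$sequence[i]
    if (!nzchar(seq)) stop("empty sequence for protein ", proteins$protein_id[i])
    residues <- strsplit(seq, "")[[1]]
    bad <- which(!residues %in% CANONICAL_RESIDUES)
    if (length(bad) > 0) {
      stop(sprintf("non-canonical residue '%s' at position %d of protein %s",
                   residues[bad[1]], bad[1], proteins$protein_id[i]))
    }
  }
  invisible(proteins)
}

#' In-silico tryptic digest of one protein sequence
#'
#' Cleaves after K or R except when the next residue is proline (the standard
#' trypsin rule, Mascot convention), then enumerates all peptides carrying
#' 0..`max_missed` internal missed cleavages, in order of position.
#'
#' @param sequence Protein sequence (uppercase, canonical residues).
#' @param max_missed Maximum number of internal missed cleavages (default 1).
#' @param min_length,max_length Peptide length window retained (defaults 6 and
#'   30 residues, a typical detectability window for ESI-TOF instruments).
#'   Pass `min_length = 1, max_length = Inf` for an unfiltered digest.
#' @return Tibble with columns `peptide`, `start`, `missed_cleavages`.
#' @examples
#' tryptic_digest("MKGPRVITTK", max_missed = 0, min_length = 1)
#' @export
tryptic_digest <- function(sequence, max_missed = 1,
                           min_length = 6, max_length = 30) {
  stopifnot(is.character(sequence), length(sequence) == 1, nzchar(sequence),
            max_missed >= 0)
  residues <- strsplit(sequence, "")[[1]]
  n <- length(residues)
  # cut after position i when residue is K/R and successor exists and is not P
  cuts <- which(residues %in% c("K", "R"))
  cuts <- cuts[cuts < n & residues[pmin(cuts + 1, n)] != "P"]
  bounds <- c(0L, cuts, n)
  starts <- bounds[-length(bounds)] + 1L
  ends <- bounds[-1]
  n_seg <- length(starts)

  out <- list()
  for (mc in 0:max_missed) {
    if (mc + 1 > n_seg && mc > 0) break
    first <- seq_len(max(n_seg - mc, 0))
    if (length(first) == 0) next
    out[[mc + 1]] <- tibble::tibble(
      peptide = vapply(first, function(i) {
        paste(residues[starts[i]:ends[i + mc]], collapse = "")
      }, character(1)),
      start = starts[first],
      missed_cleavages = mc
    )
  }
  pep <- dplyr::bind_rows(out)
  pep <- pep[nchar(pep$peptide) >= min_length & nchar(pep$peptide) <= max_length, ]
  dplyr::arrange(pep, .data$start, .data$missed_cleavages)
}

#' Build the unique-peptide quantitation index
#'
#' Digests every protein, marks peptide sequences shared by more than one
#' protein as non-unique (they are retained for audit but excluded from
#' quantitation downstream), and attaches elemental compositions and
#' monoisotopic masses.
#'
#' @param proteins Tibble with columns `protein_id`, `sequence`.
#' @inheritParams tryptic_digest
#' @param carbamidomethyl Apply fixed carbamidomethyl-Cys? Default `TRUE`.
#' @return Tibble with one row per (protein, peptide): `protein_id`, `peptide`,
#'   `missed_cleavages`, element counts `nC`..`nS`, `formula` (Hill order),
#'   `monoisotopic_mass`, `is_unique`.
#' @export
peptide_index <- function(proteins, max_missed = 1, min_length = 6,
                          max_length = 30, carbamidomethyl = TRUE) {
  validate_proteome(proteins)
  if (nrow(proteins) == 0) stop("protein set is empty")
  digested <- purrr::map2_dfr(
    proteins$protein_id, proteins$sequence,
    function(id, seq) {
      d <- tryptic_digest(seq, max_missed = max_missed,
                          min_length = min_length, max_length = max_length)
      d$protein_id <- id
      d
    }
  )
  if (nrow(digested) == 0) {
    stop("digest produced no peptides within the length window")
  }
  # one row per (protein, peptide), keeping the fewest-missed-cleavage form
  digested <- digested |>
    dplyr::group_by(.data$protein_id, .data$peptide) |>
    dplyr::slice_min(.data$missed_cleavages, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()

  n_parents <- digested |>
    dplyr::distinct(.data$peptide, .data$protein_id) |>
    dplyr::count(.data$peptide, name = "n_proteins")
  digested <- dplyr::left_join(digested, n_parents, by = "peptide")

  comps <- t(vapply(digested$peptide, peptide_composition,
                    numeric(length(ELEMENTS)),
                    carbamidomethyl = carbamidomethyl))
  colnames(comps) <- paste0("n", ELEMENTS)

  tibble::tibble(
    protein_id = digested$protein_id,
    peptide = digested$peptide,
    missed_cleavages = digested$missed_cleavages,
    tibble::as_tibble(comps),
    formula = apply(comps, 1, function(x) {
      composition_formula(stats::setNames(x, ELEMENTS))
    }),
    monoisotopic_mass = comps %*% MONO_MASS |> as.numeric(),
    is_unique = digested$n_proteins == 1
  ) |>
    dplyr::arrange(.data$protein_id, .data$monoisotopic_mass)
}

#' Look up index peptides inside a mass window
#'
#' @param index Peptide index from [peptide_index()].
#' @param mass Query neutral monoisotopic mass (Da).
#' @param tolerance_ppm Half-width of the window in parts per million.
#' @return The index rows whose monoisotopic mass lies within the window.
#' @export
peptides_in_window <- function(index, mass, tolerance_ppm = 10) {
  stopifnot(tolerance_ppm > 0, mass > 0)
  dplyr::filter(index,
                abs(.data$monoisotopic_mass - mass) <= mass * tolerance_ppm * 1e-6)
}

# row of the index -> named composition vector
index_composition <- function(row) {
  stats::setNames(as.numeric(row[paste0("n", ELEMENTS)]), ELEMENTS)
}
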