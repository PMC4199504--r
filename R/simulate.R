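#' Describe a double-spike sample mixture
#'
#' A sample design captures everything the spectrum simulator needs: the
#' amount of experimental 14N-labeled particles, the two internal-standard
#' amounts (the "double spike": 14N- and 15N-labeled mature particles added
#' to every sample so that each 15N peak has a guaranteed 14N partner), the
#' 15N labeling efficiency, the charge states emitted, and the noise model.
#'
#' Defaults follow the published mixing design: 20 pmol experimental sample,
#' 10 pmol 14N spike, 30 pmol 15N spike.
#'
#' @param experimental_pmol Amount of experimental 14N particles (pmol).
#' @param spike14_pmol 14N internal-standard amount (pmol), default 10.
#' @param spike15_pmol 15N internal-standard amount (pmol), default 30.
#' @param enrichment 15N labeling fraction of the 15N spike, default 0.995.
#' @param charges Integer charge states emitted per peptide, default `c(2, 3)`
#'   (typical ESI charge states of tryptic peptides).
#' @param noise_cv Coefficient of variation of multiplicative log-normal
#'   intensity noise, default 0.05; set 0 for noiseless spectra.
#' @param baseline Mean of the uniform additive intensity floor, default 0.
#' @param mz_jitter_ppm Gaussian m/z jitter (ppm), default 0 (off).
#' @param response_factor Intensity units per pmol per unit isotopologue
#'   abundance, identical for all peptides (the 15N standard cancels
#'   peptide-specific efficiency; see [simulate_spectrum()]'s `efficiency`).
#' @param seed RNG seed making the simulated spectrum reproducible.
#' @return A `sample_design` list.
#' @export
sample_design <- function(experimental_pmol = 20, spike14_pmol = 10,
                          spike15_pmol = 30, enrichment = 0.995,
                          charges = c(2L, 3L), noise_cv = 0.05, baseline = 0,
                          mz_jitter_ppm = 0, response_factor = 1e4, seed = 1L) {
  stopifnot(experimental_pmol >= 0, spike14_pmol >= 0, spike15_pmol >= 0,
            enrichment >= 0, enrichment <= 1, length(charges) >= 1,
            all(charges >= 1), noise_cv >= 0, baseline >= 0,
            mz_jitter_ppm >= 0, response_factor > 0)
  structure(
    list(experimental_pmol = experimental_pmol, spike14_pmol = spike14_pmol,
         spike15_pmol = spike15_pmol, enrichment = enrichment,
         charges = as.integer(charges), noise_cv = noise_cv,
         baseline = baseline, mz_jitter_ppm = mz_jitter_ppm,
         response_factor = response_factor, seed = as.integer(seed)),
    class = "sample_design"
  )
}

#' @export
print.sample_design <- function(x, ...) {
  cat("<sample_design> ",
      x$experimental_pmol, " pmol experimental + double spike (",
      x$spike14_pmol, " pmol 14N / ", x$spike15_pmol, " pmol 15N), ",
      "enrichment ", x$enrichment, ", charges {",
      paste(x$charges, collapse = ","), "}, noise_cv ", x$noise_cv,
      ", seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Derive the spike-alone reference design
#'
#' The double-spike mixture measured in isolation: the same design with the
#' experimental amount set to zero.
#'
#' @param design A [sample_design()].
#' @return A `sample_design` with `experimental_pmol = 0`.
#' @export
spike_alone_design <- function(design) {
  design$experimental_pmol <- 0
  design
}

#' Designs for a standard-curve dilution series
#'
#' One design per amount, differing from `base` only in `experimental_pmol`
#' (the published series is 0, 2, 4, 8, 16, 32 pmol of 14N 70S particles
#' mixed with the double spike).
#'
#' @param amounts Non-empty vector of experimental amounts (pmol), each >= 0.
#' @param base Template [sample_design()].
#' @return Named list of `sample_design` objects.
#' @export
standard_curve_designs <- function(amounts, base = sample_design()) {
  if (length(amounts) == 0) stop("amounts must be non-empty")
  if (any(amounts < 0)) stop("amounts must be >= 0")
  designs <- lapply(amounts, function(a) {
    d <- base
    d$experimental_pmol <- a
    d
  })
  stats::setNames(designs, paste0(amounts, "pmol"))
}

#' Generate a synthetic ribosomal-protein set
#'
#' Random protein sequences with the size range and lysine/arginine-rich
#' composition typical of bacterial large-subunit ribosomal proteins, labeled
#' with the field's protein names (L20 first, then L2, L3, ...).  Entirely
#' synthetic: these are not the real *B. subtilis* sequences, only a
#' realistic stand-in whose tryptic digest has similar peptide statistics.
#'
#' @param n_proteins Number of proteins, default 20.
#' @param seed RNG seed.
#' @param length_range Protein length range in residues, default 90--180.
#' @return Tibble with columns `protein_id`, `sequence`.
#' @export
simulate_proteome <- function(n_proteins = 20, seed = 42L,
                              length_range = c(90, 180)) {
  stopifnot(n_proteins >= 1, length(length_range) == 2,
            length_range[1] >= 10)
  # r-proteins are basic: K/R upweighted relative to average globular proteins
  freq <- c(A = 0.080, R = 0.080, N = 0.040, D = 0.050, C = 0.005, E = 0.060,
            Q = 0.035, G = 0.075, H = 0.020, I = 0.060, L = 0.090, K = 0.090,
            M = 0.025, F = 0.040, P = 0.035, S = 0.055, T = 0.055, W = 0.010,
            Y = 0.035, V = 0.070)
  ids <- c("L20", "L6", "L16", "L27", "L28", "L33", "L35", "L36",
           paste0("L", c(1:5, 9:15, 17:19, 21:26, 29:32, 34)))
  if (n_proteins > length(ids)) {
    ids <- c(ids, paste0("P", seq_len(n_proteins - length(ids))))
  }
  withr::with_seed(seed, {
    lens <- sample(seq(length_range[1], length_range[2]), n_proteins,
                   replace = TRUE)
    seqs <- vapply(lens, function(n) {
      paste(sample(names(freq), n, replace = TRUE, prob = freq), collapse = "")
    }, character(1))
  })
  tibble::tibble(protein_id = ids[seq_len(n_proteins)], sequence = seqs)
}

#' Theoretical 14N/15N envelope pairs for an index
#'
#' Precomputes, for every unique peptide and charge, the m/z positions and
#' abundances of the natural-abundance (14N) and 15N-enriched envelopes.
#' Both the spectrum simulator and the peak-pair matcher consume this table;
#' computing it once per index saves repeated convolutions.
#'
#' @param index Peptide index from [peptide_index()].
#' @param charges Integer charge states.
#' @param enrichment 15N enrichment of the labeled channel.
#' @param prune Isotope-pattern pruning threshold (see [isotope_pattern()]).
#' @return Tibble with columns `protein_id`, `peptide`, `charge`, `channel`
#'   (`"N14"` or `"N15"`), `mz`, `abundance`.
#' @export
peptide_envelopes <- function(index, charges = c(2L, 3L), enrichment = 0.995,
                              prune = 1e-4) {
  peptides <- dplyr::filter(index, .data$is_unique)
  if (nrow(peptides) == 0) stop("index contains no unique peptides")
  comp_mat <- as.matrix(peptides[, paste0("n", ELEMENTS)])
  chunks <- vector("list", nrow(peptides))
  for (i in seq_len(nrow(peptides))) {
    comp <- stats::setNames(comp_mat[i, ], ELEMENTS)
    p14 <- isotope_pattern(comp, "natural", prune = prune)
    p15 <- isotope_pattern(comp, "nitrogen15", enrichment = enrichment,
                           prune = prune)
    mass <- c(p14$mass, p15$mass)
    abundance <- c(p14$abundance, p15$abundance)
    channel <- rep(c("N14", "N15"), c(nrow(p14), nrow(p15)))
    k <- length(mass)
    chunks[[i]] <- data.frame(
      protein_id = peptides$protein_id[i],
      peptide = peptides$peptide[i],
      charge = rep(as.integer(charges), each = k),
      channel = rep(channel, length(charges)),
      mz = as.vector(vapply(charges, function(z) {
        (mass + z * PROTON_MASS) / z
      }, numeric(k))),
      abundance = rep(abundance, length(charges))
    )
  }
  tibble::as_tibble(do.call(rbind, chunks))
}

#' Simulate a centroided MS1 spectrum of a double-spike mixture
#'
#' For each unique peptide and charge, the 14N envelope is emitted with
#' amplitude `response_factor * (experimental_pmol * occupancy + spike14_pmol)`
#' and the 15N envelope with amplitude `response_factor * spike15_pmol`;
#' occupancy is the fraction of experimental particles carrying the peptide's
#' parent protein (1 for proteins absent from `truth`).  Centroids closer
#' than the merge bin (0.005 m/z) are summed.  Multiplicative log-normal
#' noise, an additive uniform baseline, and optional m/z jitter are applied
#' under the design's seed, so identical inputs give byte-identical spectra.
#'
#' @param index Peptide index from [peptide_index()].
#' @param design A [sample_design()].
#' @param truth Optional occupancy ground truth: named numeric vector or
#'   tibble with columns `protein_id`, `occupancy`.  Missing proteins
#'   default to occupancy 1.
#' @param efficiency Optional per-peptide ionization-efficiency map (named
#'   numeric vector keyed by peptide sequence; default 1 for all).  Scales
#'   both channels of a peptide equally, as electrospray response does.
#' @param envelopes Optional precomputed [peptide_envelopes()] table
#'   (must match the design's charges and enrichment).
#' @param label Metadata label, `"sample"` or `"spike_alone"`.
#' @return Tibble with columns `mz` (strictly increasing), `intensity`;
#'   attributes `design` and `label`.
#' @export
simulate_spectrum <- function(index, design, truth = NULL, efficiency = NULL,
                              envelopes = NULL, label = "sample") {
  stopifnot(inherits(design, "sample_design"))
  if (is.null(envelopes)) {
    envelopes <- peptide_envelopes(index, charges = design$charges,
                                   enrichment = design$enrichment)
  }
  occ <- occupancy_lookup(truth)
  eff <- efficiency %||% numeric(0)

  amp <- envelopes |>
    dplyr::mutate(
      occupancy = dplyr::coalesce(occ[.data$protein_id], 1),
      eff = dplyr::coalesce(eff[.data$peptide], 1),
      amplitude = dplyr::if_else(
        .data$channel == "N14",
        design$response_factor *
          (design$experimental_pmol * .data$occupancy + design$spike14_pmol),
        design$response_factor * design$spike15_pmol
      ) * .data$eff,
      intensity = .data$amplitude * .data$abundance
    )

  peaks <- merge_centroids(amp$mz, amp$intensity, bin = 0.005)

  withr::with_seed(design$seed, {
    n <- nrow(peaks)
    if (design$mz_jitter_ppm > 0) {
      peaks$mz <- peaks$mz *
        (1 + stats::rnorm(n, 0, design$mz_jitter_ppm * 1e-6))
    }
    if (design$noise_cv > 0) {
      sdlog <- sqrt(log(1 + design$noise_cv^2))
      peaks$intensity <- peaks$intensity *
        stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    }
    if (design$baseline > 0) {
      peaks$intensity <- peaks$intensity +
        design$baseline * stats::runif(n, 0, 2)
    }
  })
  peaks <- peaks[order(peaks$mz), ]
  out <- tibble::as_tibble(peaks)
  attr(out, "design") <- design
  attr(out, "label") <- label
  out
}

# sum intensities of centroids falling within `bin` m/z of each other;
# merged position is the intensity-weighted mean
merge_centroids <- function(mz, intensity, bin = 0.005) {
  ord <- order(mz)
  mz <- mz[ord]
  intensity <- intensity[ord]
  cluster <- cumsum(c(1, diff(mz) > bin))
  isum <- as.vector(rowsum(intensity, cluster))
  wmz <- as.vector(rowsum(mz * intensity, cluster))
  # zero-intensity clusters are unobservable; position the rest by intensity
  out <- tibble::tibble(
    mz = ifelse(isum > 0, wmz / isum,
                as.vector(rowsum(mz, cluster)) / tabulate(cluster)),
    intensity = isum
  )
  out[out$intensity > 0, ]
}

# Accept truth as NULL, named vector, or tibble(protein_id, occupancy);
# return a named vector for lookup.
occupancy_lookup <- function(truth) {
  if (is.null(truth)) return(stats::setNames(numeric(0), character(0)))
  if (is.data.frame(truth)) {
    stopifnot(all(c("protein_id", "occupancy") %in% names(truth)))
    truth <- stats::setNames(truth$occupancy, truth$protein_id)
  }
  if (any(truth < 0)) stop("occupancy values must be >= 0")
  truth
}

#' Write / read a centroided peak list
#'
#' Plain two-column CSV (`mz`, `intensity`) so that third-party centroided
#' exports can be substituted for simulated spectra.
#'
#' @param spectrum Tibble with columns `mz`, `intensity`.
#' @param path File path.
#' @return `write_peaks()` returns `path` invisibly; `read_peaks()` returns
#'   the peak tibble sorted by m/z.
#' @export
write_peaks <- function(spectrum, path) {
  utils::write.csv(spectrum[, c("mz", "intensity")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_peaks
#' @export
read_peaks <- function(path) {
  if (!file.exists(path)) stop("peak list not found: ", path)
  df <- utils::read.csv(path)
  if (!all(c("mz", "intensity") %in% names(df))) {
    names(df)[1:2] <- c("mz", "intensity")
  }
  stopifnot(is.numeric(df$mz), is.numeric(df$intensity),
            all(df$intensity >= 0))
  tibble::as_tibble(df[order(df$mz), c("mz", "intensity")])
}
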