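#' Corrected per-peptide ratios for one sample spectrum
#'
#' Convenience wrapper running pair fitting on the sample and the spike-alone
#' spectra, forming 15N-normalized raw ratios, and subtracting the
#' spike-alone contribution.
#'
#' @param sample_spectrum,spike_spectrum Centroid peak tibbles
#'   (`mz`, `intensity`).
#' @inheritParams fit_peak_pairs
#' @return Corrected ratio tibble (see [spike_correct()]).
#' @export
corrected_ratios <- function(sample_spectrum, spike_spectrum, index = NULL,
                             charges = c(2L, 3L), tolerance_ppm = 10,
                             enrichment = 0.995, envelopes = NULL,
                             snr_min = 3, residual_max = 0.3) {
  if (is.null(envelopes)) {
    envelopes <- peptide_envelopes(index, charges = charges,
                                   enrichment = enrichment)
  }
  fit1 <- fit_peak_pairs(sample_spectrum, envelopes = envelopes,
                         tolerance_ppm = tolerance_ppm,
                         snr_min = snr_min, residual_max = residual_max)
  fit0 <- fit_peak_pairs(spike_spectrum, envelopes = envelopes,
                         tolerance_ppm = tolerance_ppm,
                         snr_min = snr_min, residual_max = residual_max)
  spike_correct(raw_ratios(fit1), raw_ratios(fit0))
}

#' Full occupancy quantitation of one sample
#'
#' Runs the whole pipeline — peak-pair fitting of sample and spike-alone
#' spectra, 15N normalization, spike subtraction, median aggregation, and
#' reference-protein normalization — and returns the per-protein occupancy
#' table.
#'
#' @inheritParams corrected_ratios
#' @inheritParams protein_occupancy
#' @return An `occupancy_table` (see [protein_occupancy()]).
#' @export
quantify_spectrum <- function(sample_spectrum, spike_spectrum, index = NULL,
                              reference = "L20", charges = c(2L, 3L),
                              tolerance_ppm = 10, enrichment = 0.995,
                              envelopes = NULL, snr_min = 3,
                              residual_max = 0.3) {
  corrected <- corrected_ratios(sample_spectrum, spike_spectrum,
                                index = index, charges = charges,
                                tolerance_ppm = tolerance_ppm,
                                enrichment = enrichment,
                                envelopes = envelopes, snr_min = snr_min,
                                residual_max = residual_max)
  protein_occupancy(corrected, reference = reference)
}

#' Simulate and quantify a full standard-curve series
#'
#' Simulates each curve point (experimental amounts mixed with the double
#' spike) and the spike-alone reference, runs the pipeline on every point,
#' and fits the dose-response line.
#'
#' @param index Peptide index from [peptide_index()].
#' @param amounts Experimental amounts (pmol), default the published series
#'   `c(0, 2, 4, 8, 16, 32)`.
#' @param base Template [sample_design()] (enrichment, noise, seed, ...).
#' @inheritParams standard_curve
#' @inheritParams corrected_ratios
#' @return A `spike_curve` object.
#' @export
run_standard_curve <- function(index, amounts = c(0, 2, 4, 8, 16, 32),
                               base = sample_design(), reference_amount = 20,
                               tolerance_ppm = 10, snr_min = 3,
                               residual_max = 0.3) {
  envelopes <- peptide_envelopes(index, charges = base$charges,
                                 enrichment = base$enrichment)
  designs <- standard_curve_designs(amounts, base)
  spike <- simulate_spectrum(index, spike_alone_design(base),
                             envelopes = envelopes, label = "spike_alone")
  tables <- lapply(designs, function(d) {
    spec <- simulate_spectrum(index, d, envelopes = envelopes)
    corrected_ratios(spec, spike, envelopes = envelopes,
                     tolerance_ppm = tolerance_ppm, snr_min = snr_min,
                     residual_max = residual_max)
  })
  standard_curve(tables, amounts, reference_amount = reference_amount,
                 spike15_pmol = base$spike15_pmol)
}
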