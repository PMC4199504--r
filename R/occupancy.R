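#' Per-peptide raw 14N/15N ratios from accepted fits
#'
#' The 15N internal standard comes from a fixed amount of 15N-labeled 70S
#' ribosomes in every sample, so dividing each peptide's fitted 14N amplitude
#' by its 15N amplitude cancels preparation and ionization variation.
#' Fits with a zero 15N amplitude cannot be normalized and are excluded with
#' a message.
#'
#' @param fits Fit table from [fit_peak_pairs()]; only `accepted` rows are
#'   used.
#' @param use_overlapping Include fits flagged as overlapping windows?
#'   Default `FALSE` (they were fitted jointly and are kept out of summary
#'   statistics).
#' @return Tibble `protein_id`, `peptide`, `charge`, `ratio_raw`.
#' @export
raw_ratios <- function(fits, use_overlapping = FALSE) {
  records <- dplyr::filter(fits, .data$accepted)
  if (!use_overlapping) {
    records <- dplyr::filter(records, !.data$overlapping)
  }
  bad <- dplyr::filter(records, .data$amp15 <= 0)
  if (nrow(bad) > 0) {
    message(nrow(bad), " fit(s) excluded: zero 15N amplitude")
    records <- dplyr::filter(records, .data$amp15 > 0)
  }
  records |>
    dplyr::mutate(ratio_raw = .data$amp14 / .data$amp15) |>
    dplyr::select("protein_id", "peptide", "charge", "ratio_raw")
}

#' Subtract the double spike's 14N contribution
#'
#' Every sample carries 10 pmol of 14N-labeled reference particles, so the
#' measured 14N amplitude overstates the experimental material.  After 15N
#' normalization the spike's contribution is a per-peptide constant, measured
#' once from the double-spike mixture in isolation and removed by simple
#' subtraction on the ratio scale:
#' `ratio_corrected = ratio_raw(sample) - ratio_raw(spike alone)`.
#'
#' Peptides absent from the spike-alone run fall back to the spike-alone
#' median ratio of their parent protein (flagged `fallback`); peptides whose
#' protein is entirely absent are excluded with a message.  Negative
#' corrected ratios are reported and flagged, never clamped — clamping would
#' bias occupancy exactly where depletion calls live.
#'
#' @param sample_ratios,spike_ratios Ratio tables from [raw_ratios()] for the
#'   experimental sample and the spike-alone reference run.
#' @return Tibble `protein_id`, `peptide`, `charge`, `ratio_raw`,
#'   `ratio_corrected`, `fallback`, `negative`.
#' @export
spike_correct <- function(sample_ratios, spike_ratios) {
  spike_pep <- spike_ratios |>
    dplyr::group_by(.data$protein_id, .data$peptide, .data$charge) |>
    dplyr::summarise(spike_ratio = stats::median(.data$ratio_raw),
                     .groups = "drop")
  spike_prot <- spike_ratios |>
    dplyr::group_by(.data$protein_id) |>
    dplyr::summarise(spike_protein_ratio = stats::median(.data$ratio_raw),
                     .groups = "drop")
  out <- sample_ratios |>
    dplyr::left_join(spike_pep, by = c("protein_id", "peptide", "charge")) |>
    dplyr::left_join(spike_prot, by = "protein_id") |>
    dplyr::mutate(fallback = is.na(.data$spike_ratio) &
                    !is.na(.data$spike_protein_ratio),
                  spike_ratio = dplyr::coalesce(.data$spike_ratio,
                                                .data$spike_protein_ratio))
  missing <- dplyr::filter(out, is.na(.data$spike_ratio))
  if (nrow(missing) > 0) {
    message(nrow(missing),
            " peptide(s) excluded: not measured in the spike-alone run")
    out <- dplyr::filter(out, !is.na(.data$spike_ratio))
  }
  out |>
    dplyr::mutate(ratio_corrected = .data$ratio_raw - .data$spike_ratio,
                  negative = .data$ratio_corrected < 0) |>
    dplyr::select("protein_id", "peptide", "charge", "ratio_raw",
                  "ratio_corrected", "fallback", "negative")
}

#' Protein occupancy normalized to a stoichiometric reference
#'
#' Aggregates corrected per-peptide ratios to a per-protein median and
#' divides by the reference protein's median (L20 by default, a
#' primary-binding protein present stoichiometrically in every particle), so
#' differences in total sample load cancel.  The reference protein's
#' occupancy is exactly 1 by construction.  Values may exceed 1; no ceiling
#' is applied.  Occupancies below 0.1 — the validated quantitation limit,
#' corresponding to 2 pmol of experimental material under the standard
#' 20 pmol load — are flagged `below_loq`.
#'
#' @param corrected Corrected ratio table from [spike_correct()].
#' @param reference Reference protein id, default `"L20"`.  Absent reference
#'   is a hard error: silently renormalizing to something else would change
#'   the meaning of every value.
#' @param aggregate `"median"` (default) or `"mean"`.
#' @param loq Occupancy quantitation limit used for flagging, default 0.1.
#' @return An `occupancy_table`: tibble `protein_id`, `median_corrected_ratio`,
#'   `occupancy`, `n_peptides`, `below_loq`, with the per-peptide detail in
#'   attribute `"detail"` and the reference id in attribute `"reference"`.
#' @export
protein_occupancy <- function(corrected, reference = "L20",
                              aggregate = c("median", "mean"), loq = 0.1) {
  aggregate <- match.arg(aggregate)
  agg_fun <- if (aggregate == "median") stats::median else mean
  if (!reference %in% corrected$protein_id) {
    stop("reference protein '", reference,
         "' has no accepted corrected ratios")
  }
  per_protein <- corrected |>
    dplyr::group_by(.data$protein_id) |>
    dplyr::summarise(
      median_corrected_ratio = agg_fun(.data$ratio_corrected),
      n_peptides = dplyr::n_distinct(.data$peptide),
      .groups = "drop"
    )
  ref_value <- per_protein$median_corrected_ratio[
    per_protein$protein_id == reference]
  if (ref_value == 0) stop("reference protein has zero corrected ratio")
  out <- per_protein |>
    dplyr::mutate(occupancy = .data$median_corrected_ratio / ref_value,
                  below_loq = .data$occupancy < loq) |>
    dplyr::relocate("occupancy", .after = "median_corrected_ratio")
  out$occupancy[out$protein_id == reference] <- 1
  attr(out, "detail") <- corrected
  attr(out, "reference") <- reference
  class(out) <- c("occupancy_table", class(out))
  out
}

#' Whole-cell relative abundance across conditions
#'
#' Takes per-condition occupancy tables (each already normalized to the
#' reference protein within its condition) and re-normalizes each protein to
#' its level in a reference condition, so the output reads as fold change
#' relative to that condition.  Proteins missing from a condition, or with a
#' zero reference-condition value, are excluded with a message.
#'
#' @param tables Named list of `occupancy_table`s (names are condition ids),
#'   or a tibble with columns `condition`, `protein_id`, `occupancy`.
#' @param reference_condition Condition id every protein is scaled to.
#' @return Tibble `protein_id`, `condition`, `occupancy`,
#'   `relative_abundance` (reference condition column identically 1).
#' @export
whole_cell_abundance <- function(tables, reference_condition) {
  if (is.list(tables) && !is.data.frame(tables)) {
    stopifnot(!is.null(names(tables)))
    tables <- purrr::imap_dfr(tables, function(tab, cond) {
      tibble::tibble(condition = cond, protein_id = tab$protein_id,
                     occupancy = tab$occupancy)
    })
  }
  stopifnot(all(c("condition", "protein_id", "occupancy") %in% names(tables)))
  if (!reference_condition %in% tables$condition) {
    stop("reference condition '", reference_condition, "' not present")
  }
  ref <- tables |>
    dplyr::filter(.data$condition == reference_condition) |>
    dplyr::select("protein_id", ref_occupancy = "occupancy")
  out <- dplyr::inner_join(tables, ref, by = "protein_id")
  dropped <- nrow(tables) - nrow(out)
  if (dropped > 0) {
    message(dropped, " row(s) excluded: protein absent from the reference condition")
  }
  zero_ref <- dplyr::filter(out, .data$ref_occupancy == 0)
  if (nrow(zero_ref) > 0) {
    message(dplyr::n_distinct(zero_ref$protein_id),
            " protein(s) excluded: zero value in the reference condition")
    out <- dplyr::filter(out, .data$ref_occupancy != 0)
  }
  out |>
    dplyr::mutate(relative_abundance = .data$occupancy / .data$ref_occupancy) |>
    dplyr::select("protein_id", "condition", "occupancy",
                  "relative_abundance")
}

#' Standard-curve statistics for a dilution series
#'
#' Ordinary least-squares fit of the per-sample median corrected ratio
#' against the amount of 14N material added.  By construction the generating
#' line has slope `1 / spike15_pmol` and intercept 0 after spike correction.
#' Each point is also expressed in r-protein equivalents — amounts relative
#' to the load that defines occupancy 1 — as
#' `ratio_corrected / (reference_amount / spike15_pmol)`.
#'
#' @param curve_ratios Either a list of corrected ratio tables (one per
#'   curve point, from [spike_correct()]) or a numeric vector of per-point
#'   median corrected ratios.
#' @param amounts Experimental amounts (pmol), same length/order; at least 3.
#' @param reference_amount Particle load defining occupancy 1 (pmol),
#'   default 20.
#' @param spike15_pmol 15N standard amount (pmol), default 30.
#' @return A `spike_curve` object; see [tidy.spike_curve()],
#'   [glance.spike_curve()], [autoplot.spike_curve()].
#' @export
standard_curve <- function(curve_ratios, amounts, reference_amount = 20,
                           spike15_pmol = 30) {
  if (length(amounts) < 3) stop("a standard curve needs at least 3 points")
  if (is.list(curve_ratios) && !is.numeric(curve_ratios)) {
    stopifnot(length(curve_ratios) == length(amounts))
    ratios <- vapply(curve_ratios, function(tab) {
      stats::median(tab$ratio_corrected)
    }, numeric(1))
  } else {
    ratios <- as.numeric(curve_ratios)
    stopifnot(length(ratios) == length(amounts))
  }
  ratios <- unname(ratios)
  points <- tibble::tibble(
    amount_pmol = unname(amounts),
    median_corrected_ratio = ratios,
    equivalents = ratios / (reference_amount / spike15_pmol)
  )
  fit <- stats::lm(median_corrected_ratio ~ amount_pmol, data = points)
  structure(
    list(points = points, fit = fit, reference_amount = reference_amount,
         spike15_pmol = spike15_pmol),
    class = "spike_curve"
  )
}

#' @export
print.spike_curve <- function(x, ...) {
  g <- glance(x)
  cat("<spike_curve> ", nrow(x$points), " points, slope ",
      signif(g$slope, 5), " per pmol (expected ",
      signif(1 / x$spike15_pmol, 5), "), R^2 ",
      signif(g$r.squared, 5), "\n", sep = "")
  print(x$points)
  invisible(x)
}

#' Tidy a standard curve into its per-point table
#'
#' @param x A `spike_curve` from [standard_curve()].
#' @param ... Unused.
#' @return Tibble with one row per curve point: `amount_pmol`,
#'   `median_corrected_ratio`, `equivalents`, `fitted`, `residual`.
#' @method tidy spike_curve
#' @export
tidy.spike_curve <- function(x, ...) {
  dplyr::mutate(x$points,
                fitted = stats::fitted(x$fit),
                residual = stats::residuals(x$fit))
}

#' One-row summary of a standard curve
#'
#' @param x A `spike_curve` from [standard_curve()].
#' @param ... Unused.
#' @return Tibble with `slope`, `intercept`, `r.squared`, `n_points`,
#'   `min_equivalents`, `max_equivalents`.
#' @method glance spike_curve
#' @export
glance.spike_curve <- function(x, ...) {
  cf <- stats::coef(x$fit)
  nonzero <- x$points$equivalents[x$points$amount_pmol > 0]
  tibble::tibble(
    slope = unname(cf["amount_pmol"]),
    intercept = unname(cf["(Intercept)"]),
    r.squared = summary(x$fit)$r.squared,
    n_points = nrow(x$points),
    min_equivalents = if (length(nonzero)) min(nonzero) else NA_real_,
    max_equivalents = max(x$points$equivalents)
  )
}

#' Pearson correlation between two per-strain datasets
#'
#' Standard product-moment coefficient, used to compare whole-cell protein
#' levels with intermediate-particle occupancies across strains.
#'
#' @param x,y Paired numeric vectors, length >= 3, each with nonzero
#'   variance.
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined: zero variance")
  }
  stats::cor(x, y, method = "pearson")
}
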