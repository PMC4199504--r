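#' Match 14N:15N peak pairs in a centroid spectrum
#'
#' For every unique peptide and charge in the index, collects the observed
#' peaks lying within `tolerance_ppm` of each theoretical centroid of the
#' peptide's 14N and 15N envelopes.  Within one window each observed peak is
#' assigned to at most one theoretical position (the nearest in ppm).
#' Windows are kept only if, for at least one channel, all of the channel's
#' three most abundant theoretical peaks are matched — a one- or two-peak
#' "envelope" carries no pair information.  Windows whose matched peaks come
#' within one centroid resolution element of another window's are flagged
#' `overlapping` and grouped for joint fitting; overlapping fits are kept out
#' of downstream summary statistics.
#'
#' @param spectrum Tibble with columns `mz`, `intensity` (sorted by m/z).
#' @param index Peptide index from [peptide_index()]; ignored when
#'   `envelopes` is supplied.
#' @param charges Charge states searched, default `c(2, 3)`.
#' @param tolerance_ppm Match tolerance in ppm, default 10.
#' @param enrichment Assumed 15N enrichment of the labeled channel.
#' @param envelopes Optional precomputed [peptide_envelopes()] table.
#' @return Nested tibble: one row per retained window with `window_id`,
#'   `protein_id`, `peptide`, `charge`, `n_matched`, `overlapping`,
#'   `overlap_group`, and a `peaks` list-column of per-position matches
#'   (`channel`, `theo_mz`, `abundance`, `peak_idx`, `obs_mz`,
#'   `obs_intensity`).
#' @export
match_peak_pairs <- function(spectrum, index = NULL, charges = c(2L, 3L),
                             tolerance_ppm = 10, enrichment = 0.995,
                             envelopes = NULL) {
  stopifnot(tolerance_ppm > 0)
  if (is.null(envelopes)) {
    if (is.null(index)) stop("supply either `index` or `envelopes`")
    envelopes <- peptide_envelopes(index, charges = charges,
                                   enrichment = enrichment)
  }
  empty <- tibble::tibble(
    window_id = integer(), protein_id = character(), peptide = character(),
    charge = integer(), n_matched = integer(), overlapping = logical(),
    overlap_group = integer(), peaks = list()
  )
  if (nrow(spectrum) == 0) return(empty)
  spec_mz <- spectrum$mz
  spec_int <- spectrum$intensity

  matched <- envelopes |>
    dplyr::mutate(peak_idx = nearest_peak(spec_mz, .data$mz, tolerance_ppm)) |>
    dplyr::filter(!is.na(.data$peak_idx)) |>
    dplyr::mutate(obs_mz = spec_mz[.data$peak_idx],
                  obs_intensity = spec_int[.data$peak_idx],
                  ppm_error = abs(.data$obs_mz - .data$mz) / .data$mz * 1e6)

  # one theoretical position per observed peak within a window
  matched <- matched |>
    dplyr::group_by(.data$peptide, .data$charge, .data$peak_idx) |>
    dplyr::slice_min(.data$ppm_error, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()

  # keep windows where the top-3 peaks of at least one channel all matched
  top3 <- envelopes |>
    dplyr::group_by(.data$peptide, .data$charge, .data$channel) |>
    dplyr::slice_max(.data$abundance, n = 3, with_ties = FALSE) |>
    dplyr::mutate(n_top = dplyr::n()) |>
    dplyr::ungroup()
  channel_ok <- top3 |>
    dplyr::left_join(
      dplyr::select(matched, "peptide", "charge", "channel",
                    theo_mz = "mz", "peak_idx"),
      by = c("peptide", "charge", "channel"),
      relationship = "many-to-many"
    ) |>
    dplyr::group_by(.data$peptide, .data$charge, .data$channel) |>
    dplyr::summarise(
      complete = sum(!is.na(.data$peak_idx) &
                       abs(.data$theo_mz - .data$mz) < 1e-9) >=
        .data$n_top[1],
      .groups = "drop"
    ) |>
    dplyr::group_by(.data$peptide, .data$charge) |>
    dplyr::summarise(keep = any(.data$complete), .groups = "drop") |>
    dplyr::filter(.data$keep)

  matched <- dplyr::semi_join(matched, channel_ok, by = c("peptide", "charge"))
  if (nrow(matched) == 0) return(empty)

  windows <- matched |>
    dplyr::rename(theo_mz = "mz") |>
    dplyr::group_by(.data$protein_id, .data$peptide, .data$charge) |>
    tidyr::nest(peaks = c("channel", "theo_mz", "abundance", "peak_idx",
                          "obs_mz", "obs_intensity", "ppm_error")) |>
    dplyr::ungroup() |>
    dplyr::mutate(window_id = dplyr::row_number(),
                  n_matched = vapply(.data$peaks, nrow, integer(1)))

  # joint-fit groups: windows that literally share a matched observed peak
  grp <- union_groups(lapply(windows$peaks, function(p) {
    as.character(p$peak_idx)
  }))
  # overlap flag is broader: matched peaks within 0.01-0.02 m/z
  # of another window's contaminate merged centroids even
  # when the neighbor's own position fell outside the ppm tolerance
  prox <- union_groups(lapply(windows$peaks, function(p) {
    bins <- floor(p$obs_mz / 0.01)
    as.character(unique(c(bins, bins + 1)))
  }))
  windows$overlap_group <- grp
  windows$overlapping <- grp %in% grp[duplicated(grp)] |
    prox %in% prox[duplicated(prox)]
  dplyr::select(windows, "window_id", "protein_id", "peptide", "charge",
                "n_matched", "overlapping", "overlap_group", "peaks")
}

# nearest observed peak within tol ppm of each query m/z (NA when none);
# obs_mz must be sorted ascending
nearest_peak <- function(obs_mz, query_mz, tolerance_ppm) {
  pos <- findInterval(query_mz, obs_mz)
  lo <- pmax(pos, 1)
  hi <- pmin(pos + 1, length(obs_mz))
  d_lo <- abs(obs_mz[lo] - query_mz)
  d_hi <- abs(obs_mz[hi] - query_mz)
  idx <- ifelse(d_lo <= d_hi, lo, hi)
  err <- abs(obs_mz[idx] - query_mz)
  ifelse(err <= query_mz * tolerance_ppm * 1e-6, idx, NA_integer_)
}

# Union-find over windows: windows sharing any key end up in one group.
union_groups <- function(key_list) {
  n <- length(key_list)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  owner <- new.env(parent = emptyenv())
  for (w in seq_len(n)) {
    for (key in key_list[[w]]) {
      prev <- owner[[key]]
      if (is.null(prev)) {
        owner[[key]] <- w
      } else {
        ra <- find(prev); rb <- find(w)
        if (ra != rb) parent[rb] <- ra
      }
    }
  }
  vapply(seq_len(n), find, integer(1))
}

#' Fit 14N and 15N envelope amplitudes for one window
#'
#' Solves the non-negative least-squares problem
#' `observed ~ amp14 * template14 + amp15 * template15 + baseline`
#' on the matched centroid intensities, where the templates are the
#' theoretical abundance vectors and the baseline is a per-window constant
#' (so an additive intensity floor cannot bias the ratio).
#'
#' @param peaks A window's `peaks` tibble from [match_peak_pairs()].
#' @return List with `amp14`, `amp15`, `baseline`, `residual_fraction`
#'   (residual norm over observed norm) and `snr` (base peak over the
#'   baseline estimate).
#' @export
fit_pair <- function(peaks) {
  stopifnot(nrow(peaks) > 0)
  sol <- fit_window_group(list(peaks))
  sol[[1]]
}

# Joint NNLS over one overlap group.  Each window contributes an amp14 and
# amp15 column (its template abundances at its matched peaks); one constant
# baseline column is shared across the group's peaks.
fit_window_group <- function(peaks_list, max_joint = 25) {
  # very large chained components (dense spectra) are fit window-by-window:
  # they are flagged overlapping and excluded from summaries regardless, and
  # a joint solve over hundreds of columns buys nothing for its cost
  if (length(peaks_list) > max_joint) {
    return(lapply(peaks_list, function(p) fit_window_group(list(p))[[1]]))
  }
  all_idx <- sort(unique(unlist(lapply(peaks_list, function(p) p$peak_idx))))
  npk <- length(all_idx)
  nw <- length(peaks_list)
  b <- numeric(npk)
  A <- matrix(0, npk, 2 * nw + 1)
  A[, 2 * nw + 1] <- 1
  for (w in seq_len(nw)) {
    p <- peaks_list[[w]]
    rows <- match(p$peak_idx, all_idx)
    b[rows] <- p$obs_intensity
    is14 <- p$channel == "N14"
    A[rows[is14], 2 * w - 1] <- p$abundance[is14]
    A[rows[!is14], 2 * w] <- p$abundance[!is14]
  }
  if (all(b == 0)) {
    x <- numeric(2 * nw + 1)
  } else {
    # solve on a unit intensity scale (the solver's convergence tolerance is
    # absolute) and skip all-zero template columns
    scale <- max(b)
    live <- colSums(abs(A)) > 0
    x <- numeric(2 * nw + 1)
    x[live] <- pracma::lsqnonneg(A[, live, drop = FALSE], b / scale)$x * scale
  }
  fitted <- as.vector(A %*% x)
  lapply(seq_len(nw), function(w) {
    p <- peaks_list[[w]]
    rows <- match(p$peak_idx, all_idx)
    obs_norm <- sqrt(sum(b[rows]^2))
    res_norm <- sqrt(sum((b[rows] - fitted[rows])^2))
    base_hat <- x[2 * nw + 1]
    base_floor <- max(base_hat, 1e-9 * max(b, 1e-300))
    list(
      amp14 = x[2 * w - 1],
      amp15 = x[2 * w],
      baseline = base_hat,
      residual_fraction = if (obs_norm > 0) res_norm / obs_norm else 1,
      snr = max(b[rows]) / base_floor
    )
  })
}

#' Fit all peak-pair windows of a spectrum
#'
#' Runs [match_peak_pairs()], fits each overlap group of windows jointly by
#' non-negative least squares ([fit_pair()]), and applies the
#' signal-to-noise / residual acceptance rule ([filter_fits()]).  Nothing is
#' dropped: rejected fits are returned with `accepted = FALSE` for audit.
#'
#' @inheritParams match_peak_pairs
#' @param snr_min Minimum signal-to-noise ratio, default 3.
#' @param residual_max Maximum residual fraction, default 0.3.
#' @return Tibble with one row per window: `protein_id`, `peptide`, `charge`,
#'   `amp14`, `amp15`, `ratio_raw`, `snr`, `residual_fraction`,
#'   `overlapping`, `accepted`.
#' @export
fit_peak_pairs <- function(spectrum, index = NULL, charges = c(2L, 3L),
                           tolerance_ppm = 10, enrichment = 0.995,
                           envelopes = NULL, snr_min = 3, residual_max = 0.3) {
  windows <- match_peak_pairs(spectrum, index = index, charges = charges,
                              tolerance_ppm = tolerance_ppm,
                              enrichment = enrichment, envelopes = envelopes)
  if (nrow(windows) == 0) {
    return(tibble::tibble(
      protein_id = character(), peptide = character(), charge = integer(),
      amp14 = numeric(), amp15 = numeric(), ratio_raw = numeric(),
      snr = numeric(), residual_fraction = numeric(),
      overlapping = logical(), accepted = logical()
    ))
  }
  fits <- windows |>
    dplyr::group_by(.data$overlap_group) |>
    dplyr::group_modify(function(g, key) {
      sols <- fit_window_group(g$peaks)
      dplyr::bind_cols(
        dplyr::select(g, "protein_id", "peptide", "charge", "overlapping"),
        purrr::map_dfr(sols, function(s) {
          tibble::tibble(amp14 = s$amp14, amp15 = s$amp15, snr = s$snr,
                         residual_fraction = s$residual_fraction)
        })
      )
    }) |>
    dplyr::ungroup() |>
    dplyr::select(-"overlap_group") |>
    dplyr::mutate(ratio_raw = dplyr::if_else(.data$amp15 > 0,
                                             .data$amp14 / .data$amp15,
                                             NA_real_)) |>
    dplyr::relocate("ratio_raw", .after = "amp15")
  filter_fits(fits, snr_min = snr_min, residual_max = residual_max)
}

#' Apply the signal-to-noise and residual acceptance rule
#'
#' Sets `accepted = snr >= snr_min & residual_fraction <= residual_max &
#' amp15 > 0`; rejected fits are retained (flagged) rather than dropped, so
#' the output always has as many rows as the input.
#'
#' @param fits Fit table from [fit_peak_pairs()].
#' @inheritParams fit_peak_pairs
#' @return The fit table with an updated `accepted` column.
#' @export
filter_fits <- function(fits, snr_min = 3, residual_max = 0.3) {
  stopifnot(snr_min >= 0, residual_max >= 0)
  dplyr::mutate(fits,
                accepted = .data$snr >= snr_min &
                  .data$residual_fraction <= residual_max &
                  .data$amp15 > 0)
}
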