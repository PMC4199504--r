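sim_pair <- function(design, truth = NULL, efficiency = NULL,
                     index = fx_index, envelopes = fx_env) {
  list(
    sample = simulate_spectrum(index, design, truth = truth,
                               efficiency = efficiency,
                               envelopes = envelopes),
    spike = simulate_spectrum(index, spike_alone_design(design),
                              efficiency = efficiency,
                              envelopes = envelopes)
  )
}

test_that("raw ratios divide the channel amplitudes and audit exclusions", {
  fits <- tibble::tibble(
    protein_id = "L6", peptide = c("AAAGGK", "CCCGGK"), charge = 2L,
    amp14 = c(2, 5), amp15 = c(3, 0), ratio_raw = NA_real_,
    snr = 100, residual_fraction = 0.01, overlapping = FALSE, accepted = TRUE
  )
  expect_message(out <- raw_ratios(fits), "zero 15N amplitude")
  expect_equal(nrow(out), 1)
  expect_equal(out$ratio_raw, 2 / 3, tolerance = 1e-4)
})

test_that("the noiseless spike-alone sample reads 10/30 on every peptide", {
  sp <- sim_pair(fx_design())
  fits <- fit_peak_pairs(sp$spike, envelopes = fx_env)
  ratios <- raw_ratios(fits)
  expect_gt(nrow(ratios), 20)
  expect_equal(ratios$ratio_raw, rep(1 / 3, nrow(ratios)), tolerance = 1e-4)
})

test_that("spike correction zeroes the spike-alone sample against itself", {
  sp <- sim_pair(fx_design())
  ratios <- raw_ratios(fit_peak_pairs(sp$spike, envelopes = fx_env))
  corrected <- spike_correct(ratios, ratios)
  expect_equal(corrected$ratio_corrected, rep(0, nrow(corrected)))
})

test_that("corrected ratios follow the mixing arithmetic", {
  for (case in list(c(2, 12 / 30 - 10 / 30), c(20, 20 / 30))) {
    sp <- sim_pair(fx_design(experimental_pmol = case[1]))
    corrected <- corrected_ratios(sp$sample, sp$spike, envelopes = fx_env)
    expect_equal(median(corrected$ratio_corrected), case[2], tolerance = 1e-3)
  }
})

test_that("a stoichiometric sample reports occupancy 1 for every protein", {
  sp <- sim_pair(fx_design())
  occ <- quantify_spectrum(sp$sample, sp$spike, envelopes = fx_env)
  expect_setequal(occ$protein_id, unique(fx_index$protein_id))
  expect_equal(occ$occupancy, rep(1, nrow(occ)), tolerance = 1e-3)
  expect_equal(occ$occupancy[occ$protein_id == "L20"], 1)
  expect_true(all(occ$n_peptides >= 1))
})

test_that("sub-stoichiometric and depleted proteins are recovered", {
  sp <- sim_pair(fx_design(), truth = c(L16 = 0.35, L6 = 0))
  occ <- quantify_spectrum(sp$sample, sp$spike, envelopes = fx_env)
  expect_equal(occ$occupancy[occ$protein_id == "L16"], 0.35, tolerance = 0.01)
  expect_lt(occ$occupancy[occ$protein_id == "L16"], 0.4)
  expect_lt(abs(occ$occupancy[occ$protein_id == "L6"]), 0.01)
  expect_true(occ$below_loq[occ$protein_id == "L6"])
})

test_that("a missing reference protein is a hard error", {
  corrected <- tibble::tibble(
    protein_id = "L6", peptide = "AAAGGK", charge = 2L,
    ratio_raw = 0.5, ratio_corrected = 0.2, fallback = FALSE,
    negative = FALSE
  )
  expect_error(protein_occupancy(corrected, reference = "L20"),
               "reference protein")
})

test_that("2 pmol referenced to a 20 pmol load reads occupancy 0.1", {
  sp2 <- sim_pair(fx_design(experimental_pmol = 2))
  sp20 <- sim_pair(fx_design(experimental_pmol = 20))
  r2 <- corrected_ratios(sp2$sample, sp2$spike, envelopes = fx_env)
  r20 <- corrected_ratios(sp20$sample, sp20$spike, envelopes = fx_env)
  expect_equal(median(r2$ratio_corrected) / median(r20$ratio_corrected),
               0.1, tolerance = 0.01)
})

test_that("whole-cell abundances re-normalize to the reference condition", {
  sp_ref <- sim_pair(fx_design())
  sp_half <- sim_pair(fx_design(), truth = c(L6 = 0.5))
  tabs <- list(
    ref = quantify_spectrum(sp_ref$sample, sp_ref$spike, envelopes = fx_env),
    half = quantify_spectrum(sp_half$sample, sp_half$spike,
                             envelopes = fx_env)
  )
  ab <- whole_cell_abundance(tabs, "ref")
  ref_col <- dplyr::filter(ab, condition == "ref")
  expect_equal(ref_col$relative_abundance, rep(1, nrow(ref_col)))
  l6 <- dplyr::filter(ab, condition == "half", protein_id == "L6")
  expect_equal(l6$relative_abundance, 0.5, tolerance = 0.01)

  tabs$half <- tabs$half[tabs$half$protein_id != "L16", ]
  ab2 <- whole_cell_abundance(tabs, "ref")
  expect_false("L16" %in% ab2$protein_id[ab2$condition == "half"])
  expect_error(whole_cell_abundance(tabs, "nope"), "not present")
})

test_that("the noiseless standard curve has the designed slope and range", {
  curve <- run_standard_curve(fx_index, base = fx_design())
  g <- suppressWarnings(glance(curve))
  expect_gte(g$r.squared, 0.999)
  expect_equal(g$slope, 1 / 30, tolerance = 1e-3)
  pts <- tidy(curve)
  expect_equal(pts$equivalents[pts$amount_pmol == 2], 0.1, tolerance = 0.01)
  expect_equal(pts$equivalents[pts$amount_pmol == 32], 1.6, tolerance = 0.01)
  expect_equal(pts$median_corrected_ratio[pts$amount_pmol == 0], 0,
               tolerance = 1e-3)
  expect_error(standard_curve(c(0.1, 0.2), c(2, 4)), "at least 3")
})

test_that("pearson_r reproduces the product-moment formula", {
  expect_equal(pearson_r(1:5, 1:5), 1)
  expect_equal(pearson_r(1:5, -(1:5)), -1)
  x <- c(1, 2, 3, 5)
  y <- c(2, 1, 4, 6)
  hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson_r(x, y), hand)
  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(pearson_r(1:2, 1:2), "at least 3")
})

test_that("occupancy is recovered end-to-end at 5 percent noise", {
  idx <- peptide_index(simulate_proteome(6, seed = 202))
  env <- peptide_envelopes(idx, charges = 2L, enrichment = 1)
  prot <- setdiff(unique(idx$protein_id), "L20")
  levels <- c(0, 0.25, 0.5, 0.75, 1.0)
  errs <- c()
  zeros <- c()
  withr::with_seed(303, {
    for (rep in 1:4) {
      truth <- stats::setNames(sample(levels, length(prot), replace = TRUE),
                               prot)
      d <- sample_design(noise_cv = 0.05, enrichment = 1, charges = 2L,
                         seed = 1000 + rep)
      sp <- sim_pair(d, truth = truth, index = idx, envelopes = env)
      occ <- quantify_spectrum(sp$sample, sp$spike, envelopes = env)
      got <- occ$occupancy[match(prot, occ$protein_id)]
      errs <- c(errs, abs(got - truth))
      zeros <- c(zeros, got[truth == 0])
    }
  })
  expect_lt(median(errs), 0.05)
  expect_true(all(abs(zeros) < 0.1))
})

test_that("10-fold ionization efficiency differences cancel", {
  peptides <- unique(fx_index$peptide)
  eff <- withr::with_seed(17, {
    stats::setNames(10^stats::runif(length(peptides), -0.5, 0.5), peptides)
  })
  sp_flat <- sim_pair(fx_design(), truth = c(L16 = 0.6))
  sp_eff <- sim_pair(fx_design(), truth = c(L16 = 0.6), efficiency = eff)
  occ_flat <- quantify_spectrum(sp_flat$sample, sp_flat$spike,
                                envelopes = fx_env)
  occ_eff <- quantify_spectrum(sp_eff$sample, sp_eff$spike,
                               envelopes = fx_env)
  both <- dplyr::inner_join(tibble::as_tibble(occ_flat),
                            tibble::as_tibble(occ_eff),
                            by = "protein_id")
  expect_equal(both$occupancy.x, both$occupancy.y, tolerance = 1e-4)
})

test_that("ratios and occupancies are invariant to global intensity scale", {
  sp <- sim_pair(fx_design(), truth = c(L6 = 0.5))
  scaled <- dplyr::mutate(sp$sample, intensity = intensity * 7.3)
  occ1 <- quantify_spectrum(sp$sample, sp$spike, envelopes = fx_env)
  occ2 <- quantify_spectrum(scaled, sp$spike, envelopes = fx_env)
  expect_equal(occ1$occupancy, occ2$occupancy, tolerance = 1e-9)
})

test_that("occupancy is robust to deleting any single peptide", {
  sp <- sim_pair(sample_design(noise_cv = 0.05, enrichment = 1,
                               charges = 2L, seed = 404))
  corrected <- corrected_ratios(sp$sample, sp$spike, envelopes = fx_env)
  counts <- table(corrected$protein_id)
  counts <- counts[names(counts) != "L20"]  # reference occupancy is pinned
  target <- names(counts)[counts >= 5][1]
  base_occ <- protein_occupancy(corrected)
  base_val <- base_occ$occupancy[base_occ$protein_id == target]
  spread <- diff(range(
    corrected$ratio_corrected[corrected$protein_id == target]))
  ref_med <- base_occ$median_corrected_ratio[base_occ$protein_id == "L20"]
  for (pep in unique(corrected$peptide[corrected$protein_id == target])) {
    jack <- corrected[corrected$peptide != pep, ]
    occ <- protein_occupancy(jack)
    expect_lte(abs(occ$occupancy[occ$protein_id == target] - base_val),
               spread / ref_med)
  }
})
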