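# Shared fixtures (computed once per test run) and independent oracles.

AA20 <- c("G", "A", "S", "P", "V", "T", "C", "L", "I", "N", "D", "Q",
          "K", "E", "M", "H", "F", "R", "Y", "W")
WATER <- c(C = 0L, H = 2L, N = 0L, O = 1L, S = 0L)

fx_proteome <- simulate_proteome(6, seed = 101)
fx_index <- peptide_index(fx_proteome)
# enrichment pinned to 1 wherever exact spike arithmetic is asserted
fx_env <- peptide_envelopes(fx_index, charges = 2L, enrichment = 1)
fx_design <- function(...) {
  sample_design(noise_cv = 0, enrichment = 1, charges = 2L, ...)
}

# Brute-force tryptic digest: enumerate every substring bounded by cleavage
# sites (after K/R not before P) or protein ends, counting internal missed
# cleavages.  Independent of the segment-joining implementation.
oracle_digest <- function(sequence, max_missed) {
  res <- strsplit(sequence, "")[[1]]
  n <- length(res)
  is_cut_after <- vapply(seq_len(n), function(i) {
    res[i] %in% c("K", "R") && i < n && res[i + 1] != "P"
  }, logical(1))
  starts <- c(1L, which(is_cut_after) + 1L)
  ends <- c(which(is_cut_after), n)
  out <- character(0)
  for (s in starts) {
    for (e in ends) {
      if (e < s) next
      internal <- sum(is_cut_after[s:e]) - as.integer(is_cut_after[e])
      if (internal <= max_missed) {
        out <- c(out, paste(res[s:e], collapse = ""))
      }
    }
  }
  sort(unique(out))
}

# Exhaustive isotopologue enumeration: per element, all isotope count
# vectors with multinomial probabilities; cross product over elements; then
# the same nominal-offset aggregation and pruning the package applies.
oracle_pattern <- function(composition, label = "natural", enrichment = 0.995,
                           prune = 1e-4) {
  composition <- composition[composition > 0]
  per_element <- lapply(names(composition), function(el) {
    d <- as.data.frame(element_distribution(el, label, enrichment))
    n <- composition[[el]]
    k <- nrow(d)
    counts <- expand.grid(rep(list(0:n), k))
    counts <- counts[rowSums(counts) == n, , drop = FALSE]
    data.frame(
      offset = as.matrix(counts) %*% d$offset,
      mass = as.matrix(counts) %*% d$mass,
      prob = apply(counts, 1, function(x) dmultinom(x, prob = d$abundance))
    )
  })
  combined <- Reduce(function(a, b) {
    grid <- expand.grid(i = seq_len(nrow(a)), j = seq_len(nrow(b)))
    data.frame(
      offset = a$offset[grid$i] + b$offset[grid$j],
      mass = a$mass[grid$i] + b$mass[grid$j],
      prob = a$prob[grid$i] * b$prob[grid$j]
    )
  }, per_element)
  agg <- stats::aggregate(cbind(prob, wmass = prob * mass) ~ offset,
                          data = combined, FUN = sum)
  agg$mass <- agg$wmass / agg$prob
  agg <- agg[agg$prob > prune * max(agg$prob), ]
  agg <- agg[order(agg$mass), ]
  data.frame(mass = agg$mass, abundance = agg$prob / sum(agg$prob))
}

# Two-parameter grid search over (amp14, amp15) with a per-window constant
# baseline profiled out at zero (used on noiseless windows, where the true
# baseline is zero).  Hierarchical refinement down to `step_rel` times the
# plausible base amplitude; the objective is convex so refinement around the
# coarse minimum is exhaustive-equivalent.
oracle_grid_fit <- function(peaks, step_rel = 1e-4) {
  b <- peaks$obs_intensity
  t14 <- ifelse(peaks$channel == "N14", peaks$abundance, 0)
  t15 <- ifelse(peaks$channel == "N15", peaks$abundance, 0)
  base_amp <- max(b) / max(peaks$abundance)
  sse <- function(a14, a15) sum((b - a14 * t14 - a15 * t15)^2)
  lo <- c(0, 0)
  hi <- c(4 * base_amp, 4 * base_amp)
  repeat {
    g14 <- seq(lo[1], hi[1], length.out = 41)
    g15 <- seq(lo[2], hi[2], length.out = 41)
    vals <- outer(g14, g15, Vectorize(sse))
    best <- which(vals == min(vals), arr.ind = TRUE)[1, ]
    step <- c(g14[2] - g14[1], g15[2] - g15[1])
    if (all(step <= step_rel * base_amp)) {
      return(list(amp14 = g14[best[1]], amp15 = g15[best[2]],
                  step = max(step)))
    }
    lo <- pmax(c(g14[best[1]], g15[best[2]]) - 2 * step, 0)
    hi <- c(g14[best[1]], g15[best[2]]) + 2 * step
  }
}
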