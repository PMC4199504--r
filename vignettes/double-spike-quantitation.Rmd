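---
title: "Double-spike 14N/15N quantitation of ribosomal-protein occupancy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Double-spike 14N/15N quantitation of ribosomal-protein occupancy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(doublespike)
library(dplyr)
```

## The measurement model

Ribosome assembly intermediates are heterogeneous: a purified 44S/45S
population may carry a late-binding protein on only a fraction of its
particles. That fraction — the protein's **occupancy** — is what this
package measures from centroided MS^1^ spectra.

Every experimental sample (nominally 20 pmol of ^14^N-labeled particles) is
mixed with a *double spike*: 10 pmol of ^14^N-labeled and 30 pmol of
metabolically ^15^N-labeled mature 70S ribosomes. After tryptic digestion,
each detectable peptide appears as a pair of isotope envelopes: the
^14^N envelope (experimental material plus ^14^N spike) and the ^15^N
envelope (spike only), offset by the peptide's nitrogen count times the
^15^N–^14^N mass difference (0.997035 Da) divided by charge. The ^14^N half
of the spike guarantees that every ^15^N envelope has a partner even when
the experimental protein is completely absent, which is exactly the regime
where depletion calls are made.

For each peptide the fitted envelope amplitudes give

$$r_\text{raw} = \frac{A_{14}}{A_{15}}, \qquad
  r_\text{corr} = r_\text{raw} - r^\text{spike-alone}_\text{raw}, \qquad
  \text{occupancy}(P) =
  \frac{\operatorname{median}_{p \in P} r_\text{corr}(p)}
       {\operatorname{median}_{p \in \text{L20}} r_\text{corr}(p)}.$$

Dividing by $A_{15}$ first removes preparation and ionization variation
(the ^15^N standard is the same molecules at a fixed amount in every
sample); subtracting the spike-alone ratio, measured once from the double
spike in isolation, removes the 10 pmol ^14^N spike contribution; dividing
by the reference protein L20 — a primary-binding protein bound
stoichiometrically in every particle class — removes the total amount of
sample loaded. With amounts in pmol the corrected ratio of a sample
containing $x$ pmol of a fully occupied protein is $x/30$, so the
standard-curve slope is $1/30\ \text{pmol}^{-1}$ and a 20 pmol load defines
occupancy 1. The subtraction is deliberately performed on the
ratio (^15^N-normalized) scale rather than on raw amplitudes: only on that
scale is the correction independent of how much total material was
injected, which is what makes 2 pmol correspond to occupancy 0.1 regardless
of spray efficiency.

## Pipeline stages and their assumptions

1. **Theoretical digest** (`peptide_index()`). Trypsin cleaves after K/R
   except before proline (the Mascot convention). Defaults: at most 1
   missed cleavage, peptide length 6–30 residues — a typical detectability
   window for ESI-TOF instruments — and carbamidomethyl-Cys as the only
   (fixed) modification, matching standard iodoacetamide alkylation.
   Peptide sequences shared by two proteins are marked non-unique and
   excluded from quantitation.

2. **Isotopologue distributions** (`isotope_pattern()`). Per-atom isotope
   distributions are convolved over all atoms of the peptide's elemental
   composition; isotopologues sharing a nominal mass offset are aggregated
   into one centroid at the abundance-weighted mean mass, which is the
   granularity centroided TOF data actually has. Under the `nitrogen15`
   labeling state the nitrogen distribution is replaced by
   {^14^N: 1−e, ^15^N: e}. The convolution is performed element-wise with
   binary exponentiation; tests verify it against exhaustive multinomial
   enumeration to 10^-10^. Peaks below 10^-4^ of the base peak are pruned
   (below the instrument's dynamic range) and the distribution
   renormalized.

3. **Spectrum simulation** (`simulate_spectrum()`). For each unique peptide
   and charge the ^14^N envelope is emitted with amplitude
   `response_factor × (experimental_pmol × occupancy + spike14_pmol)` and
   the ^15^N envelope with `response_factor × spike15_pmol`. Centroids
   closer than 0.005 m/z (below TOF resolution) are merged by intensity
   sum. The noise model is the simplest one that exercises the downstream
   filters: multiplicative log-normal noise with configurable CV (default
   0.05, typical of ESI-TOF peak-area reproducibility), a uniform additive
   baseline (default 0), and optional ppm-scale m/z jitter (default off).
   All randomness is driven by the design's seed, so spectra are
   bit-reproducible. Defaults for the amounts are the published mixing
   design (20 pmol experimental, 10 pmol ^14^N + 30 pmol ^15^N spike);
   ^15^N enrichment defaults to 0.995, typical of minimal-media metabolic
   labeling, and is pinned to 1.0 in tests that assert exact arithmetic.
   Charges default to {2, 3}, the dominant electrospray charge states of
   tryptic peptides.

   What the simulator deliberately does **not** emulate: chromatography
   (amplitudes are already elution-integrated; retention time adds nothing
   to the ratio arithmetic), profile peak shapes, MS^2^ fragmentation, and
   non-peptide background. Passing tests therefore demonstrate the
   correctness of the quantitation arithmetic and its robustness to
   intensity noise, envelope overlap and efficiency variation — not
   robustness to chimeric chromatographic features absent from the model.

4. **Peak-pair fitting** (`fit_peak_pairs()`). Observed peaks within
   10 ppm of each theoretical centroid of either envelope form a window;
   a window is kept only if all three of the most abundant theoretical
   peaks of at least one channel are matched (a one-peak "envelope"
   carries no pair information). Amplitudes are estimated by non-negative
   least squares, `observed ≈ amp14·template14 + amp15·template15 +
   baseline`, with a per-window constant baseline so an additive intensity
   floor cannot bias the ratio. On centroided data this linear model is
   the natural realization of envelope-amplitude fitting, and tests verify
   the solution against a two-parameter grid search. Windows whose matched
   peaks approach within one centroid resolution element of another
   window's are fitted jointly and flagged `overlapping`; flagged fits are
   retained for audit but excluded from summary statistics, since even
   sub-tolerance collisions contaminate merged centroids.

5. **Acceptance filtering** (`filter_fits()`). A fit is accepted when
   `snr ≥ 3` and `residual_fraction ≤ 0.3`. The S/N definition — window
   base peak over the fitted baseline estimate — and both thresholds are
   package decisions (the underlying exclusion rule names no numbers) and
   are exposed as arguments. Rejected fits are flagged, never dropped, so
   the audit trail survives.

6. **Ratios and occupancy** (`raw_ratios()`, `spike_correct()`,
   `protein_occupancy()`). Median aggregation across a protein's peptides
   (mean available as an option). Negative corrected ratios are reported
   and flagged, never clamped — clamping would bias occupancy upward
   exactly near zero, where depletion calls live. Occupancies may exceed 1;
   no ceiling is applied. Values below 0.1 — the occupancy equivalent of
   the 2 pmol quantitation limit — are flagged `below_loq`. Peptides
   missing from the spike-alone run fall back to their protein's
   spike-alone median (flagged); the reference protein being absent is a
   hard error rather than a silent renormalization.

## Numerical and design choices

* **Embedded constants.** Monoisotopic masses and natural abundances are
  stored in one table, stated to six decimals, so results do not depend on
  an external library's tables.
* **NNLS conditioning.** The least-squares system is solved on a unit
  intensity scale (the solver's convergence tolerance is absolute) and
  all-zero template columns — e.g. the ^14^N channel of a sample with no
  ^14^N material — are skipped and their amplitudes reported as 0.
* **Degenerate windows.** An all-zero window returns both amplitudes 0
  with `accepted = FALSE`; an empty spectrum yields an empty window set,
  not an error.
* **Tie-breaks.** Within a window each observed peak serves at most one
  theoretical position (nearest in ppm); across windows, overlap grouping
  uses union-find over shared m/z resolution elements.
* **Synthetic proteome.** `simulate_proteome()` generates random sequences
  with the length range (90–180 residues) and lysine/arginine-rich
  composition of bacterial large-subunit r-proteins, under field-style ids
  (L20, L6, L16, ...). These are synthetic stand-ins — the digest
  statistics are realistic, the sequences are not real ones.
* **Problem sizes.** The shipped tests and the acceptance script run on
  synthetic proteomes of 3–10 proteins with one or two charge states —
  a few hundred peptide windows per spectrum — which already exercises
  envelope collisions, joint fitting and the full ratio arithmetic; the
  pipeline scales linearly in peptides × charges.

## A complete run

```{r example, eval = FALSE}
proteome <- simulate_proteome(6, seed = 42)
index <- peptide_index(proteome)
design <- sample_design(noise_cv = 0.05, enrichment = 0.995)

spike <- simulate_spectrum(index, spike_alone_design(design))
sample <- simulate_spectrum(index, design,
                            truth = c(L16 = 0.35, L28 = 0.8))

occ <- quantify_spectrum(sample, spike, index = index,
                         enrichment = design$enrichment,
                         charges = design$charges)
occ
autoplot(occ)

curve <- run_standard_curve(index, base = sample_design(
  noise_cv = 0, enrichment = 1, charges = 2L))
glance(curve)
autoplot(curve)
```

## Known limitations

* Occupancy is identifiable only relative to the reference protein; if the
  reference itself varied between samples, every occupancy would inherit
  that variation undetected.
* Isobaric peptide pairs (identical composition, different sequence) are
  flagged as overlapping and excluded from summaries rather than
  deconvolved; at 10 ppm tolerance this also catches near-isobaric
  collisions.
* The fine isotope structure within a nominal mass bin (e.g. ^34^S vs
  2×^13^C) is aggregated, which is correct at TOF resolution but would not
  be for FT-ICR data.
* Enrichment of the ^15^N channel is assumed known; a mis-specified
  enrichment distorts the ^15^N template shape and inflates residuals
  rather than silently biasing ratios, but is not auto-estimated.
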