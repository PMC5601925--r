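---
title: "combitet: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{combitet: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the combinatorial
decoding model and its assumptions, the synthetic world the tests run
against, the numerical choices, and the places where the design was
genuinely open. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. The combinatorial decoding model

Each antigen's peptide–MHC tetramer is assembled with an unordered set of 3
out of 9 metal-labelled streptavidins, so up to C(9,3) = 84 specificities
are encoded in 9 reporter channels. A cell carrying a T-cell receptor for
antigen *a* binds only tetramer *a* and therefore lights up exactly the 3
channels of code(*a*). Decoding assumes:

* **Code separation.** Any two distinct 3-subsets share at most 2 channels
  (symmetric difference ≥ 2), so a single bright "wrong" channel cannot
  turn one valid code into another; an asserted invariant of the code book.
* **Single specificity per cell.** A cell positive in more than 3 channels
  (doublets, dual-reactive cells, aggregates) is rejected by the rank-3 −
  rank-4 separation rule rather than force-assigned.
* **Channel independence of noise.** Background in each reporter channel is
  zero-inflated and light-tailed; the probability that three background
  channels jointly clear positivity *and* the separation gap is negligible.
  Isotopic crosstalk is not modelled by default (a single linear spillover
  fraction is available in the simulator to stress this assumption).

The decode rule per CD8+ cell, on the logicle scale: rank the 9 reporter
intensities; let S be the top-3 set; assign scheme⁻¹(S) iff (a) every
channel of S exceeds its positivity threshold, (b) rank3 − rank4 ≥ the
separation cutoff (default 0.5 transformed units), and (c) S is a code of
the active scheme. Cells passing (a)+(b) whose S is one of the unused codes
(84 − 81 = 3 by default) are counted as *decoy positives* — a built-in
false-positive meter reported in the QC output.

An antigen is a **hit** in a tissue when its frequency among CD8+ T cells
strictly exceeds 0.15% (signals below that cutoff behave like noise), and a
**consistent hit** when it is a hit in every tissue supplied (configurable
to k-of-n). With dual staining configurations — the same antigen carrying a
different code in an independently stained aliquot — `hit_concordance()`
additionally requires both configurations to agree, which suppresses
code-specific false positives.

## 2. The synthetic world

`simulate_experiment()` states the world the pipeline is tested against.
Everything the inference side consumes is the intensity matrix; ground
truth lives in a separate `truth` table that no inference function reads.

**Populations.** Each tissue draws a multinomial composition over CD8 T
cells, CD4 T cells, B cells, other CD45+ (lineage-negative contaminants),
dead cells, and equilibration beads (1%). Compositions are calibration
choices (the source study reports only antigen frequencies among CD8):
tumour 20% CD8 / 15% CD4 / 10% B / 50% other / 4% dead; spleen
15/20/35/25/4; lymph nodes 25/40/20/10/4.

**Antigen frequencies among CD8+ T cells** are the published values:
tumour mLama4 10.2%, mAlg8 9.9%; spleen 0.8%/0.6%; dLN 1%/0.3%; ndLN
0.4%/0.2%; the dLN worked example (`dln_example_spec()`) pins 0.89%/0.23%
with the published codes Gd157/Tb159/Yb173 and Dy163/Tm169/Yb173.

**No between-replicate biological variability.** Replicates differ only by
counting noise; the study's between-mouse SEM (±3.2 points in tumour) is a
property of mice, not of the assay, and adding it would make any
5-replicate mean too noisy to compare against the printed point values.
A green frequency-recovery test therefore establishes that decoding is
unbiased against its generator, not that mouse-to-mouse spread is
reproduced.

**Signal model.** CyTOF marginals are zero-heavy: "negative" channels are
exactly 0 with probability 0.85 and otherwise exponential with mean 1.5
counts; "low"/"high" antibody and reporter signals are log-normal (medians
30 and 150 counts, sdlog 0.45); DNA intercalator log-normal (median 600,
sdlog 0.3). Equilibration beads get their own tight level (median 220,
sdlog 0.1): manufactured calibration particles have ~10% CV, far below
antibody staining variation — with antibody-level variance the bead-window
medians would be too noisy for *any* interpolating normalizer to satisfy
the 5% flatness contract. `noise_model_noise_free()` (sdlog 0, no
background) defines the exact world used by the decode-oracle equivalence
tests.

**Phenotype archetypes C1–C10** encode the published sequential biaxial
cluster definitions on the load-bearing markers: C3/C4/C5 are PD-1⁺
KLRG-1⁻ Sca-1⁺ (C3 Tim-3⁻; C5 Tim-3/CD39 high; GITR high on all three,
Lag-3 on C4/C5); C6/C10 are KLRG-1⁺ split by Sca-1; C1/C2 are
triple-negative split by CD27 (C2 expresses no signature marker); C7/C8/C9
are Sca-1⁺ split by Tim-3 and CD160. Levels of the remaining markers
(CD44, CD62L, CD127, CXCR3, ICOS, CD25, CD38) are calibration choices
giving C1/C2 a naive/memory-like and the rest an antigen-experienced
profile. Numeric intensity levels per cluster are *not* published values —
only heat-map colour levels exist — so a green ≥95% rule-recovery test
establishes internal consistency of rules and generator, not fidelity to
the real clusters.

**Cluster mixtures.** Untreated tumour: mLama4 mass concentrated in C1–C3,
mAlg8 in C3–C6 (each major cluster >10%); peripheral tissues and
tetramer-negative cells are C1/C2-dominated. `apply_treatment_effect()`
scales tumour frequencies (anti-CTLA-4 defaults ×2.0 mLama4, ×1.5 mAlg8;
exact multiplication, so 0.102 → 0.204) and moves 90% of C1–C5 cluster
mass into C7–C10 proportionally, for antigen-specific cells in the tumour
only. Anti-PD-1 applies the same phenotype shift with frequency
multipliers of 1 (the source quantifies no anti-PD-1 frequency effect);
`profile_params(exclude = "PD1")` is available because the therapeutic
antibody can mask PD-1 staining.

**Artefacts.** `spike_drift()` ramps a multiplicative gain linearly from 1
to 1 + coefficient over the acquisition — the artefact bead normalization
must undo. Doublets (summed intensity pairs) and linear spillover are off
by default and exercised by dedicated tests.

## 3. Preprocessing contracts

* **Bead normalization** (`normalize_beads()`): bead events are windowed
  (default 500 beads/window; windows under 2 beads merge into a neighbour
  with a warning); per window and bead channel, gain = baseline median /
  window median; gains interpolate linearly between window centres.
  Because the simulated drift is channel-shared, non-bead channels receive
  the mean bead-channel gain curve. Post-condition (tested): bead medians
  flat across the fit's windows within 5%; normalizing already-normalized
  data moves gains by < 1e-6.
* **Zero randomization** (`randomize_zeros()`): every exact zero becomes an
  independent Uniform(−1, 0) draw — the standard CyTOF display convention
  and the reason the logicle domain extends below zero. Applied after
  normalization and before transformation.
* **Debarcoding** (`debarcode()`): on the logicle scale, an event is
  assigned iff its top-2 barcode set is a scheme code, the rank-2 − rank-3
  gap ≥ 0.3 (default), and rank-3 is below positivity (rejecting ≥3-high
  doublet-like events). The source deconvolved barcodes manually; the
  rank-gap rule automates it in the spirit of the single-cell debarcoding
  literature, and the assignment rate is provably non-increasing in the
  cutoff.

## 4. Numerical choices

* **Logicle** (w = 0.25, t = 16409, m = 4.5, a = 0): implemented from the
  biexponential definition; the inner parameter d solves
  2(ln d − ln b) + w(b + d) = 0 by Brent's method at 1e-14; the forward
  transform brackets each root with 60 bisection steps plus a 3-step Newton
  polish (≤1e-8 on the display scale, machine-precision round trips in
  practice). f(0) = w and f(t) = m by construction.
* **1-D thresholds** (`fit_threshold()`): deterministic 2-means Lloyd
  iteration seeded at the data range endpoints — robust when the positive
  mode is rare (beads at 1%, dead cells at 4%) where quantile seeding
  collapses into the background mode; threshold = midpoint of the two
  cluster means. Constant channels raise an error naming the channel.
* **Pooled gate thresholds.** In `run_pipeline()` thresholds are fitted
  once on the pooled acquisition (where every gating channel is bimodal:
  beads provide the DNA⁻/CD45⁻ mode, dead cells the cisplatin⁺ mode) and
  applied as fixed gates per debarcoded sample. Fitting per sample would
  split unimodal channels down the middle (no beads survive debarcoding).
* **Decode positivity floor.** Per-channel two-component splits are guarded
  by a floor (default 1.0 transformed units ≈ 5 counts): reporter channels
  used by no present antigen are unimodal background, where an unguarded
  split lands inside noise. Channels that are exactly constant get an
  infinite threshold (never positive).
* **Ties.** A 4-way tie among reporter channels fails the separation rule
  and stays unassigned; `order()`'s stable tie-breaking never manufactures
  an assignment because condition (b) requires a strict gap.
* **k-means best-of-restarts** runs all restarts in one seeded RNG stream
  and keeps the lowest within-cluster sum of squares, so WCSS is
  non-increasing in the restart count by construction (tested).
* **z-scores** default to the sample SD (n − 1); population SD is a
  documented option. Constant markers are flagged NA, never silently
  zeroed.
* **Holm–Šidák** is the step-down adjustment 1 − (1 − p₍ᵢ₎)^(m−i+1) with
  monotonicity enforcement; the default family is one comparison set per
  tissue/specificity (the source does not state the family).
* **Fisher's exact test** enumerates the hypergeometric support and sums
  probabilities ≤ p(observed)·(1 + 1e-7); the tolerance absorbs float
  round-off in the equal-probability tie cases that define the two-sided
  test.

## 5. Open questions, resolved

* *"Completely different combination" for configuration B*: implemented as
  ≤ 1 shared channel with the antigen's A-code (configurable); full
  disjointness for 81 antigens would exhaust the 84-code book.
* *Hit consistency across tissues*: the 0.15% cutoff applies per tissue,
  and "consistent" means hit in all supplied tissues (k-of-n
  configurable); the source is ambiguous between per-tissue and
  cross-tissue application.
* *z-scores on medians-of-experiments vs pooled cells*: both pathways
  exist (`summarize_markers()` feeds either); the default standardizes the
  replicate-level median matrix, matching the mean-of-five-experiments
  reporting style.
* *Which markers enter t-SNE*: all 16 phenotype markers by default, with
  an exclusion list (PD-1 under anti-PD-1).
* *The full antigen → code mapping is unpublished*: the fixture pins the
  two published example codes and assigns the rest uniformly at random
  without replacement under a stated seed.

## 6. Test-budget scaling

The acceptance tests run the stated problem sizes: the 4-tissue screen uses
5 replicates × 40,000 events (≈2×10⁵ events; per-tissue depth 4k/6k/10k/20k
allocated inversely to expected frequency, since the 0.15% cutoff needs
deep sampling where frequencies are 0.2–0.3%), and the cluster-machinery
criterion embeds the full 10,000 × 16 matrix with 1,000 t-SNE iterations
and 1,000 k-means restarts (~2 min). Unit tests use smaller worlds (1–40k
events) chosen so that every tolerance is ≥3 SDs from its expected value.

## 7. Known limitations

* No isotopic-impurity/oxide crosstalk matrix; the optional spillover is a
  single linear fraction into the next mass.
* Bead normalization approximates the published bead-passport method with
  windowed medians + linear interpolation; it is validated against its own
  5% flatness contract, not against the reference tool.
* The t-SNE/k-means layer is validated on separable instances and by χ²
  concordance with the rule labels; t-SNE hyperparameters (perplexity 30,
  1,000 iterations, θ = 0.5) are unstated in the source and fixed by
  config.
* Real-data p-values from the original study are not reproducible without
  its raw data and are out of scope; the statistics layer is validated
  against closed forms and enumeration oracles instead.
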