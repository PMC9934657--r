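---
title: "Composite spectra analysis: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Composite spectra analysis: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mscsa)
```

## The problem

Untargeted LC/HRMS metabolomics experiments are often acquired in
MS1-only mode: no fragmentation spectra exist, so the usual MS/MS library
search is impossible. Yet electrospray ionization rarely produces a
single ion per compound — in-source fragments, adducts and related ions
of one metabolite co-elute with essentially identical chromatographic
profiles. **Composite spectra analysis (CSA)** exploits this: it groups
MS1 peaks whose extracted-ion chromatograms (EICs) are near-identical in
shape and exports each group as a pseudo-fragmentation spectrum that can
be searched against spectral libraries with the same similarity machinery
used for genuine MS/MS data.

`mscsa` implements the full chain: EIC extraction and smoothing, cluster
deconvolution, DDA/DIA spectrum extraction, cross-sample variant
aggregation, a pre-computed spectral database (FSDB), and
entropy/cosine-based annotation.

## The deconvolution model

Peaks come from an upstream MS1 peak picker as a table of
(m/z, RT apex, RT bounds, height, S/N, optional ¹³C partner). The loop:

1. **Seed selection** — the most intense unassigned peak with
   S/N ≥ `seed_snr_min` (default 5).
2. **Grouping** — unassigned peaks with |ΔRT apex| ≤ `rt_group_window`
   (default 0.01 min, closed on both ends).
3. **Profile correlation** — each candidate's EIC over the *seed's* RT
   bounds is LOESS-smoothed, spline-interpolated onto a common grid, and
   Pearson-correlated with the seed's profile, using only grid points
   where **both** profiles exceed `height_fraction` (default 0.5) of
   their own apex. Members require r ≥ `pearson_min` (default 0.98).
4. **Cluster filters** — at least `min_ions` (2) ¹²C members and a ¹²C
   m/z span strictly greater than `min_mz_span` (8 Da). These two
   filters jointly suppress pure isotopologue envelopes and junk pairs.
5. **¹³C streamlining** — isotopologue ions are appended to the exported
   spectrum only when their ¹²C counterpart is a member; they never seed
   clusters nor count toward the ion or span filters.

Every peak is assigned to at most one cluster. A seed whose neighborhood
fails the filters is still marked assigned — it can never be absorbed
later — which guarantees termination and makes the output invariant to
input row order (seeding depends only on height and S/N, ties broken by
peak id).

When an aligned peaks-by-samples height table is available, candidates
must also correlate with the seed across samples
(r ≥ `intersample_r_min`, default 0.5, computed on samples where both
are detected; the filter abstains below 5 shared samples). This is the
designed defense against chance single-file co-elution — see
*Limitations*.

### Why seed-anchored correlation

The description "correlation among EICs of grouped peaks" is ambiguous
between all-pairs and seed-anchored correlation. We correlate candidates
against the seed only: it is O(n) per cluster, makes membership
independent of candidate enumeration order, and the seed — the most
intense ion — has the best-measured profile. All-pairs correlation would
only differ for clusters on the edge of the threshold, where membership
is unstable under either rule.

### Smoothing

Raw EICs are jagged at low intensity. A locally weighted quadratic
(LOESS, span 0.2) is fitted and evaluated at the raw RT points, then a
cubic spline interpolates onto a uniform 100-point grid over the peak's
RT interval; negative interpolated values are clipped to zero. The span
floor is raised to 3/n on very short chromatograms so the local quadratic
remains determined. On a clean Gaussian sampled at 1 Hz the smoother is
near-identity (< 2% relative error at every grid point — enforced in the
tests); on noisy profiles it measurably increases correlation with the
true shape. Tail fidelity degrades at higher sampling densities where
the fixed span covers more curvature; the correlation step is insensitive
to this because `height_fraction` trims the tails anyway.

## DDA and DIA extraction

**DDA**: MS2 scans matching a peak's m/z (within `precursor_mz_tol`) and
RT bounds are consolidated by one of three options: `integrate_all`
(per-fragment-bin sums), `most_abundant` (the single largest-TIC scan,
returned verbatim), or `denoise` — remove *flat* fragments whose
across-scan relative standard deviation is ≤ `rsd_flat_max` (default
25%), then keep fragments whose across-scan profile correlates with the
precursor's MS1 EIC at r ≥ 0.8. The correlation referent is an
assumption: the criterion is stated as "a Pearson correlation threshold"
without naming the reference, and precursor co-variation is the natural
choice.

**DIA**: fragment candidates come from the single MS2 scan nearest in RT
to the peak's MS1 apex (honoring isolation windows when recorded); each
candidate's MS2-channel EIC is correlated against the precursor's MS1
EIC exactly as in CSA. A fragment absent from the apex-nearest scan can
never appear in the output.

## Scoring model

With `Iᵢ` fragment intensities, `Mᵢ` fragment masses, and NP matched
pairs (greedy nearest-m/z one-to-one matching within `fragment_mz_tol`,
default 0.01 Da):

- **Cosine** = ΣIᵢˡⁱᵇIᵢᵉˣᵖ / √(Σ(Iᵢˡⁱᵇ)²·Σ(Iᵢᵉˣᵖ)²), computed "only using
  the library fragments": unmatched experimental peaks are ignored
  entirely; unmatched library peaks contribute zero numerator but their
  squared intensity stays in the library norm (switchable to
  matched-only via `cosine_lib_norm`).
- **Spectral entropy** S = −ΣI⁣ₚ ln Iₚ over unit-normalized intensities.
- **Weight transform**: for S < 3, intensities are raised to
  w = 0.25(1+S) and re-normalized; S ≥ 3 spectra are untouched.
- **Entropy similarity** = 1 − (2·S_merged − S_lib − S_exptl)/ln 4,
  where the merged spectrum is the 1:1 mix of the two weight-transformed
  spectra (peaks within tolerance combined); clipped to [0, 1] because
  pathological weightings can push the raw value slightly negative.
- **NEME** = √(Σ(Mᵢˡⁱᵇ−Mᵢᵉˣᵖ)²/NP), the RMS matched-mass error in Da.
- **Score** = Cosine × EntropySimilarity², the ranking key (ties: lower
  NEME, then library order).

Both operands are weight-transformed before any entropy enters the
similarity — including S_lib and S_exptl — following the published
transform's procedure; applying the transform only to the merged
spectrum would break the identity `similarity(q, q) = 1`.

Conditioning (adjacent-fragment merging at `resolution_tol`, then
removal of peaks below `noise_pct` = 1% of the base peak) happens once
per library entry at FSDB build time and once per query at search time.
Normalization happens only inside scoring — stored intensities stay raw,
so the scale invariance of all scores makes parse-time normalization
pointless and lossy.

### Prefiltering

Each FSDB entry caches its spectral entropy and its *characteristic
markers* — peaks at ≥ `marker_baseline_pct` (default 10%) of the base
peak. A query is scored against an entry only if (a) precursors agree
within `precursor_mz_tol` (skipped when disabled or when either side has
no precursor, as CSA spectra do not) and (b) at least
`marker_min_match_pct` (default 50%) of the entry's markers have a query
peak within `fragment_mz_tol`. The marker thresholds are package
defaults — the mechanism fixes no canonical values — and
were chosen so that any library spectrum perturbed below the noise
threshold always passes its own entry's gate. Prefilter soundness (the
prefiltered hit set equals the exhaustive one) is asserted over a
1,000-entry library in the acceptance suite.

## Variant aggregation

Spectra recurring across many files are collapsed greedily: the stream
is ordered by descending total intensity (ties by file then spectrum id)
and each spectrum joins the first variant whose RT center is within
`rt_window` (0.1 min) and whose representative scores entropy similarity
≥ `entsim_min` (0.75); otherwise it founds a new variant. Intensity
ordering makes the founder the representative, so variant membership is
deterministic. The clustering order itself is a design choice — the
method statement does not fix one — and single-linkage greedy clustering
is order-sensitive in principle; with the default thresholds exact
duplicates always collapse and the member counts always partition the
input (both asserted).

Batch consensus spectra operate on aligned-table row-id sets: clusters
with Tanimoto |A∩B|/|A∪B| ≥ `tanimoto_min` (default 0.5) merge
transitively; each group emits the ions present in ≥ 50% of its clusters
at the median apex height. Row-id sets (not binned m/z) are the primary
representation because aligned rows are already the batch-level identity
of an ion.

## The synthetic world

`gen_scan_table()` emits Gaussian elution profiles (configurable
exponential tailing) on a fixed scan grid (default 1 Hz), with apex
heights `max_height × relative_abundance`, optional +1.00336 Da
isotopologue partners at 10% abundance, log-normal multiplicative
intensity noise, and uniformly placed singleton noise ions. Peak-list
rows derive from the injected truth (bounds at apex ± 3σ). Defaults
mirror a UHPLC-Orbitrap regime: σ = 0.04–0.06 min (~15 s base width),
heights 10^5.5–10^7, 10-min gradients. `gen_compound_set()` produces the
"well-separated" regime (3–8 ions, spans > 8 Da by construction, apices
≥ 0.1 min apart) under which recovery must be exact.

What the generator does **not** emulate: isotope fine structure, matrix
suppression, correlated chemical noise, RT drift between samples, and
centroiding artifacts. A green recovery test therefore establishes the
correctness of the grouping/filter logic, not real-world annotation
rates.

## Known limitations

- **Chance co-elution of noise ions.** Two random singleton ions whose
  apices fall within the 0.01-min grouping window of each other *are*
  co-eluting by the method's definition; if their widths are similar the
  profile correlation exceeds 0.98 and a 2-ion cluster is emitted. In a
  100-noise-peak world this costs single-file membership precision
  (observed 0.89–0.97 depending on noise placement). This is a property
  of the published filter chain, not of this implementation; the
  designed remedy is the aligned-table inter-sample filter, which
  restores precision 1.0 at recall 1.0 in the same worlds
  (`recovery_precision_with_noise_aligned` in the acceptance report).
- **Smoothing fidelity is sampling-dependent** (see above); the fixed
  default span is tuned to 10–60-point EICs.
- The mzML reader covers centroided spectrumList documents with 32/64-bit
  float arrays (plain or zlib); it is not a general mzML stack.
- Greedy nearest-m/z fragment pairing is not globally optimal for
  pathological peak layouts; within realistic tolerances (0.01 Da against
  peaks ≥ 0.05 Da apart) it coincides with optimal matching.

## Numerical conventions

RT is minutes everywhere; m/z is Da; EIC tolerance defaults to 10 ppm.
RT windows for EIC extraction are half-open `[start, end)`; the seed
grouping window is closed on both ends. Entropies are nats. All
similarity outputs are clipped to [0, 1]. Degenerate inputs: empty
spectra are rejected at entropy, dropped with a warning at FSDB build;
EICs shorter than 5 points neither smooth nor correlate (r = −1);
correlation with fewer than 5 shared above-threshold grid points
returns −1.
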