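# mscsa

Annotation of untargeted LC/HRMS metabolomics data from **MS1-only**
acquisitions.

Electrospray sources fragment and adduct most metabolites in-source, so a
single compound elutes as a cluster of MS1 ions with near-identical
chromatographic profiles. `mscsa` deconvolutes those clusters into
**composite spectra** (CSA) — pseudo-fragmentation spectra built purely
from MS1 data — and annotates them against MSP/MGF spectral libraries
with the same similarity machinery used for real MS/MS spectra. DDA and
DIA (SWATH/MSe) fragment-spectrum extraction, cross-sample variant
aggregation, and study-level annotation ranking complete the workflow.

## The core statistics

For a library/experimental spectrum pair with intensities `I`, masses
`M` and `NP` greedily matched fragment pairs (tolerance 0.01 Da):

- Cosine = Σ Iᵢˡⁱᵇ Iᵢᵉˣᵖ / √(Σ(Iᵢˡⁱᵇ)² · Σ(Iᵢᵉˣᵖ)²), library-fragment
  restricted
- Spectral entropy S = −Σ Iₚ ln Iₚ (unit-normalized intensities, nats),
  with the low-entropy weight transform Iₚ ← Iₚʷ, w = 0.25(1+S) for
  S < 3
- EntropySimilarity = 1 − (2·S_merged − S_lib − S_exptl)/ln 4 for the
  1:1 merged spectrum
- NEME = √(Σ(Mᵢˡⁱᵇ − Mᵢᵉˣᵖ)²/NP) (RMS matched-mass error, Da)
- **Score = Cosine × EntropySimilarity²** (ranking key)

Deconvolution groups co-eluting peaks by Pearson correlation of
LOESS-smoothed EICs (default r ≥ 0.98) and keeps clusters with ≥ 2 ions
spanning > 8 Da, so isotopologue envelopes never masquerade as spectra.

## Worked example

Three synthetic compounds, deconvoluted and searched against their own
reference library:

```r
library(mscsa)
cps      <- gen_compound_set(3, seed = 7)     # 3-8 co-eluting ions each
fx       <- gen_scan_table(cps, seed = 7)     # scans + peak list + truth
clusters <- deconvolute_file(fx$scans, fx$peaks)
clusters[[1]]
#> <csa_cluster> seed 7 @ 4.780 min, 4 ions, file file1

sp <- clusters_to_spectra(clusters)
sp[[1]]
#> <fragment_spectrum> CSA_file1_7
#>   peaks: 5  (m/z 289.9509 - 339.7861)
#>   retention time: 4.780 min

db   <- build_fsdb(gen_library(cps, seed = 7), search_params())
hits <- search_spectrum(sp[[1]], db)
hits[, c("source_id", "np", "cosine", "entropy_sim", "neme", "score", "rank")]
#>   source_id np cosine entropy_sim neme  score rank
#> 1  cmpd_002  4      1      0.9616    0 0.9246    1
```

The cluster's four carbon-12 members (plus one appended ¹³C
isotopologue, hence 5 peaks) match compound 2's reference spectrum:
all 4 library fragments pair (`np = 4`) at zero mass error
(`neme = 0`), cosine 1 (identical relative intensities), entropy
similarity 0.96 (the extra isotopologue peak costs a little), giving
the top-ranked score 0.92.

Batch runs go through a JSON config:

```sh
Rscript inst/cli/mscsa.R --config params.json --threads 4
```

with `{"workflow": "csa", "input": {"scans": [...], "peaklists": [...]}}`
plus optional `csa`/`dda`/`dia`/`search` parameter sections; a manifest
(config snapshot, versions, per-file status) is written beside the
outputs.

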