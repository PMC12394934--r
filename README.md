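# cupep

Analysis of copper-binding peptide populations from food protein
hydrolysates.

Enzymatic digests of food proteins (the motivating system is rice bran
protein hydrolysate) contain subpopulations of peptides that coordinate
Cu(II). Enriching them on a Cu(II)–IMAC resin and sequencing the eluent
reveals characteristic signatures: elevated His, Gly and Pro content,
near-neutral isoelectric points, net charges around +1 to −2, and a
strong preference for histidine at the first N-terminal positions
(ATCUN-type architectures). `cupep` implements the computational side
of such a study for R users — from in-silico digestion through property
profiling, positional composition analysis, motif discovery and
between-condition statistics, to the arithmetic of the accompanying
plate assays.

## What it computes

- **In-silico digestion** with configurable cleavage rules
  (trypsin, pepsin, papain presets), missed cleavages, length bounds,
  and sequential two-enzyme schemes (`digest`, `sequential_digest`,
  `digest_proteins`).
- **Simulated Cu(II)-IMAC retention**: a seeded logistic model over
  peptide features (His count, N-terminal His indicators, Gly/Pro
  fractions) with a calibration routine that hits a target
  retained-population frequency, e.g. 32% His at position N1
  (`simulate_enrichment`, `calibrate_enrichment`, `run_synthetic`).
- **Physicochemical properties** per peptide: Kyte–Doolittle GRAVY
  (mean per-residue hydropathy), isoelectric point as the bisection
  root of the Henderson–Hasselbalch net charge, net charge at a given
  pH, monoisotopic mass (`gravy`, `isoelectric_point`, `net_charge`,
  `peptide_properties`).
- **Composition profiling**: global residue percentages, enrichment
  ratios against a background profile, and 20 × 6 position-specific
  frequency matrices over the N1–N3 and C3–C1 terminal windows
  (`global_composition`, `enrichment_ratio`, `positional_matrix`).
- **Motif analysis**: sliding-window catalogues with frequency
  filtering, normalized Hamming distance
  (fraction of differing positions), cross-condition comparison of the
  most frequent motifs, shared-core detection (`build_catalog`,
  `normalized_hamming`, `cross_condition_compare`, `shared_cores`).
- **Statistics**: two-sided Mann–Whitney U (exact for small untied
  samples, tie-corrected normal approximation otherwise) and
  two-sample Kolmogorov–Smirnov comparisons of property distributions
  (`mann_whitney_u`, `ks_two_sample`, `compare_all_properties`).
- **Assay calculators**: degree of hydrolysis `DH% = h/h_tot × 100`,
  copper-chelation percent
  `(A_control − A_sample)/A_control × 100`, trapezoidal luminescence
  AUC over a kinetic window, no-metal normalization, mean ± SEM
  replicate summaries (`degree_of_hydrolysis`, `chelation_percent`,
  `luminescence_auc`).
- **Pipeline orchestration**: `run_profile` runs ingest → probability
  filter → properties → composition → positions → motifs → stats from
  one config list and writes a TSV/JSON report bundle with per-stage
  counts; `run_synthetic` generates complete two-condition synthetic
  studies. FragPipe-style peptide reports (TSV/CSV, modification
  annotations stripped) and FASTA are the input formats.

## Worked example

```r
library(cupep)

# GRAVY scores for three selected hydrolysate peptides
round_half_away(gravy(c("RHASEGG", "HWPLPPF", "FVVPSGHPI")), 2)
#> [1] -1.57 -0.33  0.90

# full property records
peptide_properties(c("RHASEGG", "HWPLPPF", "FVVPSGHPI"))
#>     peptide length      gravy       pI net_charge net_charge_int mono_mass
#> 1   RHASEGG      7 -1.5714286 7.551309  0.2174018              0  712.3252
#> 2   HWPLPPF      7 -0.3285714 7.550348  0.2161477              0  892.4595
#> 3 FVVPSGHPI      9  0.9000000 7.550348  0.2161477              0  951.5178
```

RHASEGG is strongly hydrophilic on the Kyte–Doolittle scale (−1.57),
FVVPSGHPI hydrophobic (+0.90); all three are near-neutral at pH 7 with
pI just above 7 — the signature of copper-selected rather than
electrostatically-retained peptides.

A complete synthetic study — rice-bran-like proteins digested under
two schemes, passed over a simulated Cu(II)-IMAC column calibrated to
32% N1-histidine, then profiled end to end:

```r
dir <- tempfile()
run_synthetic(list(out_dir = dir, seed = 1))
prof <- run_profile(list(
  inputs = file.path(dir, c("pep_tryp_retained.tsv", "papain_retained.tsv")),
  out_dir = file.path(dir, "report"), probability_threshold = 0))

round(unclass(prof$matrices$pooled)["H", ], 1)
#>   N1   N2   N3   C3   C2   C1
#> 32.4  5.6  7.4  8.7  4.9  6.5
```

Histidine sits at 32.4% of first residues in the retained pool —
six-fold its global abundance — while the other five terminal positions
stay near background: positional architecture, not just composition,
drives simulated retention. The length distributions of the two
digestion schemes differ strongly (Kolmogorov–Smirnov D = 0.50,
p ≈ 0 in `prof$stats`), reflecting the enzymes' cleavage
specificities.

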