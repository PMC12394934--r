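---
title: "Profiling copper-binding peptide populations: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling copper-binding peptide populations: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cupep)
```

## The problem this package addresses

Food protein hydrolysates — here modelled on rice bran protein digests —
are complex peptide mixtures in which a small subpopulation can
coordinate Cu(II). Passing a hydrolysate over a Cu(II)-charged
immobilized-metal affinity (IMAC) resin splits it into a flow-through
(FT) and a retained/eluent (E) fraction, and the sequences identified in
the eluent carry the compositional and architectural signatures of
copper coordination: elevated histidine, glycine and proline content,
near-neutral isoelectric points, modest net charges, and a striking
preference for histidine at the first N-terminal positions (the ATCUN
and pseudo-ATCUN motif families).

`cupep` implements the full desk side of such a study: in-silico
digestion, a seeded model of IMAC retention, per-peptide physicochemical
properties, global and position-specific composition profiling,
sliding-window motif catalogues compared by normalized Hamming distance,
between-condition statistics, and the arithmetic of the accompanying
plate assays.

## In-silico digestion

A `cleavage_rule` cuts C-terminal to any residue in its P1 set, never
after the last residue. Fragments are maximal runs between adjacent
sites; a peptide carrying *k* internal uncleaved sites counts as *k*
missed cleavages, and every fragment with up to `max_missed_cleavages`
(default 2, a standard database-search setting) is emitted before length
bounds are applied. Length bounds default to 5–30 residues for the
simulated populations, the range over which both terminal windows of the
positional analysis are defined and which covers the bulk of observed
hydrolysate peptides.

Three presets are shipped. Trypsin cleaves after K/R. Pepsin is
promiscuous at aromatic and hydrophobic residues; since no single P1 set
captures that promiscuity, the default {F, W, Y, L} is a conventional
reduction and is configurable. Papain prefers basic or hydrophobic
residues; the default set is {K, R, H, L, V, I, F, W, A}, also
configurable. Cleavage before proline is *not* suppressed by default —
the exception is a rule flag (`no_cleave_before_P`) rather than baked
in, because the digestion schemes modelled here are not consistently
described with it.

Sequential digestion (`sequential_digest`) applies the second enzyme to
every fragment of the first, which for zero missed cleavages is provably
the same as a single digestion at the union of the two site sets; the
test suite checks `digest` against an independent brute-force enumerator
that validates every substring of the protein directly against the site
definition.

## The synthetic protein source

`random_proteins` draws residues i.i.d. from a configurable composition
whose default is a literature-style rice bran profile (Gly 6.5%, Pro
9%, His 2%, Ala 6%, Ser 8.5%, conventional values elsewhere; the same
profile ships as `extdata/rice_bran_background.tsv` and is the default
background for enrichment ratios).

An i.i.d. source, however, contains essentially no multi-histidine
peptides: with 2% His, a 12-mer has two or more histidines about 2.6% of
the time and three almost never. Real proteomes are not i.i.d. —
metal-binding loci concentrate histidine locally while global abundance
stays low — and it is precisely those loci that IMAC retention acts on.
The generator therefore overwrites sparse His-rich clusters (5–10
residues drawn from an H/G/P/S/A-biased alphabet, at a default rate of
0.5 clusters per 100 residues). This keeps the global His abundance
near the top of the native 1–3% range (~3.2% in practice) while
producing the His-rich peptide subpopulation that a retention model can
select. Setting `his_cluster_rate = 0` recovers the strictly i.i.d.
source.

## The retention model and its calibration

`simulate_enrichment` assigns each peptide independently to the retained
fraction with probability `plogis(intercept + w · features)`, where the
features are histidine count, indicators for His at N-terminal positions
1 and 2, and the Gly and Pro fractions. Independence (no resin-capacity
competition) is the simplest model consistent with a qualitative
description of affinity capture; the partition is exhaustive, disjoint,
and bit-identical for a fixed seed.

Calibration (`calibrate_enrichment`) mirrors how affinity enrichment
behaves in practice: peptides carrying the targeted binary feature
(His-N1 by default) are captured with a high, fixed probability, and the
enrichment level seen in the eluent is set by how much background
co-retains. The expected feature frequency among retained peptides is
strictly decreasing in the baseline log-odds, so the intercept is found
by `uniroot` on the logistic scale (tolerance 1e-10); unattainable
targets (feature base rate too low) raise an informative error rather
than returning a boundary solution.

`run_synthetic`'s default model combines this N1-His calibration (target
0.32, capture boost `qlogis(0.999)`) with composition weights
`w_his_count = 1.2`, `w_gly_frac = 16`, `w_pro_frac = 15`. These were
fixed once, by calibrating the retained-population profile against the
study conditions the generator is meant to emulate — roughly 13–15%
global His, 16–18% Gly and Pro, ~32% N1-His, near-neutral pI and net
charges around +1 to −2 — and are not adjusted thereafter. On the
default 40-protein source the pooled eluent lands at ≈16% His, ≈16%
Gly, ≈14.5% Pro and ≈32% N1-His, with median pI ≈ 7.5 and median net
charge ≈ +0.4. Two features of real eluents are deliberately *not*
modelled: resin-capacity competition between peptides, and the loss of
the strongest chelators to the flow-through (metal stripping); passing
tests on synthetic data therefore show correctness of the analysis
machinery, not fidelity of the generator to any particular experiment.

## Physicochemical properties

*GRAVY* is the arithmetic mean of Kyte–Doolittle per-residue hydropathy
values, computed at full precision and displayed at two decimals using
half-away-from-zero rounding (so −0.4875 prints as −0.49, matching
published tables; R's own `round` is half-even).

*Net charge* is the Henderson–Hasselbalch sum over the free termini and
the seven ionizable side chains: `+1/(1+10^(pH−pKa))` for the
N-terminus, H, K, R and `−1/(1+10^(pKa−pH))` for the C-terminus, D, E,
C, Y. Cysteine and tyrosine are included because that is standard
practice; the pKa set is the EMBOSS set (N-term 8.6, C-term 3.6, D 3.9,
E 4.1, C 8.5, Y 10.1, H 6.5, K 10.8, R 12.5). Published analyses of
this kind rarely state either choice, so both are explicit, configurable
and recorded in output metadata. The net charge is reported both as the
continuous value and as its nearest-integer bin, the form used for
charge histograms.

*Isoelectric point* is the unique root of the net charge in pH, found by
bisection on (0, 14). The titration curve can be nearly flat around the
pI (for sequences with few ionizable groups), so bisection runs to a pH
interval of 1e-7 rather than stopping at the first pH where the charge
magnitude drops below the 1e-4 tolerance; this keeps the returned pI
within ~1e-3 of the analytic value even in the flat case, while the
charge at the returned pH stays far below tolerance.

*Monoisotopic mass* is the sum of residue masses plus one water.

## Composition and positional profiling

Global composition is residue counts pooled over all peptides, as
percent of all residues. Enrichment ratios divide observed percent by a
background percent; zero-background residues yield `NA`, never infinity.

The positional matrix covers the three N-terminal and three C-terminal
positions (N1–N3, C3–C1). Its denominator is the number of peptides
contributing to a column, *not* total residues — this is what makes
statements like "32% of peptides have His at N1" read directly off the
matrix. Peptides shorter than 5 residues are excluded (and counted in
the output metadata) so both windows are defined; for a length-5 peptide
the middle residue legitimately contributes to both N3 and C3, because
the windows are computed independently. Every column sums to 100, and
the pooled matrix equals the peptide-count-weighted average of the
per-condition matrices — both properties are tested invariants.

## Motif catalogues and cross-condition comparison

For window length *N* (which must not exceed the peptide length), every
peptide contributes its L−N+1 contiguous windows, counted with
multiplicity; a per-peptide-unique mode is a flag. Catalogues are
filtered at a pooled count threshold (`min_count`, default 2 — the
lightest possible frequency filter, since no canonical threshold
exists), and the default analysis sweeps N ∈ {5, 6, 7}, bracketing the
lengths of conserved cores typically selected from such data (5–7
residues). Cross-condition comparison takes each condition's `top_k`
most frequent motifs (ties broken lexicographically) and reports all
pairs within a normalized Hamming distance threshold; the distance —
the fraction of differing positions — is only defined for equal
lengths, so comparisons are restricted to equal-N catalogues. The
metric axioms (symmetry, identity of indiscernibles, triangle
inequality) are property-tested.

## Between-condition statistics

Property distributions (length, pI, GRAVY, net charge) are compared with
the Mann–Whitney U test (midrank ties) and the two-sample
Kolmogorov–Smirnov test, both two-sided, at α = 0.05, with no
multiplicity correction by default because raw per-property p-values
are the reporting convention this package follows (a Bonferroni flag
exists). The MWU p-value is exact when the combined sample size is at
most 16 and no ties are present, and a tie- and continuity-corrected
normal approximation otherwise; the switch is recorded in the `method`
field of every result so reported p-values are reproducible. The exact
branch is verified in the tests against full enumeration of all rank
assignments. KS uses the asymptotic two-sided p-value, the appropriate
regime for the hundreds-of-peptides populations this pipeline targets.

## Assay arithmetic

Degree of hydrolysis is `DH% = h / h_tot × 100`. Chelation percent is
`(A_control − A_sample)/A_control × 100` with
`A_sample = A_full − A_sample_background`; the subtraction order is
stated explicitly because compressed prose descriptions of this formula
are ambiguous. Negative percents are reported with a warning, never
clipped — a sample that raises apparent free copper is information.
Luminescence AUC uses the trapezoidal rule over [0, window] (default 20
minutes) with linear interpolation at the window edge, exact for
piecewise-linear signals, additive over adjacent windows and invariant
to collinear point insertion; whether a plate-reader software package
trapezoids or sums raw readings is rarely stated, so the choice is
documented in output metadata. Replicates aggregate as mean ± SEM
with n.

## The pipeline and reproducibility

`run_profile` sequences ingest → probability filter → properties →
composition → positions → motifs → statistics under one config list and
writes a TSV/JSON report bundle. The probability filter retains
peptides with identification probability ≥ 0.99 by default — the
threshold is inclusive because the filtering convention it follows
removes peptides *below* the cutoff — and peptides lacking a
probability are dropped with their count recorded, never silently.
Every output table opens with a `#` metadata header naming the
parameters that regenerate it; the manifest records per-stage counts;
identical config and inputs give byte-identical outputs (absolute
output paths are deliberately kept out of the manifest). Stage failures
abort with the stage name.

This package's interface is its functions; `run_profile` and
`run_synthetic` are the orchestration layer, and `scripts/acceptance.R`
is a worked end-to-end driver.

## Problem sizes used in validation

The shipped validation suite exercises: 100 random proteins (length ≤
50) against the brute-force digestion oracle across three enzymes and
0–2 missed cleavages; 1000 random peptides for pI/charge consistency
and motif multiplicity; 10⁴ random string triples for the Hamming
metric axioms; a 2000-peptide tryptic population with 100 seeded
replicates per calibration target (0.15, 0.32, 0.50); and full
enumeration of Mann–Whitney rank assignments for all sample splits up
to combined size 10. These sizes give stable statistical behaviour
(binomial intervals in the hundreds-of-peptides regime) while keeping
the whole suite around a minute.

## Known limitations

- Digestion is positional only: no kinetics, pH dependence, enzyme
  concentration, or partial-cleavage probabilities.
- The retention model is independent per peptide; no competition,
  capacity, or metal-stripping effects, and retention depends only on
  sequence-derived features, not structure.
- GRAVY ignores sequence order by construction; discrepancies between
  GRAVY and chromatographic hydrophobicity are expected and are part of
  what the property tables are for.
- pI/charge values depend on the pKa set; cross-set differences of a
  few tenths of a pH unit are normal.
- The assay layer is arithmetic only: no binding-constant fitting, dye
  equilibria, or enzyme kinetics.
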