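---
title: "Models and methods in paleozooms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in paleozooms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleozooms)
```

# Scope

`paleozooms` implements the desk-scale inference chain used to analyse
deeply stratified Pleistocene bone assemblages with collagen mass
spectrometry: ZooMS taxonomic screening, glutamine deamidation as a
preservation proxy, shotgun-proteome consensus reconstruction with
phylogenetic placement, and NISP-based community statistics. Everything
runs on synthetic data with known ground truth; the generators are
first-class, tested code, not fixtures.

# ZooMS marker databases

Collagen type I dominates bone. Tryptic COL1 peptides whose monoisotopic
masses differ between taxa ("peptide markers") let a MALDI-TOF spectrum
of a digested bone chip be assigned to a taxon, usually at genus to
subfamily rank. `digest_sequence()` applies the classical trypsin rule
(cleave after K/R, not before P); `peptide_mz()` sums standard
monoisotopic residue masses plus water and a proton, with +15.994915 Da
per hydroxyproline and +0.984016 Da per deamidation. These constants are
compiled in: the field's marker tables assume exactly these values, and
instrument precision (~0.05-0.1 Da at MALDI-TOF) is far coarser than
their uncertainty.

`predict_markers()` digests one sequence per taxon, computes masses over
a configurable hydroxylation range (default 0-1; published marker lists
do not fix the states, so the range is a parameter, not a constant), and
assigns each distinct mass its diagnostic taxon: the lowest common
ancestor of all taxa sharing the mass. Masses closer than 0.05 Da are
treated as one marker — below that separation MALDI-TOF cannot
distinguish them anyway.

Assignment logic (`lowest_consistent_taxon()`, `assign_taxon()`) mirrors
screening practice: markers diagnostic at nested ranks reinforce one
another, so a specimen matching 14 subfamily-level and 1
superfamily-level hominid markers is called at the subfamily; genuinely
conflicting lineages coarsen the call to their common ancestor and flag
it tentative. A `secure` call needs at least `min_markers` (default 3)
distinct markers at or below the assigned rank with no conflicting
sibling reaching half that support; the threshold is conservative and
exposed because published screening studies report marker counts but not
a numeric cutoff. Deamidated satellite peaks (+0.984 Da) of a marker
count as the same peptide, never as independent evidence.

# Spectra

Peak lists are two-column TSV (a minimal uncompressed mzML reader/writer
is provided for interchange). `pick_peaks()` reproduces the standard
profile pipeline — square-root transform, moving-average smoothing,
moving-median baseline, SNR gate against the MAD of the residual — with
windowed local-maximum detection; re-running it on its own output is a
no-op, so centroided data can enter the pipeline at any point.
`merge_replicates()` implements triplicate-spot merging: single-linkage
clustering in m/z (tolerance 0.2 Da) and a 2-of-3 support rule. The
source studies do not state their merging tolerance or support rule;
these defaults are common ZooMS practice and are CLI-exposed, declared
rather than inferred.

# Glutamine deamidation

Deamidation (Q→E, +0.984016 Da) accumulates with burial time and
temperature. For the two slow-deamidating collagen peptides tracked in
the field — COL1α1 508–519 (`GVQGPPGPAGPR`, marker P1105) and COL1α1
435–453 (`DGEAGAQGPPGPAGPAGER`, P1706), both taken with one
hydroxylation because that is the observed marker state — the +0.984 Da
shift is 0.019 Da short of one isotope spacing, so the Q and deamidated
isotope combs overlap on a shared nominal grid. `estimate_deamidation()`
fits observed intensities on the first five isotope positions of each
form as a non-negative combination `α·envelope(Q) + β·envelope(deam)`
(two-column NNLS in closed form) and reports `α/(α+β)`: 1 = no
deamidation, 0 = complete. The cited methodology does not restate its
fitting formula; this NNLS-on-envelopes formulation is the package's
declared implementation, validated by the exact boundary cases (pure
forms give exactly 1 and 0) and by grid recovery under multiplicative
noise (MAE ≤ 0.03 at 5% intensity noise). Isotope envelopes come from
polynomial convolution of per-element natural-abundance distributions
over the peptide's elemental composition; higher isotopes are
noise-dominated and excluded from the fit.

Layer summaries use the arithmetic mean with a 68.2% interval taken as
the 15.9–84.1 percentiles of bootstrap means over specimens. Whether
published "68.2% probability ranges" are bootstrap, ±1 SD or ±1 SEM is
not stated; bootstrap percentile was chosen as the assumption-free
option, with the seed recorded in the output.

# Consensus proteomes

PSM tables mirror a search-engine "protein-peptides" CSV export.
`filter_fdr()` performs target–decoy estimation: PSMs ranked by score,
false-discovery proportion = decoys/targets at or above each threshold,
monotonized into q-values; the conventional ancient-proteome threshold
is 0.5% at the peptide level (spectrum- vs peptide-level is not
specified upstream; peptide-level was chosen). `build_consensus()`
rejects proteins with fewer than five distinct peptides and otherwise
calls, per reference position, the residue with the largest summed
peptide count. "Peptide count" is interpreted as distinct peptide
sequences weighted by spectral count (the multiplicity convention is not
defined upstream; the unweighted variant is a flag). Ties yield X —
downstream phylogenetics treats X as missing, which is safer than an
arbitrary pick. `concatenate_proteins()` applies isoform edits (delete /
mask / insert-unknowns on 1-based intervals) before concatenation;
deletions are padded with trailing gaps to keep the matrix rectangular.
The four published isoform edits for hominid references ship as the
example edit list `inst/extdata/isoform_edits.json`, as data rather than
hard-coded logic.

# Phylogenetic placement

The Dayhoff amino-acid model is compiled in from the canonical PAML
`dayhoff.dat` exchangeabilities and frequencies; `Q = S·diag(π)` is
rescaled to one expected substitution per site so branch lengths are in
substitutions/site. Likelihoods use Felsenstein pruning with per-node
rescaling; X and gaps are missing data. Branch lengths are optimized
coordinate-wise using the spectral form of `P(t)`, which makes a Brent
step one 20×n product; stale-message sweeps are guarded by a full
pruning pass and rolled back if they ever decrease the likelihood.
Topology search is exhaustive for ≤ 7 taxa (the 8-taxon mode exists but
enumerates 10,395 topologies and is not the default) and NNI
hill-climbing from a neighbor-joining start otherwise. Bootstrap support
resamples columns, re-searches each replicate by NNI seeded from the
full-data ML tree, and reports bipartition frequencies. Partition-aware
rate multipliers and Bayesian sampling are out of scope; an outgroup is
used for display only, likelihood is computed unrooted.

# Faunal statistics

Morphological and ZooMS identifications are united at ZooMS-compatible
group levels: agreeing pairs keep the more specific taxon and coarsen to
the group; conflicts resolve to the LCA and are flagged; excluded clades
(e.g. birds, rodents) and taxa reaching no group level drop out of the
community table. NISP is the abundance measure (MNI is parsed but never
used). Percentages round half away from zero to one decimal — the
convention that reproduces the printed ratios (386/2005 → 19.3%; note
3/2005 = 0.1496% also rounds to 0.1%, so no special-casing is needed).
Shannon H = −Σ p·ln p (natural log) and Gini–Simpson D = 1 − Σ p², with
2.5–97.5 percentile CIs from multinomial resamples, matching the
community-ecology conventions of the standard R implementation (`vegan`
serves as the independent oracle in the tests, never as the
implementation).

# The synthetic world

The generators state one world and keep it fixed:

* **Taxonomy/sequences**: 8 species in 4 single-genus families under one
  class — the smallest tree exercising species-, genus- and class-level
  assignment. A deterministic collagen-like Gly-X-Y chain (~40 tryptic
  segments) carries 2 family-level and 3 species-level substitutions per
  taxon, drawn from residues mutually ≥ 0.9 Da apart so markers never
  collide within matching tolerance. The two deamidation peptides are
  embedded verbatim, as in real terrestrial mammals. Because each family
  holds one genus, family-shared substitutions surface as
  genus-diagnostic markers; the three exercised ranks are species, genus
  and class.
* **Spectra**: triplicate spotting, log-normal intensities, Gaussian m/z
  error (default 0.03 Da; 0.05 Da in the stress test), per-replicate
  dropout 10% (20% stress), 5 uniform background peaks (10 stress).
  Deamidation enters as full isotope envelopes split q : (1−q); default
  layer gradient q = 0.7, 0.5, 0.3, 0.1 from shallow to deep, spanning
  the range reported for stratified cave sites (≈0.5 at ~40 ka to ≈0.04
  for the oldest material).
* **PSMs**: peptides tiled to depth 6 with per-residue error ε = 0.02,
  reversed-sequence decoys scoring clearly lower, geometric spectral
  counts.
* **Alignments**: sites evolved under Dayhoff along an 8-leaf
  great-ape-like tree whose `Ancient` leaf is sister to `Denisovan`
  (stem 0.05 substitutions/site) and is masked to 14.5% coverage — the
  coverage regime of the reconstructed palaeoproteome the package
  emulates.

What a green test establishes: the pipeline recovers the truth of
*this* stated world. What it does not establish: robustness to matrix
effects, instrument-specific peak shapes, contamination, reference-bias
in consensus calling, or collagen sequence variation beyond simple
substitutions — none of which the generators attempt to mimic.

# Numerical choices and degenerate inputs

* Marker m/z stored at 4 decimals (below instrument precision, above
  rounding noise); database round-trips are exact at that precision.
* NNLS with both coefficients zero, or no peaks in the isotope window,
  returns no estimate with an explanatory message rather than a 0/0.
* Single-specimen layers yield zero diversity indices with degenerate
  CIs and a warning; empty layers are omitted.
* Likelihood scaling is per-node column-sum normalization; a non-finite
  log-likelihood aborts with the first offending pattern index.
* Branch-length optimization is bounded in [1e-9, 10]
  substitutions/site; ties in consensus voting yield X; ties in marker
  clustering break by ascending m/z.

# Known limitations

Exhaustive search above 7 taxa is impractical in pure R; NNI from an NJ
start can in principle stop in a local optimum, which the bootstrap
partially exposes. The mzML support is deliberately minimal (one
centroided spectrum, uncompressed 64-bit arrays). Real-data quantities
that require the public PRIDE deposits — the Xiahe-type specimen's
marker count and its deamidation values — are documented as inputs and
excluded from desk-scale verification by design.
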