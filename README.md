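# paleozooms

Desk-scale palaeoproteomics for Pleistocene bone assemblages: ZooMS
taxonomic screening, collagen deamidation, consensus proteome
reconstruction with phylogenetic placement, and faunal community
statistics — with seeded synthetic-data generators providing ground
truth for every stage.

## Who this is for

Zooarchaeologists and palaeoproteomics researchers who screen large bone
assemblages by collagen peptide mass fingerprinting (ZooMS), track
protein preservation through glutamine deamidation, and place rare
hominin finds among reference proteomes — and who want the whole chain
reproducible from plain-text inputs without wrapping external binaries.

## The core methods

* **ZooMS identification.** Tryptic COL1 peptides carry taxon-diagnostic
  monoisotopic masses ([M+H]⁺ = Σ residue masses + H₂O + H⁺, with
  +15.9949 Da per hydroxyproline). MALDI-TOF peak lists (triplicate
  spots, merged by single-linkage clustering with a 2-of-3 support rule)
  are matched against a taxonomy-aware marker database; a specimen's
  assignment is the lowest taxon consistent with its matched markers,
  so 14 subfamily-level plus 1 superfamily-level hominid markers call
  the subfamily.
* **Deamidation.** For COL1α1 508–519 (GVQGPPGPAGPR) and COL1α1 435–453
  (DGEAGAQGPPGPAGPAGER), the Q and deamidated (+0.984016 Da) isotope
  envelopes overlap on a shared grid; the observed envelope is fit as
  α·env(Q) + β·env(deam) by non-negative least squares and the value
  α/(α+β) is reported on the 0–1 scale (1 = no deamidation).
* **Consensus proteomes.** PSM tables are filtered by target–decoy FDR
  (q ≤ 0.5%); proteins with ≥ 5 distinct peptides get a per-position
  majority consensus weighted by peptide counts; sequences concatenate
  into a partitioned alignment after isoform edits.
* **Placement.** Maximum likelihood under the Dayhoff model (Felsenstein
  pruning; exhaustive topology search ≤ 7 taxa, NNI beyond) with
  nonparametric bootstrap support on bipartitions.
* **Faunal statistics.** NISP tables at ZooMS-compatible group levels,
  modification percentages (half-away-from-zero rounding), Shannon
  H = −Σ p ln p and Gini–Simpson D = 1 − Σ p² with multinomial bootstrap
  CIs.

## Worked example

```r
library(paleozooms)

cfg <- sim_config(seed = 1, n_specimens_per_layer = 3)
sim <- simulate_col1_taxa(cfg)              # 8 species, 4 families
db  <- predict_markers(sim$sequences, sim$taxonomy)
db
#> <marker_database: 280 markers, 13 taxa, m/z 884.4-3830.7>

sp   <- simulate_spectra(cfg, db)           # triplicate MALDI peak lists
cons <- lapply(sp$spectra, merge_replicates)
ids  <- identify_specimens(cons, db)
head(ids[, 1:5], 4)
#>   specimen_id     taxon    rank n_markers quality
#> 1     SYN-001 Species1a species         8  secure
#> 2     SYN-002 Species2a species        15  secure
#> 3     SYN-003 Species3a species        14  secure
#> 4     SYN-004 Species4a species        12  secure

est  <- Filter(Negate(is.null), lapply(cons, estimate_deamidation))
lmap <- setNames(sp$truth$layer, sp$truth$specimen_id)
summarize_by_layer(est, lmap, n_boot = 500, seed = 42)
#>   layer        peptide n mean lo_68 hi_68
#> 1   L10 COL1a1 508-519 3  0.1   0.1   0.1
#> 2    L3 COL1a1 508-519 3  0.7   0.7   0.7
#> 3    L5 COL1a1 508-519 3  0.5   0.5   0.5
#> 4    L7 COL1a1 508-519 3  0.3   0.3   0.3
```

Every specimen is recovered at its true species with a `secure` call,
and the layer-mean deamidation values reproduce the generator's
stated stratigraphic gradient (0.7 shallow → 0.1 deep) exactly on
noiseless input. `percentage(2005, 2567)` returns `78.1` — the
identified fraction as printed in assemblage tables.

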