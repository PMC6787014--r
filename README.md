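# gliomaTIL

Tumor-immunology analyses for diffuse glioma, packaged as tested R
functions plus a numbered analysis workflow. The package quantifies
tumor-infiltrating T cells (TILs) in space, enumerates neo-epitope
candidates from somatic mutations, summarizes TCR-Vβ repertoire dominance,
and compares low-grade (LGG, WHO II) against high-grade (HGG, WHO IV)
glioma with nonparametric statistics — the computational core of studies
asking why LGG harbor few, perivascularly retained T cells.

## What it computes

**Perivascular spatial profiles.** From a binary vessel mask and T-cell
centroids, cells are counted in half-open concentric annuli
[kw, (k+1)w), w = 30 µm, up to 180 µm from the nearest vessel border
(exact Euclidean distance transform; one nearest-vessel map, so nothing is
double-counted). Densities are reported per annulus area (cells/mm²),
normalized to the first perimeter (= 100%), compared per annulus between
groups (Mann-Whitney U), and summarized by a decay length λ̂ from the
log-linear fit ρ(d) ≈ ρ₀·e^(−d/λ).

**Neo-epitope cascade.** Coding SNVs are edited into the CDS, translated
(stop at first stop codon), and each missense variant yields the 17-aa
window centered on the mutated residue; all mutation-spanning 9-mers are
scored per HLA class I allele through a pluggable scorer interface and a
candidate passes iff FPKM > 0 and binding, cleavage and TAP scores are all
> 0.5 (strict). Expressed nonsynonymous mutations and expressed cancer
germline antigens (FPKM > 0 against a bundled CT-antigen symbol snapshot)
are counted per sample.

**TCR-Vβ repertoire.** Productive frequency (% of unique CDR3-nt
clonotypes without a premature stop), dominant clone count k = smallest
number of top productive clones reaching 30% of productive reads, and
top-10 clone abundance (%), with two-group comparisons.

**Group statistics.** 2^−ΔCt qPCR expression against GAPDH, exact
Mann-Whitney U (enumeration when min(n) ≤ 8, no ties; corrected normal
approximation otherwise), Benjamini-Hochberg FDR, and printed-table
fold-change replication (mean ratio, rounded half-away-from-zero).

**Synthetic cohort.** Every stage has a seeded generator with ground
truth: an inhomogeneous Poisson point process (thinning, intensity
ρ₀·e^(−d/λ)) around non-overlapping disk vessels; toy transcriptomes with
planted synonymous/missense SNVs and a brute-force truth list of passing
epitopes; uniform/geometric/power-law clone repertoires; Ct tables with
planted group shifts.

## Worked example

```r
library(gliomaTIL)

# simulate a tissue with decay length 40 um and profile it
ts   <- simulate_tissue(spatial_sim_params(
          image_size_px = c(800L, 800L), pixel_size_um = 1, n_vessels = 3L,
          baseline_density_per_mm2 = 2e4, decay_length_um = 40, seed = 1))
geom <- build_annuli(ts$vessel_mask, ts$pixel_size_um)
prof <- normalize_profile(count_cells_per_annulus(ts$cells, geom))
prof$normalized_pct[1]
#> [1] 100
estimate_decay_length(prof)$lambda_hat_um
#> [1] 37.83312

# published-table fold change from printed log2 means (CCL5 row)
fold_change(6.1, 7.6)
#> [1] 0.8

# exact Mann-Whitney on fully separated groups of 3
mann_whitney_u(c(1, 2, 3), c(4, 5, 6))$p.value
#> [1] 0.1

# dominance closed form: 10 equal clones reach 30% at the third clone
u10 <- repertoire(data.frame(cdr3_nt = sprintf("N%02d", 1:10),
                             cdr3_aa = sprintf("A%02d", 1:10),
                             reads = 10L, productive = TRUE))
dominant_clone_count(u10)
#> [1] 3
```

The first value confirms the normalization contract (first perimeter
= 100%); the decay length recovers the simulated 40 µm within sampling
error; 0.8 reproduces the
printed fold-change entry for CCL5; 0.1 is the exact two-sided p for
non-overlapping groups of three; and k = 3 is the 30% dominance threshold
crossing for a flat 10-clone repertoire.

## Analysis workflow

Numbered drivers under `analysis/` run the full study on the synthetic
cohort and write tables under `results/`:

```sh
Rscript analysis/01_simulate_cohort.R    # cohort inputs in on-disk formats
Rscript analysis/02_spatial_til.R        # annulus profiles, comparison, decay
Rscript analysis/03_antigen_load.R       # neo-epitopes, expressed mutations, CGAs
Rscript analysis/04_tcr_repertoire.R     # dominance / convergence statistics
Rscript analysis/05_expression_qpcr.R    # 2^-dCt, MW + BH across the panel
Rscript analysis/06_table_replication.R  # printed fold-change replication
```

`run_pipeline()` performs the same stages programmatically from a single
(YAML-able) configuration and writes per-stage TSVs, stage reports and a
summary.

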