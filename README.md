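# ciliomics

Quantitative analysis of primary cilia in polarized kidney epithelial
cells — the computational side of a cilia-BioID2 proximity-proteomics and
3D immunofluorescence study of ciliary protein trafficking.

The package bundles four analyses that are usually scattered across
MATLAB/Fiji scripts, Perseus and GraphPad:

1. **Automated 3D cilium quantification** (`run_quantification()`).
   Multi-channel spinning-disk z-stacks are processed in five fully
   automated steps: (1) nuclei are segmented from the DAPI channel
   (Gaussian smoothing, opening-based background subtraction, global Otsu
   threshold); (2) primary cilia are segmented from the cilia-marker
   channel (smoothing + local-mean threshold) and each nucleus keeps its
   brightest overlapping candidate; (3) the ciliary **base** is the cilium
   voxel nearest the nucleus center of mass (cilia grow outward);
   (4) the **base region** is the set of cilium voxels within a
   user-defined geodesic distance of the base, measured inside the cilium
   mask with anisotropy-weighted 26-connected steps; (5) per-channel mean
   fluorescence intensities (MFI) are reported for the whole cilium, base
   region and body after subtracting a 3D median-filtered background.
   Cilium length (geodesic diameter of the mask) and per-image ciliation
   frequency are reported alongside.

2. **BioID2 LFQ differential pipeline** (`run_diff_pipeline()`). For the
   2 construct (cilia-BioID2 / BioID2 control) x 2 genotype (WT / KO) x 6
   replicate design: downshifted-normal imputation of missing values
   (mean − 1.8·SD, width 0.5·SD, applied only where zeros occupy fewer
   than half of a group's replicates), per-protein log2(KO/WT) median
   ratios with pseudovalues two units beyond the finite-ratio range for
   infinite ratios, Student's t-test with Benjamini–Hochberg correction,
   the Significance A robust outlier test
   (z from the 15.87/50/84.13 ratio percentiles, p = ½·erfc(z/√2)),
   removal of proteins significant in the whole-cell control contrast,
   and three-tier classification: **Tier 1** (q ≤ 0.05 and SigA ≤ 0.05),
   **Tier 2** (SigA only), **Tier 3** (q only), with depleted/enriched
   direction.

3. **GO term enrichment** (`fisher_enrich()`, `rank_and_prune()`).
   Classic one-sided Fisher exact tests over a supplied ontology DAG with
   true-path annotation propagation, odds-ratio ranking with a top-30 /
   p < 0.05 cut, and ancestral-redundancy pruning that keeps only the most
   specific term of each lineage.

4. **Group-comparison decision tree** (`compare_groups()`,
   `normalize_to_control()`). Control-normalized MFI values are tested for
   normality (Shapiro–Wilk for n < 8, D'Agostino K² otherwise); normal
   data get Student's t (2 groups) or ANOVA + Tukey (>2), non-normal data
   get Mann–Whitney or Kruskal–Wallis + Dunn (Bonferroni), with the
   standard significance-star mapping.

Synthetic-data generators with exported ground truth
(`generate_cell_field()`, `generate_lfq_experiment()`) emulate the study's
imaging and proteomics data so every stage is testable without downloads.

## Worked example

```r
library(ciliomics)

## simulate a field of 30 polarized epithelial cells and quantify it
p   <- synth_imaging_params(n_nuclei = 30L, volume_shape = c(32L, 320L, 320L),
                            seed = 42L)
sim <- generate_cell_field(p)
res <- run_quantification(sim$stack, quant_config())
res
#> <cilia_quant> 30 nuclei, 17 cilia (ciliation 0.567)
head(res$table[, c("cilium_label", "nucleus_label", "length_um",
                   "target_mfi_whole", "target_mfi_base", "target_mfi_body")], 4)
#>   cilium_label nucleus_label length_um target_mfi_whole target_mfi_base target_mfi_body
#> 1            1             3  5.357505         164.6004        410.5646        116.9944
#> 2            2             4  3.427009         194.4375        354.7801        117.4730
#> 3            3             5  6.251932         160.3202        424.0710        111.3987
#> 4            4             6  4.467607         183.4410        413.4802        116.4676
```

Each row is one retained cilium: its nucleus, centerline length in
micrometres and background-corrected MFIs. The simulated target protein is
base-enriched (painted at 800 vs 200 camera units before blur), and the
recovered base MFI is correspondingly several-fold the body MFI.

```r
## simulate a BioID2 LFQ experiment (100 ciliary "spikes" at log2FC -2,
## 100 whole-cell contaminants) and run the differential pipeline
lfq  <- generate_lfq_experiment(synth_proteomics_params(seed = 42L))
diff <- run_diff_pipeline(lfq$matrix, imputation_params(seed = 1L))
diff
#> <lfq_diff> cilia-BioID2 KO/WT differential results
#>    Tier1    Tier2    Tier3       NS excluded
#>       83       94        8     1566      226
#> Tier1: 79 depleted, 4 enriched

## compare control-normalized staining intensities across cell lines
rep <- compare_groups(normalize_to_control(df, "WT"))  # df: group, value
rep
#> <test_report> branch: kruskal_dunn
#>   omnibus p = 2.941e-08
#>  group1 group2            p        p_adj stars
#>      KO rescue 3.305951e-06 9.917854e-06  ****
#>      KO     WT 4.914827e-08 1.474448e-07  ****
#>  rescue     WT 4.216682e-01 1.000000e+00    ns
```

Most spiked (truly ciliary) proteins land in Tier 1 with depleted
direction; contaminants altered in both constructs are excluded by the
whole-cell control filter. The group comparison routes skewed MFI data to
the Kruskal–Wallis + Dunn branch and stars the pairwise results.

A command-line surface over the same functions ships in
`inst/cli/ciliomics` (`simulate-images`, `simulate-lfq`, `quantify`,
`diffexpr`, `enrich`, `compare-groups`); every invocation writes a JSON
run manifest next to its outputs.

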