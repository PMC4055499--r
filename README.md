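# asdconnectome

Graph-theoretic and machine-learning analysis of multiparametric brain
MRI features for two-group (autism spectrum disorder vs. typically
developing) cohort studies — as a tested, reusable R package.

The package is aimed at neuroimaging researchers who work with
*post-preprocessing* tabular MRI data: per-subject regional cortical
thickness and volumes, ROI time series, and clinical phenotype scores.
It implements the full analysis chain:

1. **Connectivity networks** — per-subject functional correlation
   matrices; per-group structural covariance networks (across-subject
   correlation of thickness or normalized volumes); binarization at a
   sparsity sweep keeping the largest positive correlations.
2. **Small-world efficiency** — global efficiency
   *E*<sub>glob</sub> = (1/n(n−1)) Σ<sub>i≠j</sub> 1/d<sub>ij</sub> and
   local efficiency *E*<sub>loc</sub> = mean over nodes of
   *E*<sub>glob</sub> of the neighbour-induced subgraph
   (Latora–Marchiori), absolute and relative to degree-matched
   Maslov–Sneppen random nulls, with subject-level t-test or
   subject-bootstrap group comparison.
3. **Quantitative fcMRI features** — seed-based connectivity summaries
   (suprathreshold count N and mean Fisher z, threshold z > 2.3),
   homotopic (VMHC) summaries, and fALFF (0.01–0.08 Hz band fraction).
4. **Feature integration** — the canonical 22-feature table (9
   subcortical volumes, 8 seed N/Z, 3 fALFF, 2 VMHC), variance
   normalization, PCA component count at a 95%/99% variance threshold,
   and greedy mRMR selection (mutual information on μ±σ three-bin
   discretization; MID criterion, MIQ behind a switch).
5. **Models** — a randomized decision tree for group classification and
   a Gaussian-kernel instance-based (K*-style) regressor for phenotype
   prediction, with full-dataset / k-fold / percentage-split evaluation
   and margin curves.
6. **Group statistics** — supratentorial volume normalization (×1000),
   percentage change Δ = (V₂−V₁)/V₁·100, two-sample t-tests with ×8
   Bonferroni correction, and feature–phenotype correlations with the
   category-structured correction (5 categories × sub-domain counts).

Raw image processing (registration, segmentation, voxel-level maps) is
out of scope. Because the package operates downstream of it, a
first-class **synthetic cohort generator** produces two-group data with
planted, configurable effects — regional volume/thickness differences,
group-specific thickness-covariance structure, seed-network and
homotopic coupling, and phenotype scores linearly coupled to the imaging
features — so every stage is testable and calibratable end to end. See
`vignettes/methods.Rmd` for the models and the design decisions.

## Worked example

```r
library(asdconnectome)

cfg    <- cohort_config(n_per_group = 100, seed = 42)
cohort <- generate_cohort(cfg)
#> <cohort> 200 subjects (100 TD / 100 ASD)
#>   thickness: 148 regions; volumes: 263 regions; ROIs: 112 x 180

feats  <- compute_feature_table(cohort)
normed <- variance_normalize(feats)
k95    <- component_count(normed, threshold = 0.95)   # 17
sel    <- mrmr_select(normed, feats$group, k = k95)
#> <selection_result> k = 17 (difference criterion)
#>    vmhc_Z > vmhc_N > fc_caudate_Z > fc_ifg_tri_Z > fc_ifg_oper_Z > ...

tab <- feats[, c("id", "group", sel$selected)]; class(tab) <- class(feats)
evaluate("random_tree", tab, protocol = "kfold", param = 10, seed = 1)
#> <eval_report> kfold(10): accuracy 0.975

p_td  <- efficiency_profile(structural_covariance_matrix(cohort, "thickness", "TD"),
                            grid = c(0.1, 0.2, 0.3), n_random = 20, seed = 1)
p_asd <- efficiency_profile(structural_covariance_matrix(cohort, "thickness", "ASD"),
                            grid = c(0.1, 0.2, 0.3), n_random = 20, seed = 2)
round(data.frame(sparsity = p_td$sparsity,
                 td_rel_glob  = p_td$e_global_rel,
                 asd_rel_glob = p_asd$e_global_rel), 3)
#>   sparsity td_rel_glob asd_rel_glob
#> 1      0.1       0.800        0.463
#> 2      0.2       0.916        0.555
#> 3      0.3       0.974        0.869
```

The selection concentrates on the features carrying the planted group
signal (connectivity Z summaries, homotopic Z, caudate volumes); the
classifier separates the groups at 97.5% cross-validated accuracy under
these (deliberately strong) defaults; and the ASD group's
structural-covariance network shows markedly lower relative global
efficiency across sparsities — the planted small-world deficit.

Phenotype prediction from the connectivity summaries within the ASD
group works the same way (`predict_phenotype()`); with the default
modest couplings it recovers, e.g., r ≈ 0.52 for the ADOS module score
from the IFG opercularis summaries at n = 100 (about the level of the
strongest single planted coupling).

The whole chain behind one configuration:

```r
run_pipeline(run_config(master_seed = 7), "out/")   # 7 stages + manifest
```

or from a shell, `Rscript inst/cli/asdconnectome.R run-all --out out
--seed 7` (subcommands: `simulate`, `features`, `select`, `stats`,
`run-all`).

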