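# periscope

Quantifying peripheral heterochromatin from two directions: radial
fluorescence profiling of nuclei, and megabase-window co-enrichment of
ChIP-seq peak sets.

Heterochromatin carrying H3K9 methylation is tethered to the nuclear lamina,
so two kinds of evidence speak to the same biology: in images, a
heterochromatin mark should form a ring at the nuclear periphery; in ChIP-seq,
the genomic windows enriched for the mark's writer should coincide with the
windows enriched for lamin B1, at the megabase scale of lamina-associated
domains (LADs). `periscope` is for chromatin biologists who have grayscale
immunofluorescence images and/or BED peak files and want small, auditable
statistics for both questions — plus a synthetic-data generator that plants
known ground truth so every stage of the analysis can be validated.

## What it computes

**Radial MFI profile.** For each segmented nucleus, 200 rays are cast from
the centroid at angles 2πk/200; each ray ends at the nuclear boundary (the
last mask pixel along the ray, refined to sub-pixel precision) and is sampled
at 200 points at radius fractions f_j = j/199. The mean over rays gives the
mean fluorescence intensity MFI(f) from center (f = 0) to periphery (f = 1);
cohorts are aggregated pointwise (mean ± population SD across nuclei). The
center-vs-periphery summary averages MFI over f ∈ [0, 0.25) and f ∈ [0.75, 1];
their ratio is the *peripheral enrichment*.

**Window observed/expected enrichment.** Each chromosome is tiled with 1 Mb
windows and peaks are counted per window by midpoint. The expected count is
the chromosome's total divided by its number of windows, so per window

    ratio = observed / expected ,   enriched ⇔ ratio > 1.5 ,

and the mean ratio within each chromosome is exactly 1. Co-enrichment of two
factors is the Spearman (or Pearson) correlation of their ratio tracks, with
a seeded permutation p-value, p = (1 + #{|r_perm| ≥ |r_obs|}) / (1 + B).
Peak-level summaries cover co-bound peaks (Venn-style overlap with both
directions reported), genomic-feature classification (upstream > exon >
intron > others, by midpoint), and strand-aware TSS composite profiles.

## Worked example

```r
library(periscope)

## --- imaging: 10 synthetic nuclei with a planted 4x peripheral ring -------
co   <- make_nucleus_cohort(10, image_size = c(512, 512),
          param_ranges = list(ring_contrast = c(4, 4), noise_sd = c(10, 10)),
          seed = 7)
recs <- segment_nuclei(co$intensity, mask = co$labels, min_area = 100)
agg  <- aggregate_profiles(lapply(recs, radial_scan))
mfi_summary(agg)
#> MFI center [0, 0.25): 99.827 | periphery [0.75, 1]: 389.823 | peripheral enrichment: 3.905

## --- genomics: two coupled peak sets on a toy 200-window genome -----------
g    <- genome_model(c("chr1", "chr2"), c(120e6, 80e6))
sim  <- make_peak_sets(g, peak_sim_params(base_rate = 10, multiplier = 8,
          enriched_fraction = 0.2, coupling = 0.8, seed = 7))
grid <- tile_windows(g)                      # 1 Mb windows
track_a <- enrichment_ratio(count_peaks_in_windows(sim$peaks_a, grid))
track_b <- enrichment_ratio(count_peaks_in_windows(sim$peaks_b, grid))
sum(track_a$flag)                            # 40 of 200 windows above 1.5-fold
window_correlation(track_a, track_b, n_permutations = 10000, seed = 8)
#> Window correlation (spearman on ratio): r = 0.3952 over 200 windows
#> Permutation p = 9.999e-05 (10000 permutations, seed 8)

cobound(sim$peaks_a, sim$peaks_b)
#> Peak overlap (min 1 bp):
#>   A: 4929 peaks, 208 co-bound, 4721 unique
#>   B: 4853 peaks, 210 co-bound, 4643 unique
#>   co-bound regions (merged): 206
```

The planted truth behind these numbers: a ring of contrast 4 starting at
75% of the radius (recovered as 3.905 with 10% noise), and 20% of windows
enriched 8-fold with 80% of enriched windows shared between the factors —
the correlation is called at the smallest p the permutation scheme can
produce. Window tracks, profiles and summaries all write to TSV/bedGraph;
a command-line wrapper (`inst/exec/periscope`) exposes the same pipelines
as `simulate-nuclei`, `simulate-peaks`, `profile`, `windows`, `overlap`,
`annotate` and `tss-profile` subcommands with explicit `--seed` everywhere.

See `vignettes/periscope-methods.Rmd` for the model, parameter and
validation details.

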