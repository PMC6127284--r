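# dendrawave

Quantification of dendritic receptor transport from photoconversion
pulse-chase microscopy, plus the 3D surface-puncta, nanodomain and
colocalization measurements used on super-resolution dendrite volumes, and
locus-enrichment statistics for differentially expressed (DE) gene lists.

The package is aimed at neuroscience labs measuring intracellular cargo
trafficking in cultured neurons: a photoconvertible tag (e.g. Dendra2 fused
to the NMDA-receptor subunit GluN1) is switched inside a region of interest
(ROI) on a dendrite, and the converted pool is imaged every 15 s for 3 min.
Dendrites are divided into 5-µm arc-length bins around the ROI and each
bin's fluorescence F(b, t) is doubly normalised,

    value(b, t) = [F(b, t) / A(b)] / [F(0, 0) / A(0)],

so that bin zero at time zero equals 1 and the matrix is gain-invariant.
Two per-neuron velocity estimators summarise the resulting wave:

* **crest velocity** `v = b / t_peak` from the 10- and 15-µm bins (time to
  peak fluorescence) — the slow, bulk receptor pool (≈ 0.2 µm/s in control
  neurons);
* **leading-edge velocity** `v = b / t_appear` from the 25–40-µm bins, where
  appearance is the first of two consecutive frames above
  `baseline + 3·sigma` — the fast, vesicular pool (≈ 0.82 µm/s).

A paired test across neurons (`classify_populations()`) asks whether the two
estimators describe distinct kinematic classes. Because the assay's raw
microscopy is not publicly deposited, the package ships synthetic-data
generators with known ground truth (movies with a stationary / slow
advective-diffusive / fast advective particle mixture; two-channel 3D
volumes with planted puncta, nanodomain clusters and co-placement; gene
universes with planted locus enrichment) so every estimator is validated by
parameter recovery.

Also included: 3D puncta segmentation with watershed splitting and
dendrite-normalised metrics, nanodomain detection and single-linkage cluster
profiling, Pearson/Manders colocalization, the group statistics used for
such panels (paired-by-timepoint t tests, ANOVA + Bonferroni,
Kruskal–Wallis + Dunn, two-way ANOVA), and hypergeometric plus permutation
locus enrichment.

## Worked example

```r
library(dendrawave)

# simulate one pulse-chase movie under the packaged control ("empty vector")
# conditions: v_slow = 0.2, v_fast = 0.82 um/s, 15-s frames for 3 min
cfg <- read_sim_config(system.file("extdata", "empty_vector.yaml",
                                   package = "dendrawave"))
cfg$seed <- 7L
sim <- simulate_pulse_chase(cfg)
sim$movie
#> Pulse-chase movie: 500 x 30 px, 13 frames (0..180 s every 15 s), 0.2 um/px

# full wave analysis: 5-um bins, 120-s window, off-cell background
wave <- pulse_wave(sim$movie, sim_trace(cfg), window = 120,
                   background = sim_background_mask(cfg))
peak_velocity(wave)
#> Crest (time-to-peak) velocity (distal): 0.211 um/s from 2 bin(s)
#>  bin t_peak  velocity excluded reason
#>   10     45 0.2222222    FALSE
#>   15     75 0.2000000    FALSE

# across 20 neurons the two estimators separate into two kinematic classes
waves <- simulate_wave_set(20, cfg)
classify_populations(velocity_table(waves))
#> Population summary: 2 kinematic class(es) (paired t = 18.1, p = 1.97e-13, n = 20)
#>   slow (crest):        0.207 +/- 0.002 um/s
#>   fast (leading edge): 0.867 +/- 0.036 um/s
```

The single-neuron bin velocities are quantised by the 15-s frame grid
(10 µm / 45 s = 0.222); the across-neuron means are the assay's readout and
sit within a few percent of the configured 0.2 and 0.82 µm/s.

Enrichment of a DE list in disease-associated loci, at the scale of a
22,753-gene universe with 1,256 DE genes and 108 loci covering 348 genes:

```r
tr <- make_enrichment_universe(seed = 1)   # planted fold 1.7
locus_enrichment(tr$universe, tr$de_genes, tr$loci,
                 n_permutations = 1000, seed = 1)
#> Gene-level enrichment: 36 of 348 target genes DE (expected 19.2; universe 22753, DE 1256)
#>   hypergeometric P(X >= 36) = 0.000229
#> Locus-level: 31 of 108 loci contain a DE gene (null mean 17.6)
#>   permutation p = 0.002 (1000 draws, seed 1)
```

The 3D pipeline mirrors isosurface-style puncta analysis:
`segment_puncta()` (Otsu threshold, 26-connectivity, watershed splitting),
`puncta_metrics()` (density / total volume / mean punctum volume per µm³ of
dendrite), `detect_nanodomains()` + `cluster_nanodomains()` (nanodomains per
cluster), and `coloc()` (Pearson r, Manders M1/M2 within the dendrite mask).

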