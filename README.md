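# tmabquant

Label-based relative quantification of endogenous peptides measured by
multiplex TMAB isotopic labeling, for peptidomics studies that use
intracellular peptide levels as a read-out of proteasome activity (for
example, comparing striatal cells expressing normal- and expanded-polyQ
huntingtin, or cells treated with proteasome inhibitors).

Up to five samples are labeled with TMAB isotopologues (D0/D3/D6/D9/D12),
pooled, and measured in one LC-MS run. A peptide with `n` labels at
charge `z` appears as a *peak group*: co-eluting isotope clusters, one
per tag channel, spaced by `n * Δm(tag pair) / z` — where the D9→D12 step
(3 × (¹³C−¹²C) = 3.0101 Da per label) differs from the deuterium steps
(3 × (²H−¹H) = 3.0188 Da) by 8.8 mDa. The package implements, as tested
tidyverse-style functions:

* **chemistry** — label counting on peptides (free N-terminus + Lys,
  unless acetylated), exact per-tag-pair mass shifts, theoretical m/z
  under the fixed-charge convention (`z ≥ n_labels`);
* **synthetic data** — a proteome/degradome generator with controlled
  cleavage-site P1 preferences, condition effects applied to
  proteasome-product peptides only, and rendered multiplex MS1 centroid
  peak lists with complete ground truth;
* **peak detection** — greedy deisotoping with an isotope-envelope
  plausibility ceiling, multiplex peak-group search, and overlap /
  coincidence flagging;
* **quantification** — per-replicate ratios against the within-run mean
  of reference channels, capped to the 5:1 signal-to-noise dynamic range
  [0.20, 5.0], form merging, per-condition mean ± SD with Student's
  t-tests, fold-change categories (decrease ≤ 0.80 / no change /
  increase ≥ 1.25) and heat-map bins;
* **cleavage analysis** — protein-coordinate mapping (internal peptides
  count two cleavages, terminal fragments one), P1 residue extraction,
  and category-wise frequency tables with hydrophobic / basic / acidic
  class summaries;
* **reporting** — rank-order plots, replicate-level heat maps, and an
  end-to-end `run_pipeline()` that writes every table as TSV plus a
  manifest.

## Worked example

```r
library(tmabquant)
library(dplyr)

s      <- simulate_study(n_proteins = 8, seed = 42)   # 4 runs, 5-plex TMAB
cl     <- detect_isotope_clusters(s$peaks)
groups <- flag_overlap(
  find_peak_groups(cl, s$scheme, identifications = s$identifications), cl)
quant  <- quantify_study(groups, s$scheme, s$identifications,
                         reference = "Q7Q7")
quant
#> TMAB quantification: 47 peptides, 172 peak groups, reference = Q7Q7
glance(quant)
#> # A tibble: 1 × 6
#>   n_peptides n_ratio_records n_conditions prop_decrease prop_no_change ...
#> 1         47             625            3         0.881          0.119
tidy(quant) |> filter(condition != "Q7Q7") |> head(2)
#>   sequence              condition     n mean_ratio sd_ratio   p_value stars
#> 1 CNIMEHLPSGAWIMKCANEAM Q111Q111      5      0.406   0.0481 0.0000425 ***
#> 2 CNIMEHLPSGAWIMKCANEAM Q7Q111        4      0.335   0.0805 0.000105  ***
#>   category heat_bin
#>   decrease bright_green
#>   decrease bright_green
```

The simulated design suppresses proteasome-product peptides to 0.35 of
reference levels in both polyQ-like conditions; the summary shows 88% of
condition summaries classified as decreased, with per-peptide means near
0.35 (`mean_ratio` 0.41 and 0.34 above) and significance stars from the
t-test against reference self-ratios. Cleavage-site analysis of the same
object recovers the generator's hydrophobic P1 preference:

```r
clv <- analyze_cleavage(quant, s$proteome)
clv$freq |> filter(category == "decrease") |>
  group_by(residue_class) |> summarise(prop = sum(prop))
#>   residue_class   prop
#> 1 acidic        0.0296
#> 2 basic         0.0217
#> 3 hydrophobic   0.662
#> 4 other         0.287
```

Decreased peptides carry hydrophobic P1 residues at ~66% of cleavage
sites, matching the generating weight of 0.65 — the package's synthetic
echo of chymotrypsin-like proteasome specificity.

`autoplot(quant)` draws the rank-order summary plot;
`plot_heatmap(heatmap_matrix(quant$merged, "Q7Q7"))` draws the
replicate-level heat map. `run_pipeline(pipeline_config(out_dir))` runs
everything and writes TSVs, plots and a manifest.

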