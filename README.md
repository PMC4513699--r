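# epigrad

Fluorescence intensity gradient signatures of stratified squamous epithelium.

## The problem

Histological grading of cervical intraepithelial neoplasia (CIN) from H&E
sections is subjective: it rests on judging how far immature basal-type
cells have expanded through the epithelial thickness, and inter-observer
agreement is poor, especially between normal tissue and CIN I. Eosin is a
fluorescein derivative whose protein complexes fluoresce, so an ordinary
H&E section imaged under fluorescent illumination carries quantitative
information: in normal epithelium, cytoplasmic fluorescence rises steadily
as keratinocytes mature from the basal layer to the surface; in CIN I the
rise is blunted; in CIN III it is nearly absent.

`epigrad` turns that observation into a number. For each straight line drawn
from the basement membrane to the epithelial surface on a single-channel
grayscale image:

1. the intensity profile along the line is sampled (bilinear interpolation,
   default 1 px spacing) and split into three equidistant segments —
   lower, middle, upper thirds, mirroring the CIN grading convention;
2. each segment *k* is reduced to the mean `m_k` of its values at or above
   the nearest-rank 89th percentile (the top decile), which excludes
   non-fluorescent dark objects — nuclei and glycogen-rich cytoplasm;
3. an ordinary least-squares line is fitted through
   `(1, m_1), (2, m_2), (3, m_3)`; with this abscissa the raw slope is
   `(m_3 − m_1) / 2` in gray-value units per segment step;
4. the means are normalized to the basal segment (`m_1 ≡ 1`), giving the
   **normalized slope** `(m_3 − m_1) / (2 m_1)` — dimensionless, invariant
   to staining intensity, exposure time and section thickness.

Per-line slopes are averaged per sample (>20 lines each), per-sample means
are averaged per histology group and reported as mean ± SEM, and groups are
compared with one-way ANOVA + Tukey HSD; the same class measured at two
institutions is compared with a t-test. The per-class mean normalized
slopes act as signatures — reference values around 0.37 (Normal), 0.19
(CIN I) and 0.02 (CIN III) — against which `classify_sample()` places a new
sample by nearest distance.

Because real slide sets are not redistributable, the package ships a
calibrated phantom generator (`generate_phantom()`, `generate_cohort()`):
synthetic epithelium images with a known ground-truth gradient, dark
nuclei/glycogen objects, multiplicative noise and institution-style global
scale factors, so the full pipeline is testable end to end.

## Worked example

Generate a small Normal-preset cohort, score it at the 89th-percentile
threshold, and summarise:

```r
library(epigrad)
d <- file.path(tempdir(), "demo")
generate_cohort("normal_siuh", n_samples = 3, base_seed = 1, out_dir = d)
sc <- score_cohort_dir(d, q = 89)
sc$samples
#>         sample_id  group n_lines excluded_lines mean_raw_slope mean_normalized_slope cohort
#> 1 normal_siuh_s01 Normal      24              0           3326                0.4154   SIUH
#> 2 normal_siuh_s02 Normal      24              0           3357                0.4111   SIUH
#> 3 normal_siuh_s03 Normal      24              0           3255                0.3817   SIUH
group_summary(sc$samples)
#>    group n_samples  mean    sem
#> 1 Normal         3 0.403 0.0106
```

Each row is one phantom slide: 24 basal-to-surface lines were scored and
averaged. The normalized slopes near 0.4 say intensity grows by roughly 40%
of the basal level per epithelial third — a normal maturation gradient
(this 3-sample cohort drew slightly steep samples; the preset's true value
is 0.37). One line in detail:

```r
anns <- read_annotations(file.path(d, "annotations.json"))
img  <- read_gray_image(file.path(d, "normal_siuh_s01.tif"))
r <- score_line(sample_line(img, anns[[1]]), q = 89)
round(r$filtered_means, 1)
#> [1]  8109.2 11322.0 14778.1
r
#> slope_result: raw 3334, normalized 0.4112 (q = 89, valid)
classify_sample(mean(sc$samples$mean_normalized_slope))$label
#> [1] "Normal"
```

The same pipeline runs from a shell via the installed CLI script:

```sh
cli=$(Rscript -e 'cat(system.file("cli", "epigrad", package = "epigrad"))')
Rscript "$cli" simulate --preset cin1_siuh --n 18 --seed 1 --out cohort/
Rscript "$cli" score --images cohort/ --out scored/ --threshold-q 89
Rscript "$cli" cohort --samples scored/samples.csv --out report/
```

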