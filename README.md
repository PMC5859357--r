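# hcmecg — computational ECG phenotyping for hypertrophic cardiomyopathy

Hypertrophic cardiomyopathy (HCM) is a genetic heart-muscle disease whose
main catastrophic outcome, sudden cardiac death from ventricular arrhythmia,
is hard to predict from clinical variables alone. The 12-lead ECG carries a
rich electrophysiological signature — QRS morphology reflects the
depolarization sequence, T-wave polarity the repolarization dynamics — but
conventional single-feature readings ("deep S in V4", "T-wave inversion")
have not stratified risk reliably. `hcmecg` implements a complete,
tested analysis pipeline that phenotypes HCM patients from multi-lead
digital ECG by unsupervised machine learning, and characterises the
resulting subgroups against the 2014 ESC HCM Risk-SCD score.

The pipeline, intended for methodologists and cardiology researchers
working with digital Holter ECG:

1. **Synthetic cohort generator** — labelled 8-lead (I, II, V1–V6) beat
   trains at 1,000 Hz for four morphological archetypes (normal QRS with
   inverted lateral T waves; normal QRS with upright T; short-R/deep-S in
   V4; left-axis deviation with short R and long S in V4–V6), with
   per-subject morphology jitter, baseline wander, 50 Hz mains interference,
   broadband noise, and matched clinical covariates. Ground-truth fiducials
   and labels make every downstream stage testable without any data
   download.
2. **Beat preprocessing** — zero-phase 45 Hz low-pass Butterworth, 50 Hz
   notch, cubic-spline baseline removal; R detection and delineation; the
   20 beats with maximal ST–T signal-to-noise; Woody iterative alignment;
   ensemble averaging.
3. **Hermite QRS morphology** — each lead's averaged QRS is projected onto
   an orthonormal basis of Hermite functions
   φₙ(t;σ) = Hₙ(t/σ)·exp(−t²/2σ²)/√(σ·2ⁿn!·√π), with the width σ
   grid-optimised to maximise the recovered energy fraction
   ‖x̂‖²/‖x‖². Three functions recover ≥ 98 % of the QRS energy in normal
   morphology; four are used for HCM.
4. **Biomarkers** — per-lead Q/R/S durations, amplitudes and slopes, QRS
   axis from net I/aVF areas, pathological-Q rule, signed T amplitudes,
   T-wave inversion (≥ 2 contiguous inverted leads in V3–V6), T axis,
   Tpeak–Tend, ST displacement, Bazett QTc/JTc.
5. **Phenotype clustering** — multi-cluster feature selection (MCFS:
   graph-Laplacian eigenvectors + L1-regularised regression, 7 features),
   Laplacian-eigenmap embedding to 2-D, DBSCAN with min_pts = ⌊n/25⌋ and an
   automatic eps rule, plus a k-means cross-check (adjusted Rand index).
6. **Cohort statistics** — normality-screened group comparisons (t/ANOVA or
   Mann–Whitney/Kruskal–Wallis; χ²/Fisher), Bonferroni-adjusted post-hoc
   pairs, and the HCM Risk-SCD score
   risk = 1 − 0.998^exp(PI) with its low (< 4 %), intermediate (4–6 %) and
   high (≥ 6 %) categories.

## Worked example

The analysis itself is the numbered scripts under `analysis/`:

```sh
Rscript analysis/01_simulate_cohort.R     # 85 subjects, mixture 20/24/19/22
Rscript analysis/02_extract_features.R    # preprocessing + Hermite + biomarkers
Rscript analysis/03_phenotype_clustering.R
Rscript analysis/04_group_statistics.R
```

Step 3 prints, for the default cohort (seed 1):

```
[qrs_only] 3 clusters, 1 noise subjects, ARI vs ground truth 1.000, k-means cross-check ARI 1.000
[qrs_plus_t] 4 clusters, 2 noise subjects, ARI vs ground truth 1.000, k-means cross-check ARI 1.000
  selected features: hermite_II_c0, hermite_II_c2, hermite_II_c3, hermite_V3_c0, hermite_V4_c0, hermite_V4_c2, hermite_V2_c1
```

QRS morphology alone resolves the three depolarization phenotypes (the two
normal-QRS archetypes merge); adding the T-wave biomarkers splits the
normal-QRS group by T-wave inversion into four phenotypes, with both label
sets matching the generator's ground truth (adjusted Rand index 1.0) and
confirmed by k-means. Step 4 then prints the median 5-year HCM Risk-SCD
score per cluster:

```
Median HCM Risk-SCD score by cluster:
   1    2    3    4
2.14 2.67 2.74 3.59
```

Cluster 4 is the inverted-T/normal-QRS phenotype: the subgroup with primary
repolarization abnormality carries the highest median risk score (3.59 %
vs 2.14–2.74 % for the others), reproducing the qualitative clinical
finding that primary T-wave inversion — not inversion secondary to
depolarization abnormalities — marks the higher-risk phenotype.

## Layout

```
R/                  package implementation (generator, preprocessing,
                    Hermite morphology, biomarkers, clustering, statistics)
analysis/           numbered workflow drivers (the analysis itself)
scripts/acceptance.R
tests/testthat/     unit, property and acceptance suites
vignettes/          methods vignette (model, assumptions, design choices)
inst/extdata/       HCM Risk-SCD coefficient config (published values)
```
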