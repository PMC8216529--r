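# musclenet

Functional muscle-network analysis and classification of chronic neck pain
(CNP) from surface EMG recorded during gait.

People with chronic neck pain show altered coordination of the neck muscles.
One way to quantify this is to record surface EMG from the
sternocleidomastoid (SCM), splenius capitis (SC) and upper trapezius (UT)
bilaterally while subjects walk along straight (rectilinear) and circular
(curvilinear) paths, and to ask two questions:

1. **Connectivity** — how strongly are the muscles functionally coupled?
   Intermuscular magnitude-squared coherence (MSC)

   MSC(f) = |Pxy(f)|² / (Pxx(f) · Pyy(f)) ∈ [0, 1]

   measures frequency-domain coupling between two EMG channels.  Band-wise
   MSC over delta (1–4 Hz), theta (4–8), alpha (8–12), beta (12–25) and
   high-beta (25–30 Hz) becomes the edge weight of a six-node *functional
   muscle network*, whose topology is summarized by node **strength**
   (Σⱼ Wᵢⱼ) and normalized **betweenness centrality** after proportional
   thresholding.
2. **Discrimination** — do spectrotemporal EMG features (MAV, RMS, VAR, WL,
   SSI; MNF, MDF, PKF, MNP, TTP, computed per 500-ms window) plus the MSC
   features separate CNP from control subjects?  Neighbourhood component
   analysis (NCA) learns per-feature relevance weights, and K-NN (k = 5,
   Euclidean), LDA and RBF-kernel SVM are evaluated under stratified
   five-fold cross-validation, reporting accuracy, sensitivity and
   specificity from the pooled confusion matrix.

Because no public recordings exist for this protocol, the package ships a
**synthetic EMG cohort generator** with analytically known coherence: each
channel mixes band-limited shared drives and independent noises so that the
population band MSC of a pair is exactly the product of the configured
shared-power fractions, modulated by a periodic gait envelope.  The default
cohort plants the study's qualitative findings (weaker delta-band
connectivity and stronger SCM activity in CNP subjects during curvilinear
gait only), so every pipeline stage can be validated against ground truth.

## Worked example

```r
library(musclenet)

params   <- cohort_params(n_per_group = 10, duration_s = 6, n_trials = 2, seed = 42)
cohort   <- simulate_cohort(params)
prep     <- preprocess_cohort(cohort)        # band-pass + notch + normalize
features <- build_feature_table(prep)        # 40 rows x 96 feature columns

group_network_analysis(prep, "delta", task = "curvilinear", metric = "strength")
#> Network comparison: strength, curvilinear task, band delta, density 0.50
#>   CNP      0.427 +/- 0.060 (n = 10)
#>   control  0.812 +/- 0.101 (n = 10)
#>   t = -10.365, df = 18, p = 5.127e-09

cross_validate(features, svm_rbf_classifier(), cv_config(seed = 42),
               task = "curvilinear",
               select = list(method = "nca", k = 16, refit = TRUE))
#> SVM | task curvilinear | features nca_top16 (positive class: CNP)
#>   TP 10  FN 0  FP 0  TN 10
#>   accuracy 100.00%  sensitivity 100.00%  specificity 100.00%
```

The network comparison shows the planted delta-band effect: the synthetic
CNP group's mean node strength (0.43) is far below the controls' (0.81)
during curvilinear gait, and a pooled t-test flags the difference.  The
cross-validated SVM on the 16 NCA-selected features separates the groups
perfectly on this cohort — the planted effect is deliberately strong; on
the rectilinear task, where no effect is planted, the same pipeline stays
at chance.

The full pipeline (cohort on disk, features, networks, NCA sweep,
classification grid) also runs from the command line:

```sh
Rscript inst/scripts/musclenet all --out run1 --seed 1
```

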