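# honeyprint

Chemometric verification of honey label claims — botanical variety and
country of origin — from multielement mass-fraction fingerprints
(mg element / kg honey, as produced by ED-XRF or ICP-based quantification
of the panel Al, P, Cl, K, Ca, Fe, Zn, Mn, Rb, Br).

It is written for food-authenticity and control-laboratory work, where the
question is not "which class does this honey resemble most?" but "is the
label *consistent* with an authentic reference population?". The package
therefore follows the SIMCA one-class philosophy:

* **One PCA model per variety–country class** (five or more reference
  honeys), fitted by NIPALS with unit-variance scaling. Non-detects below
  the ~0.1 mg/kg detection limit stay missing — they are skipped by the
  algorithm, never imputed as zeros. Uninformative elements are removed by
  an iterative loading-plot procedure.
* **Membership by distance to model.** An observation's residual standard
  deviation `s_i = sqrt(RSS_i/(K-A))`, normalised by the pooled training
  residual `s0`, gives DModX; the class rejects the sample at significance
  `alpha` when DModX exceeds
  `Dcrit = sqrt(F_{1-alpha}(K-A, (N-A-A0)(K-A)))`.
* **Pairwise PLS-DA contests** (PLS1 against a 0/1 class coding, decision
  cut 0.5) whenever a competing class also accepts the sample; classes with
  as few as three reference honeys can take part in contests.
* **A verdict per sample**: `consistent`, `consistent_resolved_by_plsda`,
  `inconsistent_rejected`, `reassigned`, or `ambiguous`, with the full
  evidence trail, plus sensitivity/specificity reporting for model
  libraries.
* **Precision statistics** for the supporting reproducibility protocol: a
  days × replicates one-way ANOVA giving a reproducibility % per element
  and honey, and pairwise Welch t-tests between honeys.
* **A seeded synthetic-data generator** that emulates the published
  per-class element ranges, sample sizes, detection limit, film-blank
  offsets and measurement noise, so the whole pipeline is testable without
  deposited measurements.

## Worked example

```r
library(honeyprint)

study <- sample_study(default_study_spec(), seed = 42, min_n = 5)
lib   <- build_model_library(study)
print(lib)
#> <model_library> 11 PCA models; 11 classes usable for PLS-DA
#>   chestnut:Italy           N= 5 K=7 A=3 R2X(cum)=0.851 Q2X(cum)=-168445.666
#>   lavender:France          N= 5 K=5 A=3 R2X(cum)=0.981 Q2X(cum)=-0.320
#>   ...
#>   robinia:Hungary          N=11 K=5 A=3 R2X(cum)=0.965 Q2X(cum)= 0.446
#>   rosemary:Spain           N= 7 K=5 A=3 R2X(cum)=0.960 Q2X(cum)= 0.335
```

Each line is one reference class: `N` training honeys, `K` elements
surviving variable selection, `A` components, cumulative explained
variation `R2X` and cross-validated `Q2X`. High `R2X` with small `N` is
expected; `Q2X` of five-row classes is numerically wild (element-wise
cross-validation has almost nothing to hold out) and serves only as a
warning sign, not for model selection.

Verifying fresh labelled samples:

```r
vspec <- default_study_spec()
vspec$classes <- lapply(vspec$classes, function(cl) { cl$n_default <- 1L; cl })
val <- sample_study(vspec, seed = 43)

verify_claim(ft_rows(val, "chestnut:Italy-001"), "chestnut:Italy", lib)
#> <cascade_verdict> sample chestnut:Italy-001, claim chestnut:Italy -> consistent
#>   - claimed model chestnut:Italy accepts the sample
#>   - no competing model accepts the sample

verify_claim(ft_rows(val, "lavender:Spain-001"), "lavender:Spain", lib)
#> <cascade_verdict> sample lavender:Spain-001, claim lavender:Spain -> consistent_resolved_by_plsda
#>   - claimed model lavender:Spain accepts the sample
#>   - PLS-DA lavender:Spain vs lime:Romania: predicted lavender:Spain (score 0.063)
#>   - PLS-DA lavender:Spain vs rosemary:Spain: predicted lavender:Spain (score -0.015)
```

The chestnut honey needs no arbitration: no other class accepts it. The
lavender sample is also accepted by two competing models, so the claim is
put head-to-head with each competitor through pairwise PLS-DA and wins both
contests (scores below 0.5 favour the first class of the pair, the claim).

Real data come in through `read_fingerprint_table()` (CSV with columns
`sample_id, botanical_variety, country` and the element panel; `"n.d."` or
empty cells mark non-detects), with optional film-blank and recovery
corrections (`blank_correct()`, `bias_correct()`) as a reporting path —
modelling deliberately runs on uncorrected values.

## Analysis workflow

The `analysis/` scripts run the study end to end, writing tables under
`results/`:

1. `01_simulate_study.R` — draw the 17-class synthetic study, apply the
   five-sample rule.
2. `02_reproducibility.R` — triplicate × three-day precision protocol on
   four honeys; reproducibility % per element and pairwise t-tests.
3. `03_fit_class_models.R` — the one-class model library with variable
   selection, DModX training screen and Q2X.
4. `04_plsda_pairs.R` — discriminant models for the overlapping pairs.
5. `05_verify_labels.R` — cascade verdicts for a fresh one-per-class draw
   and sensitivity/specificity of the library.

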