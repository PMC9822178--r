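# dstsent

Dempster–Shafer fusion of three-class sentiment classifiers, with the
epidemiological statistics used in two-period social-media surveillance
studies of mental health (health infodemiology).

## The problem

Short social-media posts about a health condition (the motivating case:
tweets mentioning *insomnia* posted in calendar 2019 vs calendar 2020) can
be scored for sentiment — negative, neutral, positive — by several
pretrained classifiers at once. Individual classifiers disagree, and no
single one is reliable across all three classes. `dstsent` combines their
probability outputs with Dempster–Shafer theory (DST), evaluates single and
fused classifiers, and then runs the downstream epidemiological analysis:
how sentiment shares shifted between two study periods, and whether
negative posts cluster after midnight.

## The model

**Evidence fusion.** Let Θ = {negative, neutral, positive} be the frame of
discernment. Each classifier's probability vector *p* is embedded as a
basic belief assignment (BBA) *m* with singleton focal elements,
*m*({c}) = δ·*p*<sub>c</sub> and *m*(Θ) = 1 − δ for a reliability discount
δ ∈ (0, 1]. BBAs satisfy *m*(∅) = 0 and Σ<sub>η⊆Θ</sub> *m*(η) = 1. The
belief function is bel(ζ) = Σ<sub>∅≠η⊆ζ</sub> *m*(η). Two BBAs combine by
Dempster's orthogonal sum,

    (m1 ⊕ m2)(ϑ) = Σ_{η∩ζ=ϑ} m1(η)·m2(ζ) / (1 − K),
    K = Σ_{η∩ζ=∅} m1(η)·m2(ζ),

where the conflict *K* is the product mass lost to empty intersections;
*K* ≥ 1 is surfaced as an error, never silently renormalised. Fused labels
are the singleton of maximal belief (canonical-order tie-break, flagged).

**Epidemiological layer.** Period and clock-bucket contrasts are 2×2 odds
ratios OR = (a·d)/(b·c) with Wald intervals
exp(ln OR ± 1.96·√(1/a+1/b+1/c+1/d)), Pearson chi-square tests (no
continuity correction, χ² = z²), and exact chi-square power from the
noncentral distribution with λ = n·w².

**Synthetic corpora.** A seeded simulator generates tweet-like records with
configurable per-period sentiment prevalences and an after-midnight
negative-odds multiplier that is *exactly* the estimand of the temporal
analysis, plus mock classifiers defined by 3×3 confusion matrices — so the
entire pipeline runs and is tested with no external data or model weights.

## Worked example

```r
library(dstsent)

# fuse two classifier outputs for one post
m1 <- bba_from_probs(c(0.60, 0.30, 0.10))
m2 <- bba_from_probs(c(0.50, 0.30, 0.20))
combine_bba(m1, m2, sources = c("model1", "model2"))
#> <dst_combination> of model1 + model2 (conflict K = 0.5900)
#> <bba> focal elements:
#>   m({negative}) = 0.731707
#>   m({neutral}) = 0.219512
#>   m({positive}) = 0.048780
```

The two models agree only through their shared mass on each singleton;
59% of the joint mass fell on contradictory pairs and was renormalised
away. The fused decision is `decide(...)` → `"negative"`.

```r
# period contrast on published-scale counts: 91,242 of 165,760 peripandemic
# and 65,164 of 139,561 prepandemic posts were negative
print(odds_ratio(two_by_two(91242, 74518, 65164, 74397)), mode = "truncate")
#> OR 1.39 (95% CI 1.37-1.41), z = 45.94, p < .001

# minimum annotation sample for a chi-square design (w = .3, df = 5)
chisq_power_sample_size(w = 0.3, alpha = 0.05, power = 0.80, df = 5)
#> [1] 143

# simulate a study-shaped corpus and recover the injected temporal effect
cfg <- default_study_profile(seed = 42)
ta  <- temporal_negative_analysis(simulate_corpus(cfg))
ta$overall
#> OR 1.46 (95% CI 1.40-1.53), z = 16.26, p < .001
```

The recovered after-midnight odds ratio (1.46) sits on the generator's
configured multiplier of 1.43, inside its Wald interval.

A command-line wrapper with the same functionality is installed at
`exec/dstsent` (subcommands `simulate`, `filter`, `preprocess`, `classify`,
`fuse`, `evaluate`, `epi`, `power`); every run writes a JSON manifest with
config hash, seed and input checksums.

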