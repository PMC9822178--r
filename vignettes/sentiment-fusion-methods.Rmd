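---
title: "Belief-function fusion of sentiment classifiers and two-period epidemiological contrasts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Belief-function fusion of sentiment classifiers and two-period epidemiological contrasts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dstsent)
```

## Scope and design

`dstsent` implements a complete pipeline for surveillance-style sentiment
analysis of short social-media posts: corpus I/O and inclusion filtering,
text cleaning, a uniform classifier contract, Dempster–Shafer (DST)
fusion of multiple classifiers' probability outputs, evaluation of single
and fused classifiers, and the epidemiological statistics of a two-period
before/after design. A seeded simulator generates corpora and classifier
ensembles with known parameters, so every stage is exercised and tested
without external data or pretrained model weights. Pretrained models are
reachable only through an adapter slot (a user function returning a
probability triple); their internals are deliberately out of scope.

## The fusion model

### Frames, mass functions, belief

The frame of discernment is fixed at Θ = {negative, neutral, positive}. A
basic belief assignment (BBA) maps each of the 8 subsets of Θ to a mass,
with m(∅) = 0 and total mass 1; subsets with positive mass are focal
elements. Belief is the total committed support,
bel(ζ) = Σ_{∅≠η⊆ζ} m(η). Masses are stored over the explicit 8-element
powerset indexed by bitmask. This trades generality for transparency: the
combination rule is a literal 8×8 intersection table, easy to audit and to
test against an independent enumeration written with set operations. A
general-frame implementation is a non-goal.

### From probabilities to evidence

Classifiers emit probability triples, not belief functions, and there is
no canonical embedding. We use singleton focal elements with an optional
uniform discount: m({c}) = δ·p_c, m(Θ) = 1 − δ. Two reasons. First, with
δ = 1 Dempster's rule on singleton BBAs reduces to the normalised
elementwise product of the probability triples — a well-understood product
rule whose closed form doubles as an independent test oracle. Second, the
discount gives a principled dial for model unreliability: δ → 0 sends a
classifier's evidence to the vacuous BBA m(Θ) = 1, the identity element of
combination, so an untrusted model can be down-weighted continuously
without being removed.

### Combination, conflict, decision

Dempster's orthogonal sum multiplies masses over intersecting focal
elements and renormalises by 1 − K, where the conflict K is the product
mass falling on empty intersections. Numerical choices:

* **Total conflict is an error.** When K ≥ 1 − 1e-12 (e.g. two
  contradictory point masses), combination aborts with an error naming the
  sources. Silent renormalisation near total conflict amplifies noise
  without bound; the batch fusion layer (`fuse_probs`) catches the error
  per record, marks the record `conflicted`, and excludes it from accuracy
  denominators while reporting its count.
* **Decision rule** is the singleton with maximal belief (for singleton
  BBAs, equivalently maximal mass). Ties — exact to 1e-12 — are broken in
  canonical order (negative, neutral, positive) and flagged, so downstream
  consumers can quantify how often the rule actually bit.
* **Order invariance.** The n-ary fold inherits commutativity and
  associativity from the pairwise rule; the test suite verifies
  permutation invariance at tolerance 1e-9, which bounds the floating-point
  drift of refactorings.

## Text cleaning

Cleaning applies, in a fixed order: URL stripping, @mention stripping,
leading retweet-marker ("RT") removal, hashtag-sigil removal (keeping the
word, since tokens like `#exhausted` carry the sentiment; a strict flag
drops whole tokens), emoji/emoticon removal, restriction to letters,
digits and sentence punctuation, and whitespace collapsing. URL stripping
precedes punctuation stripping so URL fragments cannot survive. The
retweet-marker strip is re-applied once after whitespace collapsing: an
emoticon or sigil removal can expose a leading "RT" that the earlier pass
could not see, and the re-application keeps cleaning idempotent — an
invariant the property tests rely on. The exact character classes are a
declared convention of this package, not a reconstruction of any
particular study's unpublished preprocessing.

Keyword inclusion matches the cleaned, lower-cased text at word
boundaries: `insomnia` matches `#insomnia` (after sigil removal) but not
`insomniac`. Word-boundary matching is the conservative reading of
"contains the word"; substring matching would silently widen the cohort.

## Time handling

Study periods are half-open calendar-year windows
[2019-01-01, 2020-01-01) and [2020-01-01, 2021-01-01): the boundary
instant belongs to the later window only, which resolves the otherwise
ambiguous shared endpoint deterministically. The clock buckets split the
day into before-midnight (local hours 13–23) and after-midnight (hours
0–12). Hour 0 is assigned to after-midnight: the verbal spans "1 PM to
midnight" and "1 AM to noon" leave it unassigned, and posts between
midnight and 1 AM are literally after midnight. All timestamps are UTC; a
fixed offset parameter exists because post-level time zones are typically
unavailable, and no per-user localisation is attempted.

## The statistical layer

Odds ratios are computed in closed form from 2×2 tables. For a binary
exposure this is identical to the univariate logistic-regression estimate,
without an optimizer in the loop. The Wald interval
exp(ln OR ± z·SE), SE = √(1/a+1/b+1/c+1/d), is used throughout; on
published-scale counts (hundreds of thousands of posts) the Wald, score
and exact intervals agree to the displayed precision. Zero cells raise an
error; an explicit Haldane flag adds 0.5 to every cell — never silently.
Two display conventions are provided (`format_ratio`): rounding (default)
and truncation toward zero, the latter matching reports that drop rather
than round trailing digits. Chi-square tests are Pearson without
continuity correction, so χ² equals the squared pooled two-proportion z —
an identity the tests assert. No multiple-testing adjustment is applied;
raw p-values are reported.

Power calculations use the exact noncentral chi-square distribution:
power(n) = P(χ²_df(λ = n·w²) > critical value at α). The minimum sample
size is found by integer bisection and is minimal by construction (power
at n − 1 falls below target). For w = 0.3, α = .05, power .80, df = 5 this
gives n = 143.

## The simulator

The simulator is first-class, tested code, and its defaults are the study
conditions the rest of the package is validated under
(`default_study_profile()`):

* 13,956 prepandemic and 16,576 peripandemic records — one tenth of the
  motivating study's corpus, keeping a full pipeline run around a second
  while leaving binomial standard errors small (≈0.4% on a share);
* per-period sentiment prevalences (negative, neutral, positive) of
  (0.467, 0.285, 0.248) and (0.550, 0.283, 0.167);
* an after-midnight negative odds multiplier of 1.43;
* five mock classifiers with symmetric confusion accuracies
  (0.803, 0.527, 0.530, 0.493, 0.453) at Dirichlet concentration 20.

The temporal effect is injected as an odds tilt on the hour distribution
of negative posts: after-midnight hour weights are multiplied by the
configured factor for negative records only. Because the hour distribution
given sentiment is period-independent, the generating multiplier equals
the population after-vs-before-midnight odds ratio for negative posts both
within each period and pooled — the generating parameter is exactly the
estimand, so parameter-recovery tests are unambiguous. Baseline hour
weights default to uniform; any 24-vector is accepted.

Mock classifiers draw a predicted tendency from the confusion-matrix row
of the record's gold label, then a probability triple from a Dirichlet
centred on that tendency (α = concentration on the tendency, 1
elsewhere). Concentration 20 gives sharp but non-degenerate outputs
(typical winning mass ≈ 0.9); as concentration → ∞ outputs approach point
masses, and the empirical argmax confusion converges to the parameter
confusion (verified at 10,000 draws with 3σ binomial bands). Draws are
conditionally independent across models given gold labels, each model on
its own derived stream; everything flows from one master seed through a
pinned Mersenne-Twister generator, so corpora are byte-identical across
runs and platforms.

Texts are assembled from a sentiment-keyed template lexicon and salted
with URLs, hashtags, mentions and emoji so the cleaning stage has real
work to do; every text embeds the inclusion keyword. What the simulator
does *not* emulate: natural language variety (templates, not fluent text),
user-level clustering and repeat posting, platform metadata, diurnal
posting rhythms beyond the configured hour weights, and real classifier
error correlation (mocks are conditionally independent given the gold
label, which flatters fusion relative to correlated real models).
Passing tests therefore demonstrate the correctness of the machinery and
the recoverability of known parameters — not classifier performance on
real language.

## What fusion can and cannot gain

For conditionally independent classifiers with identical symmetric
confusion (accuracy a > 1/3), the singleton product rule behaves like a
soft majority vote and the fused accuracy exceeds each individual's —
asserted at n = 5,000 with a 3σ binomial margin. With heterogeneous
ensembles the picture changes: a sharp but uninformative partner (uniform
confusion, high concentration) multiplies in gold-independent evidence and
*degrades* the product rule, which is precisely the situation the
reliability discount exists for — at δ → 0 the partner's evidence becomes
vacuous and fused decisions provably coincide with the better model's
(tested exactly). Accuracy-weighted discounting of real ensembles is left
to the user; the package exposes per-model discounts.

## Problem sizes and test design

The default test run simulates corpora of up to 50,000 records for
law-of-large-numbers checks, uses 1,000 random BBA pairs against the
brute-force powerset oracle (tolerance 1e-9), and 200 seeded replicates of
the default profile for coverage of the temporal odds multiplier and the
peripandemic negative prevalence (nominal 95% Wald coverage, asserted at
≥93% to leave Monte-Carlo room). Undefined evaluation ratios
(zero denominators in one-vs-rest metrics, κ with unit expected
agreement) are reported as flagged `NA`, never coerced to 0 — degenerate
inputs should look degenerate downstream.

## Known limitations

* The frame is fixed at three classes; other label spaces need a different
  mass representation.
* Only Dempster's rule is provided (no Yager or PCR5 variants) and only
  belief-maximising decisions; plausibility and pignistic alternatives are
  out of scope.
* Language filtering trusts a metadata field; no language detection is
  embedded.
* The Wald interval can undercover for small cells; the package targets
  surveillance-scale counts where this is immaterial, and errors rather
  than corrects zero cells unless told otherwise.
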