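---
title: "Methods: seed-window love scoring and lagged time-series inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: seed-window love scoring and lagged time-series inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amorchron)
```

## The measurement model

`amorchron` operationalizes the salience of romantic love in a play as
the contrast between two bag-of-words constructs counted *near* love
seed words. The pipeline assumes that how often tender-feeling words
(tenderness, affection, fondness, ...) versus passionate-feeling words
(passion, desire, jealousy, ...) appear in the immediate context of
"love", "lover", "beloved" and "loving" tracks which conception of love
a text foregrounds. The per-play score is

$$\text{romantic\_love} = Z(\text{freq tenderness}) - Z(\text{freq passion}),$$

with frequencies equal to near-seed counts divided by the play's
content-token total (nouns + adjectives + verbs), and $Z$ the z-score
(sample standard deviation) across the included corpus. The score is a
*salience* contrast, not a sentiment: it says which register dominates
the spatial context of love, not whether love is discussed approvingly.

### The window definition

The counting window is ±3 positions around each seed occurrence,
measured on the **noun/adjective subsequence** of the content tokens,
with seed occurrences retained as anchors regardless of their tagged
part of speech. The seed itself is excluded from its own window; edge
windows truncate; a token covered by two overlapping windows counts
once per window. This domain was chosen because the construct is about
which *qualities and objects* surround love talk — verbs mostly carry
narrative mechanics — and because seeds include verbal forms that must
still anchor windows. Both decisions are configurable
(`rawTokenWindows`, `uniquePositions`) for sensitivity analysis, and
the scorer and the candidate extractor share one window implementation
so the lexicon is built on exactly the statistic later counted. Seed
lemmas are removed from category lists when a `Lexicon` is constructed,
so one seed inside another seed's window is never counted as content.

### Inclusion rules

Two filters precede inference. Step A drops plays missing any required
category — all ten by default, or only the tender/passion pair
(`mode = "tender_passion"`) for sparser corpora where requiring all ten
would discard most plays. Z-scores are computed across step-A survivors
(the default; a `zBeforeFilter` flag standardizes before filtering, for
order-sensitivity checks). Step B removes outliers with
$|z(\text{romantic\_love})| > 3$; scores are *not* re-standardized
afterwards, keeping them on the pre-removal scale so the two samples
stay comparable. With fewer than three step-A survivors the corpus is
rejected outright.

A degenerate case worth noting: if a category's frequency is constant
across the z-scoring basis, its z-scores are defined as 0 (no signal)
rather than NaN.

## Text preprocessing

Normalization lowercases, expands contractions from a shipped editable
table that includes early-modern forms (e'en → even, 'tis → it is,
o'er → over), resolves elision patterns ('d → ed, 'n → en,
'st → est), strips possessive 's, and deletes all non-letter symbols.
The function is idempotent, which makes cached intermediates safe.

Part-of-speech tagging and lemmatization are rule-based: an exception
table for frequent or tricky words (including -ly nouns and adjectives
such as *family* and *holy* that a suffix rule would misread as
adverbs), suffix heuristics otherwise, a closed-class word list that is
dropped, and a lemmatizer handling plurals, gemination (running → run)
and silent-e restoration (loving → love). The tagger is deliberately
simple and fully deterministic; its tables ship as plain text and its
behaviour is pinned by snapshot tests, so edits are visible. On Early
Modern spelling it is necessarily noisy — the scoring model is a
bag-of-words over curated lemmas, which tolerates tagging noise that is
uncorrelated with the year of composition. A French variant (elision
table, French closed-class list, lighter suffix rules) uses the same
contract.

## Lexicon curation

Candidates are the most frequent nouns/adjectives within seed windows
(`extractCandidates`, top 1000 by default, ties alphabetical). To audit
semantic adequacy, embeddings are trained on the corpus itself:
positive pointwise mutual information over a ±5-token co-occurrence
window, factorized by truncated SVD to 100 dimensions (defaults;
`minCount = 5`). This count-based construction answers nearest-
neighbour queries like a predictive embedding but is exactly
deterministic — a property the audit workflow relies on. For each
lexicon word the 10 nearest neighbours are written to a report; a human
reviewer flags each neighbour as consistent or not with the intended
category, and a word is retained only when **more than 5 of 10**
neighbours are consistent (strict majority; `applyRetentionRule`). The
judgment stays human and recorded — the package stores flags, never
infers them.

The shipped default lexicon carries three illustrative words per
category and is labelled incomplete: real analyses should load full
curated lists from JSON. Category disjointness is enforced on load.

## Validation

*Internal*: maximum-likelihood factor analysis (`factanal`, varimax)
over the ten standardized category frequencies, expecting
emotional-investment categories (tenderness, discipline, moral and
mental qualities, long relationships) and desire categories (passion,
sensuality, physical qualities, body parts, short relationships) on
orthogonal factors. *External*: whole-text (not seed-windowed)
dictionary frequencies from user-supplied category lists, combined as
z-differences — friends-to-sexual, family-to-sexual, future-to-present.
The z-difference form was chosen for symmetry with the main measure; a
raw quotient is available by configuration. Proprietary dictionaries
are not bundled; any category word list in the same format works.

## Inference

**Mixed models.** `fitLoveLMM` fits
`response ~ predictors + (1 | author)` by REML with standardized
predictors, so coefficients are standardized effect sizes comparable
across predictors; Satterthwaite degrees of freedom give Wald 95% CIs.
When the author grouping is degenerate (fewer than two authors with two
or more plays) the model falls back to a flagged fixed-intercept
regression. An optional Box-Cox step shifts the signed response to
positivity (x → x − min + 1), profiles λ on [−2, 2], and applies the
transform only when the 95% profile CI excludes 1 — a conservative rule
that avoids needless transformation of already-Gaussian scores.

**Annual aggregation** is the unweighted mean of included plays per
year (a length-weighted mean is available); years without plays stay
missing and are dropped listwise from time-series fits. Rolling means
are centered 3-year windows shrinking at the edges.

**Cross-correlation** reports Pearson correlations of aligned segments
with the convention that positive lag k means the first series leads by
k years, with a 1.96/√n white-noise band per lag.

**Lagged regression.** The full model is
`love(T) ~ year + predictor(T + k)` for every k in [−20, 20]
(41 terms at step 1; step 2 gives the 21-term even-lag variant; step 5
with offsets 0–4 serves predictors interpolated from 5-yearly
observations, the winning offset chosen by final BIC). Backward
elimination removes the lag term whose deletion most lowers the BIC,
never removing year, with ties resolved toward the smaller model; the
BIC matches `stats::BIC` on the equivalent `lm` fit exactly, and the
selection path reproduces `step(..., k = log(n))`. The selected model
is refit by `nlme::gls` with `corAR1` errors indexed by year;
coefficients, t statistics on residual degrees of freedom, and the
fitted ρ are reported. Zero-variance lag columns are dropped with a
warning (a constant predictor thus yields a year-only model), while
rank-deficient grids — step-1 grids over interpolated series — raise an
error directing the user to the 5-year grid.

## Synthetic study conditions

The corpus generator emulates exactly the structure the estimators
assume: plays of negative-binomial length (mean 2000 content tokens)
from 60 authors over 1550–1800, seed tokens at 8 per 1000 tokens,
Poisson category emission inside seed windows (0.5 expected
tender/passion tokens per window, 0.25 for the eight validation
categories), author intercepts of SD 0.5 on the log rate, two latent
play-level factors with loading 0.7 driving the category blocks, Zipf
filler vocabulary, and optional coupling of the tender rate to a
standardized economy at a known lag. Guard blocks of noun/adjective
filler isolate adjacent seed windows, so the emitted counts are exactly
what the window scan must find — an integer identity the tests assert.
Economy series are AR(1) (φ = 0.6, innovation SD 1) plus linear trend
(0.02/year); demographic series couple nuptiality positively (0.5) and
births-per-marriage negatively (−0.5) to love six years earlier. What
the generator does **not** emulate: real Early Modern language, spelling
variation, genre drift, censorship-era gaps, or any dependence between
author identity and year — so passing recovery tests certify the
statistical machinery, not robustness to philological noise.

Problem sizes in the tests and the acceptance script (200 random
window fixtures; a 200-play corpus for score algebra; 20 factor
replicates at n = 800; 100 mixed-model replicates at 800 plays / 120
authors; 50 lag-recovery replicates per coupling lag at 251 years; 100
null replicates; 50 demographic replicates) were chosen to make
Monte-Carlo rates stable at the stated thresholds while keeping a full
run in the low minutes on one core.

## Known limitations

* **Post-selection inference.** Backward BIC selection over 41
  correlated lag terms retains at least one spurious term in most runs
  on independent autocorrelated series, and the GLS-AR(1) refit — which
  corrects the error model, not the selection — leaves many of those
  significant at p < 0.05. The package therefore treats a single
  selected lag's p-value as descriptive; claims of temporal precedence
  should rest on the pattern across predictors and on the
  cross-correlation structure, not on one post-selection test. The null
  calibration test in the acceptance suite documents this honestly
  rather than papering over it.
* Sample-standard-deviation z-scores are not exactly invariant under
  duplicating the corpus (the divisor shifts from n−1 to 2n−1); ranks
  are invariant and values agree to well under 2% at realistic corpus
  sizes.
* The rule-based tagger is weaker than a statistical tagger on genuine
  Early Modern text; corpora that ship pre-lemmatized text can bypass
  it by constructing `TokenizedPlay` objects directly.
* GLS t statistics use residual degrees of freedom (N − p); other df
  conventions exist and are not derivable from first principles here.
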