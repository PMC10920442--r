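# amorchron

Measuring the cultural salience of romantic — tender versus passionate —
love in historical theatre corpora, and relating its trajectory to
annual living-standards and demographic series.

## The problem and the method

Cultural historians have documented a rise in the importance of mutual
affection and emotional attachment in Early Modern Europe. `amorchron`
implements a quantitative pipeline for tracking that shift in play
texts:

1. **Seed-window scoring.** Category words are counted only when they
   occur near love-related *seed* lemmas (`love`, `lover`, `beloved`,
   `loving`), inside a window of ±3 noun/adjective positions around
   each seed occurrence. Ten curated categories are counted (passionate
   feelings, tender feelings, sensuality, discipline/asceticism,
   physical qualities, moral qualities, short relationships, long
   relationships, body parts, mental parts).
2. **The romantic-love score.** For each play,

   `romantic_love = Z(freq tenderness) − Z(freq passion)`

   where frequencies are near-seed counts over the play's content
   tokens (nouns, adjectives, verbs) and Z is the z-score across the
   included corpus. Plays missing a required category are excluded, and
   outliers (|z| > 3 of the score) are removed.
3. **Lexicon curation.** Candidate words are extracted as the most
   common nouns/adjectives near seeds; each lexicon word is audited
   against its 10 nearest neighbours in a corpus-trained embedding
   space (PPMI + truncated SVD), and kept only when a reviewer marks
   more than 5 of 10 neighbours consistent with the category concept.
4. **Validation.** Internal: a two-factor maximum-likelihood factor
   analysis over the ten category frequencies, checking that
   emotional-investment and desire categories load on orthogonal
   factors. External: whole-text dictionary ratios
   (friends-to-sexual, family-to-sexual, future-to-present) from
   user-supplied category word lists.
5. **Inference.** Mixed models with author as a random intercept and
   standardized predictors; cross-correlation between annual series;
   and lagged regression: `love(T) ~ Year + predictor(T+k)` for every
   lag `k ∈ [−20, +20]`, pruned backward by BIC (Year always kept),
   with the selected model refit by generalized least squares under
   AR(1) errors indexed by year. Five-yearly interpolated predictors
   use a 5-year lag grid with offset starting points. A
   birth-to-marriage ratio (birth rate / nuptial rate) supports the
   demographic analyses.
6. **Synthetic data.** Generators for corpora (Poisson category
   emission in seed windows, author random effects, two latent factors,
   optional coupling of the tender rate to an economy at a known lag),
   AR(1)+trend economies, and demographic series coupled to love at a
   known lag — each with a recorded ground truth, so every estimator is
   tested by parameter recovery.

## Worked example

```r
library(amorchron)

# a synthetic corpus whose tender emission rate follows the economy
# nine years earlier
econ <- generateEconomy(economySpec(), seed = 7)
spec <- corpusSpec(nPlays = 1500, nAuthors = 150,
                   coupling = list(b = 0.3, lag = 9))
corp <- generateCorpus(spec, economy = econ, seed = 8)

scores <- scoreCorpus(corp$tokens, defaultLexicon(), corp$metadata,
                      mode = "tender_passion")
scores
#> PlayScoreSet: 1500 plays x 10 categories
#>   included: 1197  excluded: 303 ( 279 missing-category, 24 outlier )
#>   romantic_love range: -4.025 .. 3.973

love <- annualizeScores(scores)
fit <- lagRegression(love, econ)
fit
#> LagRegressionResult for predictor 'econ'
#>   selected lags: -9, -4
#>   BIC = 332.8  AR(1) rho = 0.036  offset = 0  n = 201
#>    term lag estimate    se     t        p  ci_lo ci_hi
#> 1  year  NA   -0.086 0.059 -1.45 1.50e-01 -0.203 0.031
#> 2 lagm9  -9    0.407 0.047  8.58 2.80e-15  0.313 0.501
#> 3 lagm4  -4    0.140 0.053  2.66 8.57e-03  0.036 0.244
```

The dominant selected lag −9 says the economy value nine years *before*
a year's plays predicts that year's romantic-love score — the
generator's planted coupling — with a standardized coefficient of about
0.41 after the GLS-AR(1) refit. The weaker term at −4 is an echo of the
economy's own autocorrelation, and the year term absorbs the secular
trend. (Output shown is what this code prints with these seeds.)

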