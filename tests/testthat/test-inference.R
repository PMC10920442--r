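make_two_factor_table <- function(n = 400, loading = 0.7, seed = 1) {
  set.seed(seed)
  emo <- c("tender_feelings", "discipline_asceticism", "moral_qualities",
           "long_relationships", "mental_parts")
  des <- c("passionate_feelings", "sensuality", "physical_qualities",
           "short_relationships", "body_parts")
  L <- matrix(0, 10, 2, dimnames = list(c(emo, des), NULL))
  L[emo, 1] <- loading
  L[des, 2] <- loading
  F <- matrix(rnorm(n * 2), n, 2)
  E <- matrix(rnorm(n * 10, 0, sqrt(1 - loading^2)), n, 10)
  X <- F %*% t(L) + E
  colnames(X) <- rownames(L)
  list(X = X, L = L, emo = emo, des = des)
}

test_that("factor analysis recovers a planted orthogonal two-factor structure", {
  tf <- make_two_factor_table(n = 600, seed = 4)
  fs <- factorAnalysisCategories(tf$X)
  dominant <- apply(abs(fs$loadings), 1, which.max)
  # same factor within each block, different between blocks
  expect_length(unique(dominant[tf$emo]), 1)
  expect_length(unique(dominant[tf$des]), 1)
  expect_false(dominant[tf$emo][1] == dominant[tf$des][1])
  cong <- tuckerCongruence(tf$L, fs$loadings[rownames(tf$L), ])
  expect_true(all(cong > 0.95))
  expect_true(all(fs$communalities >= 0 & fs$communalities <= 1))
})

test_that("near-duplicate categories load on the same factor", {
  tf <- make_two_factor_table(n = 500, seed = 8)
  X <- tf$X
  X[, "body_parts"] <- X[, "sensuality"] + rnorm(nrow(X), 0, 0.15)
  fs <- factorAnalysisCategories(X)
  dom <- apply(abs(fs$loadings), 1, which.max)
  expect_identical(dom[["body_parts"]], dom[["sensuality"]])
  expect_error(factorAnalysisCategories(tf$X, nFactors = 10), "smaller")
})

test_that("factor loadings are invariant to row shuffling", {
  tf <- make_two_factor_table(n = 300, seed = 12)
  fs1 <- factorAnalysisCategories(tf$X)
  set.seed(1)
  fs2 <- factorAnalysisCategories(tf$X[sample(nrow(tf$X)), ])
  cong <- tuckerCongruence(fs1$loadings, fs2$loadings)
  expect_true(all(cong > 0.999))
})

test_that("LMM with zero author variance matches ordinary regression", {
  d <- simulateScorePanel(nPlays = 400, nAuthors = 400, authorSd = 0,
                          seed = 2)
  d$author <- d$play_id  # every author singleton: degenerate by design
  expect_warning(fit <- fitLoveLMM(d, "romantic_love", "wages"),
                 "degenerate")
  ols <- lm(romantic_love ~ scale(wages), data = d)
  expect_equal(fit$fixedEffects$estimate, unname(coef(ols)[2]),
               tolerance = 1e-6)
  expect_identical(fit$authorSd, 0)
  # non-degenerate panel: estimated author variance near zero when none simulated
  d2 <- simulateScorePanel(nPlays = 600, nAuthors = 60, authorSd = 0,
                           seed = 3)
  fit2 <- fitLoveLMM(d2, "romantic_love", "wages")
  expect_lt(fit2$authorSd, 0.1)
})

test_that("LMM coefficients are equivariant under response scaling", {
  d <- simulateScorePanel(nPlays = 500, nAuthors = 50, seed = 5)
  f1 <- fitLoveLMM(d, "romantic_love", "wages")
  d$romantic_love <- 2 * d$romantic_love
  f2 <- fitLoveLMM(d, "romantic_love", "wages")
  expect_equal(f2$fixedEffects$estimate, 2 * f1$fixedEffects$estimate,
               tolerance = 1e-6)
  expect_equal(f2$fixedEffects$t, f1$fixedEffects$t, tolerance = 1e-5)
  expect_true(all(f1$fixedEffects$ci_lo <= f1$fixedEffects$estimate &
                  f1$fixedEffects$estimate <= f1$fixedEffects$ci_hi))
})

test_that("box-cox transform is skipped when lambda CI covers 1", {
  d <- simulateScorePanel(nPlays = 500, nAuthors = 50, seed = 6)
  f <- fitLoveLMM(d, "romantic_love", "wages", boxcox = TRUE)
  expect_false(f$boxcox$applied)   # response already gaussian
  # heavily skewed response triggers a transform
  d$romantic_love <- exp(d$romantic_love)
  f2 <- fitLoveLMM(d, "romantic_love", "wages", boxcox = TRUE)
  expect_true(f2$boxcox$applied)
})

test_that("annualization averages included plays and rolling means shrink at edges", {
  tab <- data.frame(year = c(1600, 1600, 1601), romantic_love = c(1, 3, 2),
                    included = TRUE, n_content_tokens = c(10, 10, 10))
  s <- annualizeScores(tab)
  expect_identical(seriesYears(s), c(1600L, 1601L))
  expect_equal(seriesValues(s), c(2, 2))
  const <- AnnualSeries("c", 1700:1710, rep(5, 11))
  expect_equal(seriesValues(rollingMean(const)), rep(5, 11))
  spike <- AnnualSeries("s", 1:3, c(0, 3, 0))
  expect_equal(seriesValues(rollingMean(spike)), c(1.5, 1, 1.5))
})

test_that("cross-correlation peaks at the construction lag with the stated sign convention", {
  ec <- generateEconomy(economySpec(phi = 0.8, trendSlope = 0), seed = 9)
  x <- ec
  yy <- seriesYears(x) + 5
  y <- AnnualSeries("y", yy, seriesValues(x))  # y(t) = x(t - 5): x leads by 5
  cc <- crossCorrelation(x, y, maxLag = 10)
  expect_identical(cc$lags[which.max(cc$r)], 5L)
  expect_equal(max(cc$r), 1, tolerance = 1e-12)
  neg <- AnnualSeries("neg", seriesYears(x), -seriesValues(x))
  cc2 <- crossCorrelation(x, neg, maxLag = 3)
  expect_equal(cc2$r[cc2$lags == 0], -1, tolerance = 1e-12)
  expect_warning(crossCorrelation(x, AnnualSeries("z", 1550:1560, 1:11),
                                  maxLag = 20), "overlap")
})

test_that("independent white-noise series stay inside the 95% band at most lags", {
  set.seed(14)
  hits <- total <- 0
  for (i in 1:10) {
    x <- AnnualSeries("x", 1:250, rnorm(250))
    y <- AnnualSeries("y", 1:250, rnorm(250))
    cc <- crossCorrelation(x, y, maxLag = 10)
    hits <- hits + sum(abs(cc$r) > cc$band)
    total <- total + length(cc$r)
  }
  expect_lt(hits / total, 0.12)   # nominal 5%, generous margin
})

test_that("constant predictors leave a year-only model", {
  ec <- generateEconomy(economySpec(), seed = 16)
  lv <- generateCoupledLove(ec, lag = 9, seed = 17)
  const <- AnnualSeries("const", seriesYears(ec),
                        rep(1, length(seriesYears(ec))))
  expect_warning(r0 <- lagRegression(lv, const), "zero-variance")
  expect_length(selectedLags(r0), 0)
  expect_true("year" %in% r0@selected$term)
  # noise with no structure: every lag pruned
  set.seed(18)
  flat <- AnnualSeries("flat", seriesYears(ec),
                       rnorm(length(seriesYears(ec)), 0, 1e-6))
  r <- lagRegression(lv, flat, lagMin = -5, lagMax = 5)
  expect_length(selectedLags(r), 0)
  expect_true("year" %in% r@selected$term)
})

test_that("lag selection is invariant to affine rescaling of the predictor", {
  ec <- generateEconomy(economySpec(), seed = 20)
  lv <- generateCoupledLove(ec, lag = 5, seed = 21)
  r1 <- lagRegression(lv, ec, lagMin = -10, lagMax = 10)
  ec2 <- AnnualSeries("econ_scaled", seriesYears(ec),
                      3.7 * seriesValues(ec) - 42)
  r2 <- lagRegression(lv, ec2, lagMin = -10, lagMax = 10)
  expect_identical(selectedLags(r1), selectedLags(r2))
  expect_equal(r1@selected$t, r2@selected$t, tolerance = 1e-6)
})

test_that("the BIC trace is monotone non-increasing and matches stats::BIC", {
  ec <- generateEconomy(economySpec(), seed = 23)
  lv <- generateCoupledLove(ec, lag = 3, seed = 24)
  r <- lagRegression(lv, ec, lagMin = -4, lagMax = 4)
  expect_true(all(diff(r@trace$bic) <= 1e-8))
  expect_lte(r@bic, min(r@trace$bic) + 1e-8)
  # independent check of the full-model BIC against stats::BIC on lm
  yrs <- seriesYears(lv)
  lags <- -4:4
  D <- vapply(lags, function(k)
    seriesValues(ec)[match(yrs + k, seriesYears(ec))],
    numeric(length(yrs)))
  ok <- stats::complete.cases(D)
  df <- data.frame(y = seriesValues(lv)[ok],
                   year = as.numeric(scale(yrs[ok])), scale(D[ok, ]))
  full <- lm(y ~ ., data = df)
  expect_equal(r@trace$bic[1], BIC(full), tolerance = 1e-6)
})

test_that("GLS with rho fixed at zero reproduces ordinary least squares", {
  ec <- generateEconomy(economySpec(), seed = 26)
  lv <- generateCoupledLove(ec, lag = 2, seed = 27)
  yrs <- seriesYears(lv)
  d <- data.frame(y = seriesValues(lv), year = yrs,
                  x = seriesValues(ec)[match(yrs, seriesYears(ec))])
  d <- d[stats::complete.cases(d), ]
  g <- nlme::gls(y ~ year + x, data = d,
                 correlation = nlme::corAR1(0, form = ~ year, fixed = TRUE))
  o <- lm(y ~ year + x, data = d)
  expect_equal(coef(g), coef(o), tolerance = 1e-8)
})

test_that("five-year grids with offsets recover a lag off the base grid", {
  ec <- generateEconomy(economySpec(phi = 0.4), seed = 29)
  lv <- generateCoupledLove(ec, lag = 7, coef = 0.8, noiseSd = 0.5,
                            seed = 30)
  r <- lagRegression(lv, ec, gridStep = 5, offsets = 0:4)
  expect_identical(r@offset, 3L)           # -7 = 3 - 2*5 lies on the offset-3 grid
  expect_true(-7L %in% selectedLags(r))
  expect_gt(r@selected$estimate[r@selected$lag %in% -7], 0)
})

test_that("birth-to-marriage ratio divides on the overlap and validates input", {
  b <- AnnualSeries("birth", 1700:1705, rep(30, 6))
  m <- AnnualSeries("nuptial", 1703:1708, rep(10, 6))
  r <- birthToMarriage(b, m)
  expect_identical(seriesYears(r), 1703:1705)
  expect_equal(seriesValues(r), rep(3, 3))
  expect_equal(seriesValues(birthToMarriage(b, b)), rep(1, 6))
  m2 <- AnnualSeries("nuptial", 1700:1705, c(10, 10, 0, 10, 10, 10))
  expect_error(birthToMarriage(b, m2), "1702")
  expect_warning(r2 <- birthToMarriage(b, AnnualSeries("n", 1800:1801, 1:2)),
                 "no overlapping")
  expect_length(r2, 0)
})

test_that("play-level correlation report recovers perfect linear pairings", {
  tab <- data.frame(play_id = paste0("p", 1:50), year = 1601:1650,
                    romantic_love = seq(0, 1, length.out = 50),
                    included = TRUE, n_content_tokens = 100)
  up <- AnnualSeries("up", 1601:1650, 2 * (1601:1650) - 5)
  down <- AnnualSeries("down", 1601:1650, -(1601:1650))
  rep1 <- corrReport(tab, list(up = up, down = down))
  expect_equal(rep1$r, c(1, -1), tolerance = 1e-12)
  expect_identical(rep1$n, c(50L, 50L))
})
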