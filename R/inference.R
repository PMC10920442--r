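# Inference: internal validation by factor analysis, mixed models with
# author as random factor, annual aggregation, cross-correlation, lagged
# regression with backward BIC selection and a GLS-AR(1) refit, and the
# birth-to-marriage ratio.

#' Maximum-likelihood factor analysis of the ten category frequencies
#'
#' Standardizes the columns internally, extracts `nFactors` factors by
#' maximum likelihood and applies the requested rotation. Deterministic
#' given the input.
#'
#' @param freqTable numeric matrix or data.frame, plays x categories
#'   (step-A included plays).
#' @param nFactors number of factors (default 2).
#' @param rotation rotation name passed to [stats::factanal()].
#' @return list of class `FactorSolution`: `loadings` (categories x
#'   factors), `uniquenesses`, `communalities`, `rotation`, `nFactors`,
#'   and the likelihood-ratio `fitStatistics`.
#' @export
factorAnalysisCategories <- function(freqTable, nFactors = 2L,
                                     rotation = "varimax") {
  X <- as.matrix(freqTable)
  if (nFactors >= ncol(X))
    stop("nFactors must be smaller than the number of categories")
  X <- scale(X)
  fa <- factanal(X, factors = nFactors, rotation = rotation)
  L <- unclass(fa$loadings)
  structure(list(
    loadings = L,
    uniquenesses = fa$uniquenesses,
    communalities = 1 - fa$uniquenesses,
    rotation = rotation, nFactors = nFactors,
    fitStatistics = list(statistic = unname(fa$STATISTIC),
                         dof = unname(fa$dof), pvalue = unname(fa$PVALUE))),
    class = "FactorSolution")
}

#' @export
print.FactorSolution <- function(x, ...) {
  cat("FactorSolution:", x$nFactors, "factors,", x$rotation, "rotation\n")
  print(round(x$loadings, 3))
  invisible(x)
}

#' Tucker congruence between two loading matrices
#'
#' Columns of `B` are matched to columns of `A` by maximal absolute
#' congruence (sign-invariant).
#'
#' @param A,B loading matrices with equal row count.
#' @return numeric vector: congruence of each column of `A` with its
#'   best-matching column of `B`.
#' @export
tuckerCongruence <- function(A, B) {
  phi <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  vapply(seq_len(ncol(A)), function(j) {
    max(vapply(seq_len(ncol(B)), function(k)
      abs(phi(A[, j], B[, k])), numeric(1)))
  }, numeric(1))
}

# Box-Cox transform with positivity shift; identity when the
# profile-likelihood CI for lambda covers 1.
boxcox_response <- function(y, X) {
  shift <- if (min(y) <= 0) -min(y) + 1 else 0
  ys <- y + shift
  bcd <- data.frame(.ys = ys, X)
  bc <- MASS::boxcox(.ys ~ ., data = bcd, lambda = seq(-2, 2, 0.05),
                     plotit = FALSE)
  lmax <- max(bc$y)
  ci <- range(bc$x[bc$y > lmax - qchisq(0.95, 1) / 2])
  lambda <- bc$x[which.max(bc$y)]
  if (ci[1] <= 1 && ci[2] >= 1) {
    list(y = y, lambda = 1, shift = 0, applied = FALSE)
  } else {
    yt <- if (abs(lambda) < 1e-8) log(ys) else (ys^lambda - 1) / lambda
    list(y = yt, lambda = lambda, shift = shift, applied = TRUE)
  }
}

#' Linear mixed model of play scores with author random intercept
#'
#' Fits `response ~ fixed terms + (1 | author)` by REML. Fixed-term
#' predictors are standardized (mean 0, sd 1) before fitting so the
#' coefficients are standardized effect sizes; Wald 95% confidence
#' intervals use Satterthwaite denominator degrees of freedom. If fewer
#' than two authors contribute two or more plays the random effect is
#' degenerate and an ordinary fixed-intercept regression is fitted
#' instead, flagged on the result.
#'
#' @param data data.frame holding the response, fixed-term columns and
#'   the grouping column.
#' @param response response column name.
#' @param fixed character vector of fixed-term column names.
#' @param random grouping column name (default `"author"`).
#' @param boxcox if `TRUE`, the response is shifted to positivity and a
#'   Box-Cox lambda is profiled; the transform is applied only when the
#'   95% CI for lambda excludes 1.
#' @param standardize standardize fixed predictors (default `TRUE`).
#' @return list of class `LmmResult`: `fixedEffects` (term, estimate,
#'   se, df, t, p, ci_lo, ci_hi), `authorSd`, `residSd`, `boxcox`,
#'   `degenerate`, `n`, and the underlying fit.
#' @export
fitLoveLMM <- function(data, response, fixed, random = "author",
                       boxcox = FALSE, standardize = TRUE) {
  d <- data[complete.cases(data[c(response, fixed, random)]),
            c(response, fixed, random)]
  y <- d[[response]]
  if (standardize)
    for (f in fixed) d[[f]] <- as.numeric(scale(d[[f]]))
  bc <- list(lambda = 1, shift = 0, applied = FALSE)
  if (boxcox) {
    bc <- boxcox_response(y, as.matrix(d[fixed]))
    y <- bc$y
    bc <- bc[c("lambda", "shift", "applied")]
  }
  d$.y <- y
  ngrp <- table(d[[random]])
  degenerate <- sum(ngrp >= 2) < 2
  if (degenerate) {
    warning("random effect degenerate (fewer than 2 authors with >= 2 plays); ",
            "fitting fixed-intercept model")
    fml <- stats::reformulate(fixed, response = ".y")
    fit <- lm(fml, data = d)
    sm <- summary(fit)$coefficients
    rows <- sm[fixed, , drop = FALSE]
    df <- fit$df.residual
    fe <- data.frame(term = fixed, estimate = rows[, 1], se = rows[, 2],
                     df = df, t = rows[, 3], p = rows[, 4])
    authorSd <- 0; residSd <- summary(fit)$sigma
  } else {
    fml <- stats::as.formula(paste(".y ~", paste(fixed, collapse = " + "),
                                   "+ (1 |", random, ")"))
    fit <- lmerTest::lmer(fml, data = d, REML = TRUE)
    sm <- as.data.frame(summary(fit)$coefficients)
    rows <- sm[fixed, , drop = FALSE]
    fe <- data.frame(term = fixed, estimate = rows[, "Estimate"],
                     se = rows[, "Std. Error"], df = rows[, "df"],
                     t = rows[, "t value"], p = rows[, "Pr(>|t|)"])
    vc <- as.data.frame(lme4::VarCorr(fit))
    authorSd <- vc$sdcor[vc$grp == random][1]
    residSd <- vc$sdcor[vc$grp == "Residual"][1]
  }
  crit <- qt(0.975, fe$df)
  fe$ci_lo <- fe$estimate - crit * fe$se
  fe$ci_hi <- fe$estimate + crit * fe$se
  rownames(fe) <- NULL
  structure(list(fixedEffects = fe, authorSd = authorSd, residSd = residSd,
                 boxcox = bc, degenerate = degenerate, n = nrow(d),
                 fit = fit),
            class = "LmmResult")
}

#' @export
print.LmmResult <- function(x, ...) {
  cat("LmmResult (n =", x$n,
      if (x$degenerate) ", degenerate random effect" else "", ")\n")
  print(transform(x$fixedEffects,
                  estimate = round(estimate, 3), se = round(se, 3),
                  df = round(df, 1), t = round(t, 2),
                  ci_lo = round(ci_lo, 3), ci_hi = round(ci_hi, 3),
                  p = signif(p, 3)))
  cat("author SD:", round(x$authorSd, 4),
      " residual SD:", round(x$residSd, 4), "\n")
  invisible(x)
}

#' Annual aggregation of play scores
#'
#' Unweighted mean of the romantic-love score over included plays per
#' year; years without included plays are absent from the series.
#'
#' @param scores a \linkS4class{PlayScoreSet} or a score table
#'   data.frame with `year`, `romantic_love`, `included`.
#' @param value column to aggregate (default `"romantic_love"`).
#' @param weightByLength if `TRUE`, plays are weighted by
#'   `n_content_tokens`.
#' @return an \linkS4class{AnnualSeries} named `"love"`.
#' @export
annualizeScores <- function(scores, value = "romantic_love",
                            weightByLength = FALSE) {
  d <- if (is(scores, "PlayScoreSet")) scoreTable(scores) else scores
  d <- d[d$included & is.finite(d[[value]]), , drop = FALSE]
  if (!nrow(d)) stop("no included plays to annualize")
  if (weightByLength) {
    agg <- aggregate(cbind(wv = d[[value]] * d$n_content_tokens,
                           w = d$n_content_tokens) ~ year, data = d, FUN = sum)
    vals <- agg$wv / agg$w
  } else {
    agg <- aggregate(d[[value]], by = list(year = d$year), FUN = mean)
    vals <- agg$x
  }
  o <- order(agg$year)
  AnnualSeries("love", agg$year[o], vals[o])
}

#' Centered rolling mean of an annual series
#'
#' Window shrinks at the edges (the first and last points average over
#' the available neighbours only).
#'
#' @param series an \linkS4class{AnnualSeries} (assumed on a contiguous
#'   or near-contiguous grid; the mean is taken over the `window`
#'   neighbouring points by index).
#' @param window odd window size (default 3).
#' @return an \linkS4class{AnnualSeries}.
#' @export
rollingMean <- function(series, window = 3L) {
  v <- seriesValues(series)
  n <- length(v)
  h <- (window - 1L) %/% 2L
  out <- vapply(seq_len(n), function(i)
    mean(v[max(1L, i - h):min(n, i + h)]), numeric(1))
  AnnualSeries(seriesName(series), seriesYears(series), out,
               seriesInterpolated(series))
}

#' Cross-correlation of two annual series
#'
#' Pearson correlation of the aligned overlapping segments at each lag.
#' Sign convention: a positive lag `k` means `x` leads `y` by `k` years,
#' i.e. `r[k] = cor(x(t), y(t + k))`.
#'
#' @param x,y \linkS4class{AnnualSeries}.
#' @param maxLag maximum |lag| (default 20).
#' @return list of class `CrossCorrelation`: `lags`, `r`, `n` (pairs per
#'   lag), `band` (approximate 95% white-noise significance bound per
#'   lag, `1.96/sqrt(n)`).
#' @export
crossCorrelation <- function(x, y, maxLag = 20L) {
  overlap <- length(intersect(seriesYears(x), seriesYears(y)))
  if (overlap < 3L * maxLag)
    warning("series overlap (", overlap, " years) is short relative to ",
            "maxLag = ", maxLag)
  lags <- seq(-maxLag, maxLag)
  r <- n <- numeric(length(lags))
  for (i in seq_along(lags)) {
    k <- lags[i]
    yrs <- intersect(seriesYears(x), seriesYears(y) - k)
    xi <- seriesValues(x)[match(yrs, seriesYears(x))]
    yi <- seriesValues(y)[match(yrs + k, seriesYears(y))]
    n[i] <- length(yrs)
    r[i] <- if (n[i] >= 3) cor(xi, yi) else NA_real_
  }
  structure(list(lags = lags, r = r, n = n,
                 band = ifelse(n > 0, 1.96 / sqrt(n), NA_real_),
                 names = c(seriesName(x), seriesName(y))),
            class = "CrossCorrelation")
}

#' @export
print.CrossCorrelation <- function(x, ...) {
  cat("CrossCorrelation", x$names[1], "->", x$names[2], ": lags",
      min(x$lags), "..", max(x$lags), "\n")
  best <- which.max(abs(x$r))
  cat("  max |r| =", round(x$r[best], 3), "at lag", x$lags[best],
      "(positive lag:", x$names[1], "leads)\n")
  invisible(x)
}

# Gaussian BIC from a least-squares fit; `ncoef` counts regression
# coefficients including the intercept (+1 inside for sigma), matching
# stats::BIC on the equivalent lm fit.
bic_ls <- function(rss, n, ncoef) {
  n * log(2 * pi) + n * log(rss / n) + n + log(n) * (ncoef + 1)
}

#' LagRegressionResult: selected lags, coefficients and AR(1) parameter
#'
#' @slot predictor predictor series name.
#' @slot candidateLags integer lags entered into the full model.
#' @slot trace data.frame of the backward-selection path (one row per
#'   visited model: offset, step, dropped term, BIC, number of lag
#'   terms).
#' @slot selected data.frame of final-model terms from the GLS-AR(1)
#'   refit: term, lag, estimate, se, t, p, ci_lo, ci_hi.
#' @slot rho fitted AR(1) parameter of the GLS refit.
#' @slot offset grid offset of the winning model.
#' @slot n observations in the final fit.
#' @slot dfResidual residual degrees of freedom of the final fit.
#' @slot bic BIC of the selected (least squares) model.
#' @exportClass LagRegressionResult
setClass("LagRegressionResult",
  representation(predictor = "character", candidateLags = "integer",
                 trace = "data.frame", selected = "data.frame",
                 rho = "numeric", offset = "integer", n = "integer",
                 dfResidual = "integer", bic = "numeric"))

setValidity("LagRegressionResult", function(object) {
  msg <- NULL
  if (!"year" %in% object@selected$term)
    msg <- c(msg, "selected model must contain the year term")
  if (nrow(object@trace) && object@bic > min(object@trace$bic) + 1e-8)
    msg <- c(msg, "selected BIC must not exceed any visited model's BIC")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "LagRegressionResult", function(object) {
  cat("LagRegressionResult for predictor '", object@predictor, "'\n",
      sep = "")
  sel <- object@selected$lag[object@selected$term != "year"]
  cat("  selected lags:", if (length(sel)) paste(sel, collapse = ", ")
      else "(none; year-only model)", "\n")
  cat("  BIC =", round(object@bic, 1), " AR(1) rho =",
      round(object@rho, 3), " offset =", object@offset,
      " n =", object@n, "\n")
  print(transform(object@selected,
                  estimate = round(estimate, 3), se = round(se, 3),
                  t = round(t, 2), p = signif(p, 3),
                  ci_lo = round(ci_lo, 3), ci_hi = round(ci_hi, 3)))
})

# backward BIC elimination over lag columns; year (column 2 of X after
# intercept) is never removed. Returns kept lag names + trace.
backward_bic <- function(X, y, lag_cols, offset) {
  n <- length(y)
  fit_rss <- function(cols) {
    f <- lm.fit(X[, cols, drop = FALSE], y)
    sum(f$residuals^2)
  }
  base_cols <- c("(Intercept)", "year")
  keep <- lag_cols
  cur_cols <- c(base_cols, keep)
  cur_bic <- bic_ls(fit_rss(cur_cols), n, length(cur_cols))
  trace <- data.frame(offset = offset, step = 0L, dropped = NA_character_,
                      bic = cur_bic, n_lag_terms = length(keep))
  step <- 0L
  while (length(keep)) {
    step <- step + 1L
    bics <- vapply(seq_along(keep), function(j) {
      cols <- c(base_cols, keep[-j])
      bic_ls(fit_rss(cols), n, length(cols))
    }, numeric(1))
    j <- which.min(bics)
    if (bics[j] <= cur_bic + 1e-10) {   # ties prefer the smaller model
      trace <- rbind(trace, data.frame(offset = offset, step = step,
                                       dropped = keep[j], bic = bics[j],
                                       n_lag_terms = length(keep) - 1L))
      cur_bic <- bics[j]
      keep <- keep[-j]
    } else break
  }
  list(keep = keep, bic = cur_bic, trace = trace)
}

#' Lagged regression with backward BIC selection and GLS-AR(1) refit
#'
#' Builds the full least-squares model `love(T) ~ year +
#' predictor(T + k)` for every lag `k` in the grid, removes lag terms
#' backward by BIC (the year term is never removed; ties prefer the
#' smaller model), and refits the selected model by generalized least
#' squares with first-order autoregressive errors indexed by year. For
#' predictors interpolated from 5-yearly observations, call with
#' `gridStep = 5` and `offsets = 0:4`: one selection is run per offset
#' grid and the offset whose final model has the lowest BIC wins; all
#' visited models appear in the trace.
#'
#' Predictor lag columns and year are standardized before fitting, so
#' coefficients are on a standardized-beta scale. Years in the response
#' with no predictor value at some required lag are dropped listwise;
#' the grid is trimmed (with a warning) when wider than the overlap.
#'
#' @param love response \linkS4class{AnnualSeries}.
#' @param predictor predictor \linkS4class{AnnualSeries}.
#' @param lagMin,lagMax lag grid bounds (default -20, +20; positive lags
#'   are predictor values after the response year).
#' @param gridStep lag grid step (default 1; use 5 for 5-yearly
#'   interpolated predictors, 2 for the even-lag variant).
#' @param offsets integer grid offsets (default 0).
#' @return a \linkS4class{LagRegressionResult}.
#' @export
lagRegression <- function(love, predictor, lagMin = -20L, lagMax = 20L,
                          gridStep = 1L, offsets = 0L) {
  best <- NULL
  all_trace <- list()
  for (off in as.integer(offsets)) {
    lags <- as.integer(off + seq(lagMin, lagMax, by = gridStep))
    lags <- lags[lags >= lagMin & lags <= lagMax]
    yrs <- seriesYears(love)
    cols <- lapply(lags, function(k)
      seriesValues(predictor)[match(yrs + k, seriesYears(predictor))])
    D <- do.call(cbind, cols)
    colnames(D) <- paste0("lag", ifelse(lags < 0, "m", "p"), abs(lags))
    ok <- complete.cases(D)
    if (sum(ok) < length(lags) + 3L) {
      # trim extreme lags until enough complete years remain
      warning("lag grid wider than the series overlap; trimming extreme lags")
      while (length(lags) > 1L && sum(ok) < length(lags) + 3L) {
        drop <- which.max(abs(lags))
        lags <- lags[-drop]; D <- D[, -drop, drop = FALSE]
        ok <- complete.cases(D)
      }
      if (sum(ok) < length(lags) + 3L)
        stop("series overlap too short for the lag grid")
    }
    d <- data.frame(y = seriesValues(love)[ok], year = yrs[ok])
    sds <- apply(D[ok, , drop = FALSE], 2, sd)
    if (any(!is.finite(sds) | sds == 0)) {
      warning("dropping zero-variance lag columns of '",
              seriesName(predictor), "'")
      keep_col <- is.finite(sds) & sds > 0
      lags <- lags[keep_col]
      D <- D[, keep_col, drop = FALSE]
    }
    Z <- scale(D[ok, , drop = FALSE])
    qrz <- qr(cbind(1, scale(d$year), Z))
    if (qrz$rank < ncol(Z) + 2L)
      stop("collinear lag columns (interpolated predictor at step ",
           gridStep, "?); use gridStep = 5 with offsets = 0:4")
    X <- cbind("(Intercept)" = 1, year = as.numeric(scale(d$year)), Z)
    sel <- backward_bic(X, d$y, colnames(Z), off)
    all_trace[[length(all_trace) + 1L]] <- sel$trace
    if (is.null(best) || sel$bic < best$bic)
      best <- list(bic = sel$bic, keep = sel$keep, off = off, d = d,
                   Z = Z, lags = lags)
  }
  trace <- do.call(rbind, all_trace)

  # GLS-AR(1) refit of the winning model
  d <- best$d
  keep <- best$keep
  lag_of <- function(nm) {
    s <- sub("^lag", "", nm)
    as.integer(ifelse(substr(s, 1, 1) == "m", -1, 1) *
               as.integer(sub("^[mp]", "", s)))
  }
  gd <- data.frame(.y = d$y, year = d$year,
                   year_std = as.numeric(scale(d$year)))
  for (nm in keep) gd[[nm]] <- best$Z[, nm]
  fml <- stats::as.formula(paste(".y ~ year_std",
                                 if (length(keep))
                                   paste("+", paste(keep, collapse = " + "))
                                 else ""))
  fit <- nlme::gls(fml, data = gd,
                   correlation = nlme::corAR1(form = ~ year))
  rho <- as.numeric(coef(fit$modelStruct$corStruct, unconstrained = FALSE))
  tt <- summary(fit)$tTable
  terms <- rownames(tt)
  dfres <- fit$dims$N - fit$dims$p
  crit <- qt(0.975, dfres)
  sel_terms <- terms[terms != "(Intercept)"]
  sel <- data.frame(
    term = ifelse(sel_terms == "year_std", "year", sel_terms),
    lag = vapply(sel_terms, function(nm)
      if (nm == "year_std") NA_integer_ else lag_of(nm), integer(1)),
    estimate = tt[sel_terms, "Value"], se = tt[sel_terms, "Std.Error"],
    t = tt[sel_terms, "t-value"], p = tt[sel_terms, "p-value"])
  sel$ci_lo <- sel$estimate - crit * sel$se
  sel$ci_hi <- sel$estimate + crit * sel$se
  rownames(sel) <- NULL
  new("LagRegressionResult", predictor = seriesName(predictor),
      candidateLags = best$lags, trace = trace, selected = sel,
      rho = rho, offset = as.integer(best$off), n = nrow(d),
      dfResidual = as.integer(dfres), bic = best$bic)
}

#' @describeIn lagRegression lags retained in the final model (excluding
#'   year)
#' @param x a LagRegressionResult.
#' @export
selectedLags <- function(x) {
  x@selected$lag[x@selected$term != "year"]
}

#' Birth-to-marriage ratio
#'
#' Element-wise quotient `birth / nuptial` on the overlapping years; a
#' proxy for births per marriage.
#'
#' @param birth,nuptial \linkS4class{AnnualSeries} (crude birth rate and
#'   nuptial rate).
#' @return an \linkS4class{AnnualSeries} named `"bnr"`.
#' @export
birthToMarriage <- function(birth, nuptial) {
  yrs <- intersect(seriesYears(birth), seriesYears(nuptial))
  if (!length(yrs)) {
    warning("birth and nuptial series have no overlapping years")
    return(AnnualSeries("bnr", integer(), numeric()))
  }
  b <- seriesValues(birth)[match(yrs, seriesYears(birth))]
  m <- seriesValues(nuptial)[match(yrs, seriesYears(nuptial))]
  bad <- which(m <= 0)
  if (length(bad))
    stop("non-positive nuptial rate in year ",
         paste(yrs[bad], collapse = ", "))
  interp <- seriesInterpolated(birth)[match(yrs, seriesYears(birth))] |
    seriesInterpolated(nuptial)[match(yrs, seriesYears(nuptial))]
  AnnualSeries("bnr", yrs, b / m, interp)
}

#' Play-level correlations between scores and annual series
#'
#' Pairs each play with its year's series value and reports the Pearson
#' correlation per series.
#'
#' @param scores a \linkS4class{PlayScoreSet} or score table; only
#'   included plays are used.
#' @param seriesList named list of \linkS4class{AnnualSeries}.
#' @param value score column (default `"romantic_love"`).
#' @return data.frame `series, r, n, p`.
#' @export
corrReport <- function(scores, seriesList, value = "romantic_love") {
  d <- if (is(scores, "PlayScoreSet")) scoreTable(scores) else scores
  d <- d[d$included, , drop = FALSE]
  rows <- lapply(names(seriesList), function(nm) {
    s <- seriesList[[nm]]
    v <- seriesValues(s)[match(d$year, seriesYears(s))]
    ok <- !is.na(v) & is.finite(d[[value]])
    if (sum(ok) < 3)
      return(data.frame(series = nm, r = NA_real_, n = sum(ok),
                        p = NA_real_))
    ct <- stats::cor.test(d[[value]][ok], v[ok])
    data.frame(series = nm, r = unname(ct$estimate), n = sum(ok),
               p = ct$p.value)
  })
  do.call(rbind, rows)
}
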