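# Synthetic corpora and time series with recorded ground truth. These
# generators emulate the statistical structure the analysis assumes --
# Poisson category emission inside seed windows with author effects and
# two latent factors, AR(1) economy series with trend, and demographic
# series coupled to the love signal at a known lag -- so every estimator
# in the package can be tested for parameter recovery.

#' Specification of a synthetic economy series
#'
#' @param yearStart,yearEnd year range (defaults 1550-1800, the span of
#'   the English corpus the pipeline targets).
#' @param phi AR(1) coefficient, |phi| < 1.
#' @param innovationSd innovation standard deviation.
#' @param trendSlope linear trend per year.
#' @param name series name.
#' @return list of class `SyntheticEconomySpec`.
#' @export
economySpec <- function(yearStart = 1550L, yearEnd = 1800L, phi = 0.6,
                        innovationSd = 1, trendSlope = 0.02,
                        name = "econ") {
  if (abs(phi) >= 1) stop("AR(1) coefficient must satisfy |phi| < 1")
  structure(list(yearStart = as.integer(yearStart),
                 yearEnd = as.integer(yearEnd), phi = phi,
                 innovationSd = innovationSd, trendSlope = trendSlope,
                 name = name),
            class = "SyntheticEconomySpec")
}

#' Generate an AR(1)-plus-trend annual series
#'
#' `y(t) = trendSlope * (t - yearStart) + u(t)` with
#' `u(t) = phi * u(t-1) + e(t)`, `e ~ N(0, innovationSd^2)`, `u`
#' initialized from its stationary distribution. Deterministic per seed.
#'
#' @param spec an [economySpec()].
#' @param seed integer random seed.
#' @return an \linkS4class{AnnualSeries}.
#' @export
generateEconomy <- function(spec, seed = 1L) {
  set.seed(seed)
  yrs <- spec$yearStart:spec$yearEnd
  n <- length(yrs)
  u <- numeric(n)
  sd0 <- spec$innovationSd / sqrt(1 - spec$phi^2)
  u[1] <- rnorm(1, 0, if (spec$phi != 0) sd0 else spec$innovationSd)
  if (n > 1) {
    e <- rnorm(n - 1, 0, spec$innovationSd)
    for (t in 2:n) u[t] <- spec$phi * u[t - 1] + e[t - 1]
  }
  AnnualSeries(spec$name, yrs,
               spec$trendSlope * (yrs - spec$yearStart) + u)
}

#' Generate a love series coupled to an economy at a known lag
#'
#' `love(t) = coef * std(econ)(t - lag) + trendSlope * t' + noise`.
#' The economy is standardized before coupling so `coef` is on the
#' standardized scale. Years whose lagged economy value is unavailable
#' are dropped.
#'
#' @param economy an \linkS4class{AnnualSeries}.
#' @param lag coupling lag in years (positive: economy leads).
#' @param coef coupling coefficient (default 0.5).
#' @param trendSlope linear trend per year in the love series.
#' @param noiseSd white-noise standard deviation (default 1).
#' @param seed integer random seed.
#' @return an \linkS4class{AnnualSeries} named `"love"` with attribute
#'   `"truth"`.
#' @export
generateCoupledLove <- function(economy, lag = 9L, coef = 0.5,
                                trendSlope = 0.002, noiseSd = 1,
                                seed = 1L) {
  set.seed(seed)
  ey <- seriesYears(economy)
  ev <- as.numeric(scale(seriesValues(economy)))
  yrs <- ey[ey - lag >= min(ey) & ey - lag <= max(ey)]
  lagged <- ev[match(yrs - lag, ey)]
  vals <- coef * lagged + trendSlope * (yrs - min(yrs)) +
    rnorm(length(yrs), 0, noiseSd)
  out <- AnnualSeries("love", yrs, vals)
  attr(out, "truth") <- list(lag = lag, coef = coef,
                             trendSlope = trendSlope, noiseSd = noiseSd)
  out
}

#' Specification of a synthetic play corpus
#'
#' Defaults describe a mid-sized historical corpus: 400 plays over
#' 1550-1800 from 60 authors, plays of about 2000 content tokens, 8
#' seed occurrences per 1000 tokens, and a balanced tender/passion
#' emission of 0.5 expected category tokens per seed window.
#'
#' @param nPlays number of plays.
#' @param yearRange integer range plays are drawn from uniformly.
#' @param nAuthors number of authors (plays assigned uniformly).
#' @param authorSd standard deviation of author intercepts on the log
#'   emission rate.
#' @param tenderRate,passionRate expected tender/passion category tokens
#'   per seed window (before author and factor effects).
#' @param tenderTrend linear increment of the tender rate per year.
#' @param coupling optional list `list(b =, lag =)` linking the tender
#'   rate to a standardized economy series: `rate + b * econ(year - lag)`.
#' @param seedsPer1000 expected seed tokens per 1000 content tokens.
#' @param lengthMean,lengthDispersion negative-binomial play length
#'   (content tokens).
#' @param otherRate expected tokens per window for each of the eight
#'   validation categories.
#' @param factorLoading loading of each category's log rate on its own
#'   latent factor (emotional investment drives tenderness, moral
#'   qualities, discipline, mental parts and long relationships; desire
#'   drives passion, sensuality, physical qualities, body parts and
#'   short relationships).
#' @param window seed-window half-width the corpus is built for.
#' @return list of class `SyntheticCorpusSpec`.
#' @export
corpusSpec <- function(nPlays = 400L, yearRange = c(1550L, 1800L),
                       nAuthors = 60L, authorSd = 0.5,
                       tenderRate = 0.5, passionRate = 0.5,
                       tenderTrend = 0, coupling = NULL,
                       seedsPer1000 = 8, lengthMean = 2000,
                       lengthDispersion = 5, otherRate = 0.25,
                       factorLoading = 0.7, window = 3L) {
  spec <- structure(as.list(environment()), class = "SyntheticCorpusSpec")
  expected <- tenderRate + passionRate + 8 * otherRate
  if (expected > 2 * window)
    stop("emission rates imply more than the window capacity of ",
         2 * window, " tokens (expected ", round(expected, 2), ")")
  if (any(c(tenderRate, passionRate, otherRate) < 0))
    stop("emission rates must be >= 0")
  spec
}

# integer -> purely alphabetic filler token ("zb", "zc", ...). The
# alphabet avoids letters that trigger lemmatizer suffix rules (s, d, g,
# y, e) so filler words survive a text round-trip unchanged, and the "z"
# prefix avoids collisions with function words and lexicon entries.
int_to_word <- function(i, prefix = "z") {
  ab <- c("b", "c", "f", "h", "k", "l", "m", "n", "p", "r", "t", "v",
          "w", "x", "z")
  base <- length(ab)
  out <- character(length(i))
  for (k in seq_along(i)) {
    n <- i[k]; s <- ""
    repeat {
      s <- paste0(ab[n %% base + 1L], s)
      n <- n %/% base
      if (n == 0L) break
    }
    out[k] <- paste0(prefix, s)
  }
  out
}

FACTOR_OF_CATEGORY <- c(
  passionate_feelings = "desire", tender_feelings = "emotional",
  sensuality = "desire", discipline_asceticism = "emotional",
  physical_qualities = "desire", moral_qualities = "emotional",
  short_relationships = "desire", long_relationships = "emotional",
  body_parts = "desire", mental_parts = "emotional")

#' Generate a synthetic tokenized corpus with known ground truth
#'
#' Each play is a sequence of Zipf-distributed filler tokens with seed
#' tokens placed at the specified rate; within every seed window,
#' category tokens are emitted as Poisson counts whose log rates carry
#' an author intercept and a loading on one of two latent play-level
#' factors (emotional investment vs. desire), making both score and
#' factor-structure recovery testable. Category tokens are placed in the
#' noun/adjective positions directly adjacent to their seed, and filler
#' blocks between seeds are long enough that windows never bleed into a
#' neighbouring seed's emissions.
#'
#' @param spec a [corpusSpec()].
#' @param economy optional \linkS4class{AnnualSeries} for tender-rate
#'   coupling (required when `spec$coupling` is set).
#' @param lexicon lexicon supplying seed and category words (default
#'   [defaultLexicon()]).
#' @param seed integer random seed.
#' @return list with `tokens` (list of \linkS4class{TokenizedPlay}),
#'   `metadata` (play_id, year, author), `emitted` (true category count
#'   matrix, categories x plays) and `truth` (all rates, author effects,
#'   factor scores and coupling).
#' @export
generateCorpus <- function(spec, economy = NULL,
                           lexicon = defaultLexicon("english"),
                           seed = 1L) {
  set.seed(seed)
  if (!is.null(spec$coupling) && is.null(economy))
    stop("spec couples the tender rate to an economy; supply one")
  econ_std <- NULL
  if (!is.null(economy))
    econ_std <- setNames(as.numeric(scale(seriesValues(economy))),
                         seriesYears(economy))
  nV <- 600L
  vocab <- int_to_word(seq_len(nV))
  zipf <- (1 / seq_len(nV)) / sum(1 / seq_len(nV))
  vocab_pos <- sample(c("noun", "adjective", "verb"), nV, replace = TRUE,
                      prob = c(0.55, 0.2, 0.25))
  seeds <- lexiconSeeds(lexicon)
  cats <- lexiconCategories(lexicon)
  w <- spec$window

  authors <- paste0("author", sprintf("%03d", seq_len(spec$nAuthors)))
  authorEff <- setNames(rnorm(spec$nAuthors, 0, spec$authorSd), authors)

  ids <- sprintf("play%04d", seq_len(spec$nPlays))
  years <- sample(spec$yearRange[1]:spec$yearRange[2], spec$nPlays,
                  replace = TRUE)
  play_author <- sample(authors, spec$nPlays, replace = TRUE)
  f_emo <- rnorm(spec$nPlays); f_des <- rnorm(spec$nPlays)

  tokens <- vector("list", spec$nPlays)
  emitted <- matrix(0L, length(CANONICAL_CATEGORIES), spec$nPlays,
                    dimnames = list(CANONICAL_CATEGORIES, ids))
  lambda_t <- lambda_p <- numeric(spec$nPlays)

  sample_filler <- function(n) {
    j <- sample.int(nV, n, replace = TRUE, prob = zipf)
    list(lemma = vocab[j], pos = vocab_pos[j])
  }
  # filler block guaranteed to contain >= w noun/adjective tokens at
  # both ends, isolating neighbouring seed windows
  guard_block <- function(n) {
    fb <- sample_filler(n)
    na_idx <- which(vocab_pos == "noun" | vocab_pos == "adjective")
    g <- vocab[sample(na_idx, 2L * w, replace = TRUE)]
    list(lemma = c(g[seq_len(w)], fb$lemma, g[w + seq_len(w)]),
         pos = c(rep("noun", w), fb$pos, rep("noun", w)))
  }

  for (i in seq_len(spec$nPlays)) {
    yr <- years[i]
    base_t <- spec$tenderRate + spec$tenderTrend * (yr - spec$yearRange[1])
    if (!is.null(spec$coupling)) {
      ev <- econ_std[as.character(yr - spec$coupling$lag)]
      if (!is.na(ev)) base_t <- base_t + spec$coupling$b * ev
    }
    au <- play_author[i]
    lt <- max(0, base_t) * exp(authorEff[[au]] +
                               spec$factorLoading * f_emo[i])
    lp <- spec$passionRate * exp(authorEff[[au]] +
                                 spec$factorLoading * f_des[i])
    lambda_t[i] <- lt; lambda_p[i] <- lp
    lam <- setNames(numeric(length(CANONICAL_CATEGORIES)),
                    CANONICAL_CATEGORIES)
    lam["tender_feelings"] <- lt
    lam["passionate_feelings"] <- lp
    for (cat in setdiff(CANONICAL_CATEGORIES,
                        c("tender_feelings", "passionate_feelings"))) {
      f <- if (FACTOR_OF_CATEGORY[[cat]] == "emotional") f_emo[i] else f_des[i]
      lam[cat] <- spec$otherRate * exp(spec$factorLoading * f)
    }
    L <- max(300L, rnbinom(1, mu = spec$lengthMean,
                           size = spec$lengthDispersion))
    nSeeds <- max(1L, rpois(1, L * spec$seedsPer1000 / 1000))

    seg_lemma <- list(); seg_pos <- list()
    filler_total <- max(0L, L - nSeeds * (2L * w + 1L))
    block_sizes <- pmax(2L, as.integer(table(factor(
      sample.int(nSeeds + 1L, filler_total, replace = TRUE),
      levels = seq_len(nSeeds + 1L)))))
    for (s in seq_len(nSeeds)) {
      gb <- guard_block(block_sizes[s])
      seg_lemma[[length(seg_lemma) + 1L]] <- gb$lemma
      seg_pos[[length(seg_pos) + 1L]] <- gb$pos
      draws <- setNames(rpois(length(lam), lam), names(lam))
      total <- sum(draws)
      if (total > 2L * w) {   # cap at window capacity
        flat <- rep(names(lam), draws)
        flat <- sample(flat, 2L * w)
        draws <- as.integer(table(factor(flat, levels = names(lam))))
        names(draws) <- names(lam)
        total <- 2L * w
      }
      words <- unlist(lapply(names(lam)[draws > 0], function(cat)
        sample(cats[[cat]], draws[[cat]], replace = TRUE)),
        use.names = FALSE)
      emitted[, i] <- emitted[, i] +
        as.integer(table(factor(rep(names(lam), draws),
                                levels = CANONICAL_CATEGORIES)))
      na_pad_idx <- which(vocab_pos %in% c("noun", "adjective"))
      pad_lemma <- vocab[sample(na_pad_idx, 2L * w - total, replace = TRUE)]
      slot_words <- sample(c(words, pad_lemma))
      left <- slot_words[seq_len(w)]
      right <- slot_words[w + seq_len(w)]
      seed_tok <- sample(seeds, 1)
      seg_lemma[[length(seg_lemma) + 1L]] <-
        c(left, seed_tok, right)
      seg_pos[[length(seg_pos) + 1L]] <-
        c(rep("noun", w), "noun", rep("noun", w))
    }
    gb <- guard_block(block_sizes[nSeeds + 1L])
    seg_lemma[[length(seg_lemma) + 1L]] <- gb$lemma
    seg_pos[[length(seg_pos) + 1L]] <- gb$pos
    tokens[[i]] <- TokenizedPlay(ids[i],
                                 unlist(seg_lemma, use.names = FALSE),
                                 unlist(seg_pos, use.names = FALSE))
  }
  list(
    tokens = tokens,
    metadata = data.frame(play_id = ids, year = years,
                          author = play_author),
    emitted = emitted,
    truth = list(spec = spec, authorEff = authorEff, f_emo = f_emo,
                 f_des = f_des, lambda_tender = lambda_t,
                 lambda_passion = lambda_p,
                 coupling = spec$coupling, seed = seed))
}

#' Render a synthetic tokenized play as play-like text
#'
#' Produces a plain-text play (speaker labels, a prologue and bracketed
#' directions included) whose spoken content reduces back to the token
#' sequence, for exercising the ingestion and preprocessing path on
#' synthetic corpora.
#'
#' @param tp a \linkS4class{TokenizedPlay}.
#' @param lineLength tokens per spoken line.
#' @return single character string of play text.
#' @export
renderPlayText <- function(tp, lineLength = 12L) {
  n <- length(tp@lemma)
  lines <- character()
  lines <- c(lines, "PROLOGUE", "prologue words that must be dropped",
             "ACT I.", "")
  i <- 1L
  spk <- c("FIRST SPEAKER.", "SECOND SPEAKER.")
  k <- 0L
  while (i <= n) {
    k <- k + 1L
    lines <- c(lines, spk[(k %% 2L) + 1L])
    j <- min(n, i + lineLength - 1L)
    lines <- c(lines, paste(tp@lemma[i:j], collapse = " "))
    if (k == 1L) lines <- c(lines, "[aside]")
    i <- j + 1L
  }
  paste(lines, collapse = "\n")
}

#' Generate nuptiality and birth series coupled to a love signal
#'
#' `nuptial(t) = base + c1 * std(love)(t - lag) + AR(1) noise` and
#' `birth(t) = birthFactor * nuptial(t) + c2 * std(love)(t - lag) +
#' AR(1) noise`, with `c2 < 0` by default so the birth-to-marriage ratio
#' declines as love rises. Positive `c1` makes love lead nuptiality at
#' `+lag` years.
#'
#' @param love an \linkS4class{AnnualSeries}.
#' @param c1 love-to-nuptiality coupling (default 0.5).
#' @param c2 direct love-to-birth coupling (default -0.5, giving a
#'   declining birth-to-marriage ratio).
#' @param lag coupling lag in years (default 6; love leads).
#' @param base baseline nuptial rate (default 10).
#' @param birthFactor births per marriage baseline (default 3).
#' @param phi AR(1) coefficient of both noise processes.
#' @param noiseSd innovation standard deviation of both noise processes.
#' @param seed integer random seed.
#' @return list with `nuptial` and `birth` \linkS4class{AnnualSeries}
#'   and a `truth` record.
#' @export
generateDemography <- function(love, c1 = 0.5, c2 = -0.5, lag = 6L,
                               base = 10, birthFactor = 3, phi = 0.5,
                               noiseSd = 0.3, seed = 1L) {
  set.seed(seed)
  ly <- seriesYears(love)
  ls <- setNames(as.numeric(scale(seriesValues(love))), ly)
  yrs <- (min(ly) + lag):(max(ly) + lag)
  lagged <- ls[as.character(yrs - lag)]
  ar1 <- function(n) {
    u <- numeric(n)
    u[1] <- rnorm(1, 0, noiseSd / sqrt(1 - phi^2))
    if (n > 1) for (t in 2:n) u[t] <- phi * u[t - 1] + rnorm(1, 0, noiseSd)
    u
  }
  nup <- base + c1 * lagged + ar1(length(yrs))
  birth <- birthFactor * nup + c2 * lagged + ar1(length(yrs))
  if (any(nup <= 0))
    stop("generated nuptial rates non-positive; raise `base` or lower noise")
  list(nuptial = AnnualSeries("nuptial", yrs, unname(nup)),
       birth = AnnualSeries("birth", yrs, unname(birth)),
       truth = list(c1 = c1, c2 = c2, lag = lag, base = base,
                    birthFactor = birthFactor, phi = phi,
                    noiseSd = noiseSd, seed = seed))
}

#' Simulate a play-score panel with known mixed-model structure
#'
#' Directly generates a score table `romantic_love = beta * wages +
#' author intercept + residual` for mixed-model parameter-recovery
#' tests: `wages` is standard normal, author intercepts are
#' `N(0, authorSd^2)` and residuals `N(0, residSd^2)`.
#'
#' @param nPlays,nAuthors panel size (defaults 800 plays, 120 authors).
#' @param beta standardized fixed effect of `wages` (default 0.2).
#' @param authorSd author intercept standard deviation (default 0.5).
#' @param residSd residual standard deviation (default 1).
#' @param seed integer random seed.
#' @return data.frame `play_id, author, year, wages, romantic_love` with
#'   attribute `"truth"`.
#' @export
simulateScorePanel <- function(nPlays = 800L, nAuthors = 120L, beta = 0.2,
                               authorSd = 0.5, residSd = 1, seed = 1L) {
  set.seed(seed)
  authors <- paste0("author", sprintf("%03d", seq_len(nAuthors)))
  u <- setNames(rnorm(nAuthors, 0, authorSd), authors)
  a <- sample(authors, nPlays, replace = TRUE)
  wages <- rnorm(nPlays)
  y <- beta * wages + u[a] + rnorm(nPlays, 0, residSd)
  out <- data.frame(play_id = sprintf("play%04d", seq_len(nPlays)),
                    author = a, year = sample(1550:1800, nPlays, TRUE),
                    wages = wages, romantic_love = unname(y))
  attr(out, "truth") <- list(beta = beta, authorSd = authorSd,
                             residSd = residSd, seed = seed)
  out
}
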