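test_that("seed windows truncate at edges and exclude the seed itself", {
  tp <- TokenizedPlay("p", c("fair", "love", "sweet", "face", "mind"),
                      c("adjective", "noun", "adjective", "noun", "noun"))
  w <- seedWindows(tp, "love", window = 3)
  expect_length(w, 1)
  expect_setequal(w[[1]], c("fair", "sweet", "face", "mind"))
  # no seeds -> empty list
  expect_length(seedWindows(tp, "cupid"), 0)
  expect_error(seedWindows(tp, "love", window = 0), "window")
  # adjacent seeds: each window contains the other occurrence
  tp2 <- TokenizedPlay("q", c("love", "love"), c("noun", "noun"))
  w2 <- seedWindows(tp2, "love")
  expect_length(w2, 2)
  expect_identical(w2[[1]], "love")
  expect_identical(w2[[2]], "love")
})

test_that("windows skip verbs but anchor on seeds regardless of POS", {
  tp <- TokenizedPlay("p",
    c("fair", "kiss", "love", "kiss", "sweet"),
    c("adjective", "verb", "verb", "verb", "adjective"))
  w <- seedWindows(tp, "love", window = 1)
  # verbs drop out of the subsequence; seed anchors even though tagged verb
  expect_setequal(w[[1]], c("fair", "sweet"))
})

test_that("category counting matches the examples and ignores unknown words", {
  lex <- mini_lexicon()
  wins <- list(c("sweet", "tenderness"), "desire")
  counts <- countCategories(wins, lex)
  expect_identical(counts[["tender_feelings"]], 1L)
  expect_identical(counts[["passionate_feelings"]], 1L)
  expect_identical(sum(counts), 2L)
  expect_identical(sum(countCategories(list(), lex)), 0L)
})

test_that("window counting equals the brute-force oracle on random fixtures", {
  lex <- mini_lexicon()
  set.seed(123)
  for (i in 1:100) {
    n <- sample(20:200, 1)
    tp <- random_token_play(n, lex)
    wins <- seedWindows(tp, lexiconSeeds(lex), window = 3)
    got <- countCategories(wins, lex)
    want <- brute_category_counts(tp@lemma, tp@pos, lex, window = 3)
    expect_identical(got, want)
  }
})

test_that("raw-token window variant also matches its oracle", {
  lex <- mini_lexicon()
  set.seed(99)
  for (i in 1:20) {
    tp <- random_token_play(80, lex)
    wins <- seedWindows(tp, lexiconSeeds(lex), window = 3, rawTokens = TRUE)
    got <- countCategories(wins, lex)
    want <- brute_category_counts(tp@lemma, tp@pos, lex, window = 3,
                                  rawTokens = TRUE)
    expect_identical(got, want)
  }
})

test_that("z-scores use the sample sd over step-A survivors", {
  lex <- mini_lexicon()
  # three plays, tender counts 1/2/3 per 1000 tokens, all else identical
  mk <- function(id, ntender) {
    lem <- c(rep(c("love", "tenderness"), ntender),
             rep(c("love", "desire"), 1),
             c("love", "pleasure"), c("love", "modest"), c("love", "young"),
             c("love", "noble"), c("love", "conquest"), c("love", "marriage"),
             c("love", "hand"), c("love", "mind"),
             rep("filler", 1000 - 2 * (ntender + 9)))
    TokenizedPlay(id, lem, rep("noun", length(lem)))
  }
  toks <- list(mk("a", 1), mk("b", 2), mk("c", 3))
  meta <- data.frame(play_id = c("a", "b", "c"), year = 1600:1602,
                     author = c("x", "y", "z"))
  sc <- scoreCorpus(toks, lex, meta)
  cd <- SummarizedExperiment::colData(sc)
  expect_equal(unname(cd$z_tender), c(-1, 0, 1), tolerance = 1e-12)
  expect_equal(unname(cd$z_passion), c(0, 0, 0), tolerance = 1e-12)
  expect_equal(unname(cd$romantic_love), c(-1, 0, 1), tolerance = 1e-12)
})

test_that("romantic love negates exactly under a tender/passion swap", {
  cor1 <- demo_corpus(nPlays = 60, seed = 21)
  sc <- scoreCorpus(cor1$tokens, mini_lexicon(), cor1$metadata)
  sw <- scoreCorpus(cor1$tokens, swapped_lexicon(), cor1$metadata)
  a <- SummarizedExperiment::colData(sc)
  b <- SummarizedExperiment::colData(sw)
  ok <- !is.na(a$romantic_love)
  expect_equal(a$romantic_love[ok], -b$romantic_love[ok], tolerance = 1e-12)
})

test_that("scores are invariant under duplication of every play", {
  cor1 <- demo_corpus(nPlays = 40, seed = 31)
  sc <- scoreCorpus(cor1$tokens, mini_lexicon(), cor1$metadata)
  dup_tokens <- c(cor1$tokens, lapply(cor1$tokens, function(tp)
    TokenizedPlay(paste0(tp@playId, "_dup"), tp@lemma, tp@pos)))
  dup_meta <- rbind(cor1$metadata,
                    transform(cor1$metadata,
                              play_id = paste0(play_id, "_dup")))
  sc2 <- scoreCorpus(dup_tokens, mini_lexicon(), dup_meta)
  n <- nrow(cor1$metadata)
  a <- SummarizedExperiment::colData(sc)$romantic_love
  b <- SummarizedExperiment::colData(sc2)$romantic_love[seq_len(n)]
  # sample-sd z-scores shift by the (n-1)/(2n-1) divisor under doubling;
  # scores agree up to that vanishing factor and ranks agree exactly
  expect_equal(a, b, tolerance = 0.02)
  ok <- !is.na(a)
  expect_identical(rank(a[ok]), rank(b[ok]))
})

test_that("adding a tender token in a window never lowers the play's love rank", {
  lex <- mini_lexicon()
  cor1 <- demo_corpus(nPlays = 30, seed = 41)
  sc <- scoreCorpus(cor1$tokens, lex, cor1$metadata)
  rl <- romanticLove(sc)
  target <- names(which(includedPlays(sc)))[1]
  tp <- cor1$tokens[[which(vapply(cor1$tokens, function(x) x@playId,
                                  "") == target)]]
  # replace a filler token adjacent to the first seed with a tender word
  pos_seed <- which(tp@lemma %in% lexiconSeeds(lex))[1]
  lem <- tp@lemma; lem[pos_seed - 1] <- "affection"
  tp2 <- TokenizedPlay(tp@playId, lem, tp@pos)
  toks2 <- cor1$tokens
  toks2[[which(vapply(toks2, function(x) x@playId, "") == target)]] <- tp2
  sc2 <- scoreCorpus(toks2, lex, cor1$metadata)
  rl2 <- romanticLove(sc2)
  rank1 <- rank(rl)[target]
  rank2 <- rank(rl2)[target]
  expect_gte(rank2, rank1)
})

test_that("step-A filter, outlier removal and error paths behave as specified", {
  cor1 <- demo_corpus(nPlays = 150, seed = 51, lengthMean = 900)
  sc <- scoreCorpus(cor1$tokens, mini_lexicon(), cor1$metadata)
  cd <- SummarizedExperiment::colData(sc)
  stepA <- cd$exclusion_reason != "missing_category"
  counts <- SummarizedExperiment::assay(sc, "counts")
  # every step-A play has all ten categories present
  expect_true(all(colSums(counts[, stepA] > 0) == 10))
  expect_true(all(colSums(counts[, !stepA, drop = FALSE] > 0) < 10))
  # mean 0 / sd 1 over survivors; post-filter outliers bounded
  expect_lt(abs(mean(cd$z_tender[stepA])), 1e-10)
  expect_equal(sd(cd$z_tender[stepA]), 1, tolerance = 1e-10)
  rl <- cd$romantic_love[stepA]
  zrl <- (rl - mean(rl)) / sd(rl)
  expect_true(all(abs(zrl[cd$included[stepA]]) <= 3))
  expect_true(all(cd$exclusion_reason[stepA][abs(zrl) > 3] == "outlier"))
  # tender/passion-only mode admits more plays
  sc2 <- scoreCorpus(cor1$tokens, mini_lexicon(), cor1$metadata,
                     mode = "tender_passion")
  expect_gte(sum(includedPlays(sc2)), sum(includedPlays(sc)))
  # corpus-too-small error
  expect_error(scoreCorpus(cor1$tokens[1:3], mini_lexicon(),
                           cor1$metadata[1:3, ], mode = "all"),
               "fewer than 3|category filter")
})

test_that("dictionary ratios: identity gives zero, low support is flagged", {
  toks <- list(
    TokenizedPlay("a", c("friend", "comrade", "sword"), rep("noun", 3)),
    TokenizedPlay("b", c("lust", "sword", "shield"), rep("noun", 3)),
    TokenizedPlay("c", c("sword", "shield", "helm"), rep("noun", 3)))
  same <- dictionaryRatio(toks, c("friend"), c("friend"))
  expect_equal(unname(as.numeric(same)), c(0, 0, 0), tolerance = 1e-12)
  r <- dictionaryRatio(toks, c("friend", "comrade"), c("lust"))
  expect_identical(attr(r, "lowSupport"), "c")
  expect_true(all(is.finite(r)))
  expect_gt(r[["a"]], r[["b"]])
  expect_error(dictionaryRatio(toks, character(), "x"), "non-empty")
})

test_that("dictionary ratios correlate with the generator's tender signal", {
  cor1 <- demo_corpus(nPlays = 100, seed = 61)
  # dictionary A = tender word list (whole-text), B = passion word list
  lex <- mini_lexicon()
  d <- dictionaryRatios(
    cor1$tokens,
    list(friends = lexiconCategories(lex)$tender_feelings,
         sexual = lexiconCategories(lex)$passionate_feelings),
    pairs = list(friends_to_sexual = c("friends", "sexual")))
  sc <- scoreCorpus(cor1$tokens, lex, cor1$metadata,
                    mode = "tender_passion")
  rl <- romanticLove(sc)
  ok <- !is.na(rl)
  expect_gt(cor(rl[ok], d$friends_to_sexual[ok]), 0.3)
})
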