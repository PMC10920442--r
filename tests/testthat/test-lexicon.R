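test_that("candidate extraction counts noun/adjective tokens near seeds", {
  lex <- mini_lexicon()
  tp <- TokenizedPlay("p", c("sweet", "love", "sweet"),
                      c("adjective", "noun", "adjective"))
  cand <- extractCandidates(list(tp), lexiconSeeds(lex))
  expect_identical(cand$lemma, "sweet")
  expect_identical(cand$count, 2L)
  # seeds absent -> empty with warning
  tp2 <- TokenizedPlay("q", c("sweet", "face"), c("adjective", "noun"))
  expect_warning(c2 <- extractCandidates(list(tp2), "love"), "no seed")
  expect_identical(nrow(c2), 0L)
})

test_that("candidate counts equal a brute-force position scan on random fixtures", {
  lex <- mini_lexicon()
  seeds <- lexiconSeeds(lex)
  set.seed(7)
  for (i in 1:30) {
    tp <- random_token_play(50, lex, id = paste0("r", i))
    cand <- extractCandidates(list(tp), seeds, window = 3)
    # oracle: double loop on the noun/adj+seed subsequence
    keep <- tp@pos %in% c("noun", "adjective") | tp@lemma %in% seeds
    lem <- tp@lemma[keep]; pos <- tp@pos[keep]
    expected <- new.env()
    for (s in which(lem %in% seeds)) for (t in seq_along(lem)) {
      if (t == s || abs(t - s) > 3) next
      if (!(pos[t] %in% c("noun", "adjective")) || lem[t] %in% seeds) next
      k <- paste0(lem[t], "|", pos[t])
      expected[[k]] <- (if (is.null(expected[[k]])) 0L else expected[[k]]) + 1L
    }
    got <- setNames(cand$count, paste0(cand$lemma, "|", cand$pos))
    exp_keys <- ls(expected)
    expect_setequal(names(got), exp_keys)
    for (k in exp_keys) expect_identical(got[[k]], expected[[k]])
  }
  # ties broken alphabetically, counts descending
  tp <- TokenizedPlay("t", c("b", "a", "love", "c", "c"),
                      rep("noun", 5))
  cand <- extractCandidates(list(tp), "love")
  expect_identical(cand$lemma, c("c", "a", "b"))
})

test_that("embeddings place words with shared contexts close together", {
  set.seed(5)
  ctx <- paste0("ctx", letters[1:6])
  mk <- function(id) {
    lem <- unlist(lapply(1:80, function(i) {
      c(sample(c("alpha", "beta"), 1), sample(ctx, 2))
    }))
    TokenizedPlay(id, lem, rep("noun", length(lem)))
  }
  corp <- list(mk("a"), mk("b"))
  emb <- trainEmbeddings(corp, dims = 10, window = 2, minCount = 2)
  nb_a <- nearestNeighbors(emb, "alpha", k = 3)
  nb_b <- nearestNeighbors(emb, "beta", k = 3)
  expect_true("beta" %in% nb_a$neighbors$neighbor)
  expect_true("alpha" %in% nb_b$neighbors$neighbor)
  # similarities non-increasing and within [-1, 1]
  s <- nb_a$neighbors$similarity
  expect_true(all(diff(s) <= 1e-12))
  expect_true(all(abs(s) <= 1 + 1e-12))
  # determinism: retrain gives identical neighbour lists
  emb2 <- trainEmbeddings(corp, dims = 10, window = 2, minCount = 2)
  expect_identical(nearestNeighbors(emb2, "alpha", 3)$neighbors$neighbor,
                   nb_a$neighbors$neighbor)
  # out-of-vocabulary query is flagged, not an error
  oov <- nearestNeighbors(emb, "nosuchword")
  expect_false(oov$inVocab)
  expect_identical(nrow(oov$neighbors), 0L)
  expect_error(trainEmbeddings(list(TokenizedPlay("x", "one", "noun"))),
               "vocabulary below")
})

test_that("neighbour report covers lexicon words and flags OOV entries", {
  set.seed(9)
  lex <- mini_lexicon()
  words <- c(unlist(lexiconCategories(lex), use.names = FALSE), "love")
  corp <- lapply(1:3, function(i) {
    lem <- sample(words, 400, replace = TRUE)
    TokenizedPlay(paste0("p", i), lem, rep("noun", length(lem)))
  })
  emb <- trainEmbeddings(corp, dims = 15, window = 3, minCount = 2)
  rep1 <- neighborReport(lex, emb, k = 5)
  inv <- rep1[rep1$inVocab, ]
  expect_true(all(table(inv$word) == 5))
  expect_true(all(is.na(rep1$flag)))
  # report round-trips through TSV
  dir <- withr::local_tempdir()
  p <- file.path(dir, "nb.tsv")
  writeNeighborReport(rep1, p)
  back <- readNeighborReport(p)
  expect_identical(back$neighbor, rep1$neighbor)
  expect_equal(back$similarity, rep1$similarity, tolerance = 1e-12)
})

test_that("k=1 on a two-word vocabulary returns the other word", {
  corp <- list(TokenizedPlay("p", rep(c("aa", "bb"), 10), rep("noun", 20)),
               TokenizedPlay("q", rep(c("aa", "bb", "cc", "dd", "ee"), 4),
                             rep("noun", 20)))
  emb <- trainEmbeddings(corp, dims = 3, window = 2, minCount = 3)
  nb <- nearestNeighbors(emb, "aa", k = 1)
  expect_identical(nrow(nb$neighbors), 1L)
})

test_that("retention rule is a strict majority and monotone", {
  expect_true(applyRetentionRule(rep(c(TRUE, FALSE), c(6, 4))))
  expect_false(applyRetentionRule(rep(c(TRUE, FALSE), c(5, 5))))
  expect_false(applyRetentionRule(rep(FALSE, 10)))
  expect_error(applyRetentionRule(rep(TRUE, 7)), "10")
  # monotone in number of consistent flags
  kept <- vapply(0:10, function(k)
    applyRetentionRule(rep(c(TRUE, FALSE), c(k, 10 - k))), logical(1))
  expect_true(all(diff(kept) >= 0))
})

test_that("audited words failing the rule are dropped from their category", {
  lex <- mini_lexicon()
  emb <- local({
    set.seed(1)
    words <- c(unlist(lexiconCategories(lex), use.names = FALSE), "love")
    corp <- list(TokenizedPlay("p", sample(words, 2000, TRUE),
                               rep("noun", 2000)))
    trainEmbeddings(corp, dims = 10, window = 3, minCount = 2)
  })
  rep1 <- neighborReport(lex, emb, k = 10)
  rep1$flag <- TRUE
  rep1$flag[rep1$word == "jealousy"] <- FALSE
  lex2 <- auditLexicon(lex, rep1)
  expect_false("jealousy" %in% lexiconCategories(lex2)$passionate_feelings)
  expect_true("passion" %in% lexiconCategories(lex2)$passionate_feelings)
})

test_that("lexicon JSON round-trips and disjointness is enforced on load", {
  lex <- mini_lexicon()
  dir <- withr::local_tempdir()
  p <- file.path(dir, "lex.json")
  writeLexicon(lex, p)
  back <- readLexicon(p)
  expect_identical(lexiconSeeds(back), lexiconSeeds(lex))
  expect_identical(lexiconCategories(back), lexiconCategories(lex))
  expect_identical(lexiconRoles(back), lexiconRoles(lex))
  # a word in two categories is rejected
  j <- jsonlite::read_json(p, simplifyVector = TRUE)
  j$categories$sensuality <- c(j$categories$sensuality, "tenderness")
  p2 <- file.path(dir, "bad.json")
  jsonlite::write_json(j, p2, auto_unbox = TRUE)
  expect_error(readLexicon(p2), "two categories")
  # seed lemmas are removed from category lists on construction
  cats <- lexiconCategories(lex)
  cats$tender_feelings <- c(cats$tender_feelings, "love")
  relex <- Lexicon("english", lexiconSeeds(lex), cats)
  expect_false("love" %in% lexiconCategories(relex)$tender_feelings)
})
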