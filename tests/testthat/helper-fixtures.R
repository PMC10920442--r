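# Shared fixtures and independent oracles.

# Brute-force window-count oracle: double loop over (seed occurrence,
# token position) pairs on the filtered subsequence. Independent of the
# package's window machinery.
brute_category_counts <- function(lemma, pos, lexicon, window = 3,
                                  rawTokens = FALSE) {
  seeds <- lexiconSeeds(lexicon)
  keep <- if (rawTokens) rep(TRUE, length(lemma)) else
    (pos %in% c("noun", "adjective") | lemma %in% seeds)
  lem <- lemma[keep]
  counts <- setNames(integer(10), names(lexiconCategories(lexicon)))
  seed_pos <- which(lem %in% seeds)
  for (s in seed_pos) {
    for (t in seq_along(lem)) {
      if (t == s) next
      if (abs(t - s) > window) next
      for (cat in names(counts)) {
        if (lem[t] %in% lexiconCategories(lexicon)[[cat]])
          counts[[cat]] <- counts[[cat]] + 1L
      }
    }
  }
  counts
}

# Random token fixture over a small vocabulary mixing seeds, category
# words and filler, with random POS tags.
random_token_play <- function(n, lexicon, id = "rp") {
  words <- c(lexiconSeeds(lexicon),
             unlist(lexiconCategories(lexicon), use.names = FALSE),
             paste0("filler", letters[1:8]))
  lemma <- sample(words, n, replace = TRUE)
  pos <- sample(c("noun", "adjective", "verb"), n, replace = TRUE,
                prob = c(0.5, 0.3, 0.2))
  TokenizedPlay(id, lemma, pos)
}

mini_lexicon <- function() defaultLexicon("english")

# Lexicon with tender and passion word lists exchanged (categories stay
# canonical).
swapped_lexicon <- function(lex = mini_lexicon()) {
  cats <- lexiconCategories(lex)
  tmp <- cats$tender_feelings
  cats$tender_feelings <- cats$passionate_feelings
  cats$passionate_feelings <- tmp
  Lexicon(lex@language, lexiconSeeds(lex), cats, lexiconRoles(lex))
}

# Small synthetic corpus reused across scoring tests.
demo_corpus <- function(nPlays = 120, seed = 11, lengthMean = 1500,
                        ...) {
  spec <- corpusSpec(nPlays = nPlays, nAuthors = 20,
                     lengthMean = lengthMean, ...)
  generateCorpus(spec, seed = seed)
}

write_play_txt <- function(lines, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- tempfile("play", tmpdir = dir, fileext = ".txt")
  writeLines(lines, path)
  path
}

# Rendered on-disk corpus + manifest + economy CSV for pipeline tests.
make_mini_fixture <- function(dir, nPlays = 40, seed = 123) {
  spec <- corpusSpec(nPlays = nPlays, nAuthors = 8, lengthMean = 500,
                     yearRange = c(1550L, 1800L))
  cor1 <- generateCorpus(spec, seed = seed)
  corpus_dir <- file.path(dir, "corpus")
  dir.create(corpus_dir, showWarnings = FALSE)
  paths <- character(nPlays)
  for (i in seq_len(nPlays)) {
    paths[i] <- file.path(corpus_dir, paste0(cor1$metadata$play_id[i], ".txt"))
    writeLines(renderPlayText(cor1$tokens[[i]]), paths[i])
  }
  manifest <- data.frame(path = paths, id = cor1$metadata$play_id,
                         title = paste("A Comedy of",
                                       cor1$metadata$play_id),
                         author = cor1$metadata$author,
                         year = cor1$metadata$year, language = "english")
  mpath <- file.path(dir, "manifest.csv")
  write.csv(manifest, mpath, row.names = FALSE)
  ec <- generateEconomy(economySpec(), seed = seed + 1)
  spath <- file.path(dir, "econ.csv")
  write.csv(data.frame(year = seriesYears(ec), value = seriesValues(ec)),
            spath, row.names = FALSE)
  list(manifest = mpath, econ = spath, corpus = cor1)
}
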