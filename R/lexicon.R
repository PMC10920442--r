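# Lexicon construction and curation: seed sets, the ten category word
# lists, candidate extraction near seeds, count-based word embeddings for
# the semantic audit, and the majority retention rule.

#' Default mini-lexicon
#'
#' A small starter lexicon: the four English seed lemmas (love, lover,
#' beloved, loving) and three illustrative words per category. It is
#' intentionally incomplete -- real analyses should supply the full
#' curated word lists via [readLexicon()]. The French seeds are a
#' placeholder pending curation.
#'
#' @param language `"english"` or `"french"`.
#' @return a \linkS4class{Lexicon}.
#' @export
defaultLexicon <- function(language = "english") {
  if (language == "english") {
    Lexicon("english",
      seeds = c("love", "lover", "beloved", "loving"),
      categories = list(
        passionate_feelings   = c("passion", "desire", "jealousy"),
        tender_feelings       = c("tenderness", "affection", "fondness"),
        sensuality            = c("pleasure", "breast", "bosom"),
        discipline_asceticism = c("modest", "chastity", "innocence"),
        physical_qualities    = c("young", "handsome", "beautiful"),
        moral_qualities       = c("noble", "virtue", "judgment"),
        short_relationships   = c("conquest", "adventure", "affair"),
        long_relationships    = c("marriage", "family", "oath"),
        body_parts            = c("hand", "face", "eye"),
        mental_parts          = c("sound", "mind", "reason")
      ))
  } else if (language == "french") {
    Lexicon("french",
      seeds = c("amour", "amant", "amante", "aimer"),
      categories = list(
        passionate_feelings   = c("passion", "ardeur", "jalousie"),
        tender_feelings       = c("tendresse", "affection", "douceur"),
        sensuality            = c("plaisir", "sein", "volupté"),
        discipline_asceticism = c("modestie", "chasteté", "innocence"),
        physical_qualities    = c("jeune", "beau", "belle"),
        moral_qualities       = c("noble", "vertu", "jugement"),
        short_relationships   = c("conquête", "aventure", "intrigue"),
        long_relationships    = c("mariage", "famille", "serment"),
        body_parts            = c("main", "visage", "œil"),
        mental_parts          = c("esprit", "raison", "âme")
      ))
  } else stop("unsupported language: ", language)
}

#' Lexicon JSON serialization
#'
#' Format: `{language, seeds, categories: {name: [words]}, roles}`.
#' Category disjointness and the canonical category set are enforced on
#' load by the class validity check.
#'
#' @param lexicon a \linkS4class{Lexicon}.
#' @param path JSON file path.
#' @return `readLexicon` returns a \linkS4class{Lexicon}.
#' @export
writeLexicon <- function(lexicon, path) {
  jsonlite::write_json(
    list(language = lexicon@language, seeds = lexicon@seeds,
         categories = lexicon@categories,
         roles = as.list(lexicon@roles)),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname writeLexicon
#' @export
readLexicon <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  roles <- unlist(j$roles)
  cats <- lapply(j$categories, as.character)
  Lexicon(j$language, as.character(j$seeds), cats, roles)
}

#' Extract candidate lexicon words near seeds
#'
#' Counts every noun/adjective token occurring within `window` positions
#' of a seed occurrence, the window being measured on the noun/adjective
#' subsequence with seeds retained as anchors (the same window definition
#' used for scoring). Seed lemmas themselves are not reported as
#' candidates. A token falling in the windows of two seeds counts once
#' per window.
#'
#' @param tokenPlays list of \linkS4class{TokenizedPlay}.
#' @param seeds seed lemmas.
#' @param window window half-width (default 3).
#' @param topN maximum table length (default 1000).
#' @param rawTokenWindows if `TRUE`, windows are measured on the raw
#'   content-token sequence instead of the noun/adjective subsequence.
#' @return data.frame `lemma, pos, count`, sorted by count descending,
#'   ties alphabetical.
#' @export
extractCandidates <- function(tokenPlays, seeds, window = 3L, topN = 1000L,
                              rawTokenWindows = FALSE) {
  if (!length(tokenPlays)) stop("tokenized corpus is empty")
  if (!length(seeds)) stop("seeds must be non-empty")
  tally <- new.env(parent = emptyenv())
  any_seed <- FALSE
  for (tp in tokenPlays) {
    w <- window_indices(tp, seeds, window, rawTokenWindows)
    if (!length(w$windows)) next
    any_seed <- TRUE
    for (idx in w$windows) {
      if (!length(idx)) next
      lem <- w$lemma[idx]; pos <- w$pos[idx]
      keep <- pos %in% c("noun", "adjective") & !(lem %in% seeds)
      for (j in which(keep)) {
        key <- paste0(lem[j], "\t", pos[j])
        tally[[key]] <- (if (is.null(tally[[key]])) 0L else tally[[key]]) + 1L
      }
    }
  }
  if (!any_seed) {
    warning("no seed occurrences in corpus; candidate table is empty")
    return(data.frame(lemma = character(), pos = character(),
                      count = integer()))
  }
  keys <- ls(tally)
  if (!length(keys))
    return(data.frame(lemma = character(), pos = character(),
                      count = integer()))
  parts <- strsplit(keys, "\t", fixed = TRUE)
  d <- data.frame(lemma = vapply(parts, `[`, "", 1),
                  pos = vapply(parts, `[`, "", 2),
                  count = vapply(keys, function(k) tally[[k]], integer(1)),
                  row.names = NULL)
  d <- d[order(-d$count, d$lemma), , drop = FALSE]
  rownames(d) <- NULL
  head(d, topN)
}

#' Train count-based word embeddings on a tokenized corpus
#'
#' Embeddings are built from positive pointwise mutual information (PPMI)
#' weighted co-occurrence counts within a symmetric context window,
#' factorized by truncated singular value decomposition. This count-based
#' construction answers the same nearest-neighbour queries as predictive
#' embeddings and is exactly deterministic for a fixed corpus.
#'
#' @param tokenPlays list of \linkS4class{TokenizedPlay}; co-occurrence
#'   is counted within plays only.
#' @param dims embedding dimensionality (default 100, capped at
#'   vocabulary size - 1).
#' @param window symmetric context window in content tokens (default 5).
#' @param minCount minimum corpus frequency for a word to enter the
#'   vocabulary (default 5).
#' @param maxVocab vocabulary cap; most frequent words kept.
#' @param seed recorded on the handle for provenance (the construction
#'   itself is deterministic).
#' @return an object of class `WordEmbedding`: list with `vectors`
#'   (words x dims matrix), `vocabCount`, and the training parameters.
#' @export
trainEmbeddings <- function(tokenPlays, dims = 100L, window = 5L,
                            minCount = 5L, maxVocab = 5000L, seed = NULL) {
  lemmas <- unlist(lapply(tokenPlays, function(tp) tp@lemma), use.names = FALSE)
  counts <- sort(table(lemmas), decreasing = TRUE)
  vocab <- names(counts)[counts >= minCount]
  if (length(vocab) > maxVocab) vocab <- vocab[seq_len(maxVocab)]
  V <- length(vocab)
  if (V < 5L)
    stop("vocabulary below minimum size (", V, " words with count >= ",
         minCount, ")")
  idx <- setNames(seq_len(V), vocab)
  ii <- integer(0); jj <- integer(0)
  for (tp in tokenPlays) {
    s <- unname(idx[tp@lemma])
    n <- length(s)
    if (n < 2L) next
    for (k in seq_len(min(window, n - 1L))) {
      a <- s[seq_len(n - k)]; b <- s[seq_len(n - k) + k]
      ok <- !is.na(a) & !is.na(b)
      ii <- c(ii, a[ok], b[ok]); jj <- c(jj, b[ok], a[ok])
    }
  }
  if (!length(ii)) stop("no co-occurrences collected")
  X <- Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(V, V))
  total <- sum(X)
  rs <- Matrix::rowSums(X)
  Xt <- as(X, "TsparseMatrix")
  pmi <- log((Xt@x * total) / (rs[Xt@i + 1L] * rs[Xt@j + 1L]))
  keep <- pmi > 0
  P <- matrix(0, V, V)
  P[cbind(Xt@i[keep] + 1L, Xt@j[keep] + 1L)] <- pmi[keep]
  d <- min(dims, V - 1L)
  sv <- svd(P, nu = d, nv = 0)
  vec <- sv$u * rep(sqrt(sv$d[seq_len(d)]), each = V)
  # sign convention: largest-magnitude loading of each dimension positive
  for (j in seq_len(d)) {
    m <- which.max(abs(vec[, j]))
    if (vec[m, j] < 0) vec[, j] <- -vec[, j]
  }
  rownames(vec) <- vocab
  structure(list(vectors = vec, vocabCount = counts[vocab],
                 dims = d, window = window, minCount = minCount,
                 seed = seed),
            class = "WordEmbedding")
}

#' @export
print.WordEmbedding <- function(x, ...) {
  cat("WordEmbedding:", nrow(x$vectors), "words x", x$dims,
      "dims (window", x$window, ", minCount", x$minCount, ")\n")
  invisible(x)
}

#' Nearest neighbours of a word in the embedding space
#'
#' @param embedding a `WordEmbedding` from [trainEmbeddings()].
#' @param word query lemma.
#' @param k number of neighbours.
#' @return list with `word`, `inVocab`, and (when in vocabulary) a
#'   data.frame `neighbor, similarity` of the `k` nearest words by cosine
#'   similarity (non-increasing; ties alphabetical). Out-of-vocabulary
#'   queries return `inVocab = FALSE`, never an error.
#' @export
nearestNeighbors <- function(embedding, word, k = 10L) {
  M <- embedding$vectors
  if (!word %in% rownames(M))
    return(list(word = word, inVocab = FALSE,
                neighbors = data.frame(neighbor = character(),
                                       similarity = numeric())))
  v <- M[word, ]
  nrm <- sqrt(rowSums(M^2))
  sims <- as.numeric(M %*% v) / (nrm * sqrt(sum(v^2)))
  sims[nrm == 0] <- -Inf
  names(sims) <- rownames(M)
  sims <- sims[names(sims) != word]
  ord <- order(-sims, names(sims))
  top <- ord[seq_len(min(k, length(ord)))]
  list(word = word, inVocab = TRUE,
       neighbors = data.frame(neighbor = names(sims)[top],
                              similarity = unname(sims[top])))
}

#' Neighbour audit report for a lexicon
#'
#' For every category word, its `k` nearest embedding neighbours with
#' cosine similarities. The `flag` column (is this neighbour consistent
#' with the category concept?) is left `NA` for human curation; fill it
#' in, then apply [applyRetentionRule()] per word via [auditLexicon()].
#'
#' @param lexicon a \linkS4class{Lexicon}.
#' @param embedding a `WordEmbedding`.
#' @param k neighbours per word (default 10).
#' @return data.frame `category, word, inVocab, rank, neighbor,
#'   similarity, flag`. Out-of-vocabulary words get one row with
#'   `inVocab = FALSE` and no neighbours.
#' @export
neighborReport <- function(lexicon, embedding, k = 10L) {
  rows <- list()
  for (cat in names(lexicon@categories)) {
    for (w in lexicon@categories[[cat]]) {
      nn <- nearestNeighbors(embedding, w, k)
      if (!nn$inVocab) {
        rows[[length(rows) + 1L]] <- data.frame(
          category = cat, word = w, inVocab = FALSE, rank = NA_integer_,
          neighbor = NA_character_, similarity = NA_real_, flag = NA)
      } else {
        nb <- nn$neighbors
        rows[[length(rows) + 1L]] <- data.frame(
          category = cat, word = w, inVocab = TRUE,
          rank = seq_len(nrow(nb)), neighbor = nb$neighbor,
          similarity = nb$similarity, flag = NA)
      }
    }
  }
  do.call(rbind, rows)
}

#' Write / read a neighbour report as TSV
#' @param report data.frame from [neighborReport()].
#' @param path TSV path.
#' @export
writeNeighborReport <- function(report, path) {
  utils::write.table(report, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeNeighborReport
#' @export
readNeighborReport <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Majority retention rule for audited lexicon words
#'
#' A word is kept iff strictly more than `threshold` of its `k`
#' reviewed neighbours were flagged consistent with the intended concept
#' (default: more than 5 of 10).
#'
#' @param flags logical vector of length `k`: reviewer consistency
#'   judgments for one word's neighbours.
#' @param threshold keep requires `sum(flags) > threshold`.
#' @param k expected number of flags.
#' @return `TRUE` (keep) or `FALSE` (drop).
#' @export
applyRetentionRule <- function(flags, threshold = 5L, k = 10L) {
  if (length(flags) != k)
    stop("expected ", k, " reviewer flags, got ", length(flags))
  sum(as.logical(flags), na.rm = TRUE) > threshold
}

#' Apply a completed neighbour audit to a lexicon
#'
#' Words whose reviewed flags fail [applyRetentionRule()] are removed
#' from their category. Words out of vocabulary, or with unreviewed
#' (`NA`) flags, are kept unchanged.
#'
#' @param lexicon a \linkS4class{Lexicon}.
#' @param report audited data.frame (the `flag` column filled in).
#' @param threshold,k see [applyRetentionRule()].
#' @return a new \linkS4class{Lexicon}.
#' @export
auditLexicon <- function(lexicon, report, threshold = 5L, k = 10L) {
  cats <- lexicon@categories
  for (cat in names(cats)) {
    sub <- report[report$category == cat & report$inVocab, , drop = FALSE]
    for (w in unique(sub$word)) {
      flags <- sub$flag[sub$word == w]
      if (length(flags) != k || anyNA(flags)) next
      if (!applyRetentionRule(as.logical(flags), threshold, k))
        cats[[cat]] <- setdiff(cats[[cat]], w)
    }
  }
  Lexicon(lexicon@language, lexicon@seeds, cats, lexicon@roles)
}
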