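# Per-play scoring: seed windows, category counts, z-scored frequencies,
# the romantic-love score, inclusion filters, and external dictionary
# ratios.
#
# Window definition shared with candidate extraction: counting runs on
# the noun/adjective subsequence of the content tokens, with seed
# occurrences retained as anchors regardless of their tagged part of
# speech. For each seed occurrence the window is the <= `window` items
# before and after it in that subsequence, the seed itself excluded.
# Other seeds falling inside a window appear in the bag but are never
# category words (seed lemmas are removed from categories on Lexicon
# construction).

# Returns the filtered sequence (lemma, pos) and a list of index vectors,
# one per seed occurrence, of window positions in that sequence.
window_indices <- function(tokens, seeds, window = 3L, rawTokens = FALSE) {
  lem <- tokens@lemma; pos <- tokens@pos
  if (rawTokens) {
    keep <- rep(TRUE, length(lem))
  } else {
    keep <- pos %in% c("noun", "adjective") | lem %in% seeds
  }
  lem <- lem[keep]; pos <- pos[keep]
  seed_at <- which(lem %in% seeds)
  n <- length(lem)
  windows <- lapply(seed_at, function(i) {
    lo <- max(1L, i - window); hi <- min(n, i + window)
    setdiff(seq(lo, hi), i)
  })
  list(lemma = lem, pos = pos, windows = windows, seedPositions = seed_at)
}

#' Seed windows of a tokenized play
#'
#' @param tokens a \linkS4class{TokenizedPlay}.
#' @param seeds seed lemmas.
#' @param window half-width (default 3); must be >= 1.
#' @param rawTokens if `TRUE`, windows are measured on the full content
#'   token sequence instead of the noun/adjective subsequence.
#' @return list of character vectors: for each seed occurrence (in text
#'   order), the bag of window tokens. Windows at text edges truncate.
#' @export
seedWindows <- function(tokens, seeds, window = 3L, rawTokens = FALSE) {
  if (window < 1L) stop("window must be >= 1")
  w <- window_indices(tokens, seeds, window, rawTokens)
  lapply(w$windows, function(idx) w$lemma[idx])
}

#' Count category words in seed windows
#'
#' Each token occurrence in a window increments the category containing
#' its lemma; a token inside two overlapping windows counts once per
#' window. Tokens in no category are ignored.
#'
#' @param windows list of window bags from [seedWindows()].
#' @param lexicon a \linkS4class{Lexicon}.
#' @param uniquePositions if `TRUE`, a token position is counted at most
#'   once even when covered by several windows (requires windows carrying
#'   position attributes; used via [scoreCorpus()]).
#' @return named integer vector over the ten canonical categories.
#' @export
countCategories <- function(windows, lexicon, uniquePositions = FALSE) {
  counts <- setNames(integer(length(CANONICAL_CATEGORIES)),
                     CANONICAL_CATEGORIES)
  if (!length(windows)) return(counts)
  bag <- unlist(windows, use.names = FALSE)
  if (!length(bag)) return(counts)
  for (cat in CANONICAL_CATEGORIES) {
    counts[[cat]] <- sum(bag %in% lexicon@categories[[cat]])
  }
  counts
}

count_play <- function(tokens, lexicon, window = 3L, rawTokens = FALSE,
                       uniquePositions = FALSE) {
  w <- window_indices(tokens, lexiconSeeds(lexicon), window, rawTokens)
  idx <- if (uniquePositions) {
    list(unique(unlist(w$windows, use.names = FALSE)))
  } else w$windows
  counts <- setNames(integer(length(CANONICAL_CATEGORIES)),
                     CANONICAL_CATEGORIES)
  bag <- w$lemma[unlist(idx, use.names = FALSE)]
  for (cat in CANONICAL_CATEGORIES)
    counts[[cat]] <- sum(bag %in% lexicon@categories[[cat]])
  counts
}

#' PlayScoreSet: per-play category counts, frequencies and scores
#'
#' Extends \linkS4class{SummarizedExperiment}: rows are the ten
#' categories (rowData carries the role labels), columns are plays.
#' Assays `counts` (near-seed category counts) and `freq` (counts divided
#' by the play's content-token total). Per-play metadata and scores live
#' in `colData`: `play_id, year, author, n_content_tokens, z_tender,
#' z_passion, romantic_love, included, exclusion_reason`.
#'
#' @exportClass PlayScoreSet
setClass("PlayScoreSet", contains = "SummarizedExperiment")

setValidity("PlayScoreSet", function(object) {
  msg <- NULL
  need <- c("play_id", "year", "author", "n_content_tokens",
            "z_tender", "z_passion", "romantic_love", "included",
            "exclusion_reason")
  if (!all(need %in% names(SummarizedExperiment::colData(object))))
    msg <- c(msg, "colData must carry play metadata and score columns")
  if (!all(c("counts", "freq") %in%
           SummarizedExperiment::assayNames(object)))
    msg <- c(msg, "assays 'counts' and 'freq' required")
  fr <- SummarizedExperiment::assay(object, "freq")
  if (length(fr) && (min(fr) < 0 || max(fr) > 1))
    msg <- c(msg, "frequencies must lie in [0, 1]")
  if (is.null(msg)) TRUE else msg
})

# sample-sd z-score; a zero-variance vector maps to zeros (all plays
# identical on that dimension carry no signal)
z_sample <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

#' Score a tokenized corpus
#'
#' Computes near-seed category counts and frequencies per play, applies
#' the two inclusion steps, and derives the romantic-love score:
#' \enumerate{
#'   \item frequency = near-seed count / content tokens of the play;
#'   \item step A: drop plays missing any required category (all ten by
#'     default; `mode = "tender_passion"` requires only the two core
#'     categories, the configuration used for sparser corpora);
#'   \item z-score tender and passion frequencies across step-A
#'     survivors (sample standard deviation);
#'   \item romantic_love = z_tender - z_passion;
#'   \item step B: drop plays whose romantic-love score is an outlier
#'     (|z| > `outlierZ` across survivors). Scores are not
#'     re-standardized after removal, keeping them on the pre-removal
#'     scale.
#' }
#'
#' @param tokenPlays list of \linkS4class{TokenizedPlay}.
#' @param lexicon a \linkS4class{Lexicon}.
#' @param metadata data.frame with columns `play_id, year, author`
#'   matching the token plays by `play_id`.
#' @param window seed-window half-width (default 3).
#' @param mode `"all"` (all ten categories required) or
#'   `"tender_passion"`.
#' @param outlierZ outlier threshold on the romantic-love z-score
#'   (default 3).
#' @param rawTokenWindows,uniquePositions window variants; see
#'   [seedWindows()] and [countCategories()].
#' @param zBeforeFilter if `TRUE`, z-scores are computed across all
#'   plays before the step-A category filter (sensitivity variant; the
#'   default filters first, then standardizes).
#' @return a \linkS4class{PlayScoreSet} containing every play; excluded
#'   plays carry `included = FALSE` and an `exclusion_reason`.
#' @export
scoreCorpus <- function(tokenPlays, lexicon, metadata, window = 3L,
                        mode = c("all", "tender_passion"), outlierZ = 3,
                        rawTokenWindows = FALSE, uniquePositions = FALSE,
                        zBeforeFilter = FALSE) {
  mode <- match.arg(mode)
  if (!length(tokenPlays)) stop("corpus is empty")
  ids <- vapply(tokenPlays, function(tp) tp@playId, character(1))
  m <- metadata[match(ids, metadata$play_id), , drop = FALSE]
  if (anyNA(m$play_id))
    stop("metadata missing for plays: ",
         paste(ids[is.na(m$play_id)], collapse = ", "))
  counts <- vapply(tokenPlays, count_play, numeric(length(CANONICAL_CATEGORIES)),
                   lexicon = lexicon, window = window,
                   rawTokens = rawTokenWindows,
                   uniquePositions = uniquePositions)
  counts <- matrix(as.integer(counts), nrow = length(CANONICAL_CATEGORIES),
                   dimnames = list(CANONICAL_CATEGORIES, ids))
  ntok <- vapply(tokenPlays, nContentTokens, integer(1))
  if (any(ntok == 0L)) stop("plays with zero content tokens: ",
                            paste(ids[ntok == 0L], collapse = ", "))
  freq <- sweep(counts, 2, ntok, "/")

  required <- if (mode == "all") CANONICAL_CATEGORIES else
    c("tender_feelings", "passionate_feelings")
  stepA <- colSums(counts[required, , drop = FALSE] > 0) == length(required)
  if (sum(stepA) < 3L)
    stop("corpus too small: fewer than 3 plays pass the category filter")

  z_t <- z_p <- rep(NA_real_, length(ids))
  basis <- if (zBeforeFilter) rep(TRUE, length(ids)) else stepA
  z_against <- function(x, basis) {
    s <- sd(x[basis])
    if (!is.finite(s) || s == 0) return(rep(0, length(x)))
    (x - mean(x[basis])) / s
  }
  zt_all <- z_against(freq["tender_feelings", ], basis)
  zp_all <- z_against(freq["passionate_feelings", ], basis)
  z_t[stepA] <- zt_all[stepA]
  z_p[stepA] <- zp_all[stepA]
  rl <- z_t - z_p

  zrl <- rep(NA_real_, length(ids))
  zrl[stepA] <- z_sample(rl[stepA])
  outlier <- stepA & abs(zrl) > outlierZ
  included <- stepA & !outlier
  reason <- ifelse(!stepA, "missing_category",
                   ifelse(outlier, "outlier", "none"))

  cd <- S4Vectors::DataFrame(
    play_id = ids, year = as.integer(m$year), author = as.character(m$author),
    n_content_tokens = ntok, z_tender = z_t, z_passion = z_p,
    romantic_love = rl, included = included, exclusion_reason = reason,
    row.names = ids)
  rd <- S4Vectors::DataFrame(category = CANONICAL_CATEGORIES,
                             role = unname(lexiconRoles(lexicon)),
                             row.names = CANONICAL_CATEGORIES)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts, freq = freq), colData = cd, rowData = rd)
  new("PlayScoreSet", se)
}

#' @describeIn scoreCorpus romantic-love scores (named by play id)
#' @param x a PlayScoreSet.
#' @export
romanticLove <- function(x) {
  setNames(SummarizedExperiment::colData(x)$romantic_love,
           SummarizedExperiment::colData(x)$play_id)
}

#' @describeIn scoreCorpus logical inclusion flags
#' @export
includedPlays <- function(x) {
  setNames(SummarizedExperiment::colData(x)$included,
           SummarizedExperiment::colData(x)$play_id)
}

#' Flat score table of a PlayScoreSet
#'
#' One row per play: metadata, ten `count_*` columns, ten `freq_*`
#' columns, z-scores, romantic-love score and inclusion flags. This is
#' the on-disk format of [writeScoresTable()].
#'
#' @param x a \linkS4class{PlayScoreSet}.
#' @return data.frame.
#' @export
scoreTable <- function(x) {
  cd <- as.data.frame(SummarizedExperiment::colData(x))
  counts <- t(SummarizedExperiment::assay(x, "counts"))
  freq <- t(SummarizedExperiment::assay(x, "freq"))
  colnames(counts) <- paste0("count_", colnames(counts))
  colnames(freq) <- paste0("freq_", colnames(freq))
  out <- cbind(cd[c("play_id", "year", "author", "n_content_tokens")],
               as.data.frame(counts), as.data.frame(freq),
               cd[c("z_tender", "z_passion", "romantic_love", "included",
                    "exclusion_reason")])
  rownames(out) <- NULL
  out
}

setMethod("show", "PlayScoreSet", function(object) {
  cd <- SummarizedExperiment::colData(object)
  cat("PlayScoreSet:", ncol(object), "plays x", nrow(object), "categories\n")
  cat("  included:", sum(cd$included), " excluded:",
      sum(!cd$included), "(",
      sum(cd$exclusion_reason == "missing_category"), "missing-category,",
      sum(cd$exclusion_reason == "outlier"), "outlier )\n")
  if (any(cd$included))
    cat("  romantic_love range:",
        sprintf("%.3f .. %.3f", min(cd$romantic_love[cd$included]),
                max(cd$romantic_love[cd$included])), "\n")
})

#' External dictionary ratio per play
#'
#' Whole-text counting (not seed-windowed): each play's frequency of
#' words in two dictionary categories, combined as z(freq A) - z(freq B)
#' across the corpus (or a raw quotient via `method = "quotient"`). Used
#' for validation against external category dictionaries such as
#' friends/family/sexual or future/present word lists.
#'
#' @param tokenPlays list of \linkS4class{TokenizedPlay}.
#' @param dictA,dictB character vectors of lowercase words (category A
#'   and B).
#' @param method `"zdiff"` (default) or `"quotient"`
#'   (freq A / freq B, `NA` when B has no matches).
#' @return numeric vector named by play id, with attribute `lowSupport`:
#'   plays with zero matches in both categories.
#' @export
dictionaryRatio <- function(tokenPlays, dictA, dictB,
                            method = c("zdiff", "quotient")) {
  method <- match.arg(method)
  if (!length(dictA) || !length(dictB))
    stop("dictionary categories must be non-empty")
  ids <- vapply(tokenPlays, function(tp) tp@playId, character(1))
  fA <- vapply(tokenPlays, function(tp)
    sum(tp@lemma %in% dictA) / max(1L, length(tp@lemma)), numeric(1))
  fB <- vapply(tokenPlays, function(tp)
    sum(tp@lemma %in% dictB) / max(1L, length(tp@lemma)), numeric(1))
  low <- fA == 0 & fB == 0
  out <- if (method == "zdiff") z_sample(fA) - z_sample(fB) else {
    ifelse(fB > 0, fA / fB, NA_real_)
  }
  names(out) <- ids
  attr(out, "lowSupport") <- ids[low]
  out
}

#' Named dictionary ratios for a corpus
#'
#' @param tokenPlays list of \linkS4class{TokenizedPlay}.
#' @param dictionaries named list of word vectors (e.g. `friends`,
#'   `sexual`, `family`, `future`, `present`).
#' @param pairs named list of `c(A, B)` pairs, default the three
#'   validation ratios (friends/sexual, family/sexual, future/present)
#'   for whichever categories are supplied.
#' @param method see [dictionaryRatio()].
#' @return data.frame with `play_id` and one column per ratio.
#' @export
dictionaryRatios <- function(tokenPlays, dictionaries, pairs = NULL,
                             method = "zdiff") {
  if (is.null(pairs)) {
    std <- list(friends_to_sexual = c("friends", "sexual"),
                family_to_sexual = c("family", "sexual"),
                future_to_present = c("future", "present"))
    pairs <- Filter(function(p) all(p %in% names(dictionaries)), std)
  }
  ids <- vapply(tokenPlays, function(tp) tp@playId, character(1))
  out <- data.frame(play_id = ids)
  for (nm in names(pairs)) {
    p <- pairs[[nm]]
    out[[nm]] <- as.numeric(dictionaryRatio(
      tokenPlays, dictionaries[[p[1]]], dictionaries[[p[2]]], method))
  }
  out
}
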