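# Text normalization, POS tagging and lemmatization.
#
# The tagger is rule-based: a shipped exception table for common words,
# suffix heuristics otherwise, and a closed-class word list that is
# dropped. It is deliberately simple, fully deterministic, and its tables
# (inst/extdata/*_en.tsv, *_fr.*) are plain text and editable. Tests pin
# its output on fixtures so any table change is visible.

.tp_cache <- new.env(parent = emptyenv())

tp_table <- function(name, reader) {
  if (is.null(.tp_cache[[name]])) {
    path <- system.file("extdata", name, package = "amorchron")
    if (!nzchar(path)) stop("shipped table not found: ", name)
    .tp_cache[[name]] <- reader(path)
  }
  .tp_cache[[name]]
}

contraction_table <- function(language) {
  fn <- if (language == "french") "contractions_fr.tsv" else "contractions_en.tsv"
  tp_table(fn, function(p)
    read.delim(p, stringsAsFactors = FALSE, quote = ""))
}

function_words <- function(language) {
  fn <- if (language == "french") "function_words_fr.txt" else "function_words_en.txt"
  tp_table(fn, function(p) readLines(p, encoding = "UTF-8", warn = FALSE))
}

pos_exceptions <- function(language) {
  if (language == "french") return(setNames(character(), character()))
  d <- tp_table("pos_exceptions_en.tsv", function(p)
    read.delim(p, stringsAsFactors = FALSE, quote = ""))
  setNames(d$pos, d$word)
}

lemma_exceptions <- function(language) {
  if (language == "french") return(setNames(character(), character()))
  d <- tp_table("lemma_exceptions_en.tsv", function(p)
    read.delim(p, stringsAsFactors = FALSE, quote = ""))
  setNames(d$lemma, d$word)
}

#' Normalize play text
#'
#' Lowercases, expands modern and archaic contractions from the shipped
#' editable table (e.g. e'en to even, 'tis to it is), resolves remaining
#' apostrophe elisions ('d to ed, 'n to en, 'st to est), strips
#' possessive 's, and removes every non-letter symbol. Idempotent.
#'
#' @param text UTF-8 character vector (elements are concatenated).
#' @param language `"english"` or `"french"`.
#' @return a single normalized string of space-separated lowercase words.
#' @export
normalizeText <- function(text, language = "english") {
  x <- paste(text, collapse = " ")
  if (!nzchar(x)) return("")
  x <- tolower(x)
  # typographic apostrophes and accents kept; quotes normalized
  x <- gsub("[‘’ʼ]", "'", x)
  tab <- contraction_table(language)
  # longest forms first so 'twas wins over 't
  tab <- tab[order(-nchar(tab$form)), ]
  for (i in seq_len(nrow(tab))) {
    form <- tab$form[i]
    if (grepl("'$", form)) {
      # elision prefix (th', l', qu'): expand to full word + space
      pat <- paste0("(^|[^a-zà-ÿ])", gsub("'", "'", form, fixed = TRUE))
      x <- gsub(pat, paste0("\\1", tab$expansion[i], " "), x, perl = TRUE)
    } else {
      pat <- paste0("(^|[^a-zà-ÿ'])", form, "($|[^a-zà-ÿ'])")
      # fixed-string core with boundaries; repeat to catch abutting matches
      x <- gsub(pat, paste0("\\1", tab$expansion[i], "\\2"), x, perl = TRUE)
      x <- gsub(pat, paste0("\\1", tab$expansion[i], "\\2"), x, perl = TRUE)
    }
  }
  if (language == "english") {
    x <- gsub("n't($|[^a-zà-ÿ])", " not\\1", x, perl = TRUE)
    x <- gsub("'ll($|[^a-zà-ÿ])", " will\\1", x, perl = TRUE)
    x <- gsub("'re($|[^a-zà-ÿ])", " are\\1", x, perl = TRUE)
    x <- gsub("'ve($|[^a-zà-ÿ])", " have\\1", x, perl = TRUE)
    x <- gsub("'m($|[^a-zà-ÿ])", " am\\1", x, perl = TRUE)
    # early-modern elisions: lov'd -> loved, heav'n -> heaven, lov'st -> lovest
    x <- gsub("([a-zà-ÿ])'d($|[^a-zà-ÿ])", "\\1ed\\2", x, perl = TRUE)
    x <- gsub("([a-zà-ÿ])'n($|[^a-zà-ÿ])", "\\1en\\2", x, perl = TRUE)
    x <- gsub("([a-zà-ÿ])'st($|[^a-zà-ÿ])", "\\1est\\2", x, perl = TRUE)
    x <- gsub("'s($|[^a-zà-ÿ])", "\\1", x, perl = TRUE)   # possessive
  }
  x <- gsub("[^a-zà-ÿ]+", " ", x)
  trimws(gsub(" +", " ", x))
}

tag_word_en <- function(w, exc) {
  if (!is.na(p <- exc[w])) return(unname(p))
  n <- nchar(w)
  if (n > 4 && endsWith(w, "ly")) return("drop")          # adverb
  if (n > 4 && (endsWith(w, "ing") || endsWith(w, "ed"))) return("verb")
  adj_suf <- c("ful", "ous", "ive", "able", "ible", "ish", "less", "est")
  for (s in adj_suf) if (n > nchar(s) + 2 && endsWith(w, s)) return("adjective")
  "noun"
}

tag_word_fr <- function(w) {
  n <- nchar(w)
  if (n > 4 && (endsWith(w, "er") || endsWith(w, "ir"))) return("verb")
  adj_suf <- c("eux", "euse", "ible", "able", "if", "ive")
  for (s in adj_suf) if (n > nchar(s) + 2 && endsWith(w, s)) return("adjective")
  "noun"
}

lemmatize_en <- function(w, pos, exc) {
  if (!is.na(l <- exc[w])) return(unname(l))
  n <- nchar(w)
  restore <- function(stem) {
    m <- nchar(stem)
    if (m >= 3) {
      last2 <- substr(stem, m - 1, m)
      # doubled final consonant from gemination (running -> run)
      if (substr(last2, 1, 1) == substr(last2, 2, 2) &&
          grepl("[bdfglmnprt]", substr(last2, 2, 2)))
        return(substr(stem, 1, m - 1))
      # CVC ending: restore silent e (lov -> love)
      if (grepl("[^aeiou][aeiou][^aeiouwxy]$", stem))
        return(paste0(stem, "e"))
    }
    stem
  }
  if (pos == "verb") {
    if (n > 5 && endsWith(w, "ying")) return(paste0(substr(w, 1, n - 4), "y"))
    if (n > 4 && endsWith(w, "ing")) return(restore(substr(w, 1, n - 3)))
    if (n > 4 && endsWith(w, "ied")) return(paste0(substr(w, 1, n - 3), "y"))
    if (n > 3 && endsWith(w, "ed")) {
      stem <- substr(w, 1, n - 2)
      if (endsWith(stem, "e")) return(stem)        # loved handled below anyway
      return(restore(stem))
    }
    if (n > 3 && endsWith(w, "es")) return(substr(w, 1, n - 2))
    if (n > 2 && endsWith(w, "s") && !endsWith(w, "ss"))
      return(substr(w, 1, n - 1))
    return(w)
  }
  if (pos == "noun") {
    if (n > 4 && endsWith(w, "ies")) return(paste0(substr(w, 1, n - 3), "y"))
    if (n > 4 && (endsWith(w, "ses") || endsWith(w, "xes") || endsWith(w, "zes") ||
                  endsWith(w, "ches") || endsWith(w, "shes")))
      return(substr(w, 1, n - 2))
    if (n > 3 && endsWith(w, "s") && !endsWith(w, "ss") && !endsWith(w, "us") &&
        !endsWith(w, "is"))
      return(substr(w, 1, n - 1))
  }
  w
}

lemmatize_fr <- function(w, pos) {
  n <- nchar(w)
  if (n > 4 && endsWith(w, "aux")) return(paste0(substr(w, 1, n - 3), "al"))
  if (n > 3 && endsWith(w, "s")) return(substr(w, 1, n - 1))
  w
}

#' Tokenize, tag and lemmatize normalized text
#'
#' Whitespace tokenization of [normalizeText()] output, closed-class
#' words dropped, remaining words tagged noun/adjective/verb and
#' lemmatized. Output is restricted to those three parts of speech
#' (content tokens).
#'
#' @param text normalized text (see [normalizeText()]); raw text is
#'   normalized first if it contains characters outside the normal form.
#' @param language `"english"` or `"french"`.
#' @param playId identifier stored on the result.
#' @return a \linkS4class{TokenizedPlay}.
#' @export
tokenizeAndTag <- function(text, language = "english", playId = "play") {
  if (!language %in% c("english", "french"))
    stop("unsupported language: ", language)
  norm <- normalizeText(text, language)
  if (!nzchar(norm)) return(TokenizedPlay(playId))
  words <- strsplit(norm, " ", fixed = TRUE)[[1]]
  fw <- function_words(language)
  words <- words[!(words %in% fw)]
  if (!length(words)) return(TokenizedPlay(playId))
  if (language == "english") {
    pexc <- pos_exceptions(language)
    lexc <- lemma_exceptions(language)
    pos <- vapply(words, tag_word_en, character(1), exc = pexc)
    keep <- pos != "drop"
    words <- words[keep]; pos <- pos[keep]
    lem <- mapply(lemmatize_en, words, pos,
                  MoreArgs = list(exc = lexc), USE.NAMES = FALSE)
  } else {
    pos <- vapply(words, tag_word_fr, character(1))
    lem <- mapply(lemmatize_fr, words, pos, USE.NAMES = FALSE)
  }
  ok <- grepl("^[a-zà-ÿ]+$", lem)
  TokenizedPlay(playId, lem[ok], pos[ok])
}

#' Full preprocessing of a PlayDocument
#'
#' @param play a \linkS4class{PlayDocument}.
#' @return a \linkS4class{TokenizedPlay} carrying the play's id.
#' @export
prepPlay <- function(play) {
  tokenizeAndTag(play@text, language = play@language, playId = play@id)
}
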