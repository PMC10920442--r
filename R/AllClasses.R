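#' @import methods
#' @importFrom stats sd cor var rnorm rpois rnbinom runif aggregate
#'   complete.cases lm lm.fit coef qt qchisq approx setNames factanal
#' @importFrom utils read.csv write.csv read.delim head tail
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

# Canonical category names, in fixed order. The first two carry the
# tender/passion contrast; the remaining eight support internal validation.
CANONICAL_CATEGORIES <- c(
  "passionate_feelings", "tender_feelings", "sensuality",
  "discipline_asceticism", "physical_qualities", "moral_qualities",
  "short_relationships", "long_relationships", "body_parts", "mental_parts"
)

CANONICAL_ROLES <- c(
  passionate_feelings   = "passion",
  tender_feelings       = "tender",
  sensuality            = "validation_desire",
  discipline_asceticism = "validation_emotional",
  physical_qualities    = "validation_desire",
  moral_qualities       = "validation_emotional",
  short_relationships   = "validation_desire",
  long_relationships    = "validation_emotional",
  body_parts            = "validation_desire",
  mental_parts          = "validation_emotional"
)

#' PlayDocument: one play's spoken text plus metadata
#'
#' Container for a single play after ingestion: spoken text only
#' (speaker labels, stage directions, prologue and epilogue removed),
#' with identifying metadata.
#'
#' @slot id unique identifier within a corpus.
#' @slot title play title as given in the source.
#' @slot author author name; `"unknown"` is permitted.
#' @slot year integer year CE of composition/publication.
#' @slot language `"english"` or `"french"`.
#' @slot text spoken text only, single character string.
#' @slot sourceFormat `"xml"` or `"txt"`.
#' @exportClass PlayDocument
setClass("PlayDocument",
  representation(
    id = "character", title = "character", author = "character",
    year = "integer", language = "character", text = "character",
    sourceFormat = "character"
  )
)

setValidity("PlayDocument", function(object) {
  msg <- NULL
  if (length(object@id) != 1L || !nzchar(object@id))
    msg <- c(msg, "id must be a single non-empty string")
  if (!object@language %in% c("english", "french"))
    msg <- c(msg, "language must be 'english' or 'french'")
  if (!object@sourceFormat %in% c("xml", "txt"))
    msg <- c(msg, "sourceFormat must be 'xml' or 'txt'")
  if (length(object@text) != 1L || !nzchar(trimws(object@text)))
    msg <- c(msg, "text must be non-empty after stripping")
  if (is.null(msg)) TRUE else msg
})

#' Construct a PlayDocument
#'
#' @param id,title,author,year,language,text,sourceFormat see
#'   \linkS4class{PlayDocument} slots.
#' @param yearRange allowed year range; years outside it are rejected.
#' @return a \linkS4class{PlayDocument}.
#' @export
PlayDocument <- function(id, title, author = "unknown", year, language = "english",
                         text, sourceFormat = "txt", yearRange = c(1500L, 1900L)) {
  year <- as.integer(year)
  if (is.na(year))
    stop("PlayDocument requires a year; undated plays are rejected (id: ", id, ")")
  if (year < yearRange[1] || year > yearRange[2])
    stop("year ", year, " outside allowed range [", yearRange[1], ", ",
         yearRange[2], "] (id: ", id, ")")
  new("PlayDocument", id = as.character(id), title = as.character(title),
      author = as.character(author), year = year, language = language,
      text = text, sourceFormat = sourceFormat)
}

setMethod("show", "PlayDocument", function(object) {
  cat("PlayDocument '", object@id, "': ", object@title, " (",
      object@author, ", ", object@year, ", ", object@language, ")\n",
      "  ", nchar(object@text), " characters of spoken text\n", sep = "")
})

#' TokenizedPlay: lemmatized, POS-filtered token sequence
#'
#' Ordered content tokens (nouns, adjectives, verbs) of one play after
#' normalization, tagging and lemmatization.
#'
#' @slot playId play identifier.
#' @slot lemma lowercase lemmas, in text order.
#' @slot pos one of `"noun"`, `"adjective"`, `"verb"` per token.
#' @exportClass TokenizedPlay
setClass("TokenizedPlay",
  representation(playId = "character", lemma = "character", pos = "character")
)

setValidity("TokenizedPlay", function(object) {
  msg <- NULL
  if (length(object@lemma) != length(object@pos))
    msg <- c(msg, "lemma and pos must have the same length")
  if (length(object@lemma) && !all(object@pos %in% c("noun", "adjective", "verb")))
    msg <- c(msg, "pos values must be noun/adjective/verb")
  if (length(object@lemma) && !all(grepl("^[a-zà-ÿ]+$", object@lemma)))
    msg <- c(msg, "lemmas must be non-empty lowercase alphabetic")
  if (is.null(msg)) TRUE else msg
})

#' @rdname TokenizedPlay-class
#' @param playId play identifier.
#' @param lemma,pos parallel token vectors.
#' @export
TokenizedPlay <- function(playId, lemma = character(), pos = character()) {
  new("TokenizedPlay", playId = as.character(playId),
      lemma = as.character(lemma), pos = as.character(pos))
}

#' Number of content tokens in a TokenizedPlay
#' @param x a \linkS4class{TokenizedPlay}.
#' @return integer token count.
#' @export
nContentTokens <- function(x) length(x@lemma)

setMethod("show", "TokenizedPlay", function(object) {
  cat("TokenizedPlay '", object@playId, "': ", length(object@lemma),
      " content tokens\n", sep = "")
})

#' AnnualSeries: a year-indexed numeric series
#'
#' @slot name series name (e.g. `"gdppc"`).
#' @slot years strictly increasing integer years.
#' @slot values numeric values, same length as years.
#' @slot interpolated logical flag per point; `TRUE` where the value was
#'   produced by linear interpolation rather than observed.
#' @exportClass AnnualSeries
setClass("AnnualSeries",
  representation(name = "character", years = "integer", values = "numeric",
                 interpolated = "logical")
)

setValidity("AnnualSeries", function(object) {
  msg <- NULL
  n <- length(object@years)
  if (length(object@values) != n || length(object@interpolated) != n)
    msg <- c(msg, "years, values and interpolated must have equal length")
  if (n > 1 && any(diff(object@years) <= 0))
    msg <- c(msg, "years must be strictly increasing")
  if (n && anyNA(object@values))
    msg <- c(msg, "values must not contain NA inside the declared span")
  if (is.null(msg)) TRUE else msg
})

#' Construct an AnnualSeries
#' @param name series name.
#' @param years integer years (strictly increasing).
#' @param values numeric values.
#' @param interpolated per-point interpolation flags (default all FALSE).
#' @return an \linkS4class{AnnualSeries}.
#' @export
AnnualSeries <- function(name, years, values,
                         interpolated = rep(FALSE, length(years))) {
  new("AnnualSeries", name = as.character(name), years = as.integer(years),
      values = as.numeric(values), interpolated = as.logical(interpolated))
}

#' @describeIn AnnualSeries years accessor
#' @param x an AnnualSeries.
#' @export
seriesYears <- function(x) x@years

#' @describeIn AnnualSeries values accessor
#' @export
seriesValues <- function(x) x@values

#' @describeIn AnnualSeries name accessor
#' @export
seriesName <- function(x) x@name

#' @describeIn AnnualSeries interpolation-flag accessor
#' @export
seriesInterpolated <- function(x) x@interpolated

setMethod("show", "AnnualSeries", function(object) {
  n <- length(object@years)
  cat("AnnualSeries '", object@name, "': ", n, " points", sep = "")
  if (n) cat(" (", min(object@years), "-", max(object@years), "), ",
             sum(object@interpolated), " interpolated", sep = "")
  cat("\n")
})

#' @export
#' @method as.data.frame AnnualSeries
as.data.frame.AnnualSeries <- function(x, ...) {
  data.frame(year = x@years, value = x@values, interpolated = x@interpolated)
}

setMethod("length", "AnnualSeries", function(x) length(x@years))

#' Lexicon: seed words plus ten category word lists
#'
#' The ten canonical categories must all be present; no word may appear
#' in two categories, and seed lemmas are removed from category lists on
#' construction so that a seed inside another seed's window is never
#' counted as a category word.
#'
#' @slot language `"english"` or `"french"`.
#' @slot seeds seed lemmas anchoring the counting windows.
#' @slot categories named list of lowercase lemma vectors; names are the
#'   ten canonical categories.
#' @slot roles named character: role per category (tender, passion,
#'   validation_emotional, validation_desire).
#' @exportClass Lexicon
setClass("Lexicon",
  representation(language = "character", seeds = "character",
                 categories = "list", roles = "character")
)

setValidity("Lexicon", function(object) {
  msg <- NULL
  if (!setequal(names(object@categories), CANONICAL_CATEGORIES))
    msg <- c(msg, paste("categories must be exactly the ten canonical sets:",
                        paste(CANONICAL_CATEGORIES, collapse = ", ")))
  words <- unlist(object@categories, use.names = FALSE)
  if (anyDuplicated(words))
    msg <- c(msg, paste("words present in two categories:",
                        paste(unique(words[duplicated(words)]), collapse = ", ")))
  all_entries <- c(object@seeds, words)
  if (length(all_entries) && !all(grepl("^[a-zà-ÿ]+$", all_entries)))
    msg <- c(msg, "all seeds and category words must be lowercase lemmas")
  if (!length(object@seeds)) msg <- c(msg, "seeds must be non-empty")
  if (is.null(msg)) TRUE else msg
})

#' Construct a Lexicon
#'
#' @param language `"english"` or `"french"`.
#' @param seeds seed lemmas.
#' @param categories named list of word vectors covering the ten
#'   canonical categories.
#' @param roles role label per category; defaults to the canonical roles.
#' @return a \linkS4class{Lexicon}. Seed lemmas are dropped from category
#'   lists so seeds are never counted as category tokens.
#' @export
Lexicon <- function(language, seeds, categories, roles = CANONICAL_ROLES) {
  categories <- categories[CANONICAL_CATEGORIES]
  names(categories) <- CANONICAL_CATEGORIES
  categories <- lapply(categories, function(w) setdiff(tolower(w), tolower(seeds)))
  new("Lexicon", language = language, seeds = tolower(seeds),
      categories = categories, roles = roles[CANONICAL_CATEGORIES])
}

#' @describeIn Lexicon seed-word accessor
#' @param x a Lexicon.
#' @export
lexiconSeeds <- function(x) x@seeds

#' @describeIn Lexicon category-list accessor
#' @export
lexiconCategories <- function(x) x@categories

#' @describeIn Lexicon role accessor
#' @export
lexiconRoles <- function(x) x@roles

setMethod("show", "Lexicon", function(object) {
  cat("Lexicon (", object@language, "): ", length(object@seeds),
      " seeds [", paste(object@seeds, collapse = ", "), "]\n", sep = "")
  for (nm in names(object@categories))
    cat(sprintf("  %-22s (%s): %d words\n", nm, object@roles[[nm]],
                length(object@categories[[nm]])))
})
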