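# Corpus ingestion: title filtering, play parsing (TEI-like XML and plain
# text), manifests, annual series, and tabular score output.

#' Default title keyword lists for corpus curation
#'
#' Include keywords select documents whose titles mark them as plays;
#' exclude keywords remove operas and musicals, which reached a different
#' audience. English and French defaults are provided.
#'
#' @param language `"english"` or `"french"`.
#' @return list with elements `include` and `exclude`.
#' @export
defaultTitleKeywords <- function(language = "english") {
  switch(language,
    english = list(
      include = c("tragedy", "tragic", "comedy", "pastoral", "drama",
                  "theater", "theatrical", "play", "farse", "farce", "comic"),
      exclude = c("opera", "musical")
    ),
    french = list(
      include = c("comédie", "tragédie", "farce", "pastorale",
                  "drame", "parodie", "proverbe"),
      exclude = c("ballet", "musique", "liturgique")
    ),
    stop("unsupported language: ", language)
  )
}

#' Filter titles by inclusion/exclusion keywords
#'
#' A title is kept iff it contains at least one include keyword and no
#' exclude keyword (case-insensitive substring match). Order preserved.
#'
#' @param titles character vector of titles.
#' @param includeKeywords lowercase keywords, at least one required.
#' @param excludeKeywords lowercase keywords whose presence rejects a title.
#' @return logical vector, one flag per title.
#' @export
filterTitles <- function(titles,
                         includeKeywords = defaultTitleKeywords("english")$include,
                         excludeKeywords = defaultTitleKeywords("english")$exclude) {
  if (!length(includeKeywords))
    stop("includeKeywords must be non-empty")
  low <- tolower(titles)
  hit <- function(kws, x) {
    m <- rep(FALSE, length(x))
    for (kw in tolower(kws)) m <- m | grepl(kw, x, fixed = TRUE)
    m
  }
  hit(includeKeywords, low) & !hit(excludeKeywords, low)
}

#' Default stripping configuration for plain-text plays
#'
#' Controls removal of non-spoken text from `.txt` sources: speaker-label
#' lines, bracketed stage directions, and prologue/epilogue sections
#' marked by headings.
#'
#' @return list with regular expressions `speakerLine` (whole lines that
#'   are speaker labels), `direction` (inline bracketed directions),
#'   `sectionHeading` (lines opening a named section), and
#'   `dropSections` (lowercase section names to drop entirely).
#' @export
defaultStripConfig <- function() {
  list(
    # a short ALL-CAPS line, optionally ending with a period: a speaker label
    speakerLine = "^\\s*[A-Z][A-Z' .-]{0,40}\\.?\\s*$",
    direction = "\\[[^]]*\\]|\\([^)]*\\)",
    sectionHeading = "^\\s*(PROLOGUE|EPILOGUE|ACT\\b.*|SCENE\\b.*|DRAMATIS PERSONAE)\\s*\\.?\\s*$",
    dropSections = c("prologue", "epilogue", "dramatis personae")
  )
}

strip_txt <- function(lines, cfg) {
  keep <- rep(TRUE, length(lines))
  section <- ""
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (grepl(cfg$sectionHeading, ln)) {
      word <- tolower(trimws(sub("\\.?\\s*$", "", trimws(ln))))
      section <- if (word %in% cfg$dropSections) word else ""
      keep[i] <- FALSE
      next
    }
    if (section != "") { keep[i] <- FALSE; next }
    if (grepl(cfg$speakerLine, ln)) { keep[i] <- FALSE; next }
  }
  out <- lines[keep]
  out <- trimws(gsub(" +", " ", gsub(cfg$direction, " ", out)))
  paste(out[nzchar(out)], collapse = "\n")
}

strip_xml <- function(path, speechElements = c("sp", "speech"),
                      dropElements = c("speaker", "stage")) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("unparseable XML in ", path, ": ",
                                           conditionMessage(e)))
  # remove speaker names and stage directions wherever they occur
  for (el in dropElements) {
    nodes <- xml2::xml_find_all(doc, paste0(".//", el))
    xml2::xml_remove(nodes)
  }
  sel <- paste(sprintf(".//%s", speechElements), collapse = " | ")
  sp <- xml2::xml_find_all(doc, sel)
  if (!length(sp)) return("")
  paste(trimws(xml2::xml_text(sp)), collapse = "\n")
}

#' Read one play file into a PlayDocument
#'
#' XML sources: text is taken from speech elements only, with speaker and
#' stage-direction elements removed. Plain text sources: speaker-label
#' lines, bracketed directions and configured sections (prologue,
#' epilogue) are stripped per `stripConfig`.
#'
#' @param path file path.
#' @param id,title,author,year,language metadata for the play.
#' @param format `"xml"` or `"txt"`; default guessed from the extension.
#' @param stripConfig see [defaultStripConfig()]; used for txt input.
#' @param speechElements XML element names holding spoken text.
#' @param dropElements XML element names removed before text extraction.
#' @param yearRange allowed year range.
#' @return a \linkS4class{PlayDocument}.
#' @export
readPlay <- function(path, id = basename(path), title = id, author = "unknown",
                     year, language = "english",
                     format = if (grepl("\\.xml$", path, ignore.case = TRUE)) "xml" else "txt",
                     stripConfig = defaultStripConfig(),
                     speechElements = c("sp", "speech"),
                     dropElements = c("speaker", "stage"),
                     yearRange = c(1500L, 1900L)) {
  if (!file.exists(path)) stop("file not found: ", path)
  text <- if (format == "xml") {
    strip_xml(path, speechElements, dropElements)
  } else {
    strip_txt(readLines(path, warn = FALSE, encoding = "UTF-8"), stripConfig)
  }
  if (!nzchar(trimws(text)))
    stop("no spoken text remained after stripping: ", path)
  PlayDocument(id = id, title = title, author = author, year = year,
               language = language, text = text, sourceFormat = format,
               yearRange = yearRange)
}

#' Read a corpus manifest
#'
#' The manifest is a CSV with columns `path, id, title, author, year,
#' language` and an optional `status` column (`allow`/`deny`) for
#' reproducible manual curation. Duplicate plays are removed by
#' (normalized title, author, year), keeping the first by manifest order.
#'
#' @param path manifest CSV path.
#' @param baseDir directory against which relative play paths resolve.
#' @return data.frame of manifest entries (deny-listed and duplicate rows
#'   dropped), with attribute `"dropped"` recording removals.
#' @export
readCorpusManifest <- function(path, baseDir = dirname(path)) {
  m <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("path", "id", "title", "author", "year", "language")
  missing <- setdiff(required, names(m))
  if (length(missing))
    stop("manifest missing columns: ", paste(missing, collapse = ", "))
  if (anyDuplicated(m$id))
    stop("duplicate ids in manifest: ",
         paste(unique(m$id[duplicated(m$id)]), collapse = ", "))
  dropped <- character()
  if ("status" %in% names(m)) {
    deny <- tolower(m$status) == "deny"
    dropped <- c(dropped, m$id[deny])
    m <- m[!deny, , drop = FALSE]
  }
  key <- paste(trimws(gsub("[^a-zà-ÿ0-9]+", " ", tolower(m$title))),
               tolower(m$author), m$year, sep = "|")
  dup <- duplicated(key)
  dropped <- c(dropped, m$id[dup])
  m <- m[!dup, , drop = FALSE]
  m$path <- ifelse(grepl("^(/|[A-Za-z]:)", m$path), m$path,
                   file.path(baseDir, m$path))
  absent <- !file.exists(m$path)
  if (any(absent))
    stop("manifest paths not found: ", paste(m$path[absent], collapse = ", "))
  attr(m, "dropped") <- dropped
  m
}

#' Read all plays listed in a manifest
#'
#' @param manifest data.frame from [readCorpusManifest()].
#' @param ... passed to [readPlay()].
#' @return list of \linkS4class{PlayDocument}.
#' @export
readCorpus <- function(manifest, ...) {
  plays <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    r <- manifest[i, ]
    plays[[i]] <- readPlay(r$path, id = r$id, title = r$title,
                           author = r$author, year = r$year,
                           language = r$language, ...)
  }
  names(plays) <- manifest$id
  plays
}

#' Read an annual series from a two-column CSV
#'
#' @param path CSV with columns `year,value` (extra columns ignored).
#' @param name series name; default derived from the file name.
#' @return an \linkS4class{AnnualSeries} (not interpolated).
#' @export
readAnnualSeries <- function(path, name = sub("\\.[^.]*$", "", basename(path))) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("year", "value") %in% names(d)))
    stop("annual series CSV must have columns year,value: ", path)
  if (anyDuplicated(d$year))
    stop("duplicate years in ", path, ": ",
         paste(unique(d$year[duplicated(d$year)]), collapse = ", "))
  d <- d[order(d$year), ]
  AnnualSeries(name, d$year, d$value)
}

#' Linearly interpolate an annual series onto a finer grid
#'
#' Fills years between observed points by linear interpolation; never
#' extrapolates beyond the endpoints. Newly created points are flagged
#' `interpolated`.
#'
#' @param series an \linkS4class{AnnualSeries}.
#' @param step target year step (default 1).
#' @return an \linkS4class{AnnualSeries} on the full grid.
#' @export
interpolateSeries <- function(series, step = 1L) {
  yrs <- seriesYears(series)
  if (length(yrs) < 2L) return(series)
  grid <- seq(min(yrs), max(yrs), by = step)
  if (identical(as.integer(grid), yrs)) return(series)
  vals <- approx(yrs, seriesValues(series), xout = grid, method = "linear")$y
  interp <- !(grid %in% yrs)
  # points observed keep their original flag
  flags <- seriesInterpolated(series)[match(grid, yrs)]
  flags[interp] <- TRUE
  AnnualSeries(seriesName(series), grid, vals, flags)
}

#' Write / read a play-score table
#'
#' Scores round-trip losslessly at 12 significant digits. The table has
#' one row per play: metadata, ten category counts (`count_*`), ten
#' frequencies (`freq_*`), z-scores, the romantic-love score, and
#' inclusion flags.
#'
#' @param scores data.frame as produced by [scoreTable()].
#' @param path output CSV path.
#' @return `writeScoresTable` returns `path` invisibly; `readScoresTable`
#'   returns the data.frame.
#' @export
writeScoresTable <- function(scores, path) {
  num <- vapply(scores, is.numeric, logical(1)) &
    !vapply(scores, is.integer, logical(1))
  out <- scores
  out[num] <- lapply(out[num], function(x) signif(x, 12))
  write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname writeScoresTable
#' @export
readScoresTable <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
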