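# Reading, normalising and writing condition-mention records and
# per-report condition sets, plus a simple lexicon matcher for demos.

#' Normalize a condition string
#'
#' Lowercases, strips leading/trailing whitespace and collapses internal
#' whitespace runs to single spaces.  Deliberately performs no stemming
#' and no merging of surface variants: "coronavirus" and "corona virus"
#' remain distinct conditions, since merging would change every
#' downstream frequency rank.
#'
#' @param raw Character vector of raw condition strings.
#' @return Character vector of normalized conditions.
#' @export
normalize_condition <- function(raw) {
  if (!is.character(raw)) {
    stop("invalid mention: `raw` must be character", call. = FALSE)
  }
  out <- tolower(gsub("[[:space:]]+", " ", trimws(raw)))
  if (anyNA(out) || any(out == "")) {
    stop("invalid mention: empty condition after normalization",
         call. = FALSE)
  }
  out
}

#' Read a mention table from TSV
#'
#' Expects a tab-separated file with header columns `record_id`, `corpus`
#' and `condition`.  Rows with an empty `record_id` or `condition` are
#' counted, reported via a message and dropped (never silently); if more
#' than half of the rows are malformed the file is rejected.
#'
#' @param path Path to the TSV file.
#' @param corpus_id Optional corpus tag overriding the file's `corpus`
#'   column.
#' @return Data frame of mention records with normalized conditions; the
#'   number of dropped rows is attached as attribute `n_malformed`.
#' @export
read_mentions <- function(path, corpus_id = NULL) {
  if (!file.exists(path)) {
    stop("cannot read mention file: ", path, call. = FALSE)
  }
  raw <- utils::read.delim(path, header = TRUE, colClasses = "character",
                           quote = "", na.strings = character(0),
                           stringsAsFactors = FALSE)
  need <- c("record_id", "corpus", "condition")
  if (!all(need %in% names(raw))) {
    stop("format error: ", path, " must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  cond <- trimws(raw$condition)
  rid <- trimws(raw$record_id)
  bad <- is.na(cond) | cond == "" | is.na(rid) | rid == ""
  if (nrow(raw) > 0 && mean(bad) > 0.5) {
    stop("format error: more than half of the rows in ", path,
         " are malformed", call. = FALSE)
  }
  if (any(bad)) {
    message(sum(bad), " malformed row(s) dropped while reading ", path)
  }
  keep <- !bad
  out <- data.frame(
    record_id = rid[keep],
    corpus = if (is.null(corpus_id)) raw$corpus[keep]
             else rep(corpus_id, sum(keep)),
    condition = if (any(keep)) normalize_condition(cond[keep])
                else character(0),
    stringsAsFactors = FALSE)
  attr(out, "n_malformed") <- sum(bad)
  out
}

#' Write a mention table as TSV
#'
#' @param mentions Data frame with columns `record_id`, `corpus`,
#'   `condition`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mentions <- function(mentions, path) {
  utils::write.table(mentions[, c("record_id", "corpus", "condition")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read dream reports from JSONL
#'
#' One JSON object per line, `{"id": ..., "conditions": [...]}`.
#' Conditions are normalized and deduplicated (set semantics: an edge
#' later counts the number of reports in which two conditions co-occur,
#' so within-report repetition is irrelevant).
#'
#' @param path Path to the JSONL file.
#' @return Named list of character vectors, one per report.
#' @export
read_reports <- function(path) {
  if (!file.exists(path)) {
    stop("cannot read report file: ", path, call. = FALSE)
  }
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  out <- vector("list", length(lines))
  ids <- character(length(lines))
  for (i in seq_along(lines)) {
    obj <- jsonlite::fromJSON(lines[i])
    ids[i] <- as.character(obj$id)
    conds <- as.character(obj$conditions)
    out[[i]] <- if (length(conds) == 0) character(0)
                else sort(unique(normalize_condition(conds)))
  }
  names(out) <- ids
  out
}

#' Write dream reports as JSONL
#'
#' @param reports Named list of character vectors (report id -> condition
#'   set).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_reports <- function(reports, path) {
  ids <- names(reports) %||% sprintf("r%05d", seq_along(reports))
  lines <- vapply(seq_along(reports), function(i) {
    as.character(jsonlite::toJSON(
      list(id = jsonlite::unbox(ids[i]),
           conditions = as.character(reports[[i]]))))
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

regex_escape <- function(x) {
  gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)
}

#' Extract lexicon conditions from free text
#'
#' Case-insensitive longest-match-first scan on word boundaries; a longer
#' phrase suppresses shorter phrases overlapping its span (so "dry cough"
#' hides "cough" at the same position, but a second, free-standing
#' "cough" still matches).  This is demonstration plumbing standing in
#' for a trained medical named-entity extractor, not a replacement
#' for one.
#'
#' @param text A single character string.
#' @param lexicon Character vector of (normalized) condition phrases.
#' @return Sorted character vector of matched conditions (a set).
#' @export
lexicon_extract <- function(text, lexicon) {
  if (!is.character(text) || length(text) != 1L) {
    stop("`text` must be a single string", call. = FALSE)
  }
  lexicon <- unique(as.character(lexicon))
  lexicon <- lexicon[!is.na(lexicon) & nzchar(trimws(lexicon))]
  if (length(lexicon) == 0) return(character(0))
  lexicon <- normalize_condition(lexicon)
  txt <- tolower(gsub("[[:space:]]+", " ", trimws(text)))
  if (!nzchar(txt)) return(character(0))
  found <- character(0)
  for (ph in lexicon[order(-nchar(lexicon), lexicon)]) {
    m <- gregexpr(paste0("\\b", regex_escape(ph), "\\b"), txt,
                  perl = TRUE)[[1]]
    if (m[1] == -1) next
    found <- c(found, ph)
    for (k in seq_along(m)) {
      len <- attr(m, "match.length")[k]
      substr(txt, m[k], m[k] + len - 1L) <- strrep("\x01", len)
    }
  }
  sort(found)
}
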