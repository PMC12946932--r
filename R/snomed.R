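#' Load a SNOMED CT description table
#'
#' Reads an RF2-style tab-separated description file. Only `conceptId` and
#' `term` are required; the usual RF2 columns (`id`, `effectiveTime`,
#' `active`, `moduleId`, `languageCode`, `typeId`, `caseSignificanceId`) are
#' carried through when present. When an `active` column exists, only rows
#' with `active == "1"` are retained. Terms are kept verbatim; matching
#' lowercases on the fly.
#'
#' @param path Path to the TSV file.
#' @return A data.frame of class `snomed_table` (possibly zero rows).
#' @export
load_snomed <- function(path) {
  if (!file.exists(path)) io_error(sprintf("SNOMED description file not found: %s", path))
  df <- utils::read.delim(path, sep = "\t", quote = "", colClasses = "character",
                          stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(c("conceptId", "term"), names(df))
  if (length(miss)) {
    validation_error(sprintf("SNOMED file missing required column(s): %s",
                             paste(miss, collapse = ", ")))
  }
  if ("active" %in% names(df)) df <- df[df$active == "1", , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("snomed_table", "data.frame"))
}

#' Filter SNOMED rows by diagnosis keywords
#'
#' Splits the normalized diagnosis into keywords (stop words removed), builds
#' a case-insensitive alternation anchored at word boundaries, and returns
#' every row whose `term` matches at least one keyword, preserving table
#' order. Word boundaries prevent e.g. "press" from matching "depression".
#'
#' @param diagnosis Diagnosis string (e.g. `"moderate depression"`).
#' @param table A `snomed_table`.
#' @param stopwords Stop-word list.
#' @return Subset of `table` (possibly zero rows).
#' @export
keyword_filter <- function(diagnosis, table, stopwords = default_stopwords()) {
  kws <- preprocess(diagnosis, stopwords = stopwords)
  if (length(kws) == 0L) {
    validation_error("no usable keywords in diagnosis after stop-word removal")
  }
  kws <- unique(kws)
  pattern <- paste0("\\b(?:", paste(escape_regex(kws), collapse = "|"), ")\\b")
  hit <- grepl(pattern, tolower(table$term), perl = TRUE)
  out <- table[hit, , drop = FALSE]
  rownames(out) <- NULL
  out
}

escape_regex <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)

#' Rank candidate SNOMED rows by semantic similarity
#'
#' Embeds the diagnosis and every candidate term (preprocess then mean-pooled
#' embedding) and sorts by cosine similarity, descending. Ties are broken by
#' shorter term, then lexicographically smaller conceptId, so rankings are
#' deterministic across platforms.
#'
#' @param diagnosis Diagnosis string.
#' @param candidates Rows from [keyword_filter()] (>= 1 row).
#' @param embedder A `phq_embedder`.
#' @param stopwords Stop-word list.
#' @return `candidates` reordered, with a `similarity` column appended.
#' @export
rank_candidates <- function(diagnosis, candidates, embedder,
                            stopwords = default_stopwords()) {
  stopifnot(nrow(candidates) >= 1L)
  dvec <- embed_text(diagnosis, embedder, stopwords = stopwords)
  sim <- vapply(candidates$term, function(tm) {
    cosine_similarity(dvec, embed_text(tm, embedder, stopwords = stopwords))
  }, numeric(1), USE.NAMES = FALSE)
  out <- candidates
  out$similarity <- sim
  ord <- order(-sim, nchar(candidates$term), candidates$conceptId)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Attribute a diagnosis to its closest SNOMED CT concept
#'
#' The full candidate-generation-and-rerank attribution: keyword filtering of
#' the description table, cosine-similarity reranking of the candidates, and
#' wrapping of the top row as an attribution record carrying the concept
#' identifier, the matched term, the similarity score and a fixed
#' explanatory message. An optional overrides map (normalized diagnosis
#' string -> conceptId) is consulted first, so clinicians can pin mappings.
#'
#' @param diagnosis Diagnosis string.
#' @param table A `snomed_table`.
#' @param embedder A `phq_embedder`.
#' @param overrides Optional named list/vector mapping diagnosis strings to
#'   conceptIds present in `table`.
#' @param stopwords Stop-word list.
#' @return A `snomed_match` (fields `conceptId`, `term`, `moduleId`,
#'   `languageCode`, `typeId`, `caseSignificanceId`, `similarity`,
#'   `message`, `source`) or a `snomed_nomatch` when no candidate row
#'   matches any keyword.
#' @export
#' @examples
#' tab <- snomed_fixture_table()
#' emb <- make_embedder()
#' attribute("moderate depression", tab, emb)$conceptId
attribute <- function(diagnosis, table, embedder, overrides = NULL,
                      stopwords = default_stopwords()) {
  stopifnot(inherits(table, "snomed_table"))
  if (!is.null(overrides)) {
    key <- normalize_text(diagnosis)
    onames <- normalize_text(names(overrides))
    hit <- match(key, onames)
    if (!is.na(hit)) {
      cid <- as.character(overrides[[hit]])
      row <- table[table$conceptId == cid, , drop = FALSE]
      if (nrow(row) >= 1L) {
        return(as_snomed_match(row[1L, , drop = FALSE], similarity = 1,
                               source = "override"))
      }
    }
  }
  cand <- tryCatch(keyword_filter(diagnosis, table, stopwords = stopwords),
                   phqscreen_validation_error = function(e) NULL)
  if (is.null(cand) || nrow(cand) == 0L) {
    return(structure(
      list(diagnosis = diagnosis,
           message = "No SNOMED CT concept matched any diagnosis keyword."),
      class = "snomed_nomatch"))
  }
  ranked <- rank_candidates(diagnosis, cand, embedder, stopwords = stopwords)
  as_snomed_match(ranked[1L, , drop = FALSE],
                  similarity = ranked$similarity[1L], source = "similarity")
}

as_snomed_match <- function(row, similarity, source) {
  pick <- function(col) if (col %in% names(row)) row[[col]][1L] else NA_character_
  structure(list(
    conceptId = row$conceptId[1L],
    term = row$term[1L],
    moduleId = pick("moduleId"),
    languageCode = pick("languageCode"),
    typeId = pick("typeId"),
    caseSignificanceId = pick("caseSignificanceId"),
    similarity = as.numeric(similarity),
    source = source,
    message = paste("System-generated diagnosis. More information:",
                    "https://www.snomed.org/get-snomed")),
    class = "snomed_match")
}

#' @export
print.snomed_match <- function(x, ...) {
  cat("SNOMED CT attribution\n")
  cat(sprintf("  concept:    %s (conceptId %s)\n", x$term, x$conceptId))
  cat(sprintf("  similarity: %.2f\n", x$similarity))
  cat(sprintf("  %s\n", x$message))
  invisible(x)
}

#' Log a clinician override decision
#'
#' Appends one JSON line (diagnosis, chosen conceptId, timestamp) to an
#' append-only feedback log. The log is an audit trail only; the package
#' never trains on it.
#'
#' @param path Log file path (created if absent).
#' @param diagnosis Diagnosis string reviewed.
#' @param conceptId Concept chosen by the clinician.
#' @return `path`, invisibly.
#' @export
log_feedback <- function(path, diagnosis, conceptId) {
  line <- jsonlite::toJSON(list(diagnosis = diagnosis,
                                conceptId = as.character(conceptId),
                                time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
                           auto_unbox = TRUE)
  cat(line, "\n", sep = "", file = path, append = TRUE)
  invisible(path)
}
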