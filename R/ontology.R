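#' Load a PHQ-9 symptom ontology from CSV
#'
#' The ontology is a lexicon mapping surface phrases to the nine PHQ-9 items
#' S1..S9, optionally with an integer frequency weight on the 0-3 PHQ-9
#' response scale. The CSV must have a header naming at least `item` and
#' `term`; an optional `frequency_weight` column defaults to 1. Item labels
#' may be written `S1`..`S9` or as bare integers 1-9.
#'
#' Terms are lowercased and whitespace-normalized on load. Duplicate
#' `(item, term)` pairs are rejected; the same term listed under two
#' different items is permitted but flagged with a warning, since such a
#' cue is ambiguous.
#'
#' @param path Path to the ontology CSV file.
#' @return An object of class `phq_ontology`: a data.frame with columns
#'   `item_id`, `term`, `frequency_weight`.
#' @seealso [match_cues()], [default_ontology_path()]
#' @export
load_ontology <- function(path) {
  if (!file.exists(path)) io_error(sprintf("ontology file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("item", "term")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    validation_error(sprintf("ontology CSV missing column(s): %s",
                             paste(miss, collapse = ", ")))
  }
  if (nrow(df) == 0L) {
    return(new_ontology(data.frame(item_id = character(0), term = character(0),
                                   frequency_weight = integer(0))))
  }
  item_raw <- trimws(df$item)
  item_id <- toupper(item_raw)
  bare <- grepl("^[1-9]$", item_id)
  item_id[bare] <- paste0("S", item_id[bare])
  bad <- !item_id %in% phq9_items()
  if (any(bad)) {
    validation_error(sprintf("unknown PHQ-9 item label '%s' at ontology row %d",
                             item_raw[which(bad)[1]], which(bad)[1]))
  }
  term <- normalize_text(df$term)
  if (any(!nzchar(term))) {
    validation_error(sprintf("empty term at ontology row %d", which(!nzchar(term))[1]))
  }
  fw <- if ("frequency_weight" %in% names(df)) {
    w <- suppressWarnings(as.integer(df$frequency_weight))
    w[is.na(w)] <- 1L
    w
  } else rep(1L, nrow(df))
  if (any(fw < 0L | fw > 3L)) {
    validation_error(sprintf("frequency_weight outside 0..3 at ontology row %d",
                             which(fw < 0L | fw > 3L)[1]))
  }
  key <- paste(item_id, term, sep = "\r")
  if (anyDuplicated(key)) {
    d <- which(duplicated(key))[1]
    validation_error(sprintf("duplicate (item, term) pair at ontology row %d: (%s, '%s')",
                             d, item_id[d], term[d]))
  }
  if (anyDuplicated(term)) {
    warning("ontology maps the same term to multiple PHQ-9 items: ",
            paste(unique(term[duplicated(term)]), collapse = ", "),
            call. = FALSE)
  }
  new_ontology(data.frame(item_id = item_id, term = term, frequency_weight = fw,
                          stringsAsFactors = FALSE))
}

new_ontology <- function(df) {
  rownames(df) <- NULL
  structure(df, class = c("phq_ontology", "data.frame"))
}

#' Path to the packaged PHQ-9 symptom ontology fixture
#'
#' A small, hand-curated ontology (several cue phrases per PHQ-9 item) that
#' ships with the package so the full pipeline runs without external
#' resources.
#'
#' @return File path to the ontology CSV.
#' @export
default_ontology_path <- function() {
  system.file("extdata", "phq9_ontology.csv", package = "phqscreen")
}

# Temporal frequency modifiers on the PHQ-9 response scale. Matching a
# modifier phrase in the same sentence upgrades a cue's frequency value.
frequency_modifiers <- function() {
  c("nearly every day" = 3L, "more than half the days" = 2L, "several days" = 1L)
}

#' Detect symptom cue phrases in free text
#'
#' Scans the normalized text left to right for exact occurrences of ontology
#' terms at word boundaries. Overlaps are resolved greedily: at each position
#' the longest matching term wins and the scan resumes after it. A term
#' listed under several items yields one match per item at the same span.
#'
#' Each match carries a frequency value on the PHQ-9 0-3 scale: the ontology
#' entry's `frequency_weight`, upgraded when a temporal modifier phrase
#' ("nearly every day" = 3, "more than half the days" = 2, "several days" = 1)
#' occurs in the same sentence (sentences delimited by `.`, `!`, `?`).
#'
#' @param text Raw input string.
#' @param ontology A `phq_ontology` from [load_ontology()].
#' @return A data.frame of class `phq_cues` with columns `item_id`, `term`,
#'   `start`, `end` (0-based half-open offsets into `normalize_text(text)`)
#'   and `frequency_cue`.
#' @export
#' @examples
#' onto <- load_ontology(default_ontology_path())
#' match_cues("I feel a total loss of interest in everything.", onto)
match_cues <- function(text, ontology) {
  stopifnot(inherits(ontology, "phq_ontology"))
  empty <- data.frame(item_id = character(0), term = character(0),
                      start = integer(0), end = integer(0),
                      frequency_cue = integer(0), stringsAsFactors = FALSE)
  if (length(text) != 1L || is.na(text) || !nzchar(trimws(text)) ||
      nrow(ontology) == 0L) {
    return(structure(empty, class = c("phq_cues", "data.frame")))
  }

  term_tokens <- strsplit(ontology$term, " ", fixed = TRUE)
  term_len <- lengths(term_tokens)
  mods <- frequency_modifiers()

  sentences <- split_sentences(text)
  norm_sent <- normalize_text(sentences)
  norm_sent <- norm_sent[nzchar(norm_sent)]

  out <- list()
  offset <- 0L   # char offset of current sentence within the full normalized text
  for (ns in norm_sent) {
    toks <- strsplit(ns, " ", fixed = TRUE)[[1]]
    tok_start <- integer(length(toks))
    pos <- 0L
    for (i in seq_along(toks)) {
      tok_start[i] <- pos
      pos <- pos + nchar(toks[i]) + 1L
    }
    mod_val <- 0L
    for (m in names(mods)) {
      if (grepl(paste0("\\b", m, "\\b"), ns)) mod_val <- max(mod_val, mods[[m]])
    }

    i <- 1L
    n <- length(toks)
    while (i <= n) {
      best_len <- 0L
      hit <- integer(0)
      for (j in seq_len(nrow(ontology))) {
        L <- term_len[j]
        if (L < best_len || i + L - 1L > n) next
        if (identical(toks[i:(i + L - 1L)], term_tokens[[j]])) {
          if (L > best_len) {
            best_len <- L
            hit <- j
          } else {
            hit <- c(hit, j)
          }
        }
      }
      if (best_len > 0L) {
        s <- offset + tok_start[i]
        e <- offset + tok_start[i + best_len - 1L] + nchar(toks[i + best_len - 1L])
        for (j in hit) {
          out[[length(out) + 1L]] <- data.frame(
            item_id = ontology$item_id[j], term = ontology$term[j],
            start = s, end = e,
            frequency_cue = max(ontology$frequency_weight[j], mod_val),
            stringsAsFactors = FALSE)
        }
        i <- i + best_len
      } else {
        i <- i + 1L
      }
    }
    offset <- offset + nchar(ns) + 1L
  }
  res <- if (length(out)) do.call(rbind, out) else empty
  rownames(res) <- NULL
  structure(res, class = c("phq_cues", "data.frame"))
}
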