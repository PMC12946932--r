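frequency_phrase <- function(score) {
  c("not at all", "several days", "more than half the days",
    "nearly every day")[score + 1L]
}

#' Render a deterministic explanation report
#'
#' Produces clinician-readable rationales from fixed templates — no sampling
#' and no external model — so identical inputs always yield byte-identical
#' output. Each yes-item gets a rationale citing its detected cue phrases
#' (with the frequency wording implied by its score) and/or the classifier
#' confidence; the narrative summarizes the total score, severity band,
#' elevated items and, when present, the attributed SNOMED CT concept and
#' identifier.
#'
#' An optional external language model can be layered on top via
#' `postprocess`, a function taking and returning the report; the default
#' identity keeps the engine fully deterministic.
#'
#' @param checklist A `phq_checklist`.
#' @param assessment The `phq_assessment` derived from `checklist` via
#'   [diagnose()]; consistency is verified.
#' @param match A `snomed_match`, `snomed_nomatch`, or `NULL`.
#' @param postprocess Optional hook, see above.
#' @return An object of class `phq_explanation`: `per_item` (named rationale
#'   strings for yes-items), `narrative`, `highlighted_terms` (data.frame of
#'   item, term, start, end).
#' @export
explain <- function(checklist, assessment, match = NULL, postprocess = identity) {
  stopifnot(inherits(checklist, "phq_checklist"),
            inherits(assessment, "phq_assessment"))
  recheck <- diagnose(checklist)
  if (recheck$total_score != assessment$total_score ||
      !identical(recheck$band, assessment$band)) {
    validation_error("assessment is not derivable from the supplied checklist")
  }
  items <- phq9_items()
  per_item <- character(0)
  hl <- list()
  for (it in items) {
    if (checklist$answers[[it]] != "yes") next
    cues <- checklist$cues[[it]]
    score <- assessment$item_scores[[it]]
    if (nrow(cues) > 0L) {
      terms <- paste0("'", unique(cues$term), "'", collapse = ", ")
      msg <- sprintf("%s marked present: detected %s [%s]", it, terms,
                     frequency_phrase(score))
      hl[[length(hl) + 1L]] <- data.frame(item = it, term = cues$term,
                                          start = cues$start, end = cues$end,
                                          stringsAsFactors = FALSE)
    } else {
      msg <- sprintf("%s marked present: classifier confidence %.2f [%s]",
                     it, checklist$confidences[[it]], frequency_phrase(score))
    }
    if (checklist$confidences[[it]] > 0 && nrow(cues) > 0L) {
      msg <- sprintf("%s; confidence %.2f", msg, checklist$confidences[[it]])
    }
    per_item[it] <- msg
  }
  narrative <- sprintf("Total PHQ-9 score %d of 27: %s.",
                       assessment$total_score, assessment$diagnosis_label)
  elev <- assessment$provenance$elevated_items
  if (!is.null(elev) && length(elev)) {
    narrative <- paste(narrative,
                       sprintf("Elevated items: %s.", paste(elev, collapse = ", ")))
  } else if (any(checklist$answers == "yes")) {
    narrative <- paste(narrative,
                       sprintf("Items endorsed: %s.",
                               paste(items[checklist$answers == "yes"], collapse = ", ")))
  }
  if (inherits(match, "snomed_match")) {
    narrative <- paste(narrative,
                       sprintf("Closest SNOMED CT concept: '%s' (conceptId %s), similarity %.2f.",
                               match$term, match$conceptId, match$similarity))
  } else {
    narrative <- paste(narrative, "No SNOMED CT attribution available.")
  }
  report <- structure(list(
    per_item = per_item,
    narrative = narrative,
    highlighted_terms = if (length(hl)) do.call(rbind, hl) else
      data.frame(item = character(0), term = character(0),
                 start = integer(0), end = integer(0))),
    class = "phq_explanation")
  postprocess(report)
}

#' @export
print.phq_explanation <- function(x, ...) {
  cat(x$narrative, "\n")
  for (msg in x$per_item) cat(" -", msg, "\n")
  invisible(x)
}

#' Semantic similarity between two texts
#'
#' Cosine similarity between the mean-pooled embeddings of the two
#' preprocessed texts. Empty texts embed to the zero vector, giving 0.
#'
#' @param text1,text2 Strings.
#' @param embedder A `phq_embedder`.
#' @param stopwords Stop-word list.
#' @return Scalar in `[-1, 1]`.
#' @export
semantic_similarity <- function(text1, text2, embedder,
                                stopwords = default_stopwords()) {
  cosine_similarity(embed_text(text1, embedder, stopwords = stopwords),
                    embed_text(text2, embedder, stopwords = stopwords))
}

#' Context relevance of an explanation
#'
#' Measures how much of the input's content vocabulary the explanation
#' reuses: the share of distinct content tokens (stop words removed) of the
#' input that also appear in the explanation. An input with no content
#' tokens scores 0.
#'
#' @param input_text Source text.
#' @param explanation Explanation text.
#' @param stopwords Stop-word list.
#' @return Scalar in `[0, 1]`.
#' @export
context_relevance <- function(input_text, explanation,
                              stopwords = default_stopwords()) {
  inp <- unique(preprocess(input_text, stopwords = stopwords, max_tokens = .Machine$integer.max))
  if (length(inp) == 0L) return(0)
  exp_tok <- unique(preprocess(explanation, stopwords = stopwords, max_tokens = .Machine$integer.max))
  length(intersect(inp, exp_tok)) / length(inp)
}
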