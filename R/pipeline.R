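#' Run the full screening pipeline on one text
#'
#' Chains the stages end to end: checklist generation (classifier +
#' ontology), PHQ-9 scoring into a severity band and diagnosis label,
#' SNOMED CT attribution of that label, and the deterministic explanation
#' report. The output is a single self-describing structure; for fixed
#' inputs and model the result is deterministic.
#'
#' @param text Input free text.
#' @param model A `phq_classifier`.
#' @param ontology A `phq_ontology`.
#' @param snomed_table A `snomed_table`, or `NULL` to skip attribution.
#' @param embedder A `phq_embedder`.
#' @param overrides Optional clinician overrides map, see [attribute()].
#' @param stopwords Stop-word list.
#' @return A list of class `phq_diagnosis`: `checklist`, `assessment`,
#'   `snomed_match`, `explanation`, `metadata`.
#' @export
assess <- function(text, model, ontology, snomed_table = NULL, embedder,
                   overrides = NULL, stopwords = default_stopwords()) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      phq_error(sprintf("[stage %s] %s", name, conditionMessage(e)),
                class(e)[1])
    })
  }
  checklist <- stage("checklist",
    generate_checklist(text, model, ontology, embedder, stopwords = stopwords))
  assessment <- stage("scoring", diagnose(checklist))
  match <- if (!is.null(snomed_table)) {
    stage("attribution",
          attribute(assessment$diagnosis_label, snomed_table, embedder,
                    overrides = overrides, stopwords = stopwords))
  } else NULL
  explanation <- stage("explanation", explain(checklist, assessment, match))
  structure(list(checklist = checklist, assessment = assessment,
                 snomed_match = match, explanation = explanation,
                 metadata = list(
                   package_version = as.character(utils::packageVersion("phqscreen")),
                   embedder = list(name = embedder$name, dim = embedder$dim),
                   threshold = model$hyperparams$threshold,
                   model_seed = model$hyperparams$seed)),
            class = "phq_diagnosis")
}

#' Serialize a diagnosis output as JSON
#'
#' Fixed key order and 6-decimal floats, so re-running [assess()] on the
#' same inputs yields byte-identical JSON.
#'
#' @param x A `phq_diagnosis` from [assess()].
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
diagnosis_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "phq_diagnosis"))
  cl <- x$checklist
  obj <- list(
    checklist = list(
      answers = as.list(cl$answers),
      confidences = as.list(round(cl$confidences, 6)),
      cues = lapply(cl$cues, function(df) {
        lapply(seq_len(nrow(df)), function(i) as.list(df[i, , drop = FALSE]))
      })),
    assessment = list(
      item_scores = as.list(x$assessment$item_scores),
      total_score = x$assessment$total_score,
      band = x$assessment$band,
      diagnosis_label = x$assessment$diagnosis_label,
      provenance = list(
        occurrence_counts = as.list(x$assessment$provenance$occurrence_counts),
        elevated_items = as.list(x$assessment$provenance$elevated_items))),
    snomed_match = if (inherits(x$snomed_match, "snomed_match")) {
      m <- unclass(x$snomed_match)
      m$similarity <- round(m$similarity, 6)
      m
    } else if (inherits(x$snomed_match, "snomed_nomatch")) {
      list(no_match = TRUE, message = x$snomed_match$message)
    } else NULL,
    explanation = list(
      per_item = as.list(x$explanation$per_item),
      narrative = x$explanation$narrative,
      highlighted_terms = lapply(seq_len(nrow(x$explanation$highlighted_terms)),
        function(i) as.list(x$explanation$highlighted_terms[i, , drop = FALSE]))),
    metadata = x$metadata)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = 6, pretty = TRUE,
                         null = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(as.character(js)))
  }
  as.character(js)
}

#' @export
print.phq_diagnosis <- function(x, ...) {
  print(x$explanation)
  invisible(x)
}
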