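#' PHQ-9 severity band for a total score
#'
#' The five standard bands partition the integer totals 0..27: 0-4 minimal,
#' 5-9 mild, 10-14 moderate, 15-19 moderately severe, 20-27 severe.
#'
#' @param total Integer total score in 0..27.
#' @return Band name (character scalar).
#' @export
severity_band <- function(total) {
  total <- as.integer(total)
  if (is.na(total) || total < 0L || total > 27L) {
    validation_error("PHQ-9 total score must be an integer in 0..27")
  }
  if (total <= 4L) "minimal"
  else if (total <= 9L) "mild"
  else if (total <= 14L) "moderate"
  else if (total <= 19L) "moderately severe"
  else "severe"
}

#' Score a single checklist item
#'
#' A "no" answer scores 0. A "yes" answer scores the maximum frequency value
#' over its supporting cues, floored at 1: presence without any temporal
#' frequency evidence is scored conservatively as 1 ("several days").
#'
#' @param answer `"yes"` or `"no"`.
#' @param cues A `phq_cues` data.frame (possibly empty) supporting the item.
#' @return Integer score in 0..3.
#' @export
item_score <- function(answer, cues = NULL) {
  stopifnot(answer %in% c("yes", "no"))
  if (answer == "no") return(0L)
  f <- if (!is.null(cues) && nrow(cues) > 0L) max(cues$frequency_cue) else 0L
  max(1L, as.integer(f))
}

#' Assemble a severity assessment from item scores
#'
#' Sums the nine item scores, maps the total onto the severity bands and
#' builds the diagnosis label `"<band> depression"`.
#'
#' @param item_scores Named integer vector over S1..S9, each in 0..3.
#' @return An object of class `phq_assessment`: `item_scores`, `total_score`,
#'   `band`, `diagnosis_label`.
#' @export
#' @examples
#' total_and_band(stats::setNames(c(1, 0, 2, 3, 0, 1, 0, 0, 2), paste0("S", 1:9)))
total_and_band <- function(item_scores) {
  items <- phq9_items()
  if (!all(items %in% names(item_scores))) {
    validation_error("item_scores must be named over all of S1..S9")
  }
  s <- as.integer(item_scores[items])
  if (any(is.na(s) | s < 0L | s > 3L)) {
    validation_error("item scores must be integers in 0..3")
  }
  total <- sum(s)
  band <- severity_band(total)
  structure(list(item_scores = stats::setNames(s, items),
                 total_score = total, band = band,
                 diagnosis_label = paste(band, "depression")),
            class = "phq_assessment")
}

#' Diagnose from a checklist
#'
#' Scores every item from its answer and cue frequencies, computes the total
#' and severity band, and attaches a provenance record: per-item occurrence
#' counts (emitted classifier predictions plus cue matches) and the elevated
#' items (score >= 2).
#'
#' @param checklist A `phq_checklist` from [generate_checklist()].
#' @return A `phq_assessment` with a `provenance` element.
#' @export
diagnose <- function(checklist) {
  stopifnot(inherits(checklist, "phq_checklist"))
  items <- phq9_items()
  scores <- stats::setNames(integer(9L), items)
  counts <- stats::setNames(integer(9L), items)
  for (it in items) {
    scores[it] <- item_score(checklist$answers[[it]], checklist$cues[[it]])
    counts[it] <- checklist$n_emitted[[it]] + nrow(checklist$cues[[it]])
  }
  out <- total_and_band(scores)
  out$provenance <- list(occurrence_counts = counts,
                         elevated_items = items[scores >= 2L])
  out
}
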