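#' Configuration for the synthetic post generator
#'
#' The generator emulates a corpus of short first-person posts with binary
#' per-item PHQ-9 annotations. Each post carries 0-3 positive items (uniform
#' by default); each positive item produces one symptom sentence, which with
#' probability `cue_rate` uses an exact ontology cue phrase (optionally
#' carrying a temporal frequency modifier with probability `modifier_rate`)
#' and otherwise a paraphrase worded without any ontology term. Neutral
#' filler sentences are mixed in. Annotations mark exactly the planted
#' items.
#'
#' @param n_posts Number of posts to generate.
#' @param seed Integer seed; identical configs and seeds yield byte-identical
#'   corpora.
#' @param max_items Positive items per post are drawn uniformly from
#'   `0..max_items` (default 3).
#' @param cue_rate Probability a positive item is expressed with an exact
#'   ontology cue phrase (default 0.9).
#' @param modifier_rate Probability a planted cue carries a temporal modifier
#'   (default 0.5).
#' @param filler_range Integer range (length 2) of filler sentences per post.
#' @param force_items Optional character vector of items; when given, every
#'   post is annotated positive for exactly these items.
#' @return A list of class `phq_generator_config`.
#' @export
generator_config <- function(n_posts, seed = 1L, max_items = 3L, cue_rate = 0.9,
                             modifier_rate = 0.5, filler_range = c(1L, 3L),
                             force_items = NULL) {
  stopifnot(n_posts >= 0, cue_rate >= 0, cue_rate <= 1,
            modifier_rate >= 0, modifier_rate <= 1,
            length(filler_range) == 2L, filler_range[1] <= filler_range[2])
  if (!is.null(force_items)) stopifnot(all(force_items %in% phq9_items()))
  structure(list(n_posts = as.integer(n_posts), seed = as.integer(seed),
                 max_items = as.integer(max_items), cue_rate = cue_rate,
                 modifier_rate = modifier_rate,
                 filler_range = as.integer(filler_range),
                 force_items = force_items),
            class = "phq_generator_config")
}

cue_templates <- function() {
  c("Lately I have been dealing with %s%s.",
    "For the past two weeks I have noticed %s%s.",
    "I keep struggling with %s%s.")
}

#' Paraphrase sentence bank
#'
#' One positive symptom sentence per PHQ-9 item worded without any ontology
#' cue phrase, used for the `1 - cue_rate` share of positive items. This is
#' what gives the embedding classifier signal beyond the lexicon.
#'
#' @return Named list (S1..S9) of character vectors.
#' @export
paraphrase_bank <- function() {
  list(
    S1 = c("Hobbies that used to matter to me now leave me cold",
           "Nothing seems fun anymore",
           "My old passions have all faded away"),
    S2 = c("A heavy sadness hangs over me all the time",
           "My spirits have been very low lately",
           "I keep tearing up for no reason"),
    S3 = c("I lie awake for hours before drifting off",
           "My nights are broken and unrestful",
           "I toss and turn until sunrise"),
    S4 = c("Even small chores wipe me out completely",
           "My body feels heavy and sluggish all day",
           "I can barely drag myself through the afternoon"),
    S5 = c("Food has lost all its taste for me",
           "I barely touch my dinner these days",
           "I keep raiding the fridge at midnight"),
    S6 = c("I keep blaming myself for everything that goes wrong",
           "I feel like I disappoint everyone around me",
           "My self esteem has hit rock bottom"),
    S7 = c("My mind keeps drifting off in the middle of tasks",
           "I read the same page over and over without taking it in",
           "Staying on task feels impossible lately"),
    S8 = c("I keep pacing around the room unable to settle",
           "Others notice that I move and speak at a crawl",
           "I keep squirming in my seat during meetings"),
    S9 = c("I sometimes wish I could just disappear for good",
           "Dark thoughts about ending it all keep surfacing",
           "I have imagined ways of not being here anymore"))
}

#' Neutral filler sentence bank
#'
#' Everyday sentences guaranteed free of ontology cue phrases (enforced by a
#' package test), so gold labels of generated posts stay exact.
#'
#' @return Character vector.
#' @export
filler_bank <- function() {
  c("I went to the store this morning",
    "The weather has been rainy this week",
    "My neighbor plays loud music on weekends",
    "I am planning a trip to the coast next month",
    "The new season of my favorite show just came out",
    "Traffic on the highway was terrible today",
    "I repainted the kitchen over the holidays",
    "Our team meeting ran long on Tuesday",
    "The garden needs weeding again",
    "I tried a new recipe for dinner yesterday",
    "The library extended its opening hours",
    "My phone needs a software update")
}

#' Generate synthetic annotated posts
#'
#' See [generator_config()] for the generative model. The result is
#' deterministic for a fixed config.
#'
#' @param cfg A `phq_generator_config`.
#' @param ontology A `phq_ontology` with at least one term per item that can
#'   be sampled.
#' @return List of posts: `list(post_text = , annotations = named "yes"/"no"
#'   over S1..S9)`, with the planted items attached as attribute `planted`
#'   on each post.
#' @export
generate_posts <- function(cfg, ontology) {
  stopifnot(inherits(cfg, "phq_generator_config"), inherits(ontology, "phq_ontology"))
  items <- phq9_items()
  para <- paraphrase_bank()
  fillers <- filler_bank()
  templates <- cue_templates()
  mods <- names(frequency_modifiers())
  terms_by_item <- split(ontology$term, factor(ontology$item_id, levels = items))

  with_local_seed(cfg$seed, {
    lapply(seq_len(cfg$n_posts), function(i) {
      pos <- if (!is.null(cfg$force_items)) cfg$force_items else {
        k <- sample.int(cfg$max_items + 1L, 1L) - 1L
        if (k > 0L) sample(items, k) else character(0)
      }
      sentences <- character(0)
      for (it in pos) {
        if (stats::runif(1) < cfg$cue_rate) {
          pool <- terms_by_item[[it]]
          if (length(pool) == 0L) {
            validation_error(sprintf("ontology has no term for sampled item %s", it))
          }
          term <- if (length(pool) == 1L) pool else sample(pool, 1L)
          mod <- if (stats::runif(1) < cfg$modifier_rate)
            paste0(" ", sample(mods, 1L)) else ""
          sentences <- c(sentences, sprintf(sample(templates, 1L), term, mod))
        } else {
          bank <- para[[it]]
          sentences <- c(sentences, paste0(sample(bank, 1L), "."))
        }
      }
      nf <- sample(seq(cfg$filler_range[1], cfg$filler_range[2]), 1L)
      sentences <- c(sentences, paste0(sample(fillers, nf), "."))
      sentences <- sample(sentences)
      ann <- stats::setNames(ifelse(items %in% pos, "yes", "no"), items)
      structure(list(post_text = paste(sentences, collapse = " "),
                     annotations = as.list(ann)),
                planted = pos)
    })
  })
}

#' Write / read posts JSON
#'
#' Posts are exchanged as a JSON array of objects with fields `post_text`
#' and (optionally) `annotations` mapping S1..S9 to "yes"/"no".
#'
#' @param posts List of posts as produced by [generate_posts()].
#' @param path File path.
#' @return `write_posts_json` returns `path` invisibly; `read_posts_json`
#'   returns the list of posts.
#' @export
write_posts_json <- function(posts, path) {
  plain <- lapply(posts, function(p) list(post_text = p$post_text,
                                          annotations = p$annotations))
  jsonlite::write_json(plain, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_posts_json
#' @export
read_posts_json <- function(path) {
  if (!file.exists(path)) io_error(sprintf("posts file not found: %s", path))
  raw <- jsonlite::read_json(path)
  lapply(raw, function(p) {
    if (is.null(p$post_text)) validation_error("post record missing 'post_text'")
    list(post_text = p$post_text, annotations = p$annotations)
  })
}

#' Miniature synthetic SNOMED CT description table
#'
#' A ~50-row stand-in for the (licensed, unshippable) SNOMED CT description
#' file, in RF2 column layout. It contains the two published concept rows
#' used throughout the documentation — "Depressed mood (finding)"
#' (conceptId 366979004) and "Moderate major depression" (conceptId
#' 370143000) — alongside depression severity-band terms, psychiatric
#' neighbours and non-psychiatric distractors. All other conceptIds are
#' synthetic placeholders (9xxxxxx range), not real SNOMED identifiers.
#' One row is inactive to exercise the active filter.
#'
#' @return A `snomed_table` data.frame.
#' @export
snomed_fixture_table <- function() {
  terms <- c(
    "Depressed mood (finding)"            = "366979004",
    "Moderate major depression"           = "370143000",
    "Major depression"                    = "9000001",
    "Mild major depression"               = "9000002",
    "Severe major depression"             = "9000003",
    "Moderately severe major depression"  = "9000004",
    "Minimal depression"                  = "9000005",
    "Recurrent major depression"          = "9000006",
    "Major depression single episode"     = "9000007",
    "Severe major depression with psychotic features" = "9000008",
    "Postpartum depression"               = "9000009",
    "Seasonal affective disorder"         = "9000010",
    "Depressed skull fracture"            = "9000011",
    "Mood disorder"                       = "9000012",
    "Anxiety disorder"                    = "9000013",
    "Generalized anxiety disorder"        = "9000014",
    "Panic disorder"                      = "9000015",
    "Bipolar disorder"                    = "9000016",
    "Bipolar depression"                  = "9000017",
    "Dysthymia"                           = "9000018",
    "Adjustment disorder with depressed mood" = "9000019",
    "Insomnia (disorder)"                 = "9000020",
    "Sleep apnea"                         = "9000021",
    "Chronic fatigue syndrome"            = "9000022",
    "Loss of appetite (finding)"          = "9000023",
    "Feeling hopeless (finding)"          = "9000024",
    "Suicidal thoughts (finding)"         = "9000025",
    "Self-injurious behavior"             = "9000026",
    "Psychomotor retardation"             = "9000027",
    "Psychomotor agitation"               = "9000028",
    "Poor concentration (finding)"        = "9000029",
    "Low self-esteem (finding)"           = "9000030",
    "Anhedonia (finding)"                 = "9000031",
    "Fatigue (finding)"                   = "9000032",
    "Grief reaction"                      = "9000033",
    "Schizophrenia"                       = "9000034",
    "Obsessive compulsive disorder"       = "9000035",
    "Post-traumatic stress disorder"      = "9000036",
    "Fracture of femur"                   = "9000037",
    "Hypertension (disorder)"             = "9000038",
    "Type 2 diabetes mellitus"            = "9000039",
    "Asthma"                              = "9000040",
    "Migraine"                            = "9000041",
    "Common cold"                         = "9000042",
    "Appendicitis"                        = "9000043",
    "Iron deficiency anemia"              = "9000044",
    "Hypothyroidism"                      = "9000045",
    "Eczema"                              = "9000046",
    "Osteoarthritis of knee"              = "9000047",
    "Urinary tract infection"             = "9000048")
  n <- length(terms)
  df <- data.frame(
    id = sprintf("D%04d", seq_len(n)),
    effectiveTime = "20240101",
    active = "1",
    moduleId = "900000000000207008",
    conceptId = unname(terms),
    languageCode = "en",
    typeId = "900000000000003001",
    term = names(terms),
    caseSignificanceId = "900000000000448009",
    stringsAsFactors = FALSE)
  # retired synonym row, filtered out on load
  df <- rbind(df, data.frame(
    id = "D9999", effectiveTime = "20200101", active = "0",
    moduleId = "900000000000207008", conceptId = "9000049",
    languageCode = "en", typeId = "900000000000003001",
    term = "Melancholia (retired term)",
    caseSignificanceId = "900000000000448009", stringsAsFactors = FALSE))
  structure(df, class = c("snomed_table", "data.frame"))
}

#' Write the SNOMED fixture table to a TSV file
#'
#' Writes [snomed_fixture_table()] (including its inactive row) in RF2
#' tab-separated layout so it round-trips through [load_snomed()].
#'
#' @param path Destination file path.
#' @return `path`, invisibly.
#' @export
generate_snomed_fixture <- function(path) {
  df <- snomed_fixture_table()
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
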