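# Shared fixtures and independent oracles for the suite. Everything here is
# generated in code at test time; nothing binary ships with the tests.

fixture_ontology_csv <- function(terms_per_item = 3L) {
  onto <- utils::read.csv(default_ontology_path(), stringsAsFactors = FALSE)
  keep <- unlist(lapply(split(seq_len(nrow(onto)), onto$item),
                        utils::head, terms_per_item))
  path <- tempfile(fileext = ".csv")
  utils::write.csv(onto[sort(keep), ], path, row.names = FALSE)
  path
}

fixture_ontology <- function(terms_per_item = 3L) {
  load_ontology(fixture_ontology_csv(terms_per_item))
}

# Brute-force cue-matching oracle: per sentence, enumerate every
# word-boundary occurrence of every term in the normalized sentence, then
# apply the same greedy longest-match/leftmost non-overlap rule by explicit
# position scan. Independent of the tokenwise scanner in match_cues.
oracle_match_cues <- function(text, ontology) {
  mods <- c("nearly every day" = 3L, "more than half the days" = 2L,
            "several days" = 1L)
  out <- list()
  offset <- 0L
  sents <- trimws(strsplit(text, "[.!?]+")[[1]])
  sents <- sents[nzchar(sents)]
  for (raw in sents) {
    ns <- normalize_text(raw)
    if (!nzchar(ns)) next
    mod_val <- 0L
    for (m in names(mods)) {
      if (grepl(m, ns, fixed = TRUE)) {
        hit <- regexpr(paste0("(^| )", m, "( |$)"), ns)
        if (hit > 0) mod_val <- max(mod_val, mods[[m]])
      }
    }
    occ <- list()
    for (j in seq_len(nrow(ontology))) {
      pat <- paste0("(?<![a-z0-9])", gsub(" ", " ", ontology$term[j], fixed = TRUE),
                    "(?![a-z0-9])")
      g <- gregexpr(pat, ns, perl = TRUE)[[1]]
      if (g[1] > 0) {
        for (k in seq_along(g)) {
          occ[[length(occ) + 1L]] <- list(
            start = as.integer(g[k]) - 1L,
            len = attr(g, "match.length")[k], j = j)
        }
      }
    }
    pos <- 0L
    while (length(occ)) {
      starts <- vapply(occ, `[[`, integer(1), "start")
      avail <- starts >= pos
      if (!any(avail)) break
      s0 <- min(starts[avail])
      at <- occ[starts == s0]
      maxlen <- max(vapply(at, `[[`, integer(1), "len"))
      for (o in at) {
        if (o$len == maxlen) {
          j <- o$j
          out[[length(out) + 1L]] <- data.frame(
            item_id = ontology$item_id[j], term = ontology$term[j],
            start = offset + s0, end = offset + s0 + maxlen,
            frequency_cue = max(ontology$frequency_weight[j], mod_val),
            stringsAsFactors = FALSE)
        }
      }
      pos <- s0 + maxlen
      occ <- occ[starts >= pos]
    }
    offset <- offset + nchar(ns) + 1L
  }
  if (length(out)) {
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  } else {
    data.frame(item_id = character(0), term = character(0),
               start = integer(0), end = integer(0),
               frequency_cue = integer(0), stringsAsFactors = FALSE)
  }
}

# Brute-force attribution oracle: keyword containment checked per row with
# its own boundary test, every matching row scored, max by (similarity,
# shorter term, smaller conceptId). Independent of keyword_filter /
# rank_candidates / attribute.
oracle_attribute <- function(diagnosis, table, embedder,
                             stopwords = default_stopwords()) {
  kws <- setdiff(strsplit(normalize_text(diagnosis), " ")[[1]], stopwords)
  kws <- unique(kws[nzchar(kws)])
  if (length(kws) == 0L) return(NULL)
  dvec <- embed_text(diagnosis, embedder, stopwords = stopwords)
  rows <- list()
  for (i in seq_len(nrow(table))) {
    toks <- strsplit(normalize_text(table$term[i]), " ")[[1]]
    if (any(kws %in% toks)) {
      sim <- cosine_similarity(
        dvec, embed_text(table$term[i], embedder, stopwords = stopwords))
      rows[[length(rows) + 1L]] <- list(i = i, sim = sim)
    }
  }
  if (length(rows) == 0L) return(NULL)
  sims <- vapply(rows, `[[`, numeric(1), "sim")
  idx <- vapply(rows, `[[`, integer(1), "i")
  ord <- order(-sims, nchar(table$term[idx]), table$conceptId[idx])
  list(conceptId = table$conceptId[idx[ord[1]]], similarity = sims[ord[1]])
}

random_snomed_table <- function(n_rows, seed) {
  words <- c("depression", "depressed", "mood", "anxiety", "disorder",
             "moderate", "severe", "mild", "major", "recurrent", "episode",
             "chronic", "acute", "finding", "fracture", "femur", "infection",
             "syndrome", "fatigue", "sleep", "panic", "bipolar", "stress",
             "knee", "skull", "reaction", "behavior")
  withr::with_seed(seed, {
    terms <- vapply(seq_len(n_rows), function(i) {
      paste(sample(words, sample(1:4, 1), replace = TRUE), collapse = " ")
    }, character(1))
    df <- data.frame(conceptId = as.character(sample(1e6:9e6, n_rows)),
                     term = terms, stringsAsFactors = FALSE)
    structure(df, class = c("snomed_table", "data.frame"))
  })
}

# Memoized 5-seed end-to-end recovery run (train 500 / evaluate 100 fresh),
# shared between the classifier property test and the acceptance suite.
.e2e_cache <- new.env(parent = emptyenv())
e2e_recovery <- function(seeds = 1:5) {
  key <- paste(seeds, collapse = ",")
  if (!is.null(.e2e_cache[[key]])) return(.e2e_cache[[key]])
  emb <- make_embedder()
  onto <- load_ontology(default_ontology_path())
  runs <- lapply(seeds, function(s) {
    train <- generate_posts(generator_config(500L, seed = s), onto)
    test <- generate_posts(generator_config(100L, seed = s + 1000L), onto)
    model <- train_classifier(train, emb,
                              classifier_hyperparams(seed = s))
    pred <- lapply(test, function(p)
      generate_checklist(p$post_text, model, onto, emb))
    gold <- lapply(test, function(p) p$annotations)
    evaluate_checklists(pred, gold, mode = "all")
  })
  .e2e_cache[[key]] <- runs
  runs
}

make_posts <- function(texts, items_yes) {
  all_items <- paste0("S", 1:9)
  Map(function(tx, ys) {
    list(post_text = tx,
         annotations = as.list(stats::setNames(
           ifelse(all_items %in% ys, "yes", "no"), all_items)))
  }, texts, items_yes)
}
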