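# Shared small fixtures: a balanced single-item corpus and a trained model.
# The corpus uses one strong cue term per item, always planted and without
# filler, so that per-item embeddings form coherent clusters: that is the
# regime in which a nearest-centroid baseline is a meaningful oracle for the
# network (with several surface-disjoint terms per item the reference
# embedder's clusters are disjoint by construction and only the network can
# learn the union). Corpus-scale recovery under the full generator defaults
# is covered separately.
emb <- make_embedder()
onto <- load_ontology(default_ontology_path())
items <- paste0("S", 1:9)

single_term_onto <- local({
  df <- as.data.frame(onto)
  keep <- unlist(lapply(split(seq_len(nrow(df)), df$item_id), utils::head, 1L))
  structure(df[sort(keep), ], class = c("phq_ontology", "data.frame"))
})

balanced_corpus <- function(n_per_item, seed0) {
  posts <- list()
  for (k in seq_along(items)) {
    cfg <- generator_config(n_per_item, seed = seed0 + k, cue_rate = 1,
                            filler_range = c(0L, 0L), force_items = items[k])
    posts <- c(posts, generate_posts(cfg, single_term_onto))
  }
  posts
}

train_posts <- balanced_corpus(56L, 100L)   # 504 posts, 56 per item
test_posts <- balanced_corpus(11L, 900L)    # 99 posts
model <- train_classifier(train_posts, emb, classifier_hyperparams(seed = 5L))

post_label <- function(p) items[vapply(items, function(it)
  p$annotations[[it]] == "yes", logical(1))]

test_that("trained network beats the nearest-centroid oracle on held-out posts", {
  X_train <- t(vapply(train_posts, function(p) embed_text(p$post_text, emb),
                      numeric(emb$dim)))
  y_train <- vapply(train_posts, post_label, character(1))
  X_test <- t(vapply(test_posts, function(p) embed_text(p$post_text, emb),
                     numeric(emb$dim)))
  y_test <- vapply(test_posts, post_label, character(1))

  # independent baseline: cosine to per-item mean embedding
  centroids <- t(vapply(items, function(it)
    colMeans(X_train[y_train == it, , drop = FALSE]), numeric(emb$dim)))
  centroid_pred <- apply(X_test, 1L, function(v)
    items[which.max(centroids %*% v / sqrt(rowSums(centroids^2)))])
  centroid_acc <- mean(centroid_pred == y_test)

  net_pred <- items[apply(predict_proba(model, X_test), 1L, which.max)]
  net_acc <- mean(net_pred == y_test)

  expect_gte(centroid_acc, 0.85)
  expect_gte(net_acc, 0.90)
  expect_gte(net_acc, centroid_acc)
})

test_that("training is reproducible under a fixed seed", {
  m2 <- train_classifier(train_posts, emb, classifier_hyperparams(seed = 5L))
  expect_identical(model$W1, m2$W1)
  X <- t(vapply(test_posts[1:10], function(p) embed_text(p$post_text, emb),
                numeric(emb$dim)))
  expect_identical(predict_proba(model, X), predict_proba(m2, X))
})

test_that("softmax outputs are probability distributions for random weights", {
  set.seed(33)
  rnd <- structure(list(
    W1 = matrix(rnorm(32 * 128), 32, 128), b1 = rnorm(128),
    W2 = matrix(rnorm(128 * 9), 128, 9), b2 = rnorm(9),
    dim = 32L, items = items, hyperparams = classifier_hyperparams()),
    class = "phq_classifier")
  X <- matrix(rnorm(120 * 32), 120, 32)
  P <- predict_proba(rnd, X)
  expect_true(all(abs(rowSums(P) - 1) < 1e-9))
  expect_true(all(P >= 0))
})

test_that("single-class training data is refused", {
  one_class <- generate_posts(
    generator_config(10L, seed = 3L, force_items = "S2"), onto)
  expect_error(train_classifier(one_class, emb),
               class = "phqscreen_validation_error")
})

test_that("the 0.55 confidence rule suppresses strictly-below predictions", {
  expect_false(item_prediction("S1", 0.54)$emitted)
  expect_true(item_prediction("S1", 0.55)$emitted)
  expect_true(item_prediction("S1", 0.56)$emitted)
  # raising the threshold never turns an emitted prediction on
  for (p in seq(0, 1, by = 0.05)) {
    lo <- item_prediction("S1", p, threshold = 0.55)$emitted
    hi <- item_prediction("S1", p, threshold = 0.75)$emitted
    expect_true(lo || !hi)
  }
})

test_that("checklist yes-set is exactly emitted-items union cue-items", {
  for (p in test_posts[seq(1, 99, by = 10)]) {
    cl <- generate_checklist(p$post_text, model, onto, emb)
    preds <- predict_items(p$post_text, model, emb)
    emitted <- unique(vapply(Filter(function(x) x$emitted, preds),
                             `[[`, character(1), "item_id"))
    cued <- unique(match_cues(p$post_text, onto)$item_id)
    expect_setequal(names(cl$answers)[cl$answers == "yes"],
                    union(emitted, cued))
    # every yes carries provenance: confidence above threshold or a cue
    for (it in names(cl$answers)[cl$answers == "yes"]) {
      expect_true(cl$confidences[[it]] >= 0.55 || nrow(cl$cues[[it]]) > 0L)
    }
  }
})

test_that("the lexicon path alone can answer yes when the classifier abstains", {
  flat <- structure(list(
    W1 = matrix(0, emb$dim, 4L), b1 = numeric(4L),
    W2 = matrix(0, 4L, 9L), b2 = numeric(9L),
    dim = emb$dim, items = items, hyperparams = classifier_hyperparams()),
    class = "phq_classifier")  # uniform softmax 1/9 everywhere
  cl <- generate_checklist("I noticed a loss of interest lately.", flat, onto, emb)
  expect_equal(unname(cl$answers[["S1"]]), "yes")
  expect_equal(unname(cl$confidences[["S1"]]), 0)
  expect_gt(nrow(cl$cues[["S1"]]), 0L)

  empty <- generate_checklist("", flat, onto, emb)
  expect_true(all(empty$answers == "no"))
})

test_that("model serialization round-trips", {
  path <- tempfile(fileext = ".json")
  save_classifier(model, path)
  m2 <- load_classifier(path)
  X <- t(vapply(test_posts[1:5], function(p) embed_text(p$post_text, emb),
                numeric(emb$dim)))
  expect_equal(predict_proba(m2, X), predict_proba(model, X), tolerance = 1e-12)
  expect_equal(m2$hyperparams$threshold, 0.55)
})

test_that("synthetic recovery holds at corpus scale across seeds", {
  runs <- e2e_recovery(seeds = 1:5)
  macro_rec <- mean(vapply(runs, function(r) r$macro$recall, numeric(1)))
  macro_prec <- mean(vapply(runs, function(r) r$macro$precision, numeric(1)))
  expect_gte(macro_rec, 0.90)
  expect_gte(macro_prec, 0.85)
})
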