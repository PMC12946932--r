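#' Classifier hyperparameters
#'
#' Defaults follow the pipeline's training recipe: Adam with learning rate
#' 0.001, 32 epochs, a single 128-unit ReLU hidden layer, softmax output over
#' the nine PHQ-9 items, and a confidence threshold of 0.55 below which
#' predictions are suppressed. Batch size 16 and He initialization are the
#' package's own choices.
#'
#' @param learning_rate Adam learning rate.
#' @param epochs Number of passes over the training pairs.
#' @param batch_size Mini-batch size.
#' @param hidden Hidden-layer width.
#' @param threshold Softmax confidence threshold for emitting a prediction.
#' @param seed Integer seed controlling initialization and shuffling.
#' @return A named list of hyperparameters.
#' @export
classifier_hyperparams <- function(learning_rate = 0.001, epochs = 32L,
                                   batch_size = 16L, hidden = 128L,
                                   threshold = 0.55, seed = 42L) {
  list(learning_rate = learning_rate, epochs = as.integer(epochs),
       batch_size = as.integer(batch_size), hidden = as.integer(hidden),
       threshold = threshold, seed = as.integer(seed))
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Train the PHQ-9 item classifier
#'
#' A feedforward network (embedding -> 128-unit ReLU hidden layer -> softmax
#' over S1..S9) trained with mini-batch Adam on cross-entropy loss. Each post
#' contributes one training pair per positively annotated item: the post's
#' mean-pooled embedding paired with that item label. Training is fully
#' reproducible for a fixed seed.
#'
#' @param posts List of posts, each a list with `post_text` (string) and
#'   `annotations` (named "yes"/"no" over S1..S9); see [read_posts_json()].
#' @param embedder A `phq_embedder`.
#' @param hyperparams See [classifier_hyperparams()].
#' @param stopwords Stop-word list used in preprocessing.
#' @return An object of class `phq_classifier` holding the weight matrices
#'   and the hyperparameters.
#' @export
train_classifier <- function(posts, embedder,
                             hyperparams = classifier_hyperparams(),
                             stopwords = default_stopwords()) {
  stopifnot(inherits(embedder, "phq_embedder"))
  items <- phq9_items()
  X <- list(); y <- integer(0)
  for (p in posts) {
    ann <- p$annotations
    pos <- items[items %in% names(ann) & unlist(ann[items[items %in% names(ann)]]) == "yes"]
    if (length(pos) == 0L) next
    v <- embed_text(p$post_text, embedder, stopwords = stopwords)
    for (it in pos) {
      X[[length(X) + 1L]] <- v
      y <- c(y, match(it, items))
    }
  }
  if (length(unique(y)) < 2L) {
    validation_error("training data must contain at least two distinct PHQ-9 item labels")
  }
  X <- do.call(rbind, X)
  d <- embedder$dim
  if (ncol(X) != d) config_error("embedding dimension mismatch")
  hp <- hyperparams
  H <- hp$hidden; K <- length(items)

  with_local_seed(hp$seed, {
    W1 <- matrix(stats::rnorm(d * H, sd = sqrt(2 / d)), d, H)
    b1 <- numeric(H)
    W2 <- matrix(stats::rnorm(H * K, sd = sqrt(2 / H)), H, K)
    b2 <- numeric(K)

    # Adam state
    adam <- lapply(list(W1, b1, W2, b2), function(p) list(m = p * 0, v = p * 0))
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
    t <- 0L
    n <- nrow(X)

    for (epoch in seq_len(hp$epochs)) {
      ord <- sample.int(n)
      for (bs in split(ord, ceiling(seq_along(ord) / hp$batch_size))) {
        Xb <- X[bs, , drop = FALSE]
        yb <- y[bs]
        m <- length(bs)

        A1 <- Xb %*% W1 + matrix(b1, m, H, byrow = TRUE)
        Z1 <- pmax(A1, 0)
        P <- softmax_rows(Z1 %*% W2 + matrix(b2, m, K, byrow = TRUE))

        dZ2 <- P
        dZ2[cbind(seq_len(m), yb)] <- dZ2[cbind(seq_len(m), yb)] - 1
        dZ2 <- dZ2 / m
        gW2 <- t(Z1) %*% dZ2
        gb2 <- colSums(dZ2)
        dZ1 <- (dZ2 %*% t(W2)) * (A1 > 0)
        gW1 <- t(Xb) %*% dZ1
        gb1 <- colSums(dZ1)

        t <- t + 1L
        grads <- list(gW1, gb1, gW2, gb2)
        params <- list(W1, b1, W2, b2)
        for (k in seq_along(params)) {
          adam[[k]]$m <- beta1 * adam[[k]]$m + (1 - beta1) * grads[[k]]
          adam[[k]]$v <- beta2 * adam[[k]]$v + (1 - beta2) * grads[[k]]^2
          mhat <- adam[[k]]$m / (1 - beta1^t)
          vhat <- adam[[k]]$v / (1 - beta2^t)
          params[[k]] <- params[[k]] - hp$learning_rate * mhat / (sqrt(vhat) + eps)
        }
        W1 <- params[[1]]; b1 <- params[[2]]; W2 <- params[[3]]; b2 <- params[[4]]
      }
    }

    structure(list(W1 = W1, b1 = b1, W2 = W2, b2 = b2,
                   dim = d, items = items, hyperparams = hp,
                   embedder_name = embedder$name),
              class = "phq_classifier")
  })
}

#' Softmax probabilities for embedded inputs
#'
#' Forward pass of the trained network. Rows of the result sum to 1.
#'
#' @param model A `phq_classifier`.
#' @param X Numeric matrix (rows are embeddings) or a single vector.
#' @return Matrix `n x 9` of item probabilities.
#' @export
predict_proba <- function(model, X) {
  stopifnot(inherits(model, "phq_classifier"))
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  if (ncol(X) != model$dim) config_error("embedding dimension mismatch")
  m <- nrow(X)
  Z1 <- pmax(X %*% model$W1 + matrix(model$b1, m, length(model$b1), byrow = TRUE), 0)
  P <- softmax_rows(Z1 %*% model$W2 + matrix(model$b2, m, length(model$b2), byrow = TRUE))
  colnames(P) <- model$items
  P
}

#' Construct an item prediction
#'
#' Applies the confidence-threshold rule: a prediction is emitted iff its
#' softmax probability reaches the threshold; strictly lower probabilities
#' are suppressed to reduce false positives.
#'
#' @param item_id One of S1..S9.
#' @param probability Softmax probability in `[0, 1]`.
#' @param threshold Confidence threshold (default 0.55).
#' @return A list with `item_id`, `probability`, `emitted`.
#' @export
item_prediction <- function(item_id, probability, threshold = 0.55) {
  stopifnot(item_id %in% phq9_items(), probability >= 0, probability <= 1)
  list(item_id = item_id, probability = probability,
       emitted = probability >= threshold)
}

#' Per-sentence item predictions for a text
#'
#' Splits the text into sentences, embeds each and runs the classifier. Each
#' sentence yields one prediction: the argmax item with its probability and
#' an `emitted` flag per the 0.55 threshold rule.
#'
#' @param text Raw input string.
#' @param model A `phq_classifier`.
#' @param embedder The `phq_embedder` used at training time.
#' @param stopwords Stop-word list.
#' @return List of predictions from [item_prediction()] (empty for empty text).
#' @export
predict_items <- function(text, model, embedder, stopwords = default_stopwords()) {
  sentences <- split_sentences(text)
  out <- vector("list", length(sentences))
  tau <- model$hyperparams$threshold
  for (i in seq_along(sentences)) {
    v <- embed_text(sentences[i], embedder, stopwords = stopwords)
    p <- predict_proba(model, v)[1L, ]
    k <- which.max(p)
    out[[i]] <- item_prediction(model$items[k], unname(p[k]), tau)
  }
  out
}

#' Generate the PHQ-9 checklist for a text
#'
#' Combines the two evidence channels: an item is answered "yes" iff the
#' classifier emitted at least one prediction for it (softmax probability at
#' or above the threshold) or the symptom ontology matched at least one cue
#' phrase for it. Each yes therefore carries auditable provenance — a
#' confidence, supporting cues, or both.
#'
#' @inheritParams predict_items
#' @param ontology A `phq_ontology`.
#' @return An object of class `phq_checklist`: `answers` (named "yes"/"no"
#'   over S1..S9), `confidences` (max emitted probability per item, 0 if
#'   none), `cues` (per-item cue data.frames) and `n_emitted` (count of
#'   emitted predictions per item).
#' @export
generate_checklist <- function(text, model, ontology, embedder,
                               stopwords = default_stopwords()) {
  items <- phq9_items()
  preds <- predict_items(text, model, embedder, stopwords = stopwords)
  cues <- match_cues(text, ontology)
  answers <- stats::setNames(rep("no", 9L), items)
  conf <- stats::setNames(numeric(9L), items)
  n_emit <- stats::setNames(integer(9L), items)
  cue_list <- stats::setNames(vector("list", 9L), items)
  for (it in items) cue_list[[it]] <- cues[cues$item_id == it, , drop = FALSE]
  for (pr in preds) {
    if (pr$emitted) {
      answers[pr$item_id] <- "yes"
      conf[pr$item_id] <- max(conf[pr$item_id], pr$probability)
      n_emit[pr$item_id] <- n_emit[pr$item_id] + 1L
    }
  }
  for (it in items) if (nrow(cue_list[[it]]) > 0L) answers[it] <- "yes"
  structure(list(answers = answers, confidences = conf, cues = cue_list,
                 n_emitted = n_emit),
            class = "phq_checklist")
}

#' Save / load a trained classifier
#'
#' The model is serialized as a single portable JSON file holding shapes,
#' weights and hyperparameters in full double precision.
#'
#' @param model A `phq_classifier`.
#' @param path Destination file.
#' @return `save_classifier` returns `path` invisibly; `load_classifier`
#'   returns the restored `phq_classifier`.
#' @export
save_classifier <- function(model, path) {
  stopifnot(inherits(model, "phq_classifier"))
  obj <- list(W1 = model$W1, b1 = model$b1, W2 = model$W2, b2 = model$b2,
              dim = model$dim, items = model$items,
              hyperparams = model$hyperparams,
              embedder_name = model$embedder_name)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  if (!file.exists(path)) io_error(sprintf("model file not found: %s", path))
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  hp <- obj$hyperparams
  structure(list(W1 = obj$W1, b1 = as.numeric(obj$b1),
                 W2 = obj$W2, b2 = as.numeric(obj$b2),
                 dim = as.integer(obj$dim), items = as.character(obj$items),
                 hyperparams = classifier_hyperparams(
                   learning_rate = hp$learning_rate, epochs = hp$epochs,
                   batch_size = hp$batch_size, hidden = hp$hidden,
                   threshold = hp$threshold, seed = hp$seed),
                 embedder_name = obj$embedder_name),
            class = "phq_classifier")
}
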