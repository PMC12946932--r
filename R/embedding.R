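# Per-dimension memo of reference token vectors; tokens recur heavily in
# corpus work and hashing 3-grams per call would dominate runtime.
.token_cache <- new.env(parent = emptyenv())

#' Preprocess text into a token sequence
#'
#' Lowercases, strips punctuation, splits on whitespace, removes stop words
#' and truncates to a fixed cap (default 128 tokens). Mean pooling downstream
#' makes explicit padding a no-op, so the cap is realized as truncation only.
#'
#' @param text Raw input string.
#' @param stopwords Character vector of stop words; defaults to the packaged
#'   list from [default_stopwords()].
#' @param max_tokens Token cap (default 128).
#' @return Character vector of tokens (possibly empty).
#' @export
#' @examples
#' preprocess("I feel DOWN, depressed.", stopwords = c("i", "feel"))
preprocess <- function(text, stopwords = default_stopwords(), max_tokens = 128L) {
  if (length(text) != 1L || is.na(text)) return(character(0))
  norm <- normalize_text(text)
  if (!nzchar(norm)) return(character(0))
  toks <- strsplit(norm, " ", fixed = TRUE)[[1]]
  toks <- toks[!toks %in% stopwords]
  if (length(toks) > max_tokens) toks <- toks[seq_len(max_tokens)]
  toks
}

#' Construct an embedder specification
#'
#' The package computes all similarities against a pluggable embedder
#' contract: a name, a fixed output dimension and a per-token vector
#' function. The built-in `"reference"` embedder is fully deterministic and
#' dependency-free (feature-hashed character 3-grams, see
#' [reference_token_vector()]), so the whole pipeline runs offline. An
#' external sentence-transformer can be plugged in by passing its per-token
#' (or per-text) vector function as `token_fun`; it must honour the same
#' contract (fixed dimension, finite values).
#'
#' @param name `"reference"` or a custom identifier (custom names require
#'   `token_fun`).
#' @param dim Embedding dimension (>= 16 for the reference embedder).
#' @param token_fun Optional function `(token, dim) -> numeric(dim)`
#'   overriding the reference token encoder.
#' @param deterministic Whether the embedder is deterministic.
#' @return An object of class `phq_embedder`.
#' @export
make_embedder <- function(name = "reference", dim = 128L, token_fun = NULL,
                          deterministic = TRUE) {
  dim <- as.integer(dim)
  if (is.na(dim) || dim <= 0L) config_error("embedder dim must be a positive integer")
  if (is.null(token_fun)) {
    if (!identical(name, "reference")) {
      config_error(sprintf(
        "unknown embedder '%s': only 'reference' is built in; supply token_fun for a plugin",
        name))
    }
    if (dim < 16L) config_error("reference embedder requires dim >= 16")
    token_fun <- reference_token_vector
  }
  structure(list(name = name, dim = dim, token_fun = token_fun,
                 deterministic = isTRUE(deterministic)),
            class = "phq_embedder")
}

#' Deterministic reference token vector
#'
#' Encodes a token as a feature-hashed character-3-gram count vector: the
#' token is wrapped as `^token$`, each 3-gram is hashed to a bucket in
#' `[0, dim)`, a second independent hash decides the sign, and the bucket
#' counts are L2-normalized. The construction is pure integer arithmetic on
#' Unicode codepoints, so the same token yields an identical vector on every
#' platform and run. Tokens sharing 3-grams (morphological variants, typos)
#' land near each other, which is the property the cosine reranking relies
#' on.
#'
#' @param token Non-empty string.
#' @param dim Vector dimension (>= 16).
#' @return Numeric vector of length `dim` with unit L2 norm (zero vector for
#'   an empty token).
#' @export
reference_token_vector <- function(token, dim = 128L) {
  dim <- as.integer(dim)
  stopifnot(dim >= 16L)
  if (!nzchar(token)) return(numeric(dim))
  key <- paste0(dim, ":", token)
  hit <- .token_cache[[key]]
  if (!is.null(hit)) return(hit)
  s <- paste0("^", token, "$")
  n <- nchar(s)
  v <- numeric(dim)
  for (i in seq_len(n - 2L)) {
    g <- substr(s, i, i + 2L)
    bucket <- str_hash(g, mult = 31, seed = 17) %% dim + 1L
    sign <- if (str_hash(g, mult = 131, seed = 7) %% 2 == 0) 1 else -1
    v[bucket] <- v[bucket] + sign
  }
  nrm <- sqrt(sum(v^2))
  if (nrm > 0) v <- v / nrm
  .token_cache[[key]] <- v
  v
}

#' Embed a token sequence by mean pooling
#'
#' Averages the per-token vectors of the embedder and L2-normalizes the
#' result. The empty sequence maps to the zero vector, whose similarity with
#' anything is defined as 0.
#'
#' @param tokens Character vector from [preprocess()].
#' @param embedder A `phq_embedder` from [make_embedder()].
#' @return Numeric vector of length `embedder$dim`.
#' @export
embed_tokens <- function(tokens, embedder) {
  stopifnot(inherits(embedder, "phq_embedder"))
  d <- embedder$dim
  if (length(tokens) == 0L) return(numeric(d))
  m <- vapply(tokens, embedder$token_fun, numeric(d), dim = d)
  v <- if (is.null(dim(m))) m else rowMeans(m)
  if (length(v) != d) config_error("embedder returned wrong dimension")
  if (any(!is.finite(v))) config_error("embedder returned non-finite values")
  nrm <- sqrt(sum(v^2))
  if (nrm > 0) v <- v / nrm
  v
}

#' Embed raw text
#'
#' Convenience composition `preprocess()` then [embed_tokens()].
#'
#' @inheritParams preprocess
#' @inheritParams embed_tokens
#' @return Numeric vector of length `embedder$dim`.
#' @export
embed_text <- function(text, embedder, stopwords = default_stopwords()) {
  embed_tokens(preprocess(text, stopwords = stopwords), embedder)
}

#' Cosine similarity between two vectors
#'
#' Computes `A.B / (||A|| ||B||)`, with the convention that the similarity is
#' 0 when either vector has zero norm.
#'
#' @param a,b Numeric vectors of equal length.
#' @return Scalar in `[-1, 1]`.
#' @export
#' @examples
#' cosine_similarity(c(1, 2, 2), c(2, 1, 2))  # 8/9
cosine_similarity <- function(a, b) {
  if (length(a) != length(b)) validation_error("cosine_similarity: dimension mismatch")
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}
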