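#' Normalize free text for matching
#'
#' Lowercases, replaces every non-alphanumeric character with a space and
#' collapses runs of whitespace. All phrase matching and character offsets in
#' the package are defined on this normalized form, so the same transform is
#' applied to ontology terms, SNOMED terms and input text.
#'
#' @param x Character vector.
#' @return Character vector of the same length, normalized.
#' @export
#' @examples
#' normalize_text("I feel DOWN,   depressed.")
normalize_text <- function(x) {
  x <- tolower(x)
  x <- gsub("[^a-z0-9]+", " ", x)
  trimws(x)
}

#' Split raw text into sentences
#'
#' Sentences are delimited by `.`, `!` or `?`. Empty fragments are dropped.
#' Used both for frequency-modifier scoping in cue matching and for
#' per-sentence classification.
#'
#' @param x A single character string.
#' @return Character vector of raw (un-normalized) sentence fragments.
#' @export
split_sentences <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  if (is.na(x) || !nzchar(x)) return(character(0))
  parts <- strsplit(x, "[.!?]+")[[1]]
  parts <- trimws(parts)
  parts[nzchar(parts)]
}

# Deterministic 31-bit polynomial string hash. Pure double arithmetic:
# h < 2^31 and codepoints < 2^21, so h * mult + code stays well below 2^53
# and is exact on every IEEE-754 platform.
str_hash <- function(s, mult = 31, seed = 17) {
  codes <- utf8ToInt(s)
  h <- seed
  for (code in codes) {
    h <- (h * mult + code) %% 2147483647
  }
  h
}

# Run expr with a temporary, explicitly seeded RNG, restoring (or removing)
# the caller's .Random.seed afterwards. Keeps all public entry points free of
# global RNG state.
with_local_seed <- function(seed, expr) {
  env <- globalenv()
  had_seed <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

#' Default English stop-word list
#'
#' Returns the packaged list of ~150 English function words removed during
#' preprocessing and keyword extraction. The list deliberately avoids
#' sentiment- or symptom-bearing words (e.g. "down" is kept as content).
#'
#' @return Character vector of lowercase stop words.
#' @export
default_stopwords <- function() {
  path <- system.file("extdata", "stopwords_en.txt", package = "phqscreen")
  if (!nzchar(path)) stop("packaged stop-word list not found", call. = FALSE)
  readLines(path, encoding = "UTF-8", warn = FALSE)
}

phq9_items <- function() paste0("S", 1:9)

# Canonical condition-style errors so the CLI can map classes to exit codes.
phq_error <- function(msg, class) {
  stop(structure(
    class = c(class, "phqscreen_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}
validation_error <- function(msg) phq_error(msg, "phqscreen_validation_error")
io_error <- function(msg) phq_error(msg, "phqscreen_io_error")
config_error <- function(msg) phq_error(msg, "phqscreen_config_error")
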