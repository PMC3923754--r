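#' @useDynLib rednotes, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rgamma runif sd setNames coef logLik predict terms
#' @importFrom utils head
NULL

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Default stopword list
#'
#' A small list of English function words removed during tokenization.
#' Clinical corpora typically warrant a longer, domain-tuned list; this
#' default keeps synthetic and toy corpora clean without imposing one.
#'
#' @return Character vector of lowercase stopwords.
#' @export
default_stopwords <- function() {
  c("a", "an", "the", "and", "or", "but", "of", "to", "in", "on", "at",
    "by", "for", "with", "from", "as", "is", "are", "was", "were", "be",
    "been", "being", "it", "its", "this", "that", "these", "those", "he",
    "she", "they", "we", "you", "i", "his", "her", "their", "our", "not",
    "no", "has", "have", "had", "do", "does", "did", "will", "would")
}

#' Tokenize text into lowercase word tokens with character spans
#'
#' Lowercases, extracts maximal alphanumeric runs, then drops single-character
#' tokens and stopwords. Spans are 0-based half-open `[start, end)` offsets
#' into the original string, so copied-span character positions can later be
#' mapped back onto tokens.
#'
#' @param text A character scalar.
#' @param stopwords Character vector of tokens to drop (compared lowercase).
#' @return A list with `terms` (character vector) and `spans`
#'   (integer matrix with columns `start`, `end`).
#' @examples
#' tokenize_text("Pt with CHF.", stopwords = "with")
#' @export
tokenize_text <- function(text, stopwords = default_stopwords()) {
  stopifnot(is.character(text), length(text) == 1L)
  empty <- list(terms = character(0),
                spans = matrix(integer(0), ncol = 2L,
                               dimnames = list(NULL, c("start", "end"))))
  if (is.na(text) || !nzchar(text)) return(empty)
  low <- tolower(text)
  m <- gregexpr("[a-z0-9]+", low, perl = TRUE)[[1]]
  if (m[1] == -1L) return(empty)
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  terms <- substring(low, starts, starts + lens - 1L)
  keep <- lens > 1L & !(terms %in% stopwords)
  if (!any(keep)) return(empty)
  spans <- cbind(start = starts[keep] - 1L, end = starts[keep] - 1L + lens[keep])
  list(terms = terms[keep], spans = spans)
}

new_note <- function(note_id, record_id, raw_text, tokens, spans = NULL) {
  structure(list(note_id = note_id, record_id = record_id,
                 raw_text = raw_text, tokens = as.integer(tokens),
                 spans = spans),
            class = "rednotes_note")
}

new_record_corpus <- function(records, vocab) {
  structure(list(records = records, vocab = vocab), class = "record_corpus")
}

#' @export
print.record_corpus <- function(x, ...) {
  nn <- sum(vapply(x$records, function(r) length(r$notes), integer(1)))
  nt <- sum(vapply(corpus_notes(x), function(n) length(n$tokens), integer(1)))
  cat(sprintf("Record corpus: %d records, %d notes, %d tokens, vocabulary %d\n",
              length(x$records), nn, nt, length(x$vocab)))
  invisible(x)
}

#' Flat list of all notes in a corpus
#'
#' @param corpus A `record_corpus`.
#' @return List of note objects, records in order, notes in stored order.
#' @export
corpus_notes <- function(corpus) {
  unlist(lapply(corpus$records, function(r) r$notes), recursive = FALSE,
         use.names = FALSE)
}

#' Number of records in a corpus
#' @param corpus A `record_corpus`.
#' @return Integer count.
#' @export
n_records <- function(corpus) length(corpus$records)

# Build a record_corpus from a data.frame of (record_id, note_id, text) or
# pre-tokenized term lists. `terms` is a list column of character vectors; if
# NULL, `text` is tokenized.
build_corpus <- function(df, stopwords, min_count, terms_list = NULL) {
  if (nrow(df) == 0L) stop("empty corpus")
  ord <- order(df$record_id, df$note_id)
  df <- df[ord, , drop = FALSE]
  if (!is.null(terms_list)) terms_list <- terms_list[ord]
  dup <- duplicated(df[, c("record_id", "note_id")])
  if (any(dup)) {
    stop(sprintf("duplicate note_id '%s' within record '%s'",
                 df$note_id[dup][1], df$record_id[dup][1]))
  }
  toks <- vector("list", nrow(df))
  spans <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    if (!is.null(terms_list) && !is.null(terms_list[[i]])) {
      toks[[i]] <- terms_list[[i]]
    } else {
      tk <- tokenize_text(df$text[i], stopwords)
      toks[[i]] <- tk$terms
      spans[[i]] <- tk$spans
    }
  }
  counts <- table(unlist(toks, use.names = FALSE))
  vocab <- sort(names(counts)[counts >= min_count])
  if (length(vocab) == 0L) stop("empty vocabulary after pruning")
  records <- list()
  for (i in seq_len(nrow(df))) {
    rid <- df$record_id[i]
    nid <- df$note_id[i]
    ids <- match(toks[[i]], vocab)
    keep <- !is.na(ids)
    sp <- if (!is.null(spans[[i]])) spans[[i]][keep, , drop = FALSE] else NULL
    note <- new_note(nid, rid, df$text[i], ids[keep], sp)
    if (is.null(records[[rid]])) records[[rid]] <- list(record_id = rid, notes = list())
    records[[rid]]$notes[[nid]] <- note
  }
  new_record_corpus(records, vocab)
}

#' Load a clustered note corpus
#'
#' Reads a collection of patient records (one cluster of notes per record)
#' from either a directory tree (`<root>/<record_id>/<note_id>.txt`) or a
#' JSON-lines file with keys `record_id`, `note_id`, `text` and optionally
#' `tokens` (pre-tokenized term strings, used verbatim when present).
#' Records are ordered by `record_id` and notes by `note_id`, so repeated
#' loads of the same input yield identical corpora.
#'
#' @param path Directory or file path.
#' @param format `"dir"` or `"jsonl"`.
#' @param stopwords Stopword list passed to [tokenize_text()].
#' @param min_count Minimum corpus frequency for a term to enter the
#'   vocabulary; rarer tokens are dropped from the notes (default 5).
#' @return A `record_corpus`.
#' @export
load_corpus <- function(path, format = c("dir", "jsonl"),
                        stopwords = default_stopwords(), min_count = 5L) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("input path does not exist: %s", path))
  if (format == "dir") {
    recs <- sort(list.dirs(path, full.names = FALSE, recursive = FALSE))
    rows <- list()
    for (rid in recs) {
      files <- sort(list.files(file.path(path, rid), pattern = "\\.txt$",
                               full.names = FALSE))
      if (length(files) == 0L) {
        warning(sprintf("record '%s' has no .txt notes; skipped", rid))
        next
      }
      for (f in files) {
        txt <- paste(readLines(file.path(path, rid, f), warn = FALSE),
                     collapse = "\n")
        rows[[length(rows) + 1L]] <- data.frame(
          record_id = rid, note_id = sub("\\.txt$", "", f), text = txt,
          stringsAsFactors = FALSE)
      }
    }
    if (length(rows) == 0L) stop("empty corpus")
    df <- do.call(rbind, rows)
    build_corpus(df, stopwords, min_count)
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0L) stop("empty corpus")
    objs <- lapply(lines, jsonlite::fromJSON)
    df <- data.frame(
      record_id = vapply(objs, function(o) as.character(o$record_id), ""),
      note_id = vapply(objs, function(o) as.character(o$note_id), ""),
      text = vapply(objs, function(o) {
        if (is.null(o$text)) "" else as.character(o$text)
      }, ""),
      stringsAsFactors = FALSE)
    terms_list <- lapply(objs, function(o) {
      if (is.null(o$tokens)) NULL else as.character(unlist(o$tokens))
    })
    if (all(vapply(terms_list, is.null, logical(1)))) terms_list <- NULL
    build_corpus(df, stopwords, min_count, terms_list = terms_list)
  }
}

#' Write a corpus as JSON lines
#'
#' One object per note with `record_id`, `note_id`, `text` and `tokens`
#' (term strings). Reloading the dump with `min_count = 1` and the same
#' stopword list reproduces the token-id sequences exactly, because the
#' vocabulary is always the sorted set of surviving terms.
#'
#' @param corpus A `record_corpus`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_corpus_jsonl <- function(corpus, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  for (note in corpus_notes(corpus)) {
    obj <- list(record_id = note$record_id, note_id = note$note_id,
                text = if (is.null(note$raw_text)) "" else note$raw_text,
                tokens = corpus$vocab[note$tokens])
    writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE), con)
  }
  invisible(path)
}

#' Split a corpus into training records and held-out test notes
#'
#' Holds out `n_test_records` whole records (so train and test patients are
#' disjoint) and, from each held-out record, keeps the single least-redundant
#' note as the test document, requiring its copied-token fraction to be at
#' most `max_test_redundancy` (the source note always qualifies at 0). Ties
#' on the copied fraction go to the lexicographically earliest `note_id`.
#'
#' @param corpus A `record_corpus`.
#' @param n_test_records Number of records to hold out.
#' @param seed Integer seed; the record sample is deterministic given it.
#' @param annotation A `redundancy_annotation` covering the corpus.
#' @param max_test_redundancy Maximum copied-token fraction a test note may
#'   have (default 0.15).
#' @return List with `train` (a `record_corpus`) and `test` (list of notes).
#' @export
split_by_record <- function(corpus, n_test_records, seed, annotation,
                            max_test_redundancy = 0.15) {
  rids <- names(corpus$records)
  if (n_test_records > length(rids)) {
    stop(sprintf("cannot hold out %d records from a corpus of %d",
                 n_test_records, length(rids)))
  }
  eligible_note <- function(rid) {
    notes <- corpus$records[[rid]]$notes
    fr <- vapply(names(notes), function(nid)
      redundancy_fraction(annotation, rid, nid), numeric(1))
    nid <- names(notes)[order(fr, names(notes))][1]
    if (fr[[nid]] <= max_test_redundancy) nid else NA_character_
  }
  picks <- vapply(rids, eligible_note, character(1))
  pool <- rids[!is.na(picks)]
  if (length(pool) < n_test_records) {
    stop("not enough records with a note under the redundancy threshold")
  }
  test_rids <- sort(with_seed(seed, sample(pool, n_test_records)))
  train <- new_record_corpus(corpus$records[setdiff(rids, test_rids)],
                             corpus$vocab)
  test <- lapply(test_rids, function(rid)
    corpus$records[[rid]]$notes[[picks[[rid]]]])
  list(train = train, test = test)
}
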