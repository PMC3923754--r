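#' Select a record's source note
#'
#' The source note of a record — the note all copied text is attributed to —
#' is the longest note by token count, ties going to the earliest `note_id`.
#'
#' @param cluster A record, i.e. an element of `corpus$records`.
#' @return The `note_id` of the source note.
#' @export
select_source <- function(cluster) {
  stopifnot(length(cluster$notes) >= 1L)
  lens <- vapply(cluster$notes, function(n) length(n$tokens), integer(1))
  ids <- names(cluster$notes)
  ids[order(-lens, ids)][1]
}

# Polynomial rolling hash of every k-gram of an integer token vector.
# Values stay below 2^31 so double arithmetic is exact. Collisions are
# harmless: every seed match is verified token-by-token before extension.
kgram_hashes <- function(tokens, k) {
  n <- length(tokens)
  if (n < k) return(numeric(0))
  mod <- 2147483647
  base <- 131
  h <- numeric(n - k + 1L)
  for (j in seq_len(k)) {
    h <- (h * base + tokens[j:(n - k + j)]) %% mod
  }
  h
}

# Winnowing selection: for each window of `window` consecutive k-gram
# hashes keep the position of the (leftmost) minimum. Any shared token run
# of length >= k + window - 1 is guaranteed to contribute a selected seed.
winnow_positions <- function(hashes, window) {
  n <- length(hashes)
  if (n == 0L) return(integer(0))
  if (n <= window) return(which.min(hashes))
  sel <- integer(n - window + 1L)
  for (s in seq_len(n - window + 1L)) {
    w <- hashes[s:(s + window - 1L)]
    sel[s] <- s + which.min(w) - 1L
  }
  sort(unique(sel))
}

# Maximal exact token run through seed (cp, sp): extend in both directions.
extend_run <- function(copy, src, cp, sp, k) {
  a <- 0L
  while (cp - a - 1L >= 1L && sp - a - 1L >= 1L &&
         copy[cp - a - 1L] == src[sp - a - 1L]) a <- a + 1L
  b <- k - 1L
  while (cp + b + 1L <= length(copy) && sp + b + 1L <= length(src) &&
         copy[cp + b + 1L] == src[sp + b + 1L]) b <- b + 1L
  c(cp_start = cp - a, s_start = sp - a, len = a + b + 1L)
}

# Annotate one non-source note against the source token vector.
annotate_note_vs_source <- function(copy, src, k, window, min_span) {
  n <- length(copy)
  copied <- rep(FALSE, n)
  source_pos <- rep(NA_integer_, n)
  if (n < k || length(src) < k) {
    return(list(copied = copied, source_pos = source_pos))
  }
  src_h <- kgram_hashes(src, k)
  src_index <- split(seq_along(src_h), src_h)
  cp_h <- kgram_hashes(copy, k)
  seeds <- winnow_positions(cp_h, window)
  runs <- list()
  seen <- character(0)
  for (cp in seeds) {
    hits <- src_index[[as.character(cp_h[cp])]]
    for (sp in hits) {
      if (!all(copy[cp:(cp + k - 1L)] == src[sp:(sp + k - 1L)])) next
      r <- extend_run(copy, src, cp, sp, k)
      key <- sprintf("%d:%d", r[["cp_start"]], r[["s_start"]])
      if (key %in% seen) next
      seen <- c(seen, key)
      if (r[["len"]] >= min_span) runs[[length(runs) + 1L]] <- r
    }
  }
  if (length(runs) > 0L) {
    rr <- do.call(rbind, runs)
    ord <- order(-rr[, "len"], rr[, "cp_start"], rr[, "s_start"])
    rr <- rr[ord, , drop = FALSE]
    for (i in seq_len(nrow(rr))) {
      idx <- seq.int(rr[i, "cp_start"], length.out = rr[i, "len"])
      fresh <- !copied[idx]
      copied[idx[fresh]] <- TRUE
      source_pos[idx[fresh]] <-
        seq.int(rr[i, "s_start"], length.out = rr[i, "len"])[fresh]
    }
  }
  list(copied = copied, source_pos = source_pos)
}

#' Detect copied spans within each record
#'
#' For every record, designates a source note via [select_source()] and flags
#' tokens of the other notes that lie in shared token runs with the source.
#' Matching uses k-gram fingerprinting with winnowing: all source k-grams are
#' indexed, the copying note keeps the minimum hash per sliding window as
#' seeds, seed matches are verified and extended to maximal exact runs, and
#' runs of at least `min_span` tokens are kept. Overlapping runs are resolved
#' greedily, longest first, then leftmost in the copy, then leftmost in the
#' source. Every shared run of length `>= k + window - 1` is guaranteed to
#' be seeded; runs between `min_span` and that bound may occasionally be
#' missed by winnowing.
#'
#' @param corpus A `record_corpus`.
#' @param k Fingerprint k-gram length in tokens (default 8).
#' @param window Winnowing window size in k-grams (default 4).
#' @param min_span Minimum copied-run length in tokens (default 10; must be
#'   `>= k`).
#' @return A `redundancy_annotation`: per record the `source_note`, and per
#'   note logical `copied` flags and integer `source_pos` (NA where not
#'   copied) aligned to the note's tokens.
#' @export
annotate_redundancy <- function(corpus, k = 8L, window = 4L, min_span = 10L) {
  stopifnot(k >= 2L, min_span >= k, window >= 1L)
  records <- list()
  for (rec in corpus$records) {
    src_id <- select_source(rec)
    src <- rec$notes[[src_id]]$tokens
    notes <- list()
    for (nid in names(rec$notes)) {
      toks <- rec$notes[[nid]]$tokens
      if (nid == src_id) {
        notes[[nid]] <- list(copied = rep(FALSE, length(toks)),
                             source_pos = rep(NA_integer_, length(toks)))
      } else {
        notes[[nid]] <- annotate_note_vs_source(toks, src, k, window, min_span)
      }
    }
    records[[rec$record_id]] <- list(source_note = src_id, notes = notes)
  }
  structure(list(records = records,
                 params = list(k = k, window = window, min_span = min_span)),
            class = "redundancy_annotation")
}

#' Empty redundancy annotation
#'
#' An annotation in which no token is copied; sources are still designated
#' (longest note per record). Fitting Red-LDA with it reproduces vanilla LDA
#' exactly.
#'
#' @param corpus A `record_corpus`.
#' @return A `redundancy_annotation` with all `copied` flags `FALSE`.
#' @export
empty_annotation <- function(corpus) {
  records <- lapply(corpus$records, function(rec) {
    notes <- lapply(rec$notes, function(n) {
      list(copied = rep(FALSE, length(n$tokens)),
           source_pos = rep(NA_integer_, length(n$tokens)))
    })
    list(source_note = select_source(rec), notes = notes)
  })
  structure(list(records = records, params = list()),
            class = "redundancy_annotation")
}

#' @export
print.redundancy_annotation <- function(x, ...) {
  nrec <- length(x$records)
  nc <- sum(vapply(x$records, function(r)
    sum(vapply(r$notes, function(n) sum(n$copied), numeric(1))), numeric(1)))
  nt <- sum(vapply(x$records, function(r)
    sum(vapply(r$notes, function(n) length(n$copied), numeric(1))), numeric(1)))
  cat(sprintf("Redundancy annotation: %d records, %.0f/%.0f tokens copied (%.1f%%)\n",
              nrec, nc, nt, if (nt > 0) 100 * nc / nt else 0))
  invisible(x)
}

#' Copied-token fraction of a note
#'
#' @param annotation A `redundancy_annotation`.
#' @param record_id,note_id Identify the note.
#' @return Fraction of the note's tokens flagged as copied; 0 for the source
#'   note and for empty notes.
#' @export
redundancy_fraction <- function(annotation, record_id, note_id) {
  ann <- annotation$records[[record_id]]$notes[[note_id]]
  if (is.null(ann)) stop(sprintf("note '%s/%s' not annotated", record_id, note_id))
  if (length(ann$copied) == 0L) return(0)
  mean(ann$copied)
}

#' Smith-Waterman similarity between two notes
#'
#' Local alignment over token sequences with unit match score (+1) and
#' mismatch/gap penalties (-1 each by default); the best local score is
#' normalised by `match * min(length_a, length_b)` and clamped to [0, 1],
#' so identical notes score 1 and notes over disjoint vocabularies score 0.
#'
#' @param note_a,note_b Notes (or bare integer token vectors).
#' @param match,mismatch,gap Alignment scores.
#' @return Similarity fraction in [0, 1].
#' @export
smith_waterman_similarity <- function(note_a, note_b, match = 1,
                                      mismatch = -1, gap = -1) {
  a <- if (is.list(note_a)) note_a$tokens else as.integer(note_a)
  b <- if (is.list(note_b)) note_b$tokens else as.integer(note_b)
  if (length(a) == 0L || length(b) == 0L) return(0)
  score <- cpp_smith_waterman(a, b, match, mismatch, gap)
  min(1, max(0, score / (match * min(length(a), length(b)))))
}

#' Same-record similarity profile of a corpus
#'
#' Uniformly samples pairs of distinct notes from the same record (records
#' with at least two notes) and reports their Smith-Waterman similarity,
#' characterising how much copy-paste redundancy the corpus carries.
#'
#' @param corpus A `record_corpus`.
#' @param n_pairs Number of pairs to sample.
#' @param seed Integer seed; sampling is deterministic given it.
#' @return A list with `pairs` (data.frame of record_id, note_a, note_b,
#'   similarity) and `mean_same_record_similarity`.
#' @export
corpus_similarity_report <- function(corpus, n_pairs = 100L, seed = 1L) {
  stopifnot(n_pairs >= 1L)
  eligible <- Filter(function(r) length(r$notes) >= 2L, corpus$records)
  if (length(eligible) == 0L) stop("no record has two or more notes")
  rows <- with_seed(seed, {
    lapply(seq_len(n_pairs), function(i) {
      rec <- eligible[[sample.int(length(eligible), 1L)]]
      ids <- sort(sample(names(rec$notes), 2L))
      sim <- smith_waterman_similarity(rec$notes[[ids[1]]], rec$notes[[ids[2]]])
      data.frame(record_id = rec$record_id, note_a = ids[1], note_b = ids[2],
                 similarity = sim, stringsAsFactors = FALSE)
    })
  })
  pairs <- do.call(rbind, rows)
  list(pairs = pairs,
       mean_same_record_similarity = mean(pairs$similarity))
}
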