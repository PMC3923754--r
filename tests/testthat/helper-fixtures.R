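# Shared fixture builders and independent oracles for the test suite.

# Build a record_corpus directly from integer token vectors:
# records = named list(record_id -> named list(note_id -> integer tokens)).
make_corpus <- function(records, V) {
  vocab <- sprintf("w%04d", seq_len(V))
  recs <- lapply(names(records), function(rid) {
    notes <- lapply(names(records[[rid]]), function(nid) {
      rednotes:::new_note(nid, rid, "", as.integer(records[[rid]][[nid]]))
    })
    names(notes) <- names(records[[rid]])
    list(record_id = rid, notes = notes)
  })
  names(recs) <- names(records)
  rednotes:::new_record_corpus(recs, vocab)
}

# Annotation with explicit copied flags:
# flags = named list(record_id -> list(source = note_id,
#                                      notes = named list(note_id ->
#                                        list(copied=, source_pos=))))
make_annotation <- function(corpus, flags) {
  recs <- lapply(names(corpus$records), function(rid) {
    f <- flags[[rid]]
    notes <- lapply(names(corpus$records[[rid]]$notes), function(nid) {
      n_tok <- length(corpus$records[[rid]]$notes[[nid]]$tokens)
      a <- f$notes[[nid]]
      if (is.null(a)) {
        list(copied = rep(FALSE, n_tok), source_pos = rep(NA_integer_, n_tok))
      } else a
    })
    names(notes) <- names(corpus$records[[rid]]$notes)
    list(source_note = f$source, notes = notes)
  })
  names(recs) <- names(corpus$records)
  structure(list(records = recs, params = list()),
            class = "redundancy_annotation")
}

# From-scratch recount oracle: rebuild the sampler count matrices from raw
# topic assignments and counted flags, independent of the C++ bookkeeping.
recount_from_z <- function(z_by_doc, counted_by_doc, tokens_by_doc, D, K, V) {
  n_dk <- matrix(0L, D, K)
  n_kw <- matrix(0L, K, V)
  n_k <- integer(K)
  for (d in seq_len(D)) {
    for (i in seq_along(z_by_doc[[d]])) {
      k <- z_by_doc[[d]][i]  # 1-based topics as stored on the model
      n_dk[d, k] <- n_dk[d, k] + 1L
      if (counted_by_doc[[d]][i]) {
        w <- tokens_by_doc[[d]][i]
        n_kw[k, w] <- n_kw[k, w] + 1L
        n_k[k] <- n_k[k] + 1L
      }
    }
  }
  list(n_dk = n_dk, n_kw = n_kw, n_k = n_k)
}

# Brute-force oracle: union of copy-note positions lying in any maximal
# common token substring of length >= min_span shared with the source.
brute_force_copied <- function(copy, src, min_span) {
  n <- length(copy); m <- length(src)
  flagged <- rep(FALSE, n)
  if (n == 0L || m == 0L) return(flagged)
  # run[i,j] = length of common suffix ending at copy[i], src[j]
  run <- matrix(0L, n + 1L, m + 1L)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      if (copy[i] == src[j]) run[i + 1L, j + 1L] <- run[i, j] + 1L
    }
  }
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      len <- run[i + 1L, j + 1L]
      maximal <- (i == n || j == m || copy[i + 1L] != src[j + 1L])
      if (len >= min_span && maximal) {
        flagged[(i - len + 1L):i] <- TRUE
      }
    }
  }
  flagged
}

# Plain R Smith-Waterman oracle (full DP table).
sw_oracle <- function(a, b, match = 1, mismatch = -1, gap = -1) {
  n <- length(a); m <- length(b)
  H <- matrix(0, n + 1, m + 1)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      H[i + 1, j + 1] <- max(0,
        H[i, j] + if (a[i] == b[j]) match else mismatch,
        H[i, j + 1] + gap, H[i + 1, j] + gap)
    }
  }
  max(H)
}

# Total copied tokens in an annotation.
total_copied <- function(annotation) {
  sum(vapply(annotation$records, function(r)
    sum(vapply(r$notes, function(n) sum(n$copied), numeric(1))), numeric(1)))
}

# Detector recall against a ground-truth annotation.
detector_recall <- function(detected, truth_ann) {
  hits <- 0; total <- 0
  for (rid in names(truth_ann$records)) {
    for (nid in names(truth_ann$records[[rid]]$notes)) {
      tr <- truth_ann$records[[rid]]$notes[[nid]]$copied
      de <- detected$records[[rid]]$notes[[nid]]$copied
      total <- total + sum(tr)
      hits <- hits + sum(tr & de)
    }
  }
  if (total == 0) return(NA_real_)
  hits / total
}
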