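rdirichlet1 <- function(n, conc) {
  g <- rgamma(n, shape = conc, rate = 1)
  if (sum(g) == 0) g <- rep(1, n)
  g / sum(g)
}

#' Simulate a clustered note corpus with copy-paste redundancy
#'
#' Generates patient-record-like clusters from the redundancy-aware
#' generative story. Topic-word distributions are drawn from a symmetric
#' Dirichlet(`beta`); each record's source note is generated by the plain
#' LDA process (note-level mixture from Dirichlet(`alpha`), then topic and
#' word per token); each remaining note copies one or more contiguous token
#' spans from random offsets of its source — totalling a per-note fraction
#' drawn from `copy_fraction` — and generates its other tokens from its own
#' mixture. By default copied tokens retain the topic assignment of their
#' source occurrence, which makes the generator exactly the model the
#' redundancy-aware sampler assumes; set `retain_topics = FALSE` to emulate
#' mis-specified copying in which pasted words carry no topic information.
#'
#' Defaults emulate the redundancy profile of a real clinical corpus, where
#' the average same-record note similarity is around 0.3, at a scale (50
#' records of 4 notes, 100-200 tokens each, K = 5, V = 200) where recovery
#' experiments run in seconds.
#'
#' @param n_records Number of records (default 50).
#' @param notes_per_record Range (min, max) of notes per record (default
#'   `c(4, 4)`).
#' @param K,V Number of topics and vocabulary size.
#' @param source_length,other_length Token-count ranges for source and
#'   non-source notes. Source notes are drawn longer and non-source notes
#'   are capped at their source's length, so the longest-note source
#'   heuristic always identifies the generating source.
#' @param alpha,beta Dirichlet concentrations of the generating mixtures.
#' @param copy_fraction Range of the per-note copied-token fraction.
#' @param span_length Range of copied-span lengths in tokens; spans shorter
#'   than a detector's `min_span` are undetectable (warned).
#' @param retain_topics Logical; copied tokens keep their source topic
#'   (default `TRUE`).
#' @param seed Integer seed; generation is deterministic given it.
#' @param min_span_warn Detector `min_span` used for the detectability
#'   warning (default 10).
#' @return List with `corpus` (a `record_corpus`), `annotation` (the exact
#'   ground-truth `redundancy_annotation`, independent of any detector), and
#'   `truth` (list with `phi`, per-note `theta`, `z`, `copied`, `source`).
#' @export
simulate_records <- function(n_records = 50L, notes_per_record = c(4L, 4L),
                             K = 5L, V = 200L,
                             source_length = c(150L, 250L),
                             other_length = c(100L, 200L),
                             alpha = 0.3, beta = 0.05,
                             copy_fraction = c(0.2, 0.4),
                             span_length = c(20L, 40L),
                             retain_topics = TRUE, seed = 1L,
                             min_span_warn = 10L) {
  stopifnot(K >= 1L, V >= 2L, n_records >= 1L,
            all(copy_fraction >= 0), all(copy_fraction <= 1))
  if (V < 5L * K) warning("V < 5*K: topics will be hard to separate")
  if (span_length[1] < min_span_warn && any(copy_fraction > 0)) {
    warning("span_length below detector min_span: copied spans may be undetectable")
  }
  vocab <- sprintf("w%04d", seq_len(V))
  runif_int <- function(rng) {
    if (rng[1] >= rng[2]) return(as.integer(rng[1]))
    sample(seq.int(rng[1], rng[2]), 1L)
  }
  with_seed(seed, {
    phi <- t(vapply(seq_len(K), function(k) rdirichlet1(V, beta), numeric(V)))
    records <- list()
    ann_records <- list()
    truth_theta <- list()
    truth_z <- list()
    for (ri in seq_len(n_records)) {
      rid <- sprintf("r%03d", ri)
      n_notes <- runif_int(notes_per_record)
      # source note: plain LDA process
      src_len <- runif_int(source_length)
      src_theta <- rdirichlet1(K, alpha)
      src_z <- sample.int(K, src_len, replace = TRUE, prob = src_theta)
      src_w <- vapply(src_z, function(k)
        sample.int(V, 1L, prob = phi[k, ]), integer(1))
      note_ids <- sprintf("n%02d", seq_len(n_notes))
      src_id <- note_ids[1]
      notes <- list()
      ann_notes <- list()
      toks_list <- list()
      z_list <- list()
      th_list <- list()
      toks_list[[src_id]] <- src_w
      z_list[[src_id]] <- src_z
      th_list[[src_id]] <- src_theta
      ann_notes[[src_id]] <- list(copied = rep(FALSE, src_len),
                                  source_pos = rep(NA_integer_, src_len))
      for (nid in note_ids[-1]) {
        # cap at the source length so the longest-note rule (ties to the
        # earliest note_id) always identifies the true source
        len <- min(runif_int(other_length), src_len)
        cf <- runif(1, copy_fraction[1], copy_fraction[2])
        n_copy <- min(round(cf * len), len)
        # partition the copied budget into spans of at least span_length[1]
        span_lens <- integer(0)
        remaining <- n_copy
        while (remaining >= span_length[1]) {
          s <- min(runif_int(span_length), remaining)
          if (remaining - s < span_length[1]) s <- remaining
          s <- min(s, src_len)  # spans cannot exceed the source
          span_lens <- c(span_lens, s)
          remaining <- remaining - s
        }
        n_copy <- sum(span_lens)
        n_fresh <- len - n_copy
        theta_d <- rdirichlet1(K, alpha)
        fresh_z <- if (n_fresh > 0)
          sample.int(K, n_fresh, replace = TRUE, prob = theta_d) else integer(0)
        fresh_w <- vapply(fresh_z, function(k)
          sample.int(V, 1L, prob = phi[k, ]), integer(1))
        # splice copied spans at random non-overlapping insertion points
        slots <- sort(sample.int(n_fresh + 1L, length(span_lens),
                                 replace = TRUE)) - 1L
        toks <- integer(0); zs <- integer(0)
        copied <- logical(0); spos <- integer(0)
        prev <- 0L
        for (si in seq_along(span_lens)) {
          sl <- span_lens[si]
          start <- sample.int(src_len - sl + 1L, 1L)
          seg <- seq.int(prev + 1L, length.out = slots[si] - prev)
          if (slots[si] > prev) {
            toks <- c(toks, fresh_w[seg]); zs <- c(zs, fresh_z[seg])
            copied <- c(copied, rep(FALSE, length(seg)))
            spos <- c(spos, rep(NA_integer_, length(seg)))
          }
          src_idx <- seq.int(start, length.out = sl)
          toks <- c(toks, src_w[src_idx])
          zs <- c(zs, if (retain_topics) src_z[src_idx]
                      else sample.int(K, sl, replace = TRUE, prob = theta_d))
          copied <- c(copied, rep(TRUE, sl))
          spos <- c(spos, src_idx)
          prev <- slots[si]
        }
        if (n_fresh > prev) {
          seg <- seq.int(prev + 1L, n_fresh)
          toks <- c(toks, fresh_w[seg]); zs <- c(zs, fresh_z[seg])
          copied <- c(copied, rep(FALSE, length(seg)))
          spos <- c(spos, rep(NA_integer_, length(seg)))
        }
        toks_list[[nid]] <- toks
        z_list[[nid]] <- zs
        th_list[[nid]] <- theta_d
        ann_notes[[nid]] <- list(copied = copied, source_pos = spos)
      }
      for (nid in note_ids) {
        terms <- vocab[toks_list[[nid]]]
        raw <- paste(terms, collapse = " ")
        ends <- cumsum(nchar(terms) + 1L) - 1L
        spans <- cbind(start = c(0L, head(ends, -1L) + 1L), end = ends)
        notes[[nid]] <- new_note(nid, rid, raw, toks_list[[nid]], spans)
      }
      records[[rid]] <- list(record_id = rid, notes = notes)
      ann_records[[rid]] <- list(source_note = src_id, notes = ann_notes)
      truth_theta[[rid]] <- th_list
      truth_z[[rid]] <- z_list
    }
    corpus <- new_record_corpus(records, vocab)
    annotation <- structure(list(records = ann_records,
                                 params = list(ground_truth = TRUE)),
                            class = "redundancy_annotation")
    truth <- list(phi = phi, theta = truth_theta, z = truth_z,
                  copied = lapply(ann_records, function(r)
                    lapply(r$notes, `[[`, "copied")),
                  source = vapply(ann_records, `[[`, "", "source_note"))
    list(corpus = corpus, annotation = annotation, truth = truth)
  })
}

#' Topic-recovery score against generating ground truth
#'
#' Greedily matches the fitted topic-word rows to the generating ones in
#' ascending Jensen-Shannon divergence and returns the mean divergence over
#' matched pairs; 0 means perfect recovery and values near \eqn{\log 2}
#' mean the topics were not recovered at all.
#'
#' @param model A fitted `redlda` model (or a phi matrix).
#' @param truth Ground truth from [simulate_records()] (or a phi matrix).
#' @return Mean matched JSD (lower is better). If the topic counts differ,
#'   the `min(K)` best pairs are scored and the attribute `"unmatched"`
#'   reports the remainder count.
#' @export
recovery_score <- function(model, truth) {
  phi_fit <- if (inherits(model, "redlda")) model$phi else model
  phi_true <- if (is.list(truth) && !is.null(truth$phi)) truth$phi else truth
  if (ncol(phi_fit) != ncol(phi_true)) stop("vocabulary sizes differ")
  al <- align_topics(phi_fit, phi_true, threshold = Inf)
  n_match <- min(nrow(phi_fit), nrow(phi_true))
  pairs <- al$pairs[seq_len(n_match), , drop = FALSE]
  structure(mean(pairs$jsd),
            unmatched = abs(nrow(phi_fit) - nrow(phi_true)))
}
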