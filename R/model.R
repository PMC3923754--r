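#' Fit a topic model to a clustered note corpus
#'
#' One entry point for the four modeling strategies compared in this package.
#' `method = "vanilla"` is standard latent Dirichlet allocation by collapsed
#' Gibbs sampling over all notes. `method = "redlda"` is the redundancy-aware
#' variant: tokens flagged as copied (see [annotate_redundancy()]) draw their
#' topic from the record's source note — the conditional for a copied
#' occurrence of word \eqn{w} is proportional to \eqn{n_{src}(w,k) + \delta},
#' where \eqn{n_{src}(w,k)} counts occurrences of \eqn{w} currently assigned
#' topic \eqn{k} in the source note — and copied tokens are excluded from the
#' topic-word count statistics, so repeated pasted text cannot inflate a
#' word's weight in its topic. Copied tokens still occupy their own note's
#' topic mixture. `"deletedoc"` and `"deleteword"` apply the corresponding
#' corpus transform (see [delete_doc_transform()], [delete_word_transform()])
#' and then fit vanilla LDA.
#'
#' Sampling is a single chain of `iterations` full sweeps. Records are swept
#' in corpus order with the source note first, so copied tokens condition on
#' fresh source assignments; with an all-false annotation the sweep reduces
#' bit-exactly to vanilla LDA under the same seed. Point estimates come from
#' the final state: \eqn{\phi_{kw} = (n_{kw} + \beta) / (n_k + V\beta)}
#' (redundancy-excluded counts) and
#' \eqn{\theta_{dk} = (n_{dk} + \alpha) / (N_d + K\alpha)} (all tokens).
#'
#' @param corpus A `record_corpus`.
#' @param K Number of topics (default 50).
#' @param method One of `"redlda"`, `"vanilla"`, `"deletedoc"`,
#'   `"deleteword"`.
#' @param annotation A `redundancy_annotation`; computed with default
#'   fingerprint parameters when `NULL` and the method needs one.
#' @param alpha Symmetric Dirichlet prior on document-topic mixtures
#'   (default `50 / K`).
#' @param beta Symmetric Dirichlet prior on topic-word distributions
#'   (default 0.01).
#' @param delta Smoothing for the copied-word source conditional, in (0, 1)
#'   (default 0.5).
#' @param iterations Number of Gibbs sweeps (default 2000).
#' @param seed Integer seed; fits are bit-reproducible given it.
#' @return An object of class `"redlda"` with components `phi` (K x V),
#'   `theta` (D x K), `vocab`, `docs` (data.frame of record_id, note_id,
#'   n_tokens), `state` (final topic assignments and count matrices), and the
#'   hyperparameters.
#' @examples
#' sim <- simulate_records(n_records = 8, K = 2, V = 50,
#'                         source_length = c(30, 50), other_length = c(30, 50),
#'                         seed = 1)
#' fit <- redlda(sim$corpus, K = 2, annotation = sim$annotation,
#'               alpha = 1, beta = 0.1, iterations = 50, seed = 1)
#' terms(fit, 5)
#' @export
redlda <- function(corpus, K = 50L,
                   method = c("redlda", "vanilla", "deletedoc", "deleteword"),
                   annotation = NULL, alpha = 50 / K, beta = 0.01,
                   delta = 0.5, iterations = 2000L, seed = 1L) {
  method <- match.arg(method)
  stopifnot(inherits(corpus, "record_corpus"), K >= 1L,
            alpha > 0, beta > 0, delta > 0, delta < 1, iterations >= 0L)
  if (length(corpus$records) == 0L) stop("empty corpus")
  cl <- match.call()

  if (is.null(annotation) && method != "vanilla") {
    annotation <- annotate_redundancy(corpus)
  }
  fit_corpus <- switch(method,
    vanilla = corpus,
    redlda = corpus,
    deletedoc = delete_doc_transform(corpus, annotation),
    deleteword = delete_word_transform(corpus, annotation))
  fit_ann <- if (method == "redlda") annotation else empty_annotation(fit_corpus)
  check_annotation(fit_corpus, fit_ann)

  flat <- flatten_corpus(fit_corpus, fit_ann)
  res <- cpp_gibbs_fit(flat$tokens, flat$doc_ptr, flat$copied,
                       flat$record_of_doc, flat$source_doc, flat$doc_order,
                       length(fit_corpus$vocab), as.integer(K),
                       alpha, beta, delta, as.integer(iterations),
                       as.double(seed))

  V <- length(fit_corpus$vocab)
  phi <- sweep(res$n_kw + beta, 1, res$n_k + V * beta, "/")
  colnames(phi) <- fit_corpus$vocab
  rownames(phi) <- paste0("topic", seq_len(K))
  Nd <- rowSums(res$n_dk)
  theta <- sweep(res$n_dk + alpha, 1, Nd + K * alpha, "/")
  rownames(theta) <- paste(flat$docs$record_id, flat$docs$note_id, sep = "/")
  colnames(theta) <- paste0("topic", seq_len(K))

  z_by_doc <- split_flat(res$z + 1L, flat$doc_ptr)  # topics 1-based in R
  copied_by_doc <- split_flat(as.integer(flat$copied), flat$doc_ptr)

  structure(list(
    call = cl, method = method, K = as.integer(K), V = V,
    alpha = alpha, beta = beta, delta = delta,
    iterations = as.integer(iterations), seed = seed,
    phi = phi, theta = theta, vocab = fit_corpus$vocab,
    docs = flat$docs, corpus = fit_corpus,
    state = list(z = z_by_doc,
                 counted = lapply(copied_by_doc, function(x) x == 0L),
                 n_dk = res$n_dk, n_kw = res$n_kw, n_k = res$n_k,
                 checksum = res$checksum)),
    class = "redlda")
}

split_flat <- function(x, doc_ptr) {
  lapply(seq_len(length(doc_ptr) - 1L), function(d) {
    if (doc_ptr[d + 1L] == doc_ptr[d]) return(integer(0))
    x[(doc_ptr[d] + 1L):doc_ptr[d + 1L]]
  })
}

check_annotation <- function(corpus, annotation) {
  for (rec in corpus$records) {
    arec <- annotation$records[[rec$record_id]]
    if (is.null(arec)) stop(sprintf("record '%s' missing from annotation",
                                    rec$record_id))
    for (nid in names(rec$notes)) {
      a <- arec$notes[[nid]]
      if (is.null(a)) stop(sprintf("note '%s/%s' missing from annotation",
                                   rec$record_id, nid))
      if (length(a$copied) != length(rec$notes[[nid]]$tokens)) {
        stop(sprintf("annotation length mismatch for note '%s/%s'",
                     rec$record_id, nid))
      }
    }
  }
  invisible(TRUE)
}

# Flatten a corpus + annotation into the vectors the C++ sampler consumes.
# Docs keep corpus order; the sweep order puts each record's source first.
flatten_corpus <- function(corpus, annotation) {
  notes <- corpus_notes(corpus)
  docs <- data.frame(
    record_id = vapply(notes, `[[`, "", "record_id"),
    note_id = vapply(notes, `[[`, "", "note_id"),
    n_tokens = vapply(notes, function(n) length(n$tokens), integer(1)),
    stringsAsFactors = FALSE)
  doc_ptr <- c(0L, cumsum(docs$n_tokens))
  tokens <- unlist(lapply(notes, function(n) n$tokens - 1L), use.names = FALSE)
  if (is.null(tokens)) tokens <- integer(0)
  rec_ids <- names(corpus$records)
  record_of_doc <- match(docs$record_id, rec_ids) - 1L
  copied <- logical(sum(docs$n_tokens))
  source_doc <- integer(length(rec_ids))
  doc_order <- integer(0)
  for (ri in seq_along(rec_ids)) {
    rid <- rec_ids[ri]
    arec <- annotation$records[[rid]]
    d_idx <- which(docs$record_id == rid)
    src_nid <- arec$source_note
    src_d <- d_idx[docs$note_id[d_idx] == src_nid]
    if (length(src_d) != 1L) stop(sprintf("source note '%s' not in record '%s'",
                                          src_nid, rid))
    source_doc[ri] <- src_d - 1L
    doc_order <- c(doc_order, src_d, setdiff(d_idx, src_d))
    for (d in d_idx) {
      nid <- docs$note_id[d]
      if (docs$n_tokens[d] > 0L) {
        copied[(doc_ptr[d] + 1L):doc_ptr[d + 1L]] <- arec$notes[[nid]]$copied
      }
    }
  }
  list(tokens = as.integer(tokens), doc_ptr = as.integer(doc_ptr),
       copied = copied, record_of_doc = as.integer(record_of_doc),
       source_doc = as.integer(source_doc),
       doc_order = as.integer(doc_order - 1L), docs = docs)
}

#' @export
print.redlda <- function(x, ...) {
  cat(sprintf("Topic model (%s): K = %d topics, V = %d terms, %d notes, %d sweeps, seed %s\n",
              x$method, x$K, x$V, nrow(x$docs), x$iterations,
              format(x$seed)))
  invisible(x)
}

#' @export
summary.redlda <- function(object, n_terms = 8L, ...) {
  structure(list(model = object,
                 top = terms(object, n_terms),
                 n_counted = sum(object$state$n_k),
                 n_tokens = sum(object$docs$n_tokens)),
            class = "summary.redlda")
}

#' @export
print.summary.redlda <- function(x, ...) {
  print(x$model)
  cat(sprintf("Tokens: %d total, %d counted toward topic-word estimates\n",
              x$n_tokens, x$n_counted))
  cat("Top terms per topic:\n")
  for (k in seq_len(ncol(x$top))) {
    cat(sprintf("  %s: %s\n", colnames(x$top)[k],
                paste(x$top[, k], collapse = " ")))
  }
  invisible(x)
}

#' Extract fitted distributions from a topic model
#'
#' @param object A fitted `redlda` model.
#' @param matrix `"phi"` for the K x V topic-word matrix, `"theta"` for the
#'   D x K document-topic matrix.
#' @param ... Unused.
#' @return The requested probability matrix (rows sum to 1).
#' @export
coef.redlda <- function(object, matrix = c("phi", "theta"), ...) {
  switch(match.arg(matrix), phi = object$phi, theta = object$theta)
}

#' Top terms per topic
#'
#' @param x A fitted `redlda` model.
#' @param n Number of terms per topic.
#' @param ... Unused.
#' @return Character matrix, one column per topic, terms in decreasing
#'   probability.
#' @export
terms.redlda <- function(x, n = 10L, ...) {
  out <- apply(x$phi, 1, function(p)
    x$vocab[order(p, decreasing = TRUE)[seq_len(n)]])
  colnames(out) <- rownames(x$phi)
  out
}

#' Infer the topic mixture of a held-out note
#'
#' Fold-in Gibbs sampling: the trained topic-word distribution is held fixed
#' and only the note's topic assignments are resampled, with conditional
#' \eqn{p(k) \propto (n_{dk} + \alpha)\,\phi_{kw}}. Tokens outside the model
#' vocabulary are skipped.
#'
#' @param model A fitted `redlda` model.
#' @param note A note object or an integer vector of token ids.
#' @param iterations Number of fold-in sweeps (default 50).
#' @param seed Integer seed.
#' @return Named numeric vector over topics (sums to 1).
#' @export
infer_theta <- function(model, note, iterations = 50L, seed = 1L) {
  toks <- if (is.list(note)) note$tokens else as.integer(note)
  toks <- toks[!is.na(toks) & toks >= 1L & toks <= model$V]
  if (length(toks) == 0L) {
    warning("note has no in-vocabulary tokens; returning uniform theta")
    return(setNames(rep(1 / model$K, model$K), rownames(model$phi)))
  }
  th <- cpp_fold_in(toks - 1L, model$phi, model$alpha,
                    as.integer(iterations), as.double(seed))
  setNames(as.numeric(th), rownames(model$phi))
}

#' Predict topic mixtures for new notes
#'
#' @param object A fitted `redlda` model.
#' @param newdata A list of notes, a `record_corpus`, or a single note.
#' @param iterations,seed Passed to [infer_theta()]; each note gets a seed
#'   derived from `seed` and its position.
#' @param ... Unused.
#' @return Matrix of topic mixtures, one row per note.
#' @export
predict.redlda <- function(object, newdata, iterations = 50L, seed = 1L, ...) {
  notes <- if (inherits(newdata, "record_corpus")) corpus_notes(newdata)
           else if (is.list(newdata) && !is.null(newdata$tokens)) list(newdata)
           else newdata
  out <- t(vapply(seq_along(notes), function(i)
    infer_theta(object, notes[[i]], iterations, derive_seed(seed, i, 0L)),
    numeric(object$K)))
  rn <- vapply(seq_along(notes), function(i) {
    n <- notes[[i]]
    if (is.list(n) && !is.null(n$note_id)) paste(n$record_id, n$note_id, sep = "/")
    else sprintf("note%d", i)
  }, "")
  rownames(out) <- rn
  out
}

#' Log-likelihood of notes under a fitted topic model
#'
#' With `newdata`, computes the held-out log-likelihood
#' \eqn{\sum_i \log \sum_k \theta_k \phi_{kw_i}} using fold-in mixtures;
#' without, scores the training notes with their fitted mixtures.
#'
#' @param object A fitted `redlda` model.
#' @param newdata Optional list of held-out notes.
#' @param iterations,seed Fold-in settings for `newdata`.
#' @param ... Unused.
#' @return A `logLik` object (attribute `nobs` = tokens scored).
#' @export
logLik.redlda <- function(object, newdata = NULL, iterations = 50L,
                          seed = 1L, ...) {
  if (is.null(newdata)) {
    notes <- corpus_notes(object$corpus)
    total <- 0
    n <- 0L
    for (d in seq_along(notes)) {
      toks <- notes[[d]]$tokens
      if (length(toks) == 0L) next
      mix <- object$theta[d, ] %*% object$phi[, toks, drop = FALSE]
      total <- total + sum(log(mix))
      n <- n + length(toks)
    }
    val <- total
  } else {
    rep <- heldout_loglikelihood(object, newdata, iterations = iterations,
                                 seed = seed)
    val <- rep$total
    n <- rep$n_tokens
  }
  structure(val, nobs = n, df = object$K * (object$V - 1), class = "logLik")
}

#' Plot top terms of selected topics
#'
#' Horizontal barplots of per-term probability for the top terms of each
#' requested topic.
#'
#' @param x A fitted `redlda` model.
#' @param topics Topic indices to show (default first 4).
#' @param n Terms per topic.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.redlda <- function(x, topics = seq_len(min(4L, x$K)), n = 10L, ...) {
  old <- graphics::par(mfrow = c(1, length(topics)),
                       mar = c(4, 6, 2, 1))
  on.exit(graphics::par(old))
  for (k in topics) {
    p <- sort(x$phi[k, ], decreasing = TRUE)[seq_len(n)]
    graphics::barplot(rev(p), horiz = TRUE, las = 1,
                      main = rownames(x$phi)[k], xlab = "probability", ...)
  }
  invisible(x)
}

derive_seed <- function(seed, a, b) {
  (as.double(seed) + 99991 * as.double(a) + 7919 * as.double(b)) %% 2147483647
}

#' Gibbs conditional for an ordinary (non-copied) token
#'
#' The collapsed conditional \eqn{p(k) \propto (n_{dk} + \alpha)\,
#' (n_{kw} + \beta) / (n_k + V\beta)}, with the token itself already removed
#' from the counts. Under Red-LDA the same form is applied to
#' redundancy-excluded count matrices (the fallback for copied words absent
#' from their source note).
#'
#' @param state List with `n_dk` (D x K), `n_kw` (K x V), `n_k` (length K).
#' @param d Document index.
#' @param w Token id (column of `n_kw`).
#' @param hyper List with `alpha`, `beta`, and optionally `V` (defaults to
#'   `ncol(state$n_kw)`).
#' @return Probability vector over the K topics (sums to 1).
#' @export
gibbs_conditional_vanilla <- function(state, d, w, hyper) {
  V <- if (!is.null(hyper$V)) hyper$V else ncol(state$n_kw)
  p <- (state$n_dk[d, ] + hyper$alpha) *
    (state$n_kw[, w] + hyper$beta) / (state$n_k + V * hyper$beta)
  p / sum(p)
}

#' Gibbs conditional for a copied token whose word occurs in the source note
#'
#' A copied occurrence of word `w` draws its topic from the source note's
#' current assignments of that word: \eqn{p(k) \propto n_{src}(w,k) +
#' \delta}.
#'
#' @param source_z Current topic assignments of the source note's tokens.
#' @param source_tokens The source note's token ids, aligned with `source_z`.
#' @param w Token id of the copied word (must occur in `source_tokens`).
#' @param hyper List with `K` and `delta`.
#' @return Probability vector over the K topics.
#' @export
gibbs_conditional_copied <- function(source_z, source_tokens, w, hyper) {
  occ <- source_z[source_tokens == w]
  if (length(occ) == 0L) {
    stop("word does not occur in the source note; use the fallback conditional")
  }
  p <- tabulate(occ, nbins = hyper$K) + hyper$delta
  p / sum(p)
}

#' Gibbs conditional for a copied token absent from the source note
#'
#' Identical in form to [gibbs_conditional_vanilla()] but defined over count
#' matrices from which all copied tokens are excluded — exactly the matrices
#' a Red-LDA sampler maintains.
#'
#' @inheritParams gibbs_conditional_vanilla
#' @return Probability vector over the K topics.
#' @export
gibbs_conditional_copied_fallback <- function(state, d, w, hyper) {
  gibbs_conditional_vanilla(state, d, w, hyper)
}

#' Save a fitted topic model to a directory
#'
#' Writes `phi.tsv` (K x V), `theta.tsv` (D x K), `vocab.txt` (one term per
#' line, line number = id) and `meta.json` (hyperparameters and seed).
#'
#' @param model A fitted `redlda` model.
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
save_model <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(model$phi, file.path(dir, "phi.tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(model$theta, file.path(dir, "theta.tsv"), sep = "\t",
                     row.names = TRUE, col.names = FALSE)
  writeLines(model$vocab, file.path(dir, "vocab.txt"))
  meta <- list(method = model$method, K = model$K, V = model$V,
               alpha = model$alpha, beta = model$beta, delta = model$delta,
               iterations = model$iterations, seed = model$seed)
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA),
             file.path(dir, "meta.json"))
  invisible(dir)
}

#' Load a topic model saved by [save_model()]
#'
#' @param dir Directory written by [save_model()].
#' @return A `redlda` object sufficient for prediction and evaluation
#'   (`phi`, `theta`, `vocab`, hyperparameters; no sampler state).
#' @export
load_model <- function(dir) {
  meta <- jsonlite::fromJSON(file.path(dir, "meta.json"))
  vocab <- readLines(file.path(dir, "vocab.txt"))
  phi <- as.matrix(utils::read.table(file.path(dir, "phi.tsv"), sep = "\t"))
  dimnames(phi) <- list(paste0("topic", seq_len(nrow(phi))), vocab)
  th <- utils::read.table(file.path(dir, "theta.tsv"), sep = "\t",
                          row.names = 1)
  theta <- as.matrix(th)
  colnames(theta) <- paste0("topic", seq_len(ncol(theta)))
  structure(list(method = meta$method, K = meta$K, V = meta$V,
                 alpha = meta$alpha, beta = meta$beta, delta = meta$delta,
                 iterations = meta$iterations, seed = meta$seed,
                 phi = phi, theta = theta, vocab = vocab),
            class = "redlda")
}
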