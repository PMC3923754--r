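random_state <- function(K, D, V) {
  # random raw assignments + copied flags, then naive counts
  tokens <- lapply(seq_len(D), function(d) sample.int(V, sample(3:12, 1),
                                                      replace = TRUE))
  z <- lapply(tokens, function(t) sample.int(K, length(t), replace = TRUE))
  copied <- lapply(tokens, function(t) runif(length(t)) < 0.3)
  counted <- lapply(copied, `!`)
  cnt <- recount_from_z(z, counted, tokens, D, K, V)
  list(tokens = tokens, z = z, copied = copied,
       state = list(n_dk = cnt$n_dk, n_kw = cnt$n_kw, n_k = cnt$n_k))
}

test_that("the ordinary-token conditional matches naive recomputation", {
  # fixed worked example: n_dk = [3,1], n_kw[,w] = [2,0], n_k = [10,5],
  # alpha = 1, beta = 0.1, V = 10
  state <- list(n_dk = matrix(c(3L, 1L), 1), n_kw = cbind(c(2L, 0L)),
                n_k = c(10L, 5L))
  p <- gibbs_conditional_vanilla(state, 1L, 1L,
                                 list(alpha = 1, beta = 0.1, V = 10L))
  expected <- c(4 * 2.1 / 11, 2 * 0.1 / 6)
  expect_equal(p, expected / sum(expected))

  st1 <- list(n_dk = matrix(0L, 1, 1), n_kw = matrix(0L, 1, 3), n_k = 0L)
  expect_equal(gibbs_conditional_vanilla(st1, 1L, 2L,
                                         list(alpha = 1, beta = 1)), 1.0)
  st2 <- list(n_dk = matrix(0L, 1, 2), n_kw = matrix(0L, 2, 3),
              n_k = c(0L, 0L))
  expect_equal(gibbs_conditional_vanilla(st2, 1L, 1L,
                                         list(alpha = 0.7, beta = 0.2)),
               c(0.5, 0.5))
})

test_that("all three conditionals agree with from-scratch oracles on random states", {
  set.seed(101)
  n_checked <- 0L
  for (rep in seq_len(1000L)) {
    K <- sample(1:4, 1); D <- sample(1:5, 1); V <- sample(2:8, 1)
    rs <- random_state(K, D, V)
    hyper <- list(K = K, V = V, alpha = runif(1, 0.1, 2),
                  beta = runif(1, 0.01, 1), delta = runif(1, 0.05, 0.95))
    d <- sample.int(D, 1); w <- sample.int(V, 1)
    # naive oracle computed directly from the raw assignments
    ndk_d <- tabulate(rs$z[[d]], K)
    nkw_w <- vapply(seq_len(K), function(k)
      sum(unlist(Map(function(zz, tt, cc) sum(zz == k & tt == w & !cc),
                     rs$z, rs$tokens, rs$copied))), numeric(1))
    nk <- vapply(seq_len(K), function(k)
      sum(unlist(Map(function(zz, cc) sum(zz == k & !cc),
                     rs$z, rs$copied))), numeric(1))
    p_naive <- (ndk_d + hyper$alpha) * (nkw_w + hyper$beta) /
      (nk + V * hyper$beta)
    p_naive <- p_naive / sum(p_naive)
    expect_equal(gibbs_conditional_vanilla(rs$state, d, w, hyper), p_naive)
    expect_equal(gibbs_conditional_copied_fallback(rs$state, d, w, hyper),
                 p_naive)
    # copied-word conditional vs direct tally of the source assignments
    src_tokens <- rs$tokens[[1]]; src_z <- rs$z[[1]]
    if (any(src_tokens == w)) {
      p_src <- tabulate(src_z[src_tokens == w], K) + hyper$delta
      expect_equal(gibbs_conditional_copied(src_z, src_tokens, w, hyper),
                   p_src / sum(p_src))
      n_checked <- n_checked + 1L
    }
  }
  expect_gt(n_checked, 100L)
})

test_that("the copied-word conditional reproduces the delta-smoothing closed forms", {
  # source counts for w: topic1 x2, topic2 x0; delta = 0.5
  p <- gibbs_conditional_copied(source_z = c(1L, 1L), source_tokens = c(3L, 3L),
                                w = 3L, hyper = list(K = 2L, delta = 0.5))
  expect_equal(p, c(5 / 6, 1 / 6))
  # counts [1,2] of 3 occurrences, delta = 0.5 -> [1.5/4, 2.5/4]
  p2 <- gibbs_conditional_copied(c(2L, 2L, 1L), c(7L, 7L, 7L), 7L,
                                 list(K = 2L, delta = 0.5))
  expect_equal(p2, c(1.5 / 4, 2.5 / 4))
  expect_error(gibbs_conditional_copied(c(1L), c(2L), 9L,
                                        list(K = 2L, delta = 0.5)),
               "fallback")
})

test_that("fits are bit-reproducible and counts match from-scratch recounts", {
  sim <- simulate_records(n_records = 6L, K = 3L, V = 60L, seed = 13L)
  f1 <- redlda(sim$corpus, K = 3L, annotation = sim$annotation, alpha = 1,
               beta = 0.1, iterations = 30L, seed = 77L)
  f2 <- redlda(sim$corpus, K = 3L, annotation = sim$annotation, alpha = 1,
               beta = 0.1, iterations = 30L, seed = 77L)
  expect_identical(f1$state$z, f2$state$z)
  expect_identical(f1$state$checksum, f2$state$checksum)

  tokens <- lapply(corpus_notes(f1$corpus), `[[`, "tokens")
  cnt <- recount_from_z(f1$state$z, f1$state$counted, tokens,
                        nrow(f1$docs), f1$K, f1$V)
  expect_equal(unname(f1$state$n_dk), unname(cnt$n_dk))
  expect_equal(unname(f1$state$n_kw), unname(cnt$n_kw))
  expect_equal(unname(f1$state$n_k), unname(cnt$n_k))
  # copied tokens are exactly the uncounted ones
  expect_equal(sum(f1$state$n_k), sum(unlist(f1$state$counted)))
})

test_that("phi and theta rows are normalized probability distributions", {
  sim <- simulate_records(n_records = 5L, K = 4L, V = 50L, seed = 3L)
  fit <- redlda(sim$corpus, K = 4L, annotation = sim$annotation,
                alpha = 0.5, beta = 0.05, iterations = 10L, seed = 1L)
  expect_true(all(abs(rowSums(fit$phi) - 1) < 1e-8))
  expect_true(all(abs(rowSums(fit$theta) - 1) < 1e-8))
  expect_true(all(fit$phi >= 0) && all(fit$theta >= 0))
})

test_that("K = 1 vanilla fit gives the smoothed empirical unigram distribution", {
  corpus <- make_corpus(list(r1 = list(n1 = c(1L, 1L, 2L, 3L)),
                             r2 = list(n1 = c(2L, 2L, 3L, 3L, 3L))), V = 4L)
  fit <- redlda(corpus, K = 1L, method = "vanilla", alpha = 1, beta = 0.5,
                iterations = 5L, seed = 1L)
  counts <- c(2L, 3L, 4L, 0L)
  expect_equal(unname(fit$phi[1, ]), (counts + 0.5) / (9 + 4 * 0.5))
  expect_equal(unname(fit$theta[, 1]), c(1, 1))
})

test_that("a fully copied note contributes nothing to the topic-word counts", {
  set.seed(5)
  src <- sample.int(40L, 50L, replace = TRUE)
  corpus <- make_corpus(list(r1 = list(n1 = src, n2 = src)), V = 40L)
  flags <- list(r1 = list(source = "n1", notes = list(
    n2 = list(copied = rep(TRUE, 50L), source_pos = 1:50))))
  ann <- make_annotation(corpus, flags)
  fit <- redlda(corpus, K = 2L, annotation = ann, alpha = 1, beta = 0.1,
                iterations = 20L, seed = 3L)
  expect_equal(sum(fit$state$n_kw), 50L)  # only the source is counted
  expect_equal(sum(fit$state$n_dk), 100L) # but both occupy topic mixtures
})

test_that("two disjoint vocabulary blocks separate into two topics", {
  # documents draw from block A (tokens 1-20) or block B (21-40)
  hits <- 0L
  for (seed in 1:3) {
    set.seed(seed)
    recs <- list()
    for (r in 1:12) {
      block <- if (r %% 2 == 0) 1:20 else 21:40
      recs[[sprintf("r%02d", r)]] <-
        list(n1 = sample(block, 60, replace = TRUE))
    }
    corpus <- make_corpus(recs, V = 40L)
    fit <- redlda(corpus, K = 2L, method = "vanilla", alpha = 0.5, beta = 0.1,
                  iterations = 200L, seed = seed)
    massA <- rowSums(fit$phi[, 1:20])
    ok <- (massA[1] >= 0.9 && massA[2] <= 0.1) ||
          (massA[2] >= 0.9 && massA[1] <= 0.1)
    hits <- hits + ok
  }
  expect_gte(hits, 2L)
})

test_that("fold-in inference recovers the dominant topic of a peaked model", {
  sim <- simulate_records(n_records = 10L, K = 3L, V = 90L, seed = 8L)
  fit <- redlda(sim$corpus, K = 3L, annotation = sim$annotation, alpha = 0.5,
                beta = 0.05, iterations = 150L, seed = 2L)
  # a note drawn purely from each fitted topic should fold back onto it
  for (j in 1:3) {
    for (seed in 1:3) {
      set.seed(seed)
      note <- sample.int(fit$V, 80L, replace = TRUE, prob = fit$phi[j, ])
      th <- infer_theta(fit, note, iterations = 50L, seed = seed)
      expect_equal(unname(which.max(th)), j)
    }
  }
  # K = 1 degenerate case
  fit1 <- redlda(sim$corpus, K = 1L, method = "vanilla", iterations = 2L,
                 alpha = 1, seed = 1L)
  expect_equal(unname(infer_theta(fit1, c(1L, 2L, 3L))), 1.0)
  # all-OOV note: uniform with warning
  expect_warning(th <- infer_theta(fit, c(-5L, 0L, NA_integer_)), "uniform")
  expect_equal(unname(th), rep(1 / 3, 3))
})

test_that("annotation errors are fatal and name the offending note", {
  corpus <- make_corpus(list(r1 = list(n1 = 1:10, n2 = 1:10)), V = 10L)
  flags <- list(r1 = list(source = "n1", notes = list(
    n2 = list(copied = rep(TRUE, 4L), source_pos = 1:4))))  # wrong length
  ann <- make_annotation(corpus, flags)
  ann$records$r1$notes$n2 <- list(copied = rep(TRUE, 4L), source_pos = 1:4)
  expect_error(redlda(corpus, K = 2L, annotation = ann, iterations = 1L),
               "n2")
  ann$records$r1$notes$n2 <- NULL
  expect_error(redlda(corpus, K = 2L, annotation = ann, iterations = 1L),
               "n2")
})
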