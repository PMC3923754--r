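test_that("Jensen-Shannon divergence satisfies its closed forms and symmetry", {
  expect_equal(js_divergence(c(0.3, 0.7), c(0.3, 0.7)), 0, tolerance = 1e-12)
  expect_equal(js_divergence(c(1, 0), c(0, 1)), log(2), tolerance = 1e-12)
  set.seed(9)
  for (i in 1:20) {
    p <- rgamma(5, 1); p <- p / sum(p)
    q <- rgamma(5, 1); q <- q / sum(q)
    expect_equal(js_divergence(p, q), js_divergence(q, p))
    expect_gte(js_divergence(p, q), 0)
    expect_lte(js_divergence(p, q), log(2) + 1e-12)
  }
  expect_error(js_divergence(c(1, 0), c(1, 0, 0)), "length")
})

test_that("coherence matches hand counts on a toy corpus", {
  # 5 documents over 4 words; document frequencies by construction:
  # D(1)=4, D(2)=3, D(3)=2, D(4)=1; D(1,2)=3, D(1,3)=1, D(2,3)=1
  corpus <- make_corpus(list(
    r1 = list(n1 = c(1L, 2L), n2 = c(1L, 2L, 3L)),
    r2 = list(n1 = c(1L, 2L), n2 = c(1L, 4L), n3 = c(3L, 3L))), V = 4L)
  phi <- matrix(c(0.4, 0.3, 0.2, 0.1), 1)  # ranks words 1 > 2 > 3 > 4
  model <- structure(list(phi = phi, K = 1L, V = 4L, vocab = corpus$vocab),
                     class = "redlda")
  coh <- topic_coherence(model, corpus, top_m = 3L)
  hand <- log((3 + 1) / 4) + log((1 + 1) / 4) + log((1 + 1) / 3)
  expect_equal(coh$per_topic[1], hand)

  # D(v1) = 5, D(v2,v1) = 4 at top_m = 2: log((4+1)/5) = 0
  corpus2 <- make_corpus(list(r1 = list(n1 = c(1L, 2L), n2 = c(1L, 2L)),
                              r2 = list(n1 = c(1L, 2L), n2 = c(1L, 2L),
                                        n3 = c(1L, 1L))), V = 2L)
  model2 <- structure(list(phi = matrix(c(0.6, 0.4), 1), K = 1L, V = 2L,
                           vocab = corpus2$vocab), class = "redlda")
  expect_equal(topic_coherence(model2, corpus2, top_m = 2L)$per_topic[1], 0)

  # never co-occurring pair: log(1 / D(v1))
  corpus3 <- make_corpus(list(
    r1 = list(n1 = rep(1L, 3), n2 = rep(1L, 3)),
    r2 = list(n1 = rep(1L, 2), n2 = rep(1L, 2), n3 = rep(2L, 2)),
    r3 = list(n1 = rep(1L, 2), n2 = rep(1L, 2), n3 = rep(1L, 2),
              n4 = rep(1L, 2), n5 = rep(1L, 2), n6 = rep(1L, 2))), V = 2L)
  model3 <- structure(list(phi = matrix(c(0.6, 0.4), 1), K = 1L, V = 2L,
                           vocab = corpus3$vocab), class = "redlda")
  expect_equal(topic_coherence(model3, corpus3, top_m = 2L)$per_topic[1],
               log(1 / 10))
})

test_that("coherence is order-invariant and never positive", {
  sim <- simulate_records(n_records = 8L, seed = 41L)
  fit <- redlda(sim$corpus, K = 5L, annotation = sim$annotation, alpha = 1,
                beta = 0.1, iterations = 50L, seed = 1L)
  coh <- topic_coherence(fit, sim$corpus, top_m = 10L)
  expect_true(all(coh$per_topic <= 1e-12))
  # reversing record order changes nothing
  rev_corpus <- sim$corpus
  rev_corpus$records <- rev(rev_corpus$records)
  expect_equal(topic_coherence(fit, rev_corpus, top_m = 10L)$per_topic,
               coh$per_topic)
})

test_that("held-out log-likelihood matches closed forms", {
  # uniform phi: every token scores log(1/V) regardless of theta
  V <- 25L
  model <- structure(list(phi = matrix(1 / V, 2, V,
                                       dimnames = list(paste0("topic", 1:2),
                                                       sprintf("w%04d", 1:V))),
                          K = 2L, V = V, alpha = 1,
                          vocab = sprintf("w%04d", 1:V)), class = "redlda")
  notes <- list(c(1L, 5L, 7L, 7L), c(2L, 2L))
  rep <- heldout_loglikelihood(model, notes, iterations = 5L, seed = 1L)
  expect_equal(rep$total, 6 * log(1 / V))
  expect_equal(rep$per_token, log(1 / V))
  expect_equal(rep$n_tokens, 6L)

  # K = 1: loglik is exactly sum log phi[1, w]
  phi1 <- matrix(c(0.5, 0.3, 0.2), 1)
  m1 <- structure(list(phi = phi1, K = 1L, V = 3L, alpha = 1,
                       vocab = c("a1", "b1", "c1")), class = "redlda")
  r1 <- heldout_loglikelihood(m1, list(c(1L, 2L, 3L, 1L)), 5L, 1L)
  expect_equal(r1$total, log(0.5) + log(0.3) + log(0.2) + log(0.5))

  expect_error(heldout_loglikelihood(m1, list()), "empty")
})

test_that("the generating model beats a uniform model on held-out likelihood", {
  wins <- 0L
  for (seed in 1:3) {
    sim <- simulate_records(n_records = 12L, K = 3L, V = 60L, seed = seed)
    sp <- split_by_record(sim$corpus, 4L, seed, sim$annotation)
    truth_model <- structure(list(
      phi = sim$truth$phi, K = 3L, V = 60L, alpha = 0.3,
      vocab = sim$corpus$vocab), class = "redlda")
    unif_model <- truth_model
    unif_model$phi <- matrix(1 / 60, 3L, 60L)
    llt <- heldout_loglikelihood(truth_model, sp$test, 30L, seed)$total
    llu <- heldout_loglikelihood(unif_model, sp$test, 30L, seed)$total
    wins <- wins + (llt > llu)
  }
  expect_equal(wins, 3L)
})

test_that("topic alignment is exact on self, strict at zero, optimal on a toy", {
  sim <- simulate_records(n_records = 6L, K = 4L, V = 50L, seed = 51L)
  fit <- redlda(sim$corpus, K = 4L, annotation = sim$annotation, alpha = 1,
                beta = 0.1, iterations = 20L, seed = 1L)
  self <- align_topics(fit, fit)
  expect_equal(nrow(self$pairs), 4L)
  expect_true(all(self$pairs$jsd < 1e-12))
  expect_true(all(self$pairs$topic_a == self$pairs$topic_b))

  fit2 <- redlda(sim$corpus, K = 4L, annotation = sim$annotation, alpha = 1,
                 beta = 0.1, iterations = 20L, seed = 999L)
  strict <- align_topics(fit, fit2, threshold = 0)
  expect_equal(nrow(strict$pairs), 0L)

  # 2x2 toy with one obvious pairing: greedy equals exhaustive search
  A <- rbind(c(0.9, 0.05, 0.05), c(0.05, 0.9, 0.05))
  B <- rbind(c(0.06, 0.88, 0.06), c(0.88, 0.06, 0.06))
  al <- align_topics(A, B, threshold = log(2))
  perms <- list(c(1L, 2L), c(2L, 1L))
  costs <- vapply(perms, function(p)
    js_divergence(A[1, ], B[p[1], ]) + js_divergence(A[2, ], B[p[2], ]),
    numeric(1))
  best <- perms[[which.min(costs)]]
  got <- al$pairs[order(al$pairs$topic_a), ]
  expect_equal(got$topic_b, best)
  expect_error(align_topics(A, B[, 1:2]), "vocabular")
})

test_that("method comparison is deterministic and well-formed", {
  sim <- simulate_records(n_records = 10L, K = 3L, V = 60L, seed = 61L)
  tab <- compare_methods(sim$corpus, sim$annotation,
                         methods = c("vanilla", "vanilla"), n_runs = 1L,
                         seed = 5L, K = 3L, alpha = 1, beta = 0.1,
                         iterations = 20L, n_test_records = 3L,
                         fold_iterations = 10L, top_m = 5L)
  expect_equal(nrow(tab), 1L)  # aggregated over the duplicated method name
  runs <- attr(tab, "runs")
  expect_equal(nrow(runs), 2L)
  expect_equal(runs$loglik[1], runs$loglik[2])  # same seed, same method
  expect_equal(tab$sd_loglik, sd(runs$loglik))
  tab2 <- compare_methods(sim$corpus, sim$annotation, methods = "redlda",
                          n_runs = 1L, seed = 5L, K = 3L, alpha = 1,
                          beta = 0.1, iterations = 20L, n_test_records = 3L,
                          fold_iterations = 10L, top_m = 5L)
  expect_equal(tab2$sd_loglik, 0)
})
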