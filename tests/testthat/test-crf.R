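test_that("forward-backward matches closed forms on single positions", {
  r <- forward_backward(matrix(0, 1, 2), matrix(0, 2, 2))
  expect_equal(r$log_z, log(2))
  expect_equal(as.vector(r$unary), c(0.5, 0.5))

  s <- 1.7
  r1 <- forward_backward(matrix(s, 1, 1), matrix(0, 1, 1))
  expect_equal(r1$log_z, s)
})

test_that("log-partition and marginals agree with exhaustive enumeration", {
  withr::local_seed(101)
  for (rep in 1:25) {
    L <- sample(1:6, 1); K <- sample(2:5, 1)
    em <- matrix(rnorm(L * K, sd = 2), L, K)
    tr <- matrix(rnorm(K * K), K, K)
    r <- forward_backward(em, tr)
    expect_equal(r$log_z, brute_log_z(em, tr), tolerance = 1e-10)
    expect_equal(rowSums(r$unary), rep(1, L), tolerance = 1e-10)
    if (L > 1) {
      pw <- array(r$pairwise, dim = c(L - 1, K, K))
      for (l in seq_len(L - 1)) {
        expect_equal(rowSums(pw[l, , , drop = TRUE]), r$unary[l, ],
                     tolerance = 1e-8)
        expect_equal(colSums(pw[l, , , drop = TRUE]), r$unary[l + 1, ],
                     tolerance = 1e-8)
      }
    }
  }
})

test_that("Viterbi reaches the brute-force optimum and breaks ties low", {
  expect_equal(viterbi_decode(matrix(0, 4, 3), matrix(0, 3, 3)),
               rep(1L, 4))
  em <- rbind(c(0, 5, 0), c(3, 0, 0))
  expect_equal(viterbi_decode(em, matrix(0, 3, 3)), c(2L, 1L))
  withr::local_seed(202)
  for (rep in 1:25) {
    L <- sample(1:6, 1); K <- sample(2:5, 1)
    em <- matrix(rnorm(L * K, sd = 2), L, K)
    tr <- matrix(rnorm(K * K), K, K)
    path <- viterbi_decode(em, tr)
    expect_equal(path_score(em, tr, path), brute_best_score(em, tr),
                 tolerance = 1e-10)
  }
})

test_that("sentence potentials are the sparse dot products", {
  sch <- toy_schema()
  corp <- toy_tagged_corpus(5)
  m <- train_crf(corp, NULL, sch, config = train_config(max_epochs = 3,
                                                        seed = 1))
  toks <- c("aa", "ba", "na1")
  pot <- sentence_potentials(m, toks)
  # independent arithmetic: rebuild the feature vectors and take dot products
  fv <- extract_features(toks, m$templates, m$index, grow = FALSE)
  for (l in seq_along(toks))
    for (k in seq_along(sch$labels))
      expect_equal(pot$emission[l, k],
                   sum(m$W_f[k, fv[[l]]$i] * fv[[l]]$x), tolerance = 1e-12)
  zero <- m
  zero$W_f[] <- 0
  expect_true(all(sentence_potentials(zero, toks)$emission == 0))
})

test_that("emission posterior is a stable softmax", {
  W <- matrix(0, 4, 3)
  f <- list(i = 2L, x = 1)
  expect_equal(emission_posterior(W, f), rep(0.25, 4))
  W2 <- rbind(c(1, 0), c(0, 0))  # scores (1, 0) for one-hot feature 1
  expect_equal(emission_posterior(W2, list(i = 1L, x = 1)),
               c(exp(1), 1) / (exp(1) + 1))
  # shift invariance and huge-score stability
  W3 <- rbind(c(1000, 0), c(999, 0))
  expect_equal(emission_posterior(W3, list(i = 1L, x = 1)),
               c(exp(1), 1) / (exp(1) + 1))
  expect_equal(sum(emission_posterior(W3, list(i = 1L, x = 1))), 1,
               tolerance = 1e-12)
})

test_that("NLL is the pure regularizer when the label space is trivial", {
  W_f <- matrix(rnorm(3), 1, 3)
  W_g <- matrix(rnorm(1), 1, 1)
  s <- list(idx = 2L, val = 1.5, off = c(0L, 1L), y = 1L)
  lam <- 0.7
  r <- crf_nll_grad(W_f, W_g, list(s), lam)
  expect_equal(r$loss, lam / 2 * (sum(W_f^2) + sum(W_g^2)))
})

test_that("NLL is non-negative and its gradient passes finite differences", {
  withr::local_seed(303)
  for (rep in 1:5) {
    K <- 3; F_ <- 6
    sents <- lapply(1:2, function(i)
      random_flat_sentence(sample(2:4, 1), K, F_))
    W_f <- matrix(rnorm(K * F_, sd = 0.5), K, F_)
    W_g <- matrix(rnorm(K * K, sd = 0.5), K, K)
    r <- crf_nll_grad(W_f, W_g, sents, 0)
    expect_gte(r$loss, 0)
    pack <- function(wf, wg) c(as.vector(wf), as.vector(wg))
    f <- function(th) {
      wf <- matrix(th[1:(K * F_)], K, F_)
      wg <- matrix(th[-(1:(K * F_))], K, K)
      crf_nll_grad(wf, wg, sents, 0.01)$loss
    }
    r2 <- crf_nll_grad(W_f, W_g, sents, 0.01)
    num <- fd_grad(f, pack(W_f, W_g))
    expect_lt(max_rel_err(pack(r2$grad_f, r2$grad_g), num), 1e-4)
  }
})

test_that("training solves a deterministic toy task and is reproducible", {
  sch <- toy_schema()
  train <- toy_tagged_corpus(30, seed = 5)
  cfg <- train_config(max_epochs = 20, seed = 2)
  m <- train_crf(train, NULL, sch, config = cfg)
  pred <- predict(m, train)
  expect_equal(mean(pred$label == train$label), 1.0)
  m2 <- train_crf(train, NULL, sch, config = cfg)
  expect_identical(m$W_f, m2$W_f)
  expect_identical(m$W_g, m2$W_g)
})

test_that("zero-epoch training returns the initialization unchanged", {
  sch <- toy_schema()
  train <- toy_tagged_corpus(10)
  m <- train_crf(train, NULL, sch, config = train_config(max_epochs = 5,
                                                         seed = 1))
  m0 <- train_crf(train, NULL, sch,
                  config = train_config(max_epochs = 0),
                  init = list(W_f = m$W_f, W_g = m$W_g),
                  index = m$index, grow_index = FALSE)
  expect_equal(m0$W_f, unname(m$W_f))
  expect_equal(m0$W_g, unname(m$W_g))
})

test_that("the regularized objective has one optimum: seeds converge", {
  sch <- toy_schema()
  train <- toy_tagged_corpus(6, seed = 42)
  loss_of <- function(seed) {
    m <- train_crf(train, NULL, sch,
                   config = train_config(l2_lambda = 0.05,
                                         adagrad_step = 0.3,
                                         max_epochs = 800, seed = seed))
    fz <- crfbridge:::featurize(train, m$templates, m$index, sch,
                                grow = FALSE)
    crf_nll_grad(m$W_f, m$W_g, fz$sents, 0.05)$loss
  }
  expect_lt(abs(loss_of(1) - loss_of(2)), 1e-3)
})

test_that("early stopping returns the best development epoch", {
  spec <- synthetic_spec(n_sentences = list(source_train = 60,
                                            source_dev = 30,
                                            target_train = 5,
                                            target_dev = 5,
                                            target_test = 5), seed = 4)
  corp <- generate_tagged_corpora(spec)
  m <- train_crf(corp$source_train, corp$source_dev, corp$source_schema,
                 config = train_config(max_epochs = 10, patience = 3,
                                       seed = 1))
  expect_equal(m$best_epoch, which.max(m$history$dev_macro_f1))
  expect_lte(nrow(m$history), 10)
})

test_that("models survive a JSON serialization round trip", {
  sch <- toy_schema()
  train <- toy_tagged_corpus(8)
  m <- train_crf(train, NULL, sch, config = train_config(max_epochs = 4,
                                                         seed = 1))
  f <- withr::local_tempfile(fileext = ".json")
  write_crf_model(m, f)
  back <- read_crf_model(f)
  expect_equal(back$W_f, m$W_f, tolerance = 1e-12)
  expect_equal(back$W_g, m$W_g, tolerance = 1e-12)
  expect_equal(predict(back, train), predict(m, train))
})
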