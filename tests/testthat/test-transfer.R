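# small shared-feature-space fixture: source model + correlated target data
transfer_fixture <- function(seed = 1, n_source = 120, n_target = 10,
                             epochs = 10) {
  spec <- synthetic_spec(n_sentences = list(source_train = n_source,
                                            source_dev = 30,
                                            target_train = n_target,
                                            target_dev = 30,
                                            target_test = 60), seed = seed)
  corp <- generate_tagged_corpora(spec)
  idx <- feature_index()
  tpl <- feature_templates()
  crfbridge:::featurize(dplyr::bind_rows(corp$source_train,
                                         corp$target_train),
                        tpl, idx, grow = TRUE)
  cfg <- train_config(max_epochs = epochs, patience = 3, seed = seed)
  src <- train_crf(corp$source_train, corp$source_dev, corp$source_schema,
                   tpl, cfg, index = idx, grow_index = FALSE)
  list(corp = corp, src = src, cfg = cfg, tpl = tpl)
}

test_that("source scores are the raw linear map W_s f", {
  fx <- transfer_fixture(seed = 3, n_source = 40, epochs = 4)
  br <- train_bridge(fx$src, fx$corp$target_train,
                     fx$corp$target_schema,
                     train_config(max_epochs = 3, seed = 1))
  W_s <- br$source_emission
  expect_equal(source_scores(br, list(i = integer(), x = numeric())),
               rep(0, nrow(W_s)))
  expect_equal(source_scores(br, list(i = 7L, x = 1)), unname(W_s[, 7]))
  withr::local_seed(4)
  f <- list(i = sort(sample.int(ncol(W_s), 4)), x = runif(4))
  hand <- vapply(seq_len(nrow(W_s)),
                 function(k) sum(W_s[k, f$i] * f$x), numeric(1))
  expect_equal(source_scores(br, f), hand, tolerance = 1e-12)
  expect_error(source_scores(br, list(i = ncol(W_s) + 1L, x = 1)),
               "range")
})

test_that("bridge training never modifies the frozen source weights", {
  fx <- transfer_fixture(seed = 5, n_source = 40, epochs = 4)
  W_before <- fx$src$W_f + 0
  br <- train_bridge(fx$src, fx$corp$target_train, fx$corp$target_schema,
                     train_config(max_epochs = 5, seed = 2))
  expect_identical(fx$src$W_f, W_before)
  expect_identical(br$source_emission, W_before)
  expect_error(train_bridge(fx$src,
                            fx$corp$target_train[0, ],
                            fx$corp$target_schema),
               "empty")
})

test_that("with identical label sets the composed model recovers the task", {
  # target labels = source labels on noise-free separable data: the source
  # emissions are near-one-hot correct and the bridge has to learn ~identity
  spec <- synthetic_spec(noise_rate = 0,
                         n_sentences = list(source_train = 200,
                                            source_dev = 50,
                                            target_train = 10,
                                            target_dev = 10,
                                            target_test = 10), seed = 6)
  corp <- generate_tagged_corpora(spec)
  idx <- feature_index(); tpl <- feature_templates()
  crfbridge:::featurize(corp$source_train, tpl, idx, grow = TRUE)
  src <- train_crf(corp$source_train, corp$source_dev, corp$source_schema,
                   tpl, train_config(max_epochs = 15, patience = 5,
                                     seed = 6),
                   index = idx, grow_index = FALSE)
  br <- train_bridge(src, corp$source_train, corp$source_schema,
                     train_config(max_epochs = 10, seed = 3))
  init <- compose_init(br)
  comp <- src
  comp$W_f <- init$W_f
  comp$W_g <- init$W_g
  pred <- predict(comp, corp$source_dev)
  expect_gte(mean(pred$label == corp$source_dev$label), 0.95)
})

test_that("the bridge recovers the refinement mapping", {
  wins <- 0L
  for (seed in 1:10) {
    fx <- transfer_fixture(seed = seed, n_source = 100, n_target = 30,
                           epochs = 8)
    br <- train_bridge(fx$src, fx$corp$target_train,
                       fx$corp$target_schema,
                       train_config(max_epochs = 15, seed = seed))
    refinement <- synthetic_spec()$refinement
    parent_of <- unlist(lapply(names(refinement), function(s)
      setNames(rep(s, length(refinement[[s]])), refinement[[s]])))
    ent <- setdiff(fx$corp$target_schema$labels, "NA")
    hits <- vapply(ent, function(t) {
      row <- br$bridge_weights[match(t, fx$corp$target_schema$labels), ]
      fx$corp$source_schema$labels[which.max(abs(row))] == parent_of[[t]]
    }, logical(1))
    if (all(hits)) wins <- wins + 1L
  }
  expect_gte(wins, 8)
})

test_that("composition is exact and the NA row is zeroed", {
  fx <- transfer_fixture(seed = 7, n_source = 40, epochs = 4)
  br <- train_bridge(fx$src, fx$corp$target_train, fx$corp$target_schema,
                     train_config(max_epochs = 5, seed = 1))
  init <- compose_init(br)
  na_row <- match("NA", fx$corp$target_schema$labels)
  expect_true(all(init$W_f[na_row, ] == 0))
  expect_true(all(init$W_g == 0))

  # identity bridge on the square case reproduces W_s with NA zeroed
  br2 <- br
  br2$target_schema <- fx$corp$source_schema
  br2$bridge_weights <- diag(length(fx$corp$source_schema$labels))
  init2 <- compose_init(br2)
  expected <- br$source_emission
  expected[match("O", fx$corp$source_schema$labels), ] <- 0
  expect_equal(init2$W_f, expected, tolerance = 1e-15)
})

test_that("zero-epoch fine-tuning returns exactly the composed init", {
  fx <- transfer_fixture(seed = 8, n_source = 40, epochs = 4)
  cfg0 <- train_config(max_epochs = 0, seed = 1)
  m <- transfer_train(fx$src, fx$corp$target_train, fx$corp$target_dev,
                      fx$corp$target_schema, config = cfg0,
                      bridge_config = train_config(max_epochs = 5,
                                                   seed = 1))
  init <- compose_init(attr(m, "bridge"))
  expect_equal(m$W_f, unname(init$W_f))
  expect_equal(m$W_g, init$W_g)
})

test_that("with abundant target data transfer and cold start converge", {
  spec <- synthetic_spec(n_sentences = list(source_train = 150,
                                            source_dev = 30,
                                            target_train = 400,
                                            target_dev = 80,
                                            target_test = 50), seed = 9)
  corp <- generate_tagged_corpora(spec)
  idx <- feature_index(); tpl <- feature_templates()
  crfbridge:::featurize(dplyr::bind_rows(corp$source_train,
                                         corp$target_train),
                        tpl, idx, grow = TRUE)
  cfg <- train_config(max_epochs = 25, patience = 8, seed = 9)
  src <- train_crf(corp$source_train, corp$source_dev, corp$source_schema,
                   tpl, cfg, index = idx, grow_index = FALSE)
  tm <- transfer_train(src, corp$target_train, corp$target_dev,
                       corp$target_schema, cfg)
  cold <- train_crf(corp$target_train, corp$target_dev,
                    corp$target_schema, tpl, cfg)
  f1_t <- max(tm$history$dev_macro_f1)
  f1_c <- max(cold$history$dev_macro_f1)
  expect_lt(abs(f1_t - f1_c), 0.05)
})
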