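mk_corpus <- function(labels) {
  tibble::tibble(sentence_id = 1L, token = paste0("t", seq_along(labels)),
                 label = labels)
}

# independent confusion-matrix oracle: per-class and averaged metrics
# computed directly from a table()
hand_score <- function(gold, pred, labels, na_label) {
  cm <- table(factor(gold, levels = labels), factor(pred, levels = labels))
  prec <- rec <- f1 <- numeric(length(labels))
  for (i in seq_along(labels)) {
    tp <- cm[i, i]
    prec[i] <- if (sum(cm[, i]) > 0) tp / sum(cm[, i]) else 0
    rec[i] <- if (sum(cm[i, ]) > 0) tp / sum(cm[i, ]) else 0
    f1[i] <- if (prec[i] + rec[i] > 0)
      2 * prec[i] * rec[i] / (prec[i] + rec[i]) else 0
  }
  keep <- labels != na_label
  list(macro_f1 = mean(f1[keep]), micro_f1 = sum(diag(cm)) / sum(cm),
       f1 = setNames(f1, labels))
}

test_that("perfect predictions score 1 everywhere", {
  sch <- label_schema(c("A", "B", "NA"))
  gold <- mk_corpus(c("A", "B", "NA", "A"))
  r <- score(gold, gold, sch)
  expect_equal(r$macro_f1, 1)
  expect_equal(r$micro_f1, 1)
  expect_equal(r$na_f1, 1)
  expect_true(all(tidy(r)$f1[tidy(r)$support > 0] == 1))
})

test_that("the all-A predictor reproduces the hand confusion matrix", {
  sch <- label_schema(c("A", "B", "NA"))
  gold <- mk_corpus(rep(c("A", "B"), each = 5))
  pred <- mk_corpus(rep("A", 10))
  r <- score(gold, pred, sch)
  pc <- tidy(r)
  expect_equal(pc$precision[pc$label == "A"], 0.5)
  expect_equal(pc$recall[pc$label == "A"], 1.0)
  expect_equal(pc$f1[pc$label == "A"], 2 / 3)
  expect_equal(pc$f1[pc$label == "B"], 0)
  expect_equal(r$macro_f1, 1 / 3)   # mean over non-NA classes {A, B}
  expect_equal(r$micro_f1, 0.5)
  expect_equal(sum(pc$support), r$n_tokens)
  # matches the independent oracle
  h <- hand_score(gold$label, pred$label, sch$labels, "NA")
  expect_equal(r$macro_f1, h$macro_f1)
  expect_equal(r$micro_f1, h$micro_f1)
})

test_that("micro metrics equal accuracy for exhaustive single labels", {
  sch <- label_schema(c("A", "B", "C", "NA"))
  withr::local_seed(21)
  for (rep in 1:5) {
    gold <- mk_corpus(sample(sch$labels, 40, replace = TRUE))
    pred <- mk_corpus(sample(sch$labels, 40, replace = TRUE))
    r <- score(gold, pred, sch)
    acc <- mean(gold$label == pred$label)
    expect_equal(r$micro_precision, acc)
    expect_equal(r$micro_recall, acc)
    expect_equal(r$micro_f1, acc)
  }
})

test_that("macro-F1 is invariant to relabeling and swap exchanges P and R", {
  sch <- label_schema(c("A", "B", "NA"))
  withr::local_seed(22)
  gold <- mk_corpus(sample(sch$labels, 30, replace = TRUE))
  pred <- mk_corpus(sample(sch$labels, 30, replace = TRUE))
  r <- score(gold, pred, sch)
  # permute label names (keeping NA fixed)
  perm <- c(A = "B", B = "A", "NA" = "NA")
  gold2 <- mk_corpus(unname(perm[gold$label]))
  pred2 <- mk_corpus(unname(perm[pred$label]))
  expect_equal(score(gold2, pred2, sch)$macro_f1, r$macro_f1)
  # swapping gold and pred swaps precision and recall per class
  rs <- score(pred, gold, sch)
  expect_equal(tidy(rs)$precision, tidy(r)$recall)
  expect_equal(tidy(rs)$recall, tidy(r)$precision)
})

test_that("degenerate and symmetric Wilcoxon cases behave", {
  x <- c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6)
  r <- wilcoxon_signed_rank(x, x)
  expect_true(r$degenerate)
  expect_equal(r$p_value, 1)
  withr::local_seed(23)
  a <- runif(9); b <- runif(9)
  expect_equal(wilcoxon_signed_rank(a, b)$p_value,
               wilcoxon_signed_rank(b, a)$p_value)
})

test_that("exact Wilcoxon p equals full sign-assignment enumeration", {
  # independent oracle: walk all 2^n sign vectors explicitly
  enum_p <- function(d) {
    n <- length(d)
    r <- rank(abs(d))
    v <- sum(r[d > 0])
    mu <- n * (n + 1) / 4
    signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
    vs <- apply(signs, 1, function(s) sum(r[s]))
    mean(abs(vs - mu) >= abs(v - mu) - 1e-12)
  }
  withr::local_seed(24)
  for (n in c(5, 8, 10)) {
    a <- runif(n); b <- runif(n)
    r <- wilcoxon_signed_rank(a, b)
    expect_equal(r$method, "exact enumeration")
    expect_equal(r$p_value, enum_p(a - b))
  }
  # case with distinct absolute differences agrees with the standard
  # implementation (which can only be exact without rank ties)
  a <- c(1.1, 2.3, 0.4, 5.1, 2.2, 0.9, 3.3, 1.8)
  b <- c(0.9, 2.9, 0.1, 4.0, 2.7, 1.65, 2.1, 1.75)
  expect_equal(wilcoxon_signed_rank(a, b)$p_value,
               stats::wilcox.test(a, b, paired = TRUE, exact = TRUE)$p.value)
})

test_that("the normal-approximation branch tracks the standard test", {
  withr::local_seed(25)
  a <- rnorm(30); b <- rnorm(30, 0.4)
  r <- wilcoxon_signed_rank(a, b)
  expect_equal(r$method, "normal approximation")
  ref <- stats::wilcox.test(a, b, paired = TRUE, exact = FALSE,
                            correct = TRUE)$p.value
  expect_equal(r$p_value, ref, tolerance = 1e-10)
})

test_that("the random baseline is seeded and hits uniform recall", {
  sch <- label_schema(c("A", "B", "C", "NA"))
  gold <- mk_corpus(rep(sch$labels, each = 250))
  p1 <- baseline_random(gold, sch, seed = 13)
  expect_identical(p1, baseline_random(gold, sch, seed = 13))
  r <- score(gold, p1, sch, include_na = TRUE)
  # per-class recall ~ Binomial(250, 1/4): 3 SEs
  se <- sqrt(0.25 * 0.75 / 250)
  expect_true(all(abs(tidy(r)$recall - 0.25) < 3 * se))
  one <- label_schema("Z", na_label = "Z")
  expect_true(all(baseline_random(gold, one, 1)$label == "Z"))
})

test_that("the majority baseline predicts the modal training label", {
  sch <- label_schema(c("A", "B", "NA"))
  train <- mk_corpus(c("A", "A", "B", "NA"))
  test <- mk_corpus(c("B", "B", "A"))
  expect_true(all(baseline_majority(train, test)$label == "A"))
  # tie broken lexicographically
  train2 <- mk_corpus(c("B", "B", "A", "A"))
  expect_true(all(baseline_majority(train2, test)$label == "A"))

  # micro accuracy equals the test frequency of the majority train label
  withr::local_seed(26)
  gold <- mk_corpus(sample(sch$labels, 60, replace = TRUE,
                           prob = c(0.2, 0.3, 0.5)))
  trn <- mk_corpus(sample(sch$labels, 60, replace = TRUE,
                          prob = c(0.2, 0.3, 0.5)))
  maj <- names(which.max(table(trn$label)))
  r <- score(gold, baseline_majority(trn, gold), sch, include_na = TRUE)
  expect_equal(r$micro_f1, mean(gold$label == maj))

  # macro-F1 of majority on balanced k-class gold, via the hand oracle
  k <- 3
  gold_b <- mk_corpus(rep(c("A", "B", "NA"), each = 10))
  pred_b <- baseline_majority(mk_corpus(rep("A", 5)), gold_b)
  h <- hand_score(gold_b$label, pred_b$label, sch$labels, "NA")
  r_b <- score(gold_b, pred_b, sch, include_na = TRUE)
  expect_equal(mean(h$f1), (2 / (k + 1)) / k)
  expect_equal(score(gold_b, pred_b, sch, include_na = TRUE)$macro_f1,
               mean(h$f1))
})

test_that("mismatched tokenization is rejected", {
  sch <- label_schema(c("A", "NA"))
  gold <- mk_corpus(c("A", "NA"))
  pred <- gold
  pred$token <- c("x", "y")
  expect_error(score(gold, pred, sch), "tokenization")
  expect_error(score(gold, pred[1, ], sch), "token count")
})
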