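#' Token-level precision/recall/F1 evaluation
#'
#' Scores a predicted labeling against the gold standard at the token
#' level. Per-class precision is `TP/(TP+FP)` and recall `TP/(TP+FN)`
#' (0 when undefined); F1 is their harmonic mean (0 when `P + R = 0`).
#' Macro averages are unweighted means over the non-NA classes — the NA
#' ("not applicable") class dominates clinical text and would swamp the
#' average, so its F1 is reported separately — while micro averages pool
#' counts over all tokens.
#'
#' @param gold,pred Labeled corpus tibbles with identical tokenization.
#' @param schema The [label_schema()].
#' @param include_na Include the NA class in macro averages.
#' @param drop_absent Drop schema classes with neither gold nor predicted
#'   tokens from macro averages instead of counting them as 0.
#' @return An `eval_report`: `per_class` tibble (`label`, `precision`,
#'   `recall`, `f1`, `support`, `predicted`), `macro_precision/recall/f1`,
#'   `micro_precision/recall/f1`, `na_f1` and `n_tokens`.
#' @examples
#' sch <- label_schema(c("A", "B", "NA"))
#' gold <- tibble::tibble(sentence_id = 1L, token = letters[1:4],
#'                        label = c("A", "B", "NA", "NA"))
#' pred <- dplyr::mutate(gold, label = c("A", "A", "NA", "NA"))
#' glance(score(gold, pred, sch))
#' @export
score <- function(gold, pred, schema, include_na = FALSE,
                  drop_absent = FALSE) {
  check_corpus(gold, schema)
  check_corpus(pred, schema)
  if (nrow(gold) != nrow(pred))
    abort("Gold and predicted corpora differ in token count.")
  if (!identical(gold$token, pred$token))
    abort("Gold and predicted corpora must share the same tokenization.")
  K <- length(schema$labels)
  g <- label_ids(schema, gold$label)
  p <- label_ids(schema, pred$label)
  tp <- tabulate(g[g == p], nbins = K)
  ng <- tabulate(g, nbins = K)
  np <- tabulate(p, nbins = K)
  prec <- ifelse(np > 0, tp / np, 0)
  rec <- ifelse(ng > 0, tp / ng, 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  per_class <- tibble::tibble(label = schema$labels, precision = prec,
                              recall = rec, f1 = f1, support = ng,
                              predicted = np)
  na_id <- match(schema$na_label, schema$labels)
  sel <- if (include_na) seq_len(K) else setdiff(seq_len(K), na_id)
  if (drop_absent) sel <- sel[ng[sel] > 0 | np[sel] > 0]
  micro_p <- sum(tp) / sum(np)   # predictions are exhaustive single labels,
  micro_r <- sum(tp) / sum(ng)   # so both equal token accuracy
  structure(list(per_class = per_class,
                 macro_precision = mean(prec[sel]),
                 macro_recall = mean(rec[sel]),
                 macro_f1 = mean(f1[sel]),
                 micro_precision = micro_p, micro_recall = micro_r,
                 micro_f1 = if (micro_p + micro_r > 0)
                   2 * micro_p * micro_r / (micro_p + micro_r) else 0,
                 na_f1 = f1[na_id], n_tokens = length(g),
                 include_na = include_na),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, digits = 3, ...) {
  cat("<eval_report> ", x$n_tokens, " tokens\n", sep = "")
  cat(sprintf("  macro P/R/F1 (%s NA): %.*f / %.*f / %.*f\n",
              if (x$include_na) "incl." else "excl.",
              digits, x$macro_precision, digits, x$macro_recall,
              digits, x$macro_f1))
  cat(sprintf("  micro P/R/F1: %.*f / %.*f / %.*f   NA F1: %.*f\n",
              digits, x$micro_precision, digits, x$micro_recall,
              digits, x$micro_f1, digits, x$na_f1))
  invisible(x)
}

#' @rdname score
#' @param x,object An `eval_report`.
#' @param ... Unused.
#' @export
tidy.eval_report <- function(x, ...) x$per_class

#' @rdname score
#' @export
glance.eval_report <- function(x, ...) {
  tibble::tibble(macro_precision = x$macro_precision,
                 macro_recall = x$macro_recall, macro_f1 = x$macro_f1,
                 micro_precision = x$micro_precision,
                 micro_recall = x$micro_recall, micro_f1 = x$micro_f1,
                 na_f1 = x$na_f1, n_tokens = x$n_tokens)
}

#' Per-class F1 bar chart for an evaluation report
#'
#' @param object An `eval_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.eval_report <- function(object, ...) {
  d <- dplyr::mutate(object$per_class,
                     label = stats::reorder(.data$label, .data$f1))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$f1, y = .data$label)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = object$macro_f1, linetype = "dashed") +
    ggplot2::labs(x = "F1", y = NULL,
                  title = "Per-class F1 (dashed: macro-F1)")
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided paired comparison of per-document scores from two systems.
#' Zero differences are dropped; for `n <= 12` remaining pairs the null
#' distribution of the positive-rank sum is enumerated exactly over all
#' `2^n` sign assignments (exact also under rank ties), otherwise a normal
#' approximation with continuity and tie correction is used. When every
#' difference is zero the comparison is degenerate and `p = 1`.
#'
#' @param scores_a,scores_b Equal-length numeric vectors of paired scores
#'   (e.g. per-document macro-F1 of two systems).
#' @param exact_max Largest `n` for which the exact enumeration is used.
#' @return List with `statistic` (positive-rank sum `V`), `p_value`,
#'   `n_effective` (non-zero differences), `method` and `degenerate`.
#' @export
wilcoxon_signed_rank <- function(scores_a, scores_b, exact_max = 12) {
  if (length(scores_a) != length(scores_b))
    abort("Paired score vectors must have equal length.")
  d <- scores_a - scores_b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0)
    return(list(statistic = 0, p_value = 1, n_effective = 0L,
                method = "degenerate", degenerate = TRUE))
  if (n < 5)
    abort("Need at least 5 non-zero differences (or all zero).")
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  if (n <= exact_max) {
    # null distribution of V: each rank enters the positive sum with p=1/2
    sums <- 0
    for (ri in r) sums <- c(sums, sums + ri)
    p <- mean(abs(sums - mu) >= abs(v - mu) - 1e-12)
    method <- "exact enumeration"
  } else {
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (abs(v - mu) - 0.5) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-max(z, 0)))
    method <- "normal approximation"
  }
  list(statistic = v, p_value = p, n_effective = as.integer(n),
       method = method, degenerate = FALSE)
}

#' Random-label baseline tagger
#'
#' Assigns every token a uniformly random label from the schema; a floor
#' reference for task difficulty.
#'
#' @param test Corpus tibble to tag.
#' @param schema The [label_schema()].
#' @param seed RNG seed.
#' @return The corpus with random `label`s.
#' @export
baseline_random <- function(test, schema, seed = 1L) {
  check_corpus(test, labeled = FALSE)
  out <- test[c("sentence_id", "token")]
  out$label <- with_seed(seed,
    sample(schema$labels, nrow(test), replace = TRUE))
  tibble::as_tibble(out)
}

#' Majority-class baseline tagger
#'
#' Assigns every test token the most frequent training label (ties broken
#' toward the lexicographically first label).
#'
#' @param train Labeled training corpus tibble.
#' @param test Corpus tibble to tag.
#' @return The test corpus with the majority `label`.
#' @export
baseline_majority <- function(train, test) {
  check_corpus(train, labeled = TRUE)
  if (nrow(train) == 0) abort("Training corpus is empty.")
  check_corpus(test, labeled = FALSE)
  tab <- table(train$label)
  maj <- sort(names(tab)[tab == max(tab)])[1]
  out <- test[c("sentence_id", "token")]
  out$label <- maj
  tibble::as_tibble(out)
}
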