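# Independent oracles used across tests. These deliberately re-derive
# quantities by brute force / direct arithmetic and never call the code
# paths they are checking.

# log-partition by exhaustive enumeration of all K^L label paths
brute_log_z <- function(emission, transition) {
  L <- nrow(emission); K <- ncol(emission)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), L)))
  scores <- apply(paths, 1, function(y) {
    s <- sum(emission[cbind(seq_len(L), y)])
    if (L > 1) s <- s + sum(transition[cbind(y[-L], y[-1])])
    s
  })
  m <- max(scores)
  m + log(sum(exp(scores - m)))
}

# best path score by exhaustive enumeration
brute_best_score <- function(emission, transition) {
  L <- nrow(emission); K <- ncol(emission)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), L)))
  max(apply(paths, 1, function(y) {
    s <- sum(emission[cbind(seq_len(L), y)])
    if (L > 1) s <- s + sum(transition[cbind(y[-L], y[-1])])
    s
  }))
}

# score of a specific path under the potentials
path_score <- function(emission, transition, y) {
  L <- nrow(emission)
  s <- sum(emission[cbind(seq_len(L), y)])
  if (L > 1) s <- s + sum(transition[cbind(y[-L], y[-1])])
  s
}

# central finite-difference gradient of scalar f at x (a numeric vector)
fd_grad <- function(f, x, h = 1e-5) {
  vapply(seq_along(x), function(i) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    (f(xp) - f(xm)) / (2 * h)
  }, numeric(1))
}

max_rel_err <- function(analytic, numeric) {
  max(abs(analytic - numeric) / pmax(abs(analytic), abs(numeric), 1e-8))
}

# small random featurized sentence in the flat encoding used by the CRF
random_flat_sentence <- function(L, K, F_, nnz = 2) {
  idx <- integer(); off <- 0L
  for (l in seq_len(L)) {
    idx <- c(idx, sample.int(F_, nnz))
    off <- c(off, off[length(off)] + nnz)
  }
  list(idx = as.integer(idx), val = runif(length(idx), -1, 1),
       off = as.integer(off), y = sample.int(K, L, replace = TRUE))
}

# deterministic toy tagging task: disjoint per-label vocabularies
toy_tagged_corpus <- function(n_sentences, len = 5, seed = 7) {
  vocab <- c(aa = "A", ab = "A", ba = "B", bb = "B", na1 = "NA", na2 = "NA")
  withr::local_seed(seed)
  toks <- lapply(seq_len(n_sentences),
                 function(i) sample(names(vocab), len, replace = TRUE))
  tibble::tibble(sentence_id = rep(seq_len(n_sentences), each = len),
                 token = unlist(toks),
                 label = unname(vocab[unlist(toks)]))
}

toy_schema <- function() label_schema(c("A", "B", "NA"))
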