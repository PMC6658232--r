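#' Replace digit runs with length-coded placeholders
#'
#' Every maximal run of consecutive digits of length `m` is replaced by the
#' literal `NUM` followed by `m`; all other characters are untouched. This
#' keeps the pattern of dates, phone numbers, room numbers and doses while
#' collapsing the vocabulary: `"08-08-1988"` becomes `"NUM2-NUM2-NUM4"`.
#'
#' @param x Character vector of tokens.
#' @return `x` with digit runs replaced.
#' @examples
#' normalize_digits(c("08-08-1988", "room", "12B"))
#' @export
normalize_digits <- function(x) {
  m <- gregexpr("[0-9]+", x)
  regmatches(x, m) <- lapply(regmatches(x, m),
                             function(r) paste0("NUM", nchar(r)))
  x
}

#' Build a tokenized text corpus
#'
#' @param x Sentences as a list of character token vectors, a character
#'   vector of whitespace-tokenized sentences, or a tibble with
#'   `sentence_id` and `token` columns.
#' @param digits Apply [normalize_digits()] to every token.
#' @return A `text_corpus`: list with `sentences` (token vectors), `vocab`
#'   (distinct tokens, by decreasing frequency then alphabetically),
#'   `counts` (named occurrence counts) and `n_tokens` (total occurrences).
#' @export
text_corpus <- function(x, digits = FALSE) {
  sentences <-
    if (is.data.frame(x)) {
      check_corpus(x, labeled = FALSE)
      unname(split(x$token, factor(x$sentence_id, levels = unique(x$sentence_id))))
    } else if (is.character(x)) {
      strsplit(trimws(x), "[ \t]+")
    } else if (is.list(x)) {
      lapply(x, as.character)
    } else abort("Cannot interpret `x` as a text corpus.")
  sentences <- sentences[lengths(sentences) > 0]
  if (digits) sentences <- lapply(sentences, normalize_digits)
  tokens <- unlist(sentences, use.names = FALSE)
  if (length(tokens) == 0) abort("Text corpus is empty.")
  tab <- table(tokens)
  ord <- order(-as.integer(tab), names(tab), method = "radix")
  structure(list(sentences = sentences,
                 vocab = names(tab)[ord],
                 counts = setNames(as.integer(tab)[ord], names(tab)[ord]),
                 n_tokens = length(tokens)),
            class = "text_corpus")
}

#' @export
print.text_corpus <- function(x, ...) {
  cat("<text_corpus>", length(x$sentences), "sentences,", x$n_tokens,
      "tokens,", length(x$vocab), "distinct words\n")
  invisible(x)
}

#' Skip-gram training configuration
#'
#' Defaults follow the settings commonly used for named-entity work and
#' adopted here: 200 dimensions, context window 5, 10 negative samples,
#' initial learning rate 0.05, 20 epochs.
#'
#' @param dim Embedding dimension `d`.
#' @param window Context window size `c`: offsets `-c..c` (excluding 0,
#'   truncated at sentence bounds) are context positions.
#' @param negatives Number of negative samples `k` per positive pair.
#' @param initial_lr Initial learning rate; decays linearly to 0 over the
#'   run.
#' @param epochs Training passes over the corpus.
#' @param noise_exponent Exponent applied to the unigram distribution U(w)
#'   for negative sampling. Default 1 (raw unigram frequency); 0.75 is the
#'   common smoothed alternative.
#' @param min_count Words occurring fewer than `min_count` times map to the
#'   `<unk>` entry, whose trained vector is the unknown-word vector. The
#'   default 1 keeps every word.
#' @param subsample Frequent-word subsampling threshold; 0 (default)
#'   disables it. When positive, each occurrence of word `w` with corpus
#'   frequency `f_w` is dropped with probability
#'   `max(0, 1 - sqrt(subsample / f_w))` before training.
#' @param seed RNG seed; training is fully deterministic given the seed.
#' @return A `skipgram_config` list.
#' @export
skipgram_config <- function(dim = 200, window = 5, negatives = 10,
                            initial_lr = 0.05, epochs = 20,
                            noise_exponent = 1, min_count = 1,
                            subsample = 0, seed = 1L) {
  stopifnot(dim >= 1, window >= 1, negatives >= 1, initial_lr > 0,
            epochs >= 1, min_count >= 1, subsample >= 0)
  structure(list(dim = as.integer(dim), window = as.integer(window),
                 negatives = as.integer(negatives), initial_lr = initial_lr,
                 epochs = as.integer(epochs), noise_exponent = noise_exponent,
                 min_count = as.integer(min_count), subsample = subsample,
                 seed = as.integer(seed)),
            class = "skipgram_config")
}

# embedding model constructor; unknown vector = <unk> row when present
new_embedding_model <- function(vocab, input, output) {
  rownames(input) <- vocab
  rownames(output) <- vocab
  unk <- if ("<unk>" %in% vocab) input["<unk>", ] else numeric(ncol(input))
  structure(list(vocab = vocab, input = input, output = output,
                 unknown = unk, dim = ncol(input)),
            class = "embedding_model")
}

#' @export
print.embedding_model <- function(x, ...) {
  cat("<embedding_model>", length(x$vocab), "words x", x$dim, "dims\n")
  invisible(x)
}

#' Negative-sampling objective and exact gradients
#'
#' The per-pair training objective distinguishes the true context word from
#' `k` noise words:
#' `log sigma(u_o . v_c) + sum_i log sigma(-u_i . v_c)`,
#' where `v_c` is the center word's input vector, `u_o` the context word's
#' output vector and `u_i` the negative words' output vectors.
#'
#' @param center,context Word ids (1-based indices into `model$vocab`) or
#'   words.
#' @param negatives Vector of `k` negative word ids or words.
#' @param model An [embedding_model].
#' @return List with `objective` (scalar) and gradients `grad_center` (d),
#'   `grad_context` (d) and `grad_negatives` (k x d), for gradient ascent.
#' @export
negative_sampling_objective <- function(center, context, negatives, model) {
  as_id <- function(w) {
    if (is.character(w)) w <- match(w, model$vocab)
    w <- as.integer(w)
    if (anyNA(w) || any(w < 1) || any(w > length(model$vocab)))
      abort("Invalid word id.")
    w
  }
  ci <- as_id(center); oi <- as_id(context); ni <- as_id(negatives)
  v <- model$input[ci, ]
  uo <- model$output[oi, ]
  un <- model$output[ni, , drop = FALSE]
  so <- sum(uo * v)
  sn <- as.vector(un %*% v)
  sig <- function(x) 1 / (1 + exp(-x))
  objective <- log(sig(so)) + sum(log(sig(-sn)))
  g_pos <- 1 - sig(so)            # d/ds log sigma(s)
  g_neg <- -sig(sn)               # d/ds log sigma(-s) = -sigma(s)
  list(objective = objective,
       grad_center = g_pos * uo + as.vector(t(un) %*% g_neg),
       grad_context = g_pos * v,
       grad_negatives = outer(g_neg, v))
}

# ---- internal encoding shared by train_skipgram / incremental_train ----

# map corpus tokens onto a vocab (rare -> <unk>), returning integer ids,
# sentence offsets and per-word counts in vocab order
encode_corpus <- function(corpus, vocab) {
  ids <- lapply(corpus$sentences, function(s) {
    i <- match(s, vocab)
    i[is.na(i)] <- match("<unk>", vocab)
    i
  })
  list(words = as.integer(unlist(ids, use.names = FALSE)),
       off = as.integer(c(0L, cumsum(lengths(ids)))))
}

# deterministic negative-sampling table over U(w)^exponent
build_neg_table <- function(counts_by_id, exponent, size = 100000L) {
  w <- counts_by_id^exponent
  reps <- pmax(ifelse(counts_by_id > 0, 1L, 0L), round(size * w / sum(w)))
  rep(seq_along(counts_by_id), times = reps)
}

# drop frequent tokens in place (word2vec-style subsampling), seeded
subsample_sentences <- function(sentences, counts, threshold, n_tokens) {
  freq <- counts / n_tokens
  p_drop <- pmax(0, 1 - sqrt(threshold / freq))
  lapply(sentences, function(s) {
    keep <- runif(length(s)) >= p_drop[match(s, names(p_drop))]
    s[keep]
  })
}

#' Train skip-gram embeddings with negative sampling
#'
#' Sequential stochastic ascent over all (center, context) pairs within the
#' window, one positive and `k` negative updates per pair, learning rate
#' decaying linearly to 0 over the run. Sentence order is reshuffled every
#' epoch from the seeded generator; the result is bit-identical across runs
#' with the same seed.
#'
#' @param corpus A [text_corpus()] (or anything it accepts).
#' @param config A [skipgram_config()].
#' @return An [embedding_model] over the corpus vocabulary (plus `<unk>`).
#' @export
train_skipgram <- function(corpus, config = skipgram_config()) {
  corpus <- if (inherits(corpus, "text_corpus")) corpus else text_corpus(corpus)
  with_seed(config$seed, {
    counts <- corpus$counts
    kept <- names(counts)[counts >= config$min_count]
    vocab <- c(kept, "<unk>")
    sentences <- corpus$sentences
    if (config$subsample > 0)
      sentences <- subsample_sentences(sentences, counts, config$subsample,
                                       corpus$n_tokens)
    enc <- encode_corpus(list(sentences = sentences), vocab)
    W <- length(vocab); d <- config$dim
    counts_by_id <- tabulate(enc$words, nbins = W)
    input <- matrix(runif(W * d, -0.5, 0.5) / d, W, d)
    output <- matrix(0, W, d)
    tin <- t(input); tout <- t(output)
    cpp_skipgram_train(enc$words, enc$off, tin, tout, config$window,
                       config$negatives, config$epochs,
                       build_neg_table(counts_by_id, config$noise_exponent),
                       c(config$initial_lr, config$initial_lr),
                       rep(2L, W), config$seed)
    new_embedding_model(vocab, t(tin), t(tout))
  })
}

#' Sentence-averaged initialization for a new word
#'
#' A word unseen in the base vocabulary is initialized to the per-dimension
#' mean of the vectors of the words in the sentence where it first appears:
#' `(1/S) * sum_i v_i`, where `v_i` is the stored input vector when word `i`
#' is in the base vocabulary and the unknown-word vector `v_0` otherwise,
#' and `S` is the sentence length. Words in similar contexts tend to be
#' similar, so this starts new domain terms from an averaged optimized point
#' rather than from scratch.
#'
#' @param tokens Character vector: the sentence (non-empty).
#' @param base The base [embedding_model].
#' @return A numeric vector of length `base$dim`.
#' @export
averaged_init <- function(tokens, base) {
  if (length(tokens) == 0) abort("Cannot average over an empty sentence.")
  colMeans(attach_embedding_features(base, tokens))
}

#' Split learning-rate schedule for incremental adaptation
#'
#' New words (`V1 \ V0`, present only in the adaptation corpus) start at
#' `alpha0_new` (default 0.2); words already trained in the base model
#' (`V0 ∩ V1`) start at `alpha0_new * |V1 \ V0| / |V0 ∪ V1|` — the share of
#' new words in the joint vocabulary, so old vectors move more when there is
#' more new material to reconcile with. Both rates decay linearly to 0 at
#' `t = n`.
#'
#' @param n Total number of training samples (center-word occurrences times
#'   epochs).
#' @param alpha0_new Initial rate for new words.
#' @param alpha0_old Initial rate for old words; when `NULL`, computed from
#'   the vocabulary sizes.
#' @param n_new,n_union Sizes `|V1 \ V0|` and `|V0 ∪ V1|`; required when
#'   `alpha0_old` is `NULL`.
#' @return An `adapt_schedule` list.
#' @export
adapt_schedule <- function(n, alpha0_new = 0.2, alpha0_old = NULL,
                           n_new = NULL, n_union = NULL) {
  if (is.null(alpha0_old)) {
    if (is.null(n_new) || is.null(n_union))
      abort("Supply `alpha0_old` or both `n_new` and `n_union`.")
    alpha0_old <- alpha0_new * n_new / n_union
  }
  stopifnot(n >= 1, alpha0_new >= 0, alpha0_old >= 0)
  structure(list(alpha0_new = alpha0_new, alpha0_old = alpha0_old, n = n),
            class = "adapt_schedule")
}

#' Learning rate at sample t under an adaptation schedule
#'
#' @param t Samples consumed so far, `0 <= t <= n`.
#' @param word_class `"new"` (word in `V1 \ V0`) or `"old"` (in `V0 ∩ V1`).
#' @param schedule An [adapt_schedule()].
#' @return The non-negative learning rate `alpha0 * (1 - t/n)`.
#' @export
adapt_learning_rate <- function(t, word_class = c("new", "old"), schedule) {
  word_class <- match.arg(word_class)
  if (any(t < 0) || any(t > schedule$n))
    abort("`t` must lie in [0, n].")
  a0 <- if (word_class == "new") schedule$alpha0_new else schedule$alpha0_old
  a0 * (1 - t / schedule$n)
}

#' Incrementally adapt embeddings to a new domain corpus
#'
#' Extends a base model's vocabulary with the new corpus's words: new words
#' are initialized by [averaged_init()] from the first sentence in which
#' they appear (output vectors start at zero) and trained under the
#' new-word learning rate; words shared with the base vocabulary are
#' fine-tuned under the smaller old-word rate; base words absent from the
#' new corpus are left untouched.
#'
#' @param base The base [embedding_model] (trained on the general corpus
#'   `D0`).
#' @param new_corpus The domain corpus `D1`, a [text_corpus()].
#' @param config A [skipgram_config()]; `config$dim` must equal `base$dim`.
#' @param schedule An [adapt_schedule()]; by default built with
#'   `alpha0_new = 0.2` and the vocabulary-fraction old rate over
#'   `n = epochs * n_tokens` samples.
#' @return An [embedding_model] over `V0 ∪ V1`.
#' @export
incremental_train <- function(base, new_corpus,
                              config = skipgram_config(dim = base$dim),
                              schedule = NULL) {
  stopifnot(inherits(base, "embedding_model"))
  new_corpus <- if (inherits(new_corpus, "text_corpus")) new_corpus
                else text_corpus(new_corpus)
  if (config$dim != base$dim)
    abort(sprintf("config$dim (%d) must match base$dim (%d).",
                  config$dim, base$dim))
  with_seed(config$seed, {
    v1 <- new_corpus$vocab
    new_words <- setdiff(v1, base$vocab)
    vocab <- c(base$vocab, new_words)
    if (is.null(schedule))
      schedule <- adapt_schedule(n = config$epochs * new_corpus$n_tokens,
                                 alpha0_new = 0.2,
                                 n_new = length(new_words),
                                 n_union = length(vocab))
    input <- rbind(base$input, matrix(0, length(new_words), base$dim))
    output <- rbind(base$output, matrix(0, length(new_words), base$dim))
    rownames(input) <- rownames(output) <- vocab
    for (w in new_words) {
      first <- Find(function(s) w %in% s, new_corpus$sentences)
      input[w, ] <- averaged_init(first, base)
    }
    enc <- encode_corpus(new_corpus, vocab)
    counts_by_id <- tabulate(enc$words, nbins = length(vocab))
    word_class <- ifelse(vocab %in% new_words, 2L, 1L)
    tin <- t(input); tout <- t(output)
    cpp_skipgram_train(enc$words, enc$off, tin, tout, config$window,
                       config$negatives, config$epochs,
                       build_neg_table(counts_by_id, config$noise_exponent),
                       c(schedule$alpha0_old, schedule$alpha0_new),
                       word_class, config$seed)
    new_embedding_model(vocab, t(tin), t(tout))
  })
}

#' Cosine similarity between two words' input vectors
#'
#' @param model An [embedding_model].
#' @param a,b Words; out-of-vocabulary words use the unknown vector.
#' @return Cosine similarity in `[-1, 1]` (0 when either vector is zero).
#' @export
word_similarity <- function(model, a, b) {
  va <- attach_embedding_features(model, a)[1, ]
  vb <- attach_embedding_features(model, b)[1, ]
  den <- sqrt(sum(va^2)) * sqrt(sum(vb^2))
  if (den == 0) 0 else sum(va * vb) / den
}
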