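#' CRF training configuration
#'
#' Training uses per-sentence AdaGrad updates (per-coordinate step
#' `adagrad_step / sqrt(accumulated_grad_sq + adagrad_epsilon)`) with L2
#' regularization, and early stopping on development-set macro-F1
#' (excluding the NA class) when a development corpus is supplied.
#'
#' @param l2_lambda L2 regularization strength; the objective is
#'   `sum -log p(y|x) + (l2_lambda/2) * ||W||^2`.
#' @param adagrad_step Base AdaGrad step size.
#' @param adagrad_epsilon Stabilizer inside the AdaGrad square root.
#' @param max_epochs Maximum training epochs (0 returns the initialization
#'   unchanged).
#' @param patience Epochs without development macro-F1 improvement before
#'   stopping.
#' @param seed RNG seed controlling the per-epoch sentence shuffle.
#' @return A `train_config` list.
#' @export
train_config <- function(l2_lambda = 1e-3, adagrad_step = 0.1,
                         adagrad_epsilon = 1e-8, max_epochs = 30,
                         patience = 5, seed = 1L) {
  stopifnot(l2_lambda >= 0, adagrad_step > 0, adagrad_epsilon > 0,
            max_epochs >= 0, patience >= 1)
  structure(list(l2_lambda = l2_lambda, adagrad_step = adagrad_step,
                 adagrad_epsilon = adagrad_epsilon,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), seed = as.integer(seed)),
            class = "train_config")
}

#' Forward-backward inference for a linear chain
#'
#' Computes, in log space, the log-partition function and the exact unary
#' and pairwise label marginals of a linear-chain model with the given
#' emission log-potentials (`L x K`) and position-independent transition
#' log-potentials (`K x K`, entry `[a, b]` scoring the move `a -> b`).
#'
#' @param emission `L x K` numeric matrix of per-position label scores.
#' @param transition `K x K` numeric matrix of label-pair scores.
#' @return List with `log_z`, `unary` (`L x K`, rows sum to 1) and
#'   `pairwise` (`(L-1) x K x K` array; empty for `L = 1`).
#' @export
forward_backward <- function(emission, transition) {
  emission <- as.matrix(emission)
  cpp_forward_backward(emission, as.matrix(transition))
}

#' Viterbi decoding
#'
#' Highest-scoring label path under the potentials; ties are broken toward
#' the lower label index at every step.
#'
#' @inheritParams forward_backward
#' @return Integer vector of 1-based label indices, length `L`.
#' @export
viterbi_decode <- function(emission, transition) {
  cpp_viterbi(as.matrix(emission), as.matrix(transition))
}

#' Per-position potential tables for a sentence
#'
#' @param model A fitted [crf_model][train_crf()].
#' @param x Either the sentence's token character vector (featurized with
#'   the model's frozen templates and index) or a per-position feature list
#'   as returned by [extract_features()].
#' @return List with `emission` (`L x K`) and `transition` (`K x K`).
#' @export
sentence_potentials <- function(model, x) {
  stopifnot(inherits(model, "crf_model"))
  enc <- encode_for_model(model, x)
  if (length(enc$idx) > 0 && max(enc$idx) > ncol(model$W_f))
    abort("Feature id out of range for this model.")
  list(emission = cpp_emission_scores(enc$idx, enc$val, enc$off, model$W_f),
       transition = model$W_g)
}

# tokens or feature list -> flat (idx, val, off) in the model's space
encode_for_model <- function(model, x) {
  if (is.character(x)) {
    fz <- featurize(tibble::tibble(sentence_id = 1L, token = x),
                    model$templates, model$index,
                    embeddings = model$embeddings, grow = FALSE)
    fz$sents[[1]][c("idx", "val", "off")]
  } else {
    list(idx = as.integer(unlist(lapply(x, `[[`, "i"))),
         val = as.numeric(unlist(lapply(x, `[[`, "x"))),
         off = c(0L, cumsum(vapply(x, function(f) length(f$i), 1L))))
  }
}

#' Negative log-likelihood and gradient of a CRF on a batch
#'
#' The model is the standard log-linear chain
#' `p(y|x) = exp(sum_l W_f f(y_l, x) + W_g g(y_{l-1}, y_l)) / Z`, so the
#' loss is `-sum log p(y|x) + (lambda/2) ||W||^2` and the gradient is
#' expected minus observed feature counts plus `lambda W`.
#'
#' @param W_f `K x F` emission weight matrix.
#' @param W_g `K x K` transition weight matrix.
#' @param sentences Featurized sentences: each `list(idx, val, off, y)`
#'   with 1-based feature ids, 0-based offsets of length `L + 1`, and
#'   1-based gold labels (as produced by the internal featurizer).
#' @param l2_lambda L2 strength.
#' @return List with `loss`, `grad_f` (`K x F`) and `grad_g` (`K x K`).
#' @export
crf_nll_grad <- function(W_f, W_g, sentences, l2_lambda = 0) {
  if (length(sentences) == 0) abort("Batch must be non-empty.")
  loss <- l2_lambda / 2 * (sum(W_f^2) + sum(W_g^2))
  gf <- l2_lambda * W_f
  gg <- l2_lambda * W_g
  for (s in sentences) {
    r <- cpp_sentence_nll_grad(s$idx, s$val, s$off, s$y, W_f, W_g)
    loss <- loss + r$nll
    gf <- gf + r$grad_f
    gg <- gg + r$grad_g
  }
  list(loss = loss, grad_f = gf, grad_g = gg)
}

#' Emission posterior: the CRF's logistic-regression lower layer
#'
#' Softmax over labels of the emission scores of one position,
#' `p(y) = exp(W_f[y, ] . f) / sum_y' exp(W_f[y', ] . f)`, computed with
#' max-subtraction for stability.
#'
#' @param W_f `K x F` emission weight matrix.
#' @param f A feature vector: `list(i = ids, x = values)` or a dense
#'   numeric vector of length `F`.
#' @return Strictly positive probability vector of length `K` summing to 1.
#' @export
emission_posterior <- function(W_f, f) {
  scores <- if (is.list(f)) {
    as.vector(W_f[, f$i, drop = FALSE] %*% f$x)
  } else {
    as.vector(W_f %*% f)
  }
  softmax(scores)
}

softmax <- function(scores) {
  e <- exp(scores - max(scores))
  e / sum(e)
}

# macro-F1 over non-NA classes from integer gold/pred; absent schema
# classes contribute 0
macro_f1_int <- function(gold, pred, K, na_id) {
  tp <- tabulate(gold[gold == pred], nbins = K)
  ng <- tabulate(gold, nbins = K)
  np <- tabulate(pred, nbins = K)
  p <- ifelse(np > 0, tp / np, 0)
  r <- ifelse(ng > 0, tp / ng, 0)
  f1 <- ifelse(p + r > 0, 2 * p * r / (p + r), 0)
  mean(f1[-na_id])
}

#' Train a linear-chain CRF with AdaGrad and early stopping
#'
#' Optimizes the L2-regularized conditional log-likelihood with
#' per-sentence AdaGrad updates. After every epoch the development corpus
#' (when given) is decoded and macro-F1 excluding the NA class is recorded;
#' the returned weights are those of the best development epoch, and
#' training stops once `config$patience` epochs pass without improvement.
#' Runs are deterministic given `config$seed`.
#'
#' @param train Labeled training corpus tibble (`sentence_id`, `token`,
#'   `label`).
#' @param dev Optional labeled development corpus for early stopping.
#' @param schema The [label_schema()].
#' @param templates [feature_templates()] used to featurize sentences.
#' @param config A [train_config()].
#' @param embeddings Optional [embedding_model]; adds a dense per-position
#'   feature block (the token's input vector) next to the sparse templates.
#' @param init Optional warm start: list with `W_f` (`K x F`) and `W_g`
#'   (`K x K`) in the feature space of `index`. Used by [transfer_train()].
#' @param index A [feature_index()] to featurize against; grown from the
#'   training corpus when `grow_index = TRUE`. Supply the source model's
#'   index (with `grow_index = FALSE`) to share a feature space.
#' @param grow_index Whether featurization may extend `index`.
#' @return A `crf_model`: emission weights `W_f` (`K x F`), transition
#'   weights `W_g` (`K x K`), the schema, templates, frozen feature index,
#'   per-epoch `history` tibble and `best_epoch`.
#' @seealso [predict.crf_model()], [transfer_train()]
#' @export
train_crf <- function(train, dev = NULL, schema,
                      templates = feature_templates(),
                      config = train_config(), embeddings = NULL,
                      init = NULL, index = NULL, grow_index = is.null(init)) {
  check_corpus(train, schema)
  if (nrow(train) == 0) abort("Training corpus is empty.")
  if (is.null(index)) index <- feature_index()
  ftr <- featurize(train, templates, index, schema, embeddings,
                   grow = grow_index)
  fdev <- if (!is.null(dev))
    featurize(dev, templates, index, schema, embeddings, grow = FALSE)
  K <- length(schema$labels)
  F_ <- ftr$n_features
  na_id <- match(schema$na_label, schema$labels)

  if (!is.null(init)) {
    if (!all(dim(init$W_f) == c(K, F_)) || !all(dim(init$W_g) == c(K, K)))
      abort("`init` dimensions do not match the label/feature space.")
    W_f <- unname(init$W_f) + 0  # private copies: epochs mutate in place
    W_g <- unname(init$W_g) + 0
  } else {
    W_f <- matrix(0, K, F_)
    W_g <- matrix(0, K, K)
  }

  history <- list()
  best <- list(W_f = W_f + 0, W_g = W_g + 0, f1 = -Inf, epoch = 0L)
  if (config$max_epochs > 0) {
    Gf <- matrix(0, K, F_)
    Gg <- matrix(0, K, K)
    n <- length(ftr$sents)
    stall <- 0L
    with_seed(config$seed, {
      for (epoch in seq_len(config$max_epochs)) {
        ord <- sample.int(n)
        nll <- cpp_crf_epoch(ftr$sents, W_f, W_g, Gf, Gg,
                             config$adagrad_step, config$adagrad_epsilon,
                             config$l2_lambda, ord)
        loss <- nll + config$l2_lambda / 2 * (sum(W_f^2) + sum(W_g^2))
        dev_f1 <- NA_real_
        if (!is.null(fdev)) {
          gold <- unlist(lapply(fdev$sents, `[[`, "y"))
          pred <- unlist(lapply(fdev$sents, function(s)
            cpp_viterbi(cpp_emission_scores(s$idx, s$val, s$off, W_f), W_g)))
          dev_f1 <- macro_f1_int(gold, pred, K, na_id)
        }
        history[[epoch]] <- c(epoch = epoch, loss = loss,
                              dev_macro_f1 = dev_f1)
        if (is.null(fdev) || dev_f1 > best$f1 + 1e-12) {
          best <- list(W_f = W_f + 0, W_g = W_g + 0,
                       f1 = if (is.null(fdev)) -Inf else dev_f1,
                       epoch = epoch)
          stall <- 0L
        } else {
          stall <- stall + 1L
          if (stall >= config$patience) break
        }
      }
    })
  }

  structure(list(W_f = best$W_f, W_g = best$W_g, schema = schema,
                 templates = templates, index = index,
                 embeddings = embeddings, n_sparse = ftr$n_sparse,
                 d_dense = ftr$d_dense, config = config,
                 history = if (length(history))
                   dplyr::bind_rows(lapply(history, as.list))
                 else tibble::tibble(epoch = integer(), loss = numeric(),
                                     dev_macro_f1 = numeric()),
                 best_epoch = best$epoch),
            class = "crf_model")
}

#' @export
print.crf_model <- function(x, ...) {
  cat("<crf_model> ", length(x$schema$labels), " labels x ",
      ncol(x$W_f), " features (", x$n_sparse, " sparse + ", x$d_dense,
      " dense); trained ", nrow(x$history), " epoch(s), best epoch ",
      x$best_epoch, "\n", sep = "")
  invisible(x)
}

#' Tag a corpus with a fitted CRF
#'
#' Featurizes each sentence against the model's frozen feature space
#' (unseen features are dropped) and Viterbi-decodes the best label path.
#'
#' @param object A `crf_model`.
#' @param newdata Corpus tibble with `sentence_id` and `token` (a `label`
#'   column, if present, is ignored).
#' @param ... Unused.
#' @return A corpus tibble with the predicted `label` column.
#' @export
predict.crf_model <- function(object, newdata, ...) {
  check_corpus(newdata, labeled = FALSE)
  fz <- featurize(newdata, object$templates, object$index,
                  embeddings = object$embeddings, grow = FALSE)
  labs <- lapply(fz$sents, function(s) {
    em <- cpp_emission_scores(s$idx, s$val, s$off, object$W_f)
    object$schema$labels[cpp_viterbi(em, object$W_g)]
  })
  out <- newdata[c("sentence_id", "token")]
  out$label <- unlist(labs, use.names = FALSE)
  tibble::as_tibble(out)
}

#' Serialize a CRF model to JSON
#'
#' The file holds the schema, feature names, template offsets and dense
#' weight arrays. Template hooks (R functions) and attached embedding
#' models are not serialized; models using them should be re-assembled in
#' code.
#'
#' @param model A `crf_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_crf_model <- function(model, path) {
  if (length(model$templates$hooks) > 0)
    warn("Template hooks are functions and are not serialized.")
  if (!is.null(model$embeddings))
    abort("Models with attached embeddings cannot be serialized to JSON; save the vectors with write_vectors() and re-attach.")
  obj <- list(labels = model$schema$labels,
              na_label = model$schema$na_label,
              feature_names = feature_names(model$index),
              unigram_offsets = model$templates$unigram_offsets,
              bigram_offsets = model$templates$bigram_offsets,
              n_sparse = model$n_sparse, d_dense = model$d_dense,
              W_f = model$W_f, W_g = model$W_g,
              best_epoch = model$best_epoch)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a CRF model written by [write_crf_model()]
#'
#' @param path Path to the JSON model file.
#' @return A `crf_model`.
#' @export
read_crf_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  schema <- label_schema(obj$labels, obj$na_label)
  idx <- feature_index()
  if (length(obj$feature_names) > 0) fi_ids(idx, obj$feature_names, TRUE)
  templates <- feature_templates(
    unigram_offsets = obj$unigram_offsets,
    bigram_offsets = if (is.matrix(obj$bigram_offsets))
      lapply(seq_len(nrow(obj$bigram_offsets)),
             function(i) obj$bigram_offsets[i, ])
    else obj$bigram_offsets)
  structure(list(W_f = matrix(unlist(obj$W_f), nrow = length(schema$labels)),
                 W_g = matrix(unlist(obj$W_g), nrow = length(schema$labels)),
                 schema = schema, templates = templates, index = idx,
                 embeddings = NULL, n_sparse = obj$n_sparse,
                 d_dense = obj$d_dense, config = train_config(),
                 history = tibble::tibble(epoch = integer(),
                                          loss = numeric(),
                                          dev_macro_f1 = numeric()),
                 best_epoch = obj$best_epoch),
            class = "crf_model")
}
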