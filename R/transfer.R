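#' Linear source-label scores for a feature vector
#'
#' The frozen lower layer of the transfer stack: `a = W_s f`, the source
#' model's raw emission scores. Scores are deliberately left un-normalized
#' so that the learned bridge composes with them exactly linearly, making
#' the product initialization `W_f = W_t W_s` exact.
#'
#' @param bridge A [transfer_bridge][train_bridge()].
#' @param f Feature vector `list(i, x)` (1-based ids in the shared feature
#'   space) or a dense numeric vector.
#' @return Numeric vector of length `|Y_source|`.
#' @export
source_scores <- function(bridge, f) {
  W_s <- bridge$source_emission
  if (is.list(f)) {
    if (length(f$i) > 0 && max(f$i) > ncol(W_s))
      abort("Feature id out of range for the shared feature space.")
    as.vector(W_s[, f$i, drop = FALSE] %*% f$x)
  } else {
    if (length(f) != ncol(W_s)) abort("Dense feature length mismatch.")
    as.vector(W_s %*% f)
  }
}

# multinomial NLL and gradient of the bridge: rows of A are per-token
# source-score vectors a_i, y are 1-based target labels
bridge_nll_grad <- function(W_t, A, y) {
  S <- A %*% t(W_t)                       # n x K_t
  m <- apply(S, 1, max)
  P <- exp(S - m)
  P <- P / rowSums(P)
  n <- nrow(A)
  ll <- sum(log(P[cbind(seq_len(n), y)]))
  D <- P
  D[cbind(seq_len(n), y)] <- D[cbind(seq_len(n), y)] - 1
  list(loss = -ll, grad = t(D) %*% A)     # K_t x K_s
}

#' Learn the source-to-target label-correlation bridge
#'
#' Step two of the transfer procedure: with the source model's emission
#' weights `W_s` frozen, a multinomial logistic classifier `W_t`
#' (`|Y_target| x |Y_source|`) is trained to predict target labels from the
#' source score vectors `a_i = W_s f(x_i)`, by per-token AdaGrad from zero
#' initialization. The composed predictor is
#' `p(y'|x) = softmax(W_t W_s f(x))`.
#'
#' The target corpus must be featurized in the source model's feature
#' space, i.e. the source model should have been trained with a feature
#' index built over the union of both corpora (see [transfer_train()]).
#'
#' @param source_model The fitted source-domain `crf_model`.
#' @param target_train Labeled target-domain corpus tibble.
#' @param target_schema [label_schema()] of the target domain.
#' @param config A [train_config()]; `max_epochs`, `adagrad_step`,
#'   `adagrad_epsilon` and `seed` are used (no regularization is applied to
#'   the bridge).
#' @return A `transfer_bridge`: `source_emission` (`W_s`, frozen copy),
#'   `bridge_weights` (`W_t`), both schemas and the shared feature index.
#' @export
train_bridge <- function(source_model, target_train, target_schema,
                         config = train_config()) {
  stopifnot(inherits(source_model, "crf_model"))
  check_corpus(target_train, target_schema)
  if (nrow(target_train) == 0) abort("Target training corpus is empty.")
  fz <- featurize(target_train, source_model$templates, source_model$index,
                  target_schema, source_model$embeddings, grow = FALSE)
  if (fz$n_features != ncol(source_model$W_f))
    abort("Feature-space mismatch between source model and target corpus.")
  W_s <- source_model$W_f
  # per-token source score vectors a_i = W_s f(x_i)
  A <- do.call(rbind, lapply(fz$sents, function(s)
    cpp_emission_scores(s$idx, s$val, s$off, W_s)))
  y <- unlist(lapply(fz$sents, `[[`, "y"))
  K_t <- length(target_schema$labels)
  K_s <- length(source_model$schema$labels)
  W_t <- matrix(0, K_t, K_s)
  G <- matrix(0, K_t, K_s)
  n <- nrow(A)
  with_seed(config$seed, {
    for (epoch in seq_len(max(config$max_epochs, 1L))) {
      for (i in sample.int(n)) {
        p <- softmax(as.vector(W_t %*% A[i, ]))
        p[y[i]] <- p[y[i]] - 1
        g <- p %o% A[i, ]
        G <- G + g^2
        W_t <- W_t - config$adagrad_step * g / sqrt(G + config$adagrad_epsilon)
      }
    }
  })
  structure(list(source_emission = W_s, bridge_weights = W_t,
                 source_schema = source_model$schema,
                 target_schema = target_schema,
                 index = source_model$index,
                 templates = source_model$templates,
                 embeddings = source_model$embeddings,
                 n_sparse = source_model$n_sparse,
                 d_dense = source_model$d_dense),
            class = "transfer_bridge")
}

#' @export
print.transfer_bridge <- function(x, ...) {
  cat("<transfer_bridge> ", length(x$target_schema$labels), " target x ",
      length(x$source_schema$labels), " source labels over ",
      ncol(x$source_emission), " features\n", sep = "")
  invisible(x)
}

#' Compose the target CRF initialization from a trained bridge
#'
#' Step three of the transfer procedure: the target emission weights are
#' initialized to the product `W_f = W_t W_s`, after which the row of the
#' target NA class is reset to zero — the NA class dominates the corpus and
#' would otherwise bias the transferred model toward it. Transition weights
#' are initialized to zero: label co-occurrence structure is domain-specific
#' and is not transferred.
#'
#' @param bridge A trained [transfer_bridge][train_bridge()].
#' @return List with `W_f` (`|Y_target| x F`, NA row zero) and `W_g`
#'   (`|Y_target| x |Y_target|`, all zero).
#' @export
compose_init <- function(bridge) {
  stopifnot(inherits(bridge, "transfer_bridge"))
  na_row <- match(bridge$target_schema$na_label, bridge$target_schema$labels)
  if (is.na(na_row)) abort("Target schema has no NA label.")
  W_f <- bridge$bridge_weights %*% bridge$source_emission
  W_f[na_row, ] <- 0
  K_t <- length(bridge$target_schema$labels)
  list(W_f = W_f, W_g = matrix(0, K_t, K_t))
}

#' Three-step transfer training of a target-domain CRF
#'
#' 1. freeze the source CRF's emission weights `W_s`;
#' 2. learn the label-correlation bridge `W_t` on the target training data
#'    ([train_bridge()]);
#' 3. initialize a target CRF with `W_f = W_t W_s` (NA row zeroed,
#'    transitions zero; [compose_init()]) and fine-tune it with AdaGrad and
#'    early stopping on the target development set.
#'
#' Early stopping is what preserves the transferred knowledge: prolonged
#' fine-tuning would converge to the cold-start optimum (the regularized
#' likelihood is convex) and forget the source initialization.
#'
#' The source model must share the target corpus's feature space; build the
#' feature index over the union of both corpora before training the source
#' model (pass one [feature_index()] through both training calls).
#'
#' @inheritParams train_bridge
#' @param target_dev Labeled target development corpus for early stopping.
#' @param bridge_config Optional separate [train_config()] for the bridge;
#'   defaults to `config`.
#' @return A fitted target-domain `crf_model` with the `transfer_bridge`
#'   attached as attribute `"bridge"`.
#' @export
transfer_train <- function(source_model, target_train, target_dev,
                           target_schema, config = train_config(),
                           bridge_config = config) {
  bridge <- train_bridge(source_model, target_train, target_schema,
                         bridge_config)
  init <- compose_init(bridge)
  model <- train_crf(target_train, target_dev, target_schema,
                     templates = source_model$templates, config = config,
                     embeddings = source_model$embeddings, init = init,
                     index = source_model$index, grow_index = FALSE)
  attr(model, "bridge") <- bridge
  model
}
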