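#' Feature templates for token classification
#'
#' The standard templates are word unigrams in a window of size 3
#' (`w[i-1], w[i], w[i+1]`) and adjacent bigrams in a window of size 2
#' (`w[i-1]w[i]`, `w[i]w[i+1]`). Positions past the sentence boundary use
#' explicit `<BOS>`/`<EOS>` sentinel tokens. Sparse template features are
#' binary (value 1).
#'
#' Resource-backed annotations (ontology lookups, part-of-speech tags,
#' gazetteer membership and the like) plug in as *hooks*: named functions
#' taking the sentence's token vector and returning one annotation string
#' per token (or `NA` to emit no feature at that position). Each hook `h`
#' contributes features `H[h]=value` at every position.
#'
#' @param unigram_offsets Integer offsets for unigram features.
#' @param bigram_offsets List of length-2 integer vectors, each an adjacent
#'   pair of offsets.
#' @param hooks Named list of functions `function(tokens) -> character`.
#' @return A `feature_templates` object.
#' @examples
#' tpl <- feature_templates(hooks = list(shape = function(tok)
#'   ifelse(grepl("^[0-9]", tok), "startdigit", "other")))
#' @export
feature_templates <- function(unigram_offsets = -1:1,
                              bigram_offsets = list(c(-1L, 0L), c(0L, 1L)),
                              hooks = list()) {
  stopifnot(is.numeric(unigram_offsets),
            all(vapply(bigram_offsets, length, 1L) == 2))
  if (length(hooks) > 0 &&
      (is.null(names(hooks)) || any(!nzchar(names(hooks)))))
    abort("`hooks` must be a named list of functions.")
  structure(list(unigram_offsets = as.integer(unigram_offsets),
                 bigram_offsets = lapply(bigram_offsets, as.integer),
                 hooks = hooks),
            class = "feature_templates")
}

#' Create a mutable feature index
#'
#' Maps feature name strings to contiguous integer ids. During training the
#' index grows as unseen names arrive; at prediction time growth is disabled
#' and unseen names are silently dropped, so the test-time feature space
#' never exceeds the training space.
#'
#' @return A `feature_index` environment.
#' @export
feature_index <- function() {
  e <- new.env(parent = emptyenv())
  e$map <- new.env(parent = emptyenv(), hash = TRUE)
  e$n <- 0L
  e$names <- character()
  class(e) <- "feature_index"
  e
}

#' @export
print.feature_index <- function(x, ...) {
  cat("<feature_index>", x$n, "features\n")
  invisible(x)
}

#' @rdname feature_index
#' @param index A `feature_index`.
#' @return `feature_names()`: the feature names in id order.
#' @export
feature_names <- function(index) index$names

# name -> id lookup; grows the index when grow = TRUE, else returns NA for
# unseen names
fi_ids <- function(index, names, grow) {
  ids <- unlist(mget(names, envir = index$map,
                     ifnotfound = list(NA_integer_)), use.names = FALSE)
  if (grow && anyNA(ids)) {
    new <- unique(names[is.na(ids)])
    new_ids <- index$n + seq_along(new)
    for (i in seq_along(new)) assign(new[i], new_ids[i], envir = index$map)
    index$n <- index$n + length(new)
    index$names <- c(index$names, new)
    ids[is.na(ids)] <- new_ids[match(names[is.na(ids)], new)]
  }
  ids
}

# token at offset position, with boundary sentinels
tok_at <- function(tokens, pos) {
  out <- rep("<BOS>", length(pos))
  out[pos > length(tokens)] <- "<EOS>"
  inb <- pos >= 1 & pos <= length(tokens)
  out[inb] <- tokens[pos[inb]]
  out
}

# feature-name matrix: one row per template feature, one column per position
feature_name_matrix <- function(tokens, templates) {
  L <- length(tokens)
  pos <- seq_len(L)
  rows <- list()
  for (o in templates$unigram_offsets)
    rows[[length(rows) + 1]] <- paste0("U[", o, "]=", tok_at(tokens, pos + o))
  for (b in templates$bigram_offsets)
    rows[[length(rows) + 1]] <- paste0("B[", b[1], ",", b[2], "]=",
                                       tok_at(tokens, pos + b[1]), "|",
                                       tok_at(tokens, pos + b[2]))
  for (h in names(templates$hooks)) {
    ann <- templates$hooks[[h]](tokens)
    if (length(ann) != L)
      abort(sprintf("Hook \"%s\" returned %d annotations for %d tokens.",
                    h, length(ann), L))
    rows[[length(rows) + 1]] <- ifelse(is.na(ann), NA_character_,
                                       paste0("H[", h, "]=", ann))
  }
  matrix(unlist(rows), nrow = length(rows), byrow = TRUE)
}

#' Extract sparse window features for one sentence
#'
#' @param tokens Character vector of sentence tokens (non-empty).
#' @param templates A [feature_templates()] object.
#' @param index A [feature_index()]; mutated when `grow = TRUE`.
#' @param grow Whether unseen feature names may extend the index (training
#'   mode). With `grow = FALSE` unseen names are dropped.
#' @return A list with one element per position: `list(i = sorted feature
#'   ids, x = values)` (all values 1 for template features).
#' @export
extract_features <- function(tokens, templates = feature_templates(),
                             index = feature_index(), grow = TRUE) {
  if (length(tokens) == 0) abort("Cannot featurize an empty sentence.")
  nm <- feature_name_matrix(tokens, templates)
  ids <- rep(NA_integer_, length(nm))
  ids[!is.na(nm)] <- fi_ids(index, nm[!is.na(nm)], grow)
  dim(ids) <- dim(nm)
  lapply(seq_len(ncol(ids)), function(p) {
    i <- sort(unique(ids[!is.na(ids[, p]), p]))
    list(i = i, x = rep(1, length(i)))
  })
}

#' Dense embedding feature block for one sentence
#'
#' Returns, for each position, the input vector of the token under an
#' embedding model; out-of-vocabulary tokens fall back to the model's
#' unknown-word vector. When attached to a CRF feature space these dense
#' features occupy ids disjoint from the sparse template ids.
#'
#' @param model An [embedding_model].
#' @param tokens Character vector of sentence tokens.
#' @return A numeric matrix, `length(tokens)` rows by `model$dim` columns.
#' @export
attach_embedding_features <- function(model, tokens) {
  stopifnot(inherits(model, "embedding_model"))
  ids <- match(tokens, model$vocab)
  out <- matrix(rep(model$unknown, each = length(tokens)),
                nrow = length(tokens))
  hit <- !is.na(ids)
  if (any(hit)) out[hit, ] <- model$input[ids[hit], , drop = FALSE]
  out
}

#' Grow a feature index from one or more corpora
#'
#' Registers every feature name occurring in the given corpora. Use this to
#' build the *shared* feature space required by transfer learning: grow one
#' index over the union of the source and target corpora, train the source
#' CRF against it (`grow_index = FALSE`), and the bridge composition stays
#' exact.
#'
#' @param index A [feature_index()], mutated in place.
#' @param ... Corpus tibbles (any tibble with `sentence_id` and `token`).
#' @param templates [feature_templates()] to extract with.
#' @return `index`, invisibly.
#' @export
grow_feature_index <- function(index, ..., templates = feature_templates()) {
  for (corpus in list(...)) {
    check_corpus(corpus, labeled = FALSE)
    featurize(corpus, templates, index, grow = TRUE)
  }
  invisible(index)
}

# Featurize a whole corpus into the flat sentence encoding consumed by the
# C++ CRF routines: per sentence list(idx, val, off, y, tokens), with dense
# embedding features (if any) occupying ids index$n + 1 .. index$n + d.
featurize <- function(corpus, templates, index, schema = NULL,
                      embeddings = NULL, grow = TRUE) {
  labeled <- "label" %in% names(corpus) && !is.null(schema)
  sents <- corpus_sentences(corpus, labeled = labeled)
  sparse <- lapply(sents, function(s)
    extract_features(s$tokens, templates, index, grow = grow))
  n_sparse <- index$n
  d <- if (is.null(embeddings)) 0L else embeddings$dim
  enc <- purrr::map2(sents, sparse, function(s, fv) {
    if (d > 0) {
      dense <- attach_embedding_features(embeddings, s$tokens)
      fv <- lapply(seq_along(fv), function(p)
        list(i = c(fv[[p]]$i, n_sparse + seq_len(d)),
             x = c(fv[[p]]$x, dense[p, ])))
    }
    list(idx = as.integer(unlist(lapply(fv, `[[`, "i"))),
         val = as.numeric(unlist(lapply(fv, `[[`, "x"))),
         off = c(0L, cumsum(vapply(fv, function(f) length(f$i), 1L))),
         y = if (labeled) as.integer(label_ids(schema, s$labels)) else NULL,
         tokens = s$tokens)
  })
  list(sents = unname(enc), n_sparse = n_sparse, d_dense = d,
       n_features = n_sparse + d)
}
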