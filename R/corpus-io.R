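#' Read a token-per-line tagged corpus
#'
#' Reads a CoNLL-style two-column file: one `token TAB label` pair per line,
#' sentences separated by blank lines. Files are assumed UTF-8.
#'
#' @param path Path to the file.
#' @param schema A [label_schema()]; every label in the file must belong to
#'   it.
#' @return A tibble with columns `sentence_id` (integer, 1-based, in file
#'   order), `token` and `label` — the corpus representation used throughout
#'   the package.
#' @seealso [write_tagged_tsv()]
#' @export
read_tagged_tsv <- function(path, schema) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  blank <- !nzchar(lines)
  keep <- which(!blank)
  if (length(keep) == 0) {
    return(tibble::tibble(sentence_id = integer(), token = character(),
                          label = character()))
  }
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 2)) {
    bad <- keep[which(nf != 2)[1]]
    abort(sprintf("Malformed line %d in %s: expected 2 TAB-separated fields, found %d.",
                  bad, path, nf[which(nf != 2)[1]]))
  }
  token <- vapply(parts, `[[`, character(1), 1)
  label <- vapply(parts, `[[`, character(1), 2)
  # sentence id = 1 + number of blank lines seen before each kept line
  sid <- cumsum(blank)[keep]
  sid <- match(sid, unique(sid))  # collapse runs of blank lines
  bad <- setdiff(unique(label), schema$labels)
  if (length(bad) > 0)
    abort(sprintf("Label(s) not in schema: %s",
                  paste0('"', bad, '"', collapse = ", ")))
  tibble::tibble(sentence_id = as.integer(sid), token = token, label = label)
}

#' Write a tagged corpus to token-per-line TSV
#'
#' Inverse of [read_tagged_tsv()]: `token TAB label` per line, a blank line
#' between sentences, a final newline. Tokens and labels may not contain TAB
#' or newline characters.
#'
#' @param corpus A corpus tibble (`sentence_id`, `token`, `label`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tagged_tsv <- function(corpus, path) {
  check_corpus(corpus, labeled = TRUE)
  bad <- grepl("[\t\n]", corpus$token) | grepl("[\t\n]", corpus$label)
  if (any(bad))
    abort("Tokens and labels may not contain TAB or newline characters.")
  if (nrow(corpus) == 0) {
    writeLines(character(), path, useBytes = TRUE)
    return(invisible(path))
  }
  sents <- split(paste0(corpus$token, "\t", corpus$label), corpus$sentence_id)
  body <- paste(vapply(sents, paste, character(1), collapse = "\n"),
                collapse = "\n\n")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(enc2utf8(body), con, useBytes = TRUE)
  invisible(path)
}

#' Read word vectors in word2vec text format
#'
#' The format is a header line `"vocab_count dim"` followed by one
#' whitespace-separated `word v1 ... vd` line per word.
#'
#' @param path Path to the vector file.
#' @return An [embedding_model] with the input vectors populated from the
#'   file and zero output vectors. If the vocabulary contains `"<unk>"`, its
#'   vector becomes the unknown-word vector; otherwise the unknown vector is
#'   zero.
#' @seealso [write_vectors()], [train_skipgram()]
#' @export
read_vectors <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 1) abort("Vector file is empty.")
  hdr <- scan(text = lines[1], what = integer(), quiet = TRUE)
  if (length(hdr) != 2)
    abort("Vector file header must be \"vocab_count dim\".")
  n <- hdr[1]; d <- hdr[2]
  if (length(lines) - 1 != n)
    abort(sprintf("Header promises %d words but file has %d rows.",
                  n, length(lines) - 1))
  parts <- strsplit(lines[-1], "[ \t]+")
  nf <- lengths(parts)
  if (any(nf != d + 1))
    abort(sprintf("Row %d has %d values, expected dim %d.",
                  which(nf != d + 1)[1], nf[which(nf != d + 1)[1]] - 1, d))
  vocab <- vapply(parts, `[[`, character(1), 1)
  vals <- vapply(parts, function(p) as.numeric(p[-1]), numeric(d))
  input <- if (d == 1) matrix(vals, ncol = 1) else t(vals)
  if (anyNA(input)) abort("Vector file contains non-numeric values.")
  rownames(input) <- vocab
  new_embedding_model(vocab, input, matrix(0, n, d))
}

#' Write word vectors in word2vec text format
#'
#' Writes the input vectors of an embedding model with a `"vocab_count dim"`
#' header, one word per line, values serialized with 6 significant digits.
#'
#' @param model An [embedding_model].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_vectors <- function(model, path) {
  stopifnot(inherits(model, "embedding_model"))
  vals <- apply(model$input, 1, function(v)
    paste(formatC(signif(v, 6), format = "g", digits = 6), collapse = " "))
  out <- c(paste(length(model$vocab), model$dim),
           paste(model$vocab, vals))
  writeLines(enc2utf8(out), path, useBytes = TRUE)
  invisible(path)
}

#' Convert plain per-token labels to a BIO view
#'
#' The package tags each token with a plain class (the clinical handover
#' form headings do not use span markup), but some downstream consumers
#' expect BIO encoding. Maximal runs of the same non-NA label become
#' `B-label, I-label, ...`; the NA class maps to `"O"`.
#'
#' @param corpus A labeled corpus tibble.
#' @param schema The [label_schema()] (identifies the NA class).
#' @return The corpus with `label` rewritten in BIO form.
#' @export
as_bio_labels <- function(corpus, schema) {
  check_corpus(corpus, schema)
  corpus |>
    dplyr::group_by(.data$sentence_id) |>
    dplyr::mutate(label = {
      lab <- .data$label
      run_start <- lab != dplyr::lag(lab, default = "\r")
      dplyr::if_else(lab == schema$na_label, "O",
                     paste0(dplyr::if_else(run_start, "B-", "I-"), lab))
    }) |>
    dplyr::ungroup()
}

# split a corpus tibble into a list of list(tokens=chr, labels=chr|NULL)
corpus_sentences <- function(corpus, labeled = TRUE) {
  ids <- unique(corpus$sentence_id)
  toks <- split(corpus$token, factor(corpus$sentence_id, levels = ids))
  if (labeled && "label" %in% names(corpus)) {
    labs <- split(corpus$label, factor(corpus$sentence_id, levels = ids))
    purrr::map2(toks, labs, \(t, l) list(tokens = t, labels = l))
  } else {
    purrr::map(toks, \(t) list(tokens = t, labels = NULL))
  }
}

# rebuild a corpus tibble from sentence token/label lists
sentences_corpus <- function(tokens, labels) {
  tibble::tibble(
    sentence_id = rep(seq_along(tokens), lengths(tokens)),
    token = unlist(tokens, use.names = FALSE),
    label = unlist(labels, use.names = FALSE)
  )
}
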