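#' Define a label schema
#'
#' A label schema is the ordered set of token classes a tagger can assign,
#' together with the designated "not applicable" (NA) class used for tokens
#' that carry no form-relevant information. The NA class is typically by far
#' the most frequent one in clinical handover text, which is why it is
#' excluded from macro averaging and zeroed at transfer initialization.
#'
#' Labels are plain per-token classes, not BIO-encoded; see
#' [as_bio_labels()] for an optional BIO view.
#'
#' @param labels Character vector of unique, non-empty label names. The order
#'   fixes the label indexing used by model weight matrices.
#' @param na_label The name of the not-applicable class; must be one of
#'   `labels`. Defaults to `"NA"`.
#' @return An object of class `label_schema`: a list with elements `labels`
#'   and `na_label`.
#' @examples
#' label_schema(c("PERSON", "DATE", "ID", "NA"))
#' @export
label_schema <- function(labels, na_label = "NA") {
  labels <- as.character(labels)
  if (length(labels) == 0) abort("`labels` must be non-empty.")
  if (anyDuplicated(labels)) abort("`labels` must be unique.")
  if (any(!nzchar(labels)) || anyNA(labels))
    abort("`labels` must be non-empty strings.")
  if (length(na_label) != 1 || !na_label %in% labels)
    abort(sprintf("`na_label` (\"%s\") must be a member of `labels`.", na_label))
  structure(list(labels = labels, na_label = na_label),
            class = "label_schema")
}

#' @export
print.label_schema <- function(x, ...) {
  cat("<label_schema> ", length(x$labels), " labels (NA class: \"",
      x$na_label, "\")\n", sep = "")
  cat(" ", paste(x$labels, collapse = ", "), "\n")
  invisible(x)
}

#' @export
length.label_schema <- function(x) length(x$labels)

# integer label ids (1-based, schema order); errors on unknown labels
label_ids <- function(schema, labels) {
  ids <- match(labels, schema$labels)
  if (anyNA(ids)) {
    bad <- unique(labels[is.na(ids)])
    abort(sprintf("Unknown label(s) not in schema: %s",
                  paste0('"', bad, '"', collapse = ", ")))
  }
  ids
}

# validate a corpus tibble: sentence_id/token (+ label against schema)
check_corpus <- function(x, schema = NULL, labeled = TRUE,
                         arg = deparse(substitute(x))) {
  need <- c("sentence_id", "token", if (labeled) "label")
  if (!is.data.frame(x) || !all(need %in% names(x)))
    abort(sprintf("`%s` must be a data frame with columns %s.", arg,
                  paste0("`", need, "`", collapse = ", ")))
  if (labeled && !is.null(schema)) label_ids(schema, x$label)
  invisible(x)
}
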