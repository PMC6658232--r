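#' Specification for a correlated source/target synthetic task
#'
#' Emulates the structure of the clinical transfer setting without any
#' restricted data: a *source* domain tagged with coarse entity labels
#' (PERSON, DATE, ID, HOSPITAL plus the irrelevant class O) and a *target*
#' domain whose labels refine the source labels through a known refinement
#' map (e.g. PERSON splits into Given_names and Last_name), plus a dominant
#' NA class. Each target label owns a sub-lexicon of its source label's
#' lexicon, so the true source label is informative about — but does not
#' determine — the target label; that is exactly the structure the
#' label-correlation bridge is designed to exploit.
#'
#' Lexicons are synthetic word stems rather than realistic names: the tests
#' need separability control, not realism.
#'
#' @param refinement Named list mapping each source label to the character
#'   vector of target labels refining it. Every target label must appear
#'   exactly once. The source NA class must map to the target NA class.
#' @param source_na,target_na Names of the irrelevant-content classes.
#' @param lexicon_size Words per target-label sub-lexicon.
#' @param na_lexicon_size Words in the NA lexicon.
#' @param n_sentences Named list of sentences per split (`source_train`,
#'   `source_dev`, `target_train`, `target_dev`, `target_test`).
#' @param na_fraction Probability a slot is irrelevant (the NA class is
#'   deliberately dominant, as in real handover text).
#' @param noise_rate Probability a token is emitted from the lexicon of a
#'   different (uniformly chosen) label.
#' @param vocab_overlap Fraction of each sub-lexicon shared between the two
#'   domains; the remainder is domain-specific vocabulary.
#' @param sentence_length Integer vector of admissible sentence lengths
#'   (drawn uniformly).
#' @param seed RNG seed; generation is a pure function of spec + seed.
#' @return A `synthetic_spec` with derived `source_schema` and
#'   `target_schema`.
#' @export
synthetic_spec <- function(
    refinement = list(
      PERSON = c("Given_names", "Last_name"),
      DATE = c("Day", "Time"),
      ID = c("Current_room", "Current_bed"),
      HOSPITAL = "Hospital",
      O = "NA"),
    source_na = "O", target_na = "NA",
    lexicon_size = 12, na_lexicon_size = 40,
    n_sentences = list(source_train = 500, source_dev = 50,
                       target_train = 10, target_dev = 50,
                       target_test = 200),
    na_fraction = 0.6, noise_rate = 0.05, vocab_overlap = 0.8,
    sentence_length = 5:12, seed = 1L) {
  targets <- unlist(refinement, use.names = FALSE)
  if (anyDuplicated(targets))
    abort("Every target label must appear exactly once in `refinement`.")
  if (!source_na %in% names(refinement) ||
      !identical(refinement[[source_na]], target_na))
    abort("The source NA class must map to exactly the target NA class.")
  stopifnot(na_fraction >= 0, na_fraction <= 1, noise_rate >= 0,
            noise_rate <= 1, vocab_overlap >= 0, vocab_overlap <= 1,
            lexicon_size >= 2, na_lexicon_size >= 2)
  structure(list(refinement = refinement,
                 source_schema = label_schema(names(refinement), source_na),
                 target_schema = label_schema(targets, target_na),
                 lexicon_size = as.integer(lexicon_size),
                 na_lexicon_size = as.integer(na_lexicon_size),
                 n_sentences = n_sentences, na_fraction = na_fraction,
                 noise_rate = noise_rate, vocab_overlap = vocab_overlap,
                 sentence_length = as.integer(sentence_length),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# domain-specific lexicons: one per target label (entity sub-lexicons) and
# one NA lexicon; `vocab_overlap` of each is shared between domains
build_lexicons <- function(spec) {
  mk <- function(stem, n) sprintf("%s_%02d", stem, seq_len(n))
  split2 <- function(words) {
    n_shared <- round(spec$vocab_overlap * length(words))
    own <- if (n_shared < length(words)) words[-seq_len(max(n_shared, 0))]
           else character()
    list(source = c(head(words, n_shared), paste0(own, ".s")),
         target = c(head(words, n_shared), paste0(own, ".t")))
  }
  ent <- setdiff(spec$target_schema$labels, spec$target_schema$na_label)
  sub <- lapply(setNames(ent, ent),
                function(t) split2(mk(tolower(t), spec$lexicon_size)))
  na <- split2(mk("na", spec$na_lexicon_size))
  list(sub = sub, na = na)
}

# draw one tagged sentence for a domain ("source"/"target")
draw_sentence <- function(spec, lex, domain) {
  L <- sample(spec$sentence_length, 1)
  na_lab <- if (domain == "source") spec$source_schema$na_label
            else spec$target_schema$na_label
  ent <- setdiff(
    if (domain == "source") spec$source_schema$labels
    else spec$target_schema$labels, na_lab)
  labels <- ifelse(runif(L) < spec$na_fraction, na_lab,
                   sample(ent, L, replace = TRUE))
  lex_of <- function(lab) {
    if (lab == na_lab) return(lex$na[[domain]])
    if (domain == "target") return(lex$sub[[lab]][[domain]])
    unlist(lapply(setdiff(spec$refinement[[lab]], spec$target_schema$na_label),
                  function(t) lex$sub[[t]][[domain]]), use.names = FALSE)
  }
  tokens <- vapply(labels, function(lab) {
    src <- if (runif(1) < spec$noise_rate)
      sample(setdiff(c(ent, na_lab), lab), 1) else lab
    sample(lex_of(src), 1)
  }, character(1), USE.NAMES = FALSE)
  list(tokens = tokens, labels = unname(labels))
}

#' Generate correlated source/target tagged corpora
#'
#' Draws the five splits of the synthetic transfer task described in
#' [synthetic_spec()]. Each sentence is a sequence of independent slots:
#' with probability `na_fraction` a slot is irrelevant (NA class, token
#' from the NA lexicon), otherwise it carries a uniformly chosen entity
#' label and a token from that label's lexicon, corrupted with probability
#' `noise_rate`. Target tokens for a refined label come from the refinement's
#' sub-lexicon, so source-domain knowledge is informative for the target
#' task by construction.
#'
#' @param spec A [synthetic_spec()].
#' @return Named list with corpus tibbles `source_train`, `source_dev`,
#'   `target_train`, `target_dev`, `target_test` and the two schemas. The
#'   output is byte-identical for identical spec (including its seed).
#' @export
generate_tagged_corpora <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    lex <- build_lexicons(spec)
    draw_split <- function(n, domain) {
      sents <- lapply(seq_len(n), function(i) draw_sentence(spec, lex, domain))
      sentences_corpus(lapply(sents, `[[`, "tokens"),
                       lapply(sents, `[[`, "labels"))
    }
    list(source_train = draw_split(spec$n_sentences$source_train, "source"),
         source_dev = draw_split(spec$n_sentences$source_dev, "source"),
         target_train = draw_split(spec$n_sentences$target_train, "target"),
         target_dev = draw_split(spec$n_sentences$target_dev, "target"),
         target_test = draw_split(spec$n_sentences$target_test, "target"),
         source_schema = spec$source_schema,
         target_schema = spec$target_schema)
  })
}

#' Generate a topic-structured plain-text corpus
#'
#' Builds an unlabeled corpus for embedding tests: each sentence is drawn
#' from one topic's vocabulary, mixed with shared function words. Words of
#' the same topic therefore co-occur and should end up closer in embedding
#' space than words of different topics.
#'
#' @param n_sentences Number of sentences.
#' @param topics List of character vectors (one word group per topic); at
#'   least 2. By default two topics of 15 synthetic words each.
#' @param shared Character vector of function words shared across topics.
#' @param sentence_length Tokens per sentence.
#' @param shared_fraction Probability a token is a shared function word.
#' @param seed RNG seed.
#' @return A [text_corpus()] with extra fields `topics`, `shared` and
#'   `topic_of` (the topic index of each sentence).
#' @export
generate_text_corpus <- function(n_sentences,
                                 topics = lapply(1:2, function(i)
                                   sprintf("top%d_w%02d", i, 1:15)),
                                 shared = sprintf("fn%02d", 1:10),
                                 sentence_length = 8,
                                 shared_fraction = 0.3, seed = 1L) {
  if (length(topics) < 2) abort("Need at least 2 topics.")
  with_seed(seed, {
    topic_of <- sample(length(topics), n_sentences, replace = TRUE)
    sentences <- lapply(topic_of, function(ti) {
      use_shared <- runif(sentence_length) < shared_fraction
      ifelse(use_shared,
             sample(shared, sentence_length, replace = TRUE),
             sample(topics[[ti]], sentence_length, replace = TRUE))
    })
    corpus <- text_corpus(sentences)
    corpus$topics <- topics
    corpus$shared <- shared
    corpus$topic_of <- topic_of
    corpus
  })
}
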