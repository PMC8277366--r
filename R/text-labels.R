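#' Label vocabulary
#'
#' A fixed, ordered vocabulary of DDI descriptor labels. Label sets of rich
#' DDI triples are subsets of this vocabulary and are binarized against it.
#'
#' @param labels Character vector of distinct labels (order is kept).
#' @return A `label_vocabulary` object.
#' @export
label_vocabulary <- function(labels) {
  labels <- as.character(labels)
  if (anyDuplicated(labels)) {
    abort_typed("vocabulary labels must be distinct", "prddi_vocabulary_error")
  }
  structure(labels, class = "label_vocabulary")
}

#' @export
print.label_vocabulary <- function(x, ...) {
  cat("<label_vocabulary> ", length(x), " labels: ",
      paste(utils::head(unclass(x), 5), collapse = ", "),
      if (length(x) > 5) ", ..." else "", "\n", sep = "")
  invisible(x)
}

vocab_labels <- function(vocabulary) {
  as.character(unclass(vocabulary))
}

#' Read / write a label vocabulary (one label per line)
#' @param path File path.
#' @return `read_label_vocabulary()` returns a [label_vocabulary()];
#'   `write_label_vocabulary()` returns the path invisibly.
#' @export
read_label_vocabulary <- function(path) {
  label_vocabulary(readLines(path, encoding = "UTF-8"))
}

#' @rdname read_label_vocabulary
#' @param vocabulary A vocabulary (or plain character vector).
#' @export
write_label_vocabulary <- function(vocabulary, path) {
  writeLines(vocab_labels(vocabulary), path)
  invisible(path)
}

#' A small built-in English stop-word list
#'
#' Used by default when tokenizing DDI sentences; override with any
#' character vector.
#'
#' @return Character vector of stop words.
#' @export
default_stopwords <- function() {
  c("a", "an", "and", "are", "as", "at", "be", "been", "both", "but", "by",
    "can", "could", "do", "does", "for", "from", "has", "have", "if", "in",
    "into", "is", "it", "its", "may", "might", "more", "most", "not", "of",
    "on", "or", "other", "should", "such", "than", "that", "the", "their",
    "there", "these", "they", "this", "to", "use", "used", "using", "was",
    "were", "when", "which", "while", "will", "with", "would")
}

#' Tokenize a DDI sentence
#'
#' Lowercases, strips punctuation, splits on whitespace and removes stop
#' words; token order is preserved.
#'
#' @param text Raw sentence.
#' @param stopwords Character vector of stop words to drop.
#' @return Character vector of tokens (possibly empty).
#' @export
#' @examples
#' preprocess_text("Etanercept may enhance the toxicity", c("may", "the"))
preprocess_text <- function(text, stopwords = default_stopwords()) {
  if (length(text) == 0 || is.na(text) || !nzchar(text)) return(character())
  x <- tolower(text)
  x <- gsub("[^[:alnum:][:space:]_-]", " ", x)
  tokens <- strsplit(trimws(x), "\\s+")[[1]]
  tokens <- tokens[nzchar(tokens)]
  tokens[!(tokens %in% stopwords)]
}

#' Read / write a DDI sentence corpus
#'
#' TSV dialect: `doc_id<TAB>drug_u<TAB>drug_v<TAB>sentence`.
#'
#' @param path File path.
#' @param stopwords Stop words passed to [preprocess_text()].
#' @return A tibble with columns `doc_id`, `drug_u`, `drug_v`, `sentence`
#'   and list-column `tokens`.
#' @export
read_ddi_corpus <- function(path, stopwords = default_stopwords()) {
  raw <- readr::read_tsv(
    path,
    col_names = c("doc_id", "drug_u", "drug_v", "sentence"),
    col_types = "cccc", progress = FALSE
  )
  if (anyDuplicated(raw$doc_id)) {
    abort_typed("doc_id must be unique within a corpus", "prddi_parse_error")
  }
  raw$tokens <- lapply(raw$sentence, preprocess_text, stopwords = stopwords)
  raw
}

#' @rdname read_ddi_corpus
#' @param corpus Corpus tibble with `doc_id`, `drug_u`, `drug_v`, `sentence`.
#' @export
write_ddi_corpus <- function(corpus, path) {
  writeLines(paste(corpus$doc_id, corpus$drug_u, corpus$drug_v,
                   corpus$sentence, sep = "\t"), path)
  invisible(path)
}

#' TF-IDF scores of corpus tokens
#'
#' Natural term frequency (token count divided by document length) times
#' unsmoothed inverse document frequency `ln(N / df)`. A token occurring in
#' every document therefore scores zero everywhere.
#'
#' @param corpus Tibble with `doc_id` and list-column `tokens` (as from
#'   [read_ddi_corpus()]).
#' @return A tibble with columns `doc_id`, `token`, `tf`, `idf`, `score`.
#' @export
tf_idf_scores <- function(corpus) {
  if (nrow(corpus) == 0) {
    abort_typed("corpus must be non-empty", "prddi_domain_error")
  }
  n_docs <- nrow(corpus)
  doc_len <- lengths(corpus$tokens)
  long <- tibble::tibble(
    doc_id = rep(corpus$doc_id, doc_len),
    token = unlist(corpus$tokens, use.names = FALSE)
  )
  if (nrow(long) == 0) {
    return(tibble::tibble(doc_id = character(), token = character(),
                          tf = double(), idf = double(), score = double()))
  }
  counts <- long |>
    dplyr::count(.data$doc_id, .data$token, name = "n") |>
    dplyr::left_join(
      tibble::tibble(doc_id = corpus$doc_id, doc_len = doc_len),
      by = "doc_id"
    )
  df <- counts |> dplyr::count(.data$token, name = "df")
  counts |>
    dplyr::left_join(df, by = "token") |>
    dplyr::mutate(
      tf = .data$n / .data$doc_len,
      idf = log(n_docs / .data$df),
      score = .data$tf * .data$idf
    ) |>
    dplyr::select("doc_id", "token", "tf", "idf", "score")
}

#' Select the top-n labels of one document
#'
#' Tokens are ranked by score, descending; ties are broken by lexicographic
#' token order so the selection is deterministic. Tokens with zero or
#' negative score are never selected.
#'
#' @param doc_scores Tibble with columns `token` and `score` (one document),
#'   or a named numeric vector of scores.
#' @param n Number of labels to keep (default 5).
#' @return Character vector of at most `n` labels, best first.
#' @export
select_top_labels <- function(doc_scores, n = 5) {
  if (!is.numeric(n) || length(n) != 1 || n < 1) {
    abort_typed("n must be a positive integer", "prddi_domain_error")
  }
  if (is.numeric(doc_scores)) {
    doc_scores <- tibble::tibble(token = names(doc_scores),
                                 score = as.numeric(doc_scores))
  }
  pos <- doc_scores[doc_scores$score > 0, ]
  ord <- order(-pos$score, pos$token)
  utils::head(pos$token[ord], n)
}

#' Binarize a label set against a vocabulary
#'
#' @param labels Character vector of labels, all present in `vocabulary`.
#' @param vocabulary A [label_vocabulary()] (or character vector).
#' @return Integer 0/1 vector of length `length(vocabulary)` with ones at
#'   the positions of `labels`.
#' @export
#' @examples
#' vectorize_labels(c("y"), label_vocabulary(c("x", "y", "z")))
vectorize_labels <- function(labels, vocabulary) {
  vocab <- vocab_labels(vocabulary)
  missing <- setdiff(labels, vocab)
  if (length(missing) > 0) {
    abort_typed(paste0("label(s) not in vocabulary: ",
                       paste(missing, collapse = ", ")),
                "prddi_vocabulary_error")
  }
  as.integer(vocab %in% labels)
}

#' Recover the label set encoded by a binary vector
#' @param s 0/1 vector over the vocabulary.
#' @param vocabulary A [label_vocabulary()] (or character vector).
#' @return Character vector of labels at the nonzero positions.
#' @export
unvectorize_labels <- function(s, vocabulary) {
  vocab <- vocab_labels(vocabulary)
  if (length(s) != length(vocab)) {
    abort_typed("binary vector length must match vocabulary size",
                "prddi_shape_error")
  }
  vocab[s != 0]
}

#' Read a drug alias table
#'
#' TSV dialect: `alias<TAB>canonical_id`. Lookup is case-insensitive.
#'
#' @param path File path.
#' @return A tibble with columns `alias`, `canonical_id`.
#' @export
read_alias_table <- function(path) {
  readr::read_tsv(path, col_names = c("alias", "canonical_id"),
                  col_types = "cc", progress = FALSE)
}

#' Normalize a raw drug name to its canonical entity id
#'
#' Case-insensitive lookup in an alias table. A name that already equals a
#' canonical id maps to itself. Unknown names return `NA_character_` (a
#' no-match value, not an error).
#'
#' @param name Raw drug name(s).
#' @param aliases Alias tibble (`alias`, `canonical_id`) or `NULL`.
#' @return Character vector of canonical ids (or `NA` where unmatched).
#' @export
normalize_drug <- function(name, aliases = NULL) {
  if (is.null(aliases) || nrow(aliases) == 0) return(as.character(name))
  key <- tolower(name)
  hit <- match(key, tolower(aliases$alias))
  out <- aliases$canonical_id[hit]
  canon <- match(key, tolower(aliases$canonical_id))
  out[is.na(hit) & !is.na(canon)] <- aliases$canonical_id[canon[is.na(hit) & !is.na(canon)]]
  out
}

#' Extract rich DDI triples from a sentence corpus
#'
#' Runs the TF-IDF pipeline over the tokenized corpus, selects the top-n
#' labels per document (drug mentions themselves are excluded from a
#' document's candidate labels), normalizes drug names through the alias
#' table, and builds the label vocabulary from all selected labels.
#'
#' @param corpus Corpus tibble from [read_ddi_corpus()].
#' @param n Labels per DDI sentence (default 5).
#' @param aliases Optional alias tibble for drug-name normalization.
#' @param vocabulary Optional fixed [label_vocabulary()]; when given,
#'   selected labels outside it are dropped, and documents whose labels all
#'   fall outside it are skipped. When `NULL` the vocabulary is built from
#'   the selection.
#' @return List with `ddi` (tibble `drug_u`, `drug_v`, list-column
#'   `labels`) and `vocabulary`.
#' @export
extract_ddi_triples <- function(corpus, n = 5, aliases = NULL,
                                vocabulary = NULL) {
  scores <- tf_idf_scores(corpus)
  drug_u <- normalize_drug(corpus$drug_u, aliases)
  drug_v <- normalize_drug(corpus$drug_v, aliases)
  drug_u <- ifelse(is.na(drug_u), corpus$drug_u, drug_u)
  drug_v <- ifelse(is.na(drug_v), corpus$drug_v, drug_v)
  mention_by_doc <- Map(
    function(ru, rv, nu, nv) tolower(c(ru, rv, nu, nv)),
    corpus$drug_u, corpus$drug_v, drug_u, drug_v
  )
  names(mention_by_doc) <- corpus$doc_id
  by_doc <- split(scores, scores$doc_id)
  labels <- lapply(seq_len(nrow(corpus)), function(i) {
    sc <- by_doc[[corpus$doc_id[i]]]
    if (is.null(sc)) return(character())
    sc <- sc[!(tolower(sc$token) %in% mention_by_doc[[corpus$doc_id[i]]]), ]
    select_top_labels(sc, n = n)
  })
  if (!is.null(vocabulary)) {
    vocab <- vocab_labels(vocabulary)
    labels <- lapply(labels, intersect, y = vocab)
  } else {
    vocab <- sort(unique(unlist(labels)))
  }
  keep <- lengths(labels) > 0 & drug_u != drug_v
  list(
    ddi = tibble::tibble(drug_u = drug_u[keep], drug_v = drug_v[keep],
                         labels = labels[keep]),
    vocabulary = label_vocabulary(vocab)
  )
}
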