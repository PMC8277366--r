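#' Default relation schema for basic triples
#'
#' The basic-triple layer of the drug knowledge graph uses five biological
#' relation types over four entity kinds (drug, protein, pathway, phenotype).
#' Each relation fixes the kind of its head and tail entity, which is how
#' entity kinds are inferred from a flat triple file.
#'
#' @return A tibble with columns `relation`, `head_kind`, `tail_kind`.
#' @export
#' @examples
#' default_relation_schema()
default_relation_schema <- function() {
  tibble::tribble(
    ~relation,          ~head_kind, ~tail_kind,
    "hasTarget",        "drug",     "protein",
    "hasEnzyme",        "drug",     "protein",
    "hasTransporter",   "drug",     "protein",
    "isPresentIn",      "protein",  "pathway",
    "isImplicatedIn",   "pathway",  "phenotype"
  )
}

entity_kinds <- c("drug", "protein", "pathway", "phenotype")

abort_typed <- function(message, class) {
  rlang::abort(message, class = c(class, "prddi_error"))
}

#' Read basic triples from a tab-separated file
#'
#' One triple per line as `head<TAB>relation<TAB>tail`, UTF-8. Blank lines
#' and lines starting with `#` are ignored. Every relation must appear in
#' the schema.
#'
#' @param path Path to the triple file.
#' @param schema Relation schema, as from [default_relation_schema()].
#' @return A tibble with columns `head`, `relation`, `tail`.
#' @export
read_basic_triples <- function(path, schema = default_relation_schema()) {
  if (!file.exists(path)) {
    abort_typed(paste0("triple file not found: ", path), "prddi_parse_error")
  }
  lines <- readLines(path, encoding = "UTF-8")
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0) {
    return(tibble::tibble(head = character(), relation = character(),
                          tail = character()))
  }
  parts <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 3)) {
    bad <- idx[which(nf != 3)[1]]
    abort_typed(
      paste0("malformed triple at line ", bad, ": expected 3 tab-separated ",
             "fields, got ", nf[which(nf != 3)[1]]),
      "prddi_parse_error"
    )
  }
  out <- tibble::tibble(
    head = vapply(parts, `[[`, character(1), 1),
    relation = vapply(parts, `[[`, character(1), 2),
    tail = vapply(parts, `[[`, character(1), 3)
  )
  unknown <- setdiff(unique(out$relation), schema$relation)
  if (length(unknown) > 0) {
    abort_typed(
      paste0("relation(s) not in schema: ", paste(unknown, collapse = ", ")),
      "prddi_schema_error"
    )
  }
  out
}

#' Infer entity kinds from basic triples
#'
#' Entity kinds are determined by the positions entities occupy under the
#' relation schema (e.g. the tail of `hasTarget` is a protein). An entity
#' appearing in positions that imply different kinds is an error.
#'
#' @param basic Tibble of basic triples (`head`, `relation`, `tail`).
#' @param schema Relation schema.
#' @return A tibble with columns `id`, `kind`.
#' @export
infer_entities <- function(basic, schema = default_relation_schema()) {
  joined <- dplyr::left_join(basic, schema, by = "relation")
  long <- dplyr::bind_rows(
    tibble::tibble(id = joined$head, kind = joined$head_kind),
    tibble::tibble(id = joined$tail, kind = joined$tail_kind)
  )
  ents <- dplyr::distinct(long)
  dup <- ents$id[duplicated(ents$id)]
  if (length(dup) > 0) {
    abort_typed(
      paste0("entities with conflicting kinds: ",
             paste(unique(dup), collapse = ", ")),
      "prddi_schema_error"
    )
  }
  dplyr::arrange(ents, .data$id)
}

#' Read rich DDI triples from a tab-separated file
#'
#' One record per line as `drug_u<TAB>label1|label2|...<TAB>drug_v`. Labels
#' are `|`-separated. Blank lines and `#` comments are ignored.
#'
#' @param path Path to the DDI file.
#' @return A tibble with columns `drug_u`, `drug_v` and list-column `labels`.
#' @export
read_ddi_triples <- function(path) {
  if (!file.exists(path)) {
    abort_typed(paste0("DDI file not found: ", path), "prddi_parse_error")
  }
  lines <- readLines(path, encoding = "UTF-8")
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0) {
    return(tibble::tibble(drug_u = character(), drug_v = character(),
                          labels = list()))
  }
  parts <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 3)) {
    bad <- idx[which(nf != 3)[1]]
    abort_typed(paste0("malformed DDI record at line ", bad),
                "prddi_parse_error")
  }
  tibble::tibble(
    drug_u = vapply(parts, `[[`, character(1), 1),
    drug_v = vapply(parts, `[[`, character(1), 3),
    labels = lapply(parts, function(p) strsplit(p[[2]], "|", fixed = TRUE)[[1]])
  )
}

#' Write basic or DDI triples to their TSV dialects
#'
#' @param basic Tibble of basic triples.
#' @param ddi Tibble of DDI triples with list-column `labels`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_basic_triples <- function(basic, path) {
  writeLines(paste(basic$head, basic$relation, basic$tail, sep = "\t"), path)
  invisible(path)
}

#' @rdname write_basic_triples
#' @export
write_ddi_triples <- function(ddi, path) {
  lab <- vapply(ddi$labels, paste, character(1), collapse = "|")
  writeLines(paste(ddi$drug_u, lab, ddi$drug_v, sep = "\t"), path)
  invisible(path)
}

canonical_pair <- function(u, v) {
  ifelse(u <= v, paste(u, v, sep = "\r"), paste(v, u, sep = "\r"))
}

#' Build a validated drug knowledge graph
#'
#' Assembles entities, basic triples and rich DDI triples into a `drug_kg`
#' object. DDI relations between two drugs are bidirectional, so every
#' (possibly undirected) input DDI record is expanded into two directed
#' triples of opposing directions carrying the same label set. Records for
#' the same unordered pair are merged (label sets unioned) and duplicates
#' dropped. Referential integrity and label-vocabulary membership are
#' enforced.
#'
#' @param basic Tibble of basic triples (`head`, `relation`, `tail`).
#' @param ddi Tibble of DDI records (`drug_u`, `drug_v`, list-column
#'   `labels`); may be empty.
#' @param vocabulary Character vector of allowed labels (or a
#'   [label_vocabulary()] object).
#' @param schema Relation schema used to infer entity kinds.
#' @param extra_drugs Optional character vector of drug ids that appear in
#'   no triple but should exist as entities.
#' @return A `drug_kg` object: a list with tibbles `entities`, `basic`,
#'   `ddi` (directed, both ways) and the label `vocabulary`.
#' @export
build_kg <- function(basic, ddi = NULL, vocabulary = character(),
                     schema = default_relation_schema(),
                     extra_drugs = character()) {
  if (is.null(ddi)) {
    ddi <- tibble::tibble(drug_u = character(), drug_v = character(),
                          labels = list())
  }
  vocabulary <- vocab_labels(vocabulary)
  unknown_rel <- setdiff(unique(basic$relation), schema$relation)
  if (length(unknown_rel) > 0) {
    abort_typed(paste0("relation(s) not in schema: ",
                       paste(unknown_rel, collapse = ", ")),
                "prddi_schema_error")
  }
  basic <- dplyr::distinct(basic, .data$head, .data$relation, .data$tail)
  entities <- infer_entities(basic, schema)

  if (nrow(ddi) > 0) {
    if (any(ddi$drug_u == ddi$drug_v)) {
      abort_typed("self-interaction (drug_u == drug_v) is not allowed",
                  "prddi_validation_error")
    }
    if (any(lengths(ddi$labels) == 0)) {
      abort_typed("every DDI triple needs a non-empty label set",
                  "prddi_validation_error")
    }
    all_labels <- unique(unlist(ddi$labels))
    missing <- setdiff(all_labels, vocabulary)
    if (length(missing) > 0) {
      abort_typed(paste0("label(s) outside the vocabulary: ",
                         paste(missing, collapse = ", ")),
                  "prddi_vocabulary_error")
    }
    # merge records of the same unordered pair, then expand both directions
    ddi$._pair <- canonical_pair(ddi$drug_u, ddi$drug_v)
    merged <- ddi |>
      dplyr::group_by(.data$._pair) |>
      dplyr::summarise(
        drug_u = .data$drug_u[1], drug_v = .data$drug_v[1],
        labels = list(sort(unique(unlist(.data$labels)))),
        .groups = "drop"
      ) |>
      dplyr::select(-"._pair")
    ddi <- dplyr::bind_rows(
      merged,
      tibble::tibble(drug_u = merged$drug_v, drug_v = merged$drug_u,
                     labels = merged$labels)
    )
  } else {
    ddi <- tibble::tibble(drug_u = character(), drug_v = character(),
                          labels = list())
  }

  ddi_drugs <- unique(c(ddi$drug_u, ddi$drug_v, extra_drugs))
  new_drugs <- setdiff(ddi_drugs, entities$id)
  if (length(new_drugs) > 0) {
    entities <- dplyr::bind_rows(
      entities, tibble::tibble(id = sort(new_drugs), kind = "drug")
    ) |> dplyr::arrange(.data$id)
  }
  not_drug <- entities$kind[match(ddi_drugs, entities$id)] != "drug"
  if (any(not_drug)) {
    abort_typed(paste0("DDI participants are not drug entities: ",
                       paste(ddi_drugs[not_drug], collapse = ", ")),
                "prddi_validation_error")
  }

  kg <- structure(
    list(entities = entities, basic = basic, ddi = ddi,
         vocabulary = vocabulary),
    class = "drug_kg"
  )
  kg
}

#' @export
print.drug_kg <- function(x, ...) {
  kinds <- table(x$entities$kind)
  cat("<drug_kg>\n")
  cat("  entities:", nrow(x$entities),
      paste0("(", paste(names(kinds), kinds, sep = ": ", collapse = ", "), ")"),
      "\n")
  cat("  basic triples:", nrow(x$basic), "\n")
  cat("  DDI triples (directed):", nrow(x$ddi),
      paste0("(", nrow(ddi_pairs(x)), " pairs)"), "\n")
  cat("  label vocabulary:", length(x$vocabulary), "labels\n")
  invisible(x)
}

#' Undirected DDI pairs of a knowledge graph
#'
#' Collapses the direction-expanded DDI triples back to one row per
#' unordered drug pair (lexicographically smaller drug first).
#'
#' @param kg A `drug_kg` object.
#' @return A tibble with `drug_u`, `drug_v`, list-column `labels`.
#' @export
ddi_pairs <- function(kg) {
  ddi <- kg$ddi
  if (nrow(ddi) == 0) {
    return(tibble::tibble(drug_u = character(), drug_v = character(),
                          labels = list()))
  }
  keep <- ddi$drug_u < ddi$drug_v
  dplyr::arrange(ddi[keep, ], .data$drug_u, .data$drug_v)
}

#' Drug ids of a knowledge graph
#' @param kg A `drug_kg` object.
#' @return Character vector of drug entity ids.
#' @export
kg_drugs <- function(kg) {
  kg$entities$id[kg$entities$kind == "drug"]
}

#' Hold out DDI pairs for evaluation
#'
#' Removes a random fraction of the undirected DDI pairs (both directed
#' triples of each selected pair) from the graph to serve as test
#' positives, and samples an equal number of drug pairs with no DDI
#' anywhere in the full graph as test negatives. Self-pairs are never
#' sampled as negatives.
#'
#' @param kg A `drug_kg` object with at least one DDI pair when `rate > 0`.
#' @param rate Fraction of undirected DDI pairs to hold out, in `[0, 1]`.
#' @param seed Integer seed making the split reproducible.
#' @return A `ddi_split` object: list with `train_kg` (a `drug_kg`),
#'   `test_positives` (directed tibble, both directions of each held-out
#'   pair) and `test_negatives` (tibble of `drug_u`, `drug_v`).
#' @export
split_ddi <- function(kg, rate = 0.3, seed = 1L) {
  if (!is.numeric(rate) || length(rate) != 1 || rate < 0 || rate > 1) {
    abort_typed("rate must be a single number in [0, 1]", "prddi_domain_error")
  }
  pairs <- ddi_pairs(kg)
  if (rate > 0 && nrow(pairs) == 0) {
    abort_typed("cannot split a KG with no DDI pairs", "prddi_domain_error")
  }
  n_test <- round(rate * nrow(pairs))

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  test_idx <- if (n_test > 0) sample.int(nrow(pairs), n_test) else integer()
  test_pairs <- pairs[test_idx, ]

  test_key <- canonical_pair(test_pairs$drug_u, test_pairs$drug_v)
  ddi_key <- canonical_pair(kg$ddi$drug_u, kg$ddi$drug_v)
  train_ddi <- kg$ddi[!(ddi_key %in% test_key), ]
  test_positives <- kg$ddi[ddi_key %in% test_key, ]

  train_kg <- kg
  train_kg$ddi <- train_ddi

  drugs <- kg_drugs(kg)
  if (n_test > 0) {
    all_idx <- utils::combn(length(drugs), 2)
    cand_u <- drugs[all_idx[1, ]]
    cand_v <- drugs[all_idx[2, ]]
    cand_key <- canonical_pair(cand_u, cand_v)
    free <- !(cand_key %in% unique(ddi_key))
    if (sum(free) < n_test) {
      abort_typed("not enough non-DDI drug pairs to sample negatives",
                  "prddi_sampling_error")
    }
    pick <- sample(which(free), n_test)
    test_negatives <- tibble::tibble(drug_u = cand_u[pick],
                                     drug_v = cand_v[pick])
  } else {
    test_negatives <- tibble::tibble(drug_u = character(),
                                     drug_v = character())
  }

  structure(
    list(train_kg = train_kg, test_positives = test_positives,
         test_negatives = test_negatives, rate = rate, seed = seed),
    class = "ddi_split"
  )
}

#' @export
print.ddi_split <- function(x, ...) {
  cat("<ddi_split>\n")
  cat("  hold-out rate:", x$rate, "\n")
  cat("  train DDI triples (directed):", nrow(x$train_kg$ddi), "\n")
  cat("  test positive triples (directed):", nrow(x$test_positives), "\n")
  cat("  test negative pairs:", nrow(x$test_negatives), "\n")
  invisible(x)
}

# Save/restore the global RNG state so seeded helpers do not disturb the
# caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
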