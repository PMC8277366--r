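# Synthetic drug KGs with planted translational and label-cluster structure.
#
# Geometry: drugs live in a small number of tight communities placed at
# scaled coordinate vectors; every DDI cluster is an (ordered) pair of
# communities, so the latent difference vector of a DDI pair identifies its
# cluster, and each cluster owns a coherent block of the label vocabulary.
# Proteins, pathways and phenotypes hang off the drug communities through
# the latent relation vectors, so basic triples satisfy
# latent(tail) ~ latent(head) + latent(relation) + noise.

ddi_label_pool <- function() {
  c("bleeding", "toxicity", "bradycardia", "hypotension", "hypertension",
    "sedation", "nephrotoxicity", "hepatotoxicity", "serotonin",
    "arrhythmia", "anticoagulant", "antiplatelet", "thrombolytic",
    "immunosuppressant", "anemia", "infection", "myopathy", "rhabdomyolysis",
    "hyperkalemia", "hypoglycemia", "hyperglycemia", "neutropenia",
    "thrombocytopenia", "ototoxicity", "seizure", "dizziness", "drowsiness",
    "confusion", "tachycardia", "prolongation", "diminish", "enhance",
    "inhibitor", "inducer", "absorption", "clearance", "metabolism",
    "excretion", "agonist", "antagonist", "vasodilation", "constipation",
    "diarrhea", "nausea", "photosensitivity", "hyponatremia", "acidosis",
    "alkalosis", "edema", "rash", "pruritus", "insomnia", "agitation",
    "hallucination", "gastrointestinal", "respiratory", "depression",
    "withdrawal", "overdose", "potentiation")
}

#' Configuration of the synthetic drug-KG generator
#'
#' Defaults emulate a desk-scale version of a real drug KG: 200 entities
#' over four kinds, five biological relation types, 2000 basic triples,
#' 100 DDI pairs described by 5 labels each from a 50-label vocabulary
#' organized in 5 co-occurrence clusters, and latent translational noise
#' of 0.05.
#'
#' @param n_drugs,n_proteins,n_pathways,n_phenotypes Entity counts.
#' @param n_relations Number of basic relation types used (3 to 5, taken in
#'   schema order).
#' @param n_basic Number of distinct basic triples to sample.
#' @param n_ddi_pairs Number of undirected DDI pairs.
#' @param vocab_size Label vocabulary size.
#' @param n_clusters Number of label co-occurrence clusters.
#' @param labels_per_ddi Labels per DDI pair.
#' @param ddi_drug_fraction Fraction of drugs eligible to appear in DDI
#'   pairs (most drugs in real KGs have no recorded interaction sentence).
#' @param noise_sd Standard deviation of the latent translational noise
#'   (also the within-community scatter of entity latents).
#' @param latent_dim Dimension of the generating latent space.
#' @param within_cooccur Probability that two labels of the same cluster
#'   co-occur in a pair's label set; each core label is swapped for a
#'   random outside label with probability `1 - sqrt(within_cooccur)`.
#' @param seed RNG seed.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_drugs = 100, n_proteins = 80, n_pathways = 14,
                         n_phenotypes = 6, n_relations = 5, n_basic = 2000,
                         n_ddi_pairs = 100, vocab_size = 50, n_clusters = 5,
                         labels_per_ddi = 5, ddi_drug_fraction = 0.25,
                         noise_sd = 0.05, latent_dim = 20,
                         within_cooccur = 0.8, seed = 1L) {
  counts <- c(n_drugs, n_proteins, n_pathways, n_phenotypes, n_relations,
              n_basic, n_ddi_pairs, vocab_size, n_clusters, labels_per_ddi)
  if (any(counts < 1)) {
    abort_typed("all counts must be >= 1", "prddi_config_error")
  }
  if (noise_sd < 0) abort_typed("noise_sd must be >= 0", "prddi_config_error")
  if (ddi_drug_fraction <= 0 || ddi_drug_fraction > 1) {
    abort_typed("ddi_drug_fraction must lie in (0, 1]", "prddi_config_error")
  }
  if (within_cooccur <= 0 || within_cooccur > 1) {
    abort_typed("within_cooccur must lie in (0, 1]", "prddi_config_error")
  }
  if (n_relations < 3 || n_relations > 5) {
    abort_typed("n_relations must be between 3 and 5", "prddi_config_error")
  }
  if (vocab_size > length(ddi_label_pool())) {
    abort_typed(paste0("vocab_size must be <= ", length(ddi_label_pool())),
                "prddi_config_error")
  }
  pool <- floor(vocab_size / n_clusters)
  if (labels_per_ddi > pool) {
    abort_typed("labels_per_ddi exceeds the per-cluster label pool",
                "prddi_config_error")
  }
  # smallest m with choose(m, 2) >= n_clusters communities
  m <- 2
  while (choose(m, 2) < n_clusters) m <- m + 1
  m <- max(m, 4)
  if (latent_dim < m) {
    abort_typed("latent_dim too small for the community layout",
                "prddi_config_error")
  }
  structure(
    list(n_drugs = n_drugs, n_proteins = n_proteins, n_pathways = n_pathways,
         n_phenotypes = n_phenotypes, n_relations = n_relations,
         n_basic = n_basic, n_ddi_pairs = n_ddi_pairs,
         vocab_size = vocab_size, n_clusters = n_clusters,
         labels_per_ddi = labels_per_ddi,
         ddi_drug_fraction = ddi_drug_fraction, noise_sd = noise_sd,
         latent_dim = latent_dim, n_communities = m,
         within_cooccur = within_cooccur, seed = as.integer(seed)),
    class = "synth_config"
  )
}

#' Generate a synthetic drug knowledge graph with known ground truth
#'
#' Draws latent vectors for all entities and relations, samples basic
#' triples consistent with the latent translations (tail close to head plus
#' relation, up to Gaussian noise), assigns DDI pairs to label clusters via
#' ordered community pairs, and samples each pair's label set mostly from
#' its cluster's label block. The returned KG passes [build_kg()]
#' validation; everything is reproducible given `config$seed`.
#'
#' @param config A [synth_config()].
#' @return A list with `kg` (a `drug_kg`) and `truth` (a `prd_ground_truth`
#'   with latents, communities, clusters and the generated pairs).
#' @export
generate_kg <- function(config = synth_config()) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)

  dim <- config$latent_dim
  m <- config$n_communities
  schema <- utils::head(default_relation_schema(), config$n_relations)
  rels_dp <- intersect(c("hasTarget", "hasEnzyme", "hasTransporter"),
                       schema$relation)

  # community centers: scaled coordinate vectors -> distinct differences
  centers <- diag(1.2, m, dim)
  g_rel <- matrix(stats::rnorm(nrow(schema) * dim, 0, 0.4), nrow(schema), dim,
                  dimnames = list(schema$relation, NULL))

  drug_ids <- sprintf("drug%03d", seq_len(config$n_drugs))
  drug_comm <- rep_len(seq_len(m), config$n_drugs)
  noise <- function(n) matrix(stats::rnorm(n * dim, 0, config$noise_sd), n, dim)
  drug_lat <- centers[drug_comm, , drop = FALSE] + noise(config$n_drugs)
  rownames(drug_lat) <- drug_ids

  prot_ids <- sprintf("prot%03d", seq_len(config$n_proteins))
  prot_cell <- tibble::tibble(
    comm = rep_len(seq_len(m), config$n_proteins),
    rel = rep_len(rep(rels_dp, each = m), config$n_proteins)
  )
  prot_lat <- centers[prot_cell$comm, , drop = FALSE] +
    g_rel[prot_cell$rel, , drop = FALSE] + noise(config$n_proteins)
  rownames(prot_lat) <- prot_ids

  has_r4 <- "isPresentIn" %in% schema$relation
  has_r5 <- "isImplicatedIn" %in% schema$relation
  path_ids <- sprintf("path%03d", seq_len(config$n_pathways))
  cells <- dplyr::distinct(prot_cell)
  path_cell_idx <- rep_len(seq_len(nrow(cells)), config$n_pathways)
  path_lat <- centers[cells$comm[path_cell_idx], , drop = FALSE] +
    g_rel[cells$rel[path_cell_idx], , drop = FALSE] +
    (if (has_r4) matrix(rep(g_rel["isPresentIn", ], each = config$n_pathways),
                        config$n_pathways, dim) else 0) +
    noise(config$n_pathways)
  rownames(path_lat) <- path_ids

  phen_ids <- sprintf("phen%03d", seq_len(config$n_phenotypes))
  phen_cell_idx <- rep_len(seq_len(nrow(cells)), config$n_phenotypes)
  phen_lat <- centers[cells$comm[phen_cell_idx], , drop = FALSE] +
    g_rel[cells$rel[phen_cell_idx], , drop = FALSE] +
    (if (has_r4) matrix(rep(g_rel["isPresentIn", ], each = config$n_phenotypes),
                        config$n_phenotypes, dim) else 0) +
    (if (has_r5) matrix(rep(g_rel["isImplicatedIn", ], each = config$n_phenotypes),
                        config$n_phenotypes, dim) else 0) +
    noise(config$n_phenotypes)
  rownames(phen_lat) <- phen_ids

  ## enumerate all latently consistent basic-triple combinations
  combos <- list()
  for (i in seq_len(config$n_proteins)) {
    dr <- drug_ids[drug_comm == prot_cell$comm[i]]
    combos[[length(combos) + 1]] <- tibble::tibble(
      head = dr, relation = prot_cell$rel[i], tail = prot_ids[i]
    )
  }
  if (has_r4) {
    for (i in seq_len(config$n_pathways)) {
      cell <- path_cell_idx[i]
      pr <- prot_ids[prot_cell$comm == cells$comm[cell] &
                     prot_cell$rel == cells$rel[cell]]
      if (length(pr) > 0) {
        combos[[length(combos) + 1]] <- tibble::tibble(
          head = pr, relation = "isPresentIn", tail = path_ids[i]
        )
      }
    }
  }
  if (has_r4 && has_r5) {
    for (i in seq_len(config$n_phenotypes)) {
      pw <- path_ids[phen_cell_idx[i] == path_cell_idx]
      if (length(pw) > 0) {
        combos[[length(combos) + 1]] <- tibble::tibble(
          head = pw, relation = "isImplicatedIn", tail = phen_ids[i]
        )
      }
    }
  }
  combos <- dplyr::bind_rows(combos)
  if (nrow(combos) < config$n_basic) {
    abort_typed(paste0("config supports only ", nrow(combos),
                       " distinct consistent basic triples; lower n_basic"),
                "prddi_config_error")
  }
  basic <- combos[sample.int(nrow(combos), config$n_basic), ]

  ## DDI clusters: ordered pairs of distinct communities with distinct
  ## (unordered) community pairs, so latent differences identify clusters
  upairs <- utils::combn(m, 2)
  pick <- sample.int(ncol(upairs), config$n_clusters)
  clusters <- tibble::tibble(
    cluster = seq_len(config$n_clusters),
    comm_source = upairs[1, pick],
    comm_target = upairs[2, pick]
  )
  # each cluster owns a core label set of size labels_per_ddi, laid out in
  # disjoint blocks; the remaining vocabulary is shared background
  vocab <- ddi_label_pool()[seq_len(config$vocab_size)]
  npd <- config$labels_per_ddi
  clusters$labels <- lapply(seq_len(config$n_clusters), function(c) {
    vocab[((c - 1) * npd + 1):(c * npd)]
  })

  # only a fraction of each community's drugs carries DDI records
  eligible <- unlist(lapply(seq_len(m), function(j) {
    members <- drug_ids[drug_comm == j]
    members[seq_len(max(2, floor(config$ddi_drug_fraction * length(members))))]
  }))

  n_pairs <- config$n_ddi_pairs
  pair_u <- character(n_pairs); pair_v <- character(n_pairs)
  pair_cluster <- integer(n_pairs)
  seen <- character(0)
  filled <- 0; tries <- 0
  while (filled < n_pairs) {
    tries <- tries + 1
    if (tries > 100 * n_pairs) {
      abort_typed("cannot sample enough distinct DDI pairs",
                  "prddi_config_error")
    }
    cc <- sample.int(config$n_clusters, 1)
    us <- intersect(drug_ids[drug_comm == clusters$comm_source[cc]], eligible)
    vs <- intersect(drug_ids[drug_comm == clusters$comm_target[cc]], eligible)
    u <- us[sample.int(length(us), 1)]
    v <- vs[sample.int(length(vs), 1)]
    key <- canonical_pair(u, v)
    if (key %in% seen) next
    seen <- c(seen, key)
    filled <- filled + 1
    pair_u[filled] <- u; pair_v[filled] <- v; pair_cluster[filled] <- cc
  }

  # a pair carries its cluster's core labels; each core label is swapped
  # for a random outside label with probability 1 - sqrt(within_cooccur),
  # so two core labels co-occur with probability within_cooccur
  swap_p <- 1 - sqrt(config$within_cooccur)
  pair_labels <- lapply(seq_len(n_pairs), function(i) {
    core <- clusters$labels[[pair_cluster[i]]]
    labs <- core
    swap <- stats::runif(length(labs)) < swap_p
    if (any(swap)) {
      outside <- setdiff(vocab, core)
      labs[swap] <- sample(outside, sum(swap))
    }
    sort(unique(labs))
  })

  ddi <- tibble::tibble(drug_u = pair_u, drug_v = pair_v,
                        labels = pair_labels)
  kg <- build_kg(basic, ddi, vocabulary = label_vocabulary(vocab),
                 schema = schema, extra_drugs = drug_ids)

  latent <- rbind(drug_lat, prot_lat,
                  if (has_r4) path_lat else NULL,
                  if (has_r4 && has_r5) phen_lat else NULL)
  truth <- structure(
    list(
      latent = latent,
      relation_latent = g_rel,
      communities = tibble::tibble(id = drug_ids, community = drug_comm,
                                   ddi_eligible = drug_ids %in% eligible),
      clusters = clusters,
      pairs = tibble::tibble(drug_u = pair_u, drug_v = pair_v,
                             cluster = pair_cluster, labels = pair_labels),
      config = config
    ),
    class = "prd_ground_truth"
  )
  list(kg = kg, truth = truth)
}

#' Model parameters holding the generating latent vectors
#'
#' Packs the ground-truth latents into a `prd_params` object with identity
#' projection matrices and an untrained (zero-bias Glorot) autoencoder, so
#' translational scores can be inspected under the generating geometry.
#' Requires `k = d = latent_dim`.
#'
#' @param truth A `prd_ground_truth` from [generate_kg()].
#' @param kg The matching `drug_kg`.
#' @param hp A [prd_hparams()] with `k = d = latent_dim`.
#' @return A `prd_params` object.
#' @export
truth_params <- function(truth, kg, hp) {
  dim <- truth$config$latent_dim
  if (hp$k != dim || hp$d != dim) {
    abort_typed("truth_params needs k = d = latent_dim", "prddi_shape_error")
  }
  params <- prd_init_params(kg, hp)
  ids <- rownames(params$entity)
  miss <- setdiff(ids, rownames(truth$latent))
  if (length(miss) > 0) {
    abort_typed("KG entities missing from the ground truth",
                "prddi_lookup_error")
  }
  params$entity <- truth$latent[ids, , drop = FALSE]
  rels <- rownames(params$relation)
  params$relation <- truth$relation_latent[rels, , drop = FALSE]
  eye <- diag(1, dim, dim)
  params$proj <- stats::setNames(rep(list(eye), length(rels)), rels)
  params$proj_ddi <- eye
  params
}

#' Generate a synthetic DDI sentence corpus from the ground truth
#'
#' Emits one sentence per generated DDI pair whose content tokens are
#' exactly the pair's planted labels (each appearing once), padded with
#' stop words, common filler tokens (present in every document, hence zero
#' IDF) and the two drug mentions, so the TF-IDF pipeline can recover the
#' planted labels.
#'
#' @param truth A `prd_ground_truth` from [generate_kg()].
#' @param fillers Character vector of filler words inserted in every
#'   sentence (use `character()` for label-only token streams).
#' @return A corpus tibble as from [read_ddi_corpus()].
#' @export
generate_corpus <- function(truth,
                            fillers = c("interaction", "concomitant")) {
  pairs <- truth$pairs
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(truth$config$seed + 1L)
  sentences <- vapply(seq_len(nrow(pairs)), function(i) {
    labs <- sample(pairs$labels[[i]])
    if (length(fillers) == 0) {
      paste(c("the", labs, "may"), collapse = " ")
    } else {
      paste(pairs$drug_u[i], "with", pairs$drug_v[i], "may cause",
            paste(c(labs, fillers), collapse = " "))
    }
  }, character(1))
  corpus <- tibble::tibble(
    doc_id = sprintf("doc%04d", seq_len(nrow(pairs))),
    drug_u = pairs$drug_u, drug_v = pairs$drug_v,
    sentence = sentences
  )
  corpus$tokens <- lapply(corpus$sentence, preprocess_text)
  corpus
}

#' Write a complete synthetic fixture directory
#'
#' Emits the TSV/plain-text files read back by the I/O functions: basic
#' triples, DDI triples, sentence corpus, label vocabulary, a drug alias
#' table (capitalized aliases), and the ground truth as JSON.
#'
#' @param config A [synth_config()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, a named list of the written paths plus the in-memory
#'   `kg` and `truth`.
#' @export
simulate_fixture_dir <- function(config = synth_config(), dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  gen <- generate_kg(config)
  corpus <- generate_corpus(gen$truth)
  drugs <- kg_drugs(gen$kg)
  aliases <- tibble::tibble(
    alias = paste0(toupper(substring(drugs, 1, 1)), substring(drugs, 2)),
    canonical_id = drugs
  )
  paths <- list(
    basic = file.path(dir, "basic_triples.tsv"),
    ddi = file.path(dir, "ddi_triples.tsv"),
    corpus = file.path(dir, "corpus.tsv"),
    vocabulary = file.path(dir, "vocabulary.txt"),
    aliases = file.path(dir, "aliases.tsv"),
    ground_truth = file.path(dir, "ground_truth.json")
  )
  write_basic_triples(gen$kg$basic, paths$basic)
  write_ddi_triples(ddi_pairs(gen$kg), paths$ddi)
  write_ddi_corpus(corpus, paths$corpus)
  write_label_vocabulary(gen$kg$vocabulary, paths$vocabulary)
  writeLines(paste(aliases$alias, aliases$canonical_id, sep = "\t"),
             paths$aliases)
  truth_json <- list(
    latent = gen$truth$latent,
    relation_latent = gen$truth$relation_latent,
    communities = gen$truth$communities,
    clusters = dplyr::mutate(
      gen$truth$clusters,
      labels = vapply(.data$labels, paste, character(1), collapse = "|")
    ),
    pairs = dplyr::mutate(
      gen$truth$pairs,
      labels = vapply(.data$labels, paste, character(1), collapse = "|")
    ),
    config = unclass(gen$truth$config)
  )
  jsonlite::write_json(truth_json, paths$ground_truth, digits = NA,
                       auto_unbox = TRUE, matrix = "rowmajor")
  invisible(c(paths, list(kg = gen$kg, truth = gen$truth)))
}
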