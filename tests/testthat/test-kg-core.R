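test_that("basic triple files parse, with comments and errors reported", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# drug KG extract",
               "etanercept\thasTarget\tlymphotoxin-alpha",
               "",
               "aspirin\thasEnzyme\tp450"), path)
  got <- read_basic_triples(path)
  expect_equal(nrow(got), 2)
  expect_equal(got$head[1], "etanercept")
  expect_equal(got$relation[1], "hasTarget")
  expect_equal(got$tail[1], "lymphotoxin-alpha")

  # empty file -> empty collection
  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(), empty)
  expect_equal(nrow(read_basic_triples(empty)), 0)

  # malformed line -> parse error naming the line
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("a\thasTarget\tb", "two\tfields"), bad)
  expect_error(read_basic_triples(bad), "line 2",
               class = "prddi_parse_error")

  # unknown relation -> schema error
  unk <- withr::local_tempfile(fileext = ".tsv")
  writeLines("a\tbindsTo\tb", unk)
  expect_error(read_basic_triples(unk), class = "prddi_schema_error")
})

test_that("entity kinds are inferred from the relation schema", {
  ents <- infer_entities(tiny_basic())
  expect_setequal(ents$kind[ents$id %in% c("etanercept", "aspirin", "warfarin")],
                  "drug")
  expect_equal(ents$kind[ents$id == "p1"], "protein")
  expect_equal(ents$kind[ents$id == "pw1"], "pathway")

  # an id used both as drug and protein is a conflict
  conflict <- tibble::tibble(head = c("a", "b"),
                             relation = c("hasTarget", "hasTarget"),
                             tail = c("b", "c"))
  expect_error(infer_entities(conflict), class = "prddi_schema_error")
})

test_that("build_kg expands DDI pairs into two directed triples", {
  kg <- build_kg(tiny_basic(),
                 tibble::tibble(drug_u = "aspirin", drug_v = "warfarin",
                                labels = list("bleeding")),
                 tiny_vocab())
  expect_equal(nrow(kg$ddi), 2)
  expect_setequal(kg$ddi$drug_u, c("aspirin", "warfarin"))
  expect_equal(kg$ddi$labels[[1]], kg$ddi$labels[[2]])

  # no DDI triples is fine
  kg0 <- build_kg(tiny_basic(), NULL, tiny_vocab())
  expect_equal(nrow(kg0$ddi), 0)
  expect_equal(nrow(kg0$basic), 4)

  # the same undirected pair given twice is deduplicated
  kg2 <- build_kg(tiny_basic(),
                  tibble::tibble(drug_u = c("aspirin", "warfarin"),
                                 drug_v = c("warfarin", "aspirin"),
                                 labels = list("bleeding", "bleeding")),
                  tiny_vocab())
  expect_equal(nrow(kg2$ddi), 2)
})

test_that("build_kg validates labels and self-interactions", {
  expect_error(
    build_kg(tiny_basic(),
             tibble::tibble(drug_u = "aspirin", drug_v = "warfarin",
                            labels = list("notalabel")),
             tiny_vocab()),
    class = "prddi_vocabulary_error"
  )
  expect_error(
    build_kg(tiny_basic(),
             tibble::tibble(drug_u = "aspirin", drug_v = "aspirin",
                            labels = list("bleeding")),
             tiny_vocab()),
    class = "prddi_validation_error"
  )
})

test_that("directed DDI triples are exactly twice the undirected pairs", {
  gen <- generate_kg(small_synth_config())
  expect_equal(nrow(gen$kg$ddi), 2 * nrow(ddi_pairs(gen$kg)))
})

test_that("split_ddi holds out pairs, conserves triples and samples clean negatives", {
  gen <- generate_kg(small_synth_config())
  kg <- gen$kg
  sp <- split_ddi(kg, rate = 0.3, seed = 11)
  n_pairs <- nrow(ddi_pairs(kg))
  expect_equal(nrow(ddi_pairs_test <- sp$test_positives) / 2,
               round(0.3 * n_pairs))
  expect_equal(nrow(sp$test_negatives), round(0.3 * n_pairs))

  # conservation: train + test = all directed triples, disjoint as pairs
  key <- function(d) paste(pmin(d$drug_u, d$drug_v), pmax(d$drug_u, d$drug_v))
  expect_setequal(c(key(sp$train_kg$ddi), key(sp$test_positives)), key(kg$ddi))
  expect_length(intersect(key(sp$train_kg$ddi), key(sp$test_positives)), 0)

  # negatives never occur in the full DDI set and are never self-pairs
  expect_false(any(key(sp$test_negatives) %in% key(kg$ddi)))
  expect_false(any(sp$test_negatives$drug_u == sp$test_negatives$drug_v))
})

test_that("split_ddi is reproducible by seed and handles edge rates", {
  gen <- generate_kg(small_synth_config())
  a <- split_ddi(gen$kg, 0.3, seed = 4)
  b <- split_ddi(gen$kg, 0.3, seed = 4)
  expect_identical(a$test_positives, b$test_positives)
  expect_identical(a$test_negatives, b$test_negatives)
  c <- split_ddi(gen$kg, 0.3, seed = 5)
  expect_false(identical(a$test_positives, c$test_positives))

  z <- split_ddi(gen$kg, 0, seed = 1)
  expect_equal(nrow(z$test_positives), 0)
  expect_equal(nrow(z$test_negatives), 0)
  expect_equal(nrow(z$train_kg$ddi), nrow(gen$kg$ddi))

  expect_error(split_ddi(gen$kg, 1.5, seed = 1), class = "prddi_domain_error")
})

test_that("triple writers round-trip through the readers", {
  kg <- tiny_kg()
  bpath <- withr::local_tempfile(fileext = ".tsv")
  write_basic_triples(kg$basic, bpath)
  expect_equal(read_basic_triples(bpath), kg$basic)

  dpath <- withr::local_tempfile(fileext = ".tsv")
  write_ddi_triples(ddi_pairs(kg), dpath)
  back <- read_ddi_triples(dpath)
  expect_equal(back$drug_u, ddi_pairs(kg)$drug_u)
  expect_equal(back$labels, ddi_pairs(kg)$labels)
})
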