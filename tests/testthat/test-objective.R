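test_that("negative sampling respects candidate sets and the filter", {
  gen <- generate_kg(small_synth_config())
  kg <- gen$kg
  hp <- small_hparams()
  params <- prd_init_params(kg, hp)

  pos <- list(head = kg$basic$head[1], relation = kg$basic$relation[1],
              tail = kg$basic$tail[1])
  set.seed(3)
  neg <- sample_negatives(pos, "tail", 25, kg, params, hp)
  expect_equal(nrow(neg), 25)
  key <- paste(kg$basic$head, kg$basic$relation, kg$basic$tail)
  expect_false(any(paste(neg$head, neg$relation, neg$tail) %in% key))

  # zero negatives is the identity case
  expect_equal(nrow(sample_negatives(pos, "head", 0, kg, params, hp)), 0)

  # corrupted DDI drug slots never recreate an existing pair
  dpos <- list(drug_u = kg$ddi$drug_u[1], drug_v = kg$ddi$drug_v[1])
  dneg <- sample_negatives(dpos, "drug_u", 25, kg, params, hp)
  dkey <- paste(pmin(kg$ddi$drug_u, kg$ddi$drug_v),
                pmax(kg$ddi$drug_u, kg$ddi$drug_v))
  expect_false(any(paste(pmin(dneg$drug_u, dneg$drug_v),
                         pmax(dneg$drug_u, dneg$drug_v)) %in% dkey))
  expect_false(any(dneg$drug_u == dneg$drug_v))
  # corruptions are drugs
  expect_true(all(dneg$drug_u %in% kg_drugs(kg)))
})

test_that("the one-positive surrogate matches its closed forms", {
  p <- structure(
    list(entity = matrix(0, 2, 1, dimnames = list(c("h", "t"), NULL)),
         relation = matrix(0, 1, 1, dimnames = list("hasTarget", NULL)),
         proj = list(hasTarget = matrix(1, 1, 1)),
         proj_ddi = matrix(1, 1, 1),
         ae = NULL, vocabulary = letters[1:2]),
    class = "prd_params"
  )
  hp <- prd_hparams(k = 1, d = 1, b1 = 0, norm = "L1")
  pos <- list(head = "h", relation = "hasTarget", tail = "t")
  # z(pos) = 0 and no negatives: ln sigma(0) = ln 0.5
  expect_equal(negative_sampling_objective(p, pos, NULL, hp), log(0.5),
               tolerance = 1e-12)

  # objective increases monotonically in z(pos): raise b1
  vals <- vapply(c(0, 1, 2, 4), function(b) {
    negative_sampling_objective(p, pos, NULL,
                                prd_hparams(k = 1, d = 1, b1 = b))
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("the joint objective is deterministic given a sampled batch", {
  gen <- generate_kg(small_synth_config())
  kg <- gen$kg
  hp <- small_hparams()
  params <- jitter_params(prd_init_params(kg, hp))
  set.seed(7)
  batch <- sample_training_batch(kg, params, hp)
  v1 <- joint_objective(params, batch, kg, hp)
  v2 <- joint_objective(params, batch, kg, hp)
  expect_identical(v1, v2)
  expect_true(is.finite(v1))

  # gradient value agrees with the plain evaluation
  og <- joint_objective(params, batch, kg, hp, gradient = TRUE)
  expect_equal(og$value, v1)
})

test_that("analytic gradients match central finite differences", {
  gen <- generate_kg(small_synth_config(seed = 9))
  kg <- gen$kg
  for (norm in c("L1", "L2")) {
    hp <- small_hparams(norm = norm, dropout = 0.2)
    params <- jitter_params(prd_init_params(kg, hp), seed = 17)
    set.seed(23)
    batch <- sample_training_batch(kg, params, hp,
                                   basic_idx = 1:12, ddi_idx = 1:6)
    og <- joint_objective(params, batch, kg, hp, gradient = TRUE)
    flat <- prddi:::params_flatten(params)
    ga <- prddi:::params_flatten(og$grad)
    f <- function(x) {
      joint_objective(prddi:::params_unflatten(x, params), batch, kg, hp)
    }
    h <- 1e-6
    idx <- seq(1, length(flat), by = 7)   # spot-check a spread of coordinates
    gfd <- vapply(idx, function(i) {
      xp <- flat; xp[i] <- xp[i] + h
      xm <- flat; xm[i] <- xm[i] - h
      (f(xp) - f(xm)) / (2 * h)
    }, numeric(1))
    rel <- sqrt(sum((ga[idx] - gfd)^2)) /
      max(sqrt(sum(ga[idx]^2)), sqrt(sum(gfd^2)))
    expect_lt(rel, 1e-6)
  }
})

test_that("training improves the objective, deterministically per seed", {
  gen <- generate_kg(small_synth_config())
  kg <- gen$kg
  hp <- small_hparams(iterations = 60)
  m1 <- prd_train(kg, hp)
  m2 <- prd_train(kg, hp)
  expect_identical(m1$trace, m2$trace)
  expect_identical(m1$params$entity, m2$params$entity)

  m3 <- prd_train(kg, small_hparams(iterations = 60, seed = 3))
  expect_false(identical(m1$trace$objective, m3$trace$objective))

  # smoothed trace trends upward over training
  sm <- function(x, w = 10) stats::filter(x, rep(1 / w, w), sides = 1)
  tr <- sm(m1$trace$objective)
  expect_gt(utils::tail(tr[!is.na(tr)], 1), tr[!is.na(tr)][1])
})

test_that("checkpoints round-trip bit-exactly", {
  gen <- generate_kg(small_synth_config())
  m <- prd_train(gen$kg, small_hparams(iterations = 5))
  path <- withr::local_tempfile(fileext = ".rds")
  save_prd_model(m, path)
  back <- load_prd_model(path)
  expect_identical(back$params, m$params)
  expect_identical(back$trace, m$trace)
})

test_that("soft constraints rein in embedding norms during learning", {
  gen <- generate_kg(small_synth_config())
  frac_big <- function(gamma) {
    hp <- small_hparams(iterations = 500, gamma = gamma, lr = 0.01)
    m <- prd_train(gen$kg, hp)
    mean(rowSums(m$params$entity^2) > 1.1)
  }
  f0 <- frac_big(0)
  f1 <- frac_big(0.5)
  expect_lt(f1, f0)
})

test_that("held-out true triples outscore random corruptions after training", {
  gen <- generate_kg(small_synth_config())
  kg <- gen$kg
  set.seed(3)
  hold <- sample.int(nrow(kg$basic), 10)
  kg_train <- kg
  kg_train$basic <- kg$basic[-hold, ]
  hp <- small_hparams(iterations = 400, gamma = 0.01, lr = 0.01)
  m <- prd_train(kg_train, hp)
  true_sc <- vapply(hold, function(i) {
    score_basic(m$params, kg$basic$head[i], kg$basic$relation[i],
                kg$basic$tail[i], hp)
  }, numeric(1))
  ents <- kg$entities$id
  corr_sc <- vapply(hold, function(i) {
    score_basic(m$params, kg$basic$head[i], kg$basic$relation[i],
                sample(ents, 1), hp)
  }, numeric(1))
  expect_gt(mean(true_sc), mean(corr_sc))
})
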