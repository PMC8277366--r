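# Direct construction of parameters with known values, bypassing training.
manual_params <- function(entities, k, d, relations = "hasTarget",
                          vocab = letters[1:4]) {
  E <- matrix(0, length(entities), k, dimnames = list(entities, NULL))
  R <- matrix(0, length(relations), d, dimnames = list(relations, NULL))
  eye <- diag(1, k, d)
  widths <- prddi:::ae_layer_widths(length(vocab), d)
  structure(
    list(entity = E, relation = R,
         proj = stats::setNames(rep(list(eye), length(relations)), relations),
         proj_ddi = eye,
         ae = list(W = lapply(1:4, function(i) matrix(0, widths[i + 1], widths[i])),
                   b = lapply(1:4, function(i) rep(0, widths[i + 1]))),
         vocabulary = vocab),
    class = "prd_params"
  )
}

test_that("basic-triple scores follow the projected translation residual", {
  hp <- prd_hparams(k = 2, d = 2, b1 = 5, norm = "L1")
  p <- manual_params(c("h", "t"), 2, 2)
  p$entity["h", ] <- c(0.3, 0.4)
  p$relation["hasTarget", ] <- c(0.1, 0.2)

  # exact translation scores b1
  p$entity["t", ] <- c(0.4, 0.6)
  expect_equal(score_basic(p, "h", "hasTarget", "t", hp), 5)

  # L1 residual of 0.1 costs exactly 0.1
  p$entity["t", ] <- c(0.4, 0.7)
  expect_equal(score_basic(p, "h", "hasTarget", "t", hp), 4.9)

  # L2 norm variant
  hp2 <- prd_hparams(k = 2, d = 2, b1 = 5, norm = "L2")
  expect_equal(score_basic(p, "h", "hasTarget", "t", hp2), 5 - 0.1)

  expect_error(score_basic(p, "nope", "hasTarget", "t", hp),
               class = "prddi_lookup_error")
})

test_that("DDI scores use the shared projection and attain b2 at zero residual", {
  hp <- prd_hparams(k = 2, d = 2, b2 = 5, norm = "L1")
  p <- manual_params(c("u", "v"), 2, 2)
  p$entity["u", ] <- c(0, 0)
  p$entity["v", ] <- c(1, 0)
  expect_equal(score_ddi(p, "u", c(1, 0), "v", hp), 5)
  # residual translation: score drops by the L1 norm
  expect_equal(score_ddi(p, "u", c(0.5, 0.2), "v", hp), 5 - 0.7)
})

test_that("scores never exceed their bias constants", {
  gen <- generate_kg(small_synth_config())
  hp <- small_hparams()
  params <- jitter_params(prd_init_params(gen$kg, hp))
  kg <- gen$kg
  for (i in seq_len(min(20, nrow(kg$basic)))) {
    expect_lte(score_basic(params, kg$basic$head[i], kg$basic$relation[i],
                           kg$basic$tail[i], hp), hp$b1)
  }
  set.seed(1)
  for (i in 1:10) {
    l <- rnorm(hp$d)
    expect_lte(score_ddi(params, kg$ddi$drug_u[1], l, kg$ddi$drug_v[1], hp),
               hp$b2)
  }
})

test_that("conditional probabilities are softmax-normalized", {
  hp <- prd_hparams(k = 2, d = 2, b1 = 5, norm = "L1")
  p <- manual_params(c("h", "t1", "t2"), 2, 2)
  p$entity["h", ] <- c(0.3, 0.4)
  p$relation["hasTarget", ] <- c(0.1, 0.2)
  p$entity["t1", ] <- c(0.4, 0.6)
  p$entity["t2", ] <- c(0.4, 0.6)
  triple <- list(head = "h", relation = "hasTarget", tail = "t1")

  # equal scores -> uniform probabilities
  got <- conditional_probability(p, triple, "tail", c("t1", "t2"), hp)
  expect_equal(got$probability, c(0.5, 0.5))

  # normalization holds on random candidate sets
  set.seed(2)
  p3 <- manual_params(paste0("e", 1:6), 3, 3)
  p3$entity[] <- rnorm(18)
  p3$relation[] <- rnorm(3)
  got3 <- conditional_probability(
    p3, list(head = "e1", relation = "hasTarget", tail = "e2"),
    "tail", paste0("e", 2:6), prd_hparams(k = 3, d = 3)
  )
  expect_equal(sum(got3$probability), 1, tolerance = 1e-10)
  expect_true(all(got3$probability >= 0))
  expect_error(conditional_probability(p3, list(head = "e1",
                                                relation = "hasTarget",
                                                tail = "e2"),
                                       "tail", character(), prd_hparams()),
               class = "prddi_domain_error")
})

test_that("softmax probabilities reproduce hand-computed odds", {
  # engineer scores ln(1), ln(2), ln(3) directly through b1 offsets:
  # z_j = b1 - |h + r - t_j| with h = r = 0 and t_j = b1 - ln(j)
  hp <- prd_hparams(k = 1, d = 1, b1 = 2, norm = "L1")
  p <- manual_params(c("h", "t1", "t2", "t3"), 1, 1)
  p$entity["t1", ] <- 2 - log(1)
  p$entity["t2", ] <- 2 - log(2)
  p$entity["t3", ] <- 2 - log(3)
  got <- conditional_probability(
    p, list(head = "h", relation = "hasTarget", tail = "t1"),
    "tail", c("t1", "t2", "t3"), hp
  )
  expect_equal(got$probability, c(1, 2, 3) / 6, tolerance = 1e-12)
})

test_that("encoder and decoder forward passes have the stated ranges", {
  vocab <- letters[1:6]
  p <- manual_params(c("u", "v"), 2, 3, vocab = vocab)
  s <- c(1, 0, 1, 0, 0, 0)

  # all-zero weights: code is zero, reconstruction is logistic(0) = 0.5
  expect_equal(encode_labels(p$ae, s), rep(0, 3))
  expect_equal(decode_labels(p$ae, rep(0, 3)), rep(0.5, 6))

  # randomly initialized autoencoder: code in [0,1), shat in (0,1)
  gen <- generate_kg(small_synth_config())
  hp <- small_hparams()
  params <- prd_init_params(gen$kg, hp)
  s2 <- vectorize_labels(gen$kg$ddi$labels[[1]], gen$kg$vocabulary)
  code <- encode_labels(params$ae, s2)
  expect_length(code, hp$d)
  expect_true(all(code >= 0 & code < 1))
  shat <- decode_labels(params$ae, code)
  expect_length(shat, length(gen$kg$vocabulary))
  expect_true(all(shat > 0 & shat < 1))

  expect_error(encode_labels(params$ae, c(1, 0)), class = "prddi_shape_error")
  expect_error(decode_labels(params$ae, 1), class = "prddi_shape_error")
})

test_that("tanh is applied componentwise at the code layer", {
  vocab <- letters[1:2]
  p <- manual_params("u", 2, 2, vocab = vocab)
  # single effective layer: first weight identity, second identity
  p$ae$W[[1]] <- diag(1, nrow(p$ae$W[[1]]), 2)
  p$ae$W[[2]] <- diag(1, 2, nrow(p$ae$W[[1]]))
  code <- encode_labels(p$ae, c(1, 0))
  expect_equal(code, abs(tanh(tanh(c(1, 0)))), tolerance = 1e-12)
  expect_equal(code[2], 0)
})

test_that("reconstruction weights and score follow the weighted-residual rule", {
  expect_equal(reconstruction_weights(c(0, 0, 0), 3), c(1, 1, 1))
  expect_equal(reconstruction_weights(c(1, 0, 1), 3), c(3, 1, 3))
  expect_error(reconstruction_weights(c(1, 0), 1), class = "prddi_domain_error")

  s <- c(1, 0)
  expect_equal(reconstruction_score(s, s, c(5, 1), b3 = 1), 1)
  expect_equal(
    reconstruction_score(c(1, 0), c(0.5, 0.5), c(2, 1), b3 = 1, norm = "L1"),
    1 - 1.5
  )
  expect_error(reconstruction_score(c(1, 0), c(0.5), c(1, 1), 1),
               class = "prddi_shape_error")
})

test_that("soft constraints activate only above unit squared norm", {
  gen <- generate_kg(small_synth_config())
  hp <- small_hparams()
  params <- prd_init_params(gen$kg, hp)

  # shrink everything inside the unit ball -> zero penalty
  small <- params
  small$entity <- small$entity * 0.1
  small$relation <- small$relation * 0.1
  small$proj <- lapply(small$proj, function(M) M * 0.01)
  small$proj_ddi <- small$proj_ddi * 0.01
  expect_equal(regularizer(small, gamma = 1, kg = gen$kg), 0)

  # a single entity of norm sqrt(2) contributes (2 - 1) = 1
  one <- small
  one$entity[1, ] <- 0
  one$entity[1, 1:2] <- 1
  expect_equal(regularizer(one, gamma = 1, kg = NULL), 1)
  expect_equal(regularizer(one, gamma = 0.5, kg = NULL), 0.5)

  # gamma zero switches the penalty off entirely
  expect_equal(regularizer(params, gamma = 0, kg = gen$kg), 0)
})
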