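#' Hyperparameters of the joint embedding model
#'
#' Defaults follow the method's reference configuration: learning rate 0.001, soft-constraint weight 0.01,
#' entity dimension k = 100, score offsets b1 = b2 = 5 and b3 = 1, 10
#' negatives per positive, and the L1 dissimilarity norm. The relation
#' dimension `d` defaults to `k`. `beta` (> 1) is the reconstruction weight
#' put on nonzero label components so the sparse decoder is not dominated
#' by zeros.
#'
#' @param k Entity embedding dimension.
#' @param d Relation embedding dimension (default `k`).
#' @param b1,b2,b3 Bias constants offsetting the basic-triple, DDI-triple
#'   and reconstruction scores.
#' @param beta Reconstruction weight for nonzero label components; must
#'   exceed 1.
#' @param c_neg Number of negative samples per positive.
#' @param gamma Weight of the soft norm constraints.
#' @param lr Adam learning rate.
#' @param norm Dissimilarity norm, `"L1"` or `"L2"`.
#' @param dropout Dropout probability on autoencoder hidden layers during
#'   training, in `[0, 1)`.
#' @param iterations Number of training iterations (mini-batches).
#' @param batch_size Positives per mini-batch.
#' @param seed RNG seed for initialization, sampling and dropout.
#' @param filter_corruptions Reject corrupted triples that exist in the
#'   training set (avoids false negatives).
#' @param label_flips Components flipped to form negative label vectors for
#'   the reconstruction term; default `min(5, ceiling(|L| / 10))`, resolved
#'   at training time.
#' @return A `prd_hparams` list.
#' @export
prd_hparams <- function(k = 100, d = k, b1 = 5, b2 = 5, b3 = 1, beta = 5,
                        c_neg = 10, gamma = 0.01, lr = 0.001, norm = "L1",
                        dropout = 0.2, iterations = 1000, batch_size = 128,
                        seed = 42L, filter_corruptions = TRUE,
                        label_flips = NULL) {
  if (k < 1 || d < 1) abort_typed("k and d must be >= 1", "prddi_domain_error")
  if (beta <= 1) abort_typed("beta must be > 1", "prddi_domain_error")
  if (c_neg < 0) abort_typed("c_neg must be >= 0", "prddi_domain_error")
  if (!norm %in% c("L1", "L2")) {
    abort_typed('norm must be "L1" or "L2"', "prddi_domain_error")
  }
  if (dropout < 0 || dropout >= 1) {
    abort_typed("dropout must be in [0, 1)", "prddi_domain_error")
  }
  structure(
    list(k = as.integer(k), d = as.integer(d), b1 = b1, b2 = b2, b3 = b3,
         beta = beta, c_neg = as.integer(c_neg), gamma = gamma, lr = lr,
         norm = norm, dropout = dropout, iterations = as.integer(iterations),
         batch_size = as.integer(batch_size), seed = as.integer(seed),
         filter_corruptions = isTRUE(filter_corruptions),
         label_flips = label_flips),
    class = "prd_hparams"
  )
}

# Dissimilarity norm and its (sub)gradient.
residual_norm <- function(v, norm) {
  if (norm == "L1") sum(abs(v)) else sqrt(sum(v^2))
}

residual_norm_grad <- function(v, norm) {
  if (norm == "L1") {
    sign(v)
  } else {
    n <- sqrt(sum(v^2))
    if (n == 0) rep(0, length(v)) else v / n
  }
}

sigmoid <- function(x) 1 / (1 + exp(-x))

log_sigmoid <- function(x) {
  ifelse(x >= 0, -log1p(exp(-x)), x - log1p(exp(x)))
}

ae_layer_widths <- function(n_labels, d) {
  m <- max(d, ceiling(n_labels / 2))
  c(n_labels, m, d, m, n_labels)
}

glorot <- function(nrow, ncol) {
  lim <- sqrt(6 / (nrow + ncol))
  matrix(stats::runif(nrow * ncol, -lim, lim), nrow, ncol)
}

#' Initialize model parameters for a knowledge graph
#'
#' Entity and relation vectors are drawn uniformly from
#' `(-6/sqrt(k), 6/sqrt(k))`; projection matrices start at a (rectangular)
#' identity plus small noise; autoencoder weights use Glorot-style
#' initialization. Deterministic given `hp$seed`.
#'
#' @param kg A `drug_kg` object (training graph).
#' @param hp A [prd_hparams()] object.
#' @return A `prd_params` list with elements `entity` (matrix, one row per
#'   entity), `relation` (matrix, one row per basic relation), `proj`
#'   (list of k x d matrices per relation), `proj_ddi` (k x d matrix) and
#'   `ae` (autoencoder weights `W`, biases `b`).
#' @export
prd_init_params <- function(kg, hp) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(hp$seed)

  k <- hp$k; d <- hp$d
  ents <- kg$entities$id
  rels <- sort(unique(kg$basic$relation))
  lim_e <- 6 / sqrt(k)
  entity <- matrix(stats::runif(length(ents) * k, -lim_e, lim_e),
                   nrow = length(ents), dimnames = list(ents, NULL))
  entity <- entity / sqrt(rowSums(entity^2))
  lim_r <- 6 / sqrt(d)
  relation <- matrix(stats::runif(length(rels) * d, -lim_r, lim_r),
                     nrow = length(rels), dimnames = list(rels, NULL))
  if (length(rels) > 0) {
    relation <- relation / sqrt(rowSums(relation^2))
  }
  eye <- diag(1, k, d)
  proj <- lapply(rels, function(r) eye + matrix(stats::rnorm(k * d, 0, 0.01), k, d))
  names(proj) <- rels
  proj_ddi <- eye + matrix(stats::rnorm(k * d, 0, 0.01), k, d)

  n_labels <- length(kg$vocabulary)
  widths <- ae_layer_widths(n_labels, d)
  W <- lapply(1:4, function(i) glorot(widths[i + 1], widths[i]))
  b <- lapply(1:4, function(i) rep(0, widths[i + 1]))

  structure(
    list(entity = entity, relation = relation, proj = proj,
         proj_ddi = proj_ddi, ae = list(W = W, b = b),
         vocabulary = vocab_labels(kg$vocabulary)),
    class = "prd_params"
  )
}

lookup_entity <- function(params, id) {
  i <- match(id, rownames(params$entity))
  if (is.na(i)) {
    abort_typed(paste0("unknown entity: ", id), "prddi_lookup_error")
  }
  params$entity[i, ]
}

lookup_relation <- function(params, id) {
  i <- match(id, rownames(params$relation))
  if (is.na(i)) {
    abort_typed(paste0("unknown relation: ", id), "prddi_lookup_error")
  }
  list(r = params$relation[i, ], M = params$proj[[id]])
}

#' Translational score of a basic triple
#'
#' `b1 - ||h M_r + r - t M_r||` under the configured L1/L2 norm, where
#' `M_r` is the relation-specific projection. The maximum attainable value
#' is `b1`, reached exactly when the projected translation residual is
#' zero.
#'
#' @param params A `prd_params` object.
#' @param head,relation,tail Ids of the triple.
#' @param hp A [prd_hparams()] object (uses `b1` and `norm`).
#' @return A single numeric score.
#' @export
score_basic <- function(params, head, relation, tail, hp) {
  h <- lookup_entity(params, head)
  t <- lookup_entity(params, tail)
  rel <- lookup_relation(params, relation)
  rho <- drop(h %*% rel$M) + rel$r - drop(t %*% rel$M)
  hp$b1 - residual_norm(rho, hp$norm)
}

#' Translational score of a rich DDI triple
#'
#' `b2 - ||u M_l + l - v M_l||`, with the single shared DDI projection
#' `M_l` and a relation embedding `l` (normally the autoencoder code of the
#' label set). Maximum value is `b2`.
#'
#' @param params A `prd_params` object.
#' @param u,v Drug entity ids.
#' @param l_emb Relation embedding vector of length `d`.
#' @param hp A [prd_hparams()] object (uses `b2` and `norm`).
#' @return A single numeric score.
#' @export
score_ddi <- function(params, u, l_emb, v, hp) {
  uu <- lookup_entity(params, u)
  vv <- lookup_entity(params, v)
  rho <- drop(uu %*% params$proj_ddi) + l_emb - drop(vv %*% params$proj_ddi)
  hp$b2 - residual_norm(rho, hp$norm)
}

#' Conditional probability of a triple slot filler
#'
#' Softmax of the translational scores obtained by substituting each
#' candidate into the given slot of a basic triple, i.e. the conditional
#' probability of the observed filler given the other two elements.
#'
#' @param params A `prd_params` object.
#' @param triple Named list or one-row tibble with `head`, `relation`,
#'   `tail`.
#' @param slot One of `"head"`, `"relation"`, `"tail"`.
#' @param candidates Character vector of candidate ids for the slot
#'   (must include the true filler).
#' @param hp A [prd_hparams()] object.
#' @return A tibble with columns `candidate` and `probability` (sums to 1).
#' @export
conditional_probability <- function(params, triple, slot, candidates, hp) {
  slot <- match.arg(slot, c("head", "relation", "tail"))
  if (length(candidates) == 0) {
    abort_typed("candidate set must be non-empty", "prddi_domain_error")
  }
  z <- vapply(candidates, function(cand) {
    h <- if (slot == "head") cand else triple$head
    r <- if (slot == "relation") cand else triple$relation
    t <- if (slot == "tail") cand else triple$tail
    score_basic(params, h, r, t, hp)
  }, numeric(1))
  z <- z - max(z)
  p <- exp(z) / sum(exp(z))
  tibble::tibble(candidate = candidates, probability = unname(p))
}

# Full autoencoder forward pass. Dropout masks (already inverted-scaled)
# apply to the two hidden layers h1 and h3; NULL means no dropout.
#
# DDI relations are stored bidirectionally, and under the translational
# score the relation embedding of a pair is then only identifiable up to
# coordinate signs. The code layer therefore uses the magnitude of its tanh
# activation (a nonnegative code) and the decoder consumes coordinate-wise
# magnitudes, so decoding is invariant to the sign ambiguity.
ae_forward <- function(ae, s, mask1 = NULL, mask3 = NULL) {
  W <- ae$W; b <- ae$b
  if (length(s) != ncol(W[[1]])) {
    abort_typed("label vector length does not match the autoencoder input",
                "prddi_shape_error")
  }
  h1 <- tanh(drop(W[[1]] %*% s) + b[[1]])
  h1d <- if (is.null(mask1)) h1 else h1 * mask1
  l <- abs(tanh(drop(W[[2]] %*% h1d) + b[[2]]))
  h3 <- tanh(drop(W[[3]] %*% abs(l)) + b[[3]])
  h3d <- if (is.null(mask3)) h3 else h3 * mask3
  shat <- sigmoid(drop(W[[4]] %*% h3d) + b[[4]])
  list(s = s, h1 = h1, h1d = h1d, l = l, h3 = h3, h3d = h3d, shat = shat)
}

# Decoder-only forward pass from a code vector (sign-invariant).
ae_decode <- function(ae, l_emb, mask3 = NULL) {
  W <- ae$W; b <- ae$b
  if (length(l_emb) != ncol(W[[3]])) {
    abort_typed("code vector length does not match the decoder input",
                "prddi_shape_error")
  }
  h3 <- tanh(drop(W[[3]] %*% abs(l_emb)) + b[[3]])
  h3d <- if (is.null(mask3)) h3 else h3 * mask3
  shat <- sigmoid(drop(W[[4]] %*% h3d) + b[[4]])
  list(l = l_emb, h3 = h3, h3d = h3d, shat = shat)
}

#' Encode a binary label vector into a relation embedding
#'
#' Forward pass through the encoder half of the autoencoder:
#' `h^(i) = tanh(W^(i) h^(i-1) + b^(i))` up to the code layer, whose
#' activation is the DDI relation embedding. With `training = TRUE`,
#' inverted dropout is applied to the hidden layer; at inference no units
#' are dropped. The code layer takes the magnitude of its tanh activation,
#' so codes are nonnegative.
#'
#' @param ae Autoencoder parameters (`$ae` element of `prd_params`).
#' @param s Binary label vector over the vocabulary.
#' @param dropout Dropout probability (used only when training).
#' @param training Apply dropout?
#' @return Numeric code vector of length `d`; every component lies in
#'   `[0, 1)` (and hence in the tanh range `(-1, 1)`).
#' @export
encode_labels <- function(ae, s, dropout = 0, training = FALSE) {
  mask1 <- NULL
  if (training && dropout > 0) {
    m <- length(ae$b[[1]])
    mask1 <- stats::rbinom(m, 1, 1 - dropout) / (1 - dropout)
  }
  fw <- ae_forward(ae, s, mask1 = mask1, mask3 = NULL)
  fw$l
}

#' Decode a relation embedding into label reconstruction scores
#'
#' Forward pass through the decoder half: a tanh hidden layer followed by a
#' logistic output layer, so each reconstructed component lies in `(0, 1)`.
#'
#' @param ae Autoencoder parameters.
#' @param l_emb Code vector of length `d`.
#' @return Numeric vector of length `|L|` with components in `(0, 1)`.
#' @export
decode_labels <- function(ae, l_emb) {
  ae_decode(ae, l_emb)$shat
}

#' Reconstruction weights for a sparse label vector
#'
#' Nonzero components receive weight `beta > 1`, zero components weight 1,
#' so the decoder is pushed to reconstruct the rare nonzero labels instead
#' of defaulting to zeros.
#'
#' @param s Binary label vector.
#' @param beta Weight on nonzero components, must exceed 1.
#' @return Numeric weight vector of the same length as `s`.
#' @export
reconstruction_weights <- function(s, beta) {
  if (beta <= 1) abort_typed("beta must be > 1", "prddi_domain_error")
  ifelse(s != 0, beta, 1)
}

#' Weighted reconstruction score
#'
#' `b3 - ||(s - shat) * x||` (Hadamard-weighted residual under the L1/L2
#' norm). Equals `b3` exactly when the reconstruction is perfect.
#'
#' @param s Binary label vector.
#' @param shat Reconstructed vector.
#' @param x Weight vector, as from [reconstruction_weights()].
#' @param b3 Bias constant.
#' @param norm `"L1"` or `"L2"`.
#' @return A single numeric score.
#' @export
reconstruction_score <- function(s, shat, x, b3, norm = "L1") {
  if (length(s) != length(shat) || length(s) != length(x)) {
    abort_typed("s, shat and x must have equal lengths", "prddi_shape_error")
  }
  b3 - residual_norm((s - shat) * x, norm)
}

# (entity, relation) pairs observed in the graph, used by the projection
# part of the soft constraints. Returns a list: per basic relation the
# entity ids seen with it, plus the drugs seen in DDI triples under "..ddi".
observed_projection_pairs <- function(kg) {
  obs <- list()
  if (nrow(kg$basic) > 0) {
    by_rel <- split(c(kg$basic$head, kg$basic$tail),
                    c(kg$basic$relation, kg$basic$relation))
    obs <- lapply(by_rel, unique)
  }
  obs[["..ddi"]] <- unique(c(kg$ddi$drug_u, kg$ddi$drug_v))
  obs
}

#' Soft-constraint regularizer
#'
#' Hinge penalties `max(0, ||x||^2 - 1)` summed over all entity vectors,
#' all basic-relation vectors, and the projections `e M_r` of every entity
#' observed with relation `r` in the graph (including the shared DDI
#' projection for drugs in DDI triples), scaled by `gamma`. Keeps embedding
#' norms near or below 1 during learning.
#'
#' @param params A `prd_params` object.
#' @param gamma Regularization weight.
#' @param kg The training `drug_kg` (defines which projections are
#'   observed). Optional: when `NULL`, only entity and relation norms are
#'   penalized.
#' @return A single numeric penalty (>= 0).
#' @export
regularizer <- function(params, gamma, kg = NULL) {
  if (gamma == 0) return(0)
  pen <- sum(pmax(0, rowSums(params$entity^2) - 1))
  if (nrow(params$relation) > 0) {
    pen <- pen + sum(pmax(0, rowSums(params$relation^2) - 1))
  }
  if (!is.null(kg)) {
    obs <- observed_projection_pairs(kg)
    for (rel in names(obs)) {
      ids <- obs[[rel]]
      if (length(ids) == 0) next
      M <- if (rel == "..ddi") params$proj_ddi else params$proj[[rel]]
      P <- params$entity[ids, , drop = FALSE] %*% M
      pen <- pen + sum(pmax(0, rowSums(P^2) - 1))
    }
  }
  gamma * pen
}
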