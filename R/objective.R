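# Training internals: index-based context, negative sampling, the joint
# negative-sampling objective and its analytic gradient.
#
# All id lookups are resolved to integer row indices once (build_ctx); the
# per-batch objective/gradient then runs on matrices only.

build_ctx <- function(kg, params, hp) {
  ent_ids <- rownames(params$entity)
  rel_ids <- rownames(params$relation)
  n_labels <- length(params$vocabulary)

  basic <- kg$basic
  basic_mat <- cbind(
    h = match(basic$head, ent_ids),
    r = match(basic$relation, rel_ids),
    t = match(basic$tail, ent_ids)
  )
  if (nrow(basic) > 0 && anyNA(basic_mat)) {
    abort_typed("KG references ids missing from the parameters",
                "prddi_lookup_error")
  }
  ddi <- kg$ddi
  ddi_u <- match(ddi$drug_u, ent_ids)
  ddi_v <- match(ddi$drug_v, ent_ids)
  if (nrow(ddi) > 0 && (anyNA(ddi_u) || anyNA(ddi_v))) {
    abort_typed("DDI triples reference unknown drugs", "prddi_lookup_error")
  }
  S <- if (nrow(ddi) > 0) {
    do.call(rbind, lapply(ddi$labels, vectorize_labels,
                          vocabulary = params$vocabulary))
  } else {
    matrix(0, 0, n_labels)
  }

  basic_keys <- if (nrow(basic) > 0) {
    paste(basic_mat[, 1], basic_mat[, 2], basic_mat[, 3])
  } else {
    character()
  }
  ddi_keys <- if (nrow(ddi) > 0) {
    unique(paste(pmin(ddi_u, ddi_v), pmax(ddi_u, ddi_v)))
  } else {
    character()
  }

  s_key <- if (nrow(S) > 0) apply(S, 1, paste, collapse = "") else character()

  drug_idx <- which(ent_ids %in% kg_drugs(kg))
  obs <- observed_projection_pairs(kg)
  obs_idx <- lapply(obs, function(ids) match(ids, ent_ids))

  label_flips <- hp$label_flips
  if (is.null(label_flips)) label_flips <- min(5L, max(1L, ceiling(n_labels / 10)))

  list(ent_ids = ent_ids, n_ent = length(ent_ids), rel_ids = rel_ids,
       n_rel = length(rel_ids), drug_idx = drug_idx,
       basic_mat = basic_mat, ddi_u = ddi_u, ddi_v = ddi_v, S = S,
       basic_keys = basic_keys, ddi_keys = ddi_keys, obs_idx = obs_idx,
       s_key = s_key, n_labels = n_labels,
       label_flips = as.integer(label_flips))
}

# Draw one set of c corrupted fillers for a basic triple slot, rejecting
# (when filtering is on) corruptions that reproduce the positive or any
# training triple.
draw_basic_negatives <- function(ctx, h, r, t, slot, c_neg, filter = TRUE) {
  if (c_neg == 0) return(integer())
  pool_n <- if (slot == "r") ctx$n_rel else ctx$n_ent
  if (slot == "r" && filter && pool_n < 2) return(integer())
  out <- integer(c_neg)
  filled <- 0L
  tries <- 0L
  while (filled < c_neg) {
    tries <- tries + 1L
    if (tries > 200L) {
      abort_typed("candidate set exhausted while sampling negatives",
                  "prddi_sampling_error")
    }
    cand <- sample.int(pool_n, c_neg - filled, replace = TRUE)
    if (filter) {
      keys <- switch(slot,
        h = paste(cand, r, t),
        r = paste(h, cand, t),
        t = paste(h, r, cand)
      )
      pos_key <- paste(h, r, t)
      ok <- !(keys %in% ctx$basic_keys) & keys != pos_key
      cand <- cand[ok]
    }
    n_take <- min(length(cand), c_neg - filled)
    if (n_take > 0) {
      out[(filled + 1):(filled + n_take)] <- cand[seq_len(n_take)]
      filled <- filled + n_take
    }
  }
  out
}

draw_ddi_negatives <- function(ctx, u, v, slot, c_neg, filter = TRUE) {
  if (c_neg == 0) return(integer())
  pool <- ctx$drug_idx
  out <- integer(c_neg)
  filled <- 0L
  tries <- 0L
  while (filled < c_neg) {
    tries <- tries + 1L
    if (tries > 200L) {
      abort_typed("candidate set exhausted while sampling negatives",
                  "prddi_sampling_error")
    }
    cand <- pool[sample.int(length(pool), c_neg - filled, replace = TRUE)]
    other <- if (slot == "u") v else u
    ok <- cand != other
    if (filter) {
      keys <- paste(pmin(cand, other), pmax(cand, other))
      ok <- ok & !(keys %in% ctx$ddi_keys)
    }
    cand <- cand[ok]
    n_take <- min(length(cand), c_neg - filled)
    if (n_take > 0) {
      out[(filled + 1):(filled + n_take)] <- cand[seq_len(n_take)]
      filled <- filled + n_take
    }
  }
  out
}

# Negative label vectors: flip `label_flips` random components of s.
draw_label_negatives <- function(s, c_neg, flips) {
  if (c_neg == 0) return(matrix(0, 0, length(s)))
  out <- matrix(rep(s, each = c_neg), nrow = c_neg)
  for (j in seq_len(c_neg)) {
    pos <- sample.int(length(s), flips)
    out[j, pos] <- 1 - out[j, pos]
  }
  out
}

#' Sample corrupted triples for negative sampling
#'
#' Replaces one slot of a triple with uniform draws from the appropriate
#' candidate set (all entities for basic-triple slots, all drugs for DDI
#' drug slots, all relations for the relation slot). Corruptions that
#' reproduce the positive triple or any training triple are rejected and
#' resampled when `filter` is `TRUE`.
#'
#' @param triple Named list: either `head`/`relation`/`tail` (basic) or
#'   `drug_u`/`drug_v` (DDI).
#' @param slot Slot to corrupt: `"head"`, `"relation"`, `"tail"`,
#'   `"drug_u"` or `"drug_v"`.
#' @param c_neg Number of corruptions.
#' @param kg Training `drug_kg` (defines candidate sets and the filter).
#' @param params A `prd_params` object (fixes the entity/relation indexing).
#' @param hp A [prd_hparams()] object.
#' @param filter Reject corruptions that exist in the training set.
#' @return A tibble of corrupted triples (same columns as the input kind).
#' @export
sample_negatives <- function(triple, slot, c_neg, kg, params,
                             hp = prd_hparams(), filter = hp$filter_corruptions) {
  ctx <- build_ctx(kg, params, hp)
  if (slot %in% c("head", "relation", "tail")) {
    h <- match(triple$head, ctx$ent_ids)
    r <- match(triple$relation, ctx$rel_ids)
    t <- match(triple$tail, ctx$ent_ids)
    if (anyNA(c(h, r, t))) abort_typed("unknown id in triple",
                                       "prddi_lookup_error")
    sl <- c(head = "h", relation = "r", tail = "t")[[slot]]
    neg <- draw_basic_negatives(ctx, h, r, t, sl, c_neg, filter)
    out <- tibble::tibble(
      head = if (sl == "h") ctx$ent_ids[neg] else rep(triple$head, length(neg)),
      relation = if (sl == "r") ctx$rel_ids[neg] else rep(triple$relation, length(neg)),
      tail = if (sl == "t") ctx$ent_ids[neg] else rep(triple$tail, length(neg))
    )
    return(out)
  }
  if (slot %in% c("drug_u", "drug_v")) {
    u <- match(triple$drug_u, ctx$ent_ids)
    v <- match(triple$drug_v, ctx$ent_ids)
    if (anyNA(c(u, v))) abort_typed("unknown drug in triple",
                                    "prddi_lookup_error")
    sl <- if (slot == "drug_u") "u" else "v"
    neg <- draw_ddi_negatives(ctx, u, v, sl, c_neg, filter)
    return(tibble::tibble(
      drug_u = if (sl == "u") ctx$ent_ids[neg] else rep(triple$drug_u, length(neg)),
      drug_v = if (sl == "v") ctx$ent_ids[neg] else rep(triple$drug_v, length(neg))
    ))
  }
  abort_typed("unknown slot", "prddi_domain_error")
}

#' Negative-sampling surrogate objective for one positive triple
#'
#' `log sigma(z(pos)) + sum_j log sigma(-z(neg_j))`: the sampled surrogate
#' that replaces the intractable softmax normalizer.
#'
#' @param params A `prd_params` object.
#' @param positive Named list with `head`, `relation`, `tail`.
#' @param negatives Tibble of corrupted triples (possibly empty), as from
#'   [sample_negatives()].
#' @param hp A [prd_hparams()] object.
#' @return A single finite numeric value.
#' @export
negative_sampling_objective <- function(params, positive, negatives, hp) {
  z_pos <- score_basic(params, positive$head, positive$relation,
                       positive$tail, hp)
  val <- log_sigmoid(z_pos)
  if (!is.null(negatives) && nrow(negatives) > 0) {
    z_neg <- vapply(seq_len(nrow(negatives)), function(j) {
      score_basic(params, negatives$head[j], negatives$relation[j],
                  negatives$tail[j], hp)
    }, numeric(1))
    val <- val + sum(log_sigmoid(-z_neg))
  }
  val
}

#' Assemble a training batch with pre-sampled negatives
#'
#' Draws the corrupted entities/relations/label vectors and the dropout
#' masks for one mini-batch from the current RNG state, so that the joint
#' objective evaluated on the batch is a deterministic function of the
#' parameters.
#'
#' @param kg Training `drug_kg`.
#' @param params A `prd_params` object.
#' @param hp A [prd_hparams()] object.
#' @param basic_idx,ddi_idx Integer row indices of `kg$basic` / `kg$ddi` to
#'   include; `NULL` selects all rows.
#' @param dropout Dropout probability used for the masks (default
#'   `hp$dropout`); set 0 for deterministic checks.
#' @return A `prd_batch` list, consumed by [joint_objective()].
#' @export
sample_training_batch <- function(kg, params, hp, basic_idx = NULL,
                                  ddi_idx = NULL, dropout = hp$dropout) {
  ctx <- build_ctx(kg, params, hp)
  sample_training_batch_ctx(ctx, params, hp, basic_idx, ddi_idx, dropout)
}

sample_training_batch_ctx <- function(ctx, params, hp, basic_idx = NULL,
                                      ddi_idx = NULL, dropout = hp$dropout) {
  if (is.null(basic_idx)) basic_idx <- seq_len(nrow(ctx$basic_mat))
  if (is.null(ddi_idx)) ddi_idx <- seq_along(ctx$ddi_u)
  c_neg <- hp$c_neg
  filter <- hp$filter_corruptions

  # draw n corruptions at once, redrawing the entries `bad_fn` flags
  redraw <- function(n, pool_n, bad_fn) {
    idx <- sample.int(pool_n, n, replace = TRUE)
    for (tries in seq_len(200)) {
      bad <- bad_fn(idx)
      if (!any(bad)) return(idx)
      idx[bad] <- sample.int(pool_n, sum(bad), replace = TRUE)
    }
    abort_typed("candidate set exhausted while sampling negatives",
                "prddi_sampling_error")
  }

  nb <- length(basic_idx)
  neg_h <- neg_r <- neg_t <- NULL
  if (nb > 0 && c_neg > 0) {
    bt <- ctx$basic_mat[basic_idx, , drop = FALSE]
    H <- rep(bt[, "h"], c_neg); R <- rep(bt[, "r"], c_neg)
    T <- rep(bt[, "t"], c_neg)
    neg_h <- matrix(redraw(nb * c_neg, ctx$n_ent, function(idx) {
      if (!filter) return(rep(FALSE, length(idx)))
      paste(idx, R, T) %in% ctx$basic_keys
    }), nb, c_neg)
    neg_t <- matrix(redraw(nb * c_neg, ctx$n_ent, function(idx) {
      if (!filter) return(rep(FALSE, length(idx)))
      paste(H, R, idx) %in% ctx$basic_keys
    }), nb, c_neg)
    if (ctx$n_rel >= 2 || !filter) {
      neg_r <- matrix(redraw(nb * c_neg, ctx$n_rel, function(idx) {
        if (!filter) return(rep(FALSE, length(idx)))
        paste(H, idx, T) %in% ctx$basic_keys
      }), nb, c_neg)
    }
  } else if (nb > 0) {
    neg_h <- neg_t <- matrix(0L, nb, 0)
  }

  nd <- length(ddi_idx)
  neg_u <- neg_v <- neg_l <- NULL
  neg_S <- vector("list", nd)
  if (nd > 0 && c_neg > 0) {
    u <- rep(ctx$ddi_u[ddi_idx], c_neg)
    v <- rep(ctx$ddi_v[ddi_idx], c_neg)
    n_drug <- length(ctx$drug_idx)
    neg_u <- matrix(ctx$drug_idx[redraw(nd * c_neg, n_drug, function(ii) {
      cand <- ctx$drug_idx[ii]
      bad <- cand == v
      if (filter) {
        bad <- bad | paste(pmin(cand, v), pmax(cand, v)) %in% ctx$ddi_keys
      }
      bad
    })], nd, c_neg)
    neg_v <- matrix(ctx$drug_idx[redraw(nd * c_neg, n_drug, function(ii) {
      cand <- ctx$drug_idx[ii]
      bad <- cand == u
      if (filter) {
        bad <- bad | paste(pmin(cand, u), pmax(cand, u)) %in% ctx$ddi_keys
      }
      bad
    })], nd, c_neg)
    # relation-slot corruption needs a second distinct observed label set
    if (length(unique(ctx$s_key)) >= 2 || !filter) {
      own <- rep(ctx$s_key[ddi_idx], c_neg)
      neg_l <- matrix(redraw(nd * c_neg, length(ctx$ddi_u), function(idx) {
        if (!filter) return(rep(FALSE, length(idx)))
        ctx$s_key[idx] == own
      }), nd, c_neg)
    }
  } else if (nd > 0) {
    neg_u <- neg_v <- matrix(0L, nd, 0)
  }
  for (i in seq_len(nd)) {
    neg_S[[i]] <- draw_label_negatives(ctx$S[ddi_idx[i], ], c_neg,
                                       ctx$label_flips)
  }

  # every distinct label set appearing in the batch is encoded once; dropout
  # masks are drawn per encoded column (and per decoded positive)
  enc_ids <- unique(c(ddi_idx, as.vector(neg_l)))
  pos_col <- match(ddi_idx, enc_ids)
  neg_l_col <- if (is.null(neg_l)) NULL else {
    matrix(match(as.vector(neg_l), enc_ids), nrow = nd)
  }
  mask1 <- vector("list", max(length(enc_ids), 1L))
  mask3 <- vector("list", max(nd, 1L))
  m_width <- length(params$ae$b[[1]])
  if (dropout > 0 && nd > 0) {
    for (j in seq_along(enc_ids)) {
      mask1[[j]] <- stats::rbinom(m_width, 1, 1 - dropout) / (1 - dropout)
    }
    for (j in seq_len(nd)) {
      mask3[[j]] <- stats::rbinom(m_width, 1, 1 - dropout) / (1 - dropout)
    }
  }

  structure(
    list(basic_idx = basic_idx, ddi_idx = ddi_idx,
         neg_h = neg_h, neg_r = neg_r, neg_t = neg_t,
         neg_u = neg_u, neg_v = neg_v, neg_l = neg_l, neg_S = neg_S,
         enc_ids = enc_ids, pos_col = pos_col, neg_l_col = neg_l_col,
         mask1 = mask1, mask3 = mask3, c_neg = c_neg),
    class = "prd_batch"
  )
}

zero_grad <- function(params) {
  list(
    entity = params$entity * 0,
    relation = params$relation * 0,
    proj = lapply(params$proj, function(M) M * 0),
    proj_ddi = params$proj_ddi * 0,
    ae = list(W = lapply(params$ae$W, function(W) W * 0),
              b = lapply(params$ae$b, function(b) b * 0))
  )
}

# rowsum() ordered by integer owner 1..n (rowsum sorts rownames as strings).
rowsum_by_owner <- function(X, owner, n) {
  agg <- rowsum(X, owner)
  agg[match(seq_len(n), as.integer(rownames(agg))), , drop = FALSE]
}

# Accumulate rows of `inc` into matrix rows `idx` of acc[[name]] (handles
# duplicated indices).
add_rows <- function(mat, idx, inc) {
  agg <- rowsum(inc, group = idx)
  rows <- as.integer(rownames(agg))
  mat[rows, ] <- mat[rows, , drop = FALSE] + agg
  mat
}

#' Joint objective (and gradient) of the embedding model on a batch
#'
#' The maximized objective combines, over the batch, the negative-sampling
#' surrogates of the basic-triple encoder (three corrupted slots per
#' triple), the DDI-triple encoder (corrupted drug slots, relation
#' embedding from the autoencoder code) and the weighted label
#' reconstruction (corrupted label vectors), minus `gamma` times the
#' soft-constraint penalty. With pre-sampled negatives in `batch` the value
#' is a deterministic, almost-everywhere differentiable function of the
#' parameters; `gradient = TRUE` also returns its exact analytic gradient.
#'
#' @param params A `prd_params` object.
#' @param batch A `prd_batch` from [sample_training_batch()].
#' @param kg The training `drug_kg` the batch was drawn from.
#' @param hp A [prd_hparams()] object.
#' @param gradient Also compute the gradient?
#' @return The objective value, or (with `gradient = TRUE`) a list with
#'   `value` and `grad` (same shapes as `params`).
#' @export
joint_objective <- function(params, batch, kg, hp, gradient = FALSE) {
  ctx <- build_ctx(kg, params, hp)
  joint_objective_ctx(params, batch, ctx, hp, gradient)
}

joint_objective_ctx <- function(params, batch, ctx, hp, gradient = FALSE) {
  E <- params$entity
  value <- 0
  grad <- if (gradient) zero_grad(params) else NULL
  norm <- hp$norm
  c_neg <- batch$c_neg

  row_norms <- function(X) {
    if (norm == "L1") rowSums(abs(X)) else sqrt(rowSums(X^2))
  }
  row_grads <- function(X, norms) {
    if (norm == "L1") sign(X) else X / pmax(norms, 1e-300)
  }

  ## ---- basic triples, grouped by relation ----
  nb <- length(batch$basic_idx)
  if (nb > 0) {
    bt <- ctx$basic_mat[batch$basic_idx, , drop = FALSE]
    n_slots <- 2 + as.integer(!is.null(batch$neg_r))
    for (r in unique(bt[, "r"])) {
      rows <- which(bt[, "r"] == r)
      n <- length(rows)
      rid <- ctx$rel_ids[r]
      M <- params$proj[[rid]]
      rvec <- params$relation[r, ]
      H <- bt[rows, "h"]; T <- bt[rows, "t"]
      HM <- E[H, , drop = FALSE] %*% M
      TM <- E[T, , drop = FALSE] %*% M
      rho <- sweep(HM - TM, 2, rvec, "+")
      nrm <- row_norms(rho)
      z_pos <- hp$b1 - nrm
      value <- value + n_slots * sum(log_sigmoid(z_pos))
      if (gradient) {
        wp <- n_slots * sigmoid(-z_pos)
        G <- row_grads(rho, nrm) * wp
        GM <- G %*% t(M)
        grad$entity <- add_rows(grad$entity, H, -GM)
        grad$entity <- add_rows(grad$entity, T, GM)
        grad$relation[r, ] <- grad$relation[r, ] - colSums(G)
        grad$proj[[rid]] <- grad$proj[[rid]] -
          crossprod(E[H, , drop = FALSE] - E[T, , drop = FALSE], G)
      }

      if (c_neg > 0) {
        # head corruptions
        idxn <- as.vector(batch$neg_h[rows, , drop = FALSE])
        owner <- rep(seq_len(n), times = c_neg)
        rho_n <- E[idxn, , drop = FALSE] %*% M +
          sweep(-TM, 2, rvec, "+")[owner, , drop = FALSE]
        nrm_n <- row_norms(rho_n)
        zn <- hp$b1 - nrm_n
        value <- value + sum(log_sigmoid(-zn))
        if (gradient) {
          Gw <- row_grads(rho_n, nrm_n) * (-sigmoid(zn))
          grad$entity <- add_rows(grad$entity, idxn, -(Gw %*% t(M)))
          GwM <- rowsum_by_owner(Gw %*% t(M), owner, n)
          grad$entity <- add_rows(grad$entity, T, GwM)
          grad$relation[r, ] <- grad$relation[r, ] - colSums(Gw)
          Hd <- E[idxn, , drop = FALSE] - E[T[owner], , drop = FALSE]
          grad$proj[[rid]] <- grad$proj[[rid]] - crossprod(Hd, Gw)
        }

        # tail corruptions
        idxn <- as.vector(batch$neg_t[rows, , drop = FALSE])
        rho_n <- -(E[idxn, , drop = FALSE] %*% M) +
          sweep(HM, 2, rvec, "+")[owner, , drop = FALSE]
        nrm_n <- row_norms(rho_n)
        zn <- hp$b1 - nrm_n
        value <- value + sum(log_sigmoid(-zn))
        if (gradient) {
          Gw <- row_grads(rho_n, nrm_n) * (-sigmoid(zn))
          grad$entity <- add_rows(grad$entity, idxn, Gw %*% t(M))
          GwM <- rowsum_by_owner(Gw %*% t(M), owner, n)
          grad$entity <- add_rows(grad$entity, H, -GwM)
          grad$relation[r, ] <- grad$relation[r, ] - colSums(Gw)
          Hd <- E[H[owner], , drop = FALSE] - E[idxn, , drop = FALSE]
          grad$proj[[rid]] <- grad$proj[[rid]] - crossprod(Hd, Gw)
        }
      }
    }

    # relation corruptions, grouped by the corrupted relation
    if (!is.null(batch$neg_r)) {
      flat_r <- as.vector(batch$neg_r)
      owner_all <- rep(seq_len(nb), times = c_neg)
      for (rp in unique(flat_r)) {
        sel <- flat_r == rp
        o <- owner_all[sel]
        rid2 <- ctx$rel_ids[rp]
        M2 <- params$proj[[rid2]]
        Ho <- bt[o, "h"]; To <- bt[o, "t"]
        rho2 <- sweep((E[Ho, , drop = FALSE] - E[To, , drop = FALSE]) %*% M2,
                      2, params$relation[rp, ], "+")
        nrm2 <- row_norms(rho2)
        z2 <- hp$b1 - nrm2
        value <- value + sum(log_sigmoid(-z2))
        if (gradient) {
          Gw <- row_grads(rho2, nrm2) * (-sigmoid(z2))
          GwM <- Gw %*% t(M2)
          grad$entity <- add_rows(grad$entity, Ho, -GwM)
          grad$entity <- add_rows(grad$entity, To, GwM)
          grad$relation[rp, ] <- grad$relation[rp, ] - colSums(Gw)
          Hd <- E[Ho, , drop = FALSE] - E[To, , drop = FALSE]
          grad$proj[[rid2]] <- grad$proj[[rid2]] - crossprod(Hd, Gw)
        }
      }
    }
  }

  ## ---- rich DDI triples (batched autoencoder, shared projection) ----
  nd <- length(batch$ddi_idx)
  if (nd > 0) {
    Ml <- params$proj_ddi
    ae <- params$ae
    u <- ctx$ddi_u[batch$ddi_idx]
    v <- ctx$ddi_v[batch$ddi_idx]
    enc_ids <- batch$enc_ids
    n_enc <- length(enc_ids)
    pos_col <- batch$pos_col
    Sb_all <- ctx$S[enc_ids, , drop = FALSE]            # n_enc x L
    Sb <- Sb_all[pos_col, , drop = FALSE]               # nd x L

    # batched encoder over every distinct label set in the batch
    M1 <- if (is.null(batch$mask1[[1]])) NULL else do.call(cbind, batch$mask1)
    M3 <- if (is.null(batch$mask3[[1]])) NULL else do.call(cbind, batch$mask3)
    A0 <- t(Sb_all)
    H1 <- tanh(ae$W[[1]] %*% A0 + ae$b[[1]])
    H1d <- if (is.null(M1)) H1 else H1 * M1
    T2 <- tanh(ae$W[[2]] %*% H1d + ae$b[[2]])
    Lc <- abs(T2)                                       # nonnegative code, d x n_enc
    # decoder applied to the positive columns only
    Lc_pos <- Lc[, pos_col, drop = FALSE]
    H3 <- tanh(ae$W[[3]] %*% Lc_pos + ae$b[[3]])
    H3d <- if (is.null(M3)) H3 else H3 * M3
    Shat <- sigmoid(ae$W[[4]] %*% H3d + ae$b[[4]])      # L x nd

    Lt <- t(Lc_pos)                                     # nd x d
    U <- E[u, , drop = FALSE] %*% Ml
    V <- E[v, , drop = FALSE] %*% Ml
    dL_all <- matrix(0, n_enc, ncol(Lt))
    dShat <- matrix(0, nrow(Shat), nd)
    n_slots_ddi <- 2 + as.integer(!is.null(batch$neg_l))

    rho <- U + Lt - V
    nrm <- row_norms(rho)
    z_pos <- hp$b2 - nrm
    value <- value + n_slots_ddi * sum(log_sigmoid(z_pos))
    if (gradient) {
      G <- row_grads(rho, nrm) * (n_slots_ddi * sigmoid(-z_pos))
      GM <- G %*% t(Ml)
      grad$entity <- add_rows(grad$entity, u, -GM)
      grad$entity <- add_rows(grad$entity, v, GM)
      grad$proj_ddi <- grad$proj_ddi -
        crossprod(E[u, , drop = FALSE] - E[v, , drop = FALSE], G)
      dL_all <- add_rows(dL_all, pos_col, -G)
    }

    if (batch$c_neg > 0) {
      owner <- rep(seq_len(nd), times = batch$c_neg)

      idxn <- as.vector(batch$neg_u)
      rho_n <- E[idxn, , drop = FALSE] %*% Ml + (Lt - V)[owner, , drop = FALSE]
      nrm_n <- row_norms(rho_n)
      zn <- hp$b2 - nrm_n
      value <- value + sum(log_sigmoid(-zn))
      if (gradient) {
        Gw <- row_grads(rho_n, nrm_n) * (-sigmoid(zn))
        grad$entity <- add_rows(grad$entity, idxn, -(Gw %*% t(Ml)))
        GwM <- rowsum_by_owner(Gw %*% t(Ml), owner, nd)
        grad$entity <- add_rows(grad$entity, v, GwM)
        dL_all <- add_rows(dL_all, pos_col, -rowsum_by_owner(Gw, owner, nd))
        Ud <- E[idxn, , drop = FALSE] - E[v[owner], , drop = FALSE]
        grad$proj_ddi <- grad$proj_ddi - crossprod(Ud, Gw)
      }

      idxn <- as.vector(batch$neg_v)
      rho_n <- -(E[idxn, , drop = FALSE] %*% Ml) + (U + Lt)[owner, , drop = FALSE]
      nrm_n <- row_norms(rho_n)
      zn <- hp$b2 - nrm_n
      value <- value + sum(log_sigmoid(-zn))
      if (gradient) {
        Gw <- row_grads(rho_n, nrm_n) * (-sigmoid(zn))
        grad$entity <- add_rows(grad$entity, idxn, Gw %*% t(Ml))
        GwM <- rowsum_by_owner(Gw %*% t(Ml), owner, nd)
        grad$entity <- add_rows(grad$entity, u, -GwM)
        dL_all <- add_rows(dL_all, pos_col, -rowsum_by_owner(Gw, owner, nd))
        Vd <- E[u[owner], , drop = FALSE] - E[idxn, , drop = FALSE]
        grad$proj_ddi <- grad$proj_ddi - crossprod(Vd, Gw)
      }

      # relation-slot corruption: codes of other observed label sets
      if (!is.null(batch$neg_l)) {
        cols <- as.vector(batch$neg_l_col)
        rho_n <- (U - V)[owner, , drop = FALSE] + t(Lc)[cols, , drop = FALSE]
        nrm_n <- row_norms(rho_n)
        zn <- hp$b2 - nrm_n
        value <- value + sum(log_sigmoid(-zn))
        if (gradient) {
          Gw <- row_grads(rho_n, nrm_n) * (-sigmoid(zn))
          GwM <- rowsum_by_owner(Gw %*% t(Ml), owner, nd)
          grad$entity <- add_rows(grad$entity, u, -GwM)
          grad$entity <- add_rows(grad$entity, v, GwM)
          Dd <- E[u[owner], , drop = FALSE] - E[v[owner], , drop = FALSE]
          grad$proj_ddi <- grad$proj_ddi - crossprod(Dd, Gw)
          dL_all <- add_rows(dL_all, cols, -Gw)
        }
      }
    }

    # weighted reconstruction with corrupted label vectors as negatives
    for (ii in seq_len(nd)) {
      s <- Sb[ii, ]
      shat <- Shat[, ii]
      x <- reconstruction_weights(s, hp$beta)
      rho_r <- (s - shat) * x
      z_r <- hp$b3 - residual_norm(rho_r, norm)
      value <- value + log_sigmoid(z_r)
      if (gradient) {
        dShat[, ii] <- dShat[, ii] +
          sigmoid(-z_r) * (residual_norm_grad(rho_r, norm) * x)
      }
      Sn <- batch$neg_S[[ii]]
      if (nrow(Sn) > 0) {
        Xn <- ifelse(Sn != 0, hp$beta, 1)
        Rho <- sweep(Sn, 2, shat, "-") * Xn
        nrm_r <- row_norms(Rho)
        z_j <- hp$b3 - nrm_r
        value <- value + sum(log_sigmoid(-z_j))
        if (gradient) {
          Gj <- row_grads(Rho, nrm_r) * (-sigmoid(z_j))
          dShat[, ii] <- dShat[, ii] + colSums(Gj * Xn)
        }
      }
    }

    # backprop: decoder over positive columns, encoder over all columns
    if (gradient) {
      dZ4 <- dShat * Shat * (1 - Shat)                  # L x nd
      grad$ae$W[[4]] <- grad$ae$W[[4]] + dZ4 %*% t(H3d)
      grad$ae$b[[4]] <- grad$ae$b[[4]] + rowSums(dZ4)
      dH3d <- crossprod(ae$W[[4]], dZ4)
      dH3 <- if (is.null(M3)) dH3d else dH3d * M3
      dZ3 <- dH3 * (1 - H3^2)
      grad$ae$W[[3]] <- grad$ae$W[[3]] + dZ3 %*% t(Lc_pos)
      grad$ae$b[[3]] <- grad$ae$b[[3]] + rowSums(dZ3)
      dLc_dec <- crossprod(ae$W[[3]], dZ3)              # d x nd
      dL_all <- add_rows(dL_all, pos_col, t(dLc_dec))

      dLc_all <- t(dL_all)                              # d x n_enc
      dZ2 <- dLc_all * sign(T2) * (1 - T2^2)
      grad$ae$W[[2]] <- grad$ae$W[[2]] + dZ2 %*% t(H1d)
      grad$ae$b[[2]] <- grad$ae$b[[2]] + rowSums(dZ2)
      dH1d <- crossprod(ae$W[[2]], dZ2)
      dH1 <- if (is.null(M1)) dH1d else dH1d * M1
      dZ1 <- dH1 * (1 - H1^2)
      grad$ae$W[[1]] <- grad$ae$W[[1]] + dZ1 %*% Sb_all
      grad$ae$b[[1]] <- grad$ae$b[[1]] + rowSums(dZ1)
    }
  }

  ## ---- soft constraints (subtracted) ----
  if (hp$gamma > 0) {
    gam <- hp$gamma
    sq <- rowSums(E^2)
    act <- sq > 1
    value <- value - gam * sum(sq[act] - 1)
    if (gradient && any(act)) {
      grad$entity[act, ] <- grad$entity[act, ] - gam * 2 * E[act, , drop = FALSE]
    }
    if (nrow(params$relation) > 0) {
      sqr <- rowSums(params$relation^2)
      actr <- sqr > 1
      value <- value - gam * sum(sqr[actr] - 1)
      if (gradient && any(actr)) {
        grad$relation[actr, ] <- grad$relation[actr, ] -
          gam * 2 * params$relation[actr, , drop = FALSE]
      }
    }
    for (rel in names(ctx$obs_idx)) {
      ids <- ctx$obs_idx[[rel]]
      if (length(ids) == 0) next
      M <- if (rel == "..ddi") params$proj_ddi else params$proj[[rel]]
      P <- E[ids, , drop = FALSE] %*% M
      sqp <- rowSums(P^2)
      actp <- sqp > 1
      value <- value - gam * sum(sqp[actp] - 1)
      if (gradient && any(actp)) {
        Pa <- P[actp, , drop = FALSE]
        Ea <- E[ids[actp], , drop = FALSE]
        grad$entity <- add_rows(grad$entity, ids[actp],
                                -gam * 2 * (Pa %*% t(M)))
        dM <- -gam * 2 * (t(Ea) %*% Pa)
        if (rel == "..ddi") {
          grad$proj_ddi <- grad$proj_ddi + dM
        } else {
          grad$proj[[rel]] <- grad$proj[[rel]] + dM
        }
      }
    }
  }

  if (gradient) list(value = value, grad = grad) else value
}

# Flatten parameters (or a same-shaped gradient) to one numeric vector, and
# back. Used by the finite-difference checks and by Adam bookkeeping tests.
params_flatten <- function(params) {
  c(as.numeric(params$entity), as.numeric(params$relation),
    unlist(lapply(params$proj, as.numeric), use.names = FALSE),
    as.numeric(params$proj_ddi),
    unlist(lapply(params$ae$W, as.numeric), use.names = FALSE),
    unlist(lapply(params$ae$b, as.numeric), use.names = FALSE))
}

params_unflatten <- function(flat, skeleton) {
  out <- skeleton
  pos <- 0L
  take <- function(n) {
    v <- flat[(pos + 1):(pos + n)]
    pos <<- pos + n
    v
  }
  out$entity[] <- take(length(skeleton$entity))
  if (length(skeleton$relation) > 0) out$relation[] <- take(length(skeleton$relation))
  for (r in names(skeleton$proj)) out$proj[[r]][] <- take(length(skeleton$proj[[r]]))
  out$proj_ddi[] <- take(length(skeleton$proj_ddi))
  for (i in 1:4) out$ae$W[[i]][] <- take(length(skeleton$ae$W[[i]]))
  for (i in 1:4) out$ae$b[[i]][] <- take(length(skeleton$ae$b[[i]]))
  out
}
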