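# Adam state mirrors the parameter structure; step() updates in place
# (ascent: the objective is maximized).

adam_init <- function(params) {
  list(m = zero_grad(params), v = zero_grad(params), t = 0L)
}

adam_step_array <- function(theta, g, m, v, t, lr, beta1 = 0.9,
                            beta2 = 0.999, eps = 1e-8) {
  m <- beta1 * m + (1 - beta1) * g
  v <- beta2 * v + (1 - beta2) * g^2
  mhat <- m / (1 - beta1^t)
  vhat <- v / (1 - beta2^t)
  theta <- theta + lr * mhat / (sqrt(vhat) + eps)
  list(theta = theta, m = m, v = v)
}

adam_step <- function(params, grad, state, lr) {
  state$t <- state$t + 1L
  t <- state$t
  upd <- adam_step_array(params$entity, grad$entity, state$m$entity,
                         state$v$entity, t, lr)
  params$entity <- upd$theta; state$m$entity <- upd$m; state$v$entity <- upd$v
  if (length(params$relation) > 0) {
    upd <- adam_step_array(params$relation, grad$relation, state$m$relation,
                           state$v$relation, t, lr)
    params$relation <- upd$theta; state$m$relation <- upd$m
    state$v$relation <- upd$v
  }
  for (r in names(params$proj)) {
    upd <- adam_step_array(params$proj[[r]], grad$proj[[r]],
                           state$m$proj[[r]], state$v$proj[[r]], t, lr)
    params$proj[[r]] <- upd$theta; state$m$proj[[r]] <- upd$m
    state$v$proj[[r]] <- upd$v
  }
  upd <- adam_step_array(params$proj_ddi, grad$proj_ddi, state$m$proj_ddi,
                         state$v$proj_ddi, t, lr)
  params$proj_ddi <- upd$theta; state$m$proj_ddi <- upd$m
  state$v$proj_ddi <- upd$v
  for (i in 1:4) {
    upd <- adam_step_array(params$ae$W[[i]], grad$ae$W[[i]],
                           state$m$ae$W[[i]], state$v$ae$W[[i]], t, lr)
    params$ae$W[[i]] <- upd$theta; state$m$ae$W[[i]] <- upd$m
    state$v$ae$W[[i]] <- upd$v
    upd <- adam_step_array(params$ae$b[[i]], grad$ae$b[[i]],
                           state$m$ae$b[[i]], state$v$ae$b[[i]], t, lr)
    params$ae$b[[i]] <- upd$theta; state$m$ae$b[[i]] <- upd$m
    state$v$ae$b[[i]] <- upd$v
  }
  list(params = params, state = state)
}

#' Train the joint embedding model
#'
#' Maximizes the joint negative-sampling objective with Adam over random
#' mini-batches: each iteration draws `batch_size` positives, split
#' proportionally between basic and DDI triples, samples `c_neg`
#' corruptions per positive and slot, applies dropout to the autoencoder
#' hidden layers, and takes one ascent step. The returned parameters are
#' the tail average (Polyak averaging) of the iterates over the final
#' quarter of training, which removes most of the stochastic-gradient
#' jitter of the sign (L1) gradients. Fully reproducible given `hp$seed`.
#'
#' @param kg Training `drug_kg` with at least one basic and one DDI triple.
#' @param hp A [prd_hparams()] object.
#' @param verbose Print progress every 100 iterations.
#' @return A `prd_model`: list with `params`, `hp`, `trace` (tibble of
#'   `iteration`, `objective`), `vocabulary` and `drugs`.
#' @export
prd_train <- function(kg, hp = prd_hparams(), verbose = FALSE) {
  if (nrow(kg$basic) < 1 || nrow(kg$ddi) < 1) {
    abort_typed("training needs at least one basic and one DDI triple",
                "prddi_domain_error")
  }
  params <- prd_init_params(kg, hp)
  ctx <- build_ctx(kg, params, hp)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(hp$seed)

  n_basic <- nrow(kg$basic)
  n_ddi <- nrow(kg$ddi)
  n_tot <- n_basic + n_ddi
  nb <- max(1L, round(hp$batch_size * n_basic / n_tot))
  nd <- max(1L, hp$batch_size - nb)

  state <- adam_init(params)
  trace <- numeric(hp$iterations)
  avg_start <- max(1L, hp$iterations - floor(hp$iterations / 4) + 1L)
  avg <- NULL
  n_avg <- 0L
  for (it in seq_len(hp$iterations)) {
    basic_idx <- sample.int(n_basic, min(nb, n_basic))
    ddi_idx <- sample.int(n_ddi, min(nd, n_ddi))
    batch <- sample_training_batch_ctx(ctx, params, hp, basic_idx, ddi_idx,
                                       dropout = hp$dropout)
    og <- joint_objective_ctx(params, batch, ctx, hp, gradient = TRUE)
    if (!is.finite(og$value)) {
      abort_typed(paste0("objective diverged (non-finite) at iteration ", it),
                  "prddi_divergence_error")
    }
    trace[it] <- og$value
    stepped <- adam_step(params, og$grad, state, hp$lr)
    params <- stepped$params
    state <- stepped$state
    if (it >= avg_start) {
      flat <- params_flatten(params)
      avg <- if (is.null(avg)) flat else avg + flat
      n_avg <- n_avg + 1L
    }
    if (verbose && it %% 100 == 0) {
      message(sprintf("iteration %d  objective %.3f", it, og$value))
    }
  }

  if (n_avg > 0) {
    params <- params_unflatten(avg / n_avg, params)
  }

  structure(
    list(params = params, hp = hp,
         trace = tibble::tibble(iteration = seq_len(hp$iterations),
                                objective = trace),
         vocabulary = label_vocabulary(params$vocabulary),
         drugs = kg_drugs(kg)),
    class = "prd_model"
  )
}

#' @export
print.prd_model <- function(x, ...) {
  cat("<prd_model>\n")
  cat("  entities:", nrow(x$params$entity),
      " relations:", nrow(x$params$relation), "\n")
  cat("  dimensions: k =", x$hp$k, " d =", x$hp$d,
      " norm =", x$hp$norm, "\n")
  cat("  vocabulary:", length(x$vocabulary), "labels\n")
  cat("  iterations:", x$hp$iterations,
      " final objective:", round(utils::tail(x$trace$objective, 1), 3), "\n")
  invisible(x)
}

#' Tidy the components of a fitted joint embedding model
#'
#' @param x A `prd_model`.
#' @param what `"entities"` (one row per entity with its embedding norm),
#'   `"relations"`, or `"trace"` (per-iteration objective values).
#' @param ... Unused.
#' @return A tibble.
#' @method tidy prd_model
#' @export
tidy.prd_model <- function(x, what = c("entities", "relations", "trace"),
                           ...) {
  what <- match.arg(what)
  if (what == "trace") return(x$trace)
  if (what == "relations") {
    return(tibble::tibble(
      relation = rownames(x$params$relation),
      norm = sqrt(rowSums(x$params$relation^2))
    ))
  }
  tibble::tibble(
    id = rownames(x$params$entity),
    kind = ifelse(rownames(x$params$entity) %in% x$drugs, "drug", "other"),
    norm = sqrt(rowSums(x$params$entity^2))
  )
}

#' One-row summary of a fitted joint embedding model
#'
#' @param x A `prd_model`.
#' @param ... Unused.
#' @return A one-row tibble with model sizes, the final and smoothed final
#'   objective, and key hyperparameters.
#' @method glance prd_model
#' @export
glance.prd_model <- function(x, ...) {
  obj <- x$trace$objective
  tibble::tibble(
    n_entities = nrow(x$params$entity),
    n_relations = nrow(x$params$relation),
    n_labels = length(x$vocabulary),
    k = x$hp$k, d = x$hp$d, norm = x$hp$norm,
    iterations = x$hp$iterations,
    final_objective = utils::tail(obj, 1),
    final_objective_smoothed = mean(utils::tail(obj, 10))
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Save / load a model checkpoint
#'
#' The checkpoint is a single RDS archive holding all parameter arrays, the
#' hyperparameter record, the vocabulary and a format tag; the round-trip
#' is bit-exact.
#'
#' @param model A `prd_model`.
#' @param path Checkpoint path.
#' @return `save_prd_model()` the path invisibly; `load_prd_model()` the
#'   model.
#' @export
save_prd_model <- function(model, path) {
  saveRDS(list(format = "prddi-checkpoint-1", model = model), path)
  invisible(path)
}

#' @rdname save_prd_model
#' @export
load_prd_model <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "prddi-checkpoint-1")) {
    abort_typed("not a prddi checkpoint", "prddi_parse_error")
  }
  obj$model
}
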