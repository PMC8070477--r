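# Training recipe: smooth L1 loss, Adam with a stepped learning-rate
# schedule, seeded shuffling, and optional best-on-validation checkpointing.

#' Smooth L1 (Huber, beta = 1) regression loss
#'
#' Mean over samples of `0.5 * r^2` when `|r| < 1` and `|r| - 0.5`
#' otherwise, with `r = pred - true`: quadratic near zero like L2, linear in
#' the tails like L1.
#'
#' @param pred,true Equal-length numeric vectors.
#' @return Scalar loss.
#' @export
smooth_l1 <- function(pred, true) {
  if (length(pred) == 0L) stopf("smooth_l1 needs at least one sample")
  if (length(pred) != length(true)) stopf("pred and true lengths differ")
  r <- abs(pred - true)
  mean(ifelse(r < 1, 0.5 * r^2, r - 0.5))
}

#' Training control parameters
#'
#' @param lr Initial learning rate (default `1e-4`).
#' @param lr_step Epochs between learning-rate decays (default 20).
#' @param lr_gamma Multiplicative decay factor per step (default 0.5).
#' @param epochs Number of epochs (default 200).
#' @param batch_size Mini-batch size (default 32).
#' @param seed Seed controlling initialization and shuffling (default 1).
#' @param verbose Print a progress line every `verbose` epochs; 0 is silent.
#' @return List of class `apmnet_control`.
#' @export
apmnet_control <- function(lr = 1e-4, lr_step = 20L, lr_gamma = 0.5,
                           epochs = 200L, batch_size = 32L, seed = 1L,
                           verbose = 0L) {
  if (!is.numeric(lr) || lr < 0) stopf("lr must be >= 0")
  if (!is_count(lr_step, 1L)) stopf("lr_step must be >= 1")
  if (!is_count(epochs, 1L) || !is_count(batch_size, 1L))
    stopf("epochs and batch_size must be positive integers")
  structure(list(lr = lr, lr_step = as.integer(lr_step), lr_gamma = lr_gamma,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 seed = as.integer(seed), verbose = as.integer(verbose)),
            class = "apmnet_control")
}

adam_init <- function(params) {
  zeros <- function(x) x * 0
  list(m = map_leaves(zeros, params), v = map_leaves(zeros, params), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- map_leaves(function(m, g) beta1 * m + (1 - beta1) * g, state$m, grads)
  state$v <- map_leaves(function(v, g) beta2 * v + (1 - beta2) * g^2, state$v, grads)
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  params <- map_leaves(function(p, m, v) p - lr * (m / c1) / (sqrt(v / c2) + eps),
                       params, state$m, state$v)
  list(params = params, state = state)
}

predict_prepped <- function(params, cfg, preps, chunk = 64L) {
  idx <- split(seq_along(preps), ceiling(seq_along(preps) / chunk))
  unlist(lapply(idx, function(ii) {
    forward_core(params, cfg, collate_batch(preps[ii]))
  }), use.names = FALSE)
}

# Core training loop over prepped graphs (see prep_graph). Returns final (or
# best-validation) parameters plus per-epoch traces. Deterministic given the
# control seed on a fixed platform.
train_core <- function(preps, cfg, control, preps_val = NULL, params = NULL) {
  n <- length(preps)
  if (n == 0L) stopf("training set is empty")
  y <- vapply(preps, `[[`, 0, "label")
  if (any(!is.finite(y))) stopf("all training complexes need finite labels")
  if (is.null(params)) params <- init_params(cfg, seed = control$seed)
  state <- adam_init(params)
  trace <- numeric(control$epochs)
  val_rmse <- if (is.null(preps_val)) NULL else rep(NA_real_, control$epochs)
  best <- list(params = params, rmse = Inf, epoch = 0L)
  with_seed(control$seed, {
    for (epoch in seq_len(control$epochs)) {
      lr_e <- control$lr * control$lr_gamma^((epoch - 1L) %/% control$lr_step)
      ord <- sample.int(n)
      batches <- split(ord, ceiling(seq_along(ord) / control$batch_size))
      tot <- 0
      for (b in batches) {
        fb <- loss_and_grads(params, cfg, collate_batch(preps[b]))
        if (!is.finite(fb$loss))
          stopf("training diverged (non-finite loss) at epoch %d", epoch)
        upd <- adam_step(params, fb$grads, state, lr_e)
        params <- upd$params; state <- upd$state
        tot <- tot + fb$loss * length(b)
      }
      trace[epoch] <- tot / n
      if (!is.null(preps_val)) {
        pv <- predict_prepped(params, cfg, preps_val)
        yv <- vapply(preps_val, `[[`, 0, "label")
        rmse <- sqrt(mean((pv - yv)^2))
        val_rmse[epoch] <- rmse
        if (rmse < best$rmse) best <- list(params = params, rmse = rmse, epoch = epoch)
      }
      if (control$verbose > 0L && epoch %% control$verbose == 0L)
        message(sprintf("epoch %4d  loss %.5f  lr %.2e%s", epoch, trace[epoch], lr_e,
                        if (is.null(preps_val)) "" else
                          sprintf("  val RMSE %.4f", val_rmse[epoch])))
    }
  })
  if (!is.null(preps_val) && best$epoch > 0L) {
    list(params = best$params, trace = trace, val_rmse = val_rmse,
         best_epoch = best$epoch, final_params = params)
  } else {
    list(params = params, trace = trace, val_rmse = val_rmse,
         best_epoch = control$epochs, final_params = params)
  }
}

#' PDBbind-style train/validation/test splits
#'
#' The test set is the core-set ids; the validation set is a seeded random
#' sample of `n_val` complexes from the remaining (refined) ids; everything
#' else trains, minus any overlap with an external benchmark id list
#' (`casf_ids`), which is removed from the training set so no external test
#' complex leaks into training.
#'
#' @param ids Character vector of all complex ids (e.g. `index$id` from
#'   [read_pdbbind_index()]).
#' @param core_ids Ids forming the held-out test set; must be a subset of
#'   `ids`.
#' @param casf_ids Ids of an external benchmark to deduplicate away from the
#'   training set (default none).
#' @param n_val Validation-set size.
#' @param seed Seed for the validation draw.
#' @return List of class `split_spec` with `train_ids`, `val_ids`,
#'   `test_ids`, `extra_test_ids`; pairwise disjoint.
#' @export
make_splits <- function(ids, core_ids, casf_ids = character(0), n_val, seed = 1L) {
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stopf("ids must be unique")
  if (!all(core_ids %in% ids)) stopf("core_ids must be a subset of ids")
  pool <- setdiff(ids, core_ids)
  if (n_val > length(pool))
    stopf("n_val = %d exceeds the %d available non-core complexes", n_val, length(pool))
  val <- with_seed(seed, sample(pool, n_val))
  train <- setdiff(setdiff(pool, val), casf_ids)
  structure(list(train_ids = train, val_ids = val,
                 test_ids = as.character(core_ids),
                 extra_test_ids = intersect(casf_ids, ids)),
            class = "split_spec")
}

#' @export
print.split_spec <- function(x, ...) {
  cat(sprintf("<split_spec: %d train / %d val / %d test / %d extra-test>\n",
              length(x$train_ids), length(x$val_ids), length(x$test_ids),
              length(x$extra_test_ids)))
  invisible(x)
}
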