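# User-facing fitting interface: apmnet() and its S3 methods.

#' Fit the cascade graph network to labelled complexes
#'
#' Trains the full pipeline - linear embedding, ARMA graph-convolution
#' stacks, edge-conditioned message passing, global add pooling and a dense
#' head - to regress pKa from complex graphs, using smooth L1 loss, Adam and
#' a stepped learning-rate schedule with Glorot-initialized weights. When a
#' validation set is supplied, the parameters with the best validation RMSE
#' are retained; otherwise the final-epoch parameters are returned.
#'
#' @param complexes List of `complex_graph` objects (see [build_complex()]).
#' @param labels Optional numeric pKa labels; defaults to the labels stored
#'   in the complexes.
#' @param config An [apmnet_config()].
#' @param control An [apmnet_control()]; its `seed` drives initialization
#'   and shuffling.
#' @param validation Optional list of labelled `complex_graph` objects used
#'   for model selection.
#' @return An object of class `apmnet` with components `params`, `config`,
#'   `control`, `loss_trace`, `val_rmse`, `best_epoch`, `fitted_values`,
#'   `y`, `ids`, `call`. Supports `print`, `summary`, `coef`, `predict`,
#'   `fitted`, `residuals` and `plot`.
#' @examples
#' spec <- synthetic_spec(n_complexes = 24, noise_sd = 0)
#' cplx <- synthetic_dataset(spec)
#' fit <- apmnet(cplx, config = apmnet_config(embed_dim = 8, arma_layers = 1,
#'                                            arma_stacks = 1),
#'               control = apmnet_control(epochs = 3, lr = 1e-3, seed = 1))
#' predict(fit, cplx[1:3])
#' @export
apmnet <- function(complexes, labels = NULL, config = apmnet_config(),
                   control = apmnet_control(), validation = NULL) {
  stopifnot(inherits(config, "apmnet_config"), inherits(control, "apmnet_control"))
  if (!length(complexes)) stopf("no training complexes supplied")
  preps <- lapply(complexes, prep_graph)
  if (!is.null(labels)) {
    if (length(labels) != length(preps)) stopf("labels length must match complexes")
    for (i in seq_along(preps)) preps[[i]]$label <- as.numeric(labels[i])
  }
  preps_val <- if (is.null(validation)) NULL else lapply(validation, prep_graph)
  res <- train_core(preps, config, control, preps_val)
  fitted <- predict_prepped(res$params, config, preps)
  structure(list(params = res$params, config = config, control = control,
                 loss_trace = res$trace, val_rmse = res$val_rmse,
                 best_epoch = res$best_epoch, fitted_values = fitted,
                 y = vapply(preps, `[[`, 0, "label"),
                 ids = vapply(preps, `[[`, "", "id"),
                 call = match.call()),
            class = "apmnet")
}

#' @export
print.apmnet <- function(x, ...) {
  cfg <- x$config
  cat("Cascade graph-convolution affinity model\n")
  cat(sprintf("  variant %s | embed %d | ARMA %d stacks x %d layers | MPNN %d layer(s)\n",
              cfg$variant, cfg$embed_dim, cfg$arma_stacks, cfg$arma_layers,
              if (use_mpnn(cfg)) cfg$mpnn_layers else 0L))
  cat(sprintf("  trained %d epochs on %d complexes; final loss %.4f\n",
              length(x$loss_trace), length(x$y), utils::tail(x$loss_trace, 1)))
  if (!is.null(x$val_rmse))
    cat(sprintf("  best validation RMSE %.4f at epoch %d\n",
                min(x$val_rmse, na.rm = TRUE), x$best_epoch))
  invisible(x)
}

#' @export
summary.apmnet <- function(object, ...) {
  rep <- evaluate_predictions(object$fitted_values, object$y)
  out <- list(fit = object, train_metrics = rep,
              n_params = length(leaves(object$params)))
  class(out) <- "summary.apmnet"
  out
}

#' @export
print.summary.apmnet <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  %d trainable parameters\nTraining-set metrics:\n", x$n_params))
  print(x$train_metrics)
  invisible(x)
}

#' Predict pKa for new complexes
#'
#' @param object A fitted `apmnet` model.
#' @param newdata List of `complex_graph` (or `molgraph`) objects.
#' @param ... Unused.
#' @return Numeric vector of predicted pKa values.
#' @export
predict.apmnet <- function(object, newdata, ...) {
  if (inherits(newdata, c("complex_graph", "molgraph"))) newdata <- list(newdata)
  predict_prepped(object$params, object$config, lapply(newdata, prep_graph))
}

#' @export
coef.apmnet <- function(object, ...) object$params

#' @export
fitted.apmnet <- function(object, ...) object$fitted_values

#' @export
residuals.apmnet <- function(object, ...) object$y - object$fitted_values

#' Plot the training loss trace
#'
#' @param x A fitted `apmnet` model.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.apmnet <- function(x, ...) {
  graphics::plot(seq_along(x$loss_trace), x$loss_trace, type = "l",
                 xlab = "epoch", ylab = "smooth L1 loss",
                 main = "Training loss", ...)
  if (!is.null(x$val_rmse)) {
    graphics::lines(seq_along(x$val_rmse), x$val_rmse, lty = 2)
    graphics::legend("topright", legend = c("train loss", "validation RMSE"),
                     lty = c(1, 2), bty = "n")
  }
  invisible(x)
}

# ---- checkpointing ----

leaf_to_plain <- function(x) {
  if (is.list(x)) lapply(x, leaf_to_plain)
  else list(.dim = dim(x) %||% length(x), .data = as.vector(x))
}

plain_to_leaf <- function(x) {
  if (is.list(x) && identical(sort(names(x)), c(".data", ".dim"))) {
    d <- as.integer(unlist(x$.dim))
    v <- as.numeric(unlist(x$.data))
    if (length(d) == 2L) matrix(v, d[1], d[2]) else v
  } else {
    lapply(x, plain_to_leaf)
  }
}

#' Save a fitted model (or bare parameter set) to a portable JSON checkpoint
#'
#' The checkpoint stores the configuration, the parameters at full double
#' precision and an MD5 fingerprint of the canonical YAML form of the
#' configuration, so a loaded checkpoint can be verified against the config
#' it was trained with.
#'
#' @param object An `apmnet` fit, or a list with elements `params` and
#'   `config`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_apmnet <- function(object, path) {
  cfg <- object$config
  stopifnot(inherits(cfg, "apmnet_config"))
  obj <- list(format = "apmnet-checkpoint-1",
              config = unclass(cfg),
              config_md5 = config_hash(cfg),
              params = leaf_to_plain(unclass(object$params)),
              loss_trace = object$loss_trace)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Load a checkpoint written by [save_apmnet()]
#'
#' @param path Checkpoint file path.
#' @return List with `params` (class `apmnet_params`), `config` and
#'   `loss_trace`; usable with [apmnet_forward()] or as a warm start.
#' @export
load_apmnet <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(obj$format, "apmnet-checkpoint-1"))
    stopf("'%s' is not an apmnet checkpoint", path)
  cfg <- do.call(apmnet_config, obj$config[setdiff(names(obj$config), character(0))])
  if (!identical(config_hash(cfg), obj$config_md5))
    stopf("checkpoint config hash mismatch; file may be corrupted")
  list(params = structure(plain_to_leaf(obj$params), class = "apmnet_params"),
       config = cfg,
       loss_trace = as.numeric(unlist(obj$loss_trace)))
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(unclass(cfg)), tmp)
  unname(tools::md5sum(tmp))
}
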