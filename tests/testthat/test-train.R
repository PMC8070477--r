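# Loss, optimizer behaviour, splits, metrics, ranking power.

test_that("smooth L1 matches its closed form", {
  expect_equal(smooth_l1(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(smooth_l1(0.5, 0), 0.125)
  expect_equal(smooth_l1(3, 0), 2.5)
  expect_equal(smooth_l1(c(0.5, 3), c(0, 0)), (0.125 + 2.5) / 2)
  expect_error(smooth_l1(numeric(0), numeric(0)), "at least one")
  expect_error(smooth_l1(1:3, 1:2), "lengths")
})

test_that("a zero learning rate leaves the initial parameters untouched", {
  cfg <- tiny_model_cfg()
  cplx <- tiny_complexes(6, seed = 37)
  fit <- apmnet(cplx, config = cfg,
                control = apmnet_control(lr = 0, epochs = 3, seed = 2))
  expect_equal(apmnet:::leaves(fit$params),
               apmnet:::leaves(init_params(cfg, seed = 2)))
})

test_that("training is deterministic given the seed", {
  cfg <- tiny_model_cfg()
  cplx <- tiny_complexes(8, seed = 43)
  ctl <- apmnet_control(lr = 1e-3, epochs = 4, batch_size = 4, seed = 11)
  f1 <- apmnet(cplx, config = cfg, control = ctl)
  f2 <- apmnet(cplx, config = cfg, control = ctl)
  expect_identical(f1$loss_trace, f2$loss_trace)
  expect_identical(apmnet:::leaves(f1$params), apmnet:::leaves(f2$params))
})

test_that("the network overfits a small planted-affinity set", {
  cplx <- tiny_complexes(32, seed = 47, noise_sd = 0)
  fit <- apmnet(cplx,
                config = apmnet_config(embed_dim = 16L, arma_layers = 2L,
                                       arma_stacks = 2L, mpnn_layers = 1L,
                                       edge_hidden = 16L, head_dims = 8L),
                control = apmnet_control(lr = 3e-3, lr_step = 100L,
                                         epochs = 300L, batch_size = 16L,
                                         seed = 3))
  expect_lt(sqrt(mean(residuals(fit)^2)), 0.1)
})

test_that("validation-based model selection returns the best checkpoint", {
  cplx <- tiny_complexes(12, seed = 53)
  fit <- apmnet(cplx[1:9], validation = cplx[10:12], config = tiny_model_cfg(),
                control = apmnet_control(lr = 1e-3, epochs = 5, seed = 7))
  expect_false(is.null(fit$val_rmse))
  expect_equal(min(fit$val_rmse), fit$val_rmse[fit$best_epoch])
})

test_that("splits are disjoint, seeded and apply the external-benchmark dedup", {
  ids <- sprintf("id%02d", 1:30)
  core <- ids[1:5]
  sp <- make_splits(ids, core, n_val = 8, seed = 4)
  expect_length(sp$test_ids, 5)
  expect_length(sp$val_ids, 8)
  expect_length(sp$train_ids, 17)
  expect_length(intersect(sp$train_ids, sp$val_ids), 0)
  expect_length(intersect(sp$train_ids, sp$test_ids), 0)
  expect_length(intersect(sp$val_ids, sp$test_ids), 0)
  # removing overlapping external-benchmark ids shrinks only the training set
  casf <- sp$train_ids[1:3]
  sp2 <- make_splits(ids, core, casf_ids = casf, n_val = 8, seed = 4)
  expect_length(sp2$train_ids, 14)
  expect_identical(sp2$val_ids, sp$val_ids)
  expect_identical(sort(sp2$extra_test_ids), sort(casf))
  # same seed, same validation membership
  expect_identical(make_splits(ids, core, n_val = 8, seed = 4)$val_ids, sp$val_ids)
  expect_false(identical(make_splits(ids, core, n_val = 8, seed = 5)$val_ids,
                         sp$val_ids))
  expect_error(make_splits(ids, core, n_val = 26, seed = 1), "exceeds")
  expect_error(make_splits(ids, c("zzzz"), n_val = 2), "subset")
})

# independent loop-based recomputation of the three regression metrics + SD
loop_metrics <- function(pred, obs) {
  n <- length(pred)
  se <- 0; ae <- 0
  for (i in seq_len(n)) {
    se <- se + (pred[i] - obs[i])^2
    ae <- ae + abs(pred[i] - obs[i])
  }
  mp <- sum(pred) / n; mo <- sum(obs) / n
  num <- 0; dp <- 0; do <- 0
  for (i in seq_len(n)) {
    num <- num + (obs[i] - mo) * (pred[i] - mp)
    dp <- dp + (pred[i] - mp)^2
    do <- do + (obs[i] - mo)^2
  }
  b <- num / do
  a <- mp - b * mo
  ss <- 0
  for (i in seq_len(n)) ss <- ss + (pred[i] - (a + b * obs[i]))^2
  list(rmse = sqrt(se / n), pearson = num / sqrt(dp * do), mae = ae / n,
       sd = sqrt(ss / (n - 1)))
}

test_that("evaluation metrics match an independent loop recomputation", {
  expect_equal(unclass(evaluate_predictions(c(1, 2, 3), c(1, 2, 3))[c("rmse", "mae")]),
               list(rmse = 0, mae = 0))
  expect_equal(evaluate_predictions(c(1, 2, 3), c(3, 2, 1))$pearson_r, -1)
  r <- evaluate_predictions(c(1, 2, 2, 4), c(1, 2, 3, 4))
  expect_equal(r$rmse, 0.5)
  expect_equal(r$mae, 0.25)
  set.seed(61)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    obs <- rnorm(n, 6, 1.5)
    pred <- obs + rnorm(n, 0, 0.8)
    got <- evaluate_predictions(pred, obs)
    want <- loop_metrics(pred, obs)
    expect_lt(abs(got$rmse - want$rmse), 1e-10)
    expect_lt(abs(got$pearson_r - want$pearson), 1e-10)
    expect_lt(abs(got$mae - want$mae), 1e-10)
    expect_lt(abs(got$sd - want$sd), 1e-10)
    expect_true(got$rmse >= got$mae)
    expect_true(got$pearson_r >= -1 && got$pearson_r <= 1)
  }
  expect_error(evaluate_predictions(c(1, 1, 1), c(1, 2, 3)), "variance")
  expect_error(evaluate_predictions(1, 2), "at least 2")
})

# exhaustive 3! oracle: locate the permutation sorting truth descending and
# read the prediction order off it
ranking_oracle <- function(y_true, y_pred) {
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  high <- FALSE; low <- FALSE
  for (p in perms) {
    if (y_true[p[1]] > y_true[p[2]] && y_true[p[2]] > y_true[p[3]]) {
      high <- y_pred[p[1]] > y_pred[p[2]] && y_pred[p[2]] > y_pred[p[3]]
      low <- y_pred[p[1]] > y_pred[p[2]] && y_pred[p[1]] > y_pred[p[3]]
    }
  }
  c(high = high, low = low)
}

test_that("ranking power agrees exactly with the brute-force permutation oracle", {
  perfect <- data.frame(cluster = rep(1:4, each = 3),
                        y_true = rep(c(3, 2, 1), 4), y_pred = rep(c(9, 8, 7), 4))
  rp <- ranking_power(perfect)
  expect_equal(rp$high_level_rate, 100)
  expect_equal(rp$low_level_rate, 100)
  # top correct, middle/bottom swapped: counts at the low level only
  one <- data.frame(cluster = 1, y_true = c(3, 2, 1), y_pred = c(9, 6, 7))
  rp1 <- ranking_power(one)
  expect_equal(rp1$high_level_rate, 0)
  expect_equal(rp1$low_level_rate, 100)
  # ties in predictions count as failures
  tie <- data.frame(cluster = 1, y_true = c(3, 2, 1), y_pred = c(8, 8, 1))
  expect_equal(ranking_power(tie)$low_level_rate, 0)
  expect_error(ranking_power(data.frame(cluster = 1, y_true = c(1, 2),
                                        y_pred = c(1, 2))), "exactly 3")
  expect_error(ranking_power(data.frame(cluster = 1, y_true = c(1, 1, 2),
                                        y_pred = c(1, 2, 3))), "distinct")
  set.seed(67)
  for (i in 1:50) {
    y_true <- sample(seq(1, 12, by = 0.5), 3)
    y_pred <- rnorm(3, 6, 2)
    got <- ranking_power(data.frame(cluster = 1, y_true = y_true, y_pred = y_pred))
    want <- ranking_oracle(y_true, y_pred)
    expect_equal(got$high_level_rate == 100, unname(want["high"]))
    expect_equal(got$low_level_rate == 100, unname(want["low"]))
    expect_gte(got$low_level_rate, got$high_level_rate)
  }
})

test_that("training errors are informative", {
  expect_error(apmnet(list()), "no training complexes")
  cplx <- tiny_complexes(3, seed = 71)
  expect_error(apmnet(cplx, labels = c(1, 2)), "length")
})
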