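make_feature_table <- function(n_per_group = c(healthy = 20, FFKC = 15,
                                               KC = 20),
                               sep = 3, seed = 1) {
  # synthetic, well-separated clusters on all 12 features
  set.seed(seed)
  rows <- lapply(names(n_per_group), function(g) {
    shift <- switch(g, healthy = sep, FFKC = 0, KC = -sep)
    n <- n_per_group[[g]]
    X <- matrix(rnorm(n * 12, mean = shift), n, 12)
    df <- as.data.frame(X)
    names(df) <- feature_columns()
    df$group <- g
    df
  })
  out <- do.call(rbind, rows)
  out$group <- factor(out$group, levels = c("healthy", "FFKC", "KC"))
  out
}

test_that("stratified split hits the 70% target within one subject per group", {
  tab <- make_feature_table(c(healthy = 50, FFKC = 36, KC = 50))
  sp <- split_data(tab, 0.7, seed = 3)
  expect_equal(nrow(sp$train), round(136 * 0.7))
  for (g in levels(tab$group)) {
    n_g <- sum(tab$group == g)
    got <- sum(sp$train$group == g)
    expect_lte(abs(got - 0.7 * n_g), 1)
  }
  # determinism and exhaustiveness
  sp2 <- split_data(tab, 0.7, seed = 3)
  expect_identical(sp$train_idx, sp2$train_idx)
  expect_equal(sort(c(sp$train_idx, seq_len(nrow(tab))[-sp$train_idx])),
               seq_len(nrow(tab)))
  # n = 100 at fraction 0.7 -> exactly 70 training rows
  tab100 <- make_feature_table(c(healthy = 34, FFKC = 33, KC = 33))
  expect_equal(nrow(split_data(tab100, 0.7, seed = 1)$train), 70)
})

test_that("group coding and thresholded decoding are mutually consistent", {
  expect_equal(group_code(c("healthy", "FFKC", "KC")), c(1, 0, -1))
  expect_equal(as.character(code_to_group(c(1, 0, -1))),
               c("healthy", "FFKC", "KC"))
  # boundary values land in the middle class by the documented tie rule
  expect_equal(as.character(code_to_group(c(0.5, -0.5))), c("FFKC", "FFKC"))
  expect_equal(as.character(code_to_group(c(0.51, -0.51))),
               c("healthy", "KC"))
  pred <- classify_values(c(1, 0, -1), c("healthy", "FFKC", "KC"))
  expect_equal(attr(pred, "accuracy"), 1)
})

test_that("a constant target trains to a constant output", {
  tab <- make_feature_table()
  m <- mlp_train(tab, mlp_config(max_iter = 200), target = rep(0.4, nrow(tab)))
  expect_lte(m$training_report$final_mse, 0.005)
  expect_equal(mean(mlp_predict(m, tab)), 0.4, tolerance = 0.05)
})

test_that("training is deterministic given data and seed", {
  tab <- make_feature_table()
  m1 <- mlp_train(tab, mlp_config(seed = 9))
  m2 <- mlp_train(tab, mlp_config(seed = 9))
  expect_identical(m1$W1, m2$W1)
  expect_identical(m1$W2, m2$W2)
  expect_identical(m1$training_report, m2$training_report)
  m3 <- mlp_train(tab, mlp_config(seed = 10))
  expect_false(identical(m1$W1, m3$W1))
})

test_that("the forward pass matches hand arithmetic on a 1-1-1 network", {
  model <- structure(
    list(W1 = matrix(0.7, 1, 1), b1 = -0.2, W2 = matrix(1.3, 1, 1),
         b2 = 0.25, features = "A1T",
         scaling = list(mean = c(A1T = 2), sd = c(A1T = 4))),
    class = "mlp_model")
  rows <- data.frame(A1T = c(2, 6, -2))
  xs <- (rows$A1T - 2) / 4
  expect_equal(mlp_predict(model, rows), 1.3 * tanh(0.7 * xs - 0.2) + 0.25,
               tolerance = 1e-12)
  # zero weights: output is the output bias
  model$W1[] <- 0; model$W2[] <- 0; model$b1 <- 0
  expect_equal(mlp_predict(model, rows), rep(0.25, 3))
})

test_that("Levenberg-Marquardt reaches the target error on separable clusters", {
  tab <- make_feature_table(sep = 3, seed = 2)
  sp <- split_data(tab, 0.7, seed = 2)
  m <- mlp_train(sp$train, mlp_config(seed = 2))
  expect_true(m$training_report$converged)
  expect_lte(m$training_report$final_mse, 0.005)
  expect_lt(m$training_report$iterations, 1000)
  pred <- classify_values(mlp_predict(m, sp$validation),
                          sp$validation$group)
  expect_gte(attr(pred, "accuracy"), 0.95)
})

test_that("gradient-descent fallback also reduces the training error", {
  tab <- make_feature_table(sep = 3, seed = 4)
  cfg <- mlp_config(optimizer = "gradient_descent", max_iter = 400, seed = 4)
  m <- mlp_train(tab, cfg)
  start <- mlp_train(tab, mlp_config(optimizer = "gradient_descent",
                                     max_iter = 1, seed = 4))
  expect_lt(m$training_report$final_mse,
            start$training_report$final_mse)
})

test_that("feature scaling is fitted on the training split only", {
  tab <- make_feature_table()
  sp <- split_data(tab, 0.7, seed = 5)
  m <- mlp_train(sp$train, mlp_config(seed = 5))
  X <- as.matrix(sp$train[, feature_columns()])
  expect_equal(m$scaling$mean, colMeans(X))
  expect_equal(m$scaling$sd, apply(X, 2, sd))
  # validation rows do not shift the scaling (recompute with them added)
  X_all <- as.matrix(tab[, feature_columns()])
  expect_false(isTRUE(all.equal(m$scaling$mean, colMeans(X_all))))
})

test_that("missing or non-finite features are rejected", {
  tab <- make_feature_table()
  expect_error(mlp_train(tab[, -1], mlp_config()), "missing feature")
  tab$A1T[1] <- NA
  expect_error(mlp_train(tab, mlp_config()), "non-finite")
  m <- mlp_train(make_feature_table(), mlp_config(max_iter = 5))
  expect_error(mlp_predict(m, data.frame(A1T = 1)), "missing feature")
})

test_that("model JSON serialization round-trips predictions exactly", {
  tab <- make_feature_table()
  m <- mlp_train(tab, mlp_config(max_iter = 20))
  path <- withr::local_tempfile(fileext = ".json")
  write_mlp_json(m, path)
  back <- read_mlp_json(path)
  expect_equal(mlp_predict(back, tab), mlp_predict(m, tab),
               tolerance = 1e-12)
})

test_that("with geometry overlapping, the network beats single geometric features on E-separated groups", {
  # generator: healthy and FFKC share geometry but have disjoint moduli
  gc <- cohort_defaults()
  gc$FFKC <- gc$healthy
  gc$FFKC$E <- c(mean = 0.22, sd = 0.015, lower = 0.02, upper = 1.5)
  gc$healthy$E <- c(mean = 0.38, sd = 0.015, lower = 0.02, upper = 1.5)
  rep <- run_study(pipeline_config(
    seed = 31, n_per_group = c(healthy = 25, FFKC = 20, KC = 20),
    group_configs = gc), verbose = FALSE)
  v <- rep$classifier
  vsel <- v$validation_groups %in% c("healthy", "FFKC")
  lab <- v$validation_groups[vsel] == "FFKC"
  auc_model <- roc_curve(v$predicted[vsel], lab)$auc
  sp_val <- rep$subjects[rep$subjects$quality_flags == "", ][-v$train_idx, ]
  for (feat in c("R", "CCT", "PD")) {
    auc_feat <- roc_curve(sp_val[[feat]][vsel], lab)$auc
    expect_gt(auc_model, auc_feat - 1e-9)
  }
})
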