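# Three-layer backpropagation network (12 inputs, 5 tanh hidden units,
# 1 linear output) for three-group classification through the
# healthy = 1 / FFKC = 0 / KC = -1 target coding, trained by
# Levenberg-Marquardt (damped Gauss-Newton on the squared-error Jacobian)
# with a plain gradient-descent fallback.

#' Classifier feature columns
#'
#' The 12 inputs of the keratoconus diagnosis network: eight DCR
#' parameters (A1T, A1V, A2T, A2V, SP-A1, PD, DA, ARTh), three tomographic
#' features (B.Ele.Th, Kmax, Pachymin) and the elastic modulus E.
#'
#' @return character vector of column names.
#' @export
feature_columns <- function() {
  c("A1T", "A1V", "A2T", "A2V", "SP_A1", "PD", "DA", "ARTh",
    "B_Ele_Th", "Kmax", "Pachymin", "E")
}

#' Network / training configuration
#'
#' @param layer_sizes input/hidden/output sizes; the study architecture is
#'   `c(12, 5, 1)`.
#' @param learning_rate step size of the gradient-descent fallback.
#' @param target_error training-set mean squared error at which training
#'   stops.
#' @param max_iter maximum training iterations.
#' @param train_fraction fraction of rows assigned to the training split.
#' @param seed RNG seed controlling the split and weight initialization.
#' @param optimizer `"levenberg_marquardt"` (default) or
#'   `"gradient_descent"`.
#' @return list of class `mlp_config`.
#' @export
mlp_config <- function(layer_sizes = c(12, 5, 1), learning_rate = 0.01,
                       target_error = 0.005, max_iter = 1000,
                       train_fraction = 0.70, seed = 1L,
                       optimizer = c("levenberg_marquardt",
                                     "gradient_descent")) {
  stopifnot(length(layer_sizes) == 3, all(layer_sizes >= 1),
            learning_rate > 0, target_error > 0, max_iter >= 1,
            train_fraction > 0, train_fraction < 1)
  structure(list(layer_sizes = as.integer(layer_sizes),
                 learning_rate = learning_rate, target_error = target_error,
                 max_iter = as.integer(max_iter),
                 train_fraction = train_fraction, seed = as.integer(seed),
                 optimizer = match.arg(optimizer)),
            class = "mlp_config")
}

#' Group coding for the network target
#'
#' healthy = 1, FFKC = 0, KC = -1; [code_to_group()] inverts the coding
#' with thresholds at +/- 0.5 (a value of exactly +/- 0.5 is assigned to
#' the middle class, FFKC).
#'
#' @param group character/factor vector of group labels.
#' @return numeric codes.
#' @export
group_code <- function(group) {
  code <- c(healthy = 1, FFKC = 0, KC = -1)
  g <- as.character(group)
  if (!all(g %in% names(code))) stop("unknown group label", call. = FALSE)
  unname(code[g])
}

#' @param values numeric predicted values.
#' @rdname group_code
#' @export
code_to_group <- function(values) {
  stopifnot(all(is.finite(values)))
  out <- ifelse(values > 0.5, "healthy", ifelse(values < -0.5, "KC", "FFKC"))
  factor(out, levels = c("healthy", "FFKC", "KC"))
}

#' Stratified train/validation split
#'
#' Random split stratified by group: each group contributes its share of
#' the training set to within one subject of `train_fraction`, while the
#' total training size equals `round(n * train_fraction)`
#' (largest-remainder allocation).  Deterministic given `seed`.
#'
#' @param table data frame with a `group` column.
#' @param train_fraction training fraction.
#' @param seed RNG seed.
#' @param group_col stratification column name.
#' @return list with `train`, `validation` and `train_idx`.
#' @export
split_data <- function(table, train_fraction = 0.7, seed = 1L,
                       group_col = "group") {
  stopifnot(nrow(table) >= 10)
  g <- as.factor(table[[group_col]])
  n <- nrow(table)
  total <- round(n * train_fraction)
  ng <- table(g)
  quota <- as.numeric(ng) * train_fraction
  base <- floor(quota)
  rem <- total - sum(base)
  if (rem > 0) {
    extra <- order(quota - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  names(base) <- names(ng)
  idx <- with_seed(seed, {
    unlist(lapply(names(ng), function(lv) {
      rows <- which(g == lv)
      sample(rows, base[[lv]])
    }), use.names = FALSE)
  })
  idx <- sort(idx)
  if (any(base == 0) || any(as.numeric(ng) - base == 0)) {
    warning("a group is absent from one of the splits at this n",
            call. = FALSE)
  }
  list(train = table[idx, , drop = FALSE],
       validation = table[-idx, , drop = FALSE],
       train_idx = idx)
}

# Forward pass on standardized inputs; returns hidden activations too.
mlp_forward <- function(W1, b1, W2, b2, Xs) {
  H <- tanh(Xs %*% t(W1) + matrix(b1, nrow(Xs), length(b1), byrow = TRUE))
  yhat <- as.numeric(H %*% t(W2) + b2)
  list(H = H, yhat = yhat)
}

# Jacobian of yhat w.r.t. parameter vector theta = (W1, b1, W2, b2).
mlp_jacobian <- function(W1, b1, W2, b2, Xs, H) {
  n <- nrow(Xs); d <- ncol(Xs); h <- nrow(W1)
  dH <- (1 - H^2) * matrix(W2, n, h, byrow = TRUE)   # d yhat / d preact
  J <- matrix(0, n, h * d + h + h + 1)
  for (j in seq_len(h)) {
    J[, (j - 1) * d + seq_len(d)] <- dH[, j] * Xs
  }
  J[, h * d + seq_len(h)] <- dH
  J[, h * d + h + seq_len(h)] <- H
  J[, h * d + 2 * h + 1] <- 1
  J
}

unpack_theta <- function(theta, d, h) {
  W1 <- matrix(theta[seq_len(h * d)], h, d, byrow = TRUE)
  b1 <- theta[h * d + seq_len(h)]
  W2 <- matrix(theta[h * d + h + seq_len(h)], 1, h)
  b2 <- theta[h * d + 2 * h + 1]
  list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
}

#' Train the backpropagation network
#'
#' Minimizes the training-set mean squared error of the 12-5-1 network on
#' z-scored features (scaling fitted on the training split only).
#' Training stops when the MSE reaches `target_error`, at `max_iter`
#' iterations, or when the Levenberg-Marquardt damping saturates.  Fully
#' deterministic given `config$seed`.
#'
#' @param train training data frame containing the feature columns and a
#'   `group` column (or a numeric `target` column).
#' @param config an [mlp_config()].
#' @param features feature column names (default [feature_columns()]).
#' @param target optional numeric target overriding the group coding.
#' @return object of class `mlp_model`: weights, scaling parameters, the
#'   config and a `training_report` (final MSE, iterations, converged).
#' @export
mlp_train <- function(train, config = mlp_config(),
                      features = feature_columns(), target = NULL) {
  miss <- setdiff(features, names(train))
  if (length(miss)) {
    stop("missing feature columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  X <- as.matrix(train[, features, drop = FALSE])
  if (!all(is.finite(X))) stop("non-finite feature values", call. = FALSE)
  y <- target %||% group_code(train$group)
  d <- length(features); h <- config$layer_sizes[2]
  if (config$layer_sizes[1] != d) {
    stop("layer_sizes[1] must equal the number of features", call. = FALSE)
  }
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  sdv[sdv == 0] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sdv, "/")

  n_par <- h * d + h + h + 1
  theta <- with_seed(config$seed, {
    c(stats::runif(h * d, -0.5, 0.5) / sqrt(d),
      stats::runif(h, -0.5, 0.5) / sqrt(d),
      stats::runif(h, -0.5, 0.5) / sqrt(h),
      stats::runif(1, -0.5, 0.5) / sqrt(h))
  })
  nr <- nrow(Xs)
  mse_of <- function(theta) {
    p <- unpack_theta(theta, d, h)
    fw <- mlp_forward(p$W1, p$b1, p$W2, p$b2, Xs)
    mean((y - fw$yhat)^2)
  }
  iter <- 0L
  lambda <- 1e-2
  mse <- mse_of(theta)
  converged <- mse <= config$target_error
  if (config$optimizer == "levenberg_marquardt") {
    while (!converged && iter < config$max_iter && lambda < 1e12) {
      iter <- iter + 1L
      p <- unpack_theta(theta, d, h)
      fw <- mlp_forward(p$W1, p$b1, p$W2, p$b2, Xs)
      r <- y - fw$yhat
      J <- mlp_jacobian(p$W1, p$b1, p$W2, p$b2, Xs, fw$H)
      JtJ <- crossprod(J)
      g <- crossprod(J, r)
      repeat {
        step <- tryCatch(
          solve(JtJ + lambda * diag(n_par), g),
          error = function(e) NULL)
        cand <- if (is.null(step)) NULL else theta + as.numeric(step)
        new_mse <- if (is.null(cand)) Inf else mse_of(cand)
        if (new_mse < mse) {
          theta <- cand
          mse <- new_mse
          lambda <- max(lambda * 0.1, 1e-12)
          break
        }
        lambda <- lambda * 10
        if (lambda >= 1e12) break
      }
      converged <- mse <= config$target_error
    }
  } else {
    while (!converged && iter < config$max_iter) {
      iter <- iter + 1L
      p <- unpack_theta(theta, d, h)
      fw <- mlp_forward(p$W1, p$b1, p$W2, p$b2, Xs)
      r <- y - fw$yhat
      J <- mlp_jacobian(p$W1, p$b1, p$W2, p$b2, Xs, fw$H)
      theta <- theta + config$learning_rate * (2 / nr) *
        as.numeric(crossprod(J, r))
      mse <- mse_of(theta)
      converged <- mse <= config$target_error
    }
  }
  p <- unpack_theta(theta, d, h)
  structure(
    list(W1 = p$W1, b1 = p$b1, W2 = p$W2, b2 = p$b2,
         features = features, scaling = list(mean = mu, sd = sdv),
         config = config,
         training_report = list(final_mse = mse, iterations = iter,
                                converged = converged,
                                n_train = nr)),
    class = "mlp_model")
}

#' @export
print.mlp_model <- function(x, ...) {
  r <- x$training_report
  cat(sprintf(
    "MLP %d-%d-1 (tanh/linear), %s: MSE %.4g after %d iterations%s\n",
    length(x$features), length(x$b1), x$config$optimizer, r$final_mse,
    r$iterations, if (r$converged) " (converged)" else ""))
  invisible(x)
}

#' Predict continuous network outputs
#'
#' Forward pass with the model's training-split scaling applied.
#'
#' @param model an `mlp_model`.
#' @param rows data frame containing the model's feature columns.
#' @return numeric predicted values (typically in about `[-1.5, 1.5]`).
#' @export
mlp_predict <- function(model, rows) {
  miss <- setdiff(model$features, names(rows))
  if (length(miss)) {
    stop("missing feature columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  X <- as.matrix(rows[, model$features, drop = FALSE])
  Xs <- sweep(sweep(X, 2, model$scaling$mean), 2, model$scaling$sd, "/")
  mlp_forward(model$W1, model$b1, model$W2, model$b2, Xs)$yhat
}

#' Classify predicted values and score accuracy
#'
#' @param values continuous predicted values.
#' @param truth optional true group labels; when given, the fraction of
#'   correct assignments is attached as attribute `accuracy`.
#' @return factor of predicted groups (attribute `accuracy` when `truth`
#'   is supplied).
#' @export
classify_values <- function(values, truth = NULL) {
  pred <- code_to_group(values)
  if (!is.null(truth)) {
    attr(pred, "accuracy") <- mean(as.character(pred) == as.character(truth))
  }
  pred
}

#' Serialize / restore a trained model as JSON
#'
#' @param model an `mlp_model`.
#' @param path JSON file path.
#' @export
write_mlp_json <- function(model, path) {
  obj <- list(W1 = model$W1, b1 = model$b1, W2 = as.numeric(model$W2),
              b2 = model$b2, features = model$features,
              scaling = model$scaling, config = unclass(model$config),
              training_report = model$training_report)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_mlp_json
#' @export
read_mlp_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(W1 = matrix(obj$W1, nrow = length(obj$b1)),
         b1 = obj$b1, W2 = matrix(obj$W2, nrow = 1), b2 = obj$b2,
         features = obj$features,
         scaling = list(mean = stats::setNames(obj$scaling$mean, obj$features),
                        sd = stats::setNames(obj$scaling$sd, obj$features)),
         config = do.call(mlp_config, obj$config[names(obj$config) %in%
                                                   names(formals(mlp_config))]),
         training_report = obj$training_report),
    class = "mlp_model")
}
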