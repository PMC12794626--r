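# Baseline regressors behind the model registry. All baselines conform to the
# preprocess/train/infer stage contracts:
#   gbt   — gradient-boosted trees (xgboost) on [omics || descriptors], with
#           validation-based early stopping,
#   ridge — L2-regularized linear regression (glmnet), regularization strength
#           selected on the validation set,
#   mlp   — small single-hidden-layer feed-forward network (nnet) trained in
#           warm-restart chunks through the generic early-stopping loop.

fit_gbt <- function(x_train, y_train, x_val, y_val, params, seed) {
  patience <- params$patience %||% 10L
  nrounds <- params$max_evals %||% 200L
  bst <- xgboost::xgb.train(
    params = list(objective = "reg:squarederror",
                  eta = params$learning_rate %||% 0.1,
                  max_depth = params$max_depth %||% 6L,
                  subsample = params$subsample %||% 0.8,
                  colsample_bytree = params$colsample %||% 0.8,
                  nthread = 1L, seed = seed),
    data = xgboost::xgb.DMatrix(x_train, label = y_train, nthread = 1L),
    nrounds = nrounds,
    evals = list(val = xgboost::xgb.DMatrix(x_val, label = y_val,
                                            nthread = 1L)),
    early_stopping_rounds = patience, verbose = 0
  )
  best_rmse <- attributes(bst)$evaluation_log$val_rmse[
    xgboost::xgb.attributes(bst)$best_iteration %||%
      attributes(bst)$best_iteration]
  if (is.null(best_rmse) || !length(best_rmse)) {
    best_rmse <- min(attributes(bst)$evaluation_log$val_rmse)
  }
  list(fit = bst, best_val_loss = as.numeric(best_rmse)^2,
       n_evals = nrow(attributes(bst)$evaluation_log))
}

predict_gbt <- function(fit, x) {
  stats::predict(fit, xgboost::xgb.DMatrix(x, nthread = 1L))
}

fit_ridge <- function(x_train, y_train, x_val, y_val, params, seed) {
  fit <- glmnet::glmnet(x_train, y_train, alpha = 0,
                        lambda = params$lambda %||% NULL,
                        standardize = FALSE)
  pred <- stats::predict(fit, x_val)
  val_mse <- colMeans((pred - y_val)^2)
  best <- which.min(val_mse)
  list(fit = list(glmnet = fit, lambda = fit$lambda[best]),
       best_val_loss = val_mse[best], n_evals = length(fit$lambda))
}

predict_ridge <- function(fit, x) {
  as.numeric(stats::predict(fit$glmnet, x, s = fit$lambda))
}

fit_mlp <- function(x_train, y_train, x_val, y_val, params, seed) {
  size <- params$hidden_size %||% 8L
  chunk <- params$epochs_per_eval %||% 20L
  n_w <- (ncol(x_train) + 1L) * size + (size + 1L)
  init <- list(wts = stats::runif(n_w, -0.5, 0.5), net = NULL)
  res <- early_stopping_loop(
    init = init,
    step = function(state) {
      net <- nnet::nnet(x_train, y_train, size = size, linout = TRUE,
                        Wts = state$wts, maxit = chunk,
                        decay = params$decay %||% 1e-3, trace = FALSE,
                        MaxNWts = n_w + 1L)
      list(wts = net$wts, net = net)
    },
    val_loss = function(state) {
      mean((as.numeric(stats::predict(state$net, x_val)) - y_val)^2)
    },
    patience = params$patience %||% 10L,
    max_evals = params$max_evals %||% 30L
  )
  list(fit = res$best_state$net, best_val_loss = res$best_loss,
       n_evals = res$n_evals)
}

predict_mlp <- function(fit, x) as.numeric(stats::predict(fit, x))

register_baseline_models <- function() {
  register_model(model_spec(
    "gbt", cell_features = "omics", drug_features = "descriptor",
    supports_early_stopping = TRUE, fit = fit_gbt, predict = predict_gbt))
  register_model(model_spec(
    "ridge", cell_features = "omics", drug_features = "descriptor",
    supports_early_stopping = FALSE, fit = fit_ridge, predict = predict_ridge))
  register_model(model_spec(
    "mlp", cell_features = "omics", drug_features = "fingerprint",
    supports_early_stopping = TRUE, fit = fit_mlp, predict = predict_mlp))
  invisible(list_models())
}

.onLoad <- function(libname, pkgname) {
  register_baseline_models()
}
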