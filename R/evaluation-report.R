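# Evaluation metrics, the input-variable ablation runner, and
# measured-vs-predicted exports.

#' Regression evaluation metrics
#'
#' Computes the six metrics used to judge the prediction models:
#' Pearson correlation R, coefficient of determination R^2 (squared
#' correlation between targets and predictions, matching
#' regression-based usage; the residual-based `1 - SSE/SST` variant is
#' also returned as `R2_sse`), MSE, RMSE, MAE, and SD (population
#' standard deviation of the residuals; equal to RMSE exactly when the
#' mean residual is zero). Constant predictions leave R and R^2 missing
#' with a warning; the error metrics are still returned.
#'
#' @param targets,predictions numeric vectors of equal length (>= 2), on
#'   the original (de-normalised) scale.
#' @param partition label recorded with the report (`"train"`,
#'   `"validation"`, `"test"` or `"all"`).
#' @return an object of class `metrics_report`: list with `R`, `R2`,
#'   `R2_sse`, `MSE`, `RMSE`, `MAE`, `SD`, `n` and `partition`.
#' @examples
#' compute_metrics(c(1, 2, 3), c(1.1, 2.1, 2.9))
#' @export
compute_metrics <- function(targets, predictions,
                            partition = c("test", "train", "validation", "all")) {
  partition <- match.arg(partition)
  stopifnot(is.numeric(targets), is.numeric(predictions),
            length(targets) == length(predictions), length(targets) >= 2)
  resid <- targets - predictions
  mse <- mean(resid^2)
  if (stats::sd(predictions) == 0 || stats::sd(targets) == 0) {
    warning("constant predictions or targets: R is undefined", call. = FALSE)
    r <- NA_real_
  } else {
    r <- stats::cor(targets, predictions)
  }
  sst <- sum((targets - mean(targets))^2)
  structure(
    list(R = r, R2 = r^2,
         R2_sse = if (sst > 0) 1 - sum(resid^2) / sst else NA_real_,
         MSE = mse, RMSE = sqrt(mse), MAE = mean(abs(resid)),
         SD = sd_pop(resid), n = length(targets), partition = partition),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "<metrics_report> %s (n = %d): R %.3f, R2 %.3f, MSE %.4g, RMSE %.4g, MAE %.4g, SD %.4g\n",
    x$partition, x$n, x$R, x$R2, x$MSE, x$RMSE, x$MAE, x$SD
  ))
  invisible(x)
}

#' Model-satisfaction rule
#'
#' A model is satisfactory when R exceeds 0.80 and R^2 exceeds 0.70.
#'
#' @param metrics a `metrics_report`.
#' @param r_threshold,r2_threshold the thresholds.
#' @return logical.
#' @export
is_satisfactory <- function(metrics, r_threshold = 0.80, r2_threshold = 0.70) {
  !is.na(metrics$R) && metrics$R > r_threshold && metrics$R2 > r2_threshold
}

#' Train and evaluate one prediction model
#'
#' The shared pipeline behind the ablation runner: assemble the feature
#' matrix for one configuration, split 70:15:15, fit min/max
#' normalisation (inputs and target) on the training rows only, train the
#' MLP with Levenberg-Marquardt and early stopping, and compute metrics
#' on de-normalised predictions.
#'
#' @param records hourly record table; for emission targets it must
#'   already contain the target column (see [run_ablation()]).
#' @param config an `ablation_config` from [feature_sets()].
#' @param seed RNG seed for the split and weight initialisation.
#' @param hidden hidden-layer sizes (default `c(20, 10)`).
#' @param train_cfg a [train_config()].
#' @param target_column passed to [assemble_features()].
#' @return list with `model` (with normalisation attached), `result`
#'   (`train_result`), `metrics_test`, `metrics_all`, `split`,
#'   `test_targets`, `test_predictions`.
#' @export
fit_prediction_model <- function(records, config, seed = 1L,
                                 hidden = c(20, 10),
                                 train_cfg = train_config(),
                                 target_column = NULL) {
  fx <- assemble_features(records, config, target_column = target_column)
  n <- length(fx$y)
  split <- split_70_15_15(n, seed = seed)
  px <- minmax_fit(fx$x[split$train, , drop = FALSE])
  py <- minmax_fit(matrix(fx$y[split$train], ncol = 1,
                          dimnames = list(NULL, "target")))
  xn <- minmax_apply(fx$x, px)
  yn <- as.numeric(minmax_apply(matrix(fx$y, ncol = 1,
                                       dimnames = list(NULL, "target")), py))

  model <- mlp_init(c(ncol(fx$x), hidden, 1), seed = seed)
  res <- train_lm(model, xn[split$train, , drop = FALSE], yn[split$train],
                  xn[split$validation, , drop = FALSE], yn[split$validation],
                  config = train_cfg)
  res$model$norm <- list(x = px, y = py)

  denorm <- function(v) {
    as.numeric(minmax_invert(matrix(v, ncol = 1,
                                    dimnames = list(NULL, "target")), py))
  }
  pred_all <- denorm(mlp_forward(res$model, xn))
  metrics_test <- compute_metrics(fx$y[split$test], pred_all[split$test],
                                  partition = "test")
  metrics_all <- compute_metrics(fx$y, pred_all, partition = "all")
  list(model = res$model, result = res,
       metrics_test = metrics_test, metrics_all = metrics_all,
       split = split,
       test_targets = fx$y[split$test],
       test_predictions = pred_all[split$test])
}

#' Run the input-variable ablation study
#'
#' Trains the fixed-structure MLP once per input-variable configuration
#' of the chosen target and reports the evaluation metrics, mirroring the
#' layout of the published ablation tables (Variables, ANN Structure, R,
#' R^2, MSE, RMSE, MAE, SD). For emission targets, the per-LU emission is
#' first estimated from the records with the CO2 mass-balance chain and
#' used as the target variable; hours with an invalid CO2 gradient are
#' dropped.
#'
#' @param study a `barn_study` (or an hourly record data frame).
#' @param target one of `"NH3_concentration"`, `"CH4_concentration"`,
#'   `"NH3_emission"`, `"CH4_emission"`.
#' @param seed RNG seed shared by every configuration's split and
#'   initialisation.
#' @param configs optional subset of the configurations (by name) to run.
#' @param hidden hidden-layer sizes (default `c(20, 10)`).
#' @param train_cfg a [train_config()].
#' @param herd a [herd_state()] for emission estimation; defaults to the
#'   study's generator herd when `study` is a `barn_study`.
#' @param metrics_partition partition reported in the table (`"test"`,
#'   the default, or `"all"`).
#' @return an object of class `ablation_table`: a data frame with one
#'   row per configuration (columns `variables`, `structure`, `R`, `R2`,
#'   `MSE`, `RMSE`, `MAE`, `SD`, `satisfied`, `seed`), with the per-run
#'   details in `attr(, "runs")`. Individual configuration failures are
#'   recorded as `NA` rows and the run continues.
#' @export
run_ablation <- function(study,
                         target = c("NH3_concentration", "CH4_concentration",
                                    "NH3_emission", "CH4_emission"),
                         seed = 1L, configs = NULL, hidden = c(20, 10),
                         train_cfg = train_config(), herd = NULL,
                         metrics_partition = c("test", "all")) {
  target <- match.arg(target)
  metrics_partition <- match.arg(metrics_partition)
  records <- if (inherits(study, "barn_study")) study$records else study
  stopifnot(is.data.frame(records))
  if (is.null(herd)) {
    herd <- if (inherits(study, "barn_study")) {
      herd_from_config(study$config)
    } else {
      herd_state()
    }
  }
  gas <- sub("_.*$", "", target)
  if (endsWith(target, "emission")) {
    est <- estimate_emissions_series(records, herd, gas = gas)
    records$E <- est$E
  }
  sets <- feature_sets(target)
  if (!is.null(configs)) {
    keep <- vapply(sets, function(s) s$name %in% configs, logical(1))
    if (!any(keep)) stop("no matching configuration names", call. = FALSE)
    sets <- sets[keep]
  }

  runs <- vector("list", length(sets))
  rows <- vector("list", length(sets))
  for (i in seq_along(sets)) {
    cfg <- sets[[i]]
    fit <- tryCatch(
      fit_prediction_model(records, cfg, seed = seed, hidden = hidden,
                           train_cfg = train_cfg),
      error = function(e) e
    )
    if (inherits(fit, "error")) {
      warning(sprintf("configuration '%s' failed: %s", cfg$name,
                      conditionMessage(fit)), call. = FALSE)
      rows[[i]] <- data.frame(
        variables = cfg$name, structure = paste(hidden, collapse = " "),
        R = NA_real_, R2 = NA_real_, MSE = NA_real_, RMSE = NA_real_,
        MAE = NA_real_, SD = NA_real_, satisfied = NA, seed = seed
      )
      next
    }
    m <- if (metrics_partition == "test") fit$metrics_test else fit$metrics_all
    runs[[i]] <- fit
    rows[[i]] <- data.frame(
      variables = cfg$name, structure = paste(hidden, collapse = " "),
      R = m$R, R2 = m$R2, MSE = m$MSE, RMSE = m$RMSE, MAE = m$MAE, SD = m$SD,
      satisfied = is_satisfactory(m), seed = seed
    )
  }
  out <- do.call(rbind, rows)
  attr(out, "runs") <- runs
  attr(out, "target") <- target
  class(out) <- c("ablation_table", class(out))
  out
}

#' @export
print.ablation_table <- function(x, digits = 3, ...) {
  cat(sprintf("Input-variable ablation: %s\n", attr(x, "target")))
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) signif(v, digits))
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' Export measured-vs-predicted series
#'
#' `export_timeseries()` writes the paired target/prediction series as a
#' CSV (columns `index`, `target`, `prediction`) and optionally a
#' comparison plot. `export_regression()` writes the scatter data with
#' the fitted least-squares line and the identity line Y = T, returning
#' the fit's slope and intercept.
#'
#' @param targets,predictions numeric vectors of equal length.
#' @param path output CSV path; the plot (if requested) is written next
#'   to it with a `.png` extension.
#' @param plot also render a PNG plot (default `TRUE`).
#' @return invisibly, the exported data frame (`export_timeseries`) or a
#'   list with `slope`, `intercept` and the data frame
#'   (`export_regression`).
#' @export
export_timeseries <- function(targets, predictions, path, plot = TRUE) {
  stopifnot(length(targets) == length(predictions))
  df <- data.frame(index = seq_along(targets), target = targets,
                   prediction = predictions)
  utils::write.csv(df, path, row.names = FALSE)
  if (plot) {
    png_path <- sub("\\.[^.]*$", ".png", path)
    grDevices::png(png_path, width = 900, height = 450)
    on.exit(grDevices::dev.off())
    graphics::plot(df$index, df$target, type = "l", col = "grey30",
                   xlab = "hour", ylab = "value",
                   main = "Measured vs predicted")
    graphics::lines(df$index, df$prediction, col = "darkorange")
    graphics::legend("topright", legend = c("measured", "predicted"),
                     col = c("grey30", "darkorange"), lty = 1, bty = "n")
  }
  invisible(df)
}

#' @rdname export_timeseries
#' @export
export_regression <- function(targets, predictions, path, plot = TRUE) {
  stopifnot(length(targets) == length(predictions))
  fit <- stats::lm(predictions ~ targets)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  df <- data.frame(target = targets, prediction = predictions,
                   fitted = stats::fitted(fit))
  utils::write.csv(df, path, row.names = FALSE)
  if (plot) {
    png_path <- sub("\\.[^.]*$", ".png", path)
    grDevices::png(png_path, width = 500, height = 500)
    on.exit(grDevices::dev.off())
    graphics::plot(targets, predictions, pch = 16, col = "grey40",
                   xlab = "target", ylab = "prediction",
                   main = sprintf("Y = %.2f T + %.2f", slope, intercept))
    graphics::abline(0, 1, col = "grey70", lty = 2)
    graphics::abline(intercept, slope, col = "darkorange")
  }
  invisible(list(slope = slope, intercept = intercept, data = df))
}
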