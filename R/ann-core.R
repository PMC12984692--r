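# From-scratch multilayer perceptron for scalar regression: tansig
# (hyperbolic tangent) hidden units, linear (purelin) output, trained by
# Levenberg-Marquardt on the sum of squared residuals with
# validation-based early stopping and best-weights restoration.

#' Initialise a multilayer perceptron
#'
#' Weights and biases are drawn uniformly from
#' `[-1/sqrt(fan_in), 1/sqrt(fan_in)]` per layer, deterministically under
#' `seed`.
#'
#' @param layer_sizes integer vector `(n_inputs, hidden..., 1)`; the last
#'   entry must be 1 (scalar regression output).
#' @param seed integer RNG seed.
#' @return an object of class `mlp_model`: list with `sizes`, `W` (list
#'   of weight matrices, rows = units, columns = inputs), `b` (list of
#'   bias vectors) and `norm` (attached normalisation parameters, set by
#'   the training pipeline).
#' @examples
#' m <- mlp_init(c(3, 5, 1), seed = 1)
#' mlp_n_params(m)  # 3*5 + 5 + 5*1 + 1 = 26
#' @export
mlp_init <- function(layer_sizes, seed) {
  layer_sizes <- as.integer(layer_sizes)
  stopifnot(length(layer_sizes) >= 2L, all(layer_sizes >= 1L),
            layer_sizes[length(layer_sizes)] == 1L)
  n_layers <- length(layer_sizes) - 1L
  model <- with_seed(seed, {
    W <- vector("list", n_layers)
    b <- vector("list", n_layers)
    for (l in seq_len(n_layers)) {
      fan_in <- layer_sizes[l]
      lim <- 1 / sqrt(fan_in)
      W[[l]] <- matrix(stats::runif(layer_sizes[l + 1L] * fan_in, -lim, lim),
                       nrow = layer_sizes[l + 1L], ncol = fan_in)
      b[[l]] <- stats::runif(layer_sizes[l + 1L], -lim, lim)
    }
    list(sizes = layer_sizes, W = W, b = b, norm = NULL)
  })
  structure(model, class = "mlp_model")
}

#' @export
print.mlp_model <- function(x, ...) {
  cat(sprintf("<mlp_model> %s (%d parameters)\n",
              paste(x$sizes, collapse = "-"), mlp_n_params(x)))
  invisible(x)
}

#' Number of trainable parameters of a model
#' @param model an `mlp_model`.
#' @return integer parameter count.
#' @export
mlp_n_params <- function(model) {
  sum(vapply(seq_along(model$W),
             function(l) length(model$W[[l]]) + length(model$b[[l]]),
             numeric(1)))
}

#' Forward pass
#'
#' Hidden layers apply `tanh`, the output layer is linear. Vectorised
#' over rows of `x`.
#'
#' @param model an `mlp_model`.
#' @param x numeric matrix, one row per sample; column count must match
#'   the input layer.
#' @return numeric vector of predictions, one per row.
#' @export
mlp_forward <- function(model, x) {
  mlp_activations(model, x)$out
}

mlp_activations <- function(model, x) {
  x <- as.matrix(x)
  if (ncol(x) != model$sizes[1]) {
    stop(sprintf("input has %d columns but the model expects %d",
                 ncol(x), model$sizes[1]), call. = FALSE)
  }
  n_layers <- length(model$W)
  a <- vector("list", n_layers + 1L)
  a[[1]] <- x
  for (l in seq_len(n_layers)) {
    z <- tcrossprod(a[[l]], model$W[[l]])
    z <- sweep(z, 2, model$b[[l]], "+")
    a[[l + 1L]] <- if (l < n_layers) tanh(z) else z
  }
  list(out = as.numeric(a[[n_layers + 1L]]), a = a)
}

# Flatten parameters layer by layer, each layer as (W row-major, b).
mlp_flatten <- function(model) {
  unlist(lapply(seq_along(model$W), function(l) {
    c(as.vector(t(model$W[[l]])), model$b[[l]])
  }), use.names = FALSE)
}

mlp_unflatten <- function(model, w) {
  pos <- 0L
  for (l in seq_along(model$W)) {
    nw <- length(model$W[[l]])
    nb <- length(model$b[[l]])
    model$W[[l]] <- matrix(w[pos + seq_len(nw)], nrow = nrow(model$W[[l]]),
                           byrow = TRUE)
    pos <- pos + nw
    model$b[[l]] <- w[pos + seq_len(nb)]
    pos <- pos + nb
  }
  model
}

# Jacobian of the network output with respect to all parameters, for
# every sample: n x P matrix, columns in mlp_flatten() order. Computed by
# backward accumulation of output sensitivities.
mlp_jacobian <- function(model, x) {
  act <- mlp_activations(model, x)
  a <- act$a
  n_layers <- length(model$W)
  n <- nrow(a[[1]])
  # D[[l]]: sensitivity of the scalar output to layer l's pre-activation,
  # n x units(l).
  D <- vector("list", n_layers)
  D[[n_layers]] <- matrix(1, n, 1)
  if (n_layers > 1) {
    for (l in seq(n_layers - 1L, 1L)) {
      D[[l]] <- (D[[l + 1L]] %*% model$W[[l + 1L]]) * (1 - a[[l + 1L]]^2)
    }
  }
  blocks <- vector("list", n_layers)
  for (l in seq_len(n_layers)) {
    h <- ncol(D[[l]])
    k <- ncol(a[[l]])
    # column (j-1)*k + i is dOut/dW[j, i]; then the h bias columns
    jw <- D[[l]][, rep(seq_len(h), each = k), drop = FALSE] *
      a[[l]][, rep(seq_len(k), times = h), drop = FALSE]
    blocks[[l]] <- cbind(jw, D[[l]])
  }
  list(pred = act$out, J = do.call(cbind, blocks))
}

#' Training configuration for Levenberg-Marquardt
#'
#' @param max_epochs maximum number of epochs (default 1000).
#' @param patience consecutive validation checks without improvement
#'   allowed before stopping (default 6).
#' @param mu_init initial damping factor (default 1e-3).
#' @param mu_increase multiplier applied when a step is rejected
#'   (default 10).
#' @param mu_decrease multiplier applied when a step is accepted
#'   (default 0.1).
#' @param mu_max damping ceiling; exceeding it stops training
#'   (default 1e10).
#' @param goal_mse training MSE goal (default 0, i.e. never reached).
#' @param seed RNG seed recorded with the run (initialisation happens in
#'   [mlp_init()]; training itself is deterministic).
#' @return a `train_config` list.
#' @export
train_config <- function(max_epochs = 1000, patience = 6, mu_init = 1e-3,
                         mu_increase = 10, mu_decrease = 0.1, mu_max = 1e10,
                         goal_mse = 0, seed = 1L) {
  stopifnot(max_epochs >= 1, patience >= 1, mu_init > 0, mu_increase > 1,
            mu_decrease > 0, mu_decrease < 1, mu_max > mu_init, goal_mse >= 0)
  structure(list(max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 mu_init = mu_init, mu_increase = mu_increase,
                 mu_decrease = mu_decrease, mu_max = mu_max,
                 goal_mse = goal_mse, seed = as.integer(seed)),
            class = "train_config")
}

# Early-stopping state update: `fail` counts consecutive validation
# checks at or above the best MSE seen so far.
es_update <- function(state, val_mse) {
  if (val_mse < state$best) {
    state$best <- val_mse
    state$fail <- 0L
    state$improved <- TRUE
  } else {
    state$fail <- state$fail + 1L
    state$improved <- FALSE
  }
  state
}

#' Train a multilayer perceptron with Levenberg-Marquardt
#'
#' Each epoch linearises the residuals through the Jacobian `J` and
#' solves the damped normal equations
#' `(J'J + mu I) delta = J' r` for the update. The damping `mu` shrinks
#' after an accepted step (towards Gauss-Newton) and grows after a
#' rejected one (towards gradient descent); training stops when `mu`
#' exceeds its ceiling, the training MSE goal is met, the epoch budget is
#' exhausted, or the validation MSE has failed to improve for `patience`
#' consecutive epochs. The weights with the lowest validation MSE are
#' restored on return.
#'
#' @param model an `mlp_model` from [mlp_init()].
#' @param x_train,y_train training features (matrix) and targets
#'   (vector), typically normalised to `[-1, 1]`.
#' @param x_val,y_val validation partition used for early stopping.
#' @param config a [train_config()].
#' @return an object of class `train_result`: list with `model` (best
#'   weights), `epochs_run`, `stop_reason` (one of `"patience"`,
#'   `"max_epochs"`, `"mu_overflow"`, `"goal"`) and `trace` (data frame
#'   of per-epoch train/validation MSE).
#' @export
train_lm <- function(model, x_train, y_train, x_val, y_val,
                     config = train_config()) {
  stopifnot(inherits(model, "mlp_model"), inherits(config, "train_config"))
  x_train <- as.matrix(x_train); x_val <- as.matrix(x_val)
  y_train <- as.numeric(y_train); y_val <- as.numeric(y_val)
  stopifnot(nrow(x_train) == length(y_train), nrow(x_val) == length(y_val),
            nrow(x_train) >= 1, nrow(x_val) >= 1)

  w <- mlp_flatten(model)
  n_par <- length(w)
  n_train <- length(y_train)
  sse_of <- function(wv) {
    pred <- mlp_forward(mlp_unflatten(model, wv), x_train)
    sum((y_train - pred)^2)
  }
  val_mse_of <- function(wv) {
    pred <- mlp_forward(mlp_unflatten(model, wv), x_val)
    mean((y_val - pred)^2)
  }

  mu <- config$mu_init
  sse <- sse_of(w)
  es <- list(best = Inf, fail = 0L, improved = FALSE)
  w_best <- w
  trace_train <- numeric(0)
  trace_val <- numeric(0)
  stop_reason <- "max_epochs"
  epochs <- 0L

  for (epoch in seq_len(config$max_epochs)) {
    jac <- mlp_jacobian(mlp_unflatten(model, w), x_train)
    r <- y_train - jac$pred
    g <- crossprod(jac$J, r)
    H <- crossprod(jac$J)
    accepted <- FALSE
    while (!accepted) {
      delta <- tryCatch(
        solve(H + diag(mu, n_par), g),
        error = function(e) NULL
      )
      if (!is.null(delta)) {
        w_new <- w + as.numeric(delta)
        sse_new <- sse_of(w_new)
        if (is.finite(sse_new) && sse_new < sse) {
          w <- w_new
          sse <- sse_new
          mu <- max(mu * config$mu_decrease, 1e-20)
          accepted <- TRUE
          break
        }
      }
      mu <- mu * config$mu_increase
      if (mu > config$mu_max) break
    }
    if (!accepted) {
      stop_reason <- "mu_overflow"
      break
    }
    epochs <- epoch
    val_mse <- val_mse_of(w)
    trace_train <- c(trace_train, sse / n_train)
    trace_val <- c(trace_val, val_mse)
    es <- es_update(es, val_mse)
    if (es$improved) w_best <- w
    if (sse / n_train <= config$goal_mse) {
      stop_reason <- "goal"
      break
    }
    if (es$fail >= config$patience) {
      stop_reason <- "patience"
      break
    }
    if (epoch == config$max_epochs) stop_reason <- "max_epochs"
  }

  best_model <- mlp_unflatten(model, if (is.finite(es$best)) w_best else w)
  structure(
    list(model = best_model, epochs_run = epochs, stop_reason = stop_reason,
         trace = data.frame(epoch = seq_along(trace_train),
                            train_mse = trace_train, val_mse = trace_val),
         best_val_mse = if (is.finite(es$best)) es$best else NA_real_,
         config = config),
    class = "train_result"
  )
}

#' @export
print.train_result <- function(x, ...) {
  cat(sprintf(
    "<train_result> %s, %d epochs, stop: %s, best validation MSE %.4g\n",
    paste(x$model$sizes, collapse = "-"), x$epochs_run, x$stop_reason,
    x$best_val_mse
  ))
  invisible(x)
}

#' Incremental hidden-layer architecture search
#'
#' Evaluates a documented schedule of growing structures — widen a single
#' hidden layer (5, 10, 20 units), then append a second layer with half
#' the units (20-10), then double (40-20) — training each candidate and
#' stopping at the first whose validation correlation exceeds
#' `r_threshold` and squared correlation exceeds `r2_threshold`. If no
#' candidate satisfies the thresholds, the best-so-far (highest
#' validation R^2; fewer parameters on ties) is returned with
#' `satisfied = FALSE`.
#'
#' @param x_train,y_train,x_val,y_val data partitions as in [train_lm()].
#' @param r_threshold,r2_threshold satisfaction thresholds (defaults
#'   0.80 and 0.70).
#' @param schedule list of hidden-layer size vectors to try, in order.
#' @param seed RNG seed for each candidate's initialisation.
#' @param config a [train_config()].
#' @return list with `hidden` (selected hidden sizes), `satisfied`
#'   (logical), `result` (the selected candidate's `train_result`) and
#'   `log` (data frame: structure, n_params, R, R2, satisfied).
#' @export
architecture_search <- function(x_train, y_train, x_val, y_val,
                                r_threshold = 0.80, r2_threshold = 0.70,
                                schedule = list(5, 10, 20, c(20, 10), c(40, 20)),
                                seed = 1L, config = train_config()) {
  x_train <- as.matrix(x_train)
  n_in <- ncol(x_train)
  log <- data.frame(structure = character(0), n_params = integer(0),
                    R = numeric(0), R2 = numeric(0), satisfied = logical(0))
  best <- NULL
  for (hidden in schedule) {
    sizes <- c(n_in, hidden, 1)
    model <- mlp_init(sizes, seed = seed)
    res <- train_lm(model, x_train, y_train, x_val, y_val, config = config)
    pred <- mlp_forward(res$model, x_val)
    r <- if (stats::sd(pred) > 0) stats::cor(y_val, pred) else NA_real_
    r2 <- r^2
    ok <- !is.na(r) && r > r_threshold && r2 > r2_threshold
    log <- rbind(log, data.frame(
      structure = paste(hidden, collapse = "-"),
      n_params = mlp_n_params(model), R = r, R2 = r2, satisfied = ok
    ))
    cand <- list(hidden = hidden, satisfied = ok, result = res,
                 R = r, R2 = r2, n_params = mlp_n_params(model))
    if (is.null(best) ||
        (!is.na(r2) && (is.na(best$R2) || r2 > best$R2))) {
      best <- cand
    }
    if (ok) {
      best <- cand
      break
    }
  }
  list(hidden = best$hidden, satisfied = best$satisfied,
       result = best$result, log = log)
}

#' Serialise / restore a trained model as JSON text
#'
#' Writes layer sizes, flattened weights and any attached normalisation
#' parameters to a JSON file at full precision; `mlp_load()` restores an
#' exactly equivalent model.
#'
#' @param model an `mlp_model`.
#' @param path file path.
#' @return `mlp_save()` returns `path` invisibly; `mlp_load()` returns
#'   the restored `mlp_model`.
#' @export
mlp_save <- function(model, path) {
  stopifnot(inherits(model, "mlp_model"))
  obj <- list(sizes = model$sizes, weights = mlp_flatten(model))
  pack <- function(p) {
    list(min = as.list(p$min), max = as.list(p$max),
         lower = p$lower, upper = p$upper, constant = p$constant)
  }
  if (!is.null(model$norm)) {
    obj$norm_x <- pack(model$norm$x)
    obj$norm_y <- pack(model$norm$y)
  }
  jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname mlp_save
#' @export
mlp_load <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  model <- mlp_init(obj$sizes, seed = 0L)
  model <- mlp_unflatten(model, obj$weights)
  if (!is.null(obj$norm_x)) {
    restore <- function(p) {
      structure(list(min = unlist(p$min), max = unlist(p$max),
                     lower = p$lower, upper = p$upper,
                     constant = as.logical(unlist(p$constant))),
                class = "minmax_params")
    }
    model$norm <- list(x = restore(obj$norm_x), y = restore(obj$norm_y))
  }
  model
}
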