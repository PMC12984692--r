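# Model-ready dataset assembly: hourly aggregation, feature-group
# definitions for the input-ablation study, min/max normalisation fitted
# on training rows only, and the 70:15:15 random partition.

#' Feature-group to column mapping
#'
#' The four input-variable groups used by the ablation study:
#' * `climatic`: hour of day plus indoor/outdoor temperature, relative
#'   humidity, wind speed and wind direction (9 columns);
#' * `activity`: the behavioural indices CLI and CAI (2 columns);
#' * `diet`: the 13 ration ingredient masses;
#' * `concentrations`: indoor/outdoor CO2 and target-gas concentrations
#'   (4 columns, gas-specific).
#'
#' @param gas `"NH3"` or `"CH4"`; needed only for the `concentrations`
#'   group.
#' @return named list of character vectors of column names.
#' @export
feature_groups <- function(gas = c("NH3", "CH4")) {
  gas <- match.arg(gas)
  gl <- tolower(gas)
  list(
    climatic = c("hour", "T_in", "T_out", "RH_in", "RH_out",
                 "WS_in", "WS_out", "WD_in", "WD_out"),
    activity = c("CLI", "CAI"),
    diet = diet_ingredients(),
    concentrations = c("co2_in", "co2_out",
                       paste0(gl, "_in"), paste0(gl, "_out"))
  )
}

# The published input-variable configurations: 7 for concentration
# targets (never including the concentrations group), 15 for emission
# targets (all non-empty subsets of the four groups).
concentration_config_names <- function() {
  c("Climatic variables",
    "Animal activity",
    "Diet",
    "Climatic variables and animal activity",
    "Climatic variables and diet",
    "Diet and animal activity",
    "Climatic variables, animal activity and diet")
}

emission_config_names <- function() {
  c("Concentrations",
    "Climatic variables",
    "Animal activity",
    "Diet",
    "Concentrations and climatic variables",
    "Concentrations and animal activity",
    "Concentrations and diet",
    "Climatic variables and animal activity",
    "Climatic variables and diet",
    "Animal activity and diet",
    "Concentrations, climatic variables and animal activity",
    "Concentrations, climatic variables and diet",
    "Concentrations, animal activity and diet",
    "Climatic variables, animal activity and diet",
    "Concentrations, climatic variables, animal activity and diet")
}

config_groups_from_name <- function(name) {
  g <- character(0)
  if (grepl("Concentrations", name, ignore.case = TRUE)) g <- c(g, "concentrations")
  if (grepl("Climatic", name, ignore.case = TRUE)) g <- c(g, "climatic")
  if (grepl("activity", name, ignore.case = TRUE)) g <- c(g, "activity")
  if (grepl("diet", name, ignore.case = TRUE)) g <- c(g, "diet")
  g
}

#' Enumerate the ablation configurations for a prediction target
#'
#' Returns the fixed input-variable configurations of the ablation study:
#' 7 for concentration targets (all non-empty combinations of climatic,
#' activity and diet) and 15 for emission targets (all non-empty
#' combinations additionally including the gas-concentration group).
#'
#' @param target one of `"NH3_concentration"`, `"CH4_concentration"`,
#'   `"NH3_emission"`, `"CH4_emission"`.
#' @return a list of `ablation_config` objects, each with fields `name`,
#'   `groups`, `target`, `gas` and `columns` (the mapped feature columns).
#' @examples
#' length(feature_sets("NH3_concentration"))  # 7
#' length(feature_sets("CH4_emission"))       # 15
#' @export
feature_sets <- function(target = c("NH3_concentration", "CH4_concentration",
                                    "NH3_emission", "CH4_emission")) {
  target <- match.arg(target)
  gas <- sub("_.*$", "", target)
  kind <- sub("^.*_", "", target)
  names_ <- if (kind == "concentration") {
    concentration_config_names()
  } else {
    emission_config_names()
  }
  groups_map <- feature_groups(gas)
  lapply(names_, function(nm) {
    g <- config_groups_from_name(nm)
    stopifnot(length(g) > 0)
    if (kind == "concentration" && "concentrations" %in% g) {
      stop("concentration targets never include the concentrations group",
           call. = FALSE)
    }
    structure(
      list(name = nm, groups = g, target = target, gas = gas,
           columns = unlist(groups_map[g], use.names = FALSE)),
      class = "ablation_config"
    )
  })
}

#' @export
print.ablation_config <- function(x, ...) {
  cat(sprintf("<ablation_config> %s -> %s (%d features)\n",
              x$name, x$target, length(x$columns)))
  invisible(x)
}

#' Aggregate sub-hourly samples to hourly records
#'
#' Arithmetic mean per clock hour for linear variables; circular mean for
#' wind-direction columns (names starting `WD`). Hours with no samples
#' produce a row of missing values.
#'
#' @param samples data frame with a `POSIXct` `timestamp` column and
#'   numeric variable columns.
#' @return data frame with one row per hour spanned by the samples
#'   (`timestamp` = hour start) and the per-hour means.
#' @export
aggregate_hourly <- function(samples) {
  stopifnot(is.data.frame(samples), "timestamp" %in% names(samples),
            inherits(samples$timestamp, "POSIXct"))
  hour_start <- as.POSIXct(trunc(samples$timestamp, units = "hours"))
  hours <- seq(min(hour_start), max(hour_start), by = "hour")
  key <- match(hour_start, hours)
  vars <- setdiff(names(samples), "timestamp")
  out <- data.frame(timestamp = hours)
  for (v in vars) {
    vals <- rep(NA_real_, length(hours))
    fun <- if (startsWith(v, "WD")) circular_mean else function(x) mean(x, na.rm = TRUE)
    m <- tapply(samples[[v]], key, fun)
    vals[as.integer(names(m))] <- as.numeric(m)
    out[[v]] <- vals
  }
  out
}

#' Min/max normalisation fitted on training rows
#'
#' `minmax_fit()` learns per-feature minima and maxima from the training
#' partition only; `minmax_apply()` maps features linearly into
#' `[lower, upper]` (default `[-1, 1]`, the input range that suits tansig
#' units); `minmax_invert()` restores original units exactly on in-range
#' data. Constant features map to the midpoint of the output range (0 by
#' default) with a warning.
#'
#' @param x data frame or matrix of numeric features (training rows for
#'   `minmax_fit`; any rows for apply/invert).
#' @param lower,upper bounds of the normalised range.
#' @return `minmax_fit()` returns a `minmax_params` object; apply/invert
#'   return a numeric matrix with the same columns as `x`.
#' @export
minmax_fit <- function(x, lower = -1, upper = 1) {
  x <- as.matrix(x)
  stopifnot(is.numeric(x), upper > lower, nrow(x) >= 1)
  mins <- apply(x, 2, min)
  maxs <- apply(x, 2, max)
  constant <- maxs <= mins
  if (any(constant)) {
    warning("constant feature(s) map to the midpoint of the output range: ",
            paste(colnames(x)[constant], collapse = ", "), call. = FALSE)
  }
  structure(list(min = mins, max = maxs, lower = lower, upper = upper,
                 constant = constant),
            class = "minmax_params")
}

#' @rdname minmax_fit
#' @param params a `minmax_params` object from `minmax_fit()`.
#' @export
minmax_apply <- function(x, params) {
  stopifnot(inherits(params, "minmax_params"))
  x <- as.matrix(x)
  check_minmax_cols(x, params)
  rng <- params$max - params$min
  mid <- (params$lower + params$upper) / 2
  out <- sweep(x, 2, params$min)
  out <- sweep(out, 2, ifelse(params$constant, 1, rng), "/")
  out <- params$lower + (params$upper - params$lower) * out
  out[, params$constant] <- mid
  out
}

#' @rdname minmax_fit
#' @export
minmax_invert <- function(x, params) {
  stopifnot(inherits(params, "minmax_params"))
  x <- as.matrix(x)
  check_minmax_cols(x, params)
  rng <- params$max - params$min
  out <- (x - params$lower) / (params$upper - params$lower)
  out <- sweep(out, 2, ifelse(params$constant, 0, rng), "*")
  out <- sweep(out, 2, params$min, "+")
  out
}

check_minmax_cols <- function(x, params) {
  if (ncol(x) != length(params$min)) {
    stop("feature count does not match fitted normalisation parameters",
         call. = FALSE)
  }
  if (!is.null(colnames(x)) && !is.null(names(params$min)) &&
      !identical(colnames(x), names(params$min))) {
    stop("feature names do not match fitted normalisation parameters",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Random 70:15:15 train/validation/test partition
#'
#' Rows are permuted uniformly at random under `seed` and partitioned
#' 70:15:15. Fractional seats are assigned by the largest-remainder rule;
#' remainder ties are broken in the order training, validation, test.
#'
#' @param n number of rows (>= 10).
#' @param seed integer RNG seed; identical seed gives identical partition.
#' @param ratios partition fractions summing to 1.
#' @return an object of class `split_dataset`: list with integer index
#'   vectors `train`, `validation`, `test`, and the `seed`.
#' @examples
#' s <- split_70_15_15(100, seed = 1)
#' lengths(s[c("train", "validation", "test")])  # 70 15 15
#' @export
split_70_15_15 <- function(n, seed, ratios = c(0.70, 0.15, 0.15)) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 10,
            length(ratios) == 3L, abs(sum(ratios) - 1) < 1e-12)
  n <- as.integer(n)
  exact <- n * ratios
  sizes <- floor(exact)
  left <- n - sum(sizes)
  if (left > 0) {
    rem <- exact - sizes
    # largest remainder; ties broken toward earlier partitions
    order_idx <- order(-rem, seq_along(rem))
    sizes[order_idx[seq_len(left)]] <- sizes[order_idx[seq_len(left)]] + 1L
  }
  perm <- with_seed(seed, sample.int(n))
  structure(
    list(train = sort(perm[seq_len(sizes[1])]),
         validation = sort(perm[sizes[1] + seq_len(sizes[2])]),
         test = sort(perm[sizes[1] + sizes[2] + seq_len(sizes[3])]),
         seed = as.integer(seed)),
    class = "split_dataset"
  )
}

#' @export
print.split_dataset <- function(x, ...) {
  cat(sprintf("<split_dataset> train %d / validation %d / test %d (seed %d)\n",
              length(x$train), length(x$validation), length(x$test), x$seed))
  invisible(x)
}

#' Assemble the model matrix and target for one ablation configuration
#'
#' Extracts the configuration's feature columns and the target variable
#' from an hourly record table, dropping (with a message) rows that
#' contain missing values in either.
#'
#' @param records hourly record table (see [gen_study()]), for emission
#'   targets already augmented with the estimated emission column.
#' @param config an `ablation_config` from [feature_sets()].
#' @param target_column name of the target column; defaults to
#'   `<gas>_in` for concentration targets and `"E"` for emission targets.
#' @return list with `x` (numeric feature matrix), `y` (numeric target
#'   vector), `rows` (indices of retained rows) and `n_dropped`.
#' @export
assemble_features <- function(records, config, target_column = NULL) {
  stopifnot(inherits(config, "ablation_config"))
  if (is.null(target_column)) {
    target_column <- if (endsWith(config$target, "concentration")) {
      paste0(tolower(config$gas), "_in")
    } else {
      "E"
    }
  }
  need <- c(config$columns, target_column)
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols)) {
    stop("records is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  x <- as.matrix(records[config$columns])
  y <- records[[target_column]]
  ok <- stats::complete.cases(x) & is.finite(y)
  n_dropped <- sum(!ok)
  if (n_dropped > 0) {
    message(sprintf("dropping %d row(s) with missing values", n_dropped))
  }
  list(x = x[ok, , drop = FALSE], y = y[ok], rows = which(ok),
       n_dropped = n_dropped)
}
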