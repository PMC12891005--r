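# Radius estimation from 120-sample intensity transects.
#
# The regressor maps a background-normalized transect to a hyphal radius.
# Features are physically motivated summaries of the attenuation profile: for
# an unblurred cylinder projection the integrated attenuation deficit equals
# absorbance * pi * r^2, so its square root is proportional to the radius;
# widths at fractional depths and the second moment capture blur and defocus.

.profile_cols <- function(d) grep("^p[0-9]{3}$", names(d), value = TRUE)

.as_profile_matrix <- function(samples) {
  if (is.matrix(samples)) {
    m <- samples
  } else {
    cols <- .profile_cols(samples)
    if (length(cols) != 120) stop("expected 120 profile columns p001..p120")
    m <- as.matrix(samples[, cols])
  }
  if (ncol(m) != 120) stop("profiles must have length exactly 120")
  if (any(!is.finite(m))) stop("non-finite values in profiles")
  m
}

#' Extract regression features from transect profiles
#'
#' Profiles are normalized by the background level (median of the 15 outermost
#' pixels on each side); the attenuation deficit `max(0, 1 - I/background)`
#' yields the integrated deficit (um-equivalent), its square root (linear in
#' radius for an unblurred cylinder), the maximal depth, widths at 25/50/75%
#' of maximal depth (um), the deficit second moment, and the mean central
#' deficit.
#'
#' @param samples transect data.frame (profile columns `p001..p120`) or an
#'   n x 120 matrix.
#' @param pixel_size_um physical pixel size of the transect.
#' @return numeric feature matrix, one row per sample.
#' @export
transect_features <- function(samples, pixel_size_um = 2) {
  m <- .as_profile_matrix(samples)
  n <- nrow(m)
  edge_idx <- c(1:15, 106:120)
  bg <- apply(m[, edge_idx, drop = FALSE], 1, stats::median)
  bg[bg <= 0] <- 1
  deficit <- 1 - m / bg
  deficit[deficit < 0] <- 0
  x <- (seq_len(120) - 61) * pixel_size_um
  total_def <- rowSums(deficit) * pixel_size_um
  depth <- apply(deficit, 1, max)
  width_at <- function(frac) {
    thr <- frac * depth
    thr[thr < 1e-9] <- 1e-9
    rowSums(deficit >= thr) * pixel_size_um
  }
  centroid <- ifelse(rowSums(deficit) > 0,
                     as.numeric(deficit %*% x) / rowSums(deficit), 0)
  mom2 <- sqrt(pmax(0, as.numeric(deficit %*% x^2) / pmax(rowSums(deficit), 1e-12)
                    - centroid^2))
  central <- rowMeans(deficit[, 57:64, drop = FALSE])
  f <- cbind(sqrt_def = sqrt(total_def), total_def = total_def, depth = depth,
             w25 = width_at(0.25), w50 = width_at(0.5), w75 = width_at(0.75),
             mom2 = mom2, central = central)
  f[!is.finite(f)] <- 0
  f
}

#' Source-grouped train/test split
#'
#' Splits a transect dataset so that no `source_id` spans both sets (the test
#' set is entirely independent of the training sources). Sources are assigned
#' in seeded random order so the test fraction approaches `1 - train_fraction`
#' as closely as the grouping allows.
#'
#' @param samples transect data.frame with a `source_id` column.
#' @param train_fraction fraction of samples targeted for training, in (0,1).
#' @param seed RNG seed.
#' @return list with `train` and `test` data.frames.
#' @export
split_dataset <- function(samples, train_fraction = 0.9, seed = 1) {
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must be in (0, 1)")
  src <- samples$source_id
  ids <- unique(src)
  if (length(ids) < 2)
    stop("source-grouped split impossible with a single source id")
  target_test <- (1 - train_fraction) * nrow(samples)
  with_seed(seed, {
    ord <- sample(ids)
    sizes <- vapply(ord, function(s) sum(src == s), numeric(1))
    cum <- cumsum(sizes)
    k <- which.min(abs(cum - target_test))
    test_ids <- ord[seq_len(k)]
    list(train = samples[!(src %in% test_ids), , drop = FALSE],
         test = samples[src %in% test_ids, , drop = FALSE])
  })
}

#' Resample the test set to the training label distribution
#'
#' Computes the frequency distribution of training labels over `n_bins` equal
#' bins and samples, with replacement, test elements so that the resampled
#' test follows the training distribution. Bins with training mass but no
#' test members are skipped with a warning and the remaining mass
#' renormalized. `n_bins = 1` reduces to a plain bootstrap of the test set.
#'
#' @param train,test transect data.frames with a `label_um` column.
#' @param n_bins number of label bins (default 20).
#' @param n_out size of the resampled test set; default `nrow(test)`.
#' @param seed RNG seed.
#' @return resampled test data.frame.
#' @export
resample_test_to_train <- function(train, test, n_bins = 20, n_out = nrow(test),
                                   seed = 1) {
  if (n_bins < 1) stop("n_bins must be >= 1")
  if (nrow(train) == 0 || nrow(test) == 0) stop("train and test must be non-empty")
  rng <- range(c(train$label_um, test$label_um))
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  edges[1] <- edges[1] - 1e-9; edges[n_bins + 1] <- edges[n_bins + 1] + 1e-9
  bin_train <- cut(train$label_um, edges)
  bin_test <- cut(test$label_um, edges)
  p <- as.numeric(table(bin_train)) / nrow(train)
  members <- split(seq_len(nrow(test)), bin_test)
  empty <- p > 0 & vapply(members, length, integer(1)) == 0
  if (any(empty)) {
    warning(sum(empty), " bin(s) with training mass have no test members; skipped")
    p[empty] <- 0
  }
  if (sum(p) == 0) stop("no usable bins")
  p <- p / sum(p)
  with_seed(seed, {
    bins <- sample.int(n_bins, n_out, replace = TRUE, prob = p)
    idx <- vapply(bins, function(b) {
      mb <- members[[b]]
      mb[sample.int(length(mb), 1)]
    }, integer(1))
    test[idx, , drop = FALSE]
  })
}

#' Train the transect-to-radius regressor
#'
#' Fits a regressor from [transect_features()] to the radius labels. The
#' default method is a linear model on the feature basis (closed-form, fully
#' deterministic); `method = "xgb"` fits gradient-boosted trees (requires the
#' xgboost package). Predictions are clamped at 0.
#'
#' @param train transect data.frame with `label_um` and profile columns.
#' @param model_config list: `method` ("lm" or "xgb"), `pixel_size_um`,
#'   `seed`, and for xgb `nrounds`, `eta`, `max_depth`.
#' @return object of class `radius_estimator`.
#' @export
train_estimator <- function(train, model_config = list()) {
  cfg <- utils::modifyList(list(method = "lm", pixel_size_um = 2, seed = 1,
                                nrounds = 300, eta = 0.1, max_depth = 4),
                           model_config)
  if (nrow(train) < 50) stop("need at least 50 training samples")
  X <- transect_features(train, cfg$pixel_size_um)
  y <- train$label_um
  if (cfg$method == "lm") {
    co <- stats::coef(stats::lm.fit(cbind(`(Intercept)` = 1, X), y))
    co[is.na(co)] <- 0
    fit <- co
  } else if (cfg$method == "xgb") {
    if (!requireNamespace("xgboost", quietly = TRUE))
      stop("method 'xgb' requires the xgboost package")
    dtrain <- xgboost::xgb.DMatrix(X, label = y)
    fit <- xgboost::xgb.train(params = list(eta = cfg$eta,
                                            max_depth = cfg$max_depth,
                                            nthread = 1, seed = cfg$seed,
                                            objective = "reg:squarederror"),
                              data = dtrain, nrounds = cfg$nrounds)
  } else stop("unknown method: ", cfg$method)
  structure(list(method = cfg$method, fit = fit,
                 feature_names = colnames(X), config = cfg,
                 n_train = nrow(train)),
            class = "radius_estimator")
}

#' Predict radii for transect samples
#'
#' @param object a `radius_estimator`.
#' @param newdata transect data.frame or profile matrix.
#' @param ... unused.
#' @return predicted radii (um), clamped at 0.
#' @export
predict.radius_estimator <- function(object, newdata, ...) {
  X <- transect_features(newdata, object$config$pixel_size_um)
  p <- if (object$method == "lm") {
    as.numeric(cbind(1, X[, object$feature_names, drop = FALSE]) %*% object$fit)
  } else {
    as.numeric(stats::predict(object$fit, X))
  }
  pmax(0, p)
}

#' Evaluate a radius estimator on a test set
#'
#' Root-mean-square error (um) and coefficient of determination
#' `R^2 = 1 - SSres/SStot` of predictions against labels.
#'
#' @param model a `radius_estimator`.
#' @param test transect data.frame with `label_um`.
#' @param bin_edges optional label-resampling bin edges to record.
#' @return list of class `estimator_report`: `rmse_um`, `r_squared`,
#'   `n_train`, `n_test`, `bin_edges`, `zero_label_variance` flag.
#' @export
evaluate_estimator <- function(model, test, bin_edges = NULL) {
  if (nrow(test) == 0) stop("test set is empty")
  pred <- stats::predict(model, test)
  y <- test$label_um
  rmse <- sqrt(mean((pred - y)^2))
  ss_tot <- sum((y - mean(y))^2)
  zero_var <- ss_tot == 0
  if (zero_var) warning("zero label variance: R^2 undefined")
  structure(list(rmse_um = rmse,
                 r_squared = if (zero_var) NA_real_ else 1 - sum((pred - y)^2) / ss_tot,
                 n_train = model$n_train, n_test = nrow(test),
                 bin_edges = bin_edges, zero_label_variance = zero_var),
            class = "estimator_report")
}

#' @export
print.estimator_report <- function(x, ...) {
  cat(sprintf("<estimator_report: RMSE = %.3f um, R^2 = %s (train n=%d, test n=%d)>\n",
              x$rmse_um,
              if (is.na(x$r_squared)) "NA" else sprintf("%.3f", x$r_squared),
              x$n_train, x$n_test))
  invisible(x)
}

#' Per-edge radius assignment from transect bundles
#'
#' Applies the regressor to every transect of each edge (one per 10-px
#' skeleton segment in the imaging pipeline) and aggregates per edge
#' (median by default). Predictions below `empty_threshold_um` are treated as
#' empty-background transects and excluded from the aggregate; edges with
#' only empty transects are assigned radius 0.
#'
#' @param model a `radius_estimator`.
#' @param edge_transects data.frame with `edge_id` and profile columns, e.g.
#'   from [simulate_edge_transects()].
#' @param aggregate aggregation function over per-segment predictions.
#' @param empty_threshold_um predictions below this count as empty background
#'   (default 0.6 um, below the ~1 um radius of the thinnest real hyphae).
#' @return data.frame `edge_id`, `radius_um`, `n_transects`, `n_used`.
#' @export
predict_network_radii <- function(model, edge_transects, aggregate = stats::median,
                                  empty_threshold_um = 0.6) {
  pred <- stats::predict(model, edge_transects)
  ids <- edge_transects$edge_id
  out <- lapply(split(seq_along(ids), ids), function(i) {
    p <- pred[i]
    used <- p >= empty_threshold_um
    data.frame(edge_id = ids[i[1]],
               radius_um = if (any(used)) aggregate(p[used]) else 0,
               n_transects = length(p), n_used = sum(used))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$edge_id), , drop = FALSE]
}
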