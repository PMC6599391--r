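#' Weighted-average activity score
#'
#' Maps a construct's bin-count profile to an approximate fluorescence:
#' the mean fluorescence of each bin weighted by the proportion of log2
#' transformed counts in that bin,
#' `A_i = sum_b ybar_b * n_ib / sum_b n_ib`,
#' where `n_ib` are the log2 normalized counts. The score is bounded by
#' the smallest and largest per-bin mean fluorescence.
#'
#' @param counts_log2 numeric vector of per-bin log2 normalized counts, in
#'   bin order (length must match the scheme).
#' @param scheme a `bin_scheme` providing per-bin mean fluorescence.
#' @return Activity score (a.u.).
#' @export
activity_score <- function(counts_log2, scheme) {
  stopifnot(length(counts_log2) == nrow(scheme))
  tot <- sum(counts_log2)
  if (tot <= 0) {
    stop("all-zero count profile: activity score undefined", call. = FALSE)
  }
  sum(scheme$ybar * counts_log2) / tot
}

#' Activity scores for every construct and state in a screen
#'
#' Averages normalized counts across replicates per (construct, state,
#' bin), applies `log2(1 + x)`, and evaluates [activity_score()] against
#' that state's bin scheme. Constructs with an all-zero profile get `NA`
#' and are flagged.
#'
#' @param counts a normalized count tibble (needs a `norm` column, see
#'   [normalize_counts()]).
#' @param gates named list of `bin_scheme`s, one per state.
#' @return tibble (construct_id, state, activity, flagged).
#' @export
activity_scores <- function(counts, gates) {
  prof <- bin_profiles(counts)
  out <- dplyr::distinct(prof, .data$construct_id, .data$state)
  out$activity <- NA_real_
  out$flagged <- FALSE
  for (i in seq_len(nrow(out))) {
    sub <- prof[prof$construct_id == out$construct_id[i] &
                  prof$state == out$state[i], ]
    sub <- sub[order(match(sub$bin, BIN_LEVELS)), ]
    v <- log2(1 + sub$norm_mean)
    if (sum(v) <= 0) {
      out$flagged[i] <- TRUE
    } else {
      out$activity[i] <- activity_score(v, gates[[out$state[i]]])
    }
  }
  out
}

# mean normalized counts per construct x state x bin (replicates averaged)
bin_profiles <- function(counts) {
  val <- if ("norm" %in% names(counts)) "norm" else "count"
  dplyr::summarise(
    dplyr::group_by(counts, .data$construct_id, .data$state, .data$bin),
    norm_mean = mean(.data[[val]]), .groups = "drop")
}

#' Log2 median fluorescence of gated events
#'
#' @param events numeric vector of per-cell fluorescence values (a.u.).
#' @param gate optional interval `c(lo, hi)`; only events with
#'   `lo <= x < hi` are used.
#' @return log2 of the median of the gated events (even-length medians are
#'   midpoints).
#' @export
median_fluorescence <- function(events, gate = c(-Inf, Inf)) {
  x <- events[events >= gate[1] & events < gate[2]]
  if (length(x) == 0) stop("no events inside the gate", call. = FALSE)
  log2(median(x))
}

#' Per-promoter calibration targets from event tables
#'
#' @param events tibble (construct_id, state, fluorescence) with one row
#'   per cell, as measured for single-promoter infections.
#' @param gate optional gate interval passed to [median_fluorescence()].
#' @return tibble (construct_id, state, target) with target = log2 median
#'   fluorescence.
#' @export
calibration_targets <- function(events, gate = c(-Inf, Inf)) {
  dplyr::summarise(
    dplyr::group_by(events, .data$construct_id, .data$state),
    target = median_fluorescence(.data$fluorescence, gate),
    .groups = "drop")
}

#' Pick calibration constructs spanning the activity range
#'
#' Deterministic quantile-stratified choice: constructs are ordered by
#' their mean activity score across states (ties by construct_id) and `n`
#' evenly spaced constructs along that ordering are returned, emulating
#' the selection of training promoters covering a broad fluorescence
#' spectrum.
#'
#' @param scores tibble from [activity_scores()].
#' @param n number of constructs to select.
#' @return character vector of construct ids.
#' @export
select_calibration <- function(scores, n = 81) {
  avg <- dplyr::summarise(
    dplyr::group_by(scores, .data$construct_id),
    a = mean(.data$activity, na.rm = TRUE), .groups = "drop")
  avg <- avg[is.finite(avg$a), ]
  avg <- avg[order(avg$a, avg$construct_id), ]
  n <- min(n, nrow(avg))
  idx <- unique(round(seq(1, nrow(avg), length.out = n)))
  avg$construct_id[idx]
}

base_feature_names <- function() {
  c(paste0("logn_", BIN_LEVELS), "logn_total",
    paste0("prop_", BIN_LEVELS),
    paste0("ratio_", BIN_LEVELS[-1], "_", BIN_LEVELS[-5]),
    "argmax_bin")
}

#' Engineered count features for the fluorescence predictor
#'
#' Base features per construct and state (replicate-averaged normalized
#' counts, +1 pseudocount before logs and ratios): the five per-bin log2
#' counts, the log2 total, five pseudocounted bin proportions, four
#' adjacent-bin log-ratios, and the index of the maximal-count bin. All
#' pairwise first-degree interaction products of the base features are
#' appended, giving `p + p*(p-1)/2` columns.
#'
#' @param counts normalized count tibble (see [normalize_counts()]).
#' @param interactions include the pairwise interaction block
#'   (default TRUE).
#' @return tibble (construct_id, state, then feature columns).
#' @export
build_features <- function(counts, interactions = TRUE) {
  need <- BIN_LEVELS
  if (!all(need %in% as.character(unique(counts$bin)))) {
    stop("missing bin column(s): ",
         paste(setdiff(need, unique(counts$bin)), collapse = ", "),
         call. = FALSE)
  }
  prof <- bin_profiles(counts)
  wide <- tidyr::pivot_wider(prof, id_cols = c("construct_id", "state"),
                             names_from = "bin",
                             values_from = "norm_mean", values_fill = 0)
  nm <- as.matrix(wide[, BIN_LEVELS])
  logn <- log2(1 + nm)
  total <- rowSums(nm)
  prop <- (nm + 1) / (total + ncol(nm))
  ratio <- logn[, -1, drop = FALSE] - logn[, -ncol(logn), drop = FALSE]
  argmax <- max.col(nm, ties.method = "first")

  base <- cbind(logn, log2(1 + total), prop, ratio, argmax)
  colnames(base) <- base_feature_names()
  feat <- base
  if (interactions) {
    pairs <- utils::combn(ncol(base), 2)
    inter <- base[, pairs[1, ], drop = FALSE] *
      base[, pairs[2, ], drop = FALSE]
    bn <- base_feature_names()
    colnames(inter) <- paste0(bn[pairs[1, ]], ".x.", bn[pairs[2, ]])
    feat <- cbind(base, inter)
  }
  dplyr::bind_cols(wide[, c("construct_id", "state")],
                   tibble::as_tibble(feat))
}

feature_matrix <- function(features) {
  cols <- setdiff(names(features), c("construct_id", "state", "target"))
  m <- as.matrix(features[, cols])
  rownames(m) <- paste(features$construct_id, features$state, sep = ":")
  m
}

rmse <- function(obs, pred) sqrt(mean((obs - pred)^2))

# Pearson R2, defined as 0 when either side is constant (e.g. a fully
# penalized model predicting the intercept everywhere)
pearson_r2 <- function(obs, pred) {
  if (sd(pred) < 1e-12 || sd(obs) < 1e-12) return(0)
  cor(obs, pred)^2
}

#' Train the elastic-net fluorescence predictor
#'
#' Joins features with calibration targets, holds out a fraction of the
#' calibration constructs as a test set (the split is by construct so both
#' states of a promoter fall on the same side), selects the elastic-net
#' mixing and penalty by repeated k-fold cross-validated RMSE on the
#' training split, refits on the whole training split, and reports test
#' R-squared (Pearson) and RMSE alongside an ordinary least-squares
#' baseline on the non-interaction features.
#'
#' @param features tibble from [build_features()].
#' @param calibration tibble (construct_id, state, target) from
#'   [calibration_targets()].
#' @param train_frac fraction of calibration constructs used for training
#'   (default 0.6; the remaining 40% are the untouched test split).
#' @param cv_folds,cv_repeats repeated cross-validation design (default
#'   five-times 5-fold).
#' @param alpha_grid elastic-net mixing values to scan.
#' @param lambda_grid penalty values to scan (log-spaced 1e-4..10).
#' @param seed integer seed controlling the split and fold assignment.
#' @return An `activity_model`: coefficients, chosen (alpha, lambda),
#'   feature scaling parameters, CV record and held-out report.
#' @export
train_activity_model <- function(features, calibration, train_frac = 0.6,
                                 cv_folds = 5, cv_repeats = 5,
                                 alpha_grid = c(0, 0.25, 0.5, 0.75, 1),
                                 lambda_grid = 10^seq(-4, 1,
                                                      length.out = 30),
                                 seed = 1L) {
  dat <- dplyr::inner_join(features, calibration,
                           by = c("construct_id", "state"))
  ids <- unique(dat$construct_id)
  if (length(ids) < 20) {
    stop("need at least 20 calibration constructs", call. = FALSE)
  }
  if (length(ids) < cv_folds) {
    stop("fewer calibration constructs than CV folds", call. = FALSE)
  }
  set.seed(seed)
  train_ids <- sample(ids, round(train_frac * length(ids)))
  test_ids <- setdiff(ids, train_ids)
  tr <- dat[dat$construct_id %in% train_ids, ]
  te <- dat[dat$construct_id %in% test_ids, ]

  x_tr <- feature_matrix(tr)
  y_tr <- tr$target
  center <- colMeans(x_tr)
  scale_ <- apply(x_tr, 2, sd)
  scale_[scale_ == 0] <- 1
  xs_tr <- scale(x_tr, center = center, scale = scale_)

  lambda_grid <- sort(lambda_grid, decreasing = TRUE)
  cv_err <- array(0, dim = c(length(alpha_grid), length(lambda_grid)),
                  dimnames = list(alpha = alpha_grid,
                                  lambda = signif(lambda_grid, 4)))
  n_eval <- 0L
  tr_ids <- unique(tr$construct_id)
  for (r in seq_len(cv_repeats)) {
    fold_of <- sample(rep_len(seq_len(cv_folds), length(tr_ids)))
    for (f in seq_len(cv_folds)) {
      hold <- tr_ids[fold_of == f]
      in_hold <- tr$construct_id %in% hold
      if (sum(in_hold) == 0 || sum(!in_hold) < 2) next
      for (a in seq_along(alpha_grid)) {
        fit <- glmnet::glmnet(xs_tr[!in_hold, , drop = FALSE],
                              y_tr[!in_hold], alpha = alpha_grid[a],
                              lambda = lambda_grid, standardize = FALSE)
        pred <- predict(fit, xs_tr[in_hold, , drop = FALSE],
                        s = lambda_grid, exact = FALSE)
        cv_err[a, ] <- cv_err[a, ] +
          sqrt(colMeans((pred - y_tr[in_hold])^2))
      }
      n_eval <- n_eval + 1L
    }
  }
  cv_err <- cv_err / n_eval
  best <- which(cv_err == min(cv_err), arr.ind = TRUE)[1, ]
  alpha <- alpha_grid[best[1]]
  lambda <- lambda_grid[best[2]]

  fit <- glmnet::glmnet(xs_tr, y_tr, alpha = alpha, lambda = lambda_grid,
                        standardize = FALSE)
  beta <- as.numeric(coef(fit, s = lambda))
  names(beta) <- c("(Intercept)", colnames(xs_tr))

  model <- structure(
    list(family = "gaussian-elasticnet-interactions",
         coefficients = beta, alpha = alpha, lambda = lambda,
         center = center, scale = scale_,
         feature_names = colnames(x_tr),
         cv_rmse = cv_err, seed = seed, version = "1"),
    class = "activity_model")

  pred_te <- predict_activity(model, te)$predicted
  base_cols <- intersect(base_feature_names(), names(tr))
  df_tr <- as.data.frame(tr[, base_cols])
  df_tr$.y <- y_tr
  lmfit <- stats::lm(.y ~ ., data = df_tr)
  lm_pred <- predict(lmfit, as.data.frame(te[, base_cols]))

  model$report <- list(
    n_train = nrow(tr), n_test = nrow(te),
    train_ids = sort(train_ids), test_ids = sort(test_ids),
    test_r2 = pearson_r2(te$target, pred_te),
    test_rmse = rmse(te$target, pred_te),
    baseline_lm_r2 = pearson_r2(te$target, lm_pred),
    baseline_lm_rmse = rmse(te$target, lm_pred))
  model
}

#' @exportS3Method base::print
print.activity_model <- function(x, ...) {
  cat("<activity_model> elastic net (alpha = ", x$alpha,
      ", lambda = ", signif(x$lambda, 3), "), ",
      sum(x$coefficients[-1] != 0), "/", length(x$coefficients) - 1,
      " nonzero coefficients\n", sep = "")
  if (!is.null(x$report)) {
    cat("  held-out: R2 = ", round(x$report$test_r2, 3),
        ", RMSE = ", round(x$report$test_rmse, 3),
        " (n = ", x$report$n_test, ")\n", sep = "")
  }
  invisible(x)
}

#' Predict log2 median fluorescence for a feature table
#'
#' @param model an `activity_model`.
#' @param features tibble from [build_features()]; its feature schema must
#'   match the training schema.
#' @return tibble (construct_id, state, predicted).
#' @export
predict_activity <- function(model, features) {
  missing <- setdiff(model$feature_names, names(features))
  if (length(missing) > 0) {
    stop("feature schema mismatch; missing: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  x <- as.matrix(features[, model$feature_names])
  xs <- scale(x, center = model$center, scale = model$scale)
  pred <- drop(xs %*% model$coefficients[-1]) + model$coefficients[1]
  tibble::tibble(construct_id = features$construct_id,
                 state = features$state, predicted = unname(pred))
}

#' Predict over the whole library, flagging filtered constructs
#'
#' Constructs present in `all_ids` but absent from the feature table
#' (e.g. removed by [replicate_filter()]) appear with `NA` predictions and
#' `filtered = TRUE` rather than silently disappearing.
#'
#' @param model an `activity_model`.
#' @param features feature tibble for the constructs that passed filters.
#' @param all_ids optional character vector of every library construct id.
#' @return tibble (construct_id, state, predicted, filtered).
#' @export
predict_library <- function(model, features, all_ids = NULL) {
  pred <- predict_activity(model, features)
  pred$filtered <- FALSE
  if (!is.null(all_ids)) {
    states <- unique(pred$state)
    full <- tidyr::expand_grid(construct_id = all_ids, state = states)
    pred <- dplyr::left_join(full, pred, by = c("construct_id", "state"))
    pred$filtered[is.na(pred$filtered)] <- TRUE
  }
  pred
}

#' Save / load an activity model (versioned JSON archive)
#'
#' Numeric values are stored at full precision so a reloaded model yields
#' bit-identical predictions.
#'
#' @param model an `activity_model`.
#' @param path file path for the JSON archive.
#' @return `save_model` invisibly returns the path; `load_model` returns
#'   the model.
#' @export
save_model <- function(model, path) {
  obj <- unclass(model)
  obj$cv_rmse <- NULL # bulky diagnostic, not needed for prediction
  # doubles as %.17g strings: decimal JSON numbers would lose the last ulp
  enc <- function(x) stats::setNames(sprintf("%.17g", x), names(x))
  obj$coefficients <- enc(obj$coefficients)
  obj$center <- enc(obj$center)
  obj$scale <- enc(obj$scale)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  dec <- function(x) stats::setNames(as.numeric(x), names(x))
  obj$coefficients <- dec(unlist(obj$coefficients))
  obj$center <- dec(unlist(obj$center))
  obj$scale <- dec(unlist(obj$scale))
  structure(obj, class = "activity_model")
}
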