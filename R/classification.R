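#' Predicted-denominator sensitivity and specificity
#'
#' The classification protocol reports sensitivity as the fraction of true
#' patients among the participants *predicted* as patients, and
#' specificity as the fraction of true controls among those predicted as
#' controls (note the predicted-class denominators, unlike the textbook
#' truth-denominator definitions).
#'
#' @param truth Character vector of `"control"`/`"patient"` labels.
#' @param predicted Character vector of predicted labels.
#' @return List with `sensitivity` and `specificity`; a rate is `NA` when
#'   its predicted class is empty.
#' @export
predicted_rates <- function(truth, predicted) {
  pred_pat <- predicted == "patient"
  pred_con <- predicted == "control"
  sens <- if (any(pred_pat)) mean(truth[pred_pat] == "patient") else NA_real_
  spec <- if (any(pred_con)) mean(truth[pred_con] == "control") else NA_real_
  list(sensitivity = sens, specificity = spec)
}

hist_or_zero <- function(values, bins, range) {
  if (length(values) == 0) return(rep(0, bins))
  make_histogram(values, bins, range)
}

# design matrix for one leave-one-out fold: histogram ranges and scalar
# standardisation are frozen on the training participants only
fold_design <- function(features, feature_subset, bins, test_id) {
  ids <- names(features)
  train_ids <- setdiff(ids, test_id)
  cols <- list()
  for (f in feature_subset) {
    is_scalar <- f %in% names(features[[1]]$scalars)
    if (is_scalar) {
      v <- vapply(features, function(p) p$scalars[[f]], numeric(1))
      mu <- mean(v[train_ids]); sdv <- stats::sd(v[train_ids])
      if (!is.finite(sdv) || sdv == 0) sdv <- 1
      cols[[f]] <- matrix((v - mu) / sdv, ncol = 1)
    } else {
      pooled <- unlist(lapply(features[train_ids], function(p) p$values[[f]]))
      rng <- if (length(pooled) == 0) c(0, 1) else range(pooled)
      if (rng[1] == rng[2]) rng[2] <- rng[1] + 1
      cols[[f]] <- t(vapply(features, function(p)
        hist_or_zero(p$values[[f]], bins, rng), numeric(bins)))
    }
  }
  X <- do.call(cbind, cols)
  rownames(X) <- ids
  X
}

#' Leave-one-out patient/control classification with repeated runs
#'
#' Logistic regression fitted by plain stochastic gradient descent
#' (constant learning rate, fixed step budget, random initialisation, no
#' regularisation), evaluated leave-one-participant-out: for each fold the
#' model is trained on all other participants and the held-out
#' participant's control-class probability is recorded; a participant is
#' predicted control iff that probability exceeds 0.5.  Because the
#' optimiser is stochastic, the whole experiment is repeated `runs` times;
#' prediction uncertainty is summarised as the mean over participants of
#' the standard deviation of their `runs` probabilities, and
#' sensitivity/specificity (predicted-class denominators, see
#' [predicted_rates()]) are computed per run and summarised by their
#' medians.
#'
#' Histogram bin ranges and scalar standardisation are recomputed per fold
#' from the training participants only, so the held-out participant never
#' leaks into the feature representation.
#'
#' @param features Named list (by participant) of records with `group`,
#'   `scalars` and `values` (see [assemble_feature_values()]).
#' @param feature_subset Character vector of feature names (scalars and/or
#'   histogram features) to use.
#' @param bins Histogram bins (default 10).
#' @param runs Number of repeated experiments (default 50).
#' @param steps SGD step budget per fit (default 10000).
#' @param lr Constant SGD learning rate (default 1e-3).
#' @param seed Integer master seed.
#' @return A list of class `mm_loo` with the participant-by-run
#'   probability matrix `prob`, per-run `sensitivity` and `specificity`,
#'   their medians, and `uncertainty`.
#' @export
loo_classify <- function(features, feature_subset, bins = 10, runs = 50,
                         steps = 10000, lr = 1e-3, seed = 1) {
  if (length(feature_subset) == 0) stop("empty feature subset")
  ids <- names(features)
  groups <- vapply(features, function(p) p$group, character(1))
  if (sum(groups == "control") < 2 || sum(groups == "patient") < 2)
    stop("need at least 2 participants per group")
  n <- length(ids)
  y <- as.numeric(groups == "control")
  designs <- lapply(ids, function(id)
    cbind(1, fold_design(features, feature_subset, bins, id)))
  names(designs) <- ids
  set.seed(seed)
  prob <- matrix(NA_real_, n, runs, dimnames = list(ids, NULL))
  for (r in seq_len(runs)) {
    for (k in seq_len(n)) {
      X <- designs[[k]]
      Xtr <- X[-k, , drop = FALSE]
      w0 <- stats::rnorm(ncol(X), 0, 0.01)
      ord <- sample.int(n - 1, steps, replace = TRUE)
      w <- sgd_logistic_cpp(Xtr, y[-k], w0, ord, lr)
      z <- sum(w * X[k, ])
      prob[k, r] <- 1 / (1 + exp(-z))
    }
  }
  pred <- ifelse(prob > 0.5, "control", "patient")
  sens <- numeric(runs); spec <- numeric(runs)
  for (r in seq_len(runs)) {
    rt <- predicted_rates(groups, pred[, r])
    sens[r] <- rt$sensitivity; spec[r] <- rt$specificity
  }
  if (anyNA(sens) || anyNA(spec))
    message("some runs never predicted one of the classes; ",
            "their rates are excluded from the medians")
  structure(list(prob = prob,
                 sensitivity = sens, specificity = spec,
                 median_sensitivity = stats::median(sens, na.rm = TRUE),
                 median_specificity = stats::median(spec, na.rm = TRUE),
                 uncertainty = mean(apply(prob, 1, stats::sd))),
            class = "mm_loo")
}

#' @export
print.mm_loo <- function(x, ...) {
  cat(sprintf(paste0("<mm_loo> %d participants, %d runs: median sensitivity ",
                     "%.2f, median specificity %.2f, uncertainty %.3f\n"),
              nrow(x$prob), ncol(x$prob), x$median_sensitivity,
              x$median_specificity, x$uncertainty))
  invisible(x)
}

#' Alone-versus-accompanied segment classification
#'
#' Pools the labelled segments of the patients (controls are excluded) and
#' classifies each segment as produced alone or accompanied with an
#' RBF-kernel support vector machine on raw per-segment features,
#' standardised on the training split.  Each repeat holds out a random
#' `test_fraction` of the segments; accuracy is reported per repeat and as
#' the median.
#'
#' @param seg_df Data frame of patient segments with a `companionship`
#'   column (`"alone"`/`"accompanied"`; other rows are dropped) and the
#'   feature columns.
#' @param feature_cols Feature columns to use (default: segment
#'   complexity, total turning angle, number of stops, distance from
#'   home).
#' @param test_fraction Held-out fraction per repeat (default 0.2).
#' @param repeats Number of random splits (default 20).
#' @param cost,gamma SVM parameters; `gamma = NULL` uses `1/p` on the
#'   standardised features (the library-default contract).
#' @param seed Integer master seed.
#' @return A list of class `mm_svm` with `accuracies` and
#'   `median_accuracy`.
#' @export
classify_alone_accompanied <- function(seg_df,
                                       feature_cols = c("complexity",
                                                        "total_turning_angle",
                                                        "n_stops",
                                                        "distance_from_home"),
                                       test_fraction = 0.2, repeats = 20,
                                       cost = 1, gamma = NULL, seed = 1) {
  seg_df <- seg_df[seg_df$companionship %in% c("alone", "accompanied"), ,
                   drop = FALSE]
  y <- factor(seg_df$companionship, levels = c("alone", "accompanied"))
  if (min(table(y)) < 10)
    stop("need at least 10 segments per class")
  X <- as.matrix(seg_df[, feature_cols, drop = FALSE])
  n <- nrow(X)
  n_test <- max(1L, floor(n * test_fraction))
  if (is.null(gamma)) gamma <- 1 / ncol(X)
  set.seed(seed)
  acc <- numeric(repeats)
  for (r in seq_len(repeats)) {
    repeat {
      test <- sample.int(n, n_test)
      if (length(unique(y[-test])) == 2) break
      message("training split missed a class; resampling")
    }
    mu <- colMeans(X[-test, , drop = FALSE])
    sdv <- apply(X[-test, , drop = FALSE], 2, stats::sd)
    sdv[!is.finite(sdv) | sdv == 0] <- 1
    Z <- sweep(sweep(X, 2, mu), 2, sdv, "/")
    fit <- e1071::svm(Z[-test, , drop = FALSE], y[-test], kernel = "radial",
                      cost = cost, gamma = gamma, scale = FALSE)
    pr <- stats::predict(fit, Z[test, , drop = FALSE])
    acc[r] <- mean(pr == y[test])
  }
  structure(list(accuracies = acc, median_accuracy = stats::median(acc)),
            class = "mm_svm")
}

#' @export
print.mm_svm <- function(x, ...) {
  cat(sprintf("<mm_svm> %d repeats: median accuracy %.2f\n",
              length(x$accuracies), x$median_accuracy))
  invisible(x)
}

#' Compare feature combinations by LOO classification performance
#'
#' Runs [loo_classify()] once per feature subset (same seed and settings
#' throughout) and tabulates median sensitivity, median specificity and
#' uncertainty — the grid used to compare singleton features against their
#' pairs and triples.
#'
#' @param features As for [loo_classify()].
#' @param subsets List of character vectors of feature names.
#' @param ... Passed on to [loo_classify()].
#' @return Data frame with one row per subset.
#' @export
feature_combination_report <- function(features, subsets, ...) {
  if (length(subsets) == 0)
    return(data.frame(features = character(0),
                      median_sensitivity = numeric(0),
                      median_specificity = numeric(0),
                      uncertainty = numeric(0)))
  rows <- lapply(subsets, function(fs) {
    res <- loo_classify(features, fs, ...)
    data.frame(features = paste(fs, collapse = "+"),
               median_sensitivity = res$median_sensitivity,
               median_specificity = res$median_specificity,
               uncertainty = res$uncertainty,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
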