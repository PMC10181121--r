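# Cross-validated multi-class identification (RBF-kernel SVM) and the
# incremental channel-subset accuracy curve.

#' Classifier configuration
#'
#' Settings for the cross-validated RBF-kernel SVM. The kernel scale grid
#' is relative: actual gamma = \code{gamma_grid / d} with d the number of
#' features after standardization (so \code{gamma_grid = 1} is the usual
#' 1/d default). When the grid has a single (cost, gamma) combination the
#' inner tuning loop is skipped.
#'
#' @param cost_grid Box-constraint values C to tune over.
#' @param gamma_grid Relative kernel-scale values to tune over.
#' @param folds Outer stratified fold count (default 10).
#' @param inner_folds Fold count for the inner tuning loop (default 3).
#' @param seed Integer seed controlling fold assignment.
#' @return A \code{classifier_config} list.
#' @export
classifier_config <- function(cost_grid = c(0.1, 1, 10, 100),
                              gamma_grid = c(0.01, 0.1, 1, 10),
                              folds = 10, inner_folds = 3, seed = 1) {
  stopifnot(folds >= 2, inner_folds >= 2,
            length(cost_grid) > 0, length(gamma_grid) > 0,
            all(cost_grid > 0), all(gamma_grid > 0))
  structure(list(cost_grid = cost_grid, gamma_grid = gamma_grid,
                 folds = folds, inner_folds = inner_folds, seed = seed),
            class = "classifier_config")
}

#' Classification metrics from a confusion matrix
#'
#' Macro-averaged precision, recall and F1 over classes (a class never
#' predicted contributes zero precision; a class with zero precision and
#' recall contributes zero F1) and the generalized multiclass Matthews
#' correlation coefficient (Gorodkin's R_K), all in percent.
#'
#' @param confusion Square nonnegative count matrix, rows = true class,
#'   columns = predicted class.
#' @return Named numeric vector \code{precision, recall, f1, mcc} (%).
#' @export
compute_metrics <- function(confusion) {
  cm <- as.matrix(confusion)
  if (nrow(cm) == 0L || nrow(cm) != ncol(cm) || any(cm < 0) || sum(cm) == 0)
    stop("confusion matrix must be square, nonnegative, nonempty")
  tp <- diag(cm)
  pred <- colSums(cm)
  truth <- rowSums(cm)
  prec <- ifelse(pred > 0, tp / pred, 0)
  rec <- ifelse(truth > 0, tp / truth, 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  s <- sum(cm)
  c_ok <- sum(tp)
  num <- c_ok * s - sum(pred * truth)
  den <- sqrt(s^2 - sum(pred^2)) * sqrt(s^2 - sum(truth^2))
  mcc <- if (den == 0) 0 else num / den
  100 * c(precision = mean(prec), recall = mean(rec),
          f1 = mean(f1), mcc = mcc)
}

# Stratified fold assignment: within each class, rows are shuffled and
# dealt round-robin over folds. Depends only on (row order, labels, seed).
stratified_folds <- function(labels, k, seed) {
  fold <- integer(length(labels))
  with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  fold
}

standardize_fit <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2L, stats::sd)
  sdv[sdv == 0] <- 1
  list(mu = mu, sd = sdv)
}
standardize_apply <- function(X, fit) {
  sweep(sweep(X, 2L, fit$mu), 2L, fit$sd, "/")
}

fit_predict_svm <- function(Xtr, ytr, Xte, cost, gamma) {
  m <- e1071::svm(Xtr, ytr, type = "C-classification", kernel = "radial",
                  cost = cost, gamma = gamma, scale = FALSE)
  stats::predict(m, Xte)
}

# Mean macro precision of (cost, gamma) over an inner stratified CV on the
# training split.
inner_grid_select <- function(X, y, config) {
  combos <- expand.grid(cost = config$cost_grid, gamma = config$gamma_grid)
  if (nrow(combos) == 1L) return(combos[1L, ])
  d <- ncol(X)
  fold <- stratified_folds(y, config$inner_folds, config$seed + 1L)
  best <- NULL; best_prec <- -1
  for (i in seq_len(nrow(combos))) {
    precs <- numeric(config$inner_folds)
    for (f in seq_len(config$inner_folds)) {
      tr <- fold != f
      pred <- fit_predict_svm(X[tr, , drop = FALSE], y[tr],
                              X[!tr, , drop = FALSE],
                              combos$cost[i], combos$gamma[i] / d)
      cm <- table(factor(y[!tr], levels(y)), factor(pred, levels(y)))
      precs[f] <- compute_metrics(cm)[["precision"]]
    }
    if (mean(precs) > best_prec) { best_prec <- mean(precs); best <- combos[i, ] }
  }
  best
}

#' Cross-validated multi-class identification
#'
#' Stratified k-fold cross-validation of an RBF-kernel SVM identifying the
#' subject of each epoch. Per outer fold: features are standardized on the
#' training split only, (C, gamma) are selected by inner cross-validated
#' macro precision on the training split, the model is refit and the held
#' out fold predicted. Macro precision, recall, F1 and multiclass MCC are
#' reported per fold and as mean +/- sd.
#'
#' @param table A \code{feature_table}.
#' @param config A [classifier_config()].
#' @return An object of class \code{metrics_summary}: fields
#'   \code{per_fold} (folds x 4 matrix, %), \code{mean}, \code{sd},
#'   \code{chosen} (per-fold C and gamma), \code{n} (rows used).
#' @export
crossval_classify <- function(table, config = classifier_config()) {
  stopifnot(inherits(table, "feature_table"))
  X <- table$values
  y <- factor(table$subject)
  if (nlevels(y) < 2L) stop("need at least 2 subjects")
  if (any(table(y) < config$folds))
    stop("every subject must have at least as many epochs as folds")
  fold <- stratified_folds(y, config$folds, config$seed)
  per_fold <- matrix(NA_real_, config$folds, 4L,
                     dimnames = list(NULL, c("precision", "recall",
                                             "f1", "mcc")))
  chosen <- data.frame(cost = numeric(config$folds),
                       gamma = numeric(config$folds))
  d <- ncol(X)
  for (f in seq_len(config$folds)) {
    tr <- fold != f
    if (nlevels(droplevels(y[tr])) < nlevels(y))
      stop("a class is absent from training fold ", f)
    std <- standardize_fit(X[tr, , drop = FALSE])
    Xtr <- standardize_apply(X[tr, , drop = FALSE], std)
    Xte <- standardize_apply(X[!tr, , drop = FALSE], std)
    sel <- inner_grid_select(Xtr, y[tr], config)
    chosen$cost[f] <- sel$cost
    chosen$gamma[f] <- sel$gamma / d
    pred <- fit_predict_svm(Xtr, y[tr], Xte, sel$cost, sel$gamma / d)
    cm <- table(factor(y[!tr], levels(y)), factor(pred, levels(y)))
    per_fold[f, ] <- compute_metrics(cm)
  }
  structure(list(per_fold = per_fold,
                 mean = colMeans(per_fold),
                 sd = apply(per_fold, 2L, stats::sd),
                 chosen = chosen, n = nrow(X), folds = config$folds),
            class = "metrics_summary")
}

#' @export
print.metrics_summary <- function(x, ...) {
  cat("Cross-validated identification (", x$folds, " folds, ", x$n,
      " epochs)\n", sep = "")
  for (m in colnames(x$per_fold))
    cat(sprintf("  %-9s %6.2f +/- %5.2f %%\n", m, x$mean[[m]], x$sd[[m]]))
  invisible(x)
}

#' Incremental channel-subset evaluation
#'
#' For subset sizes n = all channels down to 1, restricts the feature
#' table to the features supported by the top-n ranked channels and runs
#' [crossval_classify()], tracing identification accuracy as channels are
#' removed in reverse relevance order.
#'
#' @param table A \code{feature_table}.
#' @param ranking A \code{channel_ranking} over the table's montage.
#' @param config A [classifier_config()].
#' @return An object of class \code{subset_evaluation}: \code{results} is
#'   a data frame with one row per subset size (\code{n_channels,
#'   channels, n_features, precision_mean, precision_sd, recall_mean,
#'   recall_sd, f1_mean, f1_sd, mcc_mean, mcc_sd}); \code{summaries}
#'   holds the full \code{metrics_summary} objects.
#' @export
incremental_evaluation <- function(table, ranking,
                                   config = classifier_config()) {
  stopifnot(inherits(ranking, "channel_ranking"))
  if (!identical(ranking$montage$channels,
                 attr(table$catalog, "montage")$channels))
    stop("ranking and table are over different montages")
  ch_sorted <- ranking$table$channel
  sizes <- rev(seq_along(ch_sorted))
  rows <- list(); summaries <- list()
  for (n in sizes) {
    subset <- ch_sorted[seq_len(n)]
    sub_tab <- subset_feature_table(table, subset)
    ms <- crossval_classify(sub_tab, config)
    rows[[length(rows) + 1L]] <- data.frame(
      n_channels = n, channels = paste(subset, collapse = " "),
      n_features = ncol(sub_tab$values),
      precision_mean = ms$mean[["precision"]], precision_sd = ms$sd[["precision"]],
      recall_mean = ms$mean[["recall"]], recall_sd = ms$sd[["recall"]],
      f1_mean = ms$mean[["f1"]], f1_sd = ms$sd[["f1"]],
      mcc_mean = ms$mean[["mcc"]], mcc_sd = ms$sd[["mcc"]])
    summaries[[as.character(n)]] <- ms
  }
  structure(list(results = do.call(rbind, rows), summaries = summaries,
                 ranking = ranking, config = config),
            class = "subset_evaluation")
}

#' @export
print.subset_evaluation <- function(x, ...) {
  cat("Incremental channel-subset evaluation (", x$ranking$method,
      " ranking)\n", sep = "")
  df <- x$results[, c("n_channels", "n_features",
                      "precision_mean", "precision_sd")]
  print(df, digits = 4, row.names = FALSE)
  cat("Note: epoch-level cross-validation; epochs of one subject occur in\n")
  cat("both training and validation folds (identification protocol).\n")
  invisible(x)
}

#' Accuracy-versus-channel-count curve
#'
#' @param x A \code{subset_evaluation}.
#' @param ... Passed to \code{plot}.
#' @export
plot.subset_evaluation <- function(x, ...) {
  df <- x$results
  graphics::plot(df$n_channels, df$precision_mean, type = "b", pch = 19,
                 ylim = c(0, 100), xlab = "number of channels",
                 ylab = "macro precision (%)",
                 main = "Identification accuracy vs channel count", ...)
  graphics::arrows(df$n_channels, df$precision_mean - df$precision_sd,
                   df$n_channels, df$precision_mean + df$precision_sd,
                   angle = 90, code = 3, length = 0.03)
  invisible(x)
}
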