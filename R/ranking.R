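# Feature-relevance orderings (PCA or pairwise Wilcoxon signed-rank) and
# their conversion into weighted channel scores:
#   Score_ch = sum_i W_ch,i,j  with  W_ch,i,j = k_j * P_i / f_j,
# where P_i is the feature's position value (most relevant feature of a
# group of size f_j gets P = f_j, the least relevant gets 1) and k_j is the
# group weight constant.

group_columns <- function(table, group) {
  stopifnot(inherits(table, "feature_table"),
            group %in% c("PS", "AI", "PLV"))
  names <- table$catalog$name[table$catalog$group == group]
  if (length(names) == 0L) stop("group ", group, " is empty in this catalog")
  table$values[, names, drop = FALSE]
}

new_feature_ordering <- function(group, features, method, diagnostics) {
  f <- length(features)
  P <- seq(f, 1L)
  names(P) <- features
  structure(list(group = group, features = features, P = P,
                 method = method, diagnostics = diagnostics),
            class = "feature_ordering")
}

#' @export
print.feature_ordering <- function(x, ...) {
  cat("Feature ordering (", x$method, "), group ", x$group, ", ",
      length(x$features), " features; most relevant: ",
      paste(utils::head(x$features, 3L), collapse = ", "), " ...\n", sep = "")
  invisible(x)
}

#' Order one feature group by PCA loadings
#'
#' The group's columns are z-scored, the principal components of the group
#' submatrix are computed, and features are sorted by decreasing absolute
#' loading on the first component (ties broken by canonical catalog
#' order). Zero-variance columns are dropped from the decomposition with a
#' warning and assigned the lowest positions.
#'
#' @param table A \code{feature_table}.
#' @param group \code{"PS"}, \code{"AI"} or \code{"PLV"}.
#' @return A \code{feature_ordering} with position values \code{P}
#'   (\code{f_j} for the most relevant feature down to 1) and the loadings
#'   and explained-variance ratios as diagnostics.
#' @export
pca_order <- function(table, group) {
  X <- group_columns(table, group)
  if (nrow(X) < 2L) stop("need at least 2 rows")
  sds <- apply(X, 2L, stats::sd)
  degenerate <- sds == 0
  if (any(degenerate))
    warning("zero-variance column(s) dropped from PCA: ",
            paste(colnames(X)[degenerate], collapse = ", "))
  Xs <- scale(X[, !degenerate, drop = FALSE])
  pc <- stats::prcomp(Xs, center = FALSE, scale. = FALSE)
  loading <- abs(pc$rotation[, 1L])
  ord_live <- colnames(Xs)[order(-loading)]     # stable: ties by position
  features <- c(ord_live, colnames(X)[degenerate])
  loads <- stats::setNames(rep(0, ncol(X)), colnames(X))
  loads[names(loading)] <- loading
  new_feature_ordering(group, features, "pca",
                       list(loadings = loads[features],
                            explained = pc$sdev^2 / sum(pc$sdev^2)))
}

#' Cumulative explained-variance curve of a feature group
#'
#' Fraction of the (z-scored) group variance retained by the first
#' 1, 2, ... principal components; nondecreasing, ending at 1.
#'
#' @inheritParams pca_order
#' @return Numeric vector of cumulative explained-variance ratios.
#' @export
explained_variance_curve <- function(table, group) {
  X <- group_columns(table, group)
  sds <- apply(X, 2L, stats::sd)
  Xs <- scale(X[, sds > 0, drop = FALSE])
  pc <- stats::prcomp(Xs, center = FALSE, scale. = FALSE)
  cumsum(pc$sdev^2) / sum(pc$sdev^2)
}

# Vectorized paired Wilcoxon signed-rank p-values, one per column of the
# difference matrix D, matching stats::wilcox.test(paired = TRUE,
# exact = FALSE, correct = TRUE): zero differences dropped, average ranks
# for ties, normal approximation with tie correction and continuity
# correction. Verified against wilcox.test in the test suite.
signed_rank_p <- function(D) {
  apply(D, 2L, function(d) {
    d <- d[d != 0]
    n <- length(d)
    if (n == 0L) return(1)
    r <- rank(abs(d))
    V <- sum(r[d > 0])
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    if (sigma2 <= 0) return(1)
    z <- V - mu
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)
    min(2 * min(stats::pnorm(z), stats::pnorm(z, lower.tail = FALSE)), 1)
  })
}

#' Order one feature group by pairwise Wilcoxon signed-rank tests
#'
#' For every unordered pair of subjects, each feature of the group is
#' tested with a paired signed-rank test on epoch-index-matched samples
#' (both subjects truncated to the common epoch count), and the features
#' are sorted by ascending p-value within that test. The per-test ranks
#' are then aggregated across all subject pairs by modal rank (the
#' position a feature occupies most often), with ties broken by better
#' mean rank and then canonical order.
#'
#' @inheritParams pca_order
#' @return A \code{feature_ordering}; diagnostics hold the per-feature
#'   modal and mean ranks and the number of pairwise tests.
#' @export
wilcoxon_order <- function(table, group) {
  X <- group_columns(table, group)
  subjects <- unique(table$subject)
  if (length(subjects) < 2L) stop("need at least 2 subjects")
  counts <- table(table$subject)
  if (any(counts < 2L))
    stop("every subject needs at least 2 epochs; offending: ",
         paste(names(counts)[counts < 2L], collapse = ", "))
  pairs <- utils::combn(subjects, 2L)
  f <- ncol(X)
  ranks <- matrix(0L, ncol(pairs), f)
  for (t in seq_len(ncol(pairs))) {
    ia <- which(table$subject == pairs[1L, t])
    ib <- which(table$subject == pairs[2L, t])
    ia <- ia[order(table$epoch[ia])]
    ib <- ib[order(table$epoch[ib])]
    m <- min(length(ia), length(ib))
    p <- signed_rank_p(X[ia[seq_len(m)], , drop = FALSE] -
                         X[ib[seq_len(m)], , drop = FALSE])
    ranks[t, ] <- rank(p, ties.method = "first")
  }
  modal <- integer(f); meanr <- numeric(f)
  for (jj in seq_len(f)) {
    tab <- tabulate(ranks[, jj], nbins = f)
    modal[jj] <- which.max(tab)      # smallest most-frequent rank
    meanr[jj] <- mean(ranks[, jj])
  }
  ord <- order(modal, meanr, seq_len(f))
  features <- colnames(X)[ord]
  new_feature_ordering(group, features, "wilcoxon",
                       list(modal_rank = stats::setNames(modal, colnames(X))[ord],
                            mean_rank = stats::setNames(meanr, colnames(X))[ord],
                            n_tests = ncol(pairs)))
}

#' Group weight constants for channel scoring
#'
#' @param k_PS,k_AI,k_PLV Strictly positive dimensionless weights; the
#'   defaults (2, 1, 1.2) reflect the relative contribution of each
#'   feature group to identification accuracy.
#' @return A \code{scoring_config} list.
#' @export
scoring_config <- function(k_PS = 2, k_AI = 1, k_PLV = 1.2) {
  stopifnot(k_PS > 0, k_AI > 0, k_PLV > 0)
  structure(list(k_PS = k_PS, k_AI = k_AI, k_PLV = k_PLV),
            class = "scoring_config")
}

#' Weight of one feature towards a channel score
#'
#' \code{k * P / f}: the group constant times the feature's position value
#' over the group size.
#'
#' @param k Group weight constant (> 0).
#' @param P Position value, between 1 and \code{f}.
#' @param f Group size.
#' @return The weight, exactly \code{k * P / f}.
#' @export
feature_weight <- function(k, P, f) {
  if (any(P < 1) || any(P > f)) stop("position value out of range [1, f]")
  if (any(k <= 0)) stop("k must be positive")
  k * P / f
}

#' Convert feature orderings into a channel ranking
#'
#' Every feature contributes the weight \code{k_j * P_i / f_j} to each
#' channel it involves (one channel for PS, both channels for AI and PLV);
#' a channel's score is the sum over all its features, and channels are
#' sorted by descending score (ties by montage order).
#'
#' @param orderings Named or unnamed list of \code{feature_ordering}
#'   objects covering every catalog feature exactly once.
#' @param catalog A [feature_catalog].
#' @param config A [scoring_config()].
#' @return An object of class \code{channel_ranking}; its \code{table}
#'   field holds \code{rank, channel, score, score_PS, score_AI,
#'   score_PLV}, and \code{weights} the per-feature weight breakdown.
#' @export
score_channels <- function(orderings, catalog, config = scoring_config()) {
  stopifnot(inherits(catalog, "feature_catalog"))
  P_all <- do.call(c, unname(lapply(orderings, `[[`, "P")))
  f_all <- do.call(c, unname(lapply(orderings, function(o)
    stats::setNames(rep(length(o$P), length(o$P)), names(o$P)))))
  missing <- setdiff(catalog$name, names(P_all))
  if (length(missing) > 0L)
    stop("features missing from the orderings: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  k_of <- c(PS = config$k_PS, AI = config$k_AI, PLV = config$k_PLV)
  w <- feature_weight(k_of[catalog$group],
                      P_all[catalog$name], f_all[catalog$name])
  weights <- data.frame(feature = catalog$name, group = catalog$group,
                        ch1 = catalog$ch1, ch2 = catalog$ch2,
                        P = as.integer(P_all[catalog$name]),
                        f = as.integer(f_all[catalog$name]),
                        weight = as.numeric(w))
  mont <- attr(catalog, "montage")
  ch <- mont$channels
  score_g <- matrix(0, length(ch), 3L,
                    dimnames = list(ch, c("PS", "AI", "PLV")))
  for (g in colnames(score_g)) {
    sub <- weights[weights$group == g, , drop = FALSE]
    for (r in seq_len(nrow(sub))) {
      score_g[sub$ch1[r], g] <- score_g[sub$ch1[r], g] + sub$weight[r]
      if (!is.na(sub$ch2[r]))
        score_g[sub$ch2[r], g] <- score_g[sub$ch2[r], g] + sub$weight[r]
    }
  }
  total <- rowSums(score_g)
  ord <- order(-total, seq_along(ch))
  tab <- data.frame(rank = seq_along(ch), channel = ch[ord],
                    score = total[ord],
                    score_PS = score_g[ord, "PS"],
                    score_AI = score_g[ord, "AI"],
                    score_PLV = score_g[ord, "PLV"],
                    row.names = NULL)
  structure(list(table = tab, weights = weights, orderings = orderings,
                 montage = mont, config = config,
                 method = orderings[[1]]$method),
            class = "channel_ranking")
}

#' Rank channels by biometric relevance
#'
#' The central fitting function: orders every feature group of the table
#' by relevance with the chosen backend ([pca_order()] or
#' [wilcoxon_order()]) and converts the orderings into weighted channel
#' scores with [score_channels()].
#'
#' @param table A \code{feature_table} built by [build_feature_table()].
#' @param method \code{"pca"} (default) or \code{"wilcoxon"}.
#' @param config A [scoring_config()].
#' @return A \code{channel_ranking}; see [score_channels()]. Use
#'   \code{coef()} for the named score vector, \code{summary()} for the
#'   per-group breakdown and \code{plot()} for a schematic topography.
#' @examples
#' sim <- simulate_eeg(sim_config(n_subjects = 3, duration_s = 12, seed = 1))
#' epochs <- lapply(sim$recordings, preprocess)
#' catalog <- feature_catalog(load_montage("emotiv14"))
#' tab <- build_feature_table(epochs, catalog)
#' rk <- rank_channels(tab, method = "pca")
#' head(rk$table, 4)
#' @export
rank_channels <- function(table, method = c("pca", "wilcoxon"),
                          config = scoring_config()) {
  method <- match.arg(method)
  stopifnot(inherits(table, "feature_table"))
  groups <- intersect(c("PS", "AI", "PLV"), unique(table$catalog$group))
  backend <- if (method == "pca") pca_order else wilcoxon_order
  orderings <- lapply(groups, function(g) backend(table, g))
  names(orderings) <- groups
  score_channels(orderings, table$catalog, config)
}

#' @export
print.channel_ranking <- function(x, ...) {
  cat("Channel ranking (", x$method, " backend), montage '",
      x$montage$name, "'\n", sep = "")
  print(x$table, digits = 4)
  invisible(x)
}

#' @export
summary.channel_ranking <- function(object, ...) {
  cat("Channel ranking, method =", object$method, "\n")
  print(object$table, digits = 4)
  cat("\nTop features per group:\n")
  for (o in object$orderings)
    cat(sprintf("  %-3s (f = %d): %s\n", o$group, length(o$features),
                paste(utils::head(o$features, 5L), collapse = ", ")))
  invisible(object)
}

#' @export
coef.channel_ranking <- function(object, ...) {
  stats::setNames(object$table$score, object$table$channel)
}

#' Schematic topographic plot of channel scores
#'
#' @param x A \code{channel_ranking}.
#' @param ... Passed to \code{plot}.
#' @export
plot.channel_ranking <- function(x, ...) {
  pos <- x$montage$positions
  sc <- coef(x)[rownames(pos)]
  size <- 0.5 + 2.5 * (sc - min(sc)) / max(1e-12, diff(range(sc)))
  graphics::plot(pos[, "x"], pos[, "y"], cex = size, pch = 21,
                 bg = grDevices::grey(1 - (size - 0.5) / 2.5),
                 xlab = "x (left-right)", ylab = "y (posterior-anterior)",
                 main = paste0("Channel scores (", x$method, ")"),
                 asp = 1, ...)
  graphics::text(pos[, "x"], pos[, "y"], rownames(pos), pos = 3, cex = 0.7)
  graphics::symbols(0, 0, circles = 1.15, inches = FALSE, add = TRUE)
  invisible(x)
}
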