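# The feature universe induced by a montage: one band-power (PS) feature per
# channel, one asymmetry-index (AI) feature per mirror pair, one phase-locking
# (PLV) feature per unordered channel pair.

#' Enumerate the feature universe of a montage
#'
#' Builds the canonical feature catalog: PS features in montage channel
#' order, then AI features in mirror-pair order, then PLV features over all
#' unordered channel pairs in lexicographic channel-index order. For an
#' n-channel montage with p mirror pairs this yields
#' n + p + n(n-1)/2 features (112 for the 14-channel Emotiv layout,
#' 2107 for the 64-channel BCI2000 layout).
#'
#' @param montage A [montage] object.
#' @return An object of class \code{feature_catalog}: a data frame with
#'   columns \code{group} ("PS", "AI" or "PLV"), \code{name} (canonical
#'   names such as \code{"PS:AF3"}, \code{"AI:F3/F4"},
#'   \code{"PLV:AF3-F7"}), \code{ch1} and \code{ch2} (\code{NA} for PS;
#'   for AI, \code{ch1} is always the left channel), plus attributes
#'   \code{montage} and \code{group_sizes}.
#' @export
feature_catalog <- function(montage) {
  stopifnot(inherits(montage, "montage"))
  ch <- montage$channels
  ps <- data.frame(group = "PS", name = paste0("PS:", ch),
                   ch1 = ch, ch2 = NA_character_)
  mp <- montage$mirror_pairs
  ai <- if (nrow(mp) > 0L)
    data.frame(group = "AI",
               name = paste0("AI:", mp[, 1], "/", mp[, 2]),
               ch1 = mp[, 1], ch2 = mp[, 2])
  else ps[0L, ]
  n <- length(ch)
  if (n >= 2L) {
    idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    plv <- data.frame(group = "PLV",
                      name = paste0("PLV:", ch[idx[, 1]], "-", ch[idx[, 2]]),
                      ch1 = ch[idx[, 1]], ch2 = ch[idx[, 2]])
  } else plv <- ps[0L, ]
  cat_df <- rbind(ps, ai, plv)
  rownames(cat_df) <- NULL
  structure(cat_df,
            montage = montage,
            group_sizes = c(PS = nrow(ps), AI = nrow(ai), PLV = nrow(plv)),
            class = c("feature_catalog", "data.frame"))
}

#' Restrict a feature catalog to a channel subset
#'
#' Keeps exactly the features whose supporting channels are all contained in
#' \code{subset}, preserving the canonical order. For a subset of n channels
#' containing p intact mirror pairs the result has n + p + n(n-1)/2
#' features.
#'
#' @param catalog A [feature_catalog].
#' @param subset Character vector of channel labels, a subset of the
#'   catalog's montage channels.
#' @return A \code{feature_catalog} over the same montage.
#' @export
supported_features <- function(catalog, subset) {
  stopifnot(inherits(catalog, "feature_catalog"))
  mont <- attr(catalog, "montage")
  unknown <- setdiff(subset, mont$channels)
  if (length(unknown) > 0L)
    stop("unknown channel label(s): ", paste(unknown, collapse = ", "))
  keep <- catalog$ch1 %in% subset &
    (is.na(catalog$ch2) | catalog$ch2 %in% subset)
  out <- catalog[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out,
            montage = mont,
            group_sizes = c(PS = sum(out$group == "PS"),
                            AI = sum(out$group == "AI"),
                            PLV = sum(out$group == "PLV")),
            class = c("feature_catalog", "data.frame"))
}

#' @export
print.feature_catalog <- function(x, ...) {
  gs <- attr(x, "group_sizes")
  cat("Feature catalog over montage '", attr(x, "montage")$name, "': ",
      nrow(x), " features (", gs[["PS"]], " PS, ", gs[["AI"]], " AI, ",
      gs[["PLV"]], " PLV)\n", sep = "")
  invisible(x)
}
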