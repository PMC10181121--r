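# Montages: named electrode sets with schematic 2-D scalp positions and
# left/right mirror pairs. The montage fixes the feature universe downstream.

#' Construct a montage
#'
#' A montage is a named set of EEG channels with schematic head-centred 2-D
#' positions and an explicit left/right mirror-pair structure. Mirror pairs
#' are stored as (left, right) so that asymmetry indices always place the
#' left-hemisphere channel in the numerator.
#'
#' @param name Identifier for the montage.
#' @param channels Character vector of unique channel labels, in acquisition
#'   order.
#' @param positions Numeric matrix with one row per channel and columns
#'   \code{x} (towards the right ear) and \code{y} (towards the nasion),
#'   unitless head-centred coordinates. May be \code{NULL}, in which case a
#'   schematic layout is derived from the 10-20/10-10 label grammar.
#' @param mirror_pairs Two-column character matrix, columns
#'   \code{c("left", "right")}; every entry must be a channel label and no
#'   label may appear twice. \code{NULL} infers pairs from label homology
#'   (odd index = left, even index = right, e.g. F3/F4).
#'
#' @return An object of class \code{montage} with fields \code{name},
#'   \code{channels}, \code{positions}, \code{mirror_pairs} and
#'   \code{midline} (labels in no pair).
#' @seealso [load_montage()] for the built-in montages,
#'   [feature_catalog()] for the feature universe a montage induces.
#' @export
montage <- function(name, channels, positions = NULL, mirror_pairs = NULL) {
  channels <- as.character(channels)
  if (anyDuplicated(channels))
    stop("duplicate channel labels: ",
         paste(unique(channels[duplicated(channels)]), collapse = ", "))
  if (is.null(mirror_pairs))
    mirror_pairs <- infer_mirror_pairs(channels)
  mirror_pairs <- as.matrix(mirror_pairs)
  if (length(mirror_pairs) == 0L)
    mirror_pairs <- matrix(character(0), 0L, 2L)
  if (ncol(mirror_pairs) != 2L) stop("mirror_pairs must have two columns")
  colnames(mirror_pairs) <- c("left", "right")
  paired <- as.vector(mirror_pairs)
  if (!all(paired %in% channels))
    stop("mirror-pair label not a montage channel: ",
         paste(setdiff(paired, channels), collapse = ", "))
  if (anyDuplicated(paired))
    stop("a channel appears in more than one mirror pair")
  if (is.null(positions)) positions <- schematic_positions(channels)
  positions <- as.matrix(positions)
  if (nrow(positions) != length(channels) || ncol(positions) != 2L)
    stop("positions must be a |channels| x 2 matrix")
  rownames(positions) <- channels
  colnames(positions) <- c("x", "y")
  structure(
    list(name = name, channels = channels, positions = positions,
         mirror_pairs = mirror_pairs,
         midline = setdiff(channels, paired)),
    class = "montage")
}

#' Load a built-in or file-defined montage
#'
#' Built-ins: \code{"emotiv14"}, the 14-channel Emotiv EPOC+ layout
#' (10-20 placement, 7 mirror pairs, no midline channels), and
#' \code{"bci2000_64"}, the 64-channel BCI2000 10-10 layout (27 mirror
#' pairs, 10 midline channels). Any other string is taken as the path of a
#' plain-text definition file with one row per channel,
#' \code{label x y side} (side L, R or Z, whitespace-separated, \code{#}
#' comments); mirror pairs are inferred from label homology, with explicit
#' overrides allowed as lines \code{pair <left> <right>}.
#'
#' @param source Montage name or definition-file path.
#' @return A [montage] object.
#' @export
load_montage <- function(source) {
  if (source == "emotiv14") return(montage_emotiv14())
  if (source == "bci2000_64") return(montage_bci2000_64())
  if (!file.exists(source))
    stop("unknown montage name and no such file: ", source)
  parse_montage_file(source)
}

montage_emotiv14 <- function() {
  ch <- c("AF3", "F7", "F3", "FC5", "T7", "P7", "O1",
          "O2", "P8", "T8", "FC6", "F4", "F8", "AF4")
  montage("emotiv14", ch)
}

montage_bci2000_64 <- function() {
  ch <- c("FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6",
          "C5", "C3", "C1", "Cz", "C2", "C4", "C6",
          "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6",
          "Fp1", "Fpz", "Fp2", "AF7", "AF3", "AFz", "AF4", "AF8",
          "F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8",
          "FT7", "FT8", "T7", "T8", "T9", "T10", "TP7", "TP8",
          "P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8",
          "PO7", "PO3", "POz", "PO4", "PO8", "O1", "Oz", "O2", "Iz")
  montage("bci2000_64", ch)
}

# Split a 10-20/10-10 label into the row prefix and the site suffix
# (an integer, or "z" for midline). Returns NULL when the label does not
# follow the grammar.
parse_label <- function(label) {
  m <- regmatches(label, regexec("^([A-Za-z]+?)([0-9]+|z|Z)$", label))[[1]]
  if (length(m) == 0L) return(NULL)
  list(prefix = m[2], site = m[3])
}

# Infer (left, right) homologous pairs: odd site index = left hemisphere,
# the homologue is the same row with index + 1.
infer_mirror_pairs <- function(channels) {
  pairs <- matrix(character(0), 0L, 2L)
  for (lab in channels) {
    p <- parse_label(lab)
    if (is.null(p) || p$site %in% c("z", "Z")) next
    n <- as.integer(p$site)
    if (n %% 2L == 1L) {
      right <- paste0(p$prefix, n + 1L)
      if (right %in% channels) pairs <- rbind(pairs, c(lab, right))
    }
  }
  pairs
}

# Schematic scalp layout from the label grammar: rows give y (front positive),
# the site index gives the lateral offset. Not a geodesic projection; used
# for reports and topographic plots only.
schematic_positions <- function(channels) {
  row_y <- c(FP = 0.90, AF = 0.72, F = 0.54, FT = 0.28, FC = 0.28,
             T = 0.00, C = 0.00, TP = -0.28, CP = -0.28, P = -0.54,
             PO = -0.72, O = -0.90, I = -1.05)
  pos <- matrix(NA_real_, length(channels), 2L,
                dimnames = list(channels, c("x", "y")))
  for (i in seq_along(channels)) {
    p <- parse_label(channels[i])
    if (is.null(p)) { pos[i, ] <- c(0, 0); next }
    key <- toupper(p$prefix)
    y <- if (key %in% names(row_y)) row_y[[key]] else 0
    if (p$site %in% c("z", "Z")) {
      x <- 0
    } else {
      n <- as.integer(p$site)
      lateral <- ceiling(n / 2) * 0.22
      x <- if (n %% 2L == 1L) -lateral else lateral
    }
    pos[i, ] <- c(x, y)
  }
  pos
}

parse_montage_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty montage definition: ", path)
  toks <- strsplit(lines, "[[:space:]]+")
  is_pair <- vapply(toks, function(t) t[1] == "pair", logical(1))
  chan_toks <- toks[!is_pair]
  bad <- lengths(chan_toks) != 4L
  if (any(bad))
    stop("malformed montage definition line: ",
         paste(lines[!is_pair][bad], collapse = "; "))
  labels <- vapply(chan_toks, `[`, "", 1L)
  xy <- t(vapply(chan_toks, function(t) {
    v <- suppressWarnings(as.numeric(t[2:3]))
    if (anyNA(v)) stop("non-numeric coordinate for channel ", t[1])
    v
  }, numeric(2)))
  side <- toupper(vapply(chan_toks, `[`, "", 4L))
  if (!all(side %in% c("L", "R", "Z")))
    stop("side must be L, R or Z")
  pairs <- infer_mirror_pairs(labels)
  if (any(is_pair)) {
    overrides <- t(vapply(toks[is_pair], function(t) {
      if (length(t) != 3L) stop("pair override needs two labels")
      t[2:3]
    }, character(2)))
    keep <- !(pairs[, 1] %in% overrides) & !(pairs[, 2] %in% overrides)
    pairs <- rbind(pairs[keep, , drop = FALSE], overrides)
  }
  # a declared Z channel must not end up paired
  z <- labels[side == "Z"]
  pairs <- pairs[!(pairs[, 1] %in% z) & !(pairs[, 2] %in% z), , drop = FALSE]
  montage(basename(path), labels, positions = xy, mirror_pairs = pairs)
}

#' @export
print.montage <- function(x, ...) {
  cat("Montage '", x$name, "': ", length(x$channels), " channels, ",
      nrow(x$mirror_pairs), " mirror pairs, ",
      length(x$midline), " midline\n", sep = "")
  cat("  channels:", paste(x$channels, collapse = " "), "\n")
  invisible(x)
}
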