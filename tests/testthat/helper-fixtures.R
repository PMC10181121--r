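# Shared fixtures, all built in code.

# Minimal montages for combinatorial tests.
tiny_montage <- function() {
  montage("tiny3", c("F3", "F4", "Cz"),
          positions = cbind(c(-0.4, 0.4, 0), c(0.5, 0.5, 0)),
          mirror_pairs = matrix(c("F3", "F4"), 1L))
}

pair_montage <- function() {
  montage("pair2", c("C3", "C4"),
          positions = cbind(c(-0.4, 0.4), c(0, 0)),
          mirror_pairs = matrix(c("C3", "C4"), 1L))
}

# A feature_table built directly from a value matrix (bypassing the signal
# pipeline) for ranking/evaluation tests.
manual_table <- function(values, subject, catalog,
                         epoch = NULL, band = c(13, 30), fs = 128) {
  if (is.null(epoch))
    epoch <- as.integer(stats::ave(seq_along(subject), subject,
                                   FUN = seq_along))
  colnames(values) <- catalog$name
  structure(list(values = values, subject = subject, epoch = epoch,
                 catalog = catalog, band = band, fs = fs),
            class = "feature_table")
}

# Random montage with n channels (labels X1L/X1R... plus midline) for
# brute-force scoring oracles.
random_montage <- function(n_pairs, n_mid) {
  left <- sprintf("H%d1", seq_len(n_pairs))
  right <- sprintf("H%d2", seq_len(n_pairs))
  mid <- if (n_mid > 0) sprintf("Mz%d", seq_len(n_mid)) else character(0)
  chans <- sample(c(left, right, mid))
  montage(paste0("rand", n_pairs, "_", n_mid), chans,
          positions = cbind(stats::runif(length(chans), -1, 1),
                            stats::runif(length(chans), -1, 1)),
          mirror_pairs = cbind(left, right))
}

# Small, fast simulated study for pipeline-level tests.
quick_sim <- function(seed, n_subjects = 4, duration_s = 20, ...) {
  sim_config(n_subjects = n_subjects, duration_s = duration_s,
             seed = seed, ...)
}

quick_table <- function(seed, n_subjects = 4, duration_s = 20, ...) {
  sim <- simulate_eeg(quick_sim(seed, n_subjects, duration_s, ...))
  ep <- lapply(sim$recordings, preprocess)
  build_feature_table(ep, feature_catalog(sim$recordings[[1]]$montage))
}

# Single-combination tuning grid: fast and sufficient where accuracy level,
# not tuning, is under test.
fast_config <- function(seed, folds = 10) {
  classifier_config(cost_grid = 10, gamma_grid = 1,
                    folds = folds, seed = seed)
}
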