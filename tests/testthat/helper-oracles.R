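# Independent oracles used across tests.

# O(n^2) exhaustive nearest-neighbour search; the reference the spatial
# index is checked against.
brute_nn <- function(src, tgt) {
  apply(src, 1, function(p) {
    sqrt(min((tgt[, 1] - p[1])^2 + (tgt[, 2] - p[2])^2 +
               (tgt[, 3] - p[3])^2))
  })
}

# Greedy 1-1 matching of detections (strongest first, as returned) to
# ground-truth coordinates within `tol` um; returns the hit count.
greedy_match <- function(det_df, truth_df, tol = 0.5) {
  if (nrow(det_df) == 0L) return(0L)
  used <- rep(FALSE, nrow(truth_df))
  hits <- 0L
  for (i in seq_len(nrow(det_df))) {
    d2 <- (truth_df$x - det_df$x_um[i])^2 +
      (truth_df$y - det_df$y_um[i])^2 +
      (truth_df$z - det_df$z_um[i])^2
    d2[used] <- Inf
    j <- which.min(d2)
    if (d2[j] <= tol^2) {
      used[j] <- TRUE
      hits <- hits + 1L
    }
  }
  hits
}

# A small field preset for fast render/detect unit tests (same puncta
# density class as the shipped fields, much smaller footprint).
small_preset <- function(n_pre = 20, n_post = 25, paired_fraction = 0.8,
                         offset_mu = 1.0, offset_sigma = 0.8,
                         extent = c(x = 12, y = 12, z = 6), ...) {
  field_preset("test-small", n_pre, n_post, paired_fraction,
               offset_mu, offset_sigma, extent = extent, ...)
}

# Run the full simulate -> render -> detect -> mask-filter chain for one
# seed and return the two detected puncta sets.
run_chain <- function(preset, seed, ...) {
  fld <- sample_field(preset, seed)
  st <- render_field(fld, seed = seed + 131071L, ...)
  list(field = fld,
       pre = filter_by_mask(detect_puncta(st, "ctbp2"), st),
       post = filter_by_mask(detect_puncta(st, "shank1"), st))
}
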