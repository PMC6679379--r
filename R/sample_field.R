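#' Sample a ground-truth synapse point field from a preset
#'
#' Draws one observation field: realised puncta counts are binomial
#' thinnings of the preset counts by the expression scales (sham presets
#' have scale 1 and keep the full counts), a fixed fraction of presynaptic
#' puncta receives a postsynaptic partner displaced by a folded-normal
#' offset magnitude in a uniformly random 3D direction, and all remaining
#' puncta are placed uniformly in the field. The same `(preset, seed)`
#' always yields the identical field.
#'
#' @param preset a [field_preset()].
#' @param seed integer seed.
#' @return an object of class `ground_truth_field`: list with `pre_points`
#'   and `post_points` (data.frames with columns `x`, `y`, `z` in um),
#'   `pairing` (data.frame `pre`, `post` of 1-based row indices), `preset`
#'   and `seed`.
#' @export
sample_field <- function(preset, seed) {
  if (!inherits(preset, "field_preset"))
    stop("`preset` must be a field_preset", call. = FALSE)
  ext <- preset$extent
  with_seed(seed, {
    n_pre <- if (preset$expression_scale_pre < 1)
      rbinom(1L, preset$n_pre, preset$expression_scale_pre) else preset$n_pre
    n_post <- if (preset$expression_scale_post < 1)
      rbinom(1L, preset$n_post, preset$expression_scale_post) else preset$n_post

    n_paired <- round(preset$paired_fraction * n_pre)
    n_paired <- min(n_paired, n_post)

    runif3 <- function(n) cbind(x = runif(n, 0, ext["x"]),
                                y = runif(n, 0, ext["y"]),
                                z = runif(n, 0, ext["z"]))
    pre <- runif3(n_pre)
    post <- matrix(NA_real_, n_post, 3,
                   dimnames = list(NULL, c("x", "y", "z")))
    if (n_paired > 0L) {
      for (i in seq_len(n_paired)) {
        r <- abs(rnorm(1L, preset$offset_mu, preset$offset_sigma))
        # uniform direction; re-draw direction (then magnitude) until the
        # partner lands inside the field, so the offset law is preserved
        for (try in 1:200) {
          u <- rnorm(3L)
          u <- u / sqrt(sum(u * u))
          cand <- pre[i, ] + r * u
          if (all(cand >= 0) && all(cand <= ext[c("x", "y", "z")])) break
          if (try %% 50 == 0)
            r <- abs(rnorm(1L, preset$offset_mu, preset$offset_sigma))
        }
        post[i, ] <- cand
      }
    }
    if (n_post > n_paired)
      post[(n_paired + 1L):n_post, ] <- runif3(n_post - n_paired)

    pairing <- if (n_paired > 0L)
      data.frame(pre = seq_len(n_paired), post = seq_len(n_paired))
    else data.frame(pre = integer(0), post = integer(0))

    structure(list(pre_points = as.data.frame(pre),
                   post_points = as.data.frame(post),
                   pairing = pairing, preset = preset,
                   seed = as.integer(seed)),
              class = "ground_truth_field")
  })
}

#' @export
print.ground_truth_field <- function(x, ...) {
  cat(sprintf("<ground_truth_field '%s' seed=%d>\n", x$preset$label, x$seed))
  cat(sprintf("  %d pre, %d post, %d pairs\n",
              nrow(x$pre_points), nrow(x$post_points), nrow(x$pairing)))
  invisible(x)
}

#' Serialise a ground-truth field to a tabular file
#'
#' One row per punctum: `channel` (`pre`/`post`), `x`, `y`, `z` (um) and
#' `pair_id` (shared integer for generated pairs, `NA` otherwise).
#'
#' @param field a `ground_truth_field`.
#' @param path output CSV path.
#' @export
write_field <- function(field, path) {
  pre <- field$pre_points
  post <- field$post_points
  pid_pre <- rep(NA_integer_, nrow(pre))
  pid_post <- rep(NA_integer_, nrow(post))
  if (nrow(field$pairing) > 0L) {
    pid_pre[field$pairing$pre] <- seq_len(nrow(field$pairing))
    pid_post[field$pairing$post] <- seq_len(nrow(field$pairing))
  }
  df <- rbind(
    data.frame(channel = rep("pre", nrow(pre)), pre, pair_id = pid_pre),
    data.frame(channel = rep("post", nrow(post)), post, pair_id = pid_post))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a serialised ground-truth field table
#' @param path CSV written by [write_field()].
#' @return data.frame with columns `channel`, `x`, `y`, `z`, `pair_id`.
#' @export
read_field <- function(path) read.csv(path, stringsAsFactors = FALSE)

#' Ground-truth coordinates of one channel as a puncta set
#'
#' Convenience bridge from the generator to the distance metrics: wraps the
#' true coordinates of one channel in the same container the detector
#' returns, so metric code paths are identical for ground truth and
#' detections.
#'
#' @param field a `ground_truth_field`.
#' @param channel `"pre"` or `"post"`.
#' @return a `puncta_set`.
#' @export
field_puncta <- function(field, channel = c("pre", "post")) {
  channel <- match.arg(channel)
  pts <- if (channel == "pre") field$pre_points else field$post_points
  puncta_set(data.frame(channel = rep(channel, nrow(pts)),
                        x_um = pts$x, y_um = pts$y, z_um = pts$z,
                        peak = NA_real_, volume_um3 = NA_real_),
             channel = channel,
             field_area = unname(field$preset$extent["x"] *
                                   field$preset$extent["y"] * 1e-6),
             source = sprintf("%s/seed%d", field$preset$label, field$seed))
}
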