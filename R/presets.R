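#' Construct a synapse field preset
#'
#' A field preset describes the generating conditions for one experimental
#' group: how many presynaptic (ribbon, CtBP2-like) and postsynaptic
#' (SHANK-1-like) puncta populate one observation field, which fraction of
#' presynaptic puncta is paired with a postsynaptic partner, and the law of
#' the paired pre-post offset magnitude. Paper-calibrated presets use the
#' standard observation field of 4.5e-3 mm^2 (67.08 x 67.08 um) with a 12 um
#' axial extent.
#'
#' The paired offset magnitude is folded-normal, |N(offset_mu, offset_sigma)|
#' in um; unpaired puncta are uniform in the field. Lesion presets thin the
#' sham counts binomially through `expression_scale_pre` / `_post`, which
#' encode the group's protein expression as a fraction of sham.
#'
#' @param label preset name, e.g. `"sham-utricle"`.
#' @param n_pre,n_post sham-level puncta counts per field (non-negative).
#' @param paired_fraction fraction of (realised) presynaptic puncta given a
#'   postsynaptic partner, in `[0, 1]`.
#' @param offset_mu,offset_sigma location/scale (um) of the folded-normal
#'   paired offset magnitude.
#' @param extent named numeric `c(x=, y=, z=)` field extent in um.
#' @param expression_scale_pre,expression_scale_post binomial thinning
#'   probabilities relative to sham counts, in `[0, 1]`.
#' @param anchors optional data.frame with columns `distance_um`,
#'   `fraction` recording the cumulative-distance calibration targets.
#' @return an object of class `field_preset`.
#' @export
field_preset <- function(label, n_pre, n_post, paired_fraction,
                         offset_mu, offset_sigma,
                         extent = c(x = 67.082, y = 67.082, z = 12),
                         expression_scale_pre = 1,
                         expression_scale_post = 1,
                         anchors = NULL) {
  if (!is.character(label) || length(label) != 1L)
    stop("`label` must be a single string", call. = FALSE)
  for (nm in c("n_pre", "n_post")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0 ||
        v != round(v))
      stop(sprintf("invalid preset: `%s` must be a non-negative count", nm),
           call. = FALSE)
  }
  if (!is.numeric(paired_fraction) || paired_fraction < 0 ||
      paired_fraction > 1)
    stop("invalid preset: `paired_fraction` must lie in [0, 1]",
         call. = FALSE)
  stop_if_not_scalar_pos(offset_sigma, "offset_sigma")
  if (!is.numeric(offset_mu) || offset_mu < 0)
    stop("invalid preset: `offset_mu` must be >= 0", call. = FALSE)
  extent <- extent[c("x", "y", "z")]
  if (any(is.na(extent)) || any(extent <= 0))
    stop("invalid preset: `extent` needs positive x, y, z entries",
         call. = FALSE)
  for (nm in c("expression_scale_pre", "expression_scale_post")) {
    v <- get(nm)
    if (!is.numeric(v) || v < 0 || v > 1)
      stop(sprintf("invalid preset: `%s` must lie in [0, 1]", nm),
           call. = FALSE)
  }
  structure(list(label = label,
                 n_pre = as.integer(n_pre), n_post = as.integer(n_post),
                 paired_fraction = paired_fraction,
                 offset_mu = offset_mu, offset_sigma = offset_sigma,
                 extent = extent,
                 expression_scale_pre = expression_scale_pre,
                 expression_scale_post = expression_scale_post,
                 anchors = anchors),
            class = "field_preset")
}

#' @export
print.field_preset <- function(x, ...) {
  cat(sprintf("<field_preset '%s'>\n", x$label))
  cat(sprintf("  counts: %d pre / %d post (expr scales %.2f / %.2f)\n",
              x$n_pre, x$n_post,
              x$expression_scale_pre, x$expression_scale_post))
  cat(sprintf("  pairing: %.3f; offset |N(%.3f, %.3f)| um\n",
              x$paired_fraction, x$offset_mu, x$offset_sigma))
  cat(sprintf("  extent: %.2f x %.2f x %.2f um (%.2e mm^2)\n",
              x$extent["x"], x$extent["y"], x$extent["z"],
              x$extent["x"] * x$extent["y"] * 1e-6))
  invisible(x)
}

preset_dir <- function() system.file("extdata", "presets",
                                     package = "vestisyn", mustWork = TRUE)

#' List the field presets shipped with the package
#' @return character vector of preset labels.
#' @export
list_field_presets <- function() {
  cfg <- yaml::read_yaml(file.path(preset_dir(), "field_presets.yaml"))
  vapply(cfg, function(p) p$label, character(1))
}

#' Load a shipped (or external) field preset
#'
#' @param label a shipped preset label (see [list_field_presets()]) or a
#'   path to a YAML file holding a single preset.
#' @return a `field_preset`.
#' @export
load_field_preset <- function(label) {
  if (file.exists(label)) {
    p <- yaml::read_yaml(label)
  } else {
    cfg <- yaml::read_yaml(file.path(preset_dir(), "field_presets.yaml"))
    hit <- Filter(function(p) identical(p$label, label), cfg)
    if (length(hit) == 0L)
      stop(sprintf("unknown field preset '%s'; shipped presets: %s", label,
                   paste(list_field_presets(), collapse = ", ")),
           call. = FALSE)
    p <- hit[[1]]
  }
  anchors <- NULL
  if (!is.null(p$anchors))
    anchors <- data.frame(
      distance_um = vapply(p$anchors, function(a) a[[1]], numeric(1)),
      fraction = vapply(p$anchors, function(a) a[[2]], numeric(1)))
  field_preset(label = p$label, n_pre = p$n_pre, n_post = p$n_post,
               paired_fraction = p$paired_fraction,
               offset_mu = p$offset_mu, offset_sigma = p$offset_sigma,
               extent = c(x = p$extent$x, y = p$extent$y, z = p$extent$z),
               expression_scale_pre = p$expression_scale_pre,
               expression_scale_post = p$expression_scale_post,
               anchors = anchors)
}

# Folded-normal CDF of the paired offset magnitude.
folded_cdf <- function(d, mu, sigma) {
  pnorm((d - mu) / sigma) - pnorm((-d - mu) / sigma)
}

#' Calibrate a field preset against cumulative-distance anchors
#'
#' Finds `paired_fraction` and the folded-normal offset parameters so that
#' the ground-truth presynaptic-to-postsynaptic nearest-neighbour cumulative
#' distance curve of fields sampled from the preset matches each anchor
#' within tolerance. The background (unpaired) contribution is estimated by
#' simulation from the preset's counts and extent; the search over the
#' offset law is an analytic mixture-model fit followed by a simulation
#' check, and is deterministic given `seed`.
#'
#' With a single anchor only `paired_fraction` is searched and the offset
#' law is taken from `base` unchanged.
#'
#' @param anchors data.frame (or list of pairs) with columns `distance_um`
#'   and `fraction` (fractions in `[0, 1]`, nondecreasing with distance).
#' @param base a `field_preset` supplying counts, extent, expression scales
#'   and, for single-anchor calibration, the offset law.
#' @param seed integer controlling the simulation draws.
#' @param n_fields number of simulated fields used for the background
#'   estimate and final check.
#' @param tol_pp acceptable absolute anchor error, percentage points.
#' @return a calibrated `field_preset` carrying the anchors.
#' @export
calibrate_preset <- function(anchors, base, seed = 1L, n_fields = 20L,
                             tol_pp = 3) {
  if (is.list(anchors) && !is.data.frame(anchors))
    anchors <- data.frame(
      distance_um = vapply(anchors, function(a) a[[1]], numeric(1)),
      fraction = vapply(anchors, function(a) a[[2]], numeric(1)))
  if (nrow(anchors) < 1L) stop("need at least one anchor", call. = FALSE)
  o <- order(anchors$distance_um)
  anchors <- anchors[o, , drop = FALSE]
  if (is.unsorted(anchors$fraction))
    stop("calibration error: anchor fractions must be nondecreasing with distance",
         call. = FALSE)
  if (any(anchors$fraction < 0 | anchors$fraction > 1))
    stop("calibration error: anchor fractions must lie in [0, 1]",
         call. = FALSE)
  d <- anchors$distance_um
  target <- anchors$fraction

  # background CDF at the anchor distances: fields with no pairing at all
  bg_preset <- base
  bg_preset$paired_fraction <- 0
  B <- gt_cdf(bg_preset, d, seed = derive_seed(seed, 1L),
              n_fields = n_fields)

  if (nrow(anchors) == 1L) {
    # only the pairing fraction is free; C = B + p * F * (1 - B).  When even
    # p = 1 cannot reach the anchor, pairing saturates and the offset scale
    # is shrunk instead (scale -> 0 drives the offset CDF to 1).
    f1 <- folded_cdf(d, base$offset_mu, base$offset_sigma)
    needed <- (target - B) / (1 - B)
    mu <- base$offset_mu; sigma <- base$offset_sigma
    if (!is.finite(needed) || needed <= 0) {
      p <- 0
    } else if (needed <= f1) {
      p <- needed / f1
    } else {
      p <- 1
      lo <- 1e-6; hi <- 1
      for (it in 1:60) {
        mid <- (lo + hi) / 2
        if (folded_cdf(d, mid * base$offset_mu,
                       mid * base$offset_sigma) >= needed) lo <- mid
        else hi <- mid
      }
      mu <- lo * base$offset_mu; sigma <- lo * base$offset_sigma
    }
  } else {
    mus <- seq(0, 3.5, by = 0.05)
    sigmas <- seq(0.1, 1.6, by = 0.05)
    best <- NULL
    for (mu_c in mus) for (sg in sigmas) {
      f <- folded_cdf(d, mu_c, sg)
      a <- f * (1 - B)
      p_c <- sum(a * (target - B)) / sum(a * a)
      p_c <- min(max(p_c, 0), 1)
      err <- max(abs(B + p_c * a - target))
      if (is.null(best) || err < best$err)
        best <- list(err = err, p = p_c, mu = mu_c, sigma = sg)
    }
    p <- best$p; mu <- best$mu; sigma <- best$sigma
  }

  out <- base
  out$paired_fraction <- p
  out$offset_mu <- mu
  out$offset_sigma <- sigma
  out$anchors <- anchors

  # simulation check + one proportional correction of p if needed
  for (round in 1:3) {
    sim <- gt_cdf(out, d, seed = derive_seed(seed, 10L + round),
                  n_fields = n_fields)
    err <- sim - target
    if (max(abs(err)) <= tol_pp / 100) return(out)
    f <- folded_cdf(d, out$offset_mu, out$offset_sigma)
    grad <- f * (1 - B)
    dp <- -sum(grad * err) / sum(grad * grad)
    out$paired_fraction <- min(max(out$paired_fraction + dp, 0), 1)
  }
  stop(sprintf(paste0("calibration error: anchors not reachable within %.1f ",
                      "percentage points (worst error %.1f pp)"),
               tol_pp, 100 * max(abs(err))), call. = FALSE)
}

# Ground-truth pre->post NN cumulative fractions at distances `d`,
# aggregated over `n_fields` sampled fields.
gt_cdf <- function(preset, d, seed, n_fields = 20L) {
  dists <- unlist(lapply(seq_len(n_fields), function(i) {
    fld <- sample_field(preset, derive_seed(seed, i))
    if (nrow(fld$pre_points) == 0L || nrow(fld$post_points) == 0L)
      return(numeric(0))
    cpp_nn_dist(as.matrix(fld$pre_points), as.matrix(fld$post_points))
  }))
  if (length(dists) == 0L) return(rep(NA_real_, length(d)))
  vapply(d, function(x) mean(dists <= x), numeric(1))
}
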