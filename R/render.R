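#' Render a ground-truth field into a synthetic confocal stack
#'
#' Each punctum contributes an anisotropic 3D Gaussian photon blob (the
#' point-spread function) centred at its physical position; per-axis blob
#' weights are integrated Gaussians over the voxel edges so the expected
#' photon count of a punctum equals `photon_scale` up to boundary
#' truncation. Shot noise is Poisson on the expected counts; `noise =
#' FALSE` returns the noiseless expectation (the infinite-photon limit up
#' to scale). A third channel holds the hair-cell mask, covering the whole
#' field footprint.
#'
#' Coordinate convention: physical um, origin at the corner of voxel
#' (1,1,1); the centre of voxel `i` along an axis with pitch `d` sits at
#' `(i - 0.5) * d`.
#'
#' @param field a `ground_truth_field`.
#' @param psf_sigma named numeric `c(z=, y=, x=)`, PSF standard deviations
#'   in um. Default (0.60, 0.15, 0.15): a typical confocal PSF at NA 1.40.
#' @param photon_scale expected photons per punctum.
#' @param background expected background photons per voxel.
#' @param seed integer seed for the shot noise.
#' @param voxel_size named numeric `c(dz=, dy=, dx=)` in um. Default
#'   (0.40, 0.104, 0.104): 0.40 um optical sectioning and the lateral pitch
#'   of a 63x/NA 1.40 acquisition at 1024x1024.
#' @param noise logical; apply Poisson shot noise?
#' @param z_pad number of extra z planes acquired beyond each axial face of
#'   the field (default covers 2 PSF sigmas), so puncta near the axial
#'   borders are imaged with their full blob; the stack records its
#'   physical z origin accordingly.
#' @return a `confocal_stack`: list with `voxels` (4D array, dim =
#'   channel, z, y, x), `voxel_size` (dz, dy, dx um) and `channel_labels`
#'   (`ctbp2` = presynaptic, `shank1` = postsynaptic, `mask`).
#' @export
render_field <- function(field, psf_sigma = c(z = 0.60, y = 0.15, x = 0.15),
                         photon_scale = 500, background = 2, seed = 1L,
                         voxel_size = c(dz = 0.40, dy = 0.104, dx = 0.104),
                         noise = TRUE,
                         z_pad = ceiling(2 * psf_sigma[["z"]] /
                                           voxel_size[["dz"]])) {
  if (!inherits(field, "ground_truth_field"))
    stop("`field` must be a ground_truth_field", call. = FALSE)
  if (any(psf_sigma <= 0)) stop("psf sigmas must be positive", call. = FALSE)
  stop_if_not_scalar_pos(photon_scale, "photon_scale")
  stop_if_not_scalar_pos(background, "background", allow_zero = TRUE)
  ext <- field$preset$extent
  dz <- voxel_size[["dz"]]; dy <- voxel_size[["dy"]]; dx <- voxel_size[["dx"]]
  nx <- ceiling(ext[["x"]] / dx)
  ny <- ceiling(ext[["y"]] / dy)
  nz <- ceiling(ext[["z"]] / dz) + 2L * z_pad
  z0 <- -z_pad * dz
  pts <- rbind(as.matrix(field$pre_points), as.matrix(field$post_points))
  if (nrow(pts) > 0 &&
      (any(pts[, "x"] > nx * dx) || any(pts[, "y"] > ny * dy) ||
       any(pts[, "z"] > z0 + nz * dz) || any(pts[, "z"] < z0) ||
       any(pts[, c("x", "y")] < 0)))
    stop("extent error: voxel grid too small to contain the field",
         call. = FALSE)

  blob <- function(points) {
    mean_arr <- array(0, dim = c(nz, ny, nx))
    if (nrow(points) == 0L) return(mean_arr)
    axes <- list(z = list(n = nz, d = dz, s = psf_sigma[["z"]], o = z0),
                 y = list(n = ny, d = dy, s = psf_sigma[["y"]], o = 0),
                 x = list(n = nx, d = dx, s = psf_sigma[["x"]], o = 0))
    for (i in seq_len(nrow(points))) {
      w <- lapply(c("z", "y", "x"), function(ax) {
        a <- axes[[ax]]
        pos <- points[i, ax] - a$o
        i0 <- max(1L, floor((pos - 4 * a$s) / a$d) + 1L)
        i1 <- min(a$n, ceiling((pos + 4 * a$s) / a$d))
        edges <- (seq(i0 - 1L, i1)) * a$d
        list(idx = i0:i1, w = diff(pnorm((edges - pos) / a$s)))
      })
      contrib <- photon_scale *
        outer(w[[1]]$w, outer(w[[2]]$w, w[[3]]$w))
      mean_arr[w[[1]]$idx, w[[2]]$idx, w[[3]]$idx] <-
        mean_arr[w[[1]]$idx, w[[2]]$idx, w[[3]]$idx] + contrib
    }
    mean_arr
  }

  mean_pre <- blob(as.matrix(field$pre_points)) + background
  mean_post <- blob(as.matrix(field$post_points)) + background
  vox <- array(0, dim = c(3L, nz, ny, nx))
  if (noise) {
    with_seed(seed, {
      vox[1L, , , ] <- rpois(length(mean_pre), mean_pre)
      vox[2L, , , ] <- rpois(length(mean_post), mean_post)
    })
  } else {
    vox[1L, , , ] <- mean_pre
    vox[2L, , , ] <- mean_post
  }
  vox[3L, , , ] <- 1
  structure(list(voxels = vox,
                 voxel_size = c(dz = dz, dy = dy, dx = dx),
                 origin = c(z = z0, y = 0, x = 0),
                 channel_labels = c("ctbp2", "shank1", "mask"),
                 source = sprintf("%s/seed%d", field$preset$label,
                                  field$seed)),
            class = "confocal_stack")
}

#' Assemble a confocal stack from raw components
#'
#' Mainly used by [read_stack()] and by tests that construct bespoke
#' stacks; performs the container invariant checks.
#'
#' @param voxels 4D array, dim (channel, z, y, x), non-negative.
#' @param voxel_size named numeric `c(dz=, dy=, dx=)` um.
#' @param channel_labels character, one label per channel.
#' @param origin physical position (um) of the corner of voxel (1,1,1),
#'   named `c(z=, y=, x=)`.
#' @param source free-text identifier.
#' @return a `confocal_stack`.
#' @export
confocal_stack <- function(voxels, voxel_size, channel_labels,
                           origin = c(z = 0, y = 0, x = 0),
                           source = "unknown") {
  if (length(dim(voxels)) != 4L)
    stop("`voxels` must be a 4D (channel, z, y, x) array", call. = FALSE)
  if (dim(voxels)[1] < 2L)
    stop("a confocal stack needs at least 2 channels", call. = FALSE)
  if (dim(voxels)[1] != length(channel_labels))
    stop("channel_labels length must match channel count", call. = FALSE)
  if (any(voxels < 0)) stop("intensities must be >= 0", call. = FALSE)
  vs <- voxel_size[c("dz", "dy", "dx")]
  if (any(is.na(vs)) || any(vs <= 0))
    stop("voxel_size needs positive dz, dy, dx", call. = FALSE)
  structure(list(voxels = voxels, voxel_size = vs,
                 origin = origin[c("z", "y", "x")],
                 channel_labels = channel_labels, source = source),
            class = "confocal_stack")
}

#' @export
print.confocal_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<confocal_stack %s: %d ch x %d z x %d y x %d x>\n",
              x$source, d[1], d[2], d[3], d[4]))
  cat(sprintf("  voxel %.3f x %.3f x %.3f um (z,y,x); channels: %s\n",
              x$voxel_size[["dz"]], x$voxel_size[["dy"]],
              x$voxel_size[["dx"]],
              paste(x$channel_labels, collapse = ", ")))
  invisible(x)
}

stack_origin <- function(stack) {
  if (is.null(stack$origin)) c(z = 0, y = 0, x = 0) else stack$origin
}

# 3D array (z, y, x) for one channel.
channel_array <- function(stack, channel) {
  i <- match(channel, stack$channel_labels)
  if (is.na(i))
    stop(sprintf("unknown channel '%s'; stack has: %s", channel,
                 paste(stack$channel_labels, collapse = ", ")),
         call. = FALSE)
  d <- dim(stack$voxels)
  array(stack$voxels[i, , , ], dim = d[2:4])
}
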