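#' Write a confocal stack to a multi-page TIFF with metadata sidecar
#'
#' Pages are ordered channel-major (all z planes of channel 1, then channel
#' 2, ...; CZYX), each page a y-by-x plane, 16-bit. Voxel size and channel
#' labels are stored in a JSON sidecar next to the TIFF (`<path>.json`);
#' the installed TIFF writer exposes no free-text tags, and the sidecar is
#' required on read -- there is no silent default voxel size.
#'
#' Intensities must be integers in `[0, 65535]`; rendered stacks (Poisson
#' counts) satisfy this, and the round trip is then bit-exact.
#'
#' @param stack a `confocal_stack`.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  if (!inherits(stack, "confocal_stack"))
    stop("`stack` must be a confocal_stack", call. = FALSE)
  v <- stack$voxels
  if (any(v != round(v)) || any(v > 65535))
    stop("write_stack stores 16-bit integer counts; intensities must be ",
         "integers in [0, 65535]", call. = FALSE)
  d <- dim(v)
  pages <- vector("list", d[1] * d[2])
  k <- 1L
  for (ch in seq_len(d[1])) {
    for (z in seq_len(d[2])) {
      pages[[k]] <- matrix(v[ch, z, , ], d[3], d[4]) / 65535
      k <- k + 1L
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, reduce = FALSE)
  meta <- list(voxel_size_um = as.list(stack$voxel_size),
               origin_um = as.list(stack_origin(stack)),
               channel_labels = stack$channel_labels,
               n_channels = d[1], n_z = d[2], n_y = d[3], n_x = d[4],
               axis_order = "CZYX", source = stack$source)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

sidecar_path <- function(path) paste0(path, ".json")

#' Read a confocal stack written by [write_stack()]
#'
#' @param path TIFF path; `<path>.json` must hold the voxel-size metadata.
#' @return a `confocal_stack`.
#' @export
read_stack <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  sp <- sidecar_path(path)
  if (!file.exists(sp))
    stop("metadata error: voxel-size sidecar ", sp,
         " is missing; stacks cannot be read without physical voxel size",
         call. = FALSE)
  meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
  if (is.null(meta$voxel_size_um) ||
      !all(c("dz", "dy", "dx") %in% names(meta$voxel_size_um)))
    stop("metadata error: sidecar lacks voxel_size_um dz/dy/dx",
         call. = FALSE)
  if (is.null(meta$n_channels) || meta$n_channels < 2L)
    stop("a confocal stack needs at least 2 channels (got ",
         if (is.null(meta$n_channels)) "none" else meta$n_channels, ")",
         call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE)
  nc <- meta$n_channels; nz <- meta$n_z
  if (length(pages) != nc * nz)
    stop("metadata error: page count disagrees with sidecar", call. = FALSE)
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  vox <- array(0, dim = c(nc, nz, ny, nx))
  k <- 1L
  for (ch in seq_len(nc)) {
    for (z in seq_len(nz)) {
      vox[ch, z, , ] <- round(pages[[k]] * 65535)
      k <- k + 1L
    }
  }
  org <- if (is.null(meta$origin_um)) c(z = 0, y = 0, x = 0) else
    unlist(meta$origin_um)[c("z", "y", "x")]
  confocal_stack(vox,
                 voxel_size = unlist(meta$voxel_size_um)[c("dz", "dy", "dx")],
                 origin = org,
                 channel_labels = meta$channel_labels,
                 source = if (is.null(meta$source)) "unknown" else meta$source)
}
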