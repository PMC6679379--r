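#' Construct a puncta set
#'
#' The common container for detected or ground-truth puncta of one channel
#' in one observation field.
#'
#' @param puncta data.frame with columns `channel`, `x_um`, `y_um`, `z_um`,
#'   `peak`, `volume_um3`.
#' @param channel channel label shared by all puncta.
#' @param field_area x-y footprint of the field in mm^2.
#' @param source identifier of the originating stack/field.
#' @return an object of class `puncta_set`.
#' @export
puncta_set <- function(puncta, channel, field_area, source = "unknown") {
  need <- c("channel", "x_um", "y_um", "z_um", "peak", "volume_um3")
  if (!all(need %in% names(puncta)))
    stop("puncta data.frame needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (nrow(puncta) > 0 && !all(puncta$channel == channel))
    stop("all puncta must share the set's channel", call. = FALSE)
  stop_if_not_scalar_pos(field_area, "field_area")
  rownames(puncta) <- NULL
  structure(list(puncta = puncta, channel = channel,
                 field_area = field_area, source = source),
            class = "puncta_set")
}

#' @export
print.puncta_set <- function(x, ...) {
  cat(sprintf("<puncta_set '%s': %d puncta over %.2e mm^2 (%s)>\n",
              x$channel, nrow(x$puncta), x$field_area, x$source))
  invisible(x)
}

#' Number of puncta in a set
#' @param x a `puncta_set`.
#' @return integer count.
#' @export
n_puncta <- function(x) nrow(x$puncta)

#' Write / read a puncta set as CSV
#' @param puncta a `puncta_set`.
#' @param path CSV path.
#' @export
write_puncta <- function(puncta, path) {
  write.csv(puncta$puncta, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_puncta
#' @param channel,field_area,source metadata for the restored set.
#' @export
read_puncta <- function(path, channel, field_area, source = path) {
  puncta_set(read.csv(path, stringsAsFactors = FALSE), channel = channel,
             field_area = field_area, source = source)
}

punct_coords <- function(x) {
  m <- as.matrix(x$puncta[, c("x_um", "y_um", "z_um")])
  colnames(m) <- c("x", "y", "z")
  m
}

#' Directed nearest-neighbour distances between two puncta sets
#'
#' For every punctum of `source`, the Euclidean 3D distance (um) to its
#' nearest punctum in `target`. The search is exact (uniform-grid spatial
#' index with expanding ring search). By convention the primary reported
#' direction is presynaptic-to-postsynaptic (ctbp2 -> shank1); the reverse
#' profile is obtained by swapping the arguments.
#'
#' @param source,target `puncta_set` objects in the same physical frame
#'   (equal field area).
#' @return a `distance_profile`: sorted distances, direction label, and the
#'   two set sizes.
#' @export
nn_distances <- function(source, target) {
  if (!inherits(source, "puncta_set") || !inherits(target, "puncta_set"))
    stop("`source` and `target` must be puncta_set objects", call. = FALSE)
  if (n_puncta(target) == 0L)
    stop("empty-target error: target set has no puncta; ",
         "nearest-neighbour distances are undefined", call. = FALSE)
  if (abs(source$field_area - target$field_area) >
      1e-9 * max(source$field_area, target$field_area))
    stop("frame error: source and target come from fields of different ",
         "area", call. = FALSE)
  d <- if (n_puncta(source) == 0L) numeric(0) else
    cpp_nn_dist(punct_coords(source), punct_coords(target))
  structure(list(direction = sprintf("%s->%s", source$channel,
                                     target$channel),
                 distances = sort(d),
                 n_source = n_puncta(source), n_target = n_puncta(target)),
            class = "distance_profile")
}

#' @export
print.distance_profile <- function(x, ...) {
  cat(sprintf("<distance_profile %s: n=%d vs %d, median %.2f um>\n",
              x$direction, x$n_source, x$n_target,
              if (length(x$distances)) median(x$distances) else NA))
  invisible(x)
}

#' Cumulative distance curve of a profile
#'
#' Percentage of nearest-neighbour distances at or below each grid value.
#'
#' @param profile a `distance_profile` with at least one distance.
#' @param grid ascending distances in um.
#' @return data.frame with columns `distance_um` and `cumulative_pct`.
#' @export
cumulative_curve <- function(profile, grid) {
  if (!inherits(profile, "distance_profile"))
    stop("`profile` must be a distance_profile", call. = FALSE)
  if (length(profile$distances) == 0L)
    stop("empty profile: no distances to accumulate", call. = FALSE)
  if (is.unsorted(grid))
    stop("`grid` must be sorted ascending", call. = FALSE)
  data.frame(distance_um = grid,
             cumulative_pct = vapply(grid, function(g)
               100 * mean(profile$distances <= g), numeric(1)))
}

#' Colocalisation fraction of a distance profile
#'
#' Percentage of source puncta whose nearest target punctum lies within the
#' threshold (inclusive). The 1 um default is the operational criterion for
#' an intact pre/post synaptic pairing.
#'
#' @param profile a nonempty `distance_profile`.
#' @param threshold distance threshold in um (> 0).
#' @return percentage in `[0, 100]`.
#' @export
colocalization_fraction <- function(profile, threshold = 1) {
  if (!inherits(profile, "distance_profile"))
    stop("`profile` must be a distance_profile", call. = FALSE)
  if (!is.numeric(threshold) || threshold <= 0)
    stop("`threshold` must be a positive distance in um", call. = FALSE)
  if (length(profile$distances) == 0L)
    stop("empty profile: colocalisation fraction undefined", call. = FALSE)
  100 * mean(profile$distances <= threshold)
}

#' Normalise per-field puncta counts to a sham reference
#'
#' Each count is expressed as a percentage of the sham group mean, so the
#' sham group itself averages exactly 100%.
#'
#' @param counts numeric vector of per-field puncta counts.
#' @param sham_counts nonempty numeric vector of sham per-field counts from
#'   equal-area fields.
#' @return list with `percent` (per-field percentages), `mean_pct` and
#'   `sem_pct`.
#' @export
normalized_expression <- function(counts, sham_counts) {
  if (length(sham_counts) == 0L)
    stop("`sham_counts` must be nonempty", call. = FALSE)
  ref <- mean(sham_counts)
  if (ref == 0)
    stop("normalisation error: sham mean count is zero", call. = FALSE)
  pct <- 100 * counts / ref
  list(percent = pct, mean_pct = mean(pct),
       sem_pct = if (length(pct) > 1L) sd(pct) / sqrt(length(pct)) else NA_real_)
}
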