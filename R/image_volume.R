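# Image and label containers. Arrays are stored in R's native column-major
# order indexed [x, y, z]: x is the fastest-varying axis in memory, matching
# the on-disk layout of the MRC format (and the memory layout of a C-order
# (z, y, x) array). Particle positions (x, y, z) therefore index arrays
# directly (plus 1 for R's 1-based indexing).

#' Image volume container
#'
#' Wraps a 2D or 3D intensity array together with its pixel spacing and an
#' experiment identifier. Arrays are indexed `[x, y, z]` (x fastest in
#' memory). For deferred ("lazy") loading a `loader` function may be given
#' instead of data; [image_data()] then reads the voxels on first access.
#'
#' @param data Numeric 2D/3D array, or `NULL` when `loader` is given.
#' @param pixel_spacing Angstrom per voxel; 0 = unknown.
#' @param experiment_id Identifier tying the image to an experiment.
#' @param loader Optional zero-argument function returning the array.
#' @param dim Optional dimensions, for lazy volumes whose header has been
#'   read but whose voxels have not.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(data = NULL, pixel_spacing = 0, experiment_id = "",
                         loader = NULL, dim = NULL) {
  if (is.null(data) && is.null(loader)) {
    abort_argument("either data or a loader must be supplied")
  }
  if (!is.null(data)) {
    if (is.matrix(data) || (is.array(data) && length(dim(data)) %in% 2:3)) {
      storage.mode(data) <- "double"
    } else {
      abort_argument("data must be a 2D or 3D numeric array")
    }
    if (!all(is.finite(data))) abort_argument("image data must be finite")
    dim <- base::dim(data)
  }
  if (!is.numeric(pixel_spacing) || length(pixel_spacing) != 1 ||
      is.na(pixel_spacing) || pixel_spacing < 0) {
    abort_argument("pixel_spacing must be a single non-negative number")
  }
  structure(
    list(data = data, pixel_spacing = pixel_spacing,
         experiment_id = as.character(experiment_id),
         loader = loader, dim = dim, cache = new.env(parent = emptyenv())),
    class = "image_volume")
}

#' Access the voxel data of an image volume
#'
#' Returns the array, triggering (and caching) the deferred read for lazily
#' loaded volumes.
#'
#' @param volume An [image_volume()].
#' @return The numeric array.
#' @export
image_data <- function(volume) {
  if (!is.null(volume$data)) return(volume$data)
  if (!is.null(volume$cache$data)) return(volume$cache$data)
  if (is.null(volume$loader)) abort_argument("volume has no data and no loader")
  volume$cache$data <- volume$loader()
  volume$cache$data
}

#' @export
print.image_volume <- function(x, ...) {
  loaded <- !is.null(x$data) || !is.null(x$cache$data)
  cat(sprintf("<image_volume> %s | %s | experiment '%s'%s\n",
              paste(x$dim, collapse = " x "),
              if (x$pixel_spacing > 0) sprintf("%g A/px", x$pixel_spacing)
              else "unknown spacing",
              x$experiment_id,
              if (loaded) "" else " | lazy (not loaded)"))
  invisible(x)
}

#' Integer label volume container
#'
#' An n-dimensional array of non-negative integer labels; 0 is background.
#'
#' @param data Integer-valued array (any dimensionality).
#' @return An object of class `labeled_volume`.
#' @export
labeled_volume <- function(data) {
  if (!is.array(data) && !is.matrix(data)) {
    abort_argument("data must be an array")
  }
  if (is.double(data)) {
    if (max(abs(data - round(data)), 0) > 0) {
      abort_argument("label data must be integer-valued")
    }
    storage.mode(data) <- "integer"
  }
  if (!is.integer(data)) abort_argument("label data must be integer")
  if (any(is.na(data)) || min(data, 0L) < 0L) {
    abort_argument("labels must be non-negative integers")
  }
  structure(list(data = data), class = "labeled_volume")
}

#' @export
print.labeled_volume <- function(x, ...) {
  ids <- setdiff(sort(unique(as.vector(x$data))), 0L)
  cat(sprintf("<labeled_volume> %s | labels: %s\n",
              paste(dim(x$data), collapse = " x "),
              if (length(ids)) paste(ids, collapse = ", ") else "none"))
  invisible(x)
}
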