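# Label interpolation by signed-distance-field averaging. Sparse annotated
# slices of an n-D label volume are filled in: per label, the SDF of each
# bounding annotated slice is linearly interpolated across the gap, and a
# voxel joins the label where its interpolated field is positive.

#' Signed distance field of a binary mask
#'
#' Positive inside the mask (Euclidean distance to the nearest outside
#' voxel), negative outside (minus the distance to the nearest mask voxel),
#' zero-crossing on the boundary, clipped to `[-cap, cap]`. An empty mask
#' yields the constant `-cap` ("label absent"), a full mask `+cap`.
#'
#' @param mask Logical or 0/1 numeric array (2D or 3D).
#' @param cap Clipping value; defaults to the sum of the mask dimensions,
#'   an unreachable distance.
#' @return Numeric array of the same shape.
#' @export
signed_distance_field <- function(mask, cap = sum(dim(mask))) {
  if (is.logical(mask)) mask <- mask * 1
  if (!all(mask %in% c(0, 1))) abort_argument("mask must be binary")
  if (!is.numeric(cap) || length(cap) != 1 || cap <= 0) {
    abort_argument("cap must be a positive number")
  }
  if (all(mask == 0)) return(array(-cap, dim(mask)))
  if (all(mask == 1)) return(array(cap, dim(mask)))
  inside <- EBImage::distmap(mask)
  outside <- EBImage::distmap(1 - mask)
  sdf <- array(as.numeric(inside) - as.numeric(outside), dim(mask))
  pmin(pmax(sdf, -cap), cap)
}

#' Interpolate sparse label slices into a dense labelling
#'
#' For each pair of consecutive annotated slices `a < b` along `dim` (a
#' slice is annotated when it contains any nonzero label) and each label id
#' present on either slice, the per-label SDFs are combined at intermediate
#' position `x` as `((b - x) * SDF_a + (x - a) * SDF_b) / (b - a)` (standard
#' linear interpolation). A voxel is assigned to the label with the largest
#' positive field; ties between labels resolve to the larger field, voxels
#' with no positive field stay background. Annotated slices are copied
#' through unchanged and slices outside the first/last annotated slice
#' remain empty: no extrapolation.
#'
#' @param labels A [labeled_volume()] (or integer array).
#' @param dim Axis along which to interpolate (1-based).
#' @return A [labeled_volume()] of the same shape.
#' @export
interpolate_labels <- function(labels, dim = 3) {
  x <- if (inherits(labels, "labeled_volume")) labels$data else
    labeled_volume(labels)$data
  nd <- length(base::dim(x))
  if (!is.numeric(dim) || length(dim) != 1 || dim < 1 || dim > nd) {
    abort_argument(sprintf("dim must be between 1 and %d", nd))
  }
  dim <- as.integer(dim)

  perm <- c(dim, setdiff(seq_len(nd), dim))
  ap <- aperm(x, perm)
  full_dim <- base::dim(ap)
  ns <- full_dim[1]
  slice_dim <- full_dim[-1]
  flat <- ap
  base::dim(flat) <- c(ns, prod(slice_dim))

  annotated <- which(apply(flat != 0L, 1, any))
  if (length(annotated) < 2) {
    abort_argument("at least 2 annotated slices are required")
  }

  out <- flat
  out[] <- 0L
  out[annotated, ] <- flat[annotated, ]
  cap <- sum(slice_dim)

  get_slice <- function(s) array(flat[s, ], slice_dim)

  for (g in seq_len(length(annotated) - 1)) {
    a <- annotated[g]; b <- annotated[g + 1]
    if (b - a <= 1) next
    sa <- get_slice(a); sb <- get_slice(b)
    ids <- sort(unique(c(sa[sa > 0L], sb[sb > 0L])))
    sdf_a <- lapply(ids, function(id) signed_distance_field(sa == id, cap))
    sdf_b <- lapply(ids, function(id) signed_distance_field(sb == id, cap))
    for (pos in (a + 1):(b - 1)) {
      wa <- (b - pos) / (b - a)
      wb <- (pos - a) / (b - a)
      best_field <- array(-Inf, slice_dim)
      best_id <- array(0L, slice_dim)
      for (k in seq_along(ids)) {
        field <- wa * sdf_a[[k]] + wb * sdf_b[[k]]
        take <- field > best_field
        best_field[take] <- field[take]
        best_id[take] <- ids[k]
      }
      assigned <- ifelse(best_field > 0, best_id, 0L)
      out[pos, ] <- as.integer(assigned)
    }
  }

  base::dim(out) <- full_dim
  labeled_volume(aperm(out, order(perm)))
}
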