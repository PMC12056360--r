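#' Corticospinal-tract voxel counts per axial slice
#'
#' @param cst Binary 3-D array (or NIfTI path readable by
#'   [RNifti::readNifti()]) marking the corticospinal tract.
#' @param axial_axis Array dimension indexing axial slices (default 3, the
#'   usual superior-inferior axis of RAS-oriented volumes).
#' @return Integer vector of CST voxel counts, one per slice.
#' @export
cst_slice_areas <- function(cst, axial_axis = 3L) {
  cst <- .load_mask(cst)
  if (sum(cst) == 0) stop("empty CST mask")
  as.integer(apply(cst, axial_axis, sum))
}

#' CST-weighted lesion load
#'
#' Counts lesion voxels overlapping the corticospinal tract in each axial
#' slice, weights each slice's overlap so that narrower tract portions —
#' where a lesion of given size removes a larger fraction of the tract —
#' count for more, and sums. The default weight is
#' `w(slice) = max_slice_area / slice_area`; any positive weight function of
#' the slice areas can be substituted.
#'
#' @param lesion,cst Binary 3-D arrays (or NIfTI paths) of identical shape.
#' @param axial_axis Axial slice dimension (default 3).
#' @param weight_fn Function mapping the vector of nonzero slice areas to
#'   slice weights; default `max(areas) / areas`.
#' @return Scalar lesion load (0 when lesion and tract do not overlap).
#' @examples
#' v <- simulate_lesion_volumes(c(4, 4, 3), c(10, 5, 10), c(2, 5, 0))
#' weighted_lesion_load(v$lesion, v$cst) # 12
#' @export
weighted_lesion_load <- function(lesion, cst, axial_axis = 3L,
                                 weight_fn = function(areas) max(areas) / areas) {
  lesion <- .load_mask(lesion)
  cst <- .load_mask(cst)
  if (!identical(dim(lesion), dim(cst))) {
    stop("lesion and CST masks must have identical shape")
  }
  areas <- as.numeric(apply(cst, axial_axis, sum))
  overlap <- as.numeric(apply(lesion * cst, axial_axis, sum))
  nz <- areas > 0
  if (!any(nz)) stop("empty CST mask")
  w <- weight_fn(areas[nz])
  if (any(!is.finite(w)) || any(w <= 0)) stop("weight function returned non-positive or non-finite weights")
  sum(overlap[nz] * w)
}

.load_mask <- function(x) {
  if (is.character(x)) x <- RNifti::readNifti(x)
  x <- unclass(x)
  stopifnot(length(dim(x)) == 3L)
  u <- unique(as.vector(x))
  if (!all(u %in% c(0, 1))) stop("mask must be binary (0/1)")
  x
}

#' Append lesion load to a clinical table
#'
#' @param clinical Clinical tibble with `subject`.
#' @param loads Named numeric vector or tibble (`subject`, `lesion_load`).
#' @return The clinical tibble with a `lesion_load` column.
#' @export
add_lesion_load <- function(clinical, loads) {
  if (is.numeric(loads) && !is.null(names(loads))) {
    loads <- tibble::tibble(subject = names(loads), lesion_load = unname(loads))
  }
  stopifnot(all(c("subject", "lesion_load") %in% names(loads)))
  clinical$lesion_load <- loads$lesion_load[match(clinical$subject, loads$subject)]
  clinical
}
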