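#' Named ROI sets with hemisphere tags and homologue pairing
#'
#' The three networks analysed are the cortical sensorimotor network
#' (12 cortical ROIs), the full sensorimotor network (SMN; the 12 cortical
#' plus 12 subcortical ROIs), and the default mode network (DMN; 14 ROIs).
#' Every ROI carries a hemisphere tag — `Ip` (ipsilesional) or `C`
#' (contralesional) — and has exactly one homologue in the opposite
#' hemisphere, which is what makes left-right standardisation of
#' left-lesion subjects a pure label permutation at the ROI level.
#'
#' @param name One of `"cortical_SMN"`, `"SMN"`, `"DMN"`, or a custom set
#'   built with `roi_set_custom()`.
#' @return A tibble of class `fc_roi_set` with columns `roi` (unique label,
#'   e.g. `"Ip_M1"`), `hemisphere` (`"Ip"` or `"C"`), `region` (hemisphere-free
#'   region name) and `homologue` (label of the mirror ROI).
#' @examples
#' roi_set("DMN")
#' nrow(roi_set("SMN")) # 24
#' @export
roi_set <- function(name = c("cortical_SMN", "SMN", "DMN")) {
  name <- match.arg(name)
  regions <- switch(name,
    cortical_SMN = .smn_cortical_regions,
    SMN = c(.smn_cortical_regions, .smn_subcortical_regions),
    DMN = .dmn_regions
  )
  roi_set_custom(regions, name = name)
}

.smn_cortical_regions <- c(
  "M1", "SMA", "premotor", "S1", "sup_parietal", "precuneus"
)
.smn_subcortical_regions <- c(
  "VL_thalamus", "VA_thalamus", "VP_thalamus", "post_putamen",
  "cerebellum_I_V", "cerebellum_VIII"
)
.dmn_regions <- c(
  "med_orbitofrontal", "angular", "precuneus_cingulate", "middle_temporal",
  "parahippocampal", "ant_thalamus", "crus"
)

#' Build an ROI set from hemisphere-free region names
#'
#' @param regions Character vector of region names; each yields an `Ip_` and
#'   a `C_` ROI paired as homologues.
#' @param name Set name stored as an attribute.
#' @rdname roi_set
#' @export
roi_set_custom <- function(regions, name = "custom") {
  stopifnot(is.character(regions), length(regions) >= 2L, !anyDuplicated(regions))
  out <- tibble::tibble(
    roi = c(paste0("Ip_", regions), paste0("C_", regions)),
    hemisphere = rep(c("Ip", "C"), each = length(regions)),
    region = rep(regions, 2L),
    homologue = c(paste0("C_", regions), paste0("Ip_", regions))
  )
  structure(out, class = c("fc_roi_set", class(out)), roi_set_name = name)
}

#' Number of ROIs in a set
#' @param x An `fc_roi_set`.
#' @keywords internal
#' @noRd
n_rois <- function(x) nrow(x)

#' Swap ipsilesional and contralesional labels of a connectivity matrix
#'
#' Subjects with left-hemisphere lesions are standardised so that the
#' lesioned hemisphere is always "ipsilesional"; post ROI-extraction this is
#' a permutation of rows and columns by the homologue map, not a voxel flip.
#' Applying the permutation twice is the identity.
#'
#' @param mat Square matrix with ROI labels of `roi_set` as dimnames.
#' @param roi_set An `fc_roi_set` defining the homologue pairing.
#' @return The matrix with rows/columns permuted to the homologue labels.
#' @examples
#' rs <- roi_set("DMN")
#' m <- diag(nrow(rs)); dimnames(m) <- list(rs$roi, rs$roi)
#' identical(flip_hemispheres(flip_hemispheres(m, rs), rs), m)
#' @export
flip_hemispheres <- function(mat, roi_set) {
  stopifnot(is.matrix(mat), nrow(mat) == ncol(mat))
  labs <- rownames(mat)
  if (is.null(labs) || !setequal(labs, roi_set$roi)) {
    stop("matrix dimnames must match the ROI labels of `roi_set`")
  }
  map <- stats::setNames(roi_set$homologue, roi_set$roi)
  if (anyNA(map[labs])) stop("unpaired ROI in homologue map")
  perm <- match(map[labs], labs)
  if (anyNA(perm)) stop("homologue of some ROI is absent from the matrix")
  out <- mat[perm, perm, drop = FALSE]
  dimnames(out) <- list(labs, labs)
  out
}
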