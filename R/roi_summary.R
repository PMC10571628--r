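#' The eight cortical lobe names
#'
#' Orbitofrontal (OFC), lateral prefrontal (LPFC), medial prefrontal (MPFC),
#' lateral temporal (LTC), medial temporal (MTC), somatomotor (SMC),
#' parietal (PC) and occipital (OCC) cortex.
#'
#' @return Character vector of the eight lobe names.
#' @export
lobe_names <- function() {
  c("OFC", "LPFC", "MPFC", "LTC", "MTC", "SMC", "PC", "OCC")
}

#' Read a parcel-to-lobe lookup table
#'
#' The lookup is a TSV with columns `label` (integer parcel ID), `parcel`
#' (name, informational) and `lobe` (one of the eight lobe names, or
#' `"ignore"` for labels deliberately excluded). The packaged default,
#' `dk_lobe_lookup.tsv`, groups bilateral Desikan-Killiany `aparc+aseg`
#' cortical labels (1001-1035, 2001-2035) into the eight lobes; it is a
#' plausible reconstruction of such a grouping, not a published table, and
#' is meant to be edited to match a study's own definition.
#'
#' @param path TSV file; defaults to the packaged Desikan-Killiany lookup.
#' @return data.frame with columns `label`, `parcel`, `lobe`.
#' @export
read_lobe_lookup <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "dk_lobe_lookup.tsv", package = "ifwtools",
                        mustWork = TRUE)
  lk <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("label", "parcel", "lobe")
  if (!all(need %in% names(lk)))
    stop("lookup must have columns: ", paste(need, collapse = ", "))
  bad <- setdiff(unique(lk$lobe), c(lobe_names(), "ignore"))
  if (length(bad))
    stop("unknown lobe name(s) in lookup: ", paste(bad, collapse = ", "))
  lk
}

#' Construct a lobe parcellation
#'
#' @param label_map 3-D integer array of parcel labels in diffusion space
#'   (0 = background), or a `scalar_map` holding one.
#' @param lookup Parcel-to-lobe lookup data.frame (see [read_lobe_lookup()]).
#' @param affine 4x4 affine (ignored when `label_map` is a `scalar_map`).
#' @return A `lobe_parcellation` object.
#' @export
lobe_parcellation <- function(label_map, lookup = read_lobe_lookup(),
                              affine = diag(4)) {
  if (inherits(label_map, "scalar_map")) {
    affine <- label_map$affine
    label_map <- label_map$values
  }
  label_map <- array(as.integer(round(label_map)), dim = dim(label_map))
  labs <- setdiff(unique(as.vector(label_map)), 0L)
  unknown <- setdiff(labs, lookup$label)
  if (length(unknown))
    stop("label(s) in map absent from lookup (add them or map to 'ignore'): ",
         paste(sort(unknown), collapse = ", "))
  structure(list(label_map = label_map, lookup = lookup, affine = affine),
            class = "lobe_parcellation")
}

#' Read an integer label map as a lobe parcellation
#'
#' @param path NIfTI-1 integer label volume in diffusion space.
#' @param reference A `dwi_dataset` or `scalar_map` defining the grid.
#' @param lookup Parcel-to-lobe lookup (default: packaged Desikan-Killiany).
#' @return A `lobe_parcellation`.
#' @export
read_parcellation <- function(path, reference, lookup = read_lobe_lookup()) {
  m <- read_scalar_map(path, reference, kind = "labels")
  lobe_parcellation(m$values, lookup, affine = m$affine)
}

#' Mean of a scalar map over one cortical lobe
#'
#' Arithmetic mean of in-lobe voxels; missing-coded (`NA`) map voxels are
#' excluded from both the numerator and the voxel count.
#'
#' @param map A `scalar_map`.
#' @param parcellation A [lobe_parcellation()].
#' @param lobe One of the eight lobe names.
#' @return List with `value` (mean, `NA` if the lobe is empty) and
#'   `n_voxels`.
#' @export
roi_mean <- function(map, parcellation, lobe) {
  stopifnot(inherits(map, "scalar_map"), inherits(parcellation, "lobe_parcellation"))
  if (!lobe %in% lobe_names()) stop("unknown lobe: ", lobe)
  if (!identical(dim(map$values), dim(parcellation$label_map)))
    stop("map and parcellation grids differ")
  labels <- parcellation$lookup$label[parcellation$lookup$lobe == lobe]
  sel <- parcellation$label_map %in% labels & is.finite(map$values)
  n <- sum(sel)
  if (n == 0) {
    warning("no voxels for lobe ", lobe, "; missing-coded")
    return(list(value = NA_real_, n_voxels = 0L))
  }
  list(value = mean(map$values[sel]), n_voxels = as.integer(n))
}

#' Summarize a subject's iFW map over the eight lobes
#'
#' @param ifw An `ifw_map` (from [build_ifw_map()]) or a `scalar_map`.
#' @param parcellation A [lobe_parcellation()].
#' @param subject_id Subject identifier.
#' @param timepoint Time from baseline (years).
#' @param measure_name Measure label in the output table.
#' @return data.frame with one row per lobe: `subject_id`,
#'   `timepoint_years`, `roi`, `measure_name`, `value`, `n_voxels`.
#'   Lobes with no voxels get `NA` values, never zero fill.
#' @export
summarize_subject <- function(ifw, parcellation, subject_id, timepoint = 0,
                              measure_name = "ifw") {
  map <- if (inherits(ifw, "ifw_map")) ifw$ifw else ifw
  rows <- lapply(lobe_names(), function(lb) {
    r <- withCallingHandlers(
      roi_mean(map, parcellation, lb),
      warning = function(w) invokeRestart("muffleWarning"))
    data.frame(subject_id = subject_id, timepoint_years = timepoint,
               roi = lb, measure_name = measure_name,
               value = r$value, n_voxels = r$n_voxels,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
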