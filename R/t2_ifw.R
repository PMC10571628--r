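#' Relaxation parameters for the T2 compensation
#'
#' The two-compartment fit measures a *signal* fraction; because CSF-like
#' free water has a much longer T2 than cortical tissue, the free-water
#' compartment is over-weighted at long echo times and the signal fraction
#' overestimates the *volume* fraction. These parameters describe the
#' mono-exponential compartmental T2 weighting used to undo that bias.
#'
#' @param te Echo time (ms); default 109 ms (the multi-shell protocol this
#'   toolkit targets).
#' @param t2_tissue Tissue (cortical gray matter) T2 (ms); default 90 ms at 3T.
#' @param t2_free Free-water / CSF T2 (ms); default 2000 ms at 3T.
#' @return A `relaxation_params` list.
#' @export
relaxation_params <- function(te = 109, t2_tissue = 90, t2_free = 2000) {
  stopifnot(te >= 0, t2_tissue > 0, t2_free > 0)
  if (t2_free < t2_tissue)
    warning("t2_free < t2_tissue: the T2 correction direction is reversed")
  structure(list(te = te, t2_tissue = t2_tissue, t2_free = t2_free),
            class = "relaxation_params")
}

#' Convert an apparent free-water signal fraction to a volume fraction
#'
#' Under compartmental mono-exponential T2 weighting the apparent (signal)
#' fraction is `f_app = f * e_f / (f * e_f + (1 - f) * e_t)` with
#' `e_f = exp(-te / t2_free)` and `e_t = exp(-te / t2_tissue)`. This
#' function inverts that relation in closed form:
#' `f = f_app * k / (1 - f_app + f_app * k)` with `k = e_t / e_f`.
#' Whenever `t2_free > t2_tissue` (the physiological case) the corrected
#' fraction is smaller than the apparent one, reducing the overestimation
#' bias of the signal-domain fit. Vectorized over `f_apparent`; `NA` passes
#' through.
#'
#' @param f_apparent Apparent signal fraction(s) in `[0, 1]`.
#' @param params A [relaxation_params()].
#' @param tol Tolerance beyond `[0, 1]` that raises an error.
#' @return Corrected volume fraction(s) in `[0, 1]`.
#' @export
t2_correct <- function(f_apparent, params = relaxation_params(), tol = 1e-6) {
  stopifnot(inherits(params, "relaxation_params"))
  ok <- is.finite(f_apparent)
  if (any(f_apparent[ok] < -tol | f_apparent[ok] > 1 + tol))
    stop("f_apparent outside [0, 1] beyond tolerance")
  f_app <- pmin(pmax(f_apparent, 0), 1)
  k <- exp(-params$te / params$t2_tissue) / exp(-params$te / params$t2_free)
  f_app * k / (1 - f_app + f_app * k)
}

#' Subtract the CSF fractional volume from a free-water map
#'
#' Interstitial free water is the free-water volume fraction left after
#' removing the voxel's CSF partial volume: `ifw = fw - csfv`, with negative
#' values projected to zero (and clipped above at one to respect the
#' fraction contract).
#'
#' @param fw_corrected `scalar_map` of T2-corrected free-water volume fractions.
#' @param csfv `scalar_map` of CSF fractional volumes on the same grid.
#' @return A `scalar_map` named `"ifw"`.
#' @export
compute_ifw <- function(fw_corrected, csfv) {
  stopifnot(inherits(fw_corrected, "scalar_map"), inherits(csfv, "scalar_map"))
  if (!identical(dim(fw_corrected$values), dim(csfv$values)))
    stop("fw and CSFv maps have different grids")
  if (max(abs(fw_corrected$affine - csfv$affine)) > 1e-3)
    stop("fw and CSFv maps have different affines")
  vals <- pmin(pmax(fw_corrected$values - csfv$values, 0), 1)
  scalar_map(vals, fw_corrected$affine, "ifw")
}

#' Build the full iFW map stack from fitted free-water maps
#'
#' Composes the T2 compensation and the CSF subtraction, retaining all
#' stages (apparent FW, corrected FW, CSFv, iFW) for inspection.
#'
#' @param fw_apparent `scalar_map` of fitted (apparent) free-water signal
#'   fractions, or an `fw_fit_maps` object from [fit_volume()].
#' @param csfv `scalar_map` of CSF fractional volumes.
#' @param params A [relaxation_params()].
#' @return An `ifw_map`: list with `fw_apparent`, `fw_corrected`, `csfv`,
#'   `ifw` scalar maps and the `params` used.
#' @export
build_ifw_map <- function(fw_apparent, csfv, params = relaxation_params()) {
  if (inherits(fw_apparent, "fw_fit_maps")) fw_apparent <- fw_apparent$fw
  stopifnot(inherits(fw_apparent, "scalar_map"))
  corrected <- scalar_map(
    array(t2_correct(fw_apparent$values, params), dim = dim(fw_apparent$values)),
    fw_apparent$affine, "fw_corrected")
  csfv <- validate_scalar_map(csfv, corrected)
  structure(list(fw_apparent = fw_apparent, fw_corrected = corrected,
                 csfv = csfv, ifw = compute_ifw(corrected, csfv),
                 params = params),
            class = "ifw_map")
}
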