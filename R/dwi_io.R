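#' Construct an acquisition scheme
#'
#' An acquisition scheme pairs each diffusion-weighted volume with its
#' b-value (s/mm^2) and unit gradient direction, and records the echo time.
#' It is the contract shared by readers, the phantom simulator and the
#' two-compartment fitter.
#'
#' @param bvals Numeric vector of b-values, one per volume (s/mm^2).
#' @param bvecs Numeric matrix with one row per volume and three columns;
#'   rows for b > 0 volumes must have unit Euclidean norm (within `1e-3`;
#'   non-unit vectors are renormalized with a warning). Rows for b = 0
#'   volumes may be zero.
#' @param echo_time Echo time in milliseconds.
#' @return An object of class `acquisition_scheme` with elements `bvals`,
#'   `bvecs` and `echo_time`.
#' @export
acquisition_scheme <- function(bvals, bvecs, echo_time) {
  bvals <- as.numeric(bvals)
  bvecs <- as.matrix(bvecs)
  if (ncol(bvecs) != 3L)
    stop("bvecs must have three columns (x, y, z components)")
  if (length(bvals) != nrow(bvecs))
    stop(sprintf("bvals (%d) and bvecs (%d rows) describe different numbers of volumes",
                 length(bvals), nrow(bvecs)))
  if (any(!is.finite(bvals)) || any(bvals < 0))
    stop("b-values must be finite and non-negative")
  if (!any(bvals == 0))
    stop("scheme must contain at least one b = 0 volume")
  if (!is.numeric(echo_time) || length(echo_time) != 1L || echo_time < 0)
    stop("echo_time must be a single non-negative number (ms)")

  nrm <- sqrt(rowSums(bvecs^2))
  dwi <- bvals > 0
  bad <- dwi & abs(nrm - 1) > 1e-3
  if (any(bad)) {
    if (any(nrm[bad] == 0))
      stop("zero gradient direction supplied for a b > 0 volume")
    warning(sprintf("%d b > 0 direction(s) were not unit norm; renormalized", sum(bad)))
    bvecs[bad, ] <- bvecs[bad, ] / nrm[bad]
  }
  structure(list(bvals = bvals, bvecs = unname(bvecs),
                 echo_time = as.numeric(echo_time)),
            class = "acquisition_scheme")
}

#' @export
length.acquisition_scheme <- function(x) length(x$bvals)

#' @exportS3Method base::print
print.acquisition_scheme <- function(x, ...) {
  tab <- table(x$bvals)
  cat("Acquisition scheme:", length(x), "volumes, TE =", x$echo_time, "ms\n")
  cat("  b-values (s/mm^2):",
      paste(sprintf("%s x b=%s", tab, names(tab)), collapse = ", "), "\n")
  invisible(x)
}

#' Read FSL-dialect bval/bvec files
#'
#' The FSL dialect stores one whitespace-separated row of b-values and three
#' rows of gradient components (x, y, z), one column per volume. Other
#' dialects are rejected rather than guessed.
#'
#' @param bval_path,bvec_path Paths to the text files.
#' @return A list with `bvals` (numeric vector) and `bvecs` (volumes x 3 matrix).
#' @export
read_bvals_bvecs <- function(bval_path, bvec_path) {
  for (p in c(bval_path, bvec_path))
    if (!file.exists(p)) stop("file not found: ", p)
  bvals <- scan(bval_path, what = numeric(), quiet = TRUE)
  bv <- as.matrix(utils::read.table(bvec_path))
  if (nrow(bv) != 3L)
    stop(sprintf("bvec file must have exactly 3 rows (FSL dialect); found %d", nrow(bv)))
  list(bvals = bvals, bvecs = unname(t(bv)))
}

#' Read a 4-D diffusion-weighted dataset
#'
#' Loads a NIfTI-1 diffusion volume together with its FSL-dialect gradient
#' table and assembles a validated dataset. Volume counts across the three
#' files must agree. If no mask is given, one is derived from the mean b = 0
#' signal (see [default_mask()]).
#'
#' @param dwi_path NIfTI-1 file (.nii or .nii.gz) with a 4th volume dimension.
#' @param bval_path,bvec_path FSL-dialect gradient table files.
#' @param echo_time Echo time (ms). If `NULL`, a JSON sidecar next to
#'   `dwi_path` (same stem, `.json`) is consulted for `EchoTime`
#'   (seconds, BIDS convention) and converted to ms.
#' @param mask Optional 3-D logical array matching the spatial grid.
#' @return A `dwi_dataset`: list with `signal` (4-D array), `scheme`,
#'   `voxel_size` (mm), `mask`, `affine`.
#' @export
read_dwi <- function(dwi_path, bval_path, bvec_path, echo_time = NULL,
                     mask = NULL) {
  if (!file.exists(dwi_path)) stop("file not found: ", dwi_path)
  img <- RNifti::readNifti(dwi_path)
  arr <- as.array(img)
  if (length(dim(arr)) != 4L)
    stop("expected a 4-D diffusion volume; got ", length(dim(arr)), " dimensions")
  gt <- read_bvals_bvecs(bval_path, bvec_path)
  nv <- dim(arr)[4]
  if (length(gt$bvals) != nv || nrow(gt$bvecs) != nv)
    stop(sprintf(
      "volume count mismatch: DWI has %d volumes, bval file %d, bvec file %d",
      nv, length(gt$bvals), nrow(gt$bvecs)))
  if (is.null(echo_time)) {
    sidecar <- sub("\\.nii(\\.gz)?$", ".json", dwi_path)
    if (!file.exists(sidecar))
      stop("echo_time not given and no JSON sidecar found at ", sidecar)
    meta <- jsonlite::read_json(sidecar)
    if (is.null(meta$EchoTime))
      stop("JSON sidecar has no EchoTime field")
    echo_time <- as.numeric(meta$EchoTime) * 1000  # seconds -> ms
  }
  scheme <- acquisition_scheme(gt$bvals, gt$bvecs, echo_time)
  vx <- RNifti::pixdim(img)[seq_len(3)]
  dwi_dataset(arr, scheme, voxel_size = vx, mask = mask,
              affine = unclass(RNifti::xform(img)))
}

#' Assemble a diffusion dataset from in-memory pieces
#'
#' @param signal 4-D numeric array (x, y, z, volume).
#' @param scheme An [acquisition_scheme()] of matching length.
#' @param voxel_size Numeric length-3 voxel edge lengths (mm).
#' @param mask Optional 3-D logical array; derived from the b = 0 signal when
#'   absent.
#' @param affine 4x4 voxel-to-world transform.
#' @return A `dwi_dataset` object.
#' @export
dwi_dataset <- function(signal, scheme, voxel_size = c(2, 2, 2), mask = NULL,
                        affine = NULL) {
  stopifnot(inherits(scheme, "acquisition_scheme"))
  d <- dim(signal)
  if (length(d) != 4L) stop("signal must be a 4-D array")
  if (d[4] != length(scheme))
    stop(sprintf("signal has %d volumes but scheme describes %d", d[4], length(scheme)))
  if (is.null(affine)) affine <- diag(c(voxel_size, 1))
  if (is.null(mask)) {
    mask <- default_mask(signal, scheme)
  } else {
    mask <- array(as.logical(mask), dim = dim(mask))
    if (!identical(dim(mask), d[1:3]))
      stop("mask shape does not match the signal spatial shape")
  }
  structure(list(signal = signal, scheme = scheme,
                 voxel_size = as.numeric(voxel_size), mask = mask,
                 affine = affine),
            class = "dwi_dataset")
}

#' Default brain mask from the b = 0 signal
#'
#' Marks voxels whose mean b = 0 signal exceeds `threshold` times the 99th
#' percentile of the mean b = 0 signal.
#'
#' @param signal 4-D array.
#' @param scheme Matching acquisition scheme.
#' @param threshold Fraction of the 99th-percentile b = 0 signal (default 0.05).
#' @return 3-D logical array.
#' @export
default_mask <- function(signal, scheme, threshold = 0.05) {
  b0 <- scheme$bvals == 0
  mb0 <- apply(signal[, , , b0, drop = FALSE], 1:3, mean)
  ref <- stats::quantile(mb0, 0.99, names = FALSE)
  array(mb0 > threshold * ref, dim = dim(mb0))
}

#' Restrict a dataset to shells at or below a maximum b-value
#'
#' High shells probe non-Gaussian diffusion and are excluded from the
#' two-compartment free-water fit; the default protocol keeps b <= 1000
#' s/mm^2.
#'
#' @param data A `dwi_dataset`.
#' @param max_b Maximum b-value to retain (s/mm^2), > 0.
#' @return A `dwi_dataset` with only volumes at b <= `max_b`.
#' @export
select_shells <- function(data, max_b = 1000) {
  stopifnot(inherits(data, "dwi_dataset"))
  if (!is.numeric(max_b) || length(max_b) != 1L || max_b <= 0)
    stop("max_b must be a single positive b-value")
  keep <- data$scheme$bvals <= max_b
  b <- data$scheme$bvals[keep]
  if (!any(b == 0) || !any(b > 0))
    stop("shell selection must retain at least one b = 0 and one b > 0 volume")
  scheme <- acquisition_scheme(b, data$scheme$bvecs[keep, , drop = FALSE],
                               data$scheme$echo_time)
  dwi_dataset(data$signal[, , , keep, drop = FALSE], scheme,
              voxel_size = data$voxel_size, mask = data$mask,
              affine = data$affine)
}

#' Construct a scalar map
#'
#' @param values 3-D numeric array.
#' @param affine 4x4 voxel-to-world transform.
#' @param name Identifier (e.g. `"fw"`, `"csfv"`, `"ifw"`).
#' @return A `scalar_map` object.
#' @export
scalar_map <- function(values, affine = diag(4), name = "map") {
  values <- as.array(values)
  if (length(dim(values)) != 3L) stop("scalar map values must be a 3-D array")
  structure(list(values = values, affine = affine, name = name),
            class = "scalar_map")
}

# Fraction-valued map names subject to the [0, 1] contract.
.fraction_kinds <- c("fw", "fw_apparent", "fw_corrected", "csfv", "ifw")

# Normalize an array read from NIfTI to 3-D: readers drop trailing singleton
# dimensions, and single-volume 4-D files are really 3-D maps.
.as_map_array <- function(vals) {
  vals <- as.array(vals)
  d <- dim(vals)
  if (length(d) == 2L) dim(vals) <- c(d, 1L)
  else if (length(d) == 4L && d[4] == 1L) dim(vals) <- d[1:3]
  vals
}

#' Read a scalar map aligned to a reference dataset
#'
#' Maps consumed by the iFW pipeline (e.g. a CSF fractional-volume map) must
#' already live on the diffusion grid; registration happens upstream and no
#' resampling is performed here. Fraction-kind maps are checked to `[0, 1]`;
#' values within `eps` outside that range are clipped with a warning, larger
#' excursions are an error.
#'
#' @param path NIfTI-1 file.
#' @param reference A `dwi_dataset` defining the expected grid.
#' @param kind Map identifier; one of `"fw"`, `"fw_apparent"`,
#'   `"fw_corrected"`, `"csfv"`, `"ifw"` triggers the fraction check.
#' @param eps Clipping tolerance for fraction maps (default 1e-2).
#' @return A validated `scalar_map`.
#' @export
read_scalar_map <- function(path, reference, kind = "map", eps = 1e-2) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  map <- scalar_map(.as_map_array(img), affine = unclass(RNifti::xform(img)),
                    name = kind)
  validate_scalar_map(map, reference, eps = eps)
}

#' Validate a scalar map against a reference geometry
#'
#' @param map A `scalar_map`.
#' @param reference A `dwi_dataset` (or `scalar_map`) defining the grid.
#' @param eps Clipping tolerance for fraction maps.
#' @return The validated (possibly clipped) map.
#' @export
validate_scalar_map <- function(map, reference, eps = 1e-2) {
  ref_dim <- if (inherits(reference, "dwi_dataset")) dim(reference$signal)[1:3]
             else dim(reference$values)
  if (!identical(dim(map$values), ref_dim))
    stop(sprintf("map grid %s does not match reference grid %s; resample upstream",
                 paste(dim(map$values), collapse = "x"),
                 paste(ref_dim, collapse = "x")))
  if (max(abs(map$affine - reference$affine)) > 1e-3)
    stop("map affine differs from reference affine beyond 1e-3; resample upstream")
  if (map$name %in% .fraction_kinds) {
    v <- map$values
    finite <- is.finite(v)
    if (any(v[finite] < -eps) || any(v[finite] > 1 + eps))
      stop(sprintf("'%s' map has values outside [0, 1] beyond tolerance %g",
                   map$name, eps))
    n_clip <- sum(finite & (v < 0 | v > 1))
    if (n_clip > 0) {
      warning(sprintf("clipped %d '%s' value(s) to [0, 1] (within tolerance %g)",
                      n_clip, map$name, eps))
      v[finite] <- pmin(pmax(v[finite], 0), 1)
      map$values <- v
    }
  }
  map
}

#' Write a dataset as NIfTI + FSL gradient files
#'
#' @param data A `dwi_dataset`.
#' @param prefix Output path prefix; writes `<prefix>.nii.gz`, `<prefix>.bval`,
#'   `<prefix>.bvec`.
#' @return Invisibly, the three paths written.
#' @export
write_dwi <- function(data, prefix) {
  stopifnot(inherits(data, "dwi_dataset"))
  nii <- paste0(prefix, ".nii.gz")
  img <- RNifti::asNifti(data$signal)
  RNifti::pixdim(img) <- c(data$voxel_size, 1)
  img <- RNifti::`sform<-`(img, structure(data$affine, code = 2L))
  RNifti::writeNifti(img, nii)
  bval <- paste0(prefix, ".bval")
  writeLines(paste(format(data$scheme$bvals, trim = TRUE), collapse = " "), bval)
  bvec <- paste0(prefix, ".bvec")
  m <- t(data$scheme$bvecs)  # 3 rows
  writeLines(apply(m, 1, function(r)
    paste(formatC(r, digits = 10, format = "g"), collapse = " ")), bvec)
  invisible(c(nii, bval, bvec))
}

#' Write a scalar map as NIfTI-1
#'
#' @param map A `scalar_map`.
#' @param path Output path (.nii or .nii.gz).
#' @return Invisibly, `path`.
#' @export
write_scalar_map <- function(map, path) {
  stopifnot(inherits(map, "scalar_map"))
  img <- RNifti::asNifti(map$values)
  img <- RNifti::`sform<-`(img, structure(map$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}
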