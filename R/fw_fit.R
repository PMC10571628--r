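#' Configuration for the two-compartment free-water fit
#'
#' @param d_free Isotropic diffusivity of free water at body temperature
#'   (mm^2/s). The conventional value 3.0e-3 is fixed during fitting.
#' @param max_iter Maximum Levenberg-Marquardt iterations.
#' @param tol Convergence tolerance on the relative reduction of the
#'   sum-of-squares cost.
#' @param lambda_init Assumed tissue mean diffusivity (mm^2/s) used only to
#'   initialize the free-water fraction from the highest retained shell.
#' @param seed Integer seed recorded for provenance; the fit itself is
#'   deterministic (no random restarts).
#' @return A `fit_config` list.
#' @export
fit_config <- function(d_free = 3.0e-3, max_iter = 200L, tol = 1e-12,
                       lambda_init = 0.7e-3, seed = 1L) {
  stopifnot(d_free > 0, max_iter >= 1, tol > 0, lambda_init > 0)
  structure(list(d_free = d_free, max_iter = as.integer(max_iter), tol = tol,
                 lambda_init = lambda_init, seed = as.integer(seed)),
            class = "fit_config")
}

#' Predict the two-compartment diffusion signal
#'
#' Bi-tensor forward model: each volume's signal is
#' `s0 * ((1 - f_fw) * exp(-b g' T g) + f_fw * exp(-b d_free))`,
#' a weighted sum of an anisotropic tissue tensor compartment and an
#' isotropic free-water compartment.
#'
#' @param s0 Non-diffusion-weighted signal (> 0).
#' @param f_fw Free-water signal fraction in `[0, 1]`.
#' @param tensor Symmetric positive semidefinite 3x3 tissue tensor (mm^2/s).
#' @param scheme An [acquisition_scheme()].
#' @param d_free Free-water diffusivity (mm^2/s).
#' @return Numeric vector of predicted signals, one per volume.
#' @export
predict_signal <- function(s0, f_fw, tensor, scheme, d_free = 3.0e-3) {
  stopifnot(inherits(scheme, "acquisition_scheme"),
            f_fw >= 0, f_fw <= 1, s0 > 0)
  b <- scheme$bvals
  g <- scheme$bvecs
  q <- rowSums((g %*% tensor) * g)  # g' T g per volume
  s0 * ((1 - f_fw) * exp(-b * q) + f_fw * exp(-b * d_free))
}

# Quadratic form g' T g for every row of g, given the 6 unique tensor
# entries beta = (Dxx, Dyy, Dzz, Dxy, Dxz, Dyz).
.design_matrix <- function(g) {
  cbind(g[, 1]^2, g[, 2]^2, g[, 3]^2,
        2 * g[, 1] * g[, 2], 2 * g[, 1] * g[, 3], 2 * g[, 2] * g[, 3])
}

.tensor_from_beta <- function(beta) {
  matrix(c(beta[1], beta[4], beta[5],
           beta[4], beta[2], beta[6],
           beta[5], beta[6], beta[3]), 3, 3)
}

# Weighted linear LS estimate of the tissue tensor from log-attenuations.
# att: attenuation per b>0 volume (clamped positive by the caller).
.linear_tensor_fit <- function(att, b, g) {
  X <- .design_matrix(g) * b          # so that X beta = b * g' T g
  y <- -log(att)
  w <- att^2                          # standard log-linear DTI weighting
  XtW <- t(X * w)
  beta <- tryCatch(solve(XtW %*% X, XtW %*% y),
                   error = function(e) rep(NA_real_, 6))
  .tensor_from_beta(as.numeric(beta))
}

# Project a symmetric tensor onto eigenvalues within [lo, hi].
.clamp_tensor <- function(tensor, lo = 0, hi = Inf) {
  e <- eigen(tensor, symmetric = TRUE)
  lam <- pmin(pmax(e$values, lo), hi)
  e$vectors %*% diag(lam) %*% t(e$vectors)
}

.missing_fit <- function() {
  structure(list(f_fw = NA_real_, tensor = matrix(NA_real_, 3, 3),
                 s0 = NA_real_, residual_rms = NA_real_, converged = FALSE,
                 degenerate = FALSE, n_floored = 0L),
            class = "free_water_fit")
}

#' Fit the two-compartment model in one voxel
#'
#' Constrained nonlinear least squares on the bi-tensor model of
#' [predict_signal()]. The free-water fraction is box-constrained to
#' `[0, 1]`, the tissue tensor is kept positive semidefinite through a
#' Cholesky-factor reparameterization, and `s0` is constrained positive.
#' Initialization is deterministic: `s0` from the mean b = 0 signal, `f_fw`
#' from a two-point estimate at the highest shell against an assumed tissue
#' diffusivity, and the tensor from weighted linear least squares on the
#' free-water-corrected log-attenuations.
#'
#' When the tissue compartment is indistinguishable from free water (pure
#' CSF-like signal) the model is degenerate along a ridge in `(f_fw, MD)`;
#' the fit is then resolved toward `f_fw = 1` and flagged `degenerate`.
#'
#' @param signal Numeric vector, one entry per scheme volume.
#' @param scheme An [acquisition_scheme()]; needs at least 8 distinct b > 0
#'   measurements.
#' @param config A [fit_config()].
#' @return A `free_water_fit`: list with `f_fw`, `tensor` (3x3, eigenvalues
#'   clamped to `[0, d_free]`), `s0`, `residual_rms`, `converged`,
#'   `degenerate`, `n_floored`.
#' @export
fit_voxel <- function(signal, scheme, config = fit_config()) {
  stopifnot(inherits(scheme, "acquisition_scheme"))
  signal <- as.numeric(signal)
  if (length(signal) != length(scheme))
    stop(sprintf("signal has %d entries but scheme describes %d volumes",
                 length(signal), length(scheme)))
  if (sum(scheme$bvals > 0) < 8)
    stop("need at least 8 diffusion-weighted (b > 0) measurements")
  if (any(!is.finite(signal)) || all(signal <= 0))
    return(.missing_fit())

  b <- scheme$bvals
  g <- scheme$bvecs
  d_free <- config$d_free
  b0 <- b == 0

  s0_init <- mean(signal[b0])
  if (!is.finite(s0_init) || s0_init <= 0) return(.missing_fit())
  floor_val <- 1e-6 * s0_init
  n_floored <- sum(signal < floor_val)
  signal <- pmax(signal, floor_val)

  # f_fw init: two-point estimate at the highest shell vs assumed tissue MD
  bmax <- max(b)
  att_max <- mean(signal[b == bmax]) / s0_init
  et <- exp(-bmax * config$lambda_init)
  ef <- exp(-bmax * d_free)
  f0 <- (att_max - et) / (ef - et)
  f0 <- min(max(f0, 1e-3), 1 - 1e-3)

  # tensor init: weighted linear LS on free-water-corrected log-attenuation
  dwi <- b > 0
  att <- (signal[dwi] / s0_init - f0 * exp(-b[dwi] * d_free)) / (1 - f0)
  att <- pmin(pmax(att, 1e-6), 1)
  D0 <- .linear_tensor_fit(att, b[dwi], g[dwi, , drop = FALSE])
  if (any(!is.finite(D0))) D0 <- diag(rep(config$lambda_init, 3))
  D0 <- .clamp_tensor(D0, lo = 1e-3 * d_free, hi = d_free)
  L0 <- t(chol(D0 + diag(1e-12, 3)))

  par0 <- c(f0, s0_init, L0[lower.tri(L0, diag = TRUE)])
  lower <- c(0, floor_val, rep(-Inf, 6))
  upper <- c(1, Inf, rep(Inf, 6))

  resid_fn <- function(p) {
    L <- matrix(0, 3, 3)
    L[lower.tri(L, diag = TRUE)] <- p[3:8]
    D <- L %*% t(L)
    q <- rowSums((g %*% D) * g)
    pred <- p[2] * ((1 - p[1]) * exp(-b * q) + p[1] * exp(-b * d_free))
    signal - pred
  }

  fit <- minpack.lm::nls.lm(
    par = par0, lower = lower, upper = upper, fn = resid_fn,
    control = minpack.lm::nls.lm.control(
      maxiter = config$max_iter, ftol = config$tol, ptol = 1e-14,
      gtol = 0))

  p <- fit$par
  L <- matrix(0, 3, 3)
  L[lower.tri(L, diag = TRUE)] <- p[3:8]
  tensor <- .clamp_tensor(L %*% t(L), lo = 0, hi = d_free)
  f_hat <- p[1]
  s0_hat <- p[2]
  cost <- sum(resid_fn(p)^2)

  # degenerate ridge: a pure free-water model explains the data as well
  e_iso <- exp(-b * d_free)
  s0_iso <- sum(signal * e_iso) / sum(e_iso^2)
  cost_iso <- sum((signal - s0_iso * e_iso)^2)
  degenerate <- FALSE
  if (cost_iso <= cost + config$tol * max(cost, 1)) {
    md <- mean(diag(tensor))
    if (f_hat > 0.9 || abs(md - d_free) / d_free < 0.05) {
      f_hat <- 1
      s0_hat <- s0_iso
      cost <- cost_iso
      degenerate <- TRUE
    }
  }

  structure(list(
    f_fw = f_hat, tensor = tensor, s0 = s0_hat,
    residual_rms = sqrt(cost / length(signal)),
    converged = fit$info %in% 1:4, degenerate = degenerate,
    n_floored = n_floored), class = "free_water_fit")
}

#' Fit the two-compartment model over a masked volume
#'
#' Applies [fit_voxel()] to every in-mask voxel. Out-of-mask voxels are
#' missing-coded (`NA`) in every output map. The computation is
#' deterministic for fixed inputs.
#'
#' @param data A `dwi_dataset`.
#' @param config A [fit_config()].
#' @return A list of class `fw_fit_maps` with scalar maps `fw`, `s0`,
#'   `residual`, a 4-D `tensor` array (x, y, z, 6) in lower-triangular FSL
#'   ordering (Dxx, Dxy, Dyy, Dxz, Dyz, Dzz), and logical arrays `converged`
#'   and `degenerate`.
#' @export
fit_volume <- function(data, config = fit_config()) {
  stopifnot(inherits(data, "dwi_dataset"))
  dims <- dim(data$signal)[1:3]
  if (!any(data$mask)) stop("mask is empty; nothing to fit")

  fw <- s0 <- res <- array(NA_real_, dims)
  conv <- degen <- array(FALSE, dims)
  tens <- array(NA_real_, c(dims, 6L))
  idx <- which(data$mask, arr.ind = TRUE)
  for (k in seq_len(nrow(idx))) {
    i <- idx[k, 1]; j <- idx[k, 2]; l <- idx[k, 3]
    v <- fit_voxel(data$signal[i, j, l, ], data$scheme, config)
    fw[i, j, l] <- v$f_fw
    s0[i, j, l] <- v$s0
    res[i, j, l] <- v$residual_rms
    conv[i, j, l] <- v$converged
    degen[i, j, l] <- v$degenerate
    if (all(is.finite(v$tensor)))
      tens[i, j, l, ] <- v$tensor[c(1, 4, 5, 7, 8, 9)]  # Dxx Dxy Dyy Dxz Dyz Dzz
  }
  structure(list(
    fw = scalar_map(fw, data$affine, "fw_apparent"),
    s0 = scalar_map(s0, data$affine, "s0"),
    residual = scalar_map(res, data$affine, "residual"),
    tensor = tens, converged = conv, degenerate = degen,
    config = config), class = "fw_fit_maps")
}

#' Write fitted free-water maps to a directory
#'
#' Writes `fw.nii.gz`, `s0.nii.gz`, `residual.nii.gz` and the tensor as a
#' 6-volume NIfTI `tensor.nii.gz` in FSL lower-triangular ordering
#' (Dxx, Dxy, Dyy, Dxz, Dyz, Dzz).
#'
#' @param maps An `fw_fit_maps` object from [fit_volume()].
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_fw_maps <- function(maps, out_dir) {
  stopifnot(inherits(maps, "fw_fit_maps"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (nm in c("fw", "s0", "residual")) {
    p <- file.path(out_dir, paste0(nm, ".nii.gz"))
    write_scalar_map(maps[[nm]], p)
    paths <- c(paths, p)
  }
  img <- RNifti::asNifti(maps$tensor)
  img <- RNifti::`sform<-`(img, structure(maps$fw$affine, code = 2L))
  p <- file.path(out_dir, "tensor.nii.gz")
  RNifti::writeNifti(img, p)
  invisible(c(paths, p))
}
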