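#' Evenly spread gradient directions by electrostatic repulsion
#'
#' Minimizes the Coulomb energy of antipodally symmetric point pairs on the
#' unit sphere, the standard construction for diffusion gradient tables.
#' Deterministic: the starting configuration is drawn from a private RNG
#' stream seeded by `seed`, and the polish is a deterministic projected
#' gradient descent with backtracking line search.
#'
#' @param n Number of directions.
#' @param seed Integer seed for the starting configuration.
#' @return `n` x 3 matrix of unit vectors.
#' @export
spherical_directions <- function(n, seed = 42L) {
  stopifnot(n >= 1)
  if (n == 1L) return(matrix(c(0, 0, 1), 1, 3))
  rng <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit({
    if (is.null(rng)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", rng, envir = globalenv())
  })
  set.seed(seed)
  th <- acos(stats::runif(n, -1, 1))
  ph <- stats::runif(n, 0, 2 * pi)
  x <- cbind(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))

  # For unit vectors |xi - xj|^2 = 2 - 2 xi.xj and |xi + xj|^2 = 2 + 2 xi.xj,
  # so both the Coulomb energy of each antipodal pair and its gradient are
  # functions of the Gram matrix; projected gradient descent with
  # backtracking keeps everything on the sphere.
  energy <- function(x) {
    C <- tcrossprod(x)
    diag(C) <- NA
    0.5 * sum(1 / (2 - 2 * C) + 1 / (2 + 2 * C), na.rm = TRUE)
  }
  e <- energy(x)
  eta <- 0.01
  for (it in 1:500) {
    C <- tcrossprod(x)
    A <- 2 / (2 - 2 * C)^2
    B <- 2 / (2 + 2 * C)^2
    diag(A) <- 0
    diag(B) <- 0
    G <- (A - B) %*% x            # dE/dx_i
    repeat {
      xn <- x - eta * G
      xn <- xn / sqrt(rowSums(xn^2))
      en <- energy(xn)
      if (en < e || eta < 1e-12) break
      eta <- eta / 2
    }
    if (e - en < 1e-12 * abs(e)) {
      x <- xn
      break
    }
    x <- xn
    e <- en
    eta <- eta * 1.3
  }
  x
}

# paper_scheme() is pure; cache its (deterministic) result per session.
.scheme_cache <- new.env(parent = emptyenv())

#' The multi-shell acquisition scheme targeted by this toolkit
#'
#' A 44-volume scheme with 5 volumes at b = 0 and 3, 6 and 30
#' electrostatically spread directions at b = 200, 500 and 1000 s/mm^2,
#' echo time 109 ms. (A 2 mm isotropic grid is assumed by the matching
#' phantom generators.) Deterministic: the direction sets use fixed
#' internal seeds.
#'
#' @return An [acquisition_scheme()] with 44 volumes.
#' @export
paper_scheme <- function() {
  if (!is.null(.scheme_cache$scheme)) return(.scheme_cache$scheme)
  shells <- list(c(b = 0, n = 5), c(b = 200, n = 3),
                 c(b = 500, n = 6), c(b = 1000, n = 30))
  bvals <- unlist(lapply(shells, function(s) rep(s["b"], s["n"])))
  vecs <- do.call(rbind, lapply(shells, function(s) {
    if (s["b"] == 0) matrix(0, s["n"], 3)
    else spherical_directions(s["n"], seed = 1000L + s["n"])
  }))
  sch <- acquisition_scheme(as.numeric(bvals), vecs, echo_time = 109)
  .scheme_cache$scheme <- sch
  sch
}

#' Ground truth for one synthetic voxel
#'
#' Three-compartment description: a tissue tensor compartment, an
#' interstitial free-water compartment and a CSF compartment. The two
#' free-water-like compartments share the free-water diffusivity and T2;
#' the ground-truth iFW of the voxel is `f_interstitial` by construction.
#'
#' @param f_interstitial Interstitial free-water volume fraction.
#' @param f_csf CSF volume fraction; `f_interstitial + f_csf <= 1`.
#' @param tensor 3x3 tissue diffusion tensor (mm^2/s).
#' @param s0 Proton-density signal level (before any T2 weighting).
#' @param t2_tissue,t2_free Compartment T2 values (ms).
#' @return A `voxel_truth` list.
#' @export
voxel_truth <- function(f_interstitial = 0.1, f_csf = 0,
                        tensor = diag(c(1.2e-3, 0.5e-3, 0.5e-3)),
                        s0 = 1000, t2_tissue = 90, t2_free = 2000) {
  stopifnot(f_interstitial >= 0, f_csf >= 0, f_interstitial + f_csf <= 1,
            s0 > 0, t2_tissue > 0, t2_free > 0)
  structure(list(f_interstitial = f_interstitial, f_csf = f_csf,
                 tensor = tensor, s0 = s0,
                 t2_tissue = t2_tissue, t2_free = t2_free),
            class = "voxel_truth")
}

#' Simulate the multi-shell signal of one voxel
#'
#' Forward model with per-compartment T2 weighting:
#' `S_i = s0 * (w_t * (1 - f_int - f_csf) * exp(-b g' D g)
#'            + w_f * (f_int + f_csf) * exp(-b d_free))`,
#' `w = exp(-te / T2)`. Interstitial water and CSF share the free-water
#' diffusivity and T2, so the fit sees their combined apparent fraction.
#' Noise is Rician (magnitude-MRI standard): the noiseless signal plus
#' complex Gaussian noise of standard deviation `sigma = S_b0 / snr`, where
#' `S_b0` is the noiseless (T2-weighted) b = 0 tissue-mixture signal.
#'
#' @param truth A [voxel_truth()].
#' @param scheme An [acquisition_scheme()] (its `echo_time` sets the T2
#'   weighting).
#' @param snr Signal-to-noise ratio at b = 0; `Inf` for noiseless.
#' @param seed Integer seed; same seed reproduces the same realization.
#' @param d_free Free-water diffusivity (mm^2/s).
#' @param noise `"rician"` (default) or `"gaussian"` (debugging).
#' @return Numeric signal vector, one entry per volume.
#' @export
simulate_voxel <- function(truth, scheme, snr = Inf, seed = 1L,
                           d_free = 3.0e-3, noise = c("rician", "gaussian")) {
  stopifnot(inherits(truth, "voxel_truth"), inherits(scheme, "acquisition_scheme"),
            snr > 0)
  noise <- match.arg(noise)
  b <- scheme$bvals
  g <- scheme$bvecs
  te <- scheme$echo_time
  w_t <- exp(-te / truth$t2_tissue)
  w_f <- exp(-te / truth$t2_free)
  f_free <- truth$f_interstitial + truth$f_csf
  q <- rowSums((g %*% truth$tensor) * g)
  s <- truth$s0 * (w_t * (1 - f_free) * exp(-b * q) +
                   w_f * f_free * exp(-b * d_free))
  if (!is.finite(snr)) return(s)
  sigma <- (truth$s0 * (w_t * (1 - f_free) + w_f * f_free)) / snr
  rng <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit({
    if (is.null(rng)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", rng, envir = globalenv())
  })
  set.seed(seed)
  n1 <- stats::rnorm(length(s), 0, sigma)
  if (noise == "gaussian") return(s + n1)
  n2 <- stats::rnorm(length(s), 0, sigma)
  sqrt((s + n1)^2 + n2^2)
}

#' Simulate a phantom volume with a known truth grid
#'
#' Builds a slab of voxels whose ground-truth parameters are given per
#' voxel, simulates the multi-shell signal in each, and returns the dataset
#' together with ground-truth maps, so fitted maps can be compared against
#' truth directly.
#'
#' @param f_int 3-D array (or matrix for a single slice) of interstitial
#'   fractions.
#' @param f_csf Matching array of CSF fractions (default 0).
#' @param scheme Acquisition scheme (default [paper_scheme()]).
#' @param snr SNR at b = 0; `Inf` for noiseless.
#' @param seed Integer seed.
#' @param tensor Tissue tensor used in every voxel.
#' @param s0 Proton-density level.
#' @param t2_tissue,t2_free Compartment T2 values (ms).
#' @return List with `data` (a `dwi_dataset`, full mask), `truth`
#'   (list of `scalar_map`s: `f_interstitial`, `f_csf`, `fw_apparent`) and
#'   the generating parameters.
#' @export
simulate_volume <- function(f_int, f_csf = NULL, scheme = paper_scheme(),
                            snr = Inf, seed = 1L,
                            tensor = diag(c(1.2e-3, 0.5e-3, 0.5e-3)),
                            s0 = 1000, t2_tissue = 90, t2_free = 2000) {
  f_int <- as.array(f_int)
  if (length(dim(f_int)) == 2L) dim(f_int) <- c(dim(f_int), 1L)
  if (is.null(f_csf)) f_csf <- array(0, dim(f_int))
  f_csf <- as.array(f_csf)
  if (length(dim(f_csf)) == 2L) dim(f_csf) <- c(dim(f_csf), 1L)
  stopifnot(identical(dim(f_int), dim(f_csf)))
  dims <- dim(f_int)
  sig <- array(NA_real_, c(dims, length(scheme)))
  nvox <- prod(dims)
  for (v in seq_len(nvox)) {
    ijk <- arrayInd(v, dims)
    tr <- voxel_truth(f_int[v], f_csf[v], tensor = tensor, s0 = s0,
                      t2_tissue = t2_tissue, t2_free = t2_free)
    sig[ijk[1], ijk[2], ijk[3], ] <- simulate_voxel(tr, scheme, snr = snr,
                                                    seed = seed + v)
  }
  affine <- diag(c(2, 2, 2, 1))
  data <- dwi_dataset(sig, scheme, voxel_size = c(2, 2, 2),
                      mask = array(TRUE, dims), affine = affine)
  # apparent fraction the fitter should see, given the T2 weighting
  w_t <- exp(-scheme$echo_time / t2_tissue)
  w_f <- exp(-scheme$echo_time / t2_free)
  f_free <- f_int + f_csf
  fw_app <- w_f * f_free / (w_t * (1 - f_free) + w_f * f_free)
  list(data = data,
       truth = list(
         f_interstitial = scalar_map(f_int, affine, "f_interstitial"),
         f_csf = scalar_map(f_csf, affine, "csfv"),
         fw_apparent = scalar_map(array(fw_app, dims), affine, "fw_apparent")),
       params = list(tensor = tensor, s0 = s0, t2_tissue = t2_tissue,
                     t2_free = t2_free, snr = snr, seed = seed))
}

#' Write a simulated phantom to disk
#'
#' Writes the DWI volume with bval/bvec files, the ground-truth maps, and a
#' JSON record of the generating parameters, so downstream tests can load
#' truth instead of re-deriving it.
#'
#' @param phantom Result of [simulate_volume()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the directory.
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_dwi(phantom$data, file.path(dir, "dwi"))
  write_scalar_map(phantom$truth$f_interstitial, file.path(dir, "truth_f_interstitial.nii.gz"))
  write_scalar_map(phantom$truth$f_csf, file.path(dir, "csfv.nii.gz"))
  p <- phantom$params
  p$tensor <- as.vector(p$tensor)
  p$echo_time <- phantom$data$scheme$echo_time
  jsonlite::write_json(p, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
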