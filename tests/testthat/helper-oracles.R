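# Independent oracles and small fixture builders shared across tests.

# Exhaustive grid search over the free-water fraction with a per-f
# linearized tensor fit: for each candidate f the tissue attenuation is
# reconstructed, a tensor is fitted by (unweighted) linear least squares on
# its log, and the full-signal squared error is evaluated. Returns the
# grid minimizer. Independent of the package's Levenberg-Marquardt path.
grid_fw_oracle <- function(signal, scheme, d_free = 3.0e-3, step = 1e-3) {
  b <- scheme$bvals
  g <- scheme$bvecs
  dwi <- b > 0
  s0 <- mean(signal[b == 0])
  X <- cbind(g[dwi, 1]^2, g[dwi, 2]^2, g[dwi, 3]^2,
             2 * g[dwi, 1] * g[dwi, 2], 2 * g[dwi, 1] * g[dwi, 3],
             2 * g[dwi, 2] * g[dwi, 3]) * b[dwi]
  pinvX <- solve(crossprod(X), t(X))
  e_free <- exp(-b * d_free)
  fs <- seq(0, 1, by = step)
  best_f <- NA_real_
  best_cost <- Inf
  for (f in fs) {
    if (f < 1) {
      att <- (signal[dwi] / s0 - f * e_free[dwi]) / (1 - f)
      y <- -log(pmax(att, 1e-12))
      beta <- pinvX %*% y
      q <- as.numeric(X %*% beta)        # b * g' T g per dwi volume
      pred <- numeric(length(b))
      pred[!dwi] <- s0 * ((1 - f) + f * e_free[!dwi])
      pred[dwi] <- s0 * ((1 - f) * exp(-q) + f * e_free[dwi])
    } else {
      pred <- s0 * e_free
    }
    cost <- sum((signal - pred)^2)
    if (cost < best_cost) {
      best_cost <- cost
      best_f <- f
    }
  }
  list(f = best_f, cost = best_cost)
}

# Random tissue tensor with mean diffusivity drawn in [md_lo, md_hi] mm^2/s
# and a random orientation; eigenvalue spread fixed at (1.5, 0.75, 0.75) x MD.
random_tensor <- function(md_lo = 0.5e-3, md_hi = 1.2e-3) {
  md <- runif(1, md_lo, md_hi)
  lam <- md * c(1.5, 0.75, 0.75)
  A <- matrix(rnorm(9), 3, 3)
  Q <- qr.Q(qr(A))
  Q %*% diag(lam) %*% t(Q)
}

# A small scheme that is cheap but well-conditioned for unit tests.
small_scheme <- function() {
  dirs <- spherical_directions(12, seed = 7)
  acquisition_scheme(c(0, 0, rep(1000, 12), rep(500, 6)),
                     rbind(matrix(0, 2, 3), dirs, dirs[1:6, ]),
                     echo_time = 109)
}

# Direct evaluation of the Benjamini-Hochberg step-up definition:
# adjusted p_(i) = min_{j >= i} ( m * p_(j) / j ), mapped back to input order.
bh_stepup_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m))
    adj[i] <- min(1, min(m * ps[i:m] / (i:m)))
  out <- numeric(m)
  out[o] <- adj
  out
}

# Closed-form OLS slope.
ols_slope_oracle <- function(t, y) {
  sum((t - mean(t)) * (y - mean(y))) / sum((t - mean(t))^2)
}

# Forward compartmental T2 weighting: volume fraction -> signal fraction.
t2_forward_weight <- function(f, te, t2_tissue, t2_free) {
  ef <- exp(-te / t2_free)
  et <- exp(-te / t2_tissue)
  f * ef / (f * ef + (1 - f) * et)
}

# Cohort design used by statistics tests: small, fast, null by default.
null_design <- function(seed, n = c("HC" = 30, "CHR-NP" = 40, "CHR-P" = 10),
                        schedule = c(0, 1), rois = "LTC") {
  cohort_design(n_per_group = n,
                baseline_offsets = c("HC" = 0, "CHR-NP" = 0, "CHR-P" = 0),
                slope = c("HC" = 0, "CHR-NP" = 0, "CHR-P" = 0),
                schedule = schedule, rois = rois, seed = seed)
}
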