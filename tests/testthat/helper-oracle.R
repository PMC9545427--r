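# Independent numerical oracle for the tissue oxygenation problem:
# a finite-volume discretisation of the radial reaction-diffusion equation
#   (1/r) d/dr ( r dP/dr ) = M(P) / K,   P(r_c) = p_cap,   P'(r_t) = 0,
# with spatially varying Michaelis-Menten consumption, solved by Picard
# iteration on M and a Thomas tridiagonal solve. This never touches the
# package's closed-form Krogh solution or its fixed-point coupling.

thomas_solve <- function(lower, diag, upper, rhs) {
  n <- length(diag)
  cp <- numeric(n)
  dp <- numeric(n)
  cp[1] <- upper[1] / diag[1]
  dp[1] <- rhs[1] / diag[1]
  for (i in 2:n) {
    denom <- diag[i] - lower[i] * cp[i - 1]
    cp[i] <- if (i < n) upper[i] / denom else 0
    dp[i] <- (rhs[i] - lower[i] * dp[i - 1]) / denom
  }
  x <- numeric(n)
  x[n] <- dp[n]
  for (i in (n - 1):1) x[i] <- dp[i] - cp[i] * x[i + 1]
  x
}

# Radial profile with spatially varying consumption. Returns PO2 on the full
# grid (including the Dirichlet node at r_c).
oracle_tissue_slice <- function(p_cap, m0, p_crit, geometry, k_diff,
                                n_r = 101, max_iter = 200, tol = 1e-10) {
  r <- seq(geometry$r_c, geometry$r_t, length.out = n_r)
  h <- r[2] - r[1]
  m <- length(r) - 1            # unknowns: nodes 2..n_r
  r_unk <- r[-1]
  rhalf_lo <- r_unk - h / 2     # inner face of each unknown's control volume
  rhalf_hi <- r_unk + h / 2     # outer face (beyond r_t for the last node)

  # system matrix does not depend on the iterate: assemble once.
  # interior nodes: flux difference over the control volume
  # [rhalf_lo, rhalf_hi]; last node: half-volume [r_t - h/2, r_t] with zero
  # outer flux
  a_lo <- rhalf_lo / h
  a_hi <- rhalf_hi / h
  lower <- a_lo
  diagv <- -(a_lo + a_hi)
  upper <- a_hi
  diagv[m] <- -a_lo[m]
  upper[m] <- 0
  vol <- (rhalf_hi^2 - rhalf_lo^2) / 2
  vol[m] <- (r[n_r]^2 - rhalf_lo[m]^2) / 2
  # the Dirichlet node P_1 = p_cap is folded into the first equation's rhs
  dirichlet <- lower[1] * p_cap
  lower[1] <- 0

  po2 <- rep(p_cap, n_r)
  for (iter in seq_len(max_iter)) {
    mm <- m0 * pmax(po2[-1], 0) / (pmax(po2[-1], 0) + p_crit)
    if (p_crit == 0) mm <- ifelse(po2[-1] > 0, m0, 0)
    rhs <- (mm / k_diff) * vol
    rhs[1] <- rhs[1] - dirichlet
    new <- thomas_solve(lower, diagv, upper, rhs)
    delta <- max(abs(new - po2[-1]))
    po2[-1] <- new
    if (delta < tol) break
  }
  pmax(po2, 0)
}

# Volume-weighted (r dr) mean of a radial profile, trapezoidal.
oracle_radial_mean <- function(r, po2) {
  w <- r
  n <- length(r)
  wt <- numeric(n)
  dr <- diff(r)
  wt[1] <- w[1] * dr[1] / 2
  wt[n] <- w[n] * dr[n - 1] / 2
  if (n > 2) wt[2:(n - 1)] <- w[2:(n - 1)] * (dr[-(n - 1)] + dr[-1]) / 2
  sum(wt * po2) / sum(wt)
}

# Mean tissue PO2 over radius and capillary length for a capillary profile,
# solved entirely with the finite-volume oracle.
oracle_field_mean <- function(profile, m0, p_crit, geometry, k_diff,
                              n_r = 101) {
  z <- profile$z_m
  r <- seq(geometry$r_c, geometry$r_t, length.out = n_r)
  means <- vapply(profile$po2_mmhg, function(p_cap) {
    oracle_radial_mean(r, oracle_tissue_slice(p_cap, m0, p_crit, geometry,
                                              k_diff, n_r = n_r))
  }, numeric(1))
  n <- length(z)
  dz <- diff(z)
  wz <- numeric(n)
  wz[1] <- dz[1] / 2
  wz[n] <- dz[n - 1] / 2
  if (n > 2) wz[2:(n - 1)] <- (dz[-(n - 1)] + dz[-1]) / 2
  sum(wz * means) / sum(wz)
}
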