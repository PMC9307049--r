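# Independent oracles used across the suite. These deliberately avoid the
# package's solution paths: the growth oracle integrates the length-density
# ODE along a characteristic with RK4, the uptake oracle is the closed-form
# two-point boundary-value solution, and the distance oracle is an
# all-pairs brute force.

# rho(x, t) by RK4 time stepping of d(rho)/dt = n v - d rho along the
# characteristic through (x, t), with n = (k/v) exp(b x / v) behind the
# front and zero initial condition at t = x / v.
oracle_rho <- function(k, v, b, d, x, t, n_steps = 4000L) {
  if (x >= v * t) return(0)
  n_val <- (k / v) * exp(b * x / v)
  f <- function(rho) n_val * v - d * rho
  t0 <- x / v
  h <- (t - t0) / n_steps
  rho <- 0
  for (i in seq_len(n_steps)) {
    k1 <- f(rho)
    k2 <- f(rho + h / 2 * k1)
    k3 <- f(rho + h / 2 * k2)
    k4 <- f(rho + h * k3)
    rho <- rho + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  rho
}

# Steady state of D c'' = a c on [0, L] with Robin D c'(0) = F c(0) and
# Dirichlet c(L) = c_inf, in the overflow-safe cosh/sinh form about x = L.
oracle_steady_profile <- function(x, D, a, F_max, c_inf, L) {
  mu <- sqrt(a / D)
  th <- tanh(mu * L)
  r <- -(D * mu * th + F_max) / (F_max * th + D * mu)
  u <- L - x
  c_inf * (cosh(mu * u) + r * sinh(mu * u))
}

# All-pairs brute-force Euclidean distance transform (um).
oracle_edt <- function(mask, voxel_size) {
  dims <- dim(mask)
  fg <- which(mask != 0, arr.ind = TRUE)
  idx <- as.matrix(expand.grid(seq_len(dims[1L]), seq_len(dims[2L]),
                               seq_len(dims[3L])))
  d2 <- outer(rowSums(idx^2), rowSums(fg^2), "+") - 2 * idx %*% t(fg)
  array(voxel_size * sqrt(pmax(apply(d2, 1L, min), 0)), dims)
}

# Y-shaped voxel fixture: three 4-voxel arms meeting at one voxel, with
# arm directions chosen so no two arm voxels touch under 26-connectivity.
# Arm lengths by hand: 4 axial steps = 4 vox; 4 face-diagonal steps each
# = 4 * sqrt(2) vox.
make_y_fixture <- function() {
  ctr <- c(10L, 10L, 10L)
  arm1 <- cbind(10L + 1:4, 10L, 10L)            # +x
  arm2 <- cbind(10L - 1:4, 10L + 1:4, 10L)      # (-1, +1, 0) diagonal
  arm3 <- cbind(10L - 1:4, 10L - 1:4, 10L)      # (-1, -1, 0) diagonal
  rbind(ctr, arm1, arm2, arm3)
}

rotation_z <- function(theta) {
  rbind(c(cos(theta), -sin(theta), 0),
        c(sin(theta), cos(theta), 0),
        c(0, 0, 1))
}
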