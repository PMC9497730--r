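# Independent oracles used across the suite. These are deliberately naive
# (enumeration / hand formulas) and share no code with the implementation.

# Exact two-sided Mann-Whitney p by full enumeration of all rank splits.
enum_mw_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  rk <- rank(pooled)
  u_obs <- sum(rk[seq_len(nx)]) - nx * (nx + 1) / 2
  splits <- utils::combn(nx + ny, nx)
  u_all <- apply(splits, 2L, function(ix) sum(rk[ix]) - nx * (nx + 1) / 2)
  nm <- nx * ny
  lo <- min(u_obs, nm - u_obs); hi <- max(u_obs, nm - u_obs)
  min(1, mean(u_all <= lo) + mean(u_all >= hi))
}

# Lattice points with centers inside a disc of given radius.
disc_center_count <- function(radius) {
  r <- ceiling(radius)
  n <- 0L
  for (di in -r:r) for (dj in -r:r)
    if (di^2 + dj^2 <= radius^2) n <- n + 1L
  n
}

# Hand OLS on (x, y).
ols_hand <- function(x, y) {
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  c(a = mean(y) - b * mean(x), b = b)
}

# Finite-bath equilibrium by hand algebra:
# V_b c_b + V_c c_c = V_b c0, c_c = kappa c_b.
equilibrium_hand <- function(c_bath0, V_bath, V_cart, kappa) {
  c_b <- V_bath * c_bath0 / (V_bath + V_cart * kappa)
  c(c_bath = c_b, c_cart = kappa * c_b)
}
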