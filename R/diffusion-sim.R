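#' Acquisition time grid for planar uptake experiments
#'
#' The 17-point grid used by the planar microCT protocol: 2, 5, 10, 15, 20,
#' 30, 45 min, then 1, 1.5, 2, 3, 4, 5, 6, 24, 25, 26 h, returned in hours.
#' The pre-contrast baseline (t = 0) is acquired separately and is not part
#' of this grid.
#'
#' @return Numeric vector of times in hours, strictly increasing.
#' @export
cect_time_grid <- function() {
  c(c(2, 5, 10, 15, 20, 30, 45) / 60,
    1, 1.5, 2, 3, 4, 5, 6, 24, 25, 26)
}

#' Configuration for the 1-D cartilage slab diffusion simulation
#'
#' Describes contrast-agent diffusion from a bath into a cartilage slab of
#' thickness `L`: the bath sits above the articular surface (depth x = 0),
#' the tidemark (x = L) is sealed. Electrostatic partitioning into the
#' tissue is modelled by a dimensionless coefficient `kappa`: at the
#' surface the tissue is in local equilibrium with the bath,
#' `c(0, t) = kappa * c_bath(t)`. With `finite_bath = TRUE` the bath is
#' depleted as iodine enters the cartilage (mass balance with volumes
#' `V_bath`, `V_cart`); otherwise the bath concentration stays at
#' `c_bath0`.
#'
#' Defaults reproduce the bench protocol this simulator emulates: a 0.5 mL
#' bath at 10 mgI/mL over ~0.157 mL of cartilage about 2 mm thick, with
#' `kappa` chosen so the finite-bath equilibrium cartilage concentration is
#' 21.2 mgI/mL (see [kappa_for_equilibrium()]), and an effective
#' diffusivity (0.86 mm^2/h, the order observed for solute transport in
#' articular cartilage) that yields a saturation time in the 1.5-2 h
#' range under this protocol.
#'
#' @param D effective diffusivity, mm^2/h.
#' @param L cartilage thickness, mm.
#' @param c_bath0 initial bath iodine concentration, mgI/mL.
#' @param kappa equilibrium cartilage-to-bath partition coefficient
#'   (dimensionless, > 0; values < 1 are permitted but warned about since a
#'   cationic agent is expected to concentrate in cartilage).
#' @param V_bath bath volume, mL (used when `finite_bath`).
#' @param V_cart cartilage volume, mL (used when `finite_bath`).
#' @param finite_bath logical; deplete the bath by mass balance?
#' @param times output times, hours; strictly increasing, first >= 0.
#' @param nx number of depth nodes (>= 10).
#' @param seed integer seed carried along for downstream generators.
#' @return An object of class `slab_diffusion_config`.
#' @export
slab_diffusion_config <- function(D = 0.86, L = 2, c_bath0 = 10,
                                  kappa = NULL, V_bath = 0.5,
                                  V_cart = 0.157, finite_bath = TRUE,
                                  times = cect_time_grid(), nx = 200,
                                  seed = NULL) {
  check_scalar_pos(D, "D"); check_scalar_pos(L, "L")
  check_scalar_pos(c_bath0, "c_bath0")
  if (is.null(kappa))
    kappa <- kappa_for_equilibrium(21.2, c_bath0 = c_bath0,
                                   V_bath = V_bath, V_cart = V_cart)
  check_scalar_pos(kappa, "kappa")
  if (kappa < 1)
    warning("kappa < 1: contrast agent excluded from cartilage; a cationic ",
            "agent is expected to partition into the tissue (kappa >= 1)",
            call. = FALSE)
  if (finite_bath) {
    check_scalar_pos(V_bath, "V_bath"); check_scalar_pos(V_cart, "V_cart")
  }
  if (length(times) < 1L || any(!is.finite(times)))
    stopf("`times` must be a nonempty finite vector")
  if (times[1] < 0) stopf("`times` must start at a nonnegative time")
  if (any(diff(times) <= 0)) stopf("`times` must be strictly increasing")
  if (!is.numeric(nx) || nx < 10) stopf("`nx` must be >= 10 depth nodes")
  structure(
    list(D = D, L = L, c_bath0 = c_bath0, kappa = kappa, V_bath = V_bath,
         V_cart = V_cart, finite_bath = isTRUE(finite_bath),
         times = as.numeric(times), nx = as.integer(nx), seed = seed),
    class = "slab_diffusion_config"
  )
}

#' Finite-bath equilibrium of the partitioning slab
#'
#' At equilibrium the cartilage is uniformly loaded at
#' `c_cart = kappa * c_bath`, and total iodine mass is conserved:
#' `V_bath * c_bath + V_cart * c_cart = V_bath * c_bath0`. Solving gives
#' `c_bath_eq = V_bath * c_bath0 / (V_bath + V_cart * kappa)`.
#'
#' @inheritParams slab_diffusion_config
#' @return A list with `c_bath_eq`, `c_cart_eq` (mgI/mL) and their `ratio`
#'   (= kappa).
#' @export
equilibrium_partition <- function(c_bath0, V_bath, V_cart, kappa) {
  c_bath_eq <- V_bath * c_bath0 / (V_bath + V_cart * kappa)
  c_cart_eq <- kappa * c_bath_eq
  list(c_bath_eq = c_bath_eq, c_cart_eq = c_cart_eq,
       ratio = c_cart_eq / c_bath_eq)
}

#' @rdname equilibrium_partition
#' @param c_cart_eq target equilibrium cartilage concentration, mgI/mL.
#'   Must be below the exhaustion limit `V_bath * c_bath0 / V_cart`.
#' @return `kappa_for_equilibrium`: the partition coefficient that yields
#'   the requested equilibrium cartilage concentration.
#' @export
kappa_for_equilibrium <- function(c_cart_eq, c_bath0 = 10, V_bath = 0.5,
                                  V_cart = 0.157) {
  denom <- V_bath * c_bath0 - V_cart * c_cart_eq
  if (denom <= 0)
    stopf("requested equilibrium concentration exceeds the available iodine")
  c_cart_eq * V_bath / denom
}

#' Depth-mean uptake of a slab with fixed surface concentration
#'
#' Closed-form series solution for 1-D diffusion into a slab of thickness L
#' with the surface held at a constant concentration and a sealed base: the
#' depth-averaged concentration, as a fraction of its equilibrium value, is
#' \deqn{U(\theta) = 1 - \sum_{n \ge 0} \frac{8}{(2n+1)^2 \pi^2}
#'   \exp\!\big(-(2n+1)^2 \pi^2 \theta / 4\big),}
#' with dimensionless time `theta = D t / L^2`. This is the independent
#' analytic oracle against which the finite-difference solver
#' ([solve_slab_diffusion()]) is validated in the infinite-bath case.
#'
#' @param theta dimensionless time(s), >= 0.
#' @param n_terms number of series terms (>= 1).
#' @return Uptake fraction(s) in `[0, 1]`.
#' @export
#' @examples
#' analytic_mean_uptake(1)  # ~0.9313
analytic_mean_uptake <- function(theta, n_terms = 200L) {
  if (any(theta < 0)) stopf("`theta` must be nonnegative")
  if (n_terms < 1) stopf("`n_terms` must be >= 1")
  n <- seq_len(n_terms) - 1L
  lam <- (2 * n + 1)^2 * pi^2
  out <- vapply(theta, function(th) {
    if (th == 0) return(0)  # exact: the full series sums to 1 at theta = 0
    1 - sum(8 / lam * exp(-lam * th / 4))
  }, numeric(1))
  pmin(pmax(out, 0), 1)
}

# Composite-Simpson quadrature weights for n equally spaced nodes
# (multiples of h; they sum to n - 1). For an odd number of intervals the
# last three are handled with the 3/8 rule.
quad_weights <- function(n) {
  if ((n - 1L) %% 2L == 0L) {
    w <- rep(c(2, 4), length.out = n)
    w[1] <- 1; w[n] <- 1
    w / 3
  } else {
    w <- numeric(n)
    w1 <- rep(c(2, 4), length.out = n - 3L)
    w1[1] <- 1; w1[n - 3L] <- 1
    w[1:(n - 3L)] <- w1 / 3
    w[(n - 3L):n] <- w[(n - 3L):n] + c(1, 3, 3, 1) * 3 / 8
    w
  }
}

# One theta-scheme step of the coupled slab+bath system.
# c_prev: concentrations at interior+base nodes (indices 2..nx of the grid),
# c0_prev: surface node value, cb_prev: bath concentration.
# Returns list(c_new (nodes 2..nx), cb_new).
# w = 1 backward Euler, w = 0.5 Crank-Nicolson.
step_slab <- function(c_prev, c0_prev, cb_prev, dt, h, cfg, w, mass_total) {
  nx <- cfg$nx
  m <- nx - 1L                       # unknown nodes: 2..nx (1-based grid)
  r <- cfg$D * dt / h^2
  # implicit operator (I - w*r*Delta) for nodes 2..nx, ghost at base
  dl <- rep(-w * r, m - 1L)
  dd <- rep(1 + 2 * w * r, m)
  du <- rep(-w * r, m - 1L)
  dl[m - 1L] <- -2 * w * r           # base node: Neumann ghost
  # explicit part (I + (1-w)*r*Delta) c_prev
  ce <- c_prev
  lap <- numeric(m)
  if (m >= 2) {
    lap[1] <- c0_prev - 2 * ce[1] + ce[2]
    if (m >= 3)
      lap[2:(m - 1L)] <- ce[1:(m - 2L)] - 2 * ce[2:(m - 1L)] + ce[3:m]
    lap[m] <- 2 * ce[m - 1L] - 2 * ce[m]
  }
  rhs0 <- ce + (1 - w) * r * lap
  # superposition: c_new = u + cb_new * v, surface node c0_new = kappa*cb_new
  rhs_u <- rhs0
  rhs_v <- numeric(m)
  rhs_v[1] <- w * r * cfg$kappa
  u <- tridiag_solve_cpp(dl, dd, du, rhs_u)
  v <- tridiag_solve_cpp(dl, dd, du, rhs_v)
  if (!cfg$finite_bath) {
    cb_new <- cfg$c_bath0
  } else {
    # cartilage mass via the same Simpson weights used for reporting:
    # Q(c) = h * sum(wq * c_full), c_full = (kappa*cb_new, c_2..c_nx)
    wq <- quad_weights(nx)
    qu <- h * sum(wq[-1] * u)
    qv <- h * (wq[1] * cfg$kappa + sum(wq[-1] * v))
    A <- cfg$V_cart / cfg$L
    cb_new <- (mass_total - A * qu) / (cfg$V_bath + A * qv)
  }
  list(c_new = u + cb_new * v, cb_new = cb_new)
}

#' Simulate contrast-agent diffusion into a cartilage slab
#'
#' Solves Fick's second law, `dc/dt = D d2c/dx2`, on the depth interval
#' `[0, L]` with partition-equilibrium surface boundary
#' `c(0, t) = kappa * c_bath(t)` and a no-flux tidemark at `x = L`.
#' Time stepping is Crank-Nicolson with backward-Euler start-up substeps
#' (Rannacher smoothing of the initial surface-concentration jump), so any
#' ragged acquisition grid can be used without stability constraints. With
#' a finite bath, the bath concentration at each step is obtained from the
#' discrete mass balance, so total iodine
#' `V_bath * c_bath + (V_cart / L) * integral(c dx)` is conserved exactly
#' (to solver round-off).
#'
#' @param config a [slab_diffusion_config()].
#' @param max_step_theta largest substep in dimensionless time
#'   `D dt / L^2`; controls temporal accuracy.
#' @return An object of class `concentration_field`: list with
#'   `depth_grid` (mm), `times` (h), `c` (times x depth matrix, mgI/mL),
#'   `c_bath` (per time, mgI/mL) and `config`.
#' @seealso [analytic_mean_uptake()] for the infinite-bath oracle,
#'   [mean_uptake()], [total_iodine_mass()].
#' @export
solve_slab_diffusion <- function(config, max_step_theta = 1e-3) {
  stopifnot(inherits(config, "slab_diffusion_config"))
  cfg <- config
  nx <- cfg$nx
  h <- cfg$L / (nx - 1L)
  x <- seq(0, cfg$L, length.out = nx)
  times <- cfg$times
  out_times <- if (times[1] > 0) c(0, times) else times
  keep <- if (times[1] > 0) -1L else TRUE

  cmat <- matrix(0, nrow = length(out_times), ncol = nx)
  cb <- numeric(length(out_times))
  cb[1] <- cfg$c_bath0

  # state at t = 0: empty cartilage
  c_int <- numeric(nx - 1L)   # nodes 2..nx
  c0 <- 0                      # surface node value *as reported* at t = 0
  cb_cur <- cfg$c_bath0
  mass_total <- cfg$V_bath * cfg$c_bath0   # cartilage starts empty
  dt_max <- max_step_theta * cfg$L^2 / cfg$D
  first <- TRUE

  for (ti in seq_along(out_times)[-1]) {
    t0 <- out_times[ti - 1L]; t1 <- out_times[ti]
    n_sub <- max(2L, ceiling((t1 - t0) / dt_max))
    dt <- (t1 - t0) / n_sub
    for (s in seq_len(n_sub)) {
      if (first) {
        # Rannacher start-up: four backward-Euler quarter-steps
        for (q in 1:4) {
          st <- step_slab(c_int, cfg$kappa * cb_cur, cb_cur, dt / 4, h, cfg,
                          w = 1, mass_total = mass_total)
          c_int <- st$c_new; cb_cur <- st$cb_new
        }
        first <- FALSE
      } else {
        st <- step_slab(c_int, cfg$kappa * cb_cur, cb_cur, dt, h, cfg,
                        w = 0.5, mass_total = mass_total)
        c_int <- st$c_new; cb_cur <- st$cb_new
      }
    }
    cmat[ti, ] <- c(cfg$kappa * cb_cur, c_int)
    cb[ti] <- cb_cur
  }
  cmat[cmat < 0 & cmat > -1e-12] <- 0

  structure(
    list(depth_grid = x,
         times = out_times[keep],
         c = cmat[keep, , drop = FALSE],
         c_bath = cb[keep],
         config = cfg),
    class = "concentration_field"
  )
}

#' Depth-mean concentration and total iodine mass of a simulated field
#'
#' `mean_uptake()` returns the trapezoidal depth average of `c(x, t)` at
#' each output time (mgI/mL); `total_iodine_mass()` returns
#' `V_bath * c_bath(t) + (V_cart / L) * integral(c dx)` (mgI), the quantity
#' conserved by finite-bath simulations. At t = 0 the cartilage is empty,
#' so the total equals `V_bath * c_bath0`.
#'
#' @param field a `concentration_field` from [solve_slab_diffusion()].
#' @return Numeric vector, one value per output time.
#' @export
mean_uptake <- function(field) {
  stopifnot(inherits(field, "concentration_field"))
  nx <- ncol(field$c)
  as.numeric(field$c %*% quad_weights(nx)) / (nx - 1L)
}

#' @rdname mean_uptake
#' @export
total_iodine_mass <- function(field) {
  stopifnot(inherits(field, "concentration_field"))
  cfg <- field$config
  cart_mass <- (cfg$V_cart / cfg$L) * mean_uptake(field) * cfg$L
  bath_mass <- cfg$V_bath * field$c_bath
  # at the reported t = 0 state the slab is empty by definition
  if (length(field$times) && field$times[1] == 0)
    cart_mass[1] <- 0
  bath_mass + cart_mass
}

#' @export
print.concentration_field <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "Slab diffusion field: %d times x %d depth nodes (L = %g mm, D = %g mm^2/h)\n",
    length(x$times), ncol(x$c), cfg$L, cfg$D))
  cat(sprintf("  bath: %s, c_bath0 = %g mgI/mL, kappa = %.4g\n",
              if (cfg$finite_bath) "finite" else "infinite",
              cfg$c_bath0, cfg$kappa))
  invisible(x)
}

#' @export
print.slab_diffusion_config <- function(x, ...) {
  cat(sprintf("Slab diffusion config: D = %g mm^2/h, L = %g mm, kappa = %.4g, %s bath\n",
              x$D, x$L, x$kappa, if (x$finite_bath) "finite" else "infinite"))
  cat(sprintf("  c_bath0 = %g mgI/mL, %d output times, nx = %d\n",
              x$c_bath0, length(x$times), x$nx))
  invisible(x)
}
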