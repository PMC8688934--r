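# Stiff time integration and steady-state location.
#
# The governing equations are stiff (fast osmotic volume relaxation and blood
# washout vs. slow ion redistribution) and the raw state mixes mol-scale
# amounts with mM-scale concentrations, so both solvers work in scaled
# variables z = y / s with s a per-component magnitude. The integrator is an
# L-stable two-stage Rosenbrock method (ROS2, gamma = 1 + 1/sqrt(2)) with a
# finite-difference Jacobian, embedded first-order error estimate and
# adaptive step control. Steady states are found by pseudo-transient
# continuation followed by a damped Newton polish on the right-hand side.
# Everything is deterministic: no randomness anywhere in the pipeline.

.ROS2_GAMMA <- 1 + 1 / sqrt(2)

# Per-component magnitude scale from state names: cell amounts live near
# 1e-16 mol, volumes near 1e-15 m^3, blood concentrations near 1e2 mM.
solver_scales <- function(y) {
  floor_of <- function(nm) {
    if (grepl("_vol$", nm)) return(1e-16)
    if (nm == "cell_h") return(1e-21)
    if (nm == "blood_h") return(1e-8)
    if (grepl("^blood_", nm)) return(1e-1)     # concentrations (mM)
    1e-18                                      # amounts (mol)
  }
  fl <- vapply(names(y), floor_of, numeric(1))
  pmax(abs(y), fl)
}

# Finite-difference Jacobian of g at z (scaled space), g0 = g(z).
fd_jacobian_scaled <- function(g, z, g0) {
  n <- length(z)
  J <- matrix(0, n, n)
  for (j in seq_len(n)) {
    h <- 1e-7 * max(abs(z[j]), 1e-3)
    zp <- z; zp[j] <- zp[j] + h
    gj <- g(zp)
    if (is.null(gj)) {            # retreat across a domain boundary
      zp[j] <- z[j] - h
      gj <- g(zp)
      if (is.null(gj))
        stop("fd_jacobian: state at a domain boundary", call. = FALSE)
      J[, j] <- (g0 - gj) / h
    } else {
      J[, j] <- (gj - g0) / h
    }
  }
  J
}

# Advance dy/dt = f(y) from t0 to t1. f returns the derivative vector or NULL
# if y is outside the physical domain (negative volume/concentration), which
# triggers step rejection. Records (t, y) at every accepted step.
ros2_integrate <- function(f, y0, t0, t1, rtol = 1e-5, scales = NULL,
                           h0 = NULL, max_steps = 100000L) {
  stopifnot(t1 >= t0)
  nm <- names(y0)
  if (is.null(scales)) scales <- solver_scales(y0)
  s <- scales
  g <- function(z) {
    fy <- f(stats::setNames(z * s, nm))
    if (is.null(fy)) NULL else fy / s
  }
  z <- y0 / s
  t <- t0
  atol <- 1e-4 * rtol                 # scaled space: components are O(1)
  h <- if (is.null(h0)) min(1e-2, (t1 - t0) / 10) else h0
  h_min <- max(1e-10, (t1 - t0) * 1e-12)
  ts <- t0
  zs <- list(z)
  g0 <- g(z)
  if (is.null(g0)) stop("ros2_integrate: initial state infeasible", call. = FALSE)
  n <- length(z)
  steps <- 0L
  J <- NULL
  J_age <- 0L
  Wq <- NULL
  h_fac <- NA_real_
  while (t < t1) {
    steps <- steps + 1L
    if (steps > max_steps)
      stop(sprintf("ros2_integrate: step budget exhausted at t = %.6g s", t),
           call. = FALSE)
    h <- min(h, t1 - t)
    if (h < h_min)
      stop(sprintf("ros2_integrate: step size underflow at t = %.6g s", t),
           call. = FALSE)
    # ROS2 is a W-method: a lagged Jacobian costs accuracy only through the
    # error estimate, so J is refreshed every few accepted steps.
    if (is.null(J) || J_age > 10L) {
      J <- fd_jacobian_scaled(g, z, g0)
      J_age <- 0L
      Wq <- NULL
    }
    if (is.null(Wq) || abs(h - h_fac) > 1e-12 * h) {
      W <- diag(n) - .ROS2_GAMMA * h * J
      Wq <- tryCatch(qr(W, LAPACK = TRUE), error = function(e) NULL)
      h_fac <- h
      if (is.null(Wq)) { h <- h / 4; J <- NULL; next }
    }
    k1 <- tryCatch(as.numeric(solve.qr(Wq, g0)), error = function(e) NULL)
    if (is.null(k1) || any(!is.finite(k1))) { h <- h / 4; J <- NULL; next }
    g1 <- g(z + h * k1)
    if (is.null(g1)) { h <- h / 4; next }
    k2 <- as.numeric(solve.qr(Wq, g1 - 2 * k1))
    znew <- z + (h / 2) * (3 * k1 + k2)
    # W-filtered embedded estimate: damps the spurious contribution of fast
    # (already L-stably resolved) modes while staying O(h^2) for smooth ones.
    est <- (h / 2) * as.numeric(solve.qr(Wq, k1 + k2))
    err <- sqrt(mean((est / (atol + rtol * pmax(abs(z), abs(znew))))^2))
    if (!is.finite(err)) { h <- h / 4; next }
    if (err <= 1) {
      gnew <- g(znew)
      if (is.null(gnew)) { h <- h / 4; next }
      t <- t + h
      z <- znew
      g0 <- gnew
      J_age <- J_age + 1L
      ts <- c(ts, t)
      zs[[length(zs) + 1L]] <- z
      h <- h * min(5, max(0.3, 0.9 * err^-0.5))
    } else {
      h <- h * max(0.1, 0.9 * err^-0.5)
      J <- NULL            # refresh after a rejection
    }
  }
  Y <- do.call(rbind, zs)
  Y <- sweep(Y, 2, s, `*`)
  colnames(Y) <- nm
  list(t = ts, y = Y, h_last = h, steps = steps)
}

# Damped Newton on f(y) = 0 in scaled variables. Returns list(y, residual,
# converged, iterations); residual is max |dy/dt| / scale in 1/s.
newton_steady <- function(f, y0, scales = NULL, tol = 1e-11, max_iter = 60L) {
  nm <- names(y0)
  if (is.null(scales)) scales <- solver_scales(y0)
  s <- scales
  g <- function(z) {
    fy <- tryCatch(f(stats::setNames(z * s, nm)), error = function(e) NULL)
    if (is.null(fy)) NULL else fy / s
  }
  z <- y0 / s
  g0 <- g(z)
  if (is.null(g0)) return(list(y = y0, converged = FALSE, residual = Inf,
                               iterations = 0L))
  rnorm <- function(gv) max(abs(gv))          # 1/s in scaled space
  r <- rnorm(g0)
  it <- 0L
  for (it in seq_len(max_iter)) {
    if (r < tol) break
    J <- tryCatch(fd_jacobian_scaled(g, z, g0), error = function(e) NULL)
    if (is.null(J)) break
    step <- tryCatch(as.numeric(solve(J, -g0)), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) break
    lambda <- 1
    ok <- FALSE
    while (lambda >= 1 / 1024) {
      zn <- z + lambda * step
      gn <- g(zn)
      if (!is.null(gn) && all(is.finite(gn)) && rnorm(gn) < r) {
        z <- zn; g0 <- gn; r <- rnorm(g0); ok <- TRUE; break
      }
      lambda <- lambda / 2
    }
    if (!ok) break
  }
  list(y = stats::setNames(z * s, nm), converged = (r < tol), residual = r,
       iterations = it)
}
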