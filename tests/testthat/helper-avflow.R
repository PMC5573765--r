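# shared fixtures and independent oracles

# a small generator config keeping synthetic fields desk-sized
small_cfg <- function(seed = 1L, rank = 3L, ...) {
  args <- list(seed = seed, rank = rank,
               mesh_n_theta = 12L, mesh_n_axial = 16L,
               window_sampling = list(WT = c(n = 200, dt = 0.005),
                                      WS = c(n = 300, dt = 1e-3),
                                      WD = c(n = 300, dt = 1e-3)))
  do.call(generator_config, utils::modifyList(args, list(...)))
}

# two coplanar unit-ish triangles of equal area, labelled per `region`
two_face_mesh <- function(region = c("artery", "artery")) {
  verts <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0))
  faces <- rbind(c(1L, 2L, 3L), c(2L, 4L, 3L))
  surface_mesh(verts, faces, region, rings = list(both = 1:2))
}

# complex tridiagonal Thomas solve for the oscillatory pipe-flow oracle
thomas_solve <- function(lower, diag, upper, rhs) {
  n <- length(diag)
  cp <- complex(length.out = n); dp <- complex(length.out = n)
  cp[1L] <- upper[1L] / diag[1L]
  dp[1L] <- rhs[1L] / diag[1L]
  for (i in 2:n) {
    m <- diag[i] - lower[i - 1L] * cp[i - 1L]
    cp[i] <- if (i < n) upper[i] / m else 0
    dp[i] <- (rhs[i] - lower[i - 1L] * dp[i - 1L]) / m
  }
  x <- complex(length.out = n)
  x[n] <- dp[n]
  for (i in (n - 1L):1L) x[i] <- dp[i] - cp[i] * x[i + 1L]
  x
}

# independent finite-difference solve of the per-harmonic oscillatory
# pipe-flow equation: i*omega*rho*u = G + mu*(u'' + u'/r), u(R) = 0,
# symmetry at r = 0. Returns u on the grid and the flow integral.
womersley_fd_oracle <- function(R, omega, fluid, G = 1 + 0i, n = 1600L) {
  h <- R / n
  r <- h * (0:n)
  mu <- fluid$viscosity; rho <- fluid$density
  # interior unknowns i = 0..n-1 (u_n = 0 at the wall)
  lower <- complex(length.out = n - 1L)
  diagv <- complex(length.out = n)
  upper <- complex(length.out = n - 1L)
  rhs <- rep(-G / mu, n)
  k2 <- 1i * omega * rho / mu
  # r = 0: symmetric Laplacian 4*(u1 - u0)/h^2
  diagv[1L] <- -4 / h^2 - k2
  upper[1L] <- 4 / h^2
  for (i in 1:(n - 1L)) {
    ri <- r[i + 1L]
    lower[i] <- 1 / h^2 - 1 / (2 * h * ri)
    diagv[i + 1L] <- -2 / h^2 - k2
    if (i < n - 1L) upper[i + 1L] <- 1 / h^2 + 1 / (2 * h * ri)
  }
  u <- thomas_solve(lower, diagv, upper, rhs)
  u_full <- c(u, 0 + 0i)
  wts <- c(1, rep(c(4, 2), length.out = n - 1L), 1)  # Simpson, n even
  flow <- sum(wts * 2 * pi * r * u_full) * h / 3
  list(r = r, u = u_full, flow = flow)
}

wk_free_params <- function(wk) {
  c(wk$uao$R1, wk$uao$R2, wk$uao$C, wk$vo$R1, wk$vo$R2, wk$vo$C)
}
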