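test_that("operator is conservative and annihilates constants", {
  mesh <- mini_mesh("s50")
  op <- assemble_operator(mesh, diffusivity_map(balloon = 1e-8,
                                                plaque = 1e-12, wall = 1e-12))
  ones <- rep(1, mesh$n)
  expect_lt(max(abs(as.numeric(op$K %*% ones))),
            1e-10 * max(abs(op$K@x)))
  # uniform field is a steady state of the implicit step
  phi <- advance(ones * 3.5, op, dt = 1e4)
  expect_equal(phi, ones * 3.5, tolerance = 1e-12)
})

test_that("negative diffusivity is rejected", {
  expect_error(diffusivity_map(wall = -1e-12), class = "dcb_validation_error")
  expect_error(diffusivity_map(interface = list("balloon:wall" = -1)),
               class = "dcb_validation_error")
})

test_that("closed-system mass is conserved to 1e-10 per step", {
  mesh <- mini_mesh("s30")
  op <- assemble_operator(mesh, diffusivity_map(balloon = 1e-8,
                                                plaque = 2e-12, wall = 1e-12))
  phi <- numeric(mesh$n)
  phi[mesh$cell_region == 1L] <- 75.32
  m0 <- total_mass(phi, mesh)
  for (dt in c(1, 60, 3600)) {
    phi2 <- advance(phi, op, dt, nsteps = 5L)
    expect_lt(abs(total_mass(phi2, mesh) / m0 - 1), 1e-10)
    expect_true(all(phi2 >= 0))
  }
})

test_that("semi-discrete operator has non-positive eigenvalues", {
  mesh <- radial_1d_mesh(n = 30)
  op <- assemble_operator(mesh, diffusivity_map(wall = 1e-12))
  A <- diag(1 / op$V) %*% as.matrix(op$K)   # generator is -A
  ev <- eigen(A, only.values = TRUE)$values
  expect_true(all(Re(ev) > -1e-8 * max(Re(ev))))
  expect_true(all(abs(Im(ev)) < 1e-12))
})

test_that("backward Euler matches the dense matrix-exponential oracle", {
  mesh <- radial_1d_mesh(n = 40, h = 5e-5)
  op <- assemble_operator(mesh, diffusivity_map(wall = 1e-12))
  K <- as.matrix(op$K)
  V <- op$V
  # symmetrise: A_s = V^{-1/2} K V^{-1/2} shares eigenvalues with V^{-1} K
  S <- diag(1 / sqrt(V)) %*% K %*% diag(1 / sqrt(V))
  eg <- eigen((S + t(S)) / 2, symmetric = TRUE)
  expm_apply <- function(phi0, t) {
    y <- eg$vectors %*% (exp(-eg$values * t) * crossprod(eg$vectors, sqrt(V) * phi0))
    as.numeric(y / sqrt(V))
  }
  set.seed(7)
  phi0 <- runif(mesh$n)
  lam_max <- max(eg$values)
  dt <- 0.01 / lam_max          # keeps the O(dt) splitting error below 0.1%
  phi_be <- advance(phi0, op, dt, nsteps = 10L)
  phi_ex <- expm_apply(phi0, 10 * dt)
  expect_lt(sqrt(sum((phi_be - phi_ex)^2) / sum(phi_ex^2)), 1e-3)
  # the oracle must actually have moved the field
  expect_gt(max(abs(phi_ex - phi0)) / max(phi0), 0.01)
})

test_that("two-slab contact problem matches the erfc similarity solution", {
  h <- 1e-6
  nb <- 100; nt <- 100
  mesh <- slab_mesh(nb, nt, h)
  D <- 1e-12
  op <- assemble_operator(mesh, diffusivity_map(balloon = D, wall = D))
  c0 <- 75.32
  phi <- c(rep(c0, nb), rep(0, nt))
  t_end <- 25
  phi <- advance(phi, op, dt = 0.25, nsteps = 100L)
  # semi-infinite two-media solution with equal diffusivities:
  # tissue side phi(x, t) = c0/2 * erfc(x / (2 sqrt(D t))), x from interface
  x <- (seq_len(nt) - 0.5) * h
  exact <- c0 / 2 * (2 * stats::pnorm(-x / (2 * sqrt(D * t_end)) * sqrt(2)))
  near <- x <= 4 * sqrt(D * t_end)
  expect_lt(max(abs(phi[nb + which(near)] - exact[near])) / c0, 0.02)
})

test_that("implicit stepping is stable across 6 orders of dt", {
  mesh <- mini_mesh("exvivo")
  op <- assemble_operator(mesh, diffusivity_map(balloon = 1e-8, wall = 1e-12))
  phi0 <- numeric(mesh$n)
  phi0[mesh$cell_region == 1L] <- 75.32
  m0 <- total_mass(phi0, mesh)
  for (dt in 10^(0:6)) {
    phi <- advance(phi0, op, dt, nsteps = 3L)
    expect_true(all(is.finite(phi)))
    expect_true(all(phi >= 0))
    expect_lte(max(phi), 75.32 * (1 + 1e-9))
    expect_lt(abs(total_mass(phi, mesh) / m0 - 1), 1e-9)
  }
})

test_that("absorbed mass is grid-converged in the resolved regime", {
  # gamma and horizon chosen so the penetration depth spans several cells
  geom <- build_geometry(0, mini_dims())
  p <- transport_params(gamma_transfer = 1e-10)
  a1 <- run_transfer(mesh_geometry(geom, 5e-5), p, 900, dt = 5)$absorbed_percent
  a2 <- run_transfer(mesh_geometry(geom, 2.5e-5), p, 900, dt = 5)$absorbed_percent
  expect_lt(abs(a2 / a1 - 1), 0.01)
})

test_that("region_mass sums what it should and validates labels", {
  mesh <- mini_mesh("s50")
  phi <- numeric(mesh$n)
  expect_equal(region_mass(phi, mesh, "wall"), 0)
  phi[mesh$cell_region == 1L] <- 75.32
  vb <- sum(mesh$vol[mesh$cell_region == 1L])
  expect_equal(region_mass(phi, mesh, "balloon"), 75.32 * vb)
  phi <- runif(mesh$n)
  expect_equal(region_mass(phi, mesh, c("balloon", "plaque", "wall")),
               region_mass(phi, mesh, "balloon") +
               region_mass(phi, mesh, "plaque") +
               region_mass(phi, mesh, "wall"))
  expect_error(region_mass(phi, mesh, "lumen"), class = "dcb_validation_error")
})
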