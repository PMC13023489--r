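test_that("degenerate transfers absorb nothing", {
  mesh <- mini_mesh("exvivo")
  p <- transport_params()
  expect_equal(run_transfer(mesh, p, 0)$absorbed_percent, 0)
  sealed <- run_transfer(mesh, transport_params(gamma_transfer = 1e-20), 60)
  expect_lt(sealed$absorbed_percent, 1e-4)
})

test_that("transfer validates its inputs", {
  mesh <- mini_mesh("exvivo")
  p <- transport_params()
  expect_error(run_transfer(mesh, p, -5), class = "dcb_domain_error")
  # a mesh without a balloon region cannot host a transfer
  bare <- dcbsim:::drop_balloon(mesh)$mesh
  expect_error(run_transfer(bare, p, 60), class = "dcb_validation_error")
  expect_error(transport_params(c_effective = 100, c_toxic = 85.4),
               class = "dcb_validation_error")
})

test_that("absorbed_percent is the tissue share of the coating load", {
  mesh <- mini_mesh("exvivo")
  phi <- numeric(mesh$n)
  expect_equal(absorbed_percent(phi, mesh, 1e-9), 0)
  wall <- mesh$cell_region == 3L
  phi[wall] <- 1
  m_wall <- sum(mesh$vol[wall])
  expect_equal(absorbed_percent(phi, mesh, m_wall), 100)
  expect_equal(absorbed_percent(phi, mesh, m_wall / 0.0817), 8.17)
  expect_error(absorbed_percent(phi, mesh, 0), class = "dcb_domain_error")
})

test_that("transfer is a closed system with a consistent ledger", {
  mesh <- mini_mesh("s50")
  res <- run_transfer(mesh, transport_params(), 30)
  led <- res$ledger
  totals <- led$balloon_kg + led$plaque_kg + led$wall_kg
  expect_true(all(abs(totals / res$initial_balloon_mass - 1) < 1e-10))
  expect_true(all(res$field >= 0))
  expect_true(res$absorbed_percent > 0 && res$absorbed_percent < 100)
})

test_that("absorption increases strictly with dilation time and with gamma", {
  mesh <- mini_mesh("exvivo")
  p <- transport_params()
  res <- run_transfer(mesh, p, 120, record_times = c(15, 30, 60, 120))
  expect_true(all(diff(res$recorded$absorbed_percent) > 0))
  gams <- c(5e-13, 1e-12, 2e-12, 4e-12)
  abs_g <- vapply(gams, function(g) {
    run_transfer(mesh, transport_params(gamma_transfer = g), 60)$absorbed_percent
  }, numeric(1))
  expect_true(all(diff(abs_g) > 0))
})

test_that("higher stenosis transfers less drug into the tissue", {
  # full-length fixture: on very short test vessels the steeper plaque
  # shoulder's slant area can mask the contact-area reduction
  p <- transport_params()
  stats <- vapply(c("s10", "s30", "s50"), function(preset) {
    mesh <- mesh_geometry(make_fixture(preset), 5e-5)
    res <- run_transfer(mesh, p, 30)
    s <- mesh$surfaces
    c(tissue = res$initial_balloon_mass * res$absorbed_percent / 100,
      area = sum(s$plaque_balloon$area) + sum(s$vessel_balloon$area))
  }, numeric(2))
  # contact-area ordering: the balloon shrinks onto the narrowed lumen
  expect_true(all(diff(stats["area", ]) < 0))
  expect_true(all(diff(stats["tissue", ]) < 0))
})

test_that("reference-mesh transfer reproduces the published operating point", {
  # plain tube at the 0.01 mm reference spacing, transfer coefficient
  # 1.28e-12 m^2/s, 60 s dilation: about 8.3% of the coating load absorbed
  dims <- vessel_dims(vessel_length = 2e-3, balloon_length = 1.5e-3,
                      plaque_half_length = 0.5e-3)
  mesh <- mesh_geometry(build_geometry(0, dims), 1e-5)
  res <- run_transfer(mesh, transport_params(gamma_transfer = 1.28e-12), 60)
  expect_lt(abs(res$absorbed_percent - 8.33), 2)
})
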