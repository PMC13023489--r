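test_that("stenosis geometry honours the diameter-reduction convention", {
  geom <- build_geometry(0.5, mini_dims())
  zc <- geom$dims$vessel_length / 2
  # throat: plaque inner radius is (1 - s) * lumen radius
  expect_equal(geom$r_plaque(zc), 0.5 * geom$dims$lumen_radius)
  # shoulders taper to zero thickness at the plaque ends and beyond
  Lp <- geom$dims$plaque_half_length
  expect_equal(geom$r_plaque(zc + Lp), geom$dims$lumen_radius)
  expect_equal(geom$r_plaque(0), geom$dims$lumen_radius)
  # monotone taper between shoulder and throat
  zs <- seq(zc - Lp, zc, length.out = 50)
  expect_true(all(diff(geom$r_plaque(zs)) <= 1e-12))

  # degenerate case: no plaque at all
  tube <- build_geometry(0, mini_dims())
  mesh <- mesh_geometry(tube, 5e-5)
  expect_equal(sum(mesh$cell_region == 2L), 0L)
})

test_that("invalid geometry inputs are rejected", {
  expect_error(build_geometry(1.2), class = "dcb_domain_error")
  expect_error(build_geometry(-0.1), class = "dcb_domain_error")
  expect_error(vessel_dims(lumen_radius = -1), class = "dcb_validation_error")
  expect_error(vessel_dims(balloon_length = 30e-3), class = "dcb_validation_error")
  expect_error(vessel_dims(plaque_half_length = 15e-3), class = "dcb_validation_error")
})

test_that("meshing refuses spacing that cannot resolve a region", {
  geom <- build_geometry(0, mini_dims())   # balloon shell 0.10 mm
  err <- expect_error(mesh_geometry(geom, 2e-4), class = "dcb_resolution_error")
  expect_match(conditionMessage(err), "balloon")
})

test_that("annular region volumes are exact and labels partition active cells", {
  d <- mini_dims()
  mesh <- mesh_geometry(build_geometry(0, d), 5e-5)
  vols <- region_volumes(mesh)
  R <- d$lumen_radius
  wall_exact <- pi * ((R + d$wall_thickness)^2 - R^2) * d$vessel_length
  bal_exact <- pi * (R^2 - (R - d$balloon_thickness)^2) * d$balloon_length
  expect_lt(abs(vols[["wall"]] / wall_exact - 1), 0.01)
  expect_lt(abs(vols[["balloon"]] / bal_exact - 1), 0.01)
  # every active cell carries exactly one known label
  expect_true(all(mesh$cell_region %in% 1:3))
  expect_equal(sum(region_volumes(mesh)), sum(mesh$vol))
})

test_that("region volumes are stable under 2x mesh refinement", {
  geom <- build_geometry(0.5, mini_dims())
  v1 <- region_volumes(mesh_geometry(geom, 5e-5))
  v2 <- region_volumes(mesh_geometry(geom, 2.5e-5))
  expect_true(all(abs(v2 / v1 - 1) < 0.005))
})

test_that("interface surfaces are registered with consistent areas", {
  mesh <- mesh_geometry(build_geometry(0.5, mini_dims()), 5e-5)
  s <- mesh$surfaces
  # the balloon contacts the plaque over a larger area than the wall
  expect_gt(sum(s$plaque_balloon$area), sum(s$vessel_balloon$area))
  expect_gt(nrow(s$vessel_plaque), 0)
  # interface orientation: 'a' side carries the first-named region
  expect_true(all(mesh$cell_region[s$plaque_balloon$a] == 1L))
  expect_true(all(mesh$cell_region[s$plaque_balloon$b] == 2L))
  # outer surface area matches the cylinder
  d <- mini_dims()
  expect_equal(sum(s$vessel$area),
               2 * pi * (d$lumen_radius + d$wall_thickness) * d$vessel_length,
               tolerance = 1e-10)
})
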