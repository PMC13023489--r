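test_that("target mass trajectory composes the daily loss factors", {
  sch <- loss_schedule()   # 70% first day, 30%/day thereafter
  m0 <- 2.5e-9
  expect_equal(target_mass_trajectory(m0, sch, 0), m0)
  expect_equal(target_mass_trajectory(m0, sch, 86400), 0.30 * m0)
  expect_equal(target_mass_trajectory(m0, sch, 2 * 86400), 0.21 * m0)
  expect_equal(target_mass_trajectory(m0, sch, 7 * 86400), 0.30 * 0.70^6 * m0)
  # continuous, strictly decreasing intra-day interpolation
  ts <- seq(0, 3 * 86400, by = 3600)
  mm <- target_mass_trajectory(m0, sch, ts)
  expect_true(all(diff(mm) < 0))
  expect_error(target_mass_trajectory(m0, sch, -1), class = "dcb_domain_error")
  expect_error(loss_schedule(first_day_loss_fraction = 1), class = "dcb_validation_error")
})

mini_retention <- local({
  cache <- list()
  function(preset = "s50", t_dil = 60, horizon_days = 7) {
    key <- paste(preset, t_dil, horizon_days)
    if (is.null(cache[[key]])) {
      p <- transport_params()
      tr <- run_transfer(mini_mesh(preset), p, t_dil)
      cache[[key]] <<- run_retention(tr, p, horizon = horizon_days * 86400)
    }
    cache[[key]]
  }
})

test_that("mass ledger tracks 70% day-one and 30%/day losses", {
  ret <- mini_retention()
  led <- attr(ret, "ledger")
  m0 <- attr(ret, "m0_kg")
  m_at <- function(d) led$mass_kg[abs(led$time_s - d * 86400) < 1]
  expect_lt(abs(100 * (m0 - m_at(1)) / m0 - 70), 0.5 * 70 / 100)
  for (d in 1:6) {
    loss_pct <- 100 * (m_at(d) - m_at(d + 1)) / m_at(d)
    expect_lt(abs(loss_pct - 30), 0.5 * 30 / 100)
  }
})

test_that("removed plus remaining mass closes the ledger", {
  ret <- mini_retention()
  led <- attr(ret, "ledger")
  m0 <- attr(ret, "m0_kg")
  expect_true(all(abs((led$mass_kg + led$removed_kg) / m0 - 1) < 1e-8))
  expect_true(all(diff(ret$mass_ug) < 0))
  expect_true(all(attr(ret, "final_field") >= 0))
})

test_that("a zero-loss schedule leaves the closed system mass invariant", {
  p <- transport_params()
  tr <- run_transfer(mini_mesh("s50"), p, 30)
  ret <- run_retention(tr, p, schedule = loss_schedule(0, 0), horizon = 86400)
  led <- attr(ret, "ledger")
  expect_true(all(abs(led$mass_kg / led$mass_kg[1] - 1) < 1e-10))
  expect_true(all(led$removed_kg == 0))
})

test_that("mean concentration falls fastest in the first 24 hours", {
  ret <- mini_retention()
  daily <- ret[ret$time_s %in% (86400 * (0:7)), ]
  drops <- -diff(daily$mean_ug_per_g)
  expect_true(all(drops[1] > drops[-1]))
})

test_that("spatial heterogeneity decreases during the redistribution phase", {
  ret <- mini_retention()
  cv <- ret$cv[ret$time_s %in% (86400 * (0:2))]
  expect_true(all(diff(cv) < 0))
})

test_that("longer dilation dominates the concentration curve pointwise", {
  r20 <- mini_retention("s50", 20)
  r60 <- mini_retention("s50", 60)
  expect_true(all(r60$mean_ug_per_g > r20$mean_ug_per_g))
})

test_that("an extreme first-day schedule is still enforced exactly", {
  p <- transport_params()
  tr <- run_transfer(mini_mesh("s50"), p, 30)
  ret <- run_retention(tr, p, schedule = loss_schedule(0.999, 0.5),
                       horizon = 2 * 86400)
  led <- attr(ret, "ledger")
  m0 <- attr(ret, "m0_kg")
  m24 <- led$mass_kg[abs(led$time_s - 86400) < 1]
  expect_equal(m24 / m0, 0.001, tolerance = 1e-6)
  expect_true(all(attr(ret, "final_field") >= 0))
})

test_that("retention validates step and checkpoint compatibility", {
  p <- transport_params()
  tr <- run_transfer(mini_mesh("s50"), p, 10)
  expect_error(run_retention(tr, p, horizon = 1000, dt = 600),
               class = "dcb_validation_error")
  expect_error(run_retention(tr, p, horizon = 86400, checkpoints = c(500)),
               class = "dcb_validation_error")
})
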