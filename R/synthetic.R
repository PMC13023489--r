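# Synthetic fixtures: preset geometries and noisy "experimental" absorption
# measurements generated from the forward model, so the calibration and the
# full pipeline are testable without external data.

FIXTURE_PRESETS <- c(exvivo = 0, s10 = 0.10, s30 = 0.30, s50 = 0.50)

#' Preset fixture geometries
#'
#' `"exvivo"` is the plain-tube test-vessel configuration (no plaque);
#' `"s10"`, `"s30"`, `"s50"` carry an annular plaque with 10/30/50% diameter
#' stenosis at the throat.
#'
#' @param preset One of `"exvivo"`, `"s10"`, `"s30"`, `"s50"`.
#' @param dims A [vessel_dims()] object (defaults to the documented fixture
#'   dimensions).
#' @return A [build_geometry()] result.
#' @export
make_fixture <- function(preset, dims = vessel_dims()) {
  if (!is.character(preset) || length(preset) != 1L ||
      !preset %in% names(FIXTURE_PRESETS)) {
    dcb_abort(sprintf("unknown preset '%s'; expected one of %s",
                      as.character(preset)[1],
                      paste(names(FIXTURE_PRESETS), collapse = ", ")),
              "dcb_validation_error")
  }
  build_geometry(FIXTURE_PRESETS[[preset]], dims)
}

#' Measurement noise model
#'
#' Multiplicative lognormal noise (absorption percentages are positive and
#' assay error is plausibly proportional) with a given coefficient of
#' variation and seed. The lognormal is mean-one, so noisy measurements are
#' unbiased.
#'
#' @param cv Coefficient of variation, `>= 0`.
#' @param seed Integer RNG seed.
#' @return An object of class `measurement_noise`.
#' @export
measurement_noise <- function(cv = 0.02, seed = 1L) {
  if (!is.numeric(cv) || length(cv) != 1L || !is.finite(cv) || cv < 0) {
    dcb_abort("'cv' must be >= 0", "dcb_validation_error")
  }
  structure(list(cv = cv, seed = as.integer(seed)), class = "measurement_noise")
}

#' Generate synthetic absorption measurements
#'
#' Runs the forward transfer model at `gamma_true` on `geom` and perturbs the
#' absorbed percentages with the lognormal noise model. Reproducible: the
#' same seed yields identical measurements, and the global RNG state is
#' restored on exit.
#'
#' @param gamma_true True transfer coefficient (m^2/s).
#' @param geom A [build_geometry()] / [make_fixture()] geometry.
#' @param times Measurement (dilation) times in seconds, positive.
#' @param noise A [measurement_noise()] model.
#' @param params A [transport_params()] object.
#' @param spacing Mesh spacing (m) for the forward model.
#' @return Data frame (class `absorption_measurements`) with columns `time_s`
#'   and `absorbed_percent`.
#' @export
gen_measurements <- function(gamma_true, geom, times = c(60, 120),
                             noise = measurement_noise(),
                             params = transport_params(),
                             spacing = 5e-5) {
  stopifnot_positive(gamma_true, "gamma_true")
  if (any(times <= 0)) dcb_abort("'times' must be positive", "dcb_domain_error")
  if (!inherits(noise, "measurement_noise")) {
    dcb_abort("'noise' must be a 'measurement_noise'", "dcb_validation_error")
  }
  mesh <- mesh_geometry(geom, spacing)
  pct <- forward_percents(gamma_true, sort(times), mesh, params)
  if (noise$cv > 0) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(noise$seed)
    sigma <- sqrt(log(1 + noise$cv^2))
    pct <- pct * exp(stats::rnorm(length(pct), mean = -sigma^2 / 2, sd = sigma))
  }
  structure(data.frame(time_s = sort(times), absorbed_percent = pct),
            class = c("absorption_measurements", "data.frame"))
}
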