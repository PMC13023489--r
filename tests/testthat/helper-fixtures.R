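# Shared fixtures: a shortened vessel keeps test meshes small (absorbed
# percentages are area-normalised, so end effects aside they match the
# full-length fixture).

mini_dims <- function() {
  vessel_dims(lumen_radius = 1.0e-3, wall_thickness = 0.4e-3,
              vessel_length = 4e-3, plaque_half_length = 1e-3,
              balloon_thickness = 0.1e-3, balloon_length = 3e-3)
}

mini_mesh <- local({
  cache <- list()
  function(preset = "exvivo", spacing = 5e-5) {
    key <- paste(preset, spacing)
    if (is.null(cache[[key]])) {
      cache[[key]] <<- mesh_geometry(make_fixture(preset, mini_dims()), spacing)
    }
    cache[[key]]
  }
})

# 1D radial column (single axial slab), all one region
radial_1d_mesh <- function(n = 40, h = 5e-5, r0 = 1e-3, code = 3L) {
  dcbsim:::build_axi_mesh(r0 + h * (0:n), c(0, h), matrix(code, n, 1))
}

# planar two-slab problem along z (axial faces all share the same area, so
# the discretisation is exactly one-dimensional Cartesian)
slab_mesh <- function(n_bal, n_tis, h, r0 = 1e-3) {
  region <- matrix(c(rep(1L, n_bal), rep(3L, n_tis)), nrow = 1)
  dcbsim:::build_axi_mesh(c(r0, r0 + h), h * (0:(n_bal + n_tis)), region)
}

total_mass <- function(field, mesh) sum(field * mesh$vol)

make_report <- function(t, safe, dur) {
  structure(list(dilation_time = t, safe_at_24h = safe, safe_at_24h_peak = safe,
                 effective_duration = dur),
            class = "dosimetry_report")
}
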