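# Retention stage: free diffusion of wall-resident drug after balloon
# withdrawal, with luminal wash-off enforced as a prescribed mass-loss
# schedule.
#
# After withdrawal the balloon region is removed from the mesh. Blood flow
# continuously strips drug from the former balloon-contact surface; because
# published wash-off data prescribe daily totals rather than a flux law, the
# loss is enforced by a controller: at every step, after the free-diffusion
# update, exactly enough mass is removed at the luminal surface to keep the
# total tissue mass on the scheduled trajectory. Removal is taken from the
# blood-contacted surface cells first (weighted by local mass) and cascades
# one cell-layer deeper only when every shallower layer is exhausted, so it
# stays surface-localised whenever the surface can supply the scheduled
# loss, yet the schedule remains enforceable when it cannot (the prescribed
# daily totals come from in vivo observation and are not diffusion-limited).

#' Luminal mass-loss schedule
#'
#' Fraction of the tissue drug mass lost during the first 24 h after
#' withdrawal (default 0.70), and the fraction of the previous day's
#' remaining mass lost during each subsequent day (default 0.30).
#'
#' @param first_day_loss_fraction Fraction lost in the first 24 h, in `[0, 1)`.
#' @param subsequent_daily_loss_fraction Fraction of the previous day's end
#'   mass lost per later day, in `[0, 1)`.
#' @return An object of class `loss_schedule`.
#' @export
loss_schedule <- function(first_day_loss_fraction = 0.70,
                          subsequent_daily_loss_fraction = 0.30) {
  for (nm in c("first_day_loss_fraction", "subsequent_daily_loss_fraction")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0 || v >= 1) {
      dcb_abort(sprintf("'%s' must lie in [0, 1)", nm), "dcb_validation_error")
    }
  }
  structure(list(first_day_loss_fraction = first_day_loss_fraction,
                 subsequent_daily_loss_fraction = subsequent_daily_loss_fraction),
            class = "loss_schedule")
}

#' Scheduled total-mass trajectory
#'
#' Daily endpoints: `M(24h) = (1 - f1) * m0` and
#' `M((n+1) days) = (1 - fd) * M(n days)` for `n >= 1`, where `f1` and `fd`
#' are the schedule fractions. Within a day the trajectory interpolates
#' exponentially between the endpoints (continuous and monotone).
#'
#' @param m0 Mass at withdrawal (kg).
#' @param schedule A [loss_schedule()].
#' @param t Time(s) since withdrawal (s), non-negative; vectorised.
#' @return Scheduled mass (kg) at each `t`.
#' @export
#' @examples
#' target_mass_trajectory(1, loss_schedule(), c(0, 86400, 2 * 86400))
target_mass_trajectory <- function(m0, schedule, t) {
  if (!inherits(schedule, "loss_schedule")) {
    dcb_abort("'schedule' must be a 'loss_schedule'", "dcb_validation_error")
  }
  if (any(t < 0)) dcb_abort("'t' must be non-negative", "dcb_domain_error")
  r1 <- 1 - schedule$first_day_loss_fraction
  rd <- 1 - schedule$subsequent_daily_loss_fraction
  day <- floor(t / SECONDS_PER_DAY)
  frac <- t / SECONDS_PER_DAY - day
  # mass at the start of the current day, and the day's decay ratio
  m_day <- ifelse(day == 0, m0, m0 * r1 * rd^(day - 1))
  ratio <- ifelse(day == 0, r1, rd)
  m_day * ratio^frac
}

default_checkpoints <- function(horizon) {
  cp <- unique(sort(c(SECONDS_PER_DAY * (0:7), SECONDS_PER_WEEK * (1:8), horizon)))
  cp[cp <= horizon]
}

series_stats <- function(phi, vol, rho) {
  V <- sum(vol)
  mean_phi <- sum(phi * vol) / V
  cv <- if (mean_phi > 0) {
    sqrt(sum(vol * (phi - mean_phi)^2) / V) / mean_phi
  } else NA_real_
  c(mean_ug_per_g = mean_phi * 1e6 / rho,
    max_ug_per_g = max(phi) * 1e6 / rho,
    cv = cv)
}

#' Simulate post-withdrawal retention under the prescribed loss schedule
#'
#' Removes the balloon region from the transfer mesh (drug still in the
#' coating leaves with the balloon), then evolves the tissue field with free
#' diffusivity `d_free` and zero-flux outer/end boundaries. After every
#' diffusion step the controller removes exactly enough mass that the total
#' tissue mass follows [target_mass_trajectory()]: removal is distributed
#' over the luminal (blood-contacted) surface cells in proportion to their
#' mass, capped at each cell's content, and cascades one cell-layer deeper
#' into the tissue only when every shallower layer is exhausted.
#'
#' @param transfer A [run_transfer()] result (or a list with `field` and
#'   `mesh` from one).
#' @param params A [transport_params()] object.
#' @param schedule A [loss_schedule()].
#' @param horizon Retention horizon (s); default 8 weeks.
#' @param checkpoints Times (s) at which concentration statistics are
#'   recorded; must be multiples of `dt`. Default: daily through week 1, then
#'   weekly through the horizon.
#' @param dt Nominal step (s); default 600.
#' @return An object of class `concentration_time_series`: a data frame with
#'   columns `time_s`, `mass_ug`, `mean_ug_per_g`, `max_ug_per_g`, `cv`, with
#'   attributes `m0_kg` (mass at withdrawal), `ledger` (independent per-step
#'   data frame `time_s`, `mass_kg`, `removed_kg`), `mesh` and `final_field`.
#' @export
run_retention <- function(transfer, params, schedule = loss_schedule(),
                          horizon = 8 * SECONDS_PER_WEEK,
                          checkpoints = NULL, dt = 600) {
  if (!inherits(params, "transport_params")) {
    dcb_abort("'params' must be a 'transport_params'", "dcb_validation_error")
  }
  if (!inherits(schedule, "loss_schedule")) {
    dcb_abort("'schedule' must be a 'loss_schedule'", "dcb_validation_error")
  }
  stopifnot_positive(horizon, "horizon")
  stopifnot_positive(dt, "dt")
  if (is.null(transfer$field) || is.null(transfer$mesh)) {
    dcb_abort("'transfer' must carry 'field' and 'mesh'", "dcb_validation_error")
  }

  dropped <- drop_balloon(transfer$mesh)
  mesh <- dropped$mesh
  loss_layers <- dropped$loss_layers
  keep_old <- which(!is.na(dropped$map))
  phi <- numeric(mesh$n)
  phi[dropped$map[keep_old]] <- transfer$field[keep_old]

  if (is.null(checkpoints)) checkpoints <- default_checkpoints(horizon)
  checkpoints <- sort(unique(c(0, checkpoints)))
  nsteps <- as.integer(round(horizon / dt))
  if (abs(nsteps * dt - horizon) > 1e-6 * horizon) {
    dcb_abort("'dt' must divide 'horizon'", "dcb_validation_error")
  }
  cp_step <- round(checkpoints / dt)
  if (any(abs(cp_step * dt - checkpoints) > 1e-6 * dt)) {
    dcb_abort("'checkpoints' must be multiples of 'dt'", "dcb_validation_error")
  }

  m0 <- sum(phi * mesh$vol)
  op <- assemble_operator(mesh, diffusivity_map(plaque = params$d_free,
                                                wall = params$d_free))

  # one controller-corrected step from time t over `step` seconds
  step_once <- function(phi, t, step, removed) {
    phi_new <- advance(phi, op, step)
    m_now <- sum(phi_new * mesh$vol)
    m_target <- target_mass_trajectory(m0, schedule, t + step)
    dm <- m_now - m_target
    if (dm > 1e-12 * m_now) {       # ignore pure round-off deficits
      for (lk in loss_layers) {
        w <- phi_new[lk] * mesh$vol[lk]
        wsum <- sum(w)
        if (wsum <= 0) next
        take <- min(dm, wsum)
        phi_new[lk] <- pmax(0, phi_new[lk] - (take * w / wsum) / mesh$vol[lk])
        removed <- removed + take
        dm <- dm - take
        if (dm <= 0) break
      }
    }
    list(phi = phi_new, removed = removed)
  }

  ledger <- data.frame(time_s = numeric(nsteps + 1L),
                       mass_kg = numeric(nsteps + 1L),
                       removed_kg = numeric(nsteps + 1L))
  ledger[1L, ] <- c(0, m0, 0)
  rho <- params$rho_tissue
  tissue_vol <- mesh$vol
  stats0 <- series_stats(phi, tissue_vol, rho)
  series <- data.frame(time_s = checkpoints, mass_ug = NA_real_,
                       mean_ug_per_g = NA_real_, max_ug_per_g = NA_real_,
                       cv = NA_real_)
  fill_cp <- function(series, k, t, phi) {
    st <- series_stats(phi, tissue_vol, rho)
    series[k, ] <- c(t, sum(phi * tissue_vol) * 1e9, st[["mean_ug_per_g"]],
                     st[["max_ug_per_g"]], st[["cv"]])
    series
  }
  k0 <- match(0, cp_step)
  if (!is.na(k0)) series <- fill_cp(series, k0, 0, phi)

  removed <- 0
  degenerate <- m0 <= 0
  for (s in seq_len(nsteps)) {
    t_prev <- (s - 1L) * dt
    if (!degenerate) {
      out <- step_once(phi, t_prev, dt, removed)
      phi <- out$phi
      removed <- out$removed
    }
    ledger[s + 1L, ] <- c(s * dt, sum(phi * tissue_vol), removed)
    k <- match(s, cp_step)
    if (!is.na(k)) series <- fill_cp(series, k, s * dt, phi)
  }

  structure(series,
            class = c("concentration_time_series", "data.frame"),
            m0_kg = m0, schedule = schedule, ledger = ledger,
            mesh = mesh, final_field = phi)
}

#' @export
print.concentration_time_series <- function(x, ...) {
  cat(sprintf("<concentration_time_series> %d checkpoints over %.1f days, m0 = %.2f ug\n",
              nrow(x), max(x$time_s) / SECONDS_PER_DAY, attr(x, "m0_kg") * 1e9))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
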