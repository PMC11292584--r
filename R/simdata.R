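#' Acquisition geometry for simulated and recorded PD-US data
#'
#' Describes how echo frames are sampled. Defaults follow a 24 MHz
#' linear-array color-flow protocol: one Doppler frame holds 17 echo frames
#' at 1000 fps, Doppler frames repeat at 8 Hz, and a 12-s recording holds
#' 96 Doppler frames. The axial sample spacing is
#' `sound_speed / (2 * axial_sample_freq)`, i.e. RF depth samples.
#'
#' @param transmit_freq_hz Transmit (carrier) frequency, Hz.
#' @param sound_speed_m_per_s Speed of sound, m/s (soft-tissue 1540).
#' @param axial_sample_freq_hz RF sampling frequency along depth, Hz. Must be
#'   at least 4x the carrier so the RF carrier is represented.
#' @param line_pitch_mm Lateral spacing between image lines, mm.
#' @param doppler_frame_rate_hz Doppler frame (slow-time) rate, Hz.
#' @param echo_frames_per_doppler_frame Echo frames per Doppler frame.
#' @param intra_frame_rate_hz Echo-frame rate within a Doppler frame, Hz.
#' @param n_doppler_frames Doppler frames per recording.
#' @param psf_axial_mm,psf_lateral_mm Full width at half maximum of the
#'   Gaussian point-spread-function envelope, mm.
#' @param n_axial,n_lines Frame dimensions (depth samples x lines).
#' @return An object of class `acquisition_geometry` (a named list with the
#'   derived fields `axial_spacing_mm`, `axial_extent_mm`, `lateral_extent_mm`
#'   and `carrier_cycles_per_mm`).
#' @export
#' @examples
#' geom <- acquisition_geometry()
#' geom$axial_spacing_mm
acquisition_geometry <- function(transmit_freq_hz = 24e6,
                                 sound_speed_m_per_s = 1540,
                                 axial_sample_freq_hz = 96e6,
                                 line_pitch_mm = 0.05,
                                 doppler_frame_rate_hz = 8,
                                 echo_frames_per_doppler_frame = 17,
                                 intra_frame_rate_hz = 1000,
                                 n_doppler_frames = 96,
                                 psf_axial_mm = 0.10,
                                 psf_lateral_mm = 0.15,
                                 n_axial = 256,
                                 n_lines = 48) {
  if (transmit_freq_hz <= 0) abort("`transmit_freq_hz` must be positive.")
  if (sound_speed_m_per_s <= 0) abort("`sound_speed_m_per_s` must be positive.")
  if (axial_sample_freq_hz < 4 * transmit_freq_hz) {
    abort("`axial_sample_freq_hz` must be >= 4x the transmit frequency.")
  }
  if (line_pitch_mm <= 0 || doppler_frame_rate_hz <= 0) {
    abort("Pitch and frame rates must be positive.")
  }
  c_mm_s <- sound_speed_m_per_s * 1e3
  geom <- list(
    transmit_freq_hz = transmit_freq_hz,
    sound_speed_m_per_s = sound_speed_m_per_s,
    axial_sample_freq_hz = axial_sample_freq_hz,
    line_pitch_mm = line_pitch_mm,
    doppler_frame_rate_hz = doppler_frame_rate_hz,
    echo_frames_per_doppler_frame = echo_frames_per_doppler_frame,
    intra_frame_rate_hz = intra_frame_rate_hz,
    n_doppler_frames = n_doppler_frames,
    psf_axial_mm = psf_axial_mm,
    psf_lateral_mm = psf_lateral_mm,
    n_axial = n_axial,
    n_lines = n_lines,
    axial_spacing_mm = c_mm_s / (2 * axial_sample_freq_hz),
    carrier_cycles_per_mm = 2 * transmit_freq_hz / c_mm_s
  )
  geom$axial_extent_mm <- geom$axial_spacing_mm * n_axial
  geom$lateral_extent_mm <- line_pitch_mm * n_lines
  structure(geom, class = "acquisition_geometry")
}

#' Ground-truth specification for the RF echo simulator
#'
#' Parameterizes the physical scene a simulated recording emulates: strong
#' slowly-moving tissue clutter, weak diffusely moving blood scatterers, and
#' additive electronic noise. All power levels are in dB relative to the
#' blood baseline power (blood at `blood_power_db = 0` has unit mean RF
#' power inside the field). With the defaults, clutter sits 40 dB above
#' blood and noise 15 dB below the total echo, i.e. echo SNR = 15 dB.
#'
#' @param clutter_power_db Tissue-echo power, dB re blood baseline. `-Inf`
#'   disables clutter.
#' @param blood_power_db Blood-echo baseline power, dB. `-Inf` disables blood.
#' @param noise_power_db Additive white-noise power, dB re blood baseline.
#'   `-Inf` disables noise.
#' @param respiration_amplitude_mm Amplitude of the periodic lateral tissue
#'   translation (respiration), mm.
#' @param respiration_period_s Respiration period, s.
#' @param axial_drift_mm_per_s Slow axial tissue drift, mm/s.
#' @param blood_speed_mm_per_s RMS speed of the diffuse blood-scatterer
#'   motion, mm/s; capillary flow in muscle is below 2 mm/s.
#' @param scatterer_density_per_mm2 Scatterer density for each component,
#'   1/mm^2. The default gives fully developed speckle (around 10 scatterers
#'   per resolution cell).
#' @param perfusion_curve `NULL` for constant baseline perfusion, or a
#'   function of time post-ligation in days returning the true relative
#'   blood power in dB; must return 0 at the pre-ligation baseline (t = 0).
#' @param seed Integer seed making simulation deterministic, or `NULL`.
#' @return An object of class `ground_truth_spec`.
#' @export
#' @examples
#' spec <- ground_truth_spec(seed = 1)
ground_truth_spec <- function(clutter_power_db = 40,
                              blood_power_db = 0,
                              noise_power_db = 25,
                              respiration_amplitude_mm = 0.010,
                              respiration_period_s = 0.4,
                              axial_drift_mm_per_s = 0,
                              blood_speed_mm_per_s = 1.0,
                              scatterer_density_per_mm2 = 600,
                              perfusion_curve = NULL,
                              seed = NULL) {
  for (p in c(clutter_power_db, blood_power_db, noise_power_db)) {
    if (is.na(p) || p == Inf) abort("Power levels must be finite or -Inf.")
  }
  if (respiration_amplitude_mm < 0) {
    abort("`respiration_amplitude_mm` must be >= 0.")
  }
  if (respiration_period_s <= 0) abort("`respiration_period_s` must be > 0.")
  if (blood_speed_mm_per_s < 0) abort("`blood_speed_mm_per_s` must be >= 0.")
  if (scatterer_density_per_mm2 <= 0) {
    abort("`scatterer_density_per_mm2` must be positive.")
  }
  if (!is.null(perfusion_curve)) {
    if (!is.function(perfusion_curve)) {
      abort("`perfusion_curve` must be NULL or a function of time in days.")
    }
    if (abs(perfusion_curve(0)) > 1e-9) {
      abort("`perfusion_curve` must be 0 dB at the pre-ligation baseline.")
    }
  }
  structure(
    list(
      clutter_power_db = clutter_power_db,
      blood_power_db = blood_power_db,
      noise_power_db = noise_power_db,
      respiration_amplitude_mm = respiration_amplitude_mm,
      respiration_period_s = respiration_period_s,
      axial_drift_mm_per_s = axial_drift_mm_per_s,
      blood_speed_mm_per_s = blood_speed_mm_per_s,
      scatterer_density_per_mm2 = scatterer_density_per_mm2,
      perfusion_curve = perfusion_curve,
      seed = seed
    ),
    class = "ground_truth_spec"
  )
}

# Gaussian envelope sigma from a FWHM specification.
fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

# Amplitude scale so the rendered speckle field has the requested mean RF
# power per sample: E[P] = rho * A^2 * (sqrt(pi) sig_z / 2) * (sqrt(pi) sig_x)
# for a Gaussian-enveloped axial carrier (cos^2 averages to 1/2).
scatterer_amplitude <- function(power_linear, rho, geom) {
  sig_z <- fwhm_to_sigma(geom$psf_axial_mm)
  sig_x <- fwhm_to_sigma(geom$psf_lateral_mm)
  sqrt(power_linear / (rho * 0.5 * sqrt(pi) * sig_z * sqrt(pi) * sig_x))
}

# Render one RF frame from point scatterers by local evaluation of a
# separable Gaussian-modulated PSF (compiled kernel). Positions in mm;
# returns n_axial x n_lines matrix.
render_rf_frame <- function(ax_mm, lat_mm, amp, geom) {
  if (length(ax_mm) == 0L) return(matrix(0, geom$n_axial, geom$n_lines))
  render_rf_cpp(ax_mm, lat_mm, amp, geom$n_axial, geom$n_lines,
                geom$axial_spacing_mm, geom$line_pitch_mm,
                fwhm_to_sigma(geom$psf_axial_mm),
                fwhm_to_sigma(geom$psf_lateral_mm),
                geom$carrier_cycles_per_mm)
}

# Uniform scatterer positions over the field plus a margin so scatterers
# just outside the frame still contribute (no edge depletion).
draw_scatterers <- function(geom, rho, margin_mm) {
  z_lo <- -margin_mm
  z_hi <- geom$axial_extent_mm + margin_mm
  x_lo <- -margin_mm
  x_hi <- geom$lateral_extent_mm + margin_mm
  n <- stats::rpois(1, rho * (z_hi - z_lo) * (x_hi - x_lo))
  list(
    ax = runif(n, z_lo, z_hi),
    lat = runif(n, x_lo, x_hi),
    amp = rnorm(n)
  )
}

#' Simulate one slow-time RF echo ensemble
#'
#' Generates 16 RF echo frames spanning 2 s at the slow-time (Doppler frame)
#' rate. Tissue scatterers translate rigidly following the respiration and
#' drift parameters; blood scatterers perform a diffuse random walk with the
#' specified RMS speed, their echo power scaled by `perfusion_curve(t)`;
#' white Gaussian noise is added at the specified level. The scatterer field
#' is drawn fresh per call but frozen within the ensemble except for this
#' prescribed motion, and the output is deterministic given `spec$seed`.
#'
#' @param spec A [ground_truth_spec()].
#' @param geom An [acquisition_geometry()].
#' @param t Schedule time post-ligation in days (0 or `"pre"` = baseline).
#' @param n_frames Number of slow-time frames (default 16).
#' @return An `ensemble_stack`: list with `frames` (array
#'   `n_axial x n_lines x n_frames`), `slow_time_rate_hz`, `geom`, the true
#'   per-frame tissue displacement (`true_displacement`, a tibble), and
#'   provenance.
#' @export
#' @examples
#' ens <- simulate_ensemble(ground_truth_spec(seed = 7))
#' dim(ens$frames)
simulate_ensemble <- function(spec, geom = acquisition_geometry(), t = "pre",
                              n_frames = 16) {
  stopifnot(inherits(spec, "ground_truth_spec"),
            inherits(geom, "acquisition_geometry"))
  if (identical(t, "pre")) t <- 0
  if (!is.numeric(t) || t < 0) abort("`t` must be \"pre\" or days >= 0.")
  if (!is.null(spec$seed)) set.seed(spec$seed)

  rho <- spec$scatterer_density_per_mm2
  dt <- 1 / geom$doppler_frame_rate_hz
  times <- (seq_len(n_frames) - 1) * dt
  margin <- 3 * fwhm_to_sigma(geom$psf_lateral_mm) +
    spec$respiration_amplitude_mm +
    abs(spec$axial_drift_mm_per_s) * max(times) +
    spec$blood_speed_mm_per_s * max(times)

  p_clutter <- 10^(spec$clutter_power_db / 10)
  curve_db <- if (is.null(spec$perfusion_curve)) 0 else spec$perfusion_curve(t)
  p_blood <- 10^((spec$blood_power_db + curve_db) / 10)
  p_noise <- 10^(spec$noise_power_db / 10)

  tissue <- if (p_clutter > 0) draw_scatterers(geom, rho, margin) else NULL
  blood <- if (p_blood > 0) draw_scatterers(geom, rho, margin) else NULL
  a_t <- if (p_clutter > 0) scatterer_amplitude(p_clutter, rho, geom) else 0
  a_b <- if (p_blood > 0) scatterer_amplitude(p_blood, rho, geom) else 0
  blood_step_sd <- spec$blood_speed_mm_per_s * dt / sqrt(2)

  disp_ax <- spec$axial_drift_mm_per_s * times
  disp_lat <- spec$respiration_amplitude_mm *
    sin(2 * pi * times / spec$respiration_period_s)
  # relative to frame 1 (frame 1 sits at displacement 0 by construction
  # because sin(0) = 0 and drift starts at 0)
  frames <- array(0, c(geom$n_axial, geom$n_lines, n_frames))
  static_tissue <- !is.null(tissue) &&
    all(abs(disp_ax) < 1e-15) && all(abs(disp_lat) < 1e-15)
  tissue_frame <- NULL
  b_ax <- blood$ax
  b_lat <- blood$lat
  for (f in seq_len(n_frames)) {
    fr <- matrix(0, geom$n_axial, geom$n_lines)
    if (!is.null(tissue)) {
      if (static_tissue) {
        if (is.null(tissue_frame)) {
          tissue_frame <- render_rf_frame(tissue$ax, tissue$lat,
                                          a_t * tissue$amp, geom)
        }
        fr <- fr + tissue_frame
      } else {
        fr <- fr + render_rf_frame(tissue$ax + disp_ax[f],
                                   tissue$lat + disp_lat[f],
                                   a_t * tissue$amp, geom)
      }
    }
    if (!is.null(blood)) {
      if (f > 1) {
        b_ax <- b_ax + rnorm(length(b_ax), 0, blood_step_sd)
        b_lat <- b_lat + rnorm(length(b_lat), 0, blood_step_sd)
      }
      fr <- fr + render_rf_frame(b_ax, b_lat, a_b * blood$amp, geom)
    }
    if (p_noise > 0) {
      fr <- fr + matrix(rnorm(length(fr), 0, sqrt(p_noise)),
                        geom$n_axial, geom$n_lines)
    }
    frames[, , f] <- fr
  }
  new_ensemble_stack(frames, geom,
                     provenance = list(source = "simulate_ensemble",
                                       t_days = t, seed = spec$seed),
                     true_displacement = tibble(
                       frame = seq_len(n_frames),
                       time_s = times,
                       axial_mm = disp_ax,
                       lateral_mm = disp_lat
                     ))
}

new_ensemble_stack <- function(frames, geom, provenance = list(),
                               true_displacement = NULL) {
  stopifnot(length(dim(frames)) == 3)
  structure(
    list(frames = frames,
         n_frames = dim(frames)[3],
         slow_time_rate_hz = geom$doppler_frame_rate_hz,
         geom = geom,
         provenance = provenance,
         true_displacement = true_displacement),
    class = "ensemble_stack"
  )
}

#' @export
print.ensemble_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "<ensemble_stack> %d RF frames of %d x %d samples at %.3g Hz slow time\n",
    d[3], d[1], d[2], x$slow_time_rate_hz))
  invisible(x)
}

#' Default ischemic-recovery perfusion curve
#'
#' Builds the true relative blood-power curve (dB vs days post-ligation)
#' used by the cohort simulator: 0 dB at baseline, a quadratic decline on
#' the log-time axis reaching `p_min_db` at day 2, a transient spike of
#' `p_max_db` above the trend at 20 min, and a quadratic recovery (again on
#' log-time) crossing 0 dB at `t_recovery_days`. Both branches are exact
#' second-order polynomials in log10(time), so the downstream polynomial
#' estimators recover the parameters exactly in the noiseless case.
#'
#' @param p_max_db Height of the 20-min perfusion spike above the local
#'   trend, dB.
#' @param p_min_db Minimum relative perfusion, dB (< 0), reached at day 2.
#' @param t_recovery_days Day at which the recovery branch crosses 0 dB;
#'   must exceed 2.
#' @param late_cap_db Ceiling applied after day 14 so late points plateau
#'   near baseline, dB.
#' @return A function of time in days returning dB re baseline.
#' @export
#' @examples
#' curve <- ischemic_perfusion_curve(3, -6, 9)
#' curve(c(0, 20 / 1440, 2, 9))
ischemic_perfusion_curve <- function(p_max_db, p_min_db, t_recovery_days,
                                     late_cap_db = 1) {
  if (p_min_db >= 0) abort("`p_min_db` must be negative.")
  if (t_recovery_days <= 2 || t_recovery_days > 28) {
    abort("`t_recovery_days` must be in (2, 28].")
  }
  u0 <- log10(2)                      # recovery-branch vertex at day 2
  a <- -p_min_db / (log10(t_recovery_days) - u0)^2
  recovery <- function(u_days) a * (u_days - u0)^2 + p_min_db
  # early branch: quadratic in log10(minutes) from 0 dB at 1 min to the
  # recovery value at day 1, with zero initial slope
  u1 <- log10(1440)
  gam <- recovery(log10(1)) / u1^2
  early <- function(u_min) gam * u_min^2
  spike_u <- log10(20)
  function(t_days) {
    vapply(t_days, function(td) {
      if (td <= 0) return(0)
      t_min <- td * 1440
      if (t_min < 1440) {
        base <- early(log10(max(t_min, 1)))
        if (abs(log10(max(t_min, 1)) - spike_u) < 1e-9) base + p_max_db
        else base
      } else {
        v <- recovery(log10(td))
        if (td > 14) min(v, late_cap_db) else v
      }
    }, numeric(1))
  }
}

#' Simulate one mouse's baseline-normalized perfusion profile
#'
#' Evaluates an [ischemic_perfusion_curve()] on the measurement schedule and
#' adds independent Gaussian noise (in dB) to every post-ligation point. The
#' `"pre"` point is 0 dB by construction, the 20-min point exceeds the local
#' trend by `p_max_db`, the day-2 point equals `p_min_db` (up to noise), and
#' the noiseless recovery branch crosses 0 dB at `t_recovery_days`.
#'
#' @param p_max_db,p_min_db,t_recovery_days Ground-truth ischemic
#'   parameters; see [ischemic_perfusion_curve()].
#' @param noise_sd_db Per-point measurement noise, dB.
#' @param seed Optional integer seed.
#' @param schedule Schedule tibble; defaults to [pdus_schedule()].
#' @return A tibble (`time_label`, `time_min`, `time_days`, `pdus_db`).
#' @export
#' @examples
#' simulate_mouse_profile(3, -6, 9, noise_sd_db = 0)
simulate_mouse_profile <- function(p_max_db, p_min_db, t_recovery_days,
                                   noise_sd_db = 0.5, seed = NULL,
                                   schedule = pdus_schedule()) {
  if (!all(schedule_labels() %in% as.character(schedule$time_label))) {
    abort("`schedule` does not match the measurement schedule.")
  }
  if (!is.null(seed)) set.seed(seed)
  curve <- ischemic_perfusion_curve(p_max_db, p_min_db, t_recovery_days)
  db <- curve(ifelse(as.character(schedule$time_label) == "pre",
                     0, schedule$time_days))
  noise <- rnorm(nrow(schedule), 0, noise_sd_db)
  noise[as.character(schedule$time_label) == "pre"] <- 0
  schedule %>%
    mutate(pdus_db = db + noise)
}

#' Group specification for a simulated cohort
#'
#' @param groups Character vector of group labels among `"HS"`, `"HE"`,
#'   `"DS"`, `"DE"` (healthy/diabetic x sedentary/exercised).
#' @param sexes Character vector of sexes to simulate (`"M"`, `"F"`).
#' @param n_per_group Mice per group x sex cell.
#' @param param_means Named list mapping each group label to a numeric
#'   vector `c(p_max_db, p_min_db, t_recovery_days)`.
#' @param param_sds Same shape as `param_means`: per-group spreads.
#' @param noise_sd_db Per-point profile noise, dB.
#' @param seed Integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(groups = c("HS", "HE", "DS", "DE"),
                        sexes = c("M", "F"),
                        n_per_group = 8,
                        param_means = list(
                          HS = c(3.0, -6.5, 6.0),
                          HE = c(3.0, -6.0, 6.0),
                          DS = c(2.0, -5.5, 9.0),
                          DE = c(2.2, -5.5, 8.0)
                        ),
                        param_sds = list(
                          HS = c(0.5, 0.8, 1.2),
                          HE = c(0.5, 0.8, 1.2),
                          DS = c(0.5, 0.8, 1.6),
                          DE = c(0.5, 0.8, 1.6)
                        ),
                        noise_sd_db = 0.5,
                        seed = 1L) {
  if (length(groups) == 0) abort("`groups` must be non-empty.")
  if (!all(groups %in% c("HS", "HE", "DS", "DE"))) {
    abort("Group labels must be among HS, HE, DS, DE.")
  }
  if (n_per_group < 1) abort("`n_per_group` must be >= 1.")
  for (g in groups) {
    if (is.null(param_means[[g]]) || is.null(param_sds[[g]])) {
      abort(sprintf("Missing parameter means/sds for group %s.", g))
    }
    tm <- param_means[[g]][3]
    if (tm <= 2 || tm > 28) abort("Group mean T must be in (2, 28] days.")
  }
  structure(
    list(groups = groups, sexes = sexes, n_per_group = n_per_group,
         param_means = param_means, param_sds = param_sds,
         noise_sd_db = noise_sd_db, seed = seed),
    class = "cohort_spec"
  )
}

#' Simulate a cohort of perfusion profiles with known ground truth
#'
#' Draws per-mouse ischemic parameters from the group means and spreads of a
#' [cohort_spec()], generates each mouse's noisy perfusion profile, and
#' attaches age and weight covariates (heavier/older distributions for the
#' diabetic groups, mirroring the kind of imbalance covariate-adjusted
#' comparisons must handle). Reproducible given `cs$seed`.
#'
#' @param cs A [cohort_spec()].
#' @return A list of tibbles: `mice` (mouse_id, group, sex, age_months,
#'   weight_g, and the true parameters `p_max_true`, `p_min_true`, `t_true`)
#'   and `profiles` (mouse_id, group, sex, time_label, time_min, time_days,
#'   pdus_db).
#' @export
#' @examples
#' cohort <- simulate_cohort(cohort_spec(n_per_group = 2, seed = 3))
#' head(cohort$profiles)
simulate_cohort <- function(cs) {
  stopifnot(inherits(cs, "cohort_spec"))
  set.seed(cs$seed)
  mice <- list()
  profiles <- list()
  id <- 0L
  for (g in cs$groups) {
    mu <- cs$param_means[[g]]
    sdv <- cs$param_sds[[g]]
    diabetic <- substr(g, 1, 1) == "D"
    for (sx in cs$sexes) {
      for (i in seq_len(cs$n_per_group)) {
        id <- id + 1L
        p_max <- rnorm(1, mu[1], sdv[1])
        p_min <- min(rnorm(1, mu[2], sdv[2]), -0.5)
        t_rec <- min(max(rnorm(1, mu[3], sdv[3]), 2.5), 28)
        age <- max(rnorm(1, if (diabetic) 14 else 10, 2), 3)
        wt <- max(rnorm(1, if (diabetic) 52 else 36, 4), 15)
        mice[[id]] <- tibble(
          mouse_id = sprintf("m%03d", id), group = g, sex = sx,
          age_months = age, weight_g = wt,
          p_max_true = p_max, p_min_true = p_min, t_true = t_rec
        )
        prof <- simulate_mouse_profile(p_max, p_min, t_rec,
                                       noise_sd_db = cs$noise_sd_db)
        profiles[[id]] <- prof %>%
          mutate(mouse_id = sprintf("m%03d", id), group = g, sex = sx,
                 .before = 1)
      }
    }
  }
  list(mice = bind_rows(mice), profiles = bind_rows(profiles))
}
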