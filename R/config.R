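#' Simulation configuration for a germinal center run
#'
#' Builds a validated configuration object with the default ("intermediate")
#' study conditions: 3000 antigen units per FDC, 200 Tfh cells, Tfh signal
#' multiplier 1, founder cells at mutation distance 5-6, endogenous antibody
#' feedback on, 21-day horizon. All rates are per hour, lengths in
#' micrometers, times in hours unless suffixed otherwise.
#'
#' @param ... named overrides of any default listed below.
#' @return an object of class `gc_config` (a named list).
#' @details Key parameter groups:
#' * shape space: `shape_dim`, `shape_side`, `affinity_gamma`, `affinity_eta`
#' * founders: `founder_rate_per_h` (2 cells/h), `founder_stop_h` (96),
#'   `founder_d_min`/`founder_d_max` (5/6), `founder_initial_divisions` (6)
#' * lattice: `lattice_radius_um` (160), `lattice_spacing_um` (5),
#'   `fdc_count` (200), `fdc_arm_sites` (8), `antigen_per_fdc` (3000)
#' * Tfh: `tfh_count` (200), `tfh_signal_rate_per_h`, `tfh_signal_threshold`,
#'   `tfh_signal_multiplier` (1)
#' * motility: `b_speed_um_min` (7.5), `tfh_speed_um_min` (10), `zone_bias`,
#'   `neighborhood` ("moore" or "vonneumann")
#' * cycle: `cycle_h`, `cycle_jitter`, `p_mutation` (0.5 per division per
#'   daughter), `mutation_silent_h` (24)
#' * selection: `cc_lifetime_h` (10), `pmhc_cap`, `div_min`/`div_max` (1/6),
#'   `div_slope`, `p_output`
#' * antibody feedback: `endogenous_feedback`, `ab_kd_bins`, `ab_kd_min_nm`,
#'   `ab_kd_max_nm`, `ab_kd_scale_nm`, `ab_production_rate_nm_per_cell_h`,
#'   `ab_secretion_delay_h` (48), `inject_day`, `inject_kd_nm`,
#'   `inject_dose_nm`
#' * run control: `dt_h`, `horizon_days` (21), `record_every_h` (4),
#'   `extinction_threshold` (10), `collapse_check_after_h` (96)
#' @examples
#' cfg <- gc_config(antigen_per_fdc = 1000)
#' cfg$antigen_per_fdc
#' @export
gc_config <- function(...) {
  cfg <- list(
    # shape space / affinity
    shape_dim = 4L,
    shape_side = 10L,
    affinity_gamma = 2.8,
    affinity_eta = 2,
    # founder influx
    founder_rate_per_h = 2,
    founder_stop_h = 96,
    founder_d_min = 5L,
    founder_d_max = 6L,
    founder_initial_divisions = 6L,
    # lattice & FDC
    lattice_radius_um = 160,
    lattice_spacing_um = 5,
    fdc_count = 200L,
    fdc_arm_sites = 8L,
    antigen_per_fdc = 3000,
    # Tfh
    tfh_count = 200L,
    tfh_signal_rate_per_h = 1,
    tfh_signal_threshold = 2.5,
    tfh_signal_multiplier = 1,
    # motility
    b_speed_um_min = 7.5,
    tfh_speed_um_min = 10,
    zone_bias = 0.9,
    neighborhood = "moore",
    # division cycle / SHM
    cycle_h = 7,
    cycle_jitter = 0.3,
    p_mutation = 0.5,
    mutation_silent_h = 24,
    # LZ selection
    cc_lifetime_h = 10,
    capture_rate_per_h = 8,
    fdc_site_saturation = 20,
    pmhc_cap = 8L,
    div_min = 1L,
    div_max = 6L,
    div_slope = 1.1,
    p_output = 0.3,
    # antibody feedback
    endogenous_feedback = TRUE,
    ab_kd_bins = 10L,
    ab_kd_min_nm = 1,
    ab_kd_max_nm = 1000,
    ab_kd_scale_nm = 1,
    ab_production_rate_nm_per_cell_h = 3e-6,
    ab_secretion_delay_h = 48,
    inject_day = NA_real_,
    inject_kd_nm = NA_real_,
    inject_dose_nm = 10,
    mask_update_h = 1,
    # run control
    dt_h = 1 / 120,
    horizon_days = 21,
    record_every_h = 4,
    extinction_threshold = 10L,
    collapse_check_after_h = 96
  )
  dots <- list(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(names(dots) == "")) {
      stop("all configuration overrides must be named")
    }
    unknown <- setdiff(names(dots), names(cfg))
    if (length(unknown)) {
      stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
    }
    cfg[names(dots)] <- dots
  }
  validate_gc_config(structure(cfg, class = "gc_config"))
}

validate_gc_config <- function(cfg) {
  with(cfg, {
    stopifnot(
      shape_dim >= 1, shape_side >= 2,
      affinity_gamma > 0, affinity_eta > 0,
      founder_rate_per_h >= 0, founder_stop_h >= 0,
      founder_d_min >= 0, founder_d_max >= founder_d_min,
      founder_d_max <= shape_dim * (shape_side - 1),
      founder_initial_divisions >= 0,
      lattice_radius_um > 0, lattice_spacing_um > 0,
      fdc_count >= 0, fdc_arm_sites >= 0, antigen_per_fdc >= 0,
      tfh_count >= 0, tfh_signal_rate_per_h >= 0,
      tfh_signal_threshold > 0, tfh_signal_multiplier >= 0,
      b_speed_um_min >= 0, tfh_speed_um_min >= 0,
      zone_bias >= 0, zone_bias <= 1,
      neighborhood %in% c("moore", "vonneumann"),
      cycle_h > 0, cycle_jitter >= 0, cycle_jitter < 1,
      p_mutation >= 0, p_mutation <= 1, mutation_silent_h >= 0,
      cc_lifetime_h > 0, capture_rate_per_h >= 0, fdc_site_saturation >= 1,
      pmhc_cap >= 1,
      div_min >= 0, div_max >= div_min, div_slope >= 0,
      p_output >= 0, p_output <= 1,
      ab_kd_bins >= 1, ab_kd_min_nm > 0, ab_kd_max_nm >= ab_kd_min_nm,
      ab_kd_scale_nm > 0, ab_production_rate_nm_per_cell_h >= 0,
      ab_secretion_delay_h >= 0, inject_dose_nm >= 0, mask_update_h > 0,
      dt_h > 0, horizon_days >= 0, record_every_h > 0,
      extinction_threshold >= 1, collapse_check_after_h >= 0
    )
    if (!is.na(inject_day) && is.na(inject_kd_nm)) {
      stop("inject_day set but inject_kd_nm missing")
    }
  })
  # keep per-step move probabilities (speed*dt/spacing) at most 1 so realized
  # speeds match configured speeds
  vmax <- max(cfg$b_speed_um_min, cfg$tfh_speed_um_min) * 60
  if (vmax * cfg$dt_h / cfg$lattice_spacing_um > 1 + 1e-9) {
    stop("dt_h too large for configured cell speeds: need dt <= ",
         signif(cfg$lattice_spacing_um / vmax, 3), " h")
  }
  cfg
}

#' @export
print.gc_config <- function(x, ...) {
  cat("<gc_config>\n")
  cat(sprintf("  antigen/FDC %s, Tfh %d (multiplier %g), founders d in [%d,%d]\n",
              format(x$antigen_per_fdc), x$tfh_count, x$tfh_signal_multiplier,
              x$founder_d_min, x$founder_d_max))
  inj <- if (is.na(x$inject_day)) "none" else
    sprintf("Kd %g nM at day %g", x$inject_kd_nm, x$inject_day)
  cat(sprintf("  feedback: endogenous %s, injection %s\n",
              if (x$endogenous_feedback) "on" else "off", inj))
  cat(sprintf("  horizon %g d, dt %g h, record every %g h\n",
              x$horizon_days, x$dt_h, x$record_every_h))
  invisible(x)
}

#' Read or write a configuration as YAML
#'
#' @param path file path.
#' @param cfg a [gc_config()] object.
#' @return `read_gc_config()` returns a `gc_config`; `write_gc_config()`
#'   returns `path` invisibly.
#' @export
read_gc_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(gc_config, vals)
}

#' @rdname read_gc_config
#' @export
write_gc_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "gc_config"))
  yaml::write_yaml(unclass(cfg), path, precision = 17L)
  invisible(path)
}

#' The affinity model implied by a configuration
#'
#' The antigen's optimal point is placed at the lattice center.
#' @param cfg a [gc_config()].
#' @return an [affinity_model()].
#' @export
config_affinity_model <- function(cfg) {
  affinity_model(
    optimal = rep(cfg$shape_side %/% 2L, cfg$shape_dim),
    gamma = cfg$affinity_gamma, eta = cfg$affinity_eta,
    side = cfg$shape_side
  )
}
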