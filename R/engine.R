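#' Sample the founder-cell influx schedule
#'
#' Founder B cells enter the GC as a Poisson process at `rate` cells per hour
#' until `stop_h` hours (defaults 2/h until 96 h, giving ~180-200 clonally
#' distinct founders). Each founder receives a fresh clone identity.
#'
#' @param rate entry rate (cells/hour).
#' @param stop_h end of the influx window (hours).
#' @return numeric vector of sorted entry times in hours.
#' @export
founder_influx <- function(rate = 2, stop_h = 96) {
  n <- stats::rpois(1L, rate * stop_h)
  sort(stats::runif(n, 0, stop_h))
}

#' Equilibrium masked fraction of FDC antigen under an antibody pool
#'
#' Competitive Langmuir binding of soluble antibody species (concentrations
#' `conc`, dissociation constants `kd`, same units) to a single epitope:
#' theta = S / (1 + S) with S = sum(conc / kd). An empty pool gives 0; a
#' single species at `conc == kd` gives 0.5.
#'
#' @param conc non-negative concentrations (nM).
#' @param kd positive dissociation constants (nM).
#' @return the total occupied (masked) fraction in `[0, 1)`.
#' @export
masked_fraction <- function(conc, kd) {
  if (length(conc) == 0L) return(0)
  cpp_masked_theta(as.numeric(conc), as.numeric(kd))
}

#' Dynamic number of divisions granted at positive selection
#'
#' Selected centrocytes re-enter the dark zone with a number of divisions
#' that increases with the amount of captured antigen they displayed as
#' pMHC: `clamp(div_min + round(slope * log(pmhc)), div_min, div_max)`.
#' The default slope is calibrated so the run-average under the default
#' configuration falls in the experimentally observed 2-2.5 range.
#'
#' @param pmhc positive integer pMHC levels (captured antigen units).
#' @param cfg a [gc_config()] supplying `div_min`, `div_max`, `div_slope`.
#' @return integer division counts, non-decreasing in `pmhc`.
#' @export
dynamic_divisions <- function(pmhc, cfg = gc_config()) {
  cpp_dynamic_divisions(as.integer(pmhc), cfg$div_min, cfg$div_max,
                        cfg$div_slope)
}

#' Selection decision for a centrocyte
#'
#' A centrocyte is positively selected once its accumulated Tfh signal
#' reaches the threshold (inclusive); otherwise it dies by neglect when its
#' light-zone lifetime expires; otherwise it remains unselected.
#'
#' @param tfh_signal accumulated Tfh signal (signal units).
#' @param age_h time since becoming a centrocyte (hours).
#' @param cfg a [gc_config()].
#' @return one of `"selected"`, `"apoptotic"`, `"unselected"`.
#' @export
selection_decision <- function(tfh_signal, age_h, cfg = gc_config()) {
  stopifnot(tfh_signal >= 0, age_h >= 0)
  if (tfh_signal >= cfg$tfh_signal_threshold) "selected"
  else if (age_h > cfg$cc_lifetime_h) "apoptotic"
  else "unselected"
}

#' Run one germinal center simulation
#'
#' Simulates the full GC reaction from t = 0 to the configured horizon and
#' returns the per-timepoint clone census together with summary series and
#' run-level bookkeeping. The run is exactly reproducible: the same `cfg`
#' and `seed` give identical output.
#'
#' @param cfg a [gc_config()].
#' @param seed integer seed for the run's RNG stream.
#' @return an object of class `gc_trajectory`: a list with elements
#'   * `census`: tibble (`time_h`, `clone_id`, `count`) of live cells per
#'     founder clone at each recording time (zero counts dropped);
#'   * `summary`: tibble of per-time GC size, zone composition, mean
#'     affinity, antigen ledger and cumulative output;
#'   * `founders`, `output_count`, `collapse_h` (NA if never collapsed),
#'     `division_grants` (integer vector, one entry per positive selection),
#'     centrocyte fate counters, lattice/antigen constants, `seed`.
#' @examples
#' \donttest{
#' traj <- run_gc(gc_config(horizon_days = 1), seed = 1)
#' tail(traj$summary)
#' }
#' @export
run_gc <- function(cfg = gc_config(), seed = 1L) {
  stopifnot(inherits(cfg, "gc_config"))
  set.seed(as.integer(seed))
  model <- config_affinity_model(cfg)
  times <- founder_influx(cfg$founder_rate_per_h, cfg$founder_stop_h)
  times <- times[times <= cfg$horizon_days * 24]
  n <- length(times)
  bcr <- matrix(0L, nrow = max(n, 1L), ncol = cfg$shape_dim)
  for (i in seq_len(n)) {
    bcr[i, ] <- sample_founder_position(model, cfg$founder_d_min,
                                        cfg$founder_d_max)
  }
  raw <- cpp_run_gc(unclass(cfg), times, bcr)
  census <- tibble::as_tibble(raw$census)
  census$clone_id <- census$clone_id + 1L # 1-based clone identities
  structure(
    list(
      census = census,
      summary = tibble::as_tibble(raw$summary),
      founders = as.integer(raw$founders_admitted),
      output_count = as.integer(raw$output_count),
      collapse_h = raw$collapse_h,
      division_grants = raw$division_grants,
      cc_selected = raw$cc_selected,
      sel_pmhc_mean = raw$sel_pmhc_mean,
      cc_apoptosis_with_pmhc = raw$cc_apoptosis_with_pmhc,
      cc_apoptosis_no_pmhc = raw$cc_apoptosis_no_pmhc,
      n_sites = raw$n_sites,
      n_antigen_sites = raw$n_antigen_sites,
      initial_antigen = raw$initial_antigen,
      config = cfg,
      seed = as.integer(seed)
    ),
    class = "gc_trajectory"
  )
}

#' @export
print.gc_trajectory <- function(x, ...) {
  cat("<gc_trajectory>\n")
  cat(sprintf("  %d founders, horizon %g d, seed %d\n", x$founders,
              x$config$horizon_days, x$seed))
  n <- nrow(x$summary)
  cat(sprintf("  final size %d (peak %d), mean affinity %.3f, outputs %d\n",
              x$summary$size[n], max(x$summary$size),
              x$summary$mean_affinity[n], x$output_count))
  if (!is.na(x$collapse_h)) {
    cat(sprintf("  collapsed at day %.1f\n", x$collapse_h / 24))
  }
  invisible(x)
}

#' Write a trajectory's clone census as tidy CSV
#'
#' @param traj a `gc_trajectory`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  out <- tibble::tibble(seed = traj$seed, traj$census)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
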