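#' Define a perturbation scenario
#'
#' A scenario sweeps one configuration parameter over a set of values (one
#' condition per value) with `n_replicates` replicate GCs per condition.
#' Replicate seeds form a reproducible grid: `seed_base + replicate - 1`.
#'
#' @param name scenario label.
#' @param base a [gc_config()] shared by all conditions.
#' @param param name of the swept configuration key, or `NULL` for a single
#'   default condition. For the antibody-feedback scenario, `param` is
#'   `"condition"` and `values` is a named list of config override lists.
#' @param values vector (or named list of override lists) of swept values.
#' @param n_replicates replicate GCs per condition.
#' @param seed_base first replicate's seed.
#' @return an object of class `gc_scenario`.
#' @export
gc_scenario <- function(name, base = gc_config(), param = NULL, values = NULL,
                        n_replicates = 20L, seed_base = 1L) {
  stopifnot(n_replicates >= 1L)
  if (!is.null(param) && !identical(param, "condition")) {
    stopifnot(param %in% names(base))
  }
  structure(
    list(name = name, base = base, param = param, values = values,
         n_replicates = as.integer(n_replicates),
         seed_base = as.integer(seed_base)),
    class = "gc_scenario"
  )
}

#' Preset scenarios of the five perturbation experiments
#'
#' * `"antigen"`: 1000 / 3000 / 5000 antigen units per FDC.
#' * `"founder_affinity"`: founder mutation-distance bands 5-6 / 6-7 / 7-8.
#' * `"antibody_feedback"`: no-feedback null, exogenous Kd 500 nM and
#'   6.3 nM injections, each at day 0 and day 6 (plus the null arm).
#' * `"tfh_number"`: 100 / 200 / 300 Tfh cells.
#' * `"tfh_quality"`: Tfh signal multiplier 0.6 / 0.8 / 1.0 / 1.2.
#' * `"default"`: single condition with the default configuration.
#'
#' @param name preset name.
#' @param n_replicates replicate GCs per condition (100 reproduces the
#'   full-scale study; 20 is the reduced default).
#' @param seed_base first replicate seed.
#' @param base base configuration to perturb.
#' @return a [gc_scenario()].
#' @export
preset_scenario <- function(name = c("antigen", "founder_affinity",
                                     "antibody_feedback", "tfh_number",
                                     "tfh_quality", "default"),
                            n_replicates = 20L, seed_base = 1L,
                            base = gc_config()) {
  name <- match.arg(name)
  sc <- switch(
    name,
    antigen = gc_scenario(name, base, "antigen_per_fdc",
                          c(1000, 3000, 5000)),
    founder_affinity = gc_scenario(
      name, base, "condition",
      list(`d5_6` = list(founder_d_min = 5L, founder_d_max = 6L),
           `d6_7` = list(founder_d_min = 6L, founder_d_max = 7L),
           `d7_8` = list(founder_d_min = 7L, founder_d_max = 8L))),
    antibody_feedback = gc_scenario(
      name, base, "condition",
      list(null = list(endogenous_feedback = FALSE),
           kd500_day0 = list(inject_day = 0, inject_kd_nm = 500),
           kd6.3_day0 = list(inject_day = 0, inject_kd_nm = 6.3),
           kd500_day6 = list(inject_day = 6, inject_kd_nm = 500),
           kd6.3_day6 = list(inject_day = 6, inject_kd_nm = 6.3))),
    tfh_number = gc_scenario(name, base, "tfh_count", c(100L, 200L, 300L)),
    tfh_quality = gc_scenario(name, base, "tfh_signal_multiplier",
                              c(0.6, 0.8, 1.0, 1.2)),
    default = gc_scenario(name, base, NULL, NULL)
  )
  sc$n_replicates <- as.integer(n_replicates)
  sc$seed_base <- as.integer(seed_base)
  sc
}

condition_configs <- function(scenario) {
  if (is.null(scenario$param)) {
    cfgs <- list(default = scenario$base)
  } else if (identical(scenario$param, "condition")) {
    cfgs <- lapply(scenario$values, function(ov) {
      do.call(gc_config, utils::modifyList(
        as.list(unclass(scenario$base)), ov))
    })
  } else {
    cfgs <- lapply(scenario$values, function(v) {
      ov <- stats::setNames(list(v), scenario$param)
      do.call(gc_config, utils::modifyList(
        as.list(unclass(scenario$base)), ov))
    })
    names(cfgs) <- paste0(scenario$param, "_", scenario$values)
  }
  cfgs
}

#' Run a scenario: all conditions times all replicates
#'
#' Executes [run_gc()] for every (condition, replicate) pair and aggregates
#' each condition with [aggregate_replicates()]. When `out_dir` is given,
#' trajectory CSVs, a summary CSV, a day-18 snapshot CSV and a manifest JSON
#' are written under it; completed replicate files are skipped on re-run
#' (resumption) provided the stored config hash matches.
#'
#' @param scenario a [gc_scenario()].
#' @param out_dir optional output directory.
#' @param snapshot_day day for the snapshot table.
#' @param progress print per-replicate progress.
#' @return list with `trajectories` (condition -> list of trajectories),
#'   `summary` (tibble with a `condition` column), `snapshot` (tibble),
#'   `scenario`.
#' @export
run_scenario <- function(scenario, out_dir = NULL, snapshot_day = 18,
                         progress = FALSE) {
  stopifnot(inherits(scenario, "gc_scenario"))
  cfgs <- condition_configs(scenario)
  seeds <- scenario$seed_base + seq_len(scenario$n_replicates) - 1L
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE,
                                    recursive = TRUE)
  trajs <- list()
  for (cn in names(cfgs)) {
    hash <- config_hash(cfgs[[cn]])
    trajs[[cn]] <- lapply(seeds, function(s) {
      f <- if (is.null(out_dir)) NULL else
        file.path(out_dir, sprintf("%s_%s_seed%d.csv", scenario$name, cn, s))
      if (!is.null(f) && file.exists(f)) {
        first <- readLines(f, n = 1L)
        if (!grepl(hash, first, fixed = TRUE)) {
          stop("existing output ", f, " was produced with a different config")
        }
      }
      if (progress) message(scenario$name, " / ", cn, " / seed ", s)
      tr <- run_gc(cfgs[[cn]], seed = s)
      if (!is.null(f) && !file.exists(f)) {
        writeLines(paste0("# config_hash=", hash), f)
        out <- tibble::tibble(seed = s, tr$census)
        # header is intentional after the hash comment line
        suppressWarnings(
          utils::write.table(out, f, append = TRUE, sep = ",",
                             row.names = FALSE, quote = FALSE))
      }
      tr
    })
  }
  summary <- dplyr::bind_rows(lapply(names(trajs), function(cn) {
    dplyr::mutate(aggregate_replicates(trajs[[cn]]), condition = cn,
                  .before = 1L)
  }))
  snapshot <- dplyr::bind_rows(lapply(names(trajs), function(cn) {
    dplyr::mutate(snapshot_metrics(trajs[[cn]], day = snapshot_day),
                  condition = cn, .before = 1L)
  }))
  if (!is.null(out_dir)) {
    utils::write.csv(summary, file.path(out_dir, "summary.csv"),
                     row.names = FALSE)
    utils::write.csv(snapshot,
                     file.path(out_dir, sprintf("day%g_snapshot.csv",
                                                snapshot_day)),
                     row.names = FALSE)
    manifest <- list(
      scenario = scenario$name,
      conditions = names(cfgs),
      n_replicates = scenario$n_replicates,
      seeds = seeds,
      config_hash = vapply(cfgs, config_hash, character(1)),
      collapse_h = lapply(trajs, function(tt)
        vapply(tt, function(x) ifelse(is.na(x$collapse_h), -1, x$collapse_h),
               numeric(1)))
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  list(trajectories = trajs, summary = summary, snapshot = snapshot,
       scenario = scenario)
}

config_hash <- function(cfg) {
  s <- paste(names(cfg), vapply(cfg, function(v) paste(format(v), collapse = ","),
                                character(1)),
             sep = "=", collapse = ";")
  # small stable polynomial hash; no external digest dependency
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Synthetic clone-census fixture
#'
#' Generates clone-count trajectories with a prescribed diversity-decay
#' profile so the metrics layer can be tested against closed forms without
#' running the agent-based simulation.
#'
#' @param n_clones number of founder clones.
#' @param horizon_h duration in hours.
#' @param profile `"uniform"` (constant equal counts), `"takeover"`
#'   (deterministic geometric takeover by clone 1) or `"stochastic"`
#'   (multinomial resampling drift).
#' @param record_every_h recording cadence.
#' @param total total cells per timepoint.
#' @param rate per-hour takeover rate (profile `"takeover"`).
#' @param affinity constant mean affinity reported in the summary.
#' @return an object shaped like a [run_gc()] trajectory (census + summary),
#'   usable with [trajectory_metrics()] and [aggregate_replicates()].
#' @export
synth_census_fixture <- function(n_clones = 10L, horizon_h = 480,
                                 profile = c("uniform", "takeover",
                                             "stochastic"),
                                 record_every_h = 4, total = 1000L,
                                 rate = 0.01, affinity = 0.5) {
  profile <- match.arg(profile)
  stopifnot(n_clones >= 1L, total >= n_clones)
  times <- seq(0, horizon_h, by = record_every_h)
  # equal counts by construction (total is rounded down to a multiple)
  total <- as.integer(total %/% n_clones) * n_clones
  base <- rep(total %/% n_clones, n_clones)
  counts <- switch(
    profile,
    uniform = lapply(times, function(t) base),
    takeover = lapply(times, function(t) {
      # clone 1's share relaxes from 1/n to 1 exponentially
      w1 <- 1 - (1 - 1 / n_clones) * exp(-rate * t)
      rest <- (1 - w1) / max(1L, n_clones - 1L)
      cnt <- round(total * c(w1, rep(rest, n_clones - 1L)))
      cnt[1] <- cnt[1] + (total - sum(cnt))
      pmax(cnt, 0L)
    }),
    stochastic = {
      cur <- base
      lapply(times, function(t) {
        cur <<- as.integer(stats::rmultinom(1L, total, pmax(cur, 0) + 1e-9))
        cur
      })
    }
  )
  census <- dplyr::bind_rows(lapply(seq_along(times), function(i) {
    cnt <- counts[[i]]
    keep <- cnt > 0
    tibble::tibble(time_h = times[i], clone_id = which(keep),
                   count = as.integer(cnt[keep]))
  }))
  summary <- census |>
    dplyr::group_by(.data$time_h) |>
    dplyr::summarise(size = sum(.data$count), n_clones = dplyr::n(),
                     .groups = "drop") |>
    dplyr::mutate(mean_affinity = affinity)
  structure(
    list(census = census, summary = summary, founders = n_clones,
         collapse_h = NA_real_, division_grants = integer(),
         config = NULL, seed = NA_integer_),
    class = "gc_trajectory"
  )
}
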