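# Desk-scale configuration: full geometry but a short horizon, used where a
# test only needs the early reaction.
short_cfg <- function(...) gc_config(horizon_days = 5, ...)

test_that("masked fraction follows the competitive Langmuir isotherm", {
  expect_equal(masked_fraction(numeric(), numeric()), 0)
  expect_equal(masked_fraction(5, 5), 0.5)          # C = KD half-saturation
  expect_equal(masked_fraction(10, 500), (10 / 500) / (1 + 10 / 500))
  expect_error(masked_fraction(-1, 5), "negative")

  # two-species oracle: solve the equilibrium occupancy equations by root
  # finding (theta_i = (C_i/KD_i) (1 - theta_tot)) and compare
  kd <- c(6.3, 500); conc <- c(6.3, 500)
  f <- function(th) {
    sum((conc / kd) * (1 - th)) - th
  }
  th_oracle <- stats::uniroot(f, c(0, 1), tol = 1e-12)$root
  expect_equal(masked_fraction(conc, kd), th_oracle, tolerance = 1e-9)
  set.seed(41)
  for (i in 1:10) {
    kd <- stats::runif(3, 1, 1000); conc <- stats::runif(3, 0, 50)
    th_oracle <- stats::uniroot(function(th) sum((conc / kd) * (1 - th)) - th,
                                c(0, 1), tol = 1e-12)$root
    expect_equal(masked_fraction(conc, kd), th_oracle, tolerance = 1e-9)
  }
})

test_that("dynamic division numbers are clipped and monotone in pMHC", {
  cfg <- gc_config()
  expect_equal(dynamic_divisions(1, cfg), cfg$div_min)       # floor
  expect_equal(dynamic_divisions(10000, cfg), cfg$div_max)   # ceiling
  d <- dynamic_divisions(1:50, cfg)
  expect_true(all(diff(d) >= 0))                              # monotone
  expect_true(all(d >= cfg$div_min & d <= cfg$div_max))
  expect_error(dynamic_divisions(0, cfg), "pMHC")
})

test_that("selection decisions follow threshold and lifetime rules", {
  cfg <- gc_config()
  thr <- cfg$tfh_signal_threshold
  expect_equal(selection_decision(thr, 1, cfg), "selected")   # inclusive >=
  expect_equal(selection_decision(thr - 1e-9, cfg$cc_lifetime_h + 1, cfg),
               "apoptotic")
  expect_equal(selection_decision(0, 1, cfg), "unselected")
})

test_that("founder influx has the right rate and unique clone identities", {
  set.seed(42)
  n <- vapply(1:50, function(i) length(founder_influx(2, 96)), numeric(1))
  expect_gt(mean(n), 180); expect_lt(mean(n), 200)
  expect_length(founder_influx(0, 96), 0L)

  tr <- run_gc(gc_config(horizon_days = 5), seed = 7)
  ids <- unique(tr$census$clone_id)
  expect_true(all(ids %in% seq_len(tr$founders)))   # clone-id conservation
})

test_that("runs are exactly reproducible under a fixed seed", {
  cfg <- short_cfg()
  a <- run_gc(cfg, seed = 5)
  b <- run_gc(cfg, seed = 5)
  expect_identical(a$census, b$census)
  expect_identical(a$summary, b$summary)
  expect_identical(a$division_grants, b$division_grants)
  c <- run_gc(cfg, seed = 6)
  expect_false(identical(a$census, c$census))
})

test_that("the antigen ledger is exactly conserved", {
  # free + masked + pMHC held by live cells + consumed = initial, audited
  # inside the engine at every record; re-check the recorded series here
  tr <- run_gc(short_cfg(), seed = 8)
  s <- tr$summary
  # pMHC held is not recorded directly, but free+masked+consumed never
  # exceeds the initial total and the deficit (held pMHC) is small and
  # non-negative
  held <- tr$initial_antigen - (s$free_antigen + s$masked_antigen +
                                  s$consumed_antigen)
  expect_true(all(held >= 0))
  expect_true(all(held <= pmax(10 * s$size, 1)))
  expect_equal(s$free_antigen[1] + s$masked_antigen[1], tr$initial_antigen)
})

test_that("zero influx gives an empty, fixed-point GC", {
  tr <- run_gc(gc_config(founder_rate_per_h = 0, horizon_days = 2), seed = 9)
  expect_equal(tr$founders, 0L)
  expect_true(all(tr$summary$size == 0))
  expect_equal(nrow(tr$census), 0L)
})

test_that("horizon zero yields only the initial state", {
  tr <- run_gc(gc_config(horizon_days = 0), seed = 10)
  expect_equal(nrow(tr$summary), 1L)
  expect_equal(tr$summary$time_h, 0)
})

test_that("silent-phase mutation switch controls SHM", {
  # no mutations possible: every BCR stays on a founder's position, so every
  # clone keeps a single shape-space distance class
  cfg <- gc_config(horizon_days = 4, p_mutation = 0)
  tr <- run_gc(cfg, seed = 11)
  expect_gt(nrow(tr$census), 0)
  # mutation off: mean affinity equals the founder band's affinities only
  model <- config_affinity_model(cfg)
  a_lo <- bcr_affinity(sample_founder_position(model, 6, 6), model)
  a_hi <- bcr_affinity(sample_founder_position(model, 5, 5), model)
  aff <- tr$summary$mean_affinity[tr$summary$size > 0]
  expect_true(all(aff >= a_lo - 1e-9 & aff <= a_hi + 1e-9))
})

test_that("a GC without Tfh help cannot select and dies before day 7", {
  for (s in 1:2) {
    tr <- run_gc(gc_config(tfh_count = 0, horizon_days = 8), seed = 100 + s)
    expect_false(is.na(tr$collapse_h))
    expect_lt(tr$collapse_h / 24, 7)
    expect_equal(length(tr$division_grants), 0L)
  }
})

test_that("abundant Tfh help and antigen approach non-competitive selection", {
  # stress limit: selection capacity >> demand, so nearly every centrocyte
  # that has captured antigen is positively selected
  # few founders + an oversupply of Tfh and antigen, so centrocytes rarely
  # compete for help
  cfg <- gc_config(tfh_count = 2000, antigen_per_fdc = 50000,
                   founder_rate_per_h = 0.5, horizon_days = 5,
                   founder_d_min = 3, founder_d_max = 4)
  tr <- run_gc(cfg, seed = 12)
  frac <- tr$cc_selected / (tr$cc_selected + tr$cc_apoptosis_with_pmhc)
  expect_gt(frac, 0.8)
})

test_that("antibody injection masks antigen and shrinks the GC", {
  base <- gc_config(horizon_days = 6, endogenous_feedback = FALSE)
  inj <- gc_config(horizon_days = 6, endogenous_feedback = FALSE,
                   inject_day = 0, inject_kd_nm = 6.3)
  t0 <- run_gc(base, seed = 13)
  t1 <- run_gc(inj, seed = 13)
  expect_equal(max(t0$summary$masked_fraction), 0)
  th <- masked_fraction(inj$inject_dose_nm, 6.3)
  expect_equal(max(t1$summary$masked_fraction), th, tolerance = 1e-6)
  expect_lt(tail(t1$summary$size, 1), tail(t0$summary$size, 1))
})

test_that("Tfh signal multiplier scales accumulated signal linearly", {
  # pure-rate check through the engine: with multiplier m the same contact
  # history yields m-fold signal, so the selection threshold is reached
  # after threshold/(rate*m) hours of polarized contact; verify through the
  # selection count ordering on identical seeds
  lo <- run_gc(gc_config(tfh_signal_multiplier = 0.6, horizon_days = 6),
               seed = 14)
  hi <- run_gc(gc_config(tfh_signal_multiplier = 1.2, horizon_days = 6),
               seed = 14)
  expect_gt(hi$cc_selected, lo$cc_selected)
})

test_that("configuration validation rejects invalid inputs", {
  expect_error(gc_config(p_mutation = 1.5))
  expect_error(gc_config(unknown_key = 1), "unknown")
  expect_error(gc_config(dt_h = 0.5), "dt_h too large")
  expect_error(gc_config(inject_day = 0), "inject_kd_nm")
})

test_that("configs round-trip through YAML", {
  cfg <- gc_config(antigen_per_fdc = 1000, tfh_count = 300)
  f <- tempfile(fileext = ".yaml")
  write_gc_config(cfg, f)
  cfg2 <- read_gc_config(f)
  expect_equal(unclass(cfg)[order(names(cfg))],
               unclass(cfg2)[order(names(cfg2))])
  unlink(f)
})
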