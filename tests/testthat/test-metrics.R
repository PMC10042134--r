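test_that("fcSE matches the entropy formula", {
  expect_equal(fcse(c(100)), 0)                       # monoclonal
  expect_equal(fcse(rep(25, 4)), log(4))              # uniform
  expect_equal(fcse(c(60, 30, 10)),
               -(0.6 * log(0.6) + 0.3 * log(0.3) + 0.1 * log(0.1)))
  expect_equal(fcse(c(60, 30, 10)), 0.8979, tolerance = 1e-4)
  expect_equal(fcse(integer()), 0)                    # collapsed convention
  expect_equal(fcse(c(5, 0, 5)), log(2))              # zero counts dropped
  expect_error(fcse(c(3, -1)), "non-negative")
})

test_that("fcSE is bounded by log(N) and falls under majorization", {
  set.seed(21)
  for (i in 1:20) {
    n <- sample(2:30, 1)
    cnt <- stats::rpois(n, 40) + 1L
    h <- fcse(cnt)
    expect_gte(h, 0)
    expect_lte(h, log(n) + 1e-12)
    # move one cell from a minority clone to the dominant clone
    j_dom <- which.max(cnt)
    j_min <- which(cnt == min(cnt))[1]
    if (j_dom != j_min && cnt[j_min] > 1) {
      cnt2 <- cnt
      cnt2[j_dom] <- cnt2[j_dom] + 1L
      cnt2[j_min] <- cnt2[j_min] - 1L
      expect_lt(fcse(cnt2), h)
    }
  }
})

test_that("clonal dominance is the top clone's mole fraction", {
  expect_equal(clonal_dominance(c(60, 30, 10)), 0.6)
  expect_equal(clonal_dominance(rep(7, 10)), 1 / 10)
  expect_equal(clonal_dominance(c(42)), 1)
  expect_equal(clonal_dominance(integer()), 1)        # collapsed convention
  set.seed(22)
  for (i in 1:20) {
    cnt <- stats::rpois(8, 30) + 1L
    expect_gte(clonal_dominance(cnt), 1 / 8)
  }
  expect_equal(clonal_dominance(rep(3, 8)), 1 / 8)
})

test_that("CGR is the exact product of affinity and entropy", {
  expect_equal(cgr(0.5, 2.0), 1.0)
  expect_equal(cgr(0.8, 0), 0)
  expect_equal(cgr(1.0, log(4)), log(4))
  expect_error(cgr(1.5, 1), ">= 0|<=")
})

test_that("fcSE = 0 iff dominance = 1 on non-empty censuses", {
  set.seed(23)
  for (i in 1:20) {
    cnt <- stats::rpois(sample(1:6, 1), 10) + 1L
    h <- fcse(cnt); d <- clonal_dominance(cnt)
    expect_equal(h == 0, d == 1)
  }
})

test_that("trajectory metrics satisfy the CGR identity at all times", {
  f <- synth_census_fixture(n_clones = 8, horizon_h = 200,
                            profile = "takeover", rate = 0.02,
                            affinity = 0.4)
  m <- trajectory_metrics(f)
  expect_equal(m$cgr, m$mean_affinity * m$fcse)
  expect_true(all(m$fcse >= 0))
  expect_true(all(m$dominance >= 1 / 8 - 1e-12 & m$dominance <= 1))
})

test_that("aggregation matches a naive per-timepoint loop oracle", {
  set.seed(24)
  trajs <- lapply(1:4, function(i)
    synth_census_fixture(n_clones = 6, horizon_h = 96,
                         profile = "stochastic", total = 300))
  agg <- aggregate_replicates(trajs)
  mets <- lapply(trajs, trajectory_metrics)
  times <- mets[[1]]$time_h
  for (tt in times[c(1, 7, 13, 25)]) {
    vals <- vapply(mets, function(m) m$fcse[m$time_h == tt], numeric(1))
    row <- agg[agg$time_h == tt & agg$metric == "fcse", ]
    expect_equal(row$mean, mean(vals))
    expect_equal(row$sd, stats::sd(vals))
    expect_equal(row$n, 4L)
  }
})

test_that("identical replicates aggregate with zero dispersion", {
  f <- synth_census_fixture(n_clones = 5, horizon_h = 48, profile = "uniform")
  agg <- aggregate_replicates(list(f, f, f))
  expect_true(all(agg$sd == 0))
  expect_equal(unique(agg$mean[agg$metric == "fcse"]), log(5))
})

test_that("collapsed GCs enter averages as zero affinity/size/fcSE", {
  live <- synth_census_fixture(n_clones = 4, horizon_h = 96,
                               profile = "uniform", affinity = 0.6)
  dead <- synth_census_fixture(n_clones = 4, horizon_h = 96,
                               profile = "uniform", affinity = 0.6)
  dead$collapse_h <- 48
  agg <- aggregate_replicates(list(live, dead))
  aff <- agg[agg$metric == "mean_affinity", ]
  expect_equal(aff$mean[aff$time_h < 48], rep(0.6, sum(aff$time_h < 48)))
  expect_equal(aff$mean[aff$time_h >= 48], rep(0.3, sum(aff$time_h >= 48)))
  ent <- agg[agg$metric == "fcse", ]
  expect_equal(ent$mean[ent$time_h >= 48],
               rep(log(4) / 2, sum(ent$time_h >= 48)))
  dom <- agg[agg$metric == "dominance", ]
  expect_equal(dom$mean[dom$time_h >= 48],
               rep((0.25 + 1) / 2, sum(dom$time_h >= 48)))
  # drop rule removes the collapsed replicate instead
  agg2 <- aggregate_replicates(list(live, dead), rule = "drop")
  aff2 <- agg2[agg2$metric == "mean_affinity", ]
  expect_equal(unique(aff2$mean), 0.6)
  expect_equal(aff2$n[aff2$time_h >= 48], rep(1L, sum(aff2$time_h >= 48)))
})

test_that("snapshot picks the recorded timepoint nearest the requested day", {
  f <- synth_census_fixture(n_clones = 3, horizon_h = 480,
                            profile = "uniform", record_every_h = 7)
  snap <- snapshot_metrics(list(f), day = 18)
  expect_equal(snap$time_h, f$summary$time_h[
    which.min(abs(f$summary$time_h - 432))])
  expect_equal(snap$fcse, log(3))
})

test_that("fixture profiles behave as designed", {
  u <- synth_census_fixture(n_clones = 7, horizon_h = 120, profile = "uniform")
  mu <- trajectory_metrics(u)
  expect_equal(mu$fcse, rep(log(7), nrow(mu)))         # flat at ln(n)
  tk <- synth_census_fixture(n_clones = 7, horizon_h = 2000,
                             profile = "takeover", rate = 0.01)
  mt <- trajectory_metrics(tk)
  expect_lt(mt$fcse[nrow(mt)], 0.05)                    # -> monoclonal
  expect_gt(mt$dominance[nrow(mt)], 0.99)
  expect_true(all(diff(mt$fcse) < 1e-9))                # monotone decay
  expect_true(all(diff(mt$dominance) > -1e-9))
})
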