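test_that("mutation distance is the L1 metric", {
  expect_identical(mutation_distance(c(1, 2, 3, 4), c(1, 2, 3, 4)), 0L)
  expect_identical(mutation_distance(c(0, 0, 0, 0), c(1, 2, 0, 0)), 3L)
  expect_error(mutation_distance(c(1, 2), c(1, 2, 3)), "dimension")

  # brute-force per-component loop oracle on random points
  set.seed(11)
  for (i in 1:50) {
    p <- sample(0:9, 4, replace = TRUE)
    q <- sample(0:9, 4, replace = TRUE)
    acc <- 0L
    for (k in 1:4) acc <- acc + abs(p[k] - q[k])
    expect_identical(mutation_distance(p, q), acc)
    expect_identical(mutation_distance(q, p), acc) # symmetry
  }
})

test_that("distance satisfies identity and triangle inequality", {
  set.seed(12)
  for (i in 1:30) {
    p <- sample(0:9, 4, TRUE); q <- sample(0:9, 4, TRUE)
    r <- sample(0:9, 4, TRUE)
    expect_identical(mutation_distance(p, p), 0L)
    expect_lte(mutation_distance(p, r),
               mutation_distance(p, q) + mutation_distance(q, r))
  }
})

test_that("affinity follows the Gaussian form and its contracts", {
  m <- affinity_model(gamma = 2.8, eta = 2)
  expect_equal(affinity(0, m), 1.0)
  # hand evaluation of exp(-(5/2.8)^2)
  expect_equal(affinity(5, m), exp(-(5 / 2.8)^2), tolerance = 1e-12)
  expect_equal(affinity(5, m), 0.0412, tolerance = 1e-2)
  d <- 0:20
  a <- affinity(d, m)
  expect_true(all(diff(a) < 0))        # strictly decreasing
  expect_true(all(a > 0 & a <= 1))
  # permutation invariance through the distance metric
  p <- c(1, 5, 2, 8); q <- c(4, 4, 4, 4)
  expect_equal(affinity(mutation_distance(p, q), m),
               affinity(mutation_distance(q, p), m))
})

test_that("somatic hypermutation moves exactly one unit and respects bounds", {
  set.seed(13)
  p <- c(5L, 5L, 5L, 5L)
  for (i in 1:50) {
    q <- mutate_bcr(p)
    expect_identical(mutation_distance(p, q), 1L)
    expect_true(all(q >= 0 & q <= 9))
  }
  # boundary clipping: component at 0 never goes negative
  b <- c(0L, 0L, 0L, 0L)
  for (i in 1:50) {
    q <- mutate_bcr(b)
    expect_true(all(q >= 0))
    expect_identical(mutation_distance(b, q), 1L)
  }
  # k sequential mutations move at most k (triangle inequality)
  q <- p
  for (k in 1:10) {
    q <- mutate_bcr(q)
    expect_lte(mutation_distance(p, q), k)
  }
})

test_that("mutation is uniform over the 2D interior neighbors", {
  set.seed(14)
  p <- c(5L, 5L, 5L, 5L)
  n <- 8000
  draws <- vapply(seq_len(n), function(i) {
    q <- mutate_bcr(p)
    k <- which(q != p)
    paste0(k, ifelse(q[k] > p[k], "+", "-"))
  }, character(1))
  tab <- table(draws)
  expect_length(tab, 8L)
  chi <- suppressWarnings(stats::chisq.test(tab))
  expect_gt(chi$p.value, 1e-4)
})

test_that("founder sampling respects the requested distance band", {
  m <- affinity_model()
  set.seed(15)
  d56 <- replicate(300, mutation_distance(
    sample_founder_position(m, 5, 6), m$optimal))
  expect_true(all(d56 %in% 5:6))
  d78 <- replicate(1000, mutation_distance(
    sample_founder_position(m, 7, 8), m$optimal))
  expect_setequal(unique(d78), 7:8)
  # degenerate band returns the optimum itself
  expect_identical(sample_founder_position(m, 0, 0), m$optimal)
  # founders never exceed the band's best affinity
  affs <- affinity(d56, m)
  expect_true(all(affs <= affinity(5, m) + 1e-12))
  expect_error(sample_founder_position(m, 30, 36), "no lattice point")
})

test_that("founder sampling is uniform within a distance shell", {
  # oracle: enumerate all points at distance 2 from the optimum in a tiny
  # 2-D shape space and compare empirical frequencies
  m <- affinity_model(optimal = c(2, 2), gamma = 2.8, eta = 2, side = 5)
  pts <- expand.grid(x = 0:4, y = 0:4)
  shell <- pts[abs(pts$x - 2) + abs(pts$y - 2) == 2, ]
  set.seed(16)
  draws <- replicate(4000, paste(sample_founder_position(m, 2, 2),
                                 collapse = ","))
  tab <- table(draws)
  expect_length(tab, nrow(shell))
  chi <- suppressWarnings(stats::chisq.test(tab))
  expect_gt(chi$p.value, 1e-4)
})
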