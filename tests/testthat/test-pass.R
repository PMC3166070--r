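test_that("per-pair similarity has its closed forms and symmetries", {
  expect_identical(pair_similarity(c(1, 1), c(1, 1)), 1)
  # orthogonal unit points: 1 - sqrt(2)/2
  expect_equal(pair_similarity(c(1, 0), c(0, 1)), 1 - sqrt(2) / 2,
               tolerance = 1e-12)
  expect_equal(pair_similarity(c(1, 1e-4), c(1e-4, 1)), 1 - sqrt(2) / 2,
               tolerance = 1e-3)

  set.seed(2)
  for (r in 1:20) {
    p <- runif(2, 0.1, 2)
    q <- runif(2, 0.1, 2)
    s <- pair_similarity(p, q)
    expect_gt(s, 0)
    expect_lte(s, 1)
    expect_equal(s, pair_similarity(q, p))                      # symmetry
    expect_equal(s, pair_similarity(3.7 * p, 3.7 * q))          # scale invariance
    # w_theta scales the temperature axis before the norms
    w <- runif(1, 0.3, 3)
    expect_equal(pair_similarity(p, q, w_theta = w),
                 pair_similarity(p * c(1, w), q * c(1, w)))
  }
  expect_equal(pair_similarity(c(2, 2), c(1, 1)), 1 - 1 / 3)  # collinear case
})

test_that("optimal matching equals exhaustive enumeration and keeps contracts", {
  set.seed(31)
  for (r in 1:30) {
    a <- random_profile("a", sample(2:6, 1))
    b <- random_profile("b", sample(2:6, 1))
    opt <- match_spiddos(a, b, pass_config(mode = "optimal"))
    exh <- match_spiddos(a, b, pass_config(mode = "exhaustive"))
    expect_equal(opt$total, exh$total, tolerance = 1e-12)
    k <- min(n_spiddos(a), n_spiddos(b))
    expect_equal(nrow(opt$pairs), k)
    expect_false(anyDuplicated(opt$pairs[, 1]) > 0)
    expect_false(anyDuplicated(opt$pairs[, 2]) > 0)
  }
})

test_that("matching respects the min(nA, nB) size contract", {
  set.seed(5)
  a <- random_profile("a", 5)
  b <- random_profile("b", 3)
  m <- match_spiddos(a, b)
  expect_equal(nrow(m$pairs), 3L)
  expect_length(m$unmatched_a, 2L)
  expect_length(m$unmatched_b, 0L)

  ident <- match_spiddos(a, a)
  expect_equal(ident$pairs[, "i"], ident$pairs[, "j"])
  expect_equal(ident$total, 5)
})

test_that("tie-breaking returns the lexicographically smallest pair list", {
  # two identical points on each side: all four matchings are optimal
  a <- genome_profile("a", mu = c(1, 1), theta = c(1, 1))
  b <- genome_profile("b", mu = c(1, 1), theta = c(1, 1))
  m <- match_spiddos(a, b)
  expect_equal(unname(m$pairs), cbind(c(1L, 2L), c(1L, 2L)))
  expect_equal(m$pass_value, 1)
})

test_that("exhaustive mode refuses oversized problems with guidance", {
  set.seed(8)
  a <- random_profile("a", 9)
  b <- random_profile("b", 9)
  expect_error(match_spiddos(a, b, pass_config(mode = "exhaustive")), "optimal")
})

test_that("monotone mode returns the best order-preserving matching", {
  set.seed(41)
  # order-preserving total can never beat the unconstrained optimum
  for (r in 1:10) {
    a <- random_profile("a", sample(3:6, 1))
    b <- random_profile("b", sample(3:6, 1))
    mono <- match_spiddos(a, b, pass_config(mode = "monotone"))
    opt <- match_spiddos(a, b, pass_config(mode = "optimal"))
    expect_lte(mono$total, opt$total + 1e-12)
    expect_equal(nrow(mono$pairs), min(n_spiddos(a), n_spiddos(b)))
    expect_true(all(diff(mono$pairs[, 1]) > 0))
    expect_true(all(diff(mono$pairs[, 2]) > 0))
  }
  # on identical profiles the diagonal is order-preserving and optimal
  a <- random_profile("a", 5)
  mono <- match_spiddos(a, a, pass_config(mode = "monotone"))
  expect_equal(mono$total, 5, tolerance = 1e-12)
})

test_that("PaSS satisfies its contract suite", {
  set.seed(51)
  a <- random_profile("a", 7)
  b <- random_profile("b", 5)
  expect_identical(pass_score(a, a), 1)
  p <- pass_score(a, b)
  expect_gt(p, 0)
  expect_lte(p, 1)
  expect_equal(p, pass_score(b, a), tolerance = 1e-12)          # symmetry

  # permuting one profile's spiddo order changes nothing (order-free matching)
  perm <- sample(5)
  b_perm <- genome_profile("b", mu = b$spiddos$mu[perm], theta = b$spiddos$theta[perm])
  expect_equal(p, pass_score(a, b_perm), tolerance = 1e-12)

  # common rescaling of both profiles changes nothing
  sc <- function(pr, c_) genome_profile(pr$label, mu = pr$spiddos$mu * c_,
                                        theta = pr$spiddos$theta * c_)
  expect_equal(p, pass_score(sc(a, 2.5), sc(b, 2.5)), tolerance = 1e-12)

  # single-spiddo profiles reduce to the per-pair term
  s1 <- genome_profile("s1", mu = 1, theta = 1e-4)
  s2 <- genome_profile("s2", mu = 1e-4, theta = 1)
  expect_equal(pass_score(s1, s2), pair_similarity(c(1, 1e-4), c(1e-4, 1)),
               tolerance = 1e-12)

  # size penalty multiplies by k / max(nA, nB)
  cfgp <- pass_config(size_penalty = TRUE)
  expect_equal(pass_score(a, b, cfgp), p * 5 / 7, tolerance = 1e-12)
})

test_that("genome distance is the PaSS complement with metric-like basics", {
  set.seed(61)
  a <- random_profile("a", 6)
  b <- random_profile("b", 6)
  expect_identical(genome_distance(a, a), 0)
  d <- genome_distance(a, b)
  expect_equal(d, 1 - pass_score(a, b))
  expect_gte(d, 0)
  expect_lt(d, 1)
  expect_equal(d, genome_distance(b, a), tolerance = 1e-12)
})

test_that("distance matrix is symmetric, zero-diagonal and consistent", {
  set.seed(71)
  profiles <- lapply(sprintf("sp%d", 1:6), random_profile, n = 8)
  d <- genome_distance_matrix(profiles)
  expect_equal(d, t(d), tolerance = 1e-12)
  expect_equal(diag(d), setNames(rep(0, 6), rownames(d)))
  expect_equal(d["sp2", "sp5"], genome_distance(profiles[[2]], profiles[[5]]))

  same <- lapply(c("x", "y", "z"), function(l) {
    genome_profile(l, mu = c(0.5, 1.5), theta = c(0.8, 1.2))
  })
  expect_true(all(genome_distance_matrix(same) == 0))

  dup <- profiles
  dup[[2]] <- genome_profile("sp1", mu = 1, theta = 1)
  expect_error(genome_distance_matrix(dup), "duplicate")
})

test_that("mean PaSS decreases as Gaussian jitter grows", {
  set.seed(81)
  sigmas <- c(0, 0.01, 0.05, 0.1)
  reps <- 60
  base <- random_profile("base", 12)
  means <- vapply(sigmas, function(s) {
    mean(vapply(seq_len(reps), function(r) {
      jit <- genome_profile(
        "jit",
        mu = pmax(base$spiddos$mu + rnorm(12, 0, s), 0.05),
        theta = pmax(base$spiddos$theta + rnorm(12, 0, s), 0.05)
      )
      pass_score(base, jit)
    }, 0))
  }, 0)
  expect_equal(means[1], 1)
  expect_true(all(diff(means) < 0))
})
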