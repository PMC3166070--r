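test_that("normalization is the componentwise ratio to the reference point", {
  ref <- reference_point(20, 60)
  expect_equal(normalize_point(20, 60, ref), cbind(mu = 1, theta = 1))
  expect_equal(normalize_point(10, 30, ref), cbind(mu = 0.5, theta = 0.5))

  # batch of 3 points against independent per-element division
  mob <- c(5, 12.5, 31)
  tem <- c(22, 48.4, 61)
  got <- normalize_point(mob, tem, ref)
  for (k in 1:3) {
    expect_equal(got[k, "mu"], mob[k] / 20, ignore_attr = TRUE)
    expect_equal(got[k, "theta"], tem[k] / 60, ignore_attr = TRUE)
  }
})

test_that("normalization is scale-equivariant and rejects bad input", {
  set.seed(11)
  mob <- runif(6, 1, 40)
  tem <- runif(6, 20, 64)
  for (c_mob in c(0.5, 3)) {
    a <- normalize_point(mob, tem, reference_point(18, 55))
    b <- normalize_point(mob * c_mob, tem, reference_point(18 * c_mob, 55))
    expect_equal(a, b, tolerance = 1e-12)
  }
  expect_error(reference_point(-1, 60), "invalid reference")
  expect_error(reference_point(10, 0), "invalid reference")
  expect_error(normalize_point(Inf, 30, reference_point(10, 50)), "finite")
  expect_error(normalize_point(-2, 30, reference_point(10, 50)), "> 0")
})

test_that("normalize_profile assigns serial indices and round-trips", {
  ref <- reference_point(20, 60)
  p1 <- normalize_profile(20, 60, ref, "single")
  expect_s3_class(p1, "gp_profile")
  expect_equal(p1$spiddos$index, 1L)
  expect_equal(p1$spiddos$mu, 1)
  expect_equal(p1$spiddos$theta, 1)

  set.seed(4)
  mob <- runif(4, 5, 35)
  tem <- runif(4, 25, 62)
  p <- normalize_profile(mob, tem, ref, "four")
  expect_equal(p$spiddos$index, 1:4)
  expect_equal(n_spiddos(p), 4L)
  # denormalizing recovers the raw coordinates
  expect_equal(p$spiddos$mu * 20, mob, tolerance = 1e-12)
  expect_equal(p$spiddos$theta * 60, tem, tolerance = 1e-12)

  expect_error(normalize_profile(numeric(), numeric(), ref, "x"), "empty profile")
})

test_that("genome_profile enforces its invariants", {
  expect_error(genome_profile("", mu = 1, theta = 1), "non-empty")
  expect_error(genome_profile("x", mu = numeric(), theta = numeric()), "empty profile")
  expect_error(genome_profile("x", mu = c(1, -1), theta = c(1, 1)), "> 0")
  expect_error(genome_profile("x", mu = c(1, 1), theta = c(1, 1), index = c(2, 2)),
               "strictly increasing")
})

test_that("spiddos TSV writing and reading is a lossless round trip", {
  set.seed(21)
  profiles <- list(
    random_profile("alpha", 5),
    random_profile("beta", 3),
    random_profile("gamma sp.", 7)
  )
  names(profiles) <- vapply(profiles, `[[`, "", "label")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_spiddos(profiles, path)
  back <- read_spiddos(path)
  expect_identical(names(back), names(profiles))
  for (lab in names(profiles)) {
    expect_equal(back[[lab]]$spiddos, profiles[[lab]]$spiddos, tolerance = 1e-9)
  }
})

test_that("spiddos TSV parser reports malformed input with line numbers", {
  path <- withr::local_tempfile(fileext = ".tsv")

  writeLines(c("label\tindex\tmu\ttheta",
               "a\t1\t0.5\t0.6",
               "a\t2\tnot_a_number\t0.7"), path)
  expect_error(read_spiddos(path), "line 3.*non-numeric")

  writeLines(c("label\tindex\tmu\ttheta",
               "a\t1\t0.5\t0.6",
               "b\t1\t0.4\t0.6",
               "a\t2\t0.5\t0.6"), path)
  expect_error(read_spiddos(path), "duplicate label 'a'")

  writeLines(c("# a comment", "label\tindex\tmu\ttheta"), path)
  expect_identical(read_spiddos(path), structure(list(), names = character()))

  writeLines(c("label\tindex\tmu\ttheta", "a\t1\t0.5"), path)
  expect_error(read_spiddos(path), "line 2.*4 tab-separated")
})

test_that("raw feature-point files normalize through the @ref directive", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("@ref\t20\t60",
               "label\tindex\tmobility\ttemperature",
               "a\t1\t20\t60",
               "a\t2\t10\t30",
               "b\t1\t5\t15"), path)
  got <- read_raw_points(path)
  expect_equal(got$a$spiddos$mu, c(1, 0.5))
  expect_equal(got$a$spiddos$theta, c(1, 0.5))
  expect_equal(got$b$spiddos$mu, 0.25)

  writeLines(c("label\tindex\tmobility\ttemperature", "a\t1\t20\t60"), path)
  expect_error(read_raw_points(path), "@ref")
})
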