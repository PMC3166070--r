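caterpillar <- function() from_newick("((A:1,B:1):1,C:2);")
balanced4 <- function() from_newick("((A:1,B:1):1,(C:1,D:1):1);")
star4 <- function() from_newick("(A:2,B:2,C:2,D:2);")

test_that("clusters_of returns the internal-node leaf sets except the root", {
  cs <- clusters_of(caterpillar())
  expect_length(cs, 1L)
  expect_identical(cs[[1]]$labels, c("A", "B"))
  expect_equal(cs[[1]]$height, 1)

  cs <- clusters_of(balanced4())
  expect_length(cs, 2L)
  expect_identical(lapply(cs, `[[`, "labels"), list(c("A", "B"), c("C", "D")))

  expect_length(clusters_of(star4()), 0L)
})

test_that("clusters_of restricts to a shared leaf set before extraction", {
  t1 <- from_newick("((((A:1,B:1):1,C:2):1,D:3):1,E:4);")
  cs <- clusters_of(t1, leaf_filter = c("C", "D", "E"))
  expect_identical(attr(cs, "leaves"), c("C", "D", "E"))
  # brute-force pruning: keeping C,D,E collapses {A,B,C}->C, {A,B,C,D}->{C,D}
  expect_length(cs, 1L)
  expect_identical(cs[[1]]$labels, c("C", "D"))
  expect_error(clusters_of(t1, leaf_filter = "E"), "incomparable")
})

test_that("CMS scores identical trees fully and stars at zero", {
  t1 <- balanced4()
  m <- cluster_matching_score(t1, t1, "exact")
  expect_equal(m$cms, 2)
  expect_true(all(m$matches$score == 1))

  m0 <- cluster_matching_score(t1, star4(), "exact")
  expect_equal(m0$cms, 0)
  m0j <- cluster_matching_score(t1, star4(), "jaccard")
  expect_equal(m0j$cms, 0)
})

test_that("jaccard CMS equals the brute-force assignment oracle", {
  set.seed(19)
  for (r in 1:25) {
    n <- sample(6:8, 1)
    labs <- LETTERS[1:n]
    t1 <- ape::rtree(n, tip.label = sample(labs))
    t2 <- ape::rtree(n, tip.label = sample(labs))
    for (crit in c("exact", "jaccard")) {
      got <- cluster_matching_score(clusters_of(t1), clusters_of(t2), crit)$cms
      want <- brute_force_cms(clusters_of(t1), clusters_of(t2), crit)
      expect_equal(got, want, tolerance = 1e-10)
    }
  }
})

test_that("jaccard CMS dominates exact CMS on every tree pair", {
  set.seed(23)
  for (r in 1:40) {
    n <- sample(5:9, 1)
    labs <- paste0("L", 1:n)
    t1 <- ape::rtree(n, tip.label = sample(labs))
    t2 <- ape::rtree(n, tip.label = sample(labs))
    ex <- cluster_matching_score(clusters_of(t1), clusters_of(t2), "exact")$cms
    ja <- cluster_matching_score(clusters_of(t1), clusters_of(t2), "jaccard")$cms
    expect_gte(ja, ex - 1e-12)
  }
})

test_that("congruence value is normalized CMS with its boundary cases", {
  t1 <- balanced4()
  expect_equal(congruence_value(t1, t1)$vc, 1)
  expect_equal(congruence_value(t1, star4())$vc, 0)

  # a binary rooted n-leaf tree has n - 2 non-root clusters
  set.seed(29)
  for (r in 1:10) {
    n <- 8
    t1 <- ape::rtree(n, tip.label = sample(paste0("L", 1:n)))
    t2 <- ape::rtree(n, tip.label = sample(paste0("L", 1:n)))
    cv <- congruence_value(t1, t2)
    expect_equal(cv$n_subject_clusters, n - 2)
    want <- brute_force_cms(clusters_of(t1), clusters_of(t2), "exact") / (n - 2)
    expect_equal(cv$vc, want)
    expect_gte(cv$vc, 0)
    expect_lte(cv$vc, 1)
  }

  # star vs star: vacuous congruence, by convention 1
  expect_message(cv <- congruence_value(star4(), star4()), "degenerate")
  expect_equal(cv$vc, 1)
})

test_that("congruence is invariant under consistent relabeling", {
  set.seed(37)
  t1 <- ape::rtree(7, tip.label = paste0("L", 1:7))
  t2 <- ape::rtree(7, tip.label = sample(paste0("L", 1:7)))
  v0 <- congruence_value(t1, t2)$vc
  map <- setNames(paste0("X", sample(7)), paste0("L", 1:7))
  r1 <- t1; r1$tip.label <- unname(map[t1$tip.label])
  r2 <- t2; r2$tip.label <- unname(map[t2$tip.label])
  expect_equal(congruence_value(r1, r2)$vc, v0)
})

test_that("congruence restricts to shared leaves and reports both directions", {
  t1 <- from_newick("(((A:1,B:1):1,C:2):1,(D:1.5,E:1.5):1.5);")
  t2 <- from_newick("((C:1,D:1):1,(E:1.2,F:1.2):0.8);")
  cv <- congruence_value(t1, t2)
  expect_true(is.finite(cv$vc) && is.finite(cv$vc_reverse))
  expect_equal(cv$vc_mean, (cv$vc + cv$vc_reverse) / 2)
  expect_error(congruence_value(t1, from_newick("(X:1,Y:1);")), "incomparable")
})

test_that("random leaf swaps degrade congruence monotonically on average", {
  set.seed(43)
  ks <- c(0, 2, 4)
  reps <- 60
  means <- vapply(ks, function(k) {
    mean(vapply(seq_len(reps), function(r) {
      cfg <- sim_config(n_leaves = 10, seed = 1000 + r)
      tr <- simulate_tree(cfg)
      congruence_value(tr, perturb_tree(tr, k, seed = r * 7 + k))$vc
    }, 0))
  }, 0)
  expect_equal(means[1], 1)
  expect_true(all(diff(means) <= 0))
})
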