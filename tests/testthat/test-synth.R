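test_that("tree simulation is deterministic and respects its mode", {
  t1 <- simulate_tree(n_tips = 8, birth = 0.1, death = 0, seed = 5)
  t2 <- simulate_tree(n_tips = 8, birth = 0.1, death = 0, seed = 5)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  expect_equal(ape::Ntip(t1), 8L)
  expect_true(ape::is.ultrametric(t1, tol = 1e-8))
  expect_error(simulate_tree(n_tips = 5, age = 10), "exactly one")
})

test_that("pure-birth tip counts match the Yule expectation", {
  lambda <- 0.08; T <- 25
  counts <- vapply(1:200, function(i) {
    out <- simulate_tree(age = T, birth = lambda, death = 0, seed = 1000 + i)
    ape::Ntip(out)
  }, 0L)
  expected <- exp(lambda * T)
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("age mode reports whole-clade extinction rather than erroring", {
  # high death rate: extinction very likely for at least one seed
  outs <- lapply(1:20, function(i)
    simulate_tree(age = 50, birth = 0.01, death = 0.4, seed = i))
  expect_true(any(vapply(outs, inherits, TRUE, "lineage_extinct")))
})

test_that("joint trait simulation inherits the root when rates are zero", {
  tree <- make_tree(12, seed = 2)
  q0 <- rate_matrix(rep(0, 8))
  sim <- simulate_joint_traits(tree, q0, root_state = 2L, seed = 1)
  expect_true(all(sim$state == 2L))
  expect_true(all(sim$defence == 1L & sim$threat == 0L))
})

test_that("long-branch state frequencies approach the stationary distribution", {
  set.seed(42)
  q <- rate_matrix(runif(8, 0.05, 0.3))
  pi <- stationary_distribution(q)
  single <- read_toy("(A:400);")
  states <- simulate_joint_traits(single, q, root_state = 0L, seed = 9,
                                  n_rep = 4000)
  freq <- tabulate(states + 1L, 4L) / 4000
  se <- sqrt(pi * (1 - pi) / 4000)
  expect_true(all(abs(freq - pi) <= 3 * se + 1e-12))
})

test_that("marginal defence states under an independent model match the 2-state law", {
  tree <- make_tree(6, seed = 7)
  rates <- indep_rates(0.04, 0.06, 0.05, 0.02)
  q4 <- rate_matrix(rates)
  n_rep <- 4000
  joint <- simulate_joint_traits(tree, q4, root_state = 0L, seed = 3,
                                 n_rep = n_rep)
  defence <- joint %/% 2L
  q2 <- q2state(0.05, 0.02)
  # oracle: per-tip marginal P(defence = 1) from the 2-state law
  depths <- ape::node.depth.edgelength(tree)[seq_len(6)]
  for (i in seq_len(6)) {
    p1 <- expm_series(q2, depths[i])[1, 2]
    se <- sqrt(p1 * (1 - p1) / n_rep)
    expect_lt(abs(mean(defence[, tree$tip.label[i]]) - p1), 3.5 * se)
  }
})

test_that("event bookkeeping conserves total time", {
  tree <- make_tree(20, seed = 5)
  q <- rate_matrix(rep(0.05, 8))
  sim <- simulate_joint_traits(tree, q, seed = 4, return_events = TRUE)
  occ <- attr(sim, "occupancy")
  expect_equal(sum(occ), sum(tree$edge.length), tolerance = 1e-8)
  expect_true(all(attr(sim, "transitions") >= 0))
  # forbidden dual transitions never occur
  tm <- attr(sim, "transitions")
  expect_equal(tm[1, 4] + tm[4, 1] + tm[2, 3] + tm[3, 2], 0)
})

test_that("ordinal status generator honours its degenerate and monotone limits", {
  tree <- make_tree(40, seed = 3)
  d <- stats::setNames(rep(c(0, 1), 20), tree$tip.label)
  s0 <- simulate_ordinal_status(tree, d, beta = 0, thresholds = c(-50, 50),
                                sigma2_phylo = 0, sigma2_res = 1, seed = 1)
  expect_true(all(s0 == 1L))

  s1 <- simulate_ordinal_status(tree, d, beta = 8,
                                thresholds = c(0.8, 1.6, 2.4, 3.2, 4),
                                sigma2_phylo = 0, sigma2_res = 1, seed = 2)
  expect_gt(mean(s1[d == 1]), mean(s1[d == 0]))
  expect_true(all(s1 %in% 0:5))
  expect_error(simulate_ordinal_status(tree, d, 1, thresholds = c(1, 1)))
})

test_that("strong phylogenetic liability variance clusters status by clade", {
  # four clades on long stems: within-clade liabilities share most variance
  clade_txt <- function(k) paste0("(", paste0("t", 8 * k + 1:8, ":1",
                                              collapse = ","), "):9")
  tree <- read_toy(paste0("(", paste(sapply(0:3, clade_txt), collapse = ","),
                          ");"))
  d <- stats::setNames(rep(0, 32), tree$tip.label)
  share <- vapply(1:10, function(i) {
    s <- simulate_ordinal_status(tree, d, beta = 0,
                                 thresholds = c(-4, -1, 1, 4),
                                 sigma2_phylo = 4, sigma2_res = 1, seed = i)
    clade <- (as.integer(sub("t", "", tree$tip.label)) - 1L) %/% 8L
    a <- stats::aov(as.numeric(s[tree$tip.label]) ~ factor(clade))
    ss <- summary(a)[[1]][["Sum Sq"]]
    ss[1] / sum(ss)
  }, 0)
  expect_gt(mean(share > 0.5), 0.5)
})

test_that("Brownian covariate matches its Gaussian law", {
  tree <- read_toy()
  expect_equal(unname(simulate_brownian_covariate(tree, 0, root_value = 7)),
               rep(7, 3))
  v1 <- simulate_brownian_covariate(tree, 0.5, seed = 3)
  v2 <- simulate_brownian_covariate(tree, 0.5, seed = 3)
  expect_identical(v1, v2)

  rate <- 0.5
  draws <- simulate_brownian_covariate(tree, rate, seed = 11, n_rep = 10000)
  Shat <- stats::cov(draws)
  Strue <- rate * phylo_covariance(tree)
  se <- sqrt((outer(diag(Strue), diag(Strue)) + Strue^2) / 10000)
  expect_true(all(abs(Shat - Strue[rownames(Shat), colnames(Shat)]) <= 3.5 * se))
})

test_that("study generator yields a codable, reproducible bundle", {
  cfg <- study_config(n_tips = 60, seed = 4)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$traits, s2$traits)
  expect_identical(ape::write.tree(s1$tree), ape::write.tree(s2$tree))
  ds <- build_dataset(s1$traits, s1$tree)
  expect_equal(ds$attrition$retained, 60L)

  dir <- withr::local_tempdir()
  write_fixture_bundle(dir, cfg)
  expect_true(all(file.exists(file.path(dir, c("tree.nwk", "traits.csv",
                                               "config.yaml")))))
  back <- read_trait_table(file.path(dir, "traits.csv"))
  expect_equal(back$chemical_defence, s1$traits$chemical_defence)
})
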