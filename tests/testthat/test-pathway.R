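test_that("joint state indexing is the documented bijection", {
  expect_equal(joint_state_index(0, 0), 0L)
  expect_equal(joint_state_index(0, 1), 1L)
  expect_equal(joint_state_index(1, 0), 2L)
  expect_equal(joint_state_index(1, 1), 3L)
  pair <- joint_state_pair(0:3)
  expect_equal(joint_state_index(pair$defence, pair$threat), 0:3)
})

test_that("rate matrices enforce the structural constraints", {
  q <- rate_matrix(c(q01 = 1, q10 = 2, q02 = 3, q20 = 4,
                     q13 = 5, q31 = 6, q23 = 7, q32 = 8))
  expect_equal(unname(rowSums(q)), rep(0, 4))
  expect_equal(q[1, 4], 0)  # (0,0) -> (1,1) forbidden
  expect_equal(q[2, 3], 0)  # (0,1) -> (1,0) forbidden
  expect_equal(q[3, 2], 0)
  expect_equal(q[4, 1], 0)
  expect_error(rate_matrix(c(q01 = -1, q10 = 1, q02 = 1, q20 = 1,
                             q13 = 1, q31 = 1, q23 = 1, q32 = 1)))
  spec <- pathway_model_spec("independent")
  expect_equal(spec$n_free, 4L)
  expect_equal(pathway_model_spec("dependent_full")$n_free, 8L)
  expect_equal(pathway_model_spec("constrained_directional")$n_free, 7L)
  expect_equal(pathway_model_spec("constrained_directional", "zero")$n_free, 7L)
  r <- pathway_model_spec("constrained_directional")$expand(rep(0.1, 7))
  expect_equal(r[["q01"]], r[["q23"]])
  rz <- pathway_model_spec("constrained_directional", "zero")$expand(rep(0.1, 7))
  expect_equal(rz[["q01"]], 0)
})

test_that("transition probabilities are proper for random generators", {
  set.seed(5)
  for (i in 1:20) {
    q <- rate_matrix(runif(8, 0, 2))
    t <- runif(1, 0, 1000)
    P <- defrisk:::cpp_transition_matrix(unclass(q), t)
    expect_true(all(P >= 0))
    expect_lt(max(abs(rowSums(P) - 1)), 1e-10)
  }
})

test_that("two-tip likelihood equals the direct root-sum formula", {
  set.seed(8)
  for (i in 1:100) {
    t1 <- runif(1, 0.1, 50); t2 <- runif(1, 0.1, 50)
    tree <- read_toy(sprintf("(A:%.17g,B:%.17g);", t1, t2))
    q <- rate_matrix(runif(8, 0.001, 0.3))
    s <- c(A = sample(0:3, 1), B = sample(0:3, 1))
    P1 <- expm_series(unclass(q), t1)
    P2 <- expm_series(unclass(q), t2)
    direct <- sum(0.25 * P1[, s["A"] + 1] * P2[, s["B"] + 1])
    expect_equal(pruning_log_likelihood(tree, s, q), log(direct),
                 tolerance = 1e-10)
  }
})

test_that("single tip with zero branch returns the root frequency", {
  tree <- read_toy("(A:0);")
  q <- rate_matrix(runif(8, 0.01, 1))
  expect_equal(pruning_log_likelihood(tree, c(A = 3L), q), log(0.25))
  expect_equal(pruning_log_likelihood(tree, c(A = 1L), q,
                                      root_freq = c(0.1, 0.6, 0.2, 0.1)),
               log(0.6))
})

test_that("independent-model joint likelihood factorizes into the marginals", {
  set.seed(13)
  for (i in 1:10) {
    tree <- make_tree(sample(5:50, 1), seed = 100 + i)
    tg <- runif(1, 0.01, 0.3); tl <- runif(1, 0.01, 0.3)
    dg <- runif(1, 0.01, 0.3); dl <- runif(1, 0.01, 0.3)
    q4 <- rate_matrix(indep_rates(tg, tl, dg, dl))
    sim <- simulate_joint_traits(tree, q4, seed = i)
    ll4 <- pruning_log_likelihood(tree, state_vec(sim), q4)
    llt <- pruning_log_likelihood(tree, stats::setNames(sim$threat, sim$species),
                                  q2state(tg, tl), root_freq = c(0.5, 0.5))
    lld <- pruning_log_likelihood(tree, stats::setNames(sim$defence, sim$species),
                                  q2state(dg, dl), root_freq = c(0.5, 0.5))
    expect_equal(ll4, llt + lld, tolerance = 1e-8)
  }
})

test_that("pruning likelihood ignores tip enumeration order and handles polytomies", {
  tree <- make_tree(15, seed = 21)
  q <- rate_matrix(runif(8, 0.02, 0.2))
  sim <- simulate_joint_traits(tree, q, seed = 2)
  s <- state_vec(sim)
  ll1 <- pruning_log_likelihood(tree, s, q)
  ll2 <- pruning_log_likelihood(tree, s[sample(names(s))], q)
  expect_identical(ll1, ll2)

  poly <- read_toy("((A:1,B:1,C:1):1,(D:1.5,E:1.5):0.5);")
  sp <- c(A = 0L, B = 1L, C = 0L, D = 2L, E = 3L)
  ll <- pruning_log_likelihood(poly, sp, q)
  expect_true(is.finite(ll))
  # oracle: direct summation over the two internal states
  P <- function(t) expm_series(unclass(q), t)
  P1 <- P(1); P15 <- P(1.5); Pr <- P(1); Pr5 <- P(0.5)
  lik <- 0
  for (r in 1:4) {
    left <- sum(Pr[r, ] * (P1[, 1] * P1[, 2] * P1[, 1]))
    right <- sum(Pr5[r, ] * (P15[, 3] * P15[, 4]))
    lik <- lik + 0.25 * left * right
  }
  expect_equal(ll, log(lik), tolerance = 1e-10)
})

test_that("model fits nest properly and are reproducible", {
  tree <- make_tree(120, seed = 31)
  q_true <- rate_matrix(c(q01 = 0.01, q10 = 0.02, q02 = 0.01, q20 = 0.005,
                          q13 = 0.01, q31 = 0.005, q23 = 0.08, q32 = 0.02))
  sim <- simulate_joint_traits(tree, q_true, seed = 7)
  dep <- fit_pathway(tree, sim, pathway_model_spec("dependent_full"),
                     n_starts = 3, seed = 1)
  con <- fit_pathway(tree, sim, pathway_model_spec("constrained_directional"),
                     n_starts = 3, seed = 1)
  ind <- fit_pathway(tree, sim, pathway_model_spec("independent"),
                     n_starts = 3, seed = 1)
  expect_lte(con$log_likelihood, dep$log_likelihood + 1e-4)
  expect_lte(ind$log_likelihood, dep$log_likelihood + 1e-4)
  expect_true(all(is.finite(c(dep$log_likelihood, con$log_likelihood))))

  dep2 <- fit_pathway(tree, sim, pathway_model_spec("dependent_full"),
                      n_starts = 3, seed = 1)
  expect_identical(dep$rates, dep2$rates)
})

test_that("correlation and directional tests detect a planted dependence", {
  tree <- make_tree(300, seed = 41)
  q_true <- rate_matrix(c(q01 = 0.005, q10 = 0.02, q02 = 0.01, q20 = 0.005,
                          q13 = 0.01, q31 = 0.005, q23 = 0.12, q32 = 0.02))
  sim <- simulate_joint_traits(tree, q_true, seed = 3)
  pg <- pagel_correlation_test(tree, sim, n_starts = 3, seed = 2)
  expect_equal(pg$df, 4L)
  expect_gte(pg$statistic, 0)
  expect_lt(pg$p_value, 0.05)

  dr <- directional_test(tree, sim, n_starts = 3, seed = 2)
  expect_equal(dr$df, 1L)
  expect_lt(dr$p_value, 0.05)
  expect_true(dr$ordering$defended_gain_faster)

  drz <- directional_test(tree, sim, n_starts = 3, seed = 2,
                          constraint = "zero")
  expect_equal(drz$ordering$constraint, "zero")
  expect_gte(drz$statistic, 0)
})

test_that("parsimony origin counts match hand-checkable cases", {
  tree <- make_tree(10, seed = 51)
  same <- stats::setNames(rep(2L, 10), tree$tip.label)
  org <- count_origins(tree, same)
  expect_equal(org$defence, 0L)
  expect_equal(org$threat, 0L)

  pect <- read_toy("(((A:1,B:1):1,C:2):1,D:3);")
  alt <- stats::setNames(c(1L, 0L, 1L, 0L), c("A", "B", "C", "D"))
  expect_equal(count_origins(pect, alt)$trait, 2L)
})
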