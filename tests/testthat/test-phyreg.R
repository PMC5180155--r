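test_that("phylogenetic logistic regression reduces to ordinary GLM on a star tree", {
  set.seed(14)
  star <- make_star(150)
  x <- stats::setNames(rnorm(150), star$tip.label)
  y <- stats::setNames(rbinom(150, 1, plogis(-0.3 + 0.8 * x)), star$tip.label)
  fit <- phylo_logistic(star, y, x)
  ref <- glm(y ~ x, family = binomial())
  expect_lt(max(abs(fit$coefficients - coef(ref))), 1e-3)
  expect_equal(fit$n, 150L)
  expect_true(all(fit$se > 0))
  expect_true(all(fit$p_value >= 0 & fit$p_value <= 1))
})

test_that("logistic fit is invariant to tip reordering and flags separation", {
  set.seed(15)
  tree <- make_tree(80, seed = 61)
  x <- stats::setNames(rnorm(80), tree$tip.label)
  y <- stats::setNames(rbinom(80, 1, plogis(x)), tree$tip.label)
  f1 <- phylo_logistic(tree, y, x)
  perm <- sample(tree$tip.label)
  f2 <- phylo_logistic(tree, y[perm], x[perm])
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-10)

  ysep <- stats::setNames(as.integer(x > 0), tree$tip.label)
  expect_error(phylo_logistic(tree, ysep, x), "separation")
  expect_error(phylo_logistic(tree, stats::setNames(rep(1L, 80),
                                                    tree$tip.label), x),
               "single class")
})

test_that("logistic Wald test is approximately calibrated under the null", {
  rej <- vapply(1:100, function(i) {
    tree <- make_tree(100, seed = 7000 + i)
    set.seed(8000 + i)
    x <- stats::setNames(rep(c(0, 1), 50), tree$tip.label)
    y <- stats::setNames(rbinom(100, 1, 0.4), tree$tip.label)
    fit <- phylo_logistic(tree, y, x)
    fit$p_value[[2]] < 0.05
  }, TRUE)
  # binomial 95% CI around 0.05 at 100 replicates
  expect_gte(mean(rej), 0.05 - 1.96 * sqrt(0.05 * 0.95 / 100))
  expect_lte(mean(rej), 0.05 + 1.96 * sqrt(0.05 * 0.95 / 100))
})

test_that("Poisson GEE with identity correlation equals the Poisson GLM", {
  set.seed(16)
  tree <- make_tree(120, seed = 71)
  x <- stats::setNames(rnorm(120), tree$tip.label)
  y <- stats::setNames(rpois(120, exp(0.5 + 0.3 * x)), tree$tip.label)
  fit <- phylo_poisson_gee(tree, y, x, correlation = "identity")
  ref <- glm(y ~ x, family = poisson())
  expect_lt(max(abs(fit$coefficients - coef(ref))), 1e-4)

  yc <- stats::setNames(rep(3L, 120), tree$tip.label)
  fc <- phylo_poisson_gee(tree, yc, x)
  expect_equal(fc$coefficients[[1]], log(3), tolerance = 1e-6)
  expect_equal(fc$coefficients[[2]], 0, tolerance = 1e-6)
})

test_that("Poisson GEE recovers a planted defence effect on average", {
  b_true <- c(0.3, 0.5)
  est <- t(vapply(1:50, function(i) {
    tree <- make_tree(100, seed = 9000 + i)
    set.seed(9500 + i)
    x <- stats::setNames(rbinom(100, 1, 0.5), tree$tip.label)
    y <- stats::setNames(rpois(100, exp(b_true[1] + b_true[2] * x)),
                         tree$tip.label)
    phylo_poisson_gee(tree, y, x, correlation = "identity")$coefficients
  }, c(a = 0, b = 0)))
  se_mean <- apply(est, 2, sd) / sqrt(nrow(est))
  expect_lt(abs(mean(est[, 1]) - b_true[1]), 3 * se_mean[1])
  expect_lt(abs(mean(est[, 2]) - b_true[2]), 3 * se_mean[2])
})

test_that("threat probability contrast back-transforms correctly", {
  fit <- structure(list(coefficients = c("(Intercept)" = 0,
                                         defence = log(3)),
                        vcov = diag(c(0.04, 0.04)), family = "binomial"),
                   class = "phylo_reg")
  ct <- threat_probability_contrast(fit)
  expect_equal(ct$p_undefended$estimate, 0.5)
  expect_equal(ct$p_defended$estimate, 0.75)
  expect_equal(ct$relative_increase, 0.5)
  expect_true(ct$p_undefended$lower < 0.5 && ct$p_undefended$upper > 0.5)

  fit$coefficients[2] <- 0
  expect_equal(threat_probability_contrast(fit)$relative_increase, 0)
})

test_that("confound screen reports one fit per covariate and respects nulls", {
  tree <- make_tree(150, seed = 81)
  q2 <- q2state(0.02, 0.01)
  d <- simulate_joint_traits(tree, q2, seed = 5)
  defence <- stats::setNames(d$state, d$species)
  if (length(unique(defence)) < 2) skip("degenerate defence draw")
  covs <- data.frame(
    species = tree$tip.label,
    absolute_latitude = abs(simulate_brownian_covariate(tree, 0.05, 20, seed = 6)),
    male_length = exp(simulate_brownian_covariate(tree, 0.002, 3, seed = 7)))
  scr <- confound_screen(tree, defence, covs)
  expect_equal(nrow(scr$summary), 2L)
  expect_setequal(scr$summary$covariate, c("absolute_latitude", "male_length"))
  expect_true(all(scr$summary$p >= 0 & scr$summary$p <= 1))

  # a covariate that deterministically tracks defence must raise separation
  covs2 <- data.frame(species = tree$tip.label,
                      mimic = as.numeric(defence[tree$tip.label]))
  expect_error(confound_screen(tree, defence, covs2), "separation")
})

test_that("null confound covariates are rarely significant", {
  hits <- vapply(1:40, function(i) {
    tree <- make_tree(80, seed = 400 + i)
    set.seed(500 + i)
    defence <- stats::setNames(rbinom(80, 1, 0.4), tree$tip.label)
    if (length(unique(defence)) < 2) return(FALSE)
    covs <- data.frame(species = tree$tip.label,
                       lat = abs(simulate_brownian_covariate(tree, 0.05, 15,
                                                             seed = 600 + i)))
    scr <- confound_screen(tree, defence, covs)
    scr$summary$p[1] < 0.05
  }, TRUE)
  expect_gte(mean(!hits), 0.9)
})

test_that("phylogenetic vs plain comparison is calibrated at both extremes", {
  # star tree: the two fits coincide, the plain model wins on the penalty
  set.seed(17)
  star <- make_star(100)
  x <- stats::setNames(rnorm(100), star$tip.label)
  y <- stats::setNames(rbinom(100, 1, plogis(x)), star$tip.label)
  cmp <- compare_phylo_vs_plain(star, y, x, family = "logistic")
  expect_equal(cmp$winner, "plain")
  expect_equal(cmp$fit_phylo$coefficients, cmp$fit_plain$coefficients,
               tolerance = 1e-6)

  # strongly clustered response: phylogenetic model should win mostly
  wins <- vapply(1:15, function(i) {
    tree <- make_tree(150, seed = 700 + i)
    s <- simulate_ordinal_status(tree,
                                 stats::setNames(rep(0, 150), tree$tip.label),
                                 beta = 0, thresholds = 0, sigma2_phylo = 8,
                                 sigma2_res = 1, seed = 800 + i)
    if (length(unique(s)) < 2) return(NA)
    set.seed(900 + i)
    x <- stats::setNames(rnorm(150), tree$tip.label)
    cmp <- compare_phylo_vs_plain(tree, s, x, family = "logistic")
    cmp$winner == "phylogenetic"
  }, TRUE)
  wins <- wins[!is.na(wins)]
  expect_gte(mean(wins), 0.8)
})
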