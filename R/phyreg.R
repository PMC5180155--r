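# --- shared GEE machinery -------------------------------------------------

# align a named tip map (vector, or data.frame with a species column) to tree
# tip order
.as_tip_vector <- function(x, tree, what = "values") {
  if (is.data.frame(x)) {
    stopifnot("species" %in% names(x))
    val_col <- setdiff(names(x), "species")[1L]
    x <- stats::setNames(x[[val_col]], x$species)
  }
  out <- x[tree$tip.label]
  if (anyNA(out)) stop("missing ", what, " for some tips")
  unname(out)
}

.design_matrix <- function(predictors, tree) {
  if (is.null(predictors)) return(matrix(1, ape::Ntip(tree), 1,
                                         dimnames = list(NULL, "(Intercept)")))
  if (is.numeric(predictors) && is.null(dim(predictors)))
    predictors <- data.frame(predictor = predictors[tree$tip.label])
  if (is.data.frame(predictors)) {
    if ("species" %in% names(predictors)) {
      rownames(predictors) <- predictors$species
      predictors$species <- NULL
      predictors <- predictors[tree$tip.label, , drop = FALSE]
    }
    predictors <- as.matrix(predictors)
  }
  if (!is.null(rownames(predictors)) &&
      all(tree$tip.label %in% rownames(predictors)))
    predictors <- predictors[tree$tip.label, , drop = FALSE]
  stopifnot(nrow(predictors) == ape::Ntip(tree), !anyNA(predictors))
  X <- cbind(1, predictors)
  colnames(X) <- c("(Intercept)", colnames(predictors))
  X
}

.chol_or_ridge <- function(R) {
  ch <- tryCatch(chol(R), error = function(e) NULL)
  if (is.null(ch)) {
    warning("singular working correlation; ridge-regularized")
    ch <- chol(R + diag(1e-6, nrow(R)))
  }
  ch
}

# Fisher-scoring GEE solve for fixed working correlation (via its Cholesky
# factor). Returns coefficients, the naive information matrix, and the
# Gaussian pseudo-log-likelihood of the Pearson residuals used to profile
# the phylogenetic signal.
.gee_fit <- function(X, y, family = c("binomial", "poisson"), Rchol,
                     beta0 = NULL, maxit = 100L, tol = 1e-11) {
  family <- match.arg(family)
  n <- length(y); p <- ncol(X)
  solveR <- function(z) backsolve(Rchol, backsolve(Rchol, z, transpose = TRUE))
  beta <- if (is.null(beta0)) c(
    if (family == "binomial") stats::qlogis(pmin(pmax(mean(y), 0.05), 0.95))
    else log(max(mean(y), 0.05)), rep(0, p - 1L)) else beta0
  converged <- FALSE
  for (it in seq_len(maxit)) {
    eta <- pmin(pmax(drop(X %*% beta), -30), 30)
    mu <- if (family == "binomial") stats::plogis(eta) else exp(eta)
    a <- if (family == "binomial") mu * (1 - mu) else mu
    sa <- sqrt(pmax(a, 1e-12))
    U <- X * sa
    r <- (y - mu) / sa
    G <- crossprod(U, solveR(U))
    g <- crossprod(U, solveR(r))
    delta <- tryCatch(solve(G, g), error = function(e) NULL)
    if (is.null(delta)) break
    beta <- beta + drop(delta)
    if (max(abs(delta)) < tol) { converged <- TRUE; break }
  }
  eta <- pmin(pmax(drop(X %*% beta), -30), 30)
  mu <- if (family == "binomial") stats::plogis(eta) else exp(eta)
  a <- if (family == "binomial") mu * (1 - mu) else mu
  sa <- sqrt(pmax(a, 1e-12))
  r <- (y - mu) / sa
  U <- X * sa
  G <- crossprod(U, solveR(U))
  quad <- drop(crossprod(r, solveR(r)))
  logdetR <- 2 * sum(log(diag(Rchol)))
  pseudo_ll <- -0.5 * (logdetR + n * log(quad / n) + n * (1 + log(2 * pi)))
  list(beta = stats::setNames(drop(beta), colnames(X)), G = G, mu = mu,
       pearson = r, quad = quad, pseudo_loglik = pseudo_ll,
       converged = converged)
}

.working_correlation <- function(Cnorm, s) {
  n <- nrow(Cnorm)
  R <- diag(n) * (1 - s) + s * Cnorm
  # guard against exact singularity at high signal (e.g. duplicated tips)
  diag(R) <- diag(R) + 1e-10
  R
}

.check_separation <- function(X, y) {
  fit <- withCallingHandlers(
    stats::glm.fit(X, y, family = stats::binomial()),
    warning = function(w) invokeRestart("muffleWarning"))
  f <- fit$fitted.values
  if (all(f[y == 1] > max(c(-Inf, f[y == 0]))) &&
      (max(f[y == 1]) > 1 - 1e-8 || min(c(Inf, f[y == 0])) < 1e-8))
    stop("complete separation: a predictor perfectly splits the response")
  invisible(NULL)
}

#' Phylogenetic logistic regression
#'
#' Logistic regression for a binary trait on species data in which residual
#' dependence follows the phylogeny (Ives-Garland model family). The working
#' correlation is an attenuated Brownian correlation,
#' R(alpha) = I + exp(-alpha) * (C* - I) with C* the shared-path-length
#' matrix normalized to unit diagonal; the signal parameter alpha is profiled
#' on a log grid and refined by maximizing the Gaussian pseudo-likelihood of
#' the Pearson residuals, and beta is estimated by generalized estimating
#' equations at each candidate alpha. alpha = Inf (signal 0) recovers
#' ordinary logistic regression exactly, so on a star tree the fit equals the
#' ordinary GLM.
#'
#' @param tree A `phylo` object.
#' @param response Named binary tip map (0/1); both classes must be present.
#' @param predictors Named vector, matrix or data.frame of predictors over
#'   the tips (an intercept is added).
#' @param signal `"estimate"` (default) or a fixed value in \[0, 1\] for the
#'   attenuation s = exp(-alpha) (0 = no signal).
#' @return A `phylo_reg` object: `coefficients`, `se`, `z`, `p_value`,
#'   `vcov`, `alpha`, `signal`, `family`, `n`, `pseudo_loglik`, `converged`.
#' @export
phylo_logistic <- function(tree, response, predictors, signal = "estimate") {
  y <- .as_tip_vector(response, tree, "response")
  stopifnot(all(y %in% 0:1))
  if (length(unique(y)) < 2L) stop("response has a single class")
  X <- .design_matrix(predictors, tree)
  .check_separation(X, y)
  .phylo_gee(tree, y, X, family = "binomial", signal = signal)
}

.phylo_gee <- function(tree, y, X, family, signal = "estimate",
                       dispersion = c("fixed", "pearson")) {
  dispersion <- match.arg(dispersion)
  n <- length(y)
  Cnorm <- stats::cov2cor(phylo_covariance(tree))
  fit_at <- function(s, beta0 = NULL) {
    Rchol <- .chol_or_ridge(.working_correlation(Cnorm, s))
    .gee_fit(X, y, family, Rchol, beta0 = beta0)
  }
  if (identical(signal, "estimate")) {
    s_grid <- c(0, exp(-exp(seq(log(10), log(0.01), length.out = 10L))))
    s_grid <- s_grid[s_grid <= 0.99]
    fits <- lapply(s_grid, fit_at)
    crit <- vapply(fits, `[[`, 0, "pseudo_loglik")
    i <- which.max(crit)
    lo <- s_grid[max(i - 1L, 1L)]; hi <- s_grid[min(i + 1L, length(s_grid))]
    if (hi > lo) {
      opt <- stats::optimize(function(s) fit_at(s)$pseudo_loglik,
                             interval = c(lo, hi), maximum = TRUE,
                             tol = 1e-4)
      if (opt$objective > crit[i]) {
        s_hat <- opt$maximum
        best <- fit_at(s_hat)
      } else { s_hat <- s_grid[i]; best <- fits[[i]] }
    } else { s_hat <- s_grid[i]; best <- fits[[i]] }
  } else {
    stopifnot(is.numeric(signal), signal >= 0, signal <= 1)
    s_hat <- signal
    best <- fit_at(s_hat)
  }
  p <- ncol(X)
  phi <- if (dispersion == "pearson") best$quad / (n - p) else 1
  V <- phi * tryCatch(solve(best$G), error = function(e) MASS::ginv(best$G))
  dimnames(V) <- list(names(best$beta), names(best$beta))
  se <- sqrt(pmax(diag(V), 0))
  z <- best$beta / se
  structure(list(
    coefficients = best$beta, se = se, z = z,
    p_value = 2 * stats::pnorm(-abs(z)), vcov = V,
    signal = s_hat, alpha = if (s_hat > 0) -log(s_hat) else Inf,
    family = family, n = n, dispersion = phi,
    pseudo_loglik = best$pseudo_loglik, converged = best$converged),
    class = "phylo_reg")
}

#' @export
print.phylo_reg <- function(x, ...) {
  cat("Phylogenetic", x$family, "regression (n =", x$n, ")\n")
  tab <- data.frame(beta = x$coefficients, se = x$se, z = x$z, p = x$p_value)
  print(round(tab, 4))
  cat(sprintf("signal s = %.4f (alpha = %s)\n", x$signal,
              format(x$alpha, digits = 4)))
  invisible(x)
}

#' Back-transformed threat probabilities from a logistic fit
#'
#' Inverse-logit of the linear predictor at defence = 0 and defence = 1, with
#' back-transformed one-standard-error bands, and the relative increase in
#' threat probability attributable to defence.
#'
#' @param fit A `phylo_reg` logistic fit whose first two coefficients are the
#'   intercept and the defence effect.
#' @return List with `p_undefended`, `p_defended` (each with `estimate`,
#'   `lower`, `upper`) and `relative_increase` (p1/p0 - 1).
#' @export
threat_probability_contrast <- function(fit) {
  stopifnot(inherits(fit, "phylo_reg"), fit$family == "binomial",
            length(fit$coefficients) >= 2L)
  b <- fit$coefficients
  eta0 <- b[[1L]]; eta1 <- b[[1L]] + b[[2L]]
  se0 <- sqrt(fit$vcov[1L, 1L])
  se1 <- sqrt(sum(fit$vcov[1:2, 1:2]))
  band <- function(eta, se) list(estimate = stats::plogis(eta),
                                 lower = stats::plogis(eta - se),
                                 upper = stats::plogis(eta + se))
  p0 <- band(eta0, se0); p1 <- band(eta1, se1)
  list(p_undefended = p0, p_defended = p1,
       relative_increase = p1$estimate / p0$estimate - 1)
}

#' Phylogenetic Poisson GEE
#'
#' Generalized estimating equations with a log link and Poisson variance for
#' an ordinal count response, using as working correlation the phylogenetic
#' covariance normalized to unit diagonal (or the identity). Naive
#' model-based standard errors with a Pearson dispersion estimate.
#'
#' @param tree A `phylo` object.
#' @param response Named non-negative integer tip map.
#' @param predictors As in [phylo_logistic()].
#' @param correlation `"phylo"` (default) or `"identity"`. With the identity
#'   working correlation the coefficients coincide with an ordinary Poisson
#'   GLM.
#' @return A `phylo_reg` object (family `"poisson"`).
#' @export
phylo_poisson_gee <- function(tree, response, predictors,
                              correlation = c("phylo", "identity")) {
  correlation <- match.arg(correlation)
  y <- .as_tip_vector(response, tree, "response")
  stopifnot(all(y >= 0), all(y == round(y)))
  X <- .design_matrix(predictors, tree)
  fit <- .phylo_gee(tree, y, X, family = "poisson",
                    signal = if (correlation == "phylo") 1 else 0,
                    dispersion = "pearson")
  fit$correlation <- correlation
  fit
}

#' Confound screen: do candidate covariates predict chemical defence?
#'
#' Fits one single-predictor phylogenetic logistic regression per covariate
#' with defence as the binary response, to check whether traits known to
#' predict extinction risk (latitude, body size, sexual size dimorphism)
#' covary with defence and could confound the main analyses.
#'
#' @param tree A `phylo` object.
#' @param defence Named binary tip map.
#' @param covariates data.frame with a `species` column (or rownames) and one
#'   column per covariate; species with missing values are dropped per
#'   covariate and the tree pruned accordingly.
#' @return List with `summary` (data.frame: covariate, n, beta, se, z, p) and
#'   `fits` (named list of `phylo_reg` objects).
#' @export
confound_screen <- function(tree, defence, covariates) {
  if (!"species" %in% names(covariates)) {
    covariates <- cbind(species = rownames(covariates), covariates)
  }
  covariates$species <- normalize_labels(covariates$species)
  covnames <- setdiff(names(covariates), "species")
  fits <- list()
  rows <- list()
  for (cv in covnames) {
    ok <- !is.na(covariates[[cv]]) & covariates$species %in% tree$tip.label
    sp <- covariates$species[ok]
    if (length(sp) < 10L) stop("too few species with data for ", cv)
    tr <- prune_to(tree, sp)
    x <- stats::setNames(covariates[[cv]][ok], sp)
    fit <- phylo_logistic(tr, defence, data.frame(species = sp, x = x[sp]))
    names(fit$coefficients)[2L] <- cv
    fits[[cv]] <- fit
    rows[[cv]] <- data.frame(covariate = cv, n = fit$n,
                             beta = fit$coefficients[[2L]], se = fit$se[[2L]],
                             z = fit$z[[2L]], p = fit$p_value[[2L]])
  }
  list(summary = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       fits = fits)
}

#' Compare phylogenetic and non-phylogenetic fits of the same model
#'
#' Fits the model with the phylogenetic working correlation (signal
#' estimated for logistic; Brownian correlation for Poisson) and with the
#' identity correlation, and compares them by an AIC built on the Gaussian
#' pseudo-log-likelihood of the Pearson residuals (the phylogenetic variant
#' is charged one extra parameter for the signal).
#'
#' @param tree A `phylo` object.
#' @param response Named tip map (binary or count per `family`).
#' @param predictors As in [phylo_logistic()].
#' @param family `"logistic"` or `"poisson"`.
#' @return List with both fits, `aic_phylo`, `aic_plain`,
#'   `delta_aic` (plain minus phylo; positive favours the phylogenetic
#'   model) and `winner`.
#' @export
compare_phylo_vs_plain <- function(tree, response, predictors,
                                   family = c("logistic", "poisson")) {
  family <- match.arg(family)
  y <- .as_tip_vector(response, tree, "response")
  X <- .design_matrix(predictors, tree)
  p <- ncol(X)
  if (family == "logistic") {
    .check_separation(X, y)
    phylo <- .phylo_gee(tree, y, X, "binomial", signal = "estimate")
    plain <- .phylo_gee(tree, y, X, "binomial", signal = 0)
  } else {
    phylo <- .phylo_gee(tree, y, X, "poisson", signal = 1,
                        dispersion = "pearson")
    plain <- .phylo_gee(tree, y, X, "poisson", signal = 0,
                        dispersion = "pearson")
  }
  aic_phylo <- -2 * phylo$pseudo_loglik + 2 * (p + 2)
  aic_plain <- -2 * plain$pseudo_loglik + 2 * (p + 1)
  list(fit_phylo = phylo, fit_plain = plain,
       aic_phylo = aic_phylo, aic_plain = aic_plain,
       delta_aic = aic_plain - aic_phylo,
       winner = if (aic_phylo < aic_plain) "phylogenetic" else "plain")
}
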