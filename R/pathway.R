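#' @title Joint state coding for (defence, threat)
#'
#' @description The four joint states of the evolutionary pathway models are
#' indexed 0 = (D=0,T=0), 1 = (D=0,T=1), 2 = (D=1,T=0), 3 = (D=1,T=1), i.e.
#' `state = 2*defence + threat`. Dual transitions (both traits changing in
#' one instant) are structurally forbidden.
#'
#' @param defence,threat Binary vectors.
#' @return `joint_state_index()`: integer states in 0..3.
#'   `joint_state_pair()`: data.frame with columns `defence`, `threat`.
#' @examples
#' joint_state_index(0, 0)  # 0
#' joint_state_index(1, 0)  # 2
#' joint_state_pair(0:3)
#' @export
joint_state_index <- function(defence, threat) {
  stopifnot(all(defence %in% 0:1), all(threat %in% 0:1))
  as.integer(2L * defence + threat)
}

#' @rdname joint_state_index
#' @param state Integer states in 0..3.
#' @export
joint_state_pair <- function(state) {
  stopifnot(all(state %in% 0:3))
  data.frame(defence = state %/% 2L, threat = state %% 2L)
}

# canonical order of the 8 permitted transition rates; q01 is the rate from
# state 0=(D0,T0) to state 1=(D0,T1) (threat gain while undefended), etc.
.rate_names <- c("q01", "q10", "q02", "q20", "q13", "q31", "q23", "q32")

.rate_from_to <- matrix(c(0L,1L, 1L,0L, 0L,2L, 2L,0L, 1L,3L, 3L,1L, 2L,3L, 3L,2L),
                        ncol = 2L, byrow = TRUE,
                        dimnames = list(.rate_names, c("from", "to")))

.validate_generator <- function(q) {
  stopifnot(is.matrix(q), nrow(q) == ncol(q))
  off <- q; diag(off) <- 0
  if (any(off < 0)) stop("off-diagonal rates must be non-negative")
  if (any(abs(rowSums(q)) > 1e-8 * max(1, max(abs(q)))))
    stop("generator rows must sum to zero")
  invisible(q)
}

#' Build the 4x4 generator of the joint (defence, threat) process
#'
#' @param rates Numeric vector of the 8 permitted transition rates, named
#'   `q01, q10, q02, q20, q13, q31, q23, q32` (any order) or unnamed in that
#'   order. All must be >= 0. Dual transitions (q03, q30, q12, q21) are
#'   structurally zero; the diagonal is minus the row sum.
#' @return A 4x4 `rate_matrix` with states 0..3 as dimnames.
#' @export
rate_matrix <- function(rates) {
  if (is.null(names(rates))) {
    stopifnot(length(rates) == 8L)
    names(rates) <- .rate_names
  }
  stopifnot(setequal(names(rates), .rate_names), all(rates >= 0))
  q <- matrix(0, 4, 4, dimnames = list(0:3, 0:3))
  for (nm in .rate_names)
    q[.rate_from_to[nm, 1L] + 1L, .rate_from_to[nm, 2L] + 1L] <- rates[[nm]]
  diag(q) <- -rowSums(q)
  structure(q, class = c("rate_matrix", "matrix"))
}

#' Stationary distribution of a generator
#'
#' Left null vector of Q, normalized to sum to one.
#'
#' @param q A k x k generator matrix.
#' @return Probability vector of length k.
#' @export
stationary_distribution <- function(q) {
  q <- unclass(q)
  k <- nrow(q)
  # solve pi Q = 0, sum(pi) = 1 by replacing one equation
  A <- rbind(t(q)[-k, , drop = FALSE], rep(1, k))
  b <- c(rep(0, k - 1L), 1)
  pi <- solve(A, b)
  pi[pi < 0] <- 0
  pi / sum(pi)
}

#' Pathway model specifications
#'
#' The three model classes for joint (defence, threat) evolution:
#' `independent` (4 free rates: each trait's gain and loss rate is the same
#' regardless of the other trait's state), `dependent_full` (all 8 permitted
#' rates free), and `constrained_directional` (the dependent model with one
#' constraint on the threat-gain rates). With `constraint = "equal"` the
#' constraint is q01 = q23 (threat gain independent of defence; 7 free,
#' LRT df = 1); with `constraint = "zero"` it is q01 = 0 (threat can only be
#' gained after defence; also 7 free).
#'
#' @param name One of `"independent"`, `"dependent_full"`,
#'   `"constrained_directional"`.
#' @param constraint For the directional model, `"equal"` (default) or
#'   `"zero"`.
#' @return A `pathway_model_spec` list with fields `name`, `n_free`,
#'   `par_names`, `constraint`, and functions `expand` (free parameters ->
#'   named 8-rate vector) and `shrink` (8-rate vector -> free parameters).
#' @export
pathway_model_spec <- function(name = c("independent", "dependent_full",
                                        "constrained_directional"),
                               constraint = c("equal", "zero")) {
  name <- match.arg(name)
  constraint <- match.arg(constraint)
  spec <- switch(name,
    independent = list(
      par_names = c("threat_gain", "threat_loss", "defence_gain", "defence_loss"),
      expand = function(p) c(q01 = p[[1]], q10 = p[[2]], q02 = p[[3]],
                             q20 = p[[4]], q13 = p[[3]], q31 = p[[4]],
                             q23 = p[[1]], q32 = p[[2]]),
      shrink = function(r) c(threat_gain = mean(r[c("q01", "q23")]),
                             threat_loss = mean(r[c("q10", "q32")]),
                             defence_gain = mean(r[c("q02", "q13")]),
                             defence_loss = mean(r[c("q20", "q31")]))
    ),
    dependent_full = list(
      par_names = .rate_names,
      expand = function(p) stats::setNames(as.numeric(p), .rate_names),
      shrink = function(r) r[.rate_names]
    ),
    constrained_directional = if (constraint == "equal") list(
      par_names = c("threat_gain", "q10", "q02", "q20", "q13", "q31", "q32"),
      expand = function(p) c(q01 = p[[1]], q10 = p[[2]], q02 = p[[3]],
                             q20 = p[[4]], q13 = p[[5]], q31 = p[[6]],
                             q23 = p[[1]], q32 = p[[7]]),
      shrink = function(r) c(threat_gain = mean(r[c("q01", "q23")]),
                             r[c("q10", "q02", "q20", "q13", "q31", "q32")])
    ) else list(
      par_names = c("q10", "q02", "q20", "q13", "q31", "q23", "q32"),
      expand = function(p) c(q01 = 0, q10 = p[[1]], q02 = p[[2]],
                             q20 = p[[3]], q13 = p[[4]], q31 = p[[5]],
                             q23 = p[[6]], q32 = p[[7]]),
      shrink = function(r) r[c("q10", "q02", "q20", "q13", "q31", "q32", "q23")]
    )
  )
  structure(list(name = name, constraint = constraint,
                 n_free = length(spec$par_names), par_names = spec$par_names,
                 expand = spec$expand, shrink = spec$shrink),
            class = "pathway_model_spec")
}

# precompute everything the C++ pruning needs for repeated evaluations
.prune_context <- function(tree, tip_states, k) {
  if (is.data.frame(tip_states))
    tip_states <- stats::setNames(tip_states$state, tip_states$species)
  states <- tip_states[tree$tip.label]
  if (anyNA(names(states)) || anyNA(states))
    stop("every tip needs a state")
  stopifnot(all(states %in% 0:(k - 1)))
  tipL <- matrix(0, ape::Ntip(tree), k)
  tipL[cbind(seq_along(states), as.integer(states) + 1L)] <- 1
  if (ape::Ntip(tree) == 1L) {
    edge <- matrix(c(2L, 1L), 1, 2)
    elen <- sum(tree$edge.length)
    return(list(edge = edge, elen = elen, ntip = 1L, nnode = 1L,
                tipL = tipL, states = states))
  }
  tr <- ape::reorder.phylo(tree, "postorder")
  # reorder tip rows to match node numbering (tips keep their numbers)
  list(edge = matrix(as.integer(tr$edge), ncol = 2L), elen = tr$edge.length,
       ntip = ape::Ntip(tr), nnode = tr$Nnode, tipL = tipL, states = states)
}

.ctx_loglik <- function(ctx, q, root_freq) {
  cpp_prune_loglik(ctx$edge, ctx$elen, ctx$ntip, ctx$nnode, ctx$tipL,
                   unclass(q), root_freq)
}

#' Felsenstein pruning log-likelihood of tip states under a Markov model
#'
#' Post-order dynamic program propagating partial likelihoods with
#' per-branch transition matrices exp(Q t), returning the log of the
#' root-frequency-weighted likelihood. Works for any number of states k
#' (k = 4 for the joint pathway models, k = 2 for a single binary trait) and
#' accepts multifurcating trees.
#'
#' @param tree A `phylo` object.
#' @param tip_states Named vector of states in `0..k-1` (names are tip
#'   labels), or the data.frame returned by [simulate_joint_traits()].
#' @param q A k x k generator matrix.
#' @param root_freq Root state frequencies: a probability vector of length k,
#'   `"equal"` (default) or `"stationary"` (of `q`).
#' @return The log-likelihood (scalar). `-Inf` signals an invalid
#'   rate/branch combination.
#' @export
pruning_log_likelihood <- function(tree, tip_states, q, root_freq = "equal") {
  q <- unclass(q)
  .validate_generator(q)
  k <- nrow(q)
  ctx <- .prune_context(tree, tip_states, k)
  rf <- .resolve_root_freq(root_freq, q)
  .ctx_loglik(ctx, q, rf)
}

.resolve_root_freq <- function(root_freq, q) {
  k <- nrow(q)
  if (is.character(root_freq)) {
    switch(match.arg(root_freq, c("equal", "stationary")),
           equal = rep(1 / k, k),
           stationary = stationary_distribution(q))
  } else {
    stopifnot(length(root_freq) == k, abs(sum(root_freq) - 1) < 1e-8)
    as.numeric(root_freq)
  }
}

#' Fit an evolutionary pathway model by maximum likelihood
#'
#' Maximizes the pruning log-likelihood over the model's free rates (on the
#' log scale, bounded in \[1e-8, 100\] per Myr) with multi-start L-BFGS-B;
#' likelihood surfaces of these models are multi-modal, so several random
#' starts around a parsimony-informed heuristic are used.
#'
#' @param tree A `phylo` object.
#' @param tip_states Named 0..3 states or [simulate_joint_traits()] output.
#' @param spec A [pathway_model_spec()].
#' @param n_starts Number of optimizer starts (>= 1).
#' @param seed Integer seed for the random starts.
#' @param root_freq Passed to [pruning_log_likelihood()].
#' @param extra_starts Optional list of named 8-rate vectors used as
#'   additional starts (e.g. the MLE of a nested model).
#' @param rate_bounds Length-2 vector of rate bounds per Myr.
#' @return A `pathway_fit` list: `spec`, `rates` (named 8-vector at the MLE),
#'   `q` (the generator), `log_likelihood`, `converged`, `n_starts`,
#'   `root_freq`, `n`.
#' @export
fit_pathway <- function(tree, tip_states, spec = pathway_model_spec("dependent_full"),
                        n_starts = 10L, seed = 1L, root_freq = "equal",
                        extra_starts = NULL, rate_bounds = c(1e-8, 100)) {
  stopifnot(inherits(spec, "pathway_model_spec"), n_starts >= 1L)
  ctx <- .prune_context(tree, tip_states, 4L)
  if (length(unique(ctx$states)) < 2L && ctx$ntip >= 2L)
    warning("no variation in tip states; rates are unidentifiable")
  lb <- log(rate_bounds[1L]); ub <- log(rate_bounds[2L])
  use_stationary <- identical(root_freq, "stationary")
  rf_fixed <- if (use_stationary) NULL else .resolve_root_freq(root_freq, diag(0, 4))

  negll <- function(theta) {
    rates <- spec$expand(exp(theta))
    q <- rate_matrix(rates)
    rf <- if (use_stationary) stationary_distribution(q) else rf_fixed
    ll <- .ctx_loglik(ctx, q, rf)
    if (!is.finite(ll)) 1e10 else -ll
  }

  # parsimony-informed heuristic start
  org <- count_origins(tree, tip_states)
  total_len <- sum(tree$edge.length)
  tr_rate <- max((org$threat + 0.5) / total_len, rate_bounds[1L] * 10)
  df_rate <- max((org$defence + 0.5) / total_len, rate_bounds[1L] * 10)
  base8 <- c(q01 = tr_rate, q10 = tr_rate, q02 = df_rate, q20 = df_rate,
             q13 = df_rate, q31 = df_rate, q23 = tr_rate, q32 = tr_rate)
  starts <- list(spec$shrink(base8))
  for (es in extra_starts) starts <- c(starts, list(spec$shrink(es)))
  set.seed(derive_seed(seed, paste0("fit_pathway_", spec$name, spec$constraint)))
  while (length(starts) < n_starts) {
    jitter <- base8 * exp(stats::rnorm(8L, 0, 1.5))
    starts <- c(starts, list(spec$shrink(jitter)))
  }

  best <- NULL
  any_conv <- FALSE
  for (st in starts) {
    theta0 <- pmin(pmax(log(pmax(as.numeric(st), rate_bounds[1L])), lb), ub)
    fit <- tryCatch(
      stats::optim(theta0, negll, method = "L-BFGS-B", lower = lb, upper = ub,
                   control = list(maxit = 500L, factr = 1e7)),
      error = function(e) NULL)
    if (is.null(fit)) next
    any_conv <- any_conv || fit$convergence == 0L
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("all optimizer starts failed for model ", spec$name)
  # polish the winner
  fit2 <- tryCatch(
    stats::optim(best$par, negll, method = "L-BFGS-B", lower = lb, upper = ub,
                 control = list(maxit = 1000L, factr = 1e7)),
    error = function(e) NULL)
  if (!is.null(fit2) && fit2$value <= best$value) best <- fit2

  rates <- spec$expand(exp(best$par))
  q <- rate_matrix(rates)
  structure(list(spec = spec, rates = rates, q = q,
                 log_likelihood = -best$value,
                 converged = any_conv || best$convergence == 0L,
                 n_starts = length(starts),
                 root_freq = if (use_stationary) "stationary" else rf_fixed,
                 n = ctx$ntip),
            class = "pathway_fit")
}

#' @export
print.pathway_fit <- function(x, ...) {
  cat("Pathway model fit:", x$spec$name,
      if (x$spec$name == "constrained_directional")
        paste0("(constraint: ", x$spec$constraint, ")") else "", "\n")
  cat("  logLik:", format(x$log_likelihood, digits = 8),
      " converged:", x$converged, " n =", x$n, "\n")
  print(round(x$rates, 6))
  invisible(x)
}

.lrt <- function(fit_general, fit_restricted, df) {
  stat <- 2 * (fit_general$log_likelihood - fit_restricted$log_likelihood)
  if (stat < -1e-4)
    warning("restricted model out-fitted the general model by more than ",
            "tolerance (", format(stat), "); optimizer likely stuck")
  stat <- max(stat, 0)
  structure(list(statistic = stat, df = df,
                 p_value = stats::pchisq(stat, df, lower.tail = FALSE),
                 fit_general = fit_general, fit_restricted = fit_restricted),
            class = "pathway_lrt")
}

#' @export
print.pathway_lrt <- function(x, ...) {
  cat(sprintf("Likelihood ratio = %.4f, d.f. = %d, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  if (!is.null(x$ordering)) {
    cat(sprintf("  threat-gain rates: q01 (undefended) = %.5f, q23 (defended) = %.5f\n",
                x$ordering$q01, x$ordering$q23))
    cat("  ", x$ordering$interpretation, "\n")
  }
  invisible(x)
}

#' Pagel's test of correlated evolution
#'
#' Likelihood-ratio test of the dependent (8-rate) against the independent
#' (4-rate) model, on 4 degrees of freedom. A significant result indicates
#' that the evolution of threat depends on defence state (or vice versa).
#' The independent-model MLE seeds one start of the dependent fit, so the
#' statistic is non-negative by construction.
#'
#' @inheritParams fit_pathway
#' @return A `pathway_lrt` with `statistic`, `df = 4`, `p_value`, and both
#'   fits.
#' @export
pagel_correlation_test <- function(tree, tip_states, n_starts = 5L, seed = 1L,
                                   root_freq = "equal") {
  ind <- fit_pathway(tree, tip_states, pathway_model_spec("independent"),
                     n_starts = n_starts, seed = seed, root_freq = root_freq)
  dep <- fit_pathway(tree, tip_states, pathway_model_spec("dependent_full"),
                     n_starts = n_starts, seed = seed, root_freq = root_freq,
                     extra_starts = list(ind$rates))
  .lrt(dep, ind, df = 4L)
}

#' Directional (pathway-ordering) test
#'
#' Likelihood-ratio test of the dependent model against the
#' constrained-directional model (df = 1). With the default `"equal"`
#' constraint the restricted model forces the threat-gain rate to be the same
#' whether or not the lineage is defended; rejecting it while the fitted
#' dependent model shows q23 > q01 (threat gained faster once defended) is
#' reported as support for the "defence first, then threat" ordering. The
#' `"zero"` constraint instead forbids threat gain before defence.
#'
#' @inheritParams fit_pathway
#' @param constraint `"equal"` (default) or `"zero"`; see
#'   [pathway_model_spec()].
#' @return A `pathway_lrt` with an additional `ordering` element summarizing
#'   the fitted threat-gain rates q01 and q23, which constraint was used, and
#'   the interpretation.
#' @export
directional_test <- function(tree, tip_states, n_starts = 5L, seed = 1L,
                             root_freq = "equal",
                             constraint = c("equal", "zero")) {
  constraint <- match.arg(constraint)
  dep <- fit_pathway(tree, tip_states, pathway_model_spec("dependent_full"),
                     n_starts = n_starts, seed = seed, root_freq = root_freq)
  spec_c <- pathway_model_spec("constrained_directional", constraint)
  con_start <- dep$rates
  if (constraint == "equal")
    con_start[c("q01", "q23")] <- exp(mean(log(pmax(con_start[c("q01", "q23")], 1e-8))))
  con <- fit_pathway(tree, tip_states, spec_c, n_starts = n_starts,
                     seed = seed, root_freq = root_freq,
                     extra_starts = list(con_start))
  # the general model nests the constrained one; seed a re-fit of the
  # dependent model from the constrained MLE if it ever falls below it
  if (dep$log_likelihood < con$log_likelihood) {
    dep <- fit_pathway(tree, tip_states, pathway_model_spec("dependent_full"),
                       n_starts = n_starts, seed = seed + 1L,
                       root_freq = root_freq, extra_starts = list(con$rates))
  }
  out <- .lrt(dep, con, df = 1L)
  q01 <- unname(dep$rates["q01"]); q23 <- unname(dep$rates["q23"])
  out$ordering <- list(
    q01 = q01, q23 = q23, constraint = constraint,
    defended_gain_faster = q23 > q01,
    interpretation = if (out$p_value < 0.05 && q23 > q01)
      "constrained model rejected and q23 > q01: supports defence gained first, then threat"
    else if (out$p_value < 0.05)
      "constrained model rejected but q01 >= q23: no support for the defence-first ordering"
    else
      "constrained model not rejected: threat-gain rates consistent across defence states")
  out
}

#' Minimum (parsimony) transition counts per trait
#'
#' Sankoff parsimony counts of the minimum number of state changes required
#' for the defence and threat traits separately, used as an adequacy check
#' before fitting pathway models (which need multiple independent origins).
#'
#' @param tree A `phylo` object (polytomies allowed).
#' @param tip_states Named 0..3 joint states, [simulate_joint_traits()]
#'   output, or a named binary vector (then a single count is returned).
#' @return List with elements `defence` and `threat` (or `trait` for a
#'   binary input): minimum change counts.
#' @export
count_origins <- function(tree, tip_states) {
  if (is.data.frame(tip_states))
    tip_states <- stats::setNames(tip_states$state, tip_states$species)
  states <- tip_states[tree$tip.label]
  stopifnot(!anyNA(states))
  if (all(states %in% 0:1))
    return(list(trait = .parsimony_steps(tree, as.integer(states))))
  stopifnot(all(states %in% 0:3))
  pair <- joint_state_pair(as.integer(states))
  list(defence = .parsimony_steps(tree, pair$defence),
       threat = .parsimony_steps(tree, pair$threat))
}

.parsimony_steps <- function(tree, x) {
  if (length(unique(x)) < 2L) return(0L)
  m <- matrix(as.character(x), ncol = 1L,
              dimnames = list(tree$tip.label, NULL))
  pd <- phangorn::phyDat(m, type = "USER", levels = c("0", "1"))
  as.integer(phangorn::parsimony(tree, pd, method = "sankoff"))
}
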