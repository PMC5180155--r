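#' Derive a per-operation random seed from a master seed
#'
#' Each stochastic operation draws from its own stream, seeded by hashing the
#' master seed with an operation tag, so adding a stage never perturbs
#' another stage's draws. The result is always a valid 32-bit R seed.
#'
#' @param seed Master integer seed.
#' @param tag Character operation tag.
#' @return An integer in \[0, 2^31).
#' @export
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 48271 + h * 104729) %% 2147483647)
}

#' Simulate a birth-death tree
#'
#' Two modes: conditioned on the number of extant tips (`n_tips`), or run
#' forward for a fixed `age` in Myr. In age mode the whole clade can die;
#' that outcome is reported as a `lineage_extinct` object, not an error.
#'
#' @param n_tips Number of extant tips (condition-on-n mode).
#' @param age Clade age in Myr (condition-on-age mode). Exactly one of
#'   `n_tips`/`age` must be given.
#' @param birth,death Speciation and extinction rates per lineage per Myr.
#' @param seed Integer seed.
#' @return A `phylo` object with tips `t1, t2, ...`, or a `lineage_extinct`
#'   list (fields `age`, `birth`, `death`) if no lineage survived in age mode.
#' @export
simulate_tree <- function(n_tips = NULL, age = NULL, birth = 0.1, death = 0,
                          seed = 1L) {
  stopifnot(birth >= 0, death >= 0)
  if (is.null(n_tips) == is.null(age))
    stop("give exactly one of n_tips or age")
  set.seed(derive_seed(seed, "simulate_tree"))
  if (!is.null(n_tips)) {
    stopifnot(n_tips >= 1)
    if (n_tips == 1L)
      return(as_phylo_tree(ape::read.tree(text = "(t1:1);")))
    tree <- ape::rphylo(n_tips, birth, death)
    return(as_phylo_tree(tree))
  }
  env <- new.env()
  env$n <- 0L
  env$extant <- character()
  txt <- paste0("(", .sim_bd_clade(0, age, birth, death, env), ");")
  if (length(env$extant) == 0L)
    return(structure(list(age = age, birth = birth, death = death),
                     class = "lineage_extinct"))
  full <- ape::read.tree(text = txt)
  if (ape::Ntip(full) > 1L) full <- ape::collapse.singles(full)
  tree <- if (length(env$extant) == ape::Ntip(full)) full else
    ape::keep.tip(full, env$extant)
  if (ape::Ntip(tree) > 1L) tree <- ape::collapse.singles(tree)
  tree$tip.label <- paste0("t", seq_len(ape::Ntip(tree)))
  as_phylo_tree(tree)
}

# forward simulation of one lineage born at t0; builds a Newick fragment
# including extinct side branches, tracking extant tip labels in `env`
.sim_bd_clade <- function(t0, age, birth, death, env) {
  total <- birth + death
  wait <- if (total > 0) stats::rexp(1L, total) else Inf
  if (wait >= age - t0) {
    env$n <- env$n + 1L
    lab <- paste0("s", env$n)
    env$extant <- c(env$extant, lab)
    return(paste0(lab, ":", format(age - t0, digits = 15)))
  }
  if (stats::runif(1L) < birth / total) {
    left <- .sim_bd_clade(t0 + wait, age, birth, death, env)
    right <- .sim_bd_clade(t0 + wait, age, birth, death, env)
    paste0("(", left, ",", right, "):", format(wait, digits = 15))
  } else {
    env$n <- env$n + 1L
    paste0("s", env$n, ":", format(wait, digits = 15))
  }
}

# Evolve a vector of 1-based states over duration t under generator Q by
# exact event-driven sampling (competing exponentials). Optionally accumulate
# transition counts and per-state occupancy time into `env`.
.evolve_states <- function(states, t, Q, env = NULL) {
  k <- nrow(Q)
  leave <- -diag(Q)
  jp <- Q
  diag(jp) <- 0
  jp <- jp / ifelse(leave > 0, leave, 1)
  cum <- t(apply(jp, 1, cumsum))
  remaining <- rep(t, length(states))
  active <- seq_along(states)
  while (length(active)) {
    lam <- leave[states[active]]
    w <- rep(Inf, length(active))
    pos <- lam > 0
    if (any(pos)) w[pos] <- stats::rexp(sum(pos), lam[pos])
    jump <- w < remaining[active]
    if (!is.null(env)) {
      dwell <- pmin(w, remaining[active])
      st <- states[active]
      env$occupancy <- env$occupancy +
        vapply(seq_len(k), function(s) sum(dwell[st == s]), 0)
    }
    j <- active[jump]
    if (!length(j)) break
    remaining[j] <- remaining[j] - w[jump]
    u <- stats::runif(length(j))
    cs <- cum[states[j], , drop = FALSE]
    new <- pmin(1L + as.integer(rowSums(u > cs)), k)
    if (!is.null(env)) {
      for (r in seq_along(j))
        env$transitions[states[j[r]], new[r]] <-
          env$transitions[states[j[r]], new[r]] + 1
    }
    states[j] <- new
    active <- j
  }
  states
}

#' Simulate joint (defence, threat) evolution under a 4-state Markov model
#'
#' States are evolved down the tree by exact event-driven sampling of
#' competing exponential waiting times per branch (no time discretization).
#' Joint states are indexed 0 = (D=0,T=0), 1 = (D=0,T=1), 2 = (D=1,T=0),
#' 3 = (D=1,T=1); see [joint_state_index()].
#'
#' @param tree A `phylo` object.
#' @param q A 4x4 generator matrix (see [rate_matrix()]); any k-state
#'   generator is accepted.
#' @param root_state Root state in `0..k-1`.
#' @param seed Integer seed.
#' @param n_rep Number of independent replicates evolved on the same tree.
#' @param return_events If `TRUE`, attach attributes `transitions` (k x k
#'   realized transition counts summed over replicates) and `occupancy`
#'   (time spent per state, summed over replicates and branches).
#' @return For `n_rep = 1`, a data.frame with columns `species`, `defence`,
#'   `threat`, `state` (when k = 4) or `species`, `state` otherwise. For
#'   `n_rep > 1`, an integer matrix of states (replicates x tips, 0-based).
#' @export
simulate_joint_traits <- function(tree, q, root_state = 0L, seed = 1L,
                                  n_rep = 1L, return_events = FALSE) {
  q <- unclass(q)
  k <- nrow(q)
  stopifnot(root_state %in% 0:(k - 1))
  .validate_generator(q)
  set.seed(derive_seed(seed, "simulate_joint_traits"))
  env <- NULL
  if (return_events) {
    env <- new.env()
    env$transitions <- matrix(0, k, k)
    env$occupancy <- numeric(k)
  }
  n <- ape::Ntip(tree)
  if (n == 1L) {
    st <- .evolve_states(rep(root_state + 1L, n_rep), sum(tree$edge.length), q, env)
    states <- matrix(st - 1L, n_rep, 1L, dimnames = list(NULL, tree$tip.label))
  } else {
    tr <- ape::reorder.phylo(tree, "postorder")
    n_nodes <- n + tr$Nnode
    node_states <- matrix(NA_integer_, n_rep, n_nodes)
    node_states[, n + 1L] <- root_state + 1L
    # preorder = reverse postorder: parents are assigned before children
    for (i in rev(seq_len(nrow(tr$edge)))) {
      par <- tr$edge[i, 1L]; ch <- tr$edge[i, 2L]
      node_states[, ch] <- .evolve_states(node_states[, par],
                                          tr$edge.length[i], q, env)
    }
    states <- node_states[, seq_len(n), drop = FALSE] - 1L
    colnames(states) <- tr$tip.label
    states <- states[, tree$tip.label, drop = FALSE]
  }
  out <- if (n_rep == 1L) {
    s <- states[1L, ]
    if (k == 4L) {
      data.frame(species = names(s), defence = s %/% 2L, threat = s %% 2L,
                 state = unname(s), row.names = NULL)
    } else {
      data.frame(species = names(s), state = unname(s), row.names = NULL)
    }
  } else states
  if (return_events) {
    attr(out, "transitions") <- env$transitions
    attr(out, "occupancy") <- env$occupancy
  }
  out
}

#' Simulate ordinal status from a latent phylogenetic liability
#'
#' Liability = `beta * defence` + a phylogenetic effect (multivariate normal
#' with covariance `sigma2_phylo * C`) + an independent residual with
#' variance `sigma2_res`. Status is the count of thresholds lying below the
#' liability, so `length(thresholds)` thresholds give
#' `length(thresholds) + 1` categories.
#'
#' @param tree A `phylo` object.
#' @param defence Named 0/1 vector over the tips.
#' @param beta Defence effect on the liability scale.
#' @param thresholds Strictly increasing numeric vector.
#' @param sigma2_phylo,sigma2_res Variance components (>= 0).
#' @param seed Integer seed.
#' @return Named integer vector of statuses in `0..length(thresholds)`.
#' @export
simulate_ordinal_status <- function(tree, defence, beta, thresholds,
                                    sigma2_phylo = 0, sigma2_res = 1,
                                    seed = 1L) {
  stopifnot(sigma2_phylo >= 0, sigma2_res >= 0,
            !is.unsorted(thresholds, strictly = TRUE))
  defence <- defence[tree$tip.label]
  stopifnot(!anyNA(defence))
  set.seed(derive_seed(seed, "simulate_ordinal_status"))
  n <- ape::Ntip(tree)
  u <- if (sigma2_phylo > 0) {
    C <- phylo_covariance(tree)
    drop(MASS::mvrnorm(1L, mu = rep(0, n), Sigma = sigma2_phylo * C))
  } else numeric(n)
  liab <- beta * as.numeric(defence) + u +
    stats::rnorm(n, 0, sqrt(sigma2_res))
  status <- as.integer(rowSums(outer(liab, thresholds, `>`)))
  stats::setNames(status, tree$tip.label)
}

#' Simulate a Brownian-motion covariate on a tree
#'
#' Tip values are jointly multivariate normal with mean `root_value` and
#' covariance `rate * C` where C is the shared-path-length matrix.
#'
#' @param tree A `phylo` object.
#' @param rate Brownian rate (variance per Myr, >= 0).
#' @param root_value Value at the root.
#' @param seed Integer seed.
#' @param n_rep Number of replicate draws.
#' @return Named numeric vector (or an `n_rep` x n_tips matrix).
#' @export
simulate_brownian_covariate <- function(tree, rate, root_value = 0,
                                        seed = 1L, n_rep = 1L) {
  stopifnot(rate >= 0)
  set.seed(derive_seed(seed, "simulate_brownian_covariate"))
  n <- ape::Ntip(tree)
  if (rate == 0) {
    vals <- matrix(root_value, n_rep, n)
  } else {
    C <- phylo_covariance(tree)
    vals <- MASS::mvrnorm(n_rep, mu = rep(root_value, n), Sigma = rate * C)
    vals <- matrix(vals, n_rep, n)
  }
  colnames(vals) <- tree$tip.label
  if (n_rep == 1L) drop(vals)[tree$tip.label] else vals
}

#' Default synthetic-study configuration
#'
#' Returns the generator settings used by [simulate_study()]: a 400-tip
#' birth-death tree (birth 0.1, death 0.03 per Myr, amphibian-scale), a
#' two-state defence gain/loss process (0.01 and 0.005 per Myr), a defence
#' effect of 1 on the liability scale with unit residual variance, moderate
#' phylogenetic liability variance (0.5), and thresholds placed so least
#' concern is the most common category.
#'
#' @param ... Overrides for any field.
#' @return A named list.
#' @export
study_config <- function(...) {
  cfg <- list(
    n_tips = 400L, birth = 0.1, death = 0.03,
    defence_gain = 0.01, defence_loss = 0.005, defence_root = 0L,
    beta_defence = 1, thresholds = c(0.8, 1.6, 2.4, 3.2, 4.0),
    sigma2_phylo = 0.5, sigma2_res = 1,
    covariate_rate = 0.02, seed = 1L
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  cfg
}

#' Simulate a complete synthetic study
#'
#' Produces a tree and a trait table with the same structure the empirical
#' pipeline expects: a binary chemical defence evolved as a two-state Markov
#' process, an ordinal status generated from a latent phylogenetic liability
#' with a defence effect, the corresponding IUCN category labels, and a
#' Brownian covariate. The derived `threat`/`status` codes then follow from
#' [build_dataset()] exactly as for real data.
#'
#' @param config A list from [study_config()].
#' @return List with `tree` (`phylo`), `traits` (data.frame with columns
#'   `species`, `chemical_defence`, `iucn_category`, `absolute_latitude`),
#'   and `config`.
#' @export
simulate_study <- function(config = study_config()) {
  tree <- simulate_tree(n_tips = config$n_tips, birth = config$birth,
                        death = config$death, seed = config$seed)
  q2 <- matrix(c(-config$defence_gain, config$defence_gain,
                 config$defence_loss, -config$defence_loss),
               2, 2, byrow = TRUE)
  def <- simulate_joint_traits(tree, q2, root_state = config$defence_root,
                               seed = derive_seed(config$seed, "defence"))
  defence <- stats::setNames(def$state, def$species)
  status <- simulate_ordinal_status(
    tree, defence, beta = config$beta_defence,
    thresholds = config$thresholds, sigma2_phylo = config$sigma2_phylo,
    sigma2_res = config$sigma2_res,
    seed = derive_seed(config$seed, "status"))
  lat <- simulate_brownian_covariate(tree, rate = config$covariate_rate,
                                     root_value = 10,
                                     seed = derive_seed(config$seed, "lat"))
  traits <- data.frame(
    species = tree$tip.label,
    chemical_defence = as.integer(defence[tree$tip.label]),
    iucn_category = status_to_category(status[tree$tip.label]),
    absolute_latitude = abs(as.numeric(lat[tree$tip.label])),
    row.names = NULL
  )
  list(tree = tree, traits = traits, config = config)
}

#' Write a synthetic fixture bundle to a directory
#'
#' Writes `tree.nwk`, `traits.csv` and `config.yaml` so any run can be
#' reproduced from files alone.
#'
#' @param dir Output directory (created if needed).
#' @param config A [study_config()] list.
#' @return The directory path, invisibly.
#' @export
write_fixture_bundle <- function(dir, config = study_config()) {
  study <- simulate_study(config)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_newick(study$tree, file.path(dir, "tree.nwk"))
  utils::write.csv(study$traits, file.path(dir, "traits.csv"),
                   row.names = FALSE)
  yaml::write_yaml(config, file.path(dir, "config.yaml"))
  invisible(dir)
}
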