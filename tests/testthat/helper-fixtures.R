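# shared fixtures: all built in code at test time

toy_newick <- "((A:1,B:1):1,C:2);"

read_toy <- function(txt = toy_newick) {
  as_phylo_tree(ape::read.tree(text = txt))
}

make_tree <- function(n, seed = 1, birth = 0.1, death = 0) {
  simulate_tree(n_tips = n, birth = birth, death = death, seed = seed)
}

make_star <- function(n, depth = 1) {
  star <- ape::stree(n, "star")
  star$edge.length <- rep(depth, n)
  star$tip.label <- paste0("t", seq_len(n))
  star
}

# named 8-rate vector for a trait-independent generator
indep_rates <- function(threat_gain, threat_loss, defence_gain, defence_loss) {
  pathway_model_spec("independent")$expand(
    c(threat_gain, threat_loss, defence_gain, defence_loss))
}

# 2-state generator (state 1 -> 2 at rate gain, 2 -> 1 at rate loss)
q2state <- function(gain, loss) {
  matrix(c(-gain, gain, loss, -loss), 2, 2, byrow = TRUE)
}

# tip-state vector from a simulate_joint_traits data.frame
state_vec <- function(sim) stats::setNames(sim$state, sim$species)

# reference transition matrix by an independent route (series expansion)
expm_series <- function(Q, t, terms = 60L) {
  k <- nrow(Q)
  P <- diag(k)
  term <- diag(k)
  A <- Q * t
  # scaling and squaring on top of the series for large t
  s <- max(0L, ceiling(log2(max(1, max(abs(A))))))
  A <- A / 2^s
  for (i in seq_len(terms)) {
    term <- term %*% A / i
    P <- P + term
  }
  for (i in seq_len(s)) P <- P %*% P
  P
}
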