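## Independent oracles used across the suite.  These deliberately do not
## call the package's likelihood internals: the birth-death quantities are
## recomputed from the Kendall transition probabilities in plain R, and the
## BiSSE reference value comes from a naive fixed-step integrator.

## Kendall extinction / geometric parameters (plain-R reference)
oracle_ab <- function(b, d, t) {
  r <- b - d
  if (abs(r) < 1e-12 * (b + d)) {
    bt <- b * t
    list(alpha = d * t / (1 + bt), beta = bt / (1 + bt))
  } else {
    em <- expm1(r * t)
    den <- b * em + r
    list(alpha = d * em / den, beta = b * em / den)
  }
}

## term-by-term piece log-likelihood: b per observed split, W(s)/W(t) per
## internal edge, unconditioned geometric per tip
oracle_piece_lnl <- function(n_b, int_s, int_t, tip_s, tip_n, b, d) {
  W <- function(u) {
    ab <- oracle_ab(b, d, u)
    (1 - ab$alpha) * (1 - ab$beta)
  }
  ll <- n_b * log(b)
  for (i in seq_along(int_s)) ll <- ll + log(W(int_s[i])) - log(W(int_t[i]))
  for (i in seq_along(tip_s)) {
    ab <- oracle_ab(b, d, tip_s[i])
    ll <- ll + log((1 - ab$alpha) * (1 - ab$beta)) +
      (tip_n[i] - 1) * log(ab$beta)
  }
  ll
}

## whole-tree version of the oracle via explicit edge enumeration
oracle_tree_lnl <- function(tree, b, d, richness = NULL) {
  nt <- length(tree$tip.label)
  ages <- node_ages(tree)
  rich <- if (is.null(richness)) rep(1, nt) else unname(richness[tree$tip.label])
  parent <- tree$edge[match(seq_len(nt + tree$Nnode), tree$edge[, 2]), 1]
  internal_children <- setdiff(tree$edge[, 2], seq_len(nt))
  oracle_piece_lnl(
    n_b = tree$Nnode - 1,                  # root split taken as given
    int_s = ages[parent[internal_children]],
    int_t = ages[internal_children],
    tip_s = ages[parent[seq_len(nt)]],
    tip_n = rich, b = b, d = d)
}

## brute-force MRCA by ancestor-set intersection
oracle_mrca <- function(tree, tips) {
  nt <- length(tree$tip.label)
  parent <- tree$edge[match(seq_len(nt + tree$Nnode), tree$edge[, 2]), 1]
  anc <- function(v) {
    path <- v
    while (!is.na(parent[v])) { v <- parent[v]; path <- c(path, v) }
    path
  }
  ids <- match(tips, tree$tip.label)
  common <- Reduce(intersect, lapply(ids, anc))
  ages <- node_ages(tree)
  common[which.min(ages[common])]
}

## forward birth-death count process (no tree), vectorized over replicates
oracle_sim_counts <- function(b, d, t, reps) {
  n <- rep(1L, reps); tm <- rep(0, reps)
  repeat {
    act <- which(n > 0 & tm < t)
    if (!length(act)) break
    rate <- (b + d) * n[act]
    tm2 <- tm[act] + stats::rexp(length(act), rate)
    birth <- stats::runif(length(act)) < b / (b + d)
    ok <- tm2 <= t
    n[act[ok]] <- n[act[ok]] + ifelse(birth[ok], 1L, -1L)
    tm[act] <- ifelse(ok, tm2, t)
  }
  n
}

## naive fixed-step RK4 for the coupled BiSSE system on one branch
oracle_bisse_rk4 <- function(y, pars, len, n_steps = 20000) {
  f <- function(y) {
    E0 <- y[1]; E1 <- y[2]; D0 <- y[3]; D1 <- y[4]
    c(pars["mu0"] - (pars["lambda0"] + pars["mu0"] + pars["q01"]) * E0 +
        pars["lambda0"] * E0^2 + pars["q01"] * E1,
      pars["mu1"] - (pars["lambda1"] + pars["mu1"] + pars["q10"]) * E1 +
        pars["lambda1"] * E1^2 + pars["q10"] * E0,
      -(pars["lambda0"] + pars["mu0"] + pars["q01"]) * D0 +
        2 * pars["lambda0"] * E0 * D0 + pars["q01"] * D1,
      -(pars["lambda1"] + pars["mu1"] + pars["q10"]) * D1 +
        2 * pars["lambda1"] * E1 * D1 + pars["q10"] * D0)
  }
  h <- len / n_steps
  for (i in seq_len(n_steps)) {
    k1 <- f(y); k2 <- f(y + h / 2 * k1); k3 <- f(y + h / 2 * k2); k4 <- f(y + h * k3)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  y
}

## independent two-state Markov character pruning likelihood with the same
## relative-weight root treatment as the state-dependent likelihood
oracle_char_lnl <- function(tree, states, q01, q10) {
  nt <- length(tree$tip.label)
  po <- ape::reorder.phylo(tree, "postorder")
  L <- matrix(0, nt + tree$Nnode, 2)
  for (i in seq_len(nt)) L[i, states[tree$tip.label[i]] + 1] <- 1
  seen <- integer(nt + tree$Nnode)
  qtot <- q01 + q10; pi0 <- q10 / qtot; pi1 <- q01 / qtot
  Pm <- function(t) {
    e <- exp(-qtot * t)
    matrix(c(pi0 + pi1 * e, pi1 - pi1 * e,
             pi0 - pi0 * e, pi1 + pi0 * e), 2, 2, byrow = TRUE)
  }
  logc <- 0
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1]; ch <- po$edge[e, 2]
    v <- as.numeric(Pm(po$edge.length[e]) %*% L[ch, ])
    if (!seen[p]) { L[p, ] <- v; seen[p] <- 1 }
    else {
      L[p, ] <- L[p, ] * v
      s <- sum(L[p, ]); L[p, ] <- L[p, ] / s; logc <- logc + log(s)
    }
  }
  r <- L[nt + 1, ]
  log(sum(r^2) / sum(r)) + logc
}

## nodes within one edge of a node (the node, its parent, its children):
## a planted regime switches on the stem branch, so placement at an
## adjacent node describes the same configuration at single-branch
## resolution
adjacent_nodes <- function(tree, node) {
  c(node,
    tree$edge[tree$edge[, 2] == node, 1],
    tree$edge[tree$edge[, 1] == node, 2])
}

## deterministic fixture: a small shifted-tree scenario shared by tests
fixture_shifted <- function(seed) {
  sim_shifted_tree(0.14, 0, shifts = list(time = 20, b = 0.7, d = 0),
                   stop = list(age = 25), seed = seed, min_clade_tips = 15)
}

## leaner variant (~60-80 tips) for experiments that repeat the search
## hundreds of times
fixture_shifted_small <- function(seed) {
  sim_shifted_tree(0.14, 0, shifts = list(time = 17.5, b = 0.7, d = 0),
                   stop = list(age = 22), seed = seed, min_clade_tips = 10)
}
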