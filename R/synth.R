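## Forward simulators that plant known truth: birth-death trees, clade rate
## shifts, genus-collapsed richness, pseudo-posterior tree sets, and joint
## tree + binary-state simulation.  All are pure functions of (settings,
## seed): the caller's RNG state is saved and restored.

.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

## Internal lineage-table Gillespie engine.  Starts from two crown lineages.
## regimes: data.frame-ish list of (b, d) per regime id; lineages carry a
## regime id; `shift_plan` optionally switches one lineage to a new regime at
## a given time.  Returns the lineage table at the stop condition or NULL if
## the run died / missed the stop condition.
.gillespie <- function(b, d, stop_age = NULL, stop_taxa = NULL,
                       shifts = NULL) {
  ## lineage records, grown geometrically
  cap <- 256L
  parent <- integer(cap); t0 <- numeric(cap); t1 <- numeric(cap)
  status <- integer(cap)  # 0 = active, 1 = split, 2 = dead, 3 = extant
  regime <- integer(cap)
  n_reg <- 1L
  bs <- b; ds <- d
  parent[1:2] <- 0L; t0[1:2] <- 0; regime[1:2] <- 1L
  n <- 2L
  active <- c(1L, 2L)
  tm <- 0
  shift_i <- 1L
  shift_nodes <- integer(0)
  repeat {
    if (!length(active)) return(NULL)
    rates <- bs[regime[active]] + ds[regime[active]]
    tot <- sum(rates)
    dt <- stats::rexp(1L, tot)
    ## pending planted shift?
    if (!is.null(shifts) && shift_i <= length(shifts$time) &&
        tm + dt >= shifts$time[shift_i]) {
      tm <- shifts$time[shift_i]
      if (!is.null(stop_age) && tm >= stop_age) { tm <- stop_age; break }
      ## switch a uniformly chosen background-regime lineage
      cand <- active[regime[active] == 1L]
      if (!length(cand)) return(NULL)
      pick <- cand[sample.int(length(cand), 1L)]
      n_reg <- n_reg + 1L
      bs <- c(bs, shifts$b[shift_i]); ds <- c(ds, shifts$d[shift_i])
      regime[pick] <- n_reg
      shift_nodes <- c(shift_nodes, pick)
      shift_i <- shift_i + 1L
      next
    }
    if (!is.null(stop_age) && tm + dt >= stop_age) { tm <- stop_age; break }
    tm <- tm + dt
    lin <- active[sample.int(length(active), 1L,
                             prob = rates / tot)]
    if (stats::runif(1L) < bs[regime[lin]] / (bs[regime[lin]] + ds[regime[lin]])) {
      ## split: two daughters inherit the regime
      if (n + 2L > cap) {
        cap <- cap * 2L
        length(parent) <- cap; length(t0) <- cap; length(t1) <- cap
        length(status) <- cap; length(regime) <- cap
        parent[is.na(parent)] <- 0L
      }
      status[lin] <- 1L; t1[lin] <- tm
      kids <- c(n + 1L, n + 2L)
      parent[kids] <- lin; t0[kids] <- tm; regime[kids] <- regime[lin]
      status[kids] <- 0L; t1[kids] <- 0
      n <- n + 2L
      active <- c(active[active != lin], kids)
      if (!is.null(stop_taxa) && length(active) >= stop_taxa) {
        ## stop just before the next event so pendant branches are positive
        tot2 <- sum(bs[regime[active]] + ds[regime[active]])
        if (tot2 > 0) tm <- tm + stats::rexp(1L, tot2)
        break
      }
    } else {
      status[lin] <- 2L; t1[lin] <- tm
      active <- active[active != lin]
    }
  }
  if (length(active) < 2L) return(NULL)
  status[active] <- 3L; t1[active] <- tm
  list(parent = parent[1:n], t0 = t0[1:n], t1 = t1[1:n],
       status = status[1:n], regime = regime[1:n], age = tm,
       shift_lineages = shift_nodes)
}

## Convert a lineage table to an extant-only ultrametric phylo.
## Returns NULL if fewer than 2 extant lineages or no root split survives.
.lineages_to_phylo <- function(L, tip_prefix = "t") {
  n <- length(L$parent)
  extant <- which(L$status == 3L)
  if (length(extant) < 2L) return(NULL)
  keep <- logical(n)   # has extant descendants
  keep[extant] <- TRUE
  for (i in n:1) if (keep[i] && L$parent[i] > 0L) keep[L$parent[i]] <- TRUE
  ## count surviving children per lineage
  nkid <- integer(n)
  for (i in seq_len(n)) if (keep[i] && L$parent[i] > 0L)
    nkid[L$parent[i]] <- nkid[L$parent[i]] + 1L
  ## crown roots: the two starting lineages; require both sides alive
  if (!keep[1L] || !keep[2L]) return(NULL)
  ## Build newick by walking the pruned tree, suppressing single-child chains.
  ## span(i): the (sub)tree hanging from lineage i, with branch length from
  ## its start time down to its end through any single-child chain.
  lab <- character(n); lab[extant] <- paste0(tip_prefix, seq_along(extant))
  node_of <- integer(n)
  ## iterative postorder over kept lineages
  kids <- vector("list", n)
  for (i in seq_len(n)) if (keep[i] && L$parent[i] > 0L && keep[L$parent[i]])
    kids[[L$parent[i]]] <- c(kids[[L$parent[i]]], i)
  nw <- character(n)
  len <- numeric(n)    # branch length from lineage start to its subtree top
  order <- integer(0)
  stack <- c(1L, 2L); seen <- logical(n)
  while (length(stack)) {
    v <- stack[length(stack)]
    kk <- kids[[v]]
    if (!seen[v] && length(kk)) { seen[v] <- TRUE; stack <- c(stack, kk); next }
    stack <- stack[-length(stack)]
    order <- c(order, v)
  }
  for (v in order) {
    kk <- kids[[v]]
    span <- L$t1[v] - L$t0[v]
    if (L$status[v] == 3L) {
      nw[v] <- lab[v]; len[v] <- span
    } else if (length(kk) == 1L) {       # suppressed degree-2 node
      nw[v] <- nw[kk]; len[v] <- span + len[kk]
    } else {
      nw[v] <- paste0("(", paste0(nw[kk], ":", format(len[kk], digits = 17),
                                  collapse = ","), ")")
      len[v] <- span
    }
  }
  txt <- paste0("(", nw[1L], ":", format(len[1L], digits = 17), ",",
                nw[2L], ":", format(len[2L], digits = 17), ");")
  phy <- ape::read.tree(text = txt)
  phy
}

#' Simulate an extant-only birth-death tree
#'
#' Forward Gillespie simulation from two crown lineages; extinct lineages
#' are pruned and degree-2 nodes suppressed.  Conditioned by rejection on
#' both crown lineages leaving extant descendants (so the crown age equals
#' `stop$age` exactly under the age stop rule).
#'
#' @param b,d speciation and extinction rates (per lineage per My).
#' @param stop list with either `age` (run to a fixed crown age, My) or
#'   `taxa` (stop when the extant count first reaches this number).
#' @param seed integer seed; same seed, same tree, caller RNG untouched.
#' @param max_tries rejection budget (exceeded e.g. when d >> b).
#' @return a `time_tree` with tips labelled `t1, t2, ...`.
#' @export
sim_bd_tree <- function(b, d = 0, stop = list(age = 10), seed = NULL,
                        max_tries = 1000L) {
  stopifnot(b > 0, d >= 0)
  .with_seed(seed, {
    for (i in seq_len(max_tries)) {
      L <- .gillespie(b, d, stop_age = stop$age, stop_taxa = stop$taxa)
      if (is.null(L)) next
      phy <- .lineages_to_phylo(L)
      if (is.null(phy)) next
      if (!is.null(stop$taxa) && length(phy$tip.label) < stop$taxa) next
      return(as_time_tree(phy))
    }
    stop("rejection budget exhausted after ", max_tries,
         " tries (is d too close to or above b?)")
  })
}

#' Simulate a tree with planted diversification-rate shifts
#'
#' Background rates apply from the crown; at each planned shift time one
#' uniformly chosen background lineage (and all its descendants) switches to
#' the shift regime.  Rejection ensures every planted clade survives with at
#' least `min_clade_tips` extant tips, so the truth is always a clade of the
#' output tree.
#'
#' @param b,d background rates.
#' @param shifts list with vectors `time`, `b`, `d` (one entry per planted
#'   shift, times increasing); may be `NULL` for none.
#' @param stop,seed,max_tries as in [sim_bd_tree].
#' @param min_clade_tips minimum extant tips per planted clade.
#' @return list with `tree` (a `time_tree`) and `true_clades` (list of
#'   [clade_key]s, one per planted shift that has >= 2 tips... always
#'   `min_clade_tips` by construction).
#' @export
sim_shifted_tree <- function(b, d = 0, shifts = NULL, stop = list(age = 10),
                             seed = NULL, min_clade_tips = 2L,
                             max_tries = 1000L) {
  if (is.null(shifts) || length(shifts$time) == 0L) {
    tr <- sim_bd_tree(b, d, stop, seed, max_tries)
    return(list(tree = tr, true_clades = list()))
  }
  .with_seed(seed, {
    for (i in seq_len(max_tries)) {
      L <- .gillespie(b, d, stop_age = stop$age, stop_taxa = stop$taxa,
                      shifts = shifts)
      if (is.null(L)) next
      if (length(L$shift_lineages) < length(shifts$time)) next
      phy <- .lineages_to_phylo(L)
      if (is.null(phy)) next
      ## identify extant descendants of each shifted lineage
      n <- length(L$parent)
      extant <- which(L$status == 3L)
      lab <- paste0("t", seq_along(extant))
      keys <- vector("list", length(L$shift_lineages))
      ok <- TRUE
      for (k in seq_along(L$shift_lineages)) {
        root_lin <- L$shift_lineages[k]
        below <- logical(n); below[root_lin] <- TRUE
        for (j in seq_len(n)) if (L$parent[j] > 0L && below[L$parent[j]])
          below[j] <- TRUE
        tips <- lab[match(intersect(which(below), extant), extant)]
        if (length(tips) < min_clade_tips) { ok <- FALSE; break }
        keys[[k]] <- clade_key(tips)
      }
      if (!ok) next
      tr <- as_time_tree(phy)
      if (!is.null(stop$taxa) && length(tr$tip.label) < stop$taxa) next
      return(list(tree = tr, true_clades = keys))
    }
    stop("rejection budget exhausted: planted clade(s) kept failing to survive")
  })
}

#' Collapse tips into genus-level unresolved clades with richness
#'
#' Repeatedly merges a random cherry (two sister tips) into a single
#' representative tip carrying the summed species count, until the target
#' number of genera remains.  Collapsed blocks are therefore always
#' monophyletic and the richness total always equals the original tip
#' count.
#'
#' @param tree a `time_tree`.
#' @param target_genera number of tips to keep (>= 2).
#' @param seed integer seed.
#' @return list with `tree` (collapsed `time_tree`) and `richness` (a
#'   [richness_table] over the remaining tips).
#' @export
collapse_genera <- function(tree, target_genera, seed = NULL) {
  stopifnot(target_genera >= 2L)
  if (length(tree$tip.label) < target_genera)
    stop("tree has fewer tips than target_genera")
  .with_seed(seed, {
    rich <- stats::setNames(rep(1L, length(tree$tip.label)), tree$tip.label)
    phy <- tree
    while (length(phy$tip.label) > target_genera) {
      nt <- length(phy$tip.label)
      par <- phy$edge[match(seq_len(nt), phy$edge[, 2L]), 1L]
      tab <- table(par)
      cherries <- as.integer(names(tab)[tab == 2L])
      if (!length(cherries)) break
      ch <- cherries[sample.int(length(cherries), 1L)]
      pair <- phy$edge[phy$edge[, 1L] == ch & phy$edge[, 2L] <= nt, 2L]
      keep_lab <- phy$tip.label[pair[1L]]
      drop_lab <- phy$tip.label[pair[2L]]
      rich[keep_lab] <- rich[keep_lab] + rich[drop_lab]
      rich <- rich[names(rich) != drop_lab]
      phy <- ape::drop.tip(phy, drop_lab)
    }
    list(tree = as_time_tree(phy), richness = richness_table(rich))
  })
}

#' Pseudo-posterior sample by jittering a reference tree
#'
#' Emulates a Bayesian posterior tree sample: each replicate applies
#' multiplicative lognormal jitter to internal node ages (ultrametricity and
#' parent-older-than-child order restored) and local nearest-neighbour
#' topology rearrangements at a per-node rate.  Tip sets are preserved.
#'
#' @param tree reference `time_tree`.
#' @param n_trees number of replicates.
#' @param age_sd lognormal sd of the age jitter (0 = none).
#' @param topo_rate per-internal-edge probability of an NNI-style swap.
#' @param seed integer seed.
#' @return a `tree_sample` of `n_trees` valid `time_tree`s.
#' @export
pseudo_posterior <- function(tree, n_trees, age_sd = 0, topo_rate = 0,
                             seed = NULL) {
  stopifnot(n_trees >= 1L)
  .with_seed(seed, {
    out <- vector("list", n_trees)
    for (i in seq_len(n_trees)) out[[i]] <- .jitter_tree(tree, age_sd, topo_rate)
    tree_sample(out, source = sprintf("pseudo_posterior(age_sd=%g, topo_rate=%g)",
                                      age_sd, topo_rate))
  })
}

.jitter_tree <- function(tree, age_sd, topo_rate) {
  phy <- tree
  nt <- length(phy$tip.label)
  if (topo_rate > 0) {
    ## number of NNI-style swaps ~ Binomial(#internal edges, topo_rate);
    ## eligible edges are re-listed after every swap (node ids change)
    n_candidates <- sum(phy$edge[, 2L] > nt)
    n_swaps <- stats::rbinom(1L, n_candidates, topo_rate)
    for (k in seq_len(n_swaps)) {
      internal <- which(phy$edge[, 2L] > nt)
      if (!length(internal)) break
      e <- internal[sample.int(length(internal), 1L)]
      phy <- .nni_swap(phy, e, nt)
    }
  }
  if (age_sd > 0 || topo_rate > 0) {
    ages <- .node_ages_from_lengths(phy)
    ## postorder: jitter each internal age, keep parent > children
    po <- ape::reorder.phylo(phy, "postorder")
    childmax <- numeric(nt + phy$Nnode)
    new_age <- ages
    for (i in seq_len(nrow(po$edge))) {
      ch <- po$edge[i, 2L]; p <- po$edge[i, 1L]
      if (ch > nt) {
        a <- if (age_sd > 0) ages[ch] * exp(stats::rnorm(1L, 0, age_sd)) else ages[ch]
        new_age[ch] <- max(a, childmax[ch] * (1 + 1e-9) + 1e-9)
      } else new_age[ch] <- 0
      childmax[p] <- max(childmax[p], new_age[ch])
    }
    root <- nt + 1L
    a <- if (age_sd > 0) ages[root] * exp(stats::rnorm(1L, 0, age_sd)) else ages[root]
    new_age[root] <- max(a, childmax[root] * (1 + 1e-9) + 1e-9)
    phy$edge.length <- new_age[phy$edge[, 1L]] - new_age[phy$edge[, 2L]]
  }
  as_time_tree(phy)
}

## swap the sibling of edge e's child with one of the child's children,
## then repair the child's age if needed
.nni_swap <- function(phy, e, nt) {
  p <- phy$edge[e, 1L]; c1 <- phy$edge[e, 2L]
  ages <- .node_ages_from_lengths(phy)
  sib <- phy$edge[phy$edge[, 1L] == p & phy$edge[, 2L] != c1, 2L]
  if (length(sib) != 1L) return(phy)
  g <- phy$edge[phy$edge[, 1L] == c1, 2L]
  if (length(g) != 2L) return(phy)
  gpick <- g[sample.int(2L, 1L)]
  ## reattach: sib under c1, gpick under p
  i_sib <- which(phy$edge[, 2L] == sib)
  i_g <- which(phy$edge[, 2L] == gpick)
  phy$edge[i_sib, 1L] <- c1
  phy$edge[i_g, 1L] <- p
  ## repair c1 age: must exceed its new children's ages and stay below p
  kid_ages <- ages[phy$edge[phy$edge[, 1L] == c1, 2L]]
  lo <- max(kid_ages); hi <- ages[p]
  a_c1 <- ages[c1]
  if (a_c1 <= lo || a_c1 >= hi) a_c1 <- (lo + hi) / 2
  new_age <- ages; new_age[c1] <- a_c1
  phy$edge.length <- new_age[phy$edge[, 1L]] - new_age[phy$edge[, 2L]]
  attr(phy, "order") <- NULL
  phy <- ape::read.tree(text = ape::write.tree(phy))
  phy
}

#' Joint simulation of a tree and a binary state (BiSSE process)
#'
#' Forward Gillespie simulation where each lineage carries state 0 or 1 and
#' experiences state-specific speciation (`lambda0`/`lambda1`), extinction
#' (`mu0`/`mu1`) and state flips (`q01`, `q10`).  Extant-only ultrametric
#' output with tip states.
#'
#' @param pars named list or vector with `lambda0, lambda1, mu0, mu1, q01,
#'   q10`.
#' @param stop list with `age` or `taxa` as in [sim_bd_tree].
#' @param root_state 0 or 1.
#' @param seed integer seed.
#' @param max_tries rejection budget.
#' @param sampling_f optional `c(f0, f1)`: each extant tip in state i is
#'   retained with probability `f_i` (emulating incomplete sampling).
#' @return list with `tree` (a `time_tree`) and `states` (a [trait_table]).
#' @export
sim_bisse_tree <- function(pars, stop = list(age = 10), root_state = 0L,
                           seed = NULL, max_tries = 1000L, sampling_f = NULL) {
  p <- as.list(pars)
  need <- c("lambda0", "lambda1", "mu0", "mu1", "q01", "q10")
  stopifnot(all(need %in% names(p)))
  for (nm in need) stopifnot(p[[nm]] >= 0)
  .with_seed(seed, {
    for (try in seq_len(max_tries)) {
      sim <- .gillespie_bisse(p, stop, root_state)
      if (is.null(sim)) next
      phy <- .lineages_to_phylo(sim$L)
      if (is.null(phy)) next
      extant <- which(sim$L$status == 3L)
      st <- stats::setNames(sim$state[extant], paste0("t", seq_along(extant)))
      if (!is.null(sampling_f)) {
        keepp <- ifelse(st == 0L, sampling_f[1L], sampling_f[2L])
        keep <- stats::runif(length(st)) < keepp
        if (sum(keep) < 3L) next
        phy <- ape::drop.tip(phy, names(st)[!keep])
        st <- st[phy$tip.label]
      }
      if (!is.null(stop$taxa) && length(phy$tip.label) < stop$taxa &&
          is.null(sampling_f)) next
      return(list(tree = as_time_tree(phy), states = trait_table(st)))
    }
    stop("rejection budget exhausted in sim_bisse_tree")
  })
}

.gillespie_bisse <- function(p, stop, root_state) {
  cap <- 256L
  parent <- integer(cap); t0 <- numeric(cap); t1 <- numeric(cap)
  status <- integer(cap); state <- integer(cap)
  parent[1:2] <- 0L; t0[1:2] <- 0; state[1:2] <- root_state
  n <- 2L; active <- c(1L, 2L); tm <- 0
  lam <- c(p$lambda0, p$lambda1); mu <- c(p$mu0, p$mu1); qq <- c(p$q01, p$q10)
  repeat {
    if (!length(active)) return(NULL)
    s <- state[active] + 1L
    rts <- lam[s] + mu[s] + qq[s]
    tot <- sum(rts)
    if (tot <= 0) { tm <- if (!is.null(stop$age)) stop$age else tm; break }
    dt <- stats::rexp(1L, tot)
    if (!is.null(stop$age) && tm + dt >= stop$age) { tm <- stop$age; break }
    tm <- tm + dt
    k <- sample.int(length(active), 1L, prob = rts / tot)
    lin <- active[k]; si <- state[lin] + 1L
    u <- stats::runif(1L) * rts[k]
    if (u < lam[si]) {
      if (n + 2L > cap) {
        cap <- cap * 2L
        length(parent) <- cap; length(t0) <- cap; length(t1) <- cap
        length(status) <- cap; length(state) <- cap
      }
      status[lin] <- 1L; t1[lin] <- tm
      kids <- c(n + 1L, n + 2L)
      parent[kids] <- lin; t0[kids] <- tm; state[kids] <- state[lin]
      status[kids] <- 0L
      n <- n + 2L
      active <- c(active[active != lin], kids)
      if (!is.null(stop$taxa) && length(active) >= stop$taxa) {
        s2 <- state[active] + 1L
        tot2 <- sum(lam[s2] + mu[s2] + qq[s2])
        if (tot2 > 0) tm <- tm + stats::rexp(1L, tot2)
        break
      }
    } else if (u < lam[si] + mu[si]) {
      status[lin] <- 2L; t1[lin] <- tm
      active <- active[active != lin]
    } else {
      state[lin] <- 1L - state[lin]
    }
  }
  if (length(active) < 2L) return(NULL)
  status[active] <- 3L; t1[active] <- tm
  list(L = list(parent = parent[1:n], t0 = t0[1:n], t1 = t1[1:n],
                status = status[1:n], age = tm),
       state = state[1:n])
}
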