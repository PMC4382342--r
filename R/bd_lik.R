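## Birth-death likelihood machinery.
##
## A piecewise model partitions the tree into rate regimes ("pieces").  Each
## piece is scored with the reconstructed-process factorization of the
## constant-rate birth-death likelihood:
##
##   * every observed split in the piece contributes a factor b (except the
##     founding split of a piece that starts with two lineages: the global
##     root, or a node-convention shift);
##   * every edge subtending an internal node, spanning ages s (older) to t
##     (younger), contributes the no-observed-split factor
##       W(s) / W(t),   W(u) = (1 - alpha(u)) (1 - beta(u)),
##     the exact per-edge solution of the linear equation for the observed
##     subtree density (W(u) is the probability that a lineage of age u
##     leaves exactly one extant descendant);
##   * every terminal tip, an unresolved clade of n >= 1 species with stem
##     age s, contributes the unconditioned geometric clade-size law
##       Pr(N = n) = (1 - alpha(s)) (1 - beta(s)) beta(s)^(n-1).
##
## The search scores pieces by this plain (unconditioned) density.  Survival
## conditioning is available for whole-tree fits (resolved_lnl), but is not
## applied inside the piecewise model: per-tip conditioning (dividing by
## 1 - alpha(s_i)) is data-dependent and unbounded along the b ~ d ridge,
## and root-survival conditioning of the crown piece alone (dividing by
## (1 - alpha(T))^2) becomes unbounded in d once accepted shifts leave the
## crown piece with less than 2 * root-age of claimed branch length.  Both
## failure modes were observed; the unconditioned density is the only
## composition that stays a proper likelihood for every partition.
##
## alpha and beta are the classical Kendall transition quantities,
##   alpha = d (e^{rt}-1) / (b e^{rt} - d),  beta = b (e^{rt}-1) / (b e^{rt} - d),
## valid for any b > 0, d >= 0 including d > b (negative net diversification).
## All formulas reduce exactly to the Yule (pure-birth) case at d = 0.

## Kendall alpha/beta, vectorized over t; stable near r = 0 and for |r| t large
.bd_ab <- function(b, d, t) {
  r <- b - d
  n <- length(t)
  if (abs(r) < 1e-12 * (b + d)) {
    bt <- b * t
    beta <- bt / (1 + bt)
    alpha <- d * t / (1 + bt)
  } else {
    rt <- r * t
    big <- rt > 500
    em <- expm1(pmin(rt, 500))
    den <- b * em + r
    alpha <- d * em / den
    beta <- b * em / den
    if (any(big)) {        # e^{rt} overflow: use the t -> Inf limits
      alpha[big] <- d / b
      beta[big] <- 1
    }
  }
  eps1 <- 1e-15
  list(alpha = pmin(pmax(alpha, 0), 1 - eps1),
       beta  = pmin(pmax(beta,  0), 1 - eps1))
}

.LNL_FLOOR <- -1e10

#' Rate regime of a tree piece
#'
#' @param b speciation rate, per lineage per My (> 0).
#' @param d extinction rate, per lineage per My (>= 0; may exceed `b`, giving
#'   negative net diversification).
#' @param flavor `"yule"` (forces `d = 0`) or `"bd"`.
#' @return a `piece_rates` list with fields `b`, `d`, `r = b - d`,
#'   `epsilon = d/b` and `flavor`.
#' @export
piece_rates <- function(b, d = 0, flavor = c("yule", "bd")) {
  flavor <- match.arg(flavor)
  if (!is.finite(b) || b <= 0) stop("b must be > 0")
  if (!is.finite(d) || d < 0) stop("d must be >= 0")
  if (flavor == "yule" && d != 0) stop("yule flavor requires d = 0")
  structure(list(b = b, d = d, r = b - d, epsilon = d / b, flavor = flavor),
            class = "piece_rates")
}

#' Log-probability of an unresolved clade's species count
#'
#' The number of extant descendants of a single lineage of age `stem_age`
#' under a constant-rate birth-death process, conditioned on survival, is
#' geometric: `Pr(N = n | N > 0) = (1 - beta) beta^(n-1)`.
#'
#' @param stem_age stem age in My (> 0); vectorized.
#' @param n species count (>= 1); vectorized.
#' @param rates a [piece_rates].
#' @param conditioned if `FALSE`, drop the survival conditioning (multiply by
#'   `1 - alpha`); the unconditioned form is the density used by the
#'   state-dependent likelihood with complete sampling.
#' @return log-probability (vectorized).
#' @export
clade_size_lnl <- function(stem_age, n, rates, conditioned = TRUE) {
  if (any(n < 1)) stop("species counts must be >= 1 (tips are extant sampled clades)")
  if (any(stem_age <= 0)) stop("stem ages must be > 0")
  ab <- .bd_ab(rates$b, rates$d, stem_age)
  ll <- log1p(-ab$beta) + ifelse(n > 1, (n - 1) * log(ab$beta), 0)
  if (!conditioned) ll <- ll + log1p(-ab$alpha)
  ll
}

## ---- piece construction -------------------------------------------------

## Index of a (tree, richness) pair used by all piecewise computations.
.tree_index <- function(tree, richness = NULL) {
  validate_time_tree(tree, require_binary = TRUE)
  nt <- length(tree$tip.label)
  nn <- nt + tree$Nnode
  ages <- node_ages(tree)
  parent <- integer(nn)
  for (i in seq_len(nrow(tree$edge))) parent[tree$edge[i, 2L]] <- tree$edge[i, 1L]
  root <- nt + 1L
  if (sum(parent == 0L) != 1L || parent[root] != 0L) {
    root <- setdiff(tree$edge[, 1L], tree$edge[, 2L])[1L]
  }
  ## preorder node list (root first) for first-shift-above propagation
  pre <- integer(nn); pre[1L] <- root; np <- 1L
  kids <- vector("list", nn)
  for (i in seq_len(nrow(tree$edge)))
    kids[[tree$edge[i, 1L]]] <- c(kids[[tree$edge[i, 1L]]], tree$edge[i, 2L])
  stack <- root
  np <- 0L
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    np <- np + 1L; pre[np] <- v
    if (v > nt) stack <- c(stack, kids[[v]])
  }
  rich <- if (is.null(richness)) stats::setNames(rep(1L, nt), tree$tip.label)
          else check_richness(tree, richness)
  list(tree = tree, nt = nt, nn = nn, ages = ages, parent = parent,
       root = root, preorder = pre, children = kids,
       richness = as.numeric(rich), root_age = ages[root])
}

## first shift node at-or-above every node (root piece id = root)
.first_shift_above <- function(idx, shifts) {
  fs <- integer(idx$nn)
  shift <- logical(idx$nn); shift[shifts] <- TRUE
  for (v in idx$preorder) {
    fs[v] <- if (v == idx$root) idx$root
             else if (shift[v]) v
             else fs[idx$parent[v]]
  }
  fs
}

## Build piece structures for a shift assignment.
## fs: first-shift-at-or-above vector; convention "stem" or "node".
.build_pieces <- function(idx, fs, convention = "stem", only = NULL) {
  nt <- idx$nt
  piece_ids <- unique(c(idx$root, fs[fs > 0]))
  if (!is.null(only)) piece_ids <- intersect(piece_ids, only)
  pieces <- vector("list", length(piece_ids))
  names(pieces) <- as.character(piece_ids)
  ## owners under the two cut conventions
  node_seq <- seq_len(idx$nn)
  is_tip <- node_seq <= nt
  if (convention == "stem") {
    edge_owner <- fs                      # edge above ch -> fs[ch]
    tip_owner <- fs[seq_len(nt)]
  } else {
    edge_owner <- ifelse(node_seq == idx$root, 0L, fs[pmax(idx$parent, 1L)])
    tip_owner <- fs[idx$parent[seq_len(nt)]]
  }
  split_owner <- fs                       # split at u -> fs[u]
  for (k in seq_along(piece_ids)) {
    pid <- piece_ids[k]
    ## g-edges: edges subtending internal nodes owned by this piece
    ech <- which(!is_tip & node_seq != idx$root & edge_owner == pid)
    ## observed splits: internal nodes owned by the piece, minus its founding
    ## split when the piece starts with two lineages
    spl <- which(!is_tip & split_owner == pid)
    founding <- if (convention == "node" || pid == idx$root) pid else -1L
    n_b <- sum(spl != founding)
    tips <- which(tip_owner == pid)
    pieces[[k]] <- list(
      id = pid,
      int_s = idx$ages[idx$parent[ech]],
      int_t = idx$ages[ech],
      n_b = n_b,
      tip_s = idx$ages[idx$parent[tips]],
      tip_n = idx$richness[tips],
      tip_ids = tips,
      condition_root = FALSE,
      root_age = idx$root_age)
  }
  pieces
}

## Core piece log-likelihood at rates (b, d); compiled inner loop.
.piece_lnl <- function(piece, b, d) {
  .piece_lnl_cpp(piece$int_s, piece$int_t, piece$n_b,
                 piece$tip_s, piece$tip_n,
                 piece$condition_root, piece$root_age, b, d)
}

#' Log-likelihood of a resolved tree under constant rates
#'
#' Scores a whole binary time-calibrated tree as a single rate regime:
#' observed splits, per-edge no-split factors, and per-tip clade-size terms
#' (richness 1 unless supplied).  See the package vignette for the exact
#' factorization and conditioning conventions.
#'
#' @param tree a binary `time_tree`.
#' @param rates a [piece_rates].
#' @param richness optional [richness_table] (defaults to 1 per tip).
#' @param condition_root condition on survival of the two root daughter
#'   lineages.  Off by default, matching the piecewise search, which scores
#'   every piece by the plain density (conditioning the crown piece alone is
#'   not a constant normalization once breakpoints partition the tree).
#' @param conditioned_tips replace the unconditioned clade-size law at each
#'   tip by the survival-conditioned one.  Off by default: survival
#'   conditioning enters once, through `condition_root`; setting both
#'   conditions twice.  With `condition_root = FALSE`,
#'   `conditioned_tips = FALSE` and `include_root_split = TRUE` the result
#'   is the unconditioned density of the reconstructed tree, the convention
#'   used by the state-dependent (BiSSE) likelihood at complete sampling.
#' @param include_root_split count the root split as an observed speciation
#'   event (an extra `log b`); by default the root split is taken as given,
#'   as in the piecewise search.
#' @return log-likelihood (scalar); numerically impossible rate settings
#'   yield the floor value `-1e10` rather than an error.
#' @export
resolved_lnl <- function(tree, rates, richness = NULL, condition_root = FALSE,
                         conditioned_tips = FALSE, include_root_split = FALSE) {
  idx <- .tree_index(tree, richness)
  fs <- .first_shift_above(idx, integer(0))
  piece <- .build_pieces(idx, fs, "stem")[[1L]]
  piece$condition_root <- condition_root
  ll <- .piece_lnl(piece, rates$b, rates$d)
  if (conditioned_tips && length(piece$tip_s)) {
    ab <- .bd_ab(rates$b, rates$d, piece$tip_s)
    ll <- ll - sum(log1p(-ab$alpha))
  }
  if (include_root_split) ll <- ll + log(rates$b)
  ll
}

#' Log-likelihood of a piecewise shift model
#'
#' Decomposes the tree into rate regimes given a set of shift nodes and sums
#' the per-piece log-likelihoods.  Editing one piece's rates changes only
#' that piece's contribution.
#'
#' @param tree a binary `time_tree`.
#' @param richness a [richness_table] covering every tip.
#' @param shifts integer vector of shift node numbers (ape numbering),
#'   possibly empty; must be distinct and must not contain the root.
#' @param rates list of [piece_rates], named by piece id: the root node
#'   number for the background piece and each shift node number for its
#'   piece.
#' @param convention `"stem"` (a shift claims the branch subtending its node
#'   plus the subtree; the default) or `"node"` (the subtree only; shifts
#'   restricted to internal nodes).
#' @return total log-likelihood, with attribute `"pieces"` giving the
#'   per-piece contributions.
#' @export
piecewise_lnl <- function(tree, richness, shifts, rates,
                          convention = c("stem", "node")) {
  convention <- match.arg(convention)
  idx <- .tree_index(tree, richness)
  shifts <- as.integer(shifts)
  if (anyDuplicated(shifts)) stop("shift nodes must be distinct")
  if (idx$root %in% shifts) stop("the root cannot be a shift node")
  if (convention == "node" && any(shifts <= idx$nt))
    stop("node convention allows shifts at internal nodes only")
  fs <- .first_shift_above(idx, shifts)
  pieces <- .build_pieces(idx, fs, convention)
  need <- names(pieces)
  if (!all(need %in% names(rates)))
    stop("missing rates for piece(s): ",
         paste(setdiff(need, names(rates)), collapse = ", "))
  per <- vapply(need, function(id)
    .piece_lnl(pieces[[id]], rates[[id]]$b, rates[[id]]$d), numeric(1))
  structure(sum(per), pieces = per)
}

## ---- fitting ------------------------------------------------------------

#' Maximum-likelihood fit of one piece
#'
#' Yule pieces solve the score equation directly (closed form when every
#' tip is a singleton); birth-death pieces optimize `(log b, log d)` by
#' bounded quasi-Newton iteration from the Yule solution, with a second
#' start in the `d > b` region so that negative net diversification is
#' reachable.
#'
#' @param piece an internal piece structure (as built by the search), or use
#'   [fit_resolved] for a whole tree.
#' @param flavor `"yule"` or `"bd"`.
#' @param n_starts extra random restarts for the bd flavor.
#' @return list with `rates` ([piece_rates]), `lnl`, and `convergence`
#'   (`TRUE` if the optimizer reported success or the piece is degenerate).
#' @keywords internal
.fit_piece <- function(piece, flavor = c("yule", "bd"), n_starts = 1L) {
  flavor <- match.arg(flavor)
  if (flavor == "yule") return(.fit_yule_piece(piece))
  yf <- .fit_yule_piece(piece)
  single_tip <- piece$n_b == 0 && length(piece$int_s) == 0 &&
    length(piece$tip_s) == 1L
  if (single_tip) {
    ## a lone unresolved clade: the geometric law's supremum is already
    ## attained by the yule fit (beta is a free function of b); extinction
    ## is unidentifiable, so report the yule solution as the bd fit
    return(list(rates = piece_rates(yf$rates$b, 0, "bd"), lnl = yf$lnl,
                convergence = TRUE))
  }
  f2 <- function(p) -.piece_lnl(piece, exp(p[1L]), exp(p[2L]))
  lb0 <- log(yf$rates$b)
  starts <- list(c(lb0, lb0 - 1.5), c(lb0 + 0.4, lb0 + 0.7))
  maxit <- if (n_starts > 1L) 500L else 200L
  if (n_starts > 1L) {
    for (k in seq_len(n_starts - 1L))
      starts[[length(starts) + 1L]] <- c(lb0, lb0) + stats::rnorm(2, 0, 1.5)
  }
  best <- NULL
  conv <- FALSE
  for (s in starts) {
    op <- stats::nlminb(s, f2, lower = c(-21, -21), upper = c(5, 5),
                        control = list(iter.max = maxit, eval.max = 4L * maxit,
                                       rel.tol = 1e-12))
    if (is.null(best) || op$objective < best$objective) {
      best <- op; conv <- op$convergence == 0
    }
  }
  b <- exp(best$par[1L]); d <- exp(best$par[2L])
  lnl <- -best$objective
  ## never report a bd fit worse than its own yule limit
  if (yf$lnl > lnl) {
    b <- yf$rates$b; d <- 0; lnl <- yf$lnl; conv <- TRUE
  }
  list(rates = piece_rates(b, d, "bd"), lnl = lnl, convergence = conv)
}

## Yule (pure-birth) ML for one piece.  The log-likelihood is
##   n_b log b - b S + sum_{tips n>1} (n-1) log(1 - e^{-b s}),
## with S the summed edge + tip stem time.  The score is strictly
## decreasing in b, so the MLE is either closed-form (no n>1 tips:
## b = n_b / S, or the b -> 0 boundary when n_b = 0) or the unique root of
## the score, found by monotone bracketing.  The survival conditioning term
## vanishes for a pure-birth process.
.fit_yule_piece <- function(piece) {
  S <- sum(piece$int_s - piece$int_t) + sum(piece$tip_s)
  big <- piece$tip_n > 1
  m <- piece$n_b
  b_min <- 1e-9
  if (!any(big)) {
    b <- if (m > 0 && S > 0) m / S else b_min
  } else if (m == 0 && length(piece$tip_s) == 1L) {
    ## single unresolved clade: e^{-b s} = 1/n exactly
    b <- log(piece$tip_n[big]) / piece$tip_s[big]
  } else {
    s_i <- piece$tip_s[big]; w_i <- piece$tip_n[big] - 1
    score <- function(b) m / b - S + sum(w_i * s_i / expm1(b * s_i))
    lo <- b_min; hi <- max(m / max(S, 1e-12), 1e-3)
    while (score(hi) > 0 && hi < 1e6) hi <- hi * 4
    b <- if (score(lo) < 0) b_min
         else stats::uniroot(score, c(lo, hi), tol = 1e-12)$root
  }
  b <- max(b, b_min)
  list(rates = piece_rates(b, 0, "yule"), lnl = .piece_lnl(piece, b, 0),
       convergence = TRUE)
}

#' Fit constant-rate models to a whole resolved tree
#'
#' @inheritParams resolved_lnl
#' @param flavor `"yule"` or `"bd"`.
#' @param n_starts extra optimizer restarts (bd flavor).
#' @return list with `rates`, `lnl`, `convergence`.
#' @export
fit_resolved <- function(tree, richness = NULL, flavor = c("yule", "bd"),
                         n_starts = 1L) {
  flavor <- match.arg(flavor)
  idx <- .tree_index(tree, richness)
  fs <- .first_shift_above(idx, integer(0))
  piece <- .build_pieces(idx, fs, "stem")[[1L]]
  .fit_piece(piece, flavor, n_starts = n_starts)
}

## ---- information criteria ----------------------------------------------

#' Akaike information criteria
#'
#' `AICc = AIC + 2k(k+1)/(n_obs - k - 1)`; `n_obs` is the number of terminal
#' taxa by default (the small-sample correction is tied to terminal count).
#'
#' @param lnl log-likelihood.
#' @param k number of free parameters.
#' @param n_obs sample size for the small-sample correction.
#' @return the criterion value; `aicc` is `Inf` when `n_obs <= k + 1`.
#' @export
aic_score <- function(lnl, k) -2 * lnl + 2 * k

#' @rdname aic_score
#' @export
aicc_score <- function(lnl, k, n_obs) {
  if (n_obs <= k + 1) return(Inf)
  aic_score(lnl, k) + 2 * k * (k + 1) / (n_obs - k - 1)
}
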