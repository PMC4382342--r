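#' BiSSE parameter vector
#'
#' The six rates of the binary-state speciation-extinction model:
#' state-specific speciation (`lambda0`, `lambda1`), extinction (`mu0`,
#' `mu1`) and transition rates (`q01`, `q10`), all per lineage per My.
#' Derived net diversification rates `r0 = lambda0 - mu0`,
#' `r1 = lambda1 - mu1` are attached.
#'
#' @param lambda0,lambda1,mu0,mu1,q01,q10 non-negative rates.
#' @return a named numeric vector of class `bisse_params`.
#' @export
bisse_params <- function(lambda0, lambda1, mu0, mu1, q01, q10) {
  p <- c(lambda0 = lambda0, lambda1 = lambda1, mu0 = mu0, mu1 = mu1,
         q01 = q01, q10 = q10)
  if (any(!is.finite(p)) || any(p < 0)) stop("all BiSSE rates must be >= 0")
  structure(p, class = "bisse_params")
}

#' @rdname bisse_params
#' @param x object coercible to a `bisse_params` (named vector or list).
#' @export
as_bisse_params <- function(x) {
  x <- unlist(x)
  need <- c("lambda0", "lambda1", "mu0", "mu1", "q01", "q10")
  if (!all(need %in% names(x))) stop("missing BiSSE rates: ",
                                     paste(setdiff(need, names(x)), collapse = ", "))
  do.call(bisse_params, as.list(x[need]))
}

#' State-specific sampling fractions
#'
#' The proportion of extant species in each character state that appear as
#' tips.  Computed from the trait and richness tables as
#' `f_i = (# tips in state i) / (summed richness over tips in state i)`;
#' tips with missing state are excluded from both counts.  Override with
#' explicit values when the totals are known from elsewhere; a single global
#' fraction is expressed as `c(f, f)`.
#'
#' @param tree a `time_tree`.
#' @param traits a [trait_table].
#' @param richness a [richness_table].
#' @return numeric `c(f0, f1)`, both in (0, 1].
#' @export
sampling_fractions <- function(tree, traits, richness) {
  st <- traits[tree$tip.label]
  rich <- check_richness(tree, richness)
  f <- vapply(0:1, function(s) {
    i <- which(!is.na(st) & st == s)
    if (!length(i)) return(1)
    length(i) / sum(rich[i])
  }, numeric(1))
  pmin(pmax(f, 1e-6), 1)
}

## postorder edge matrix + tip states aligned to tree
.bisse_prep <- function(tree, traits) {
  validate_time_tree(tree, require_binary = TRUE)
  po <- ape::reorder.phylo(tree, "postorder")
  if (is.null(names(traits))) stop("traits must be named by tip label")
  miss <- setdiff(tree$tip.label, names(traits))
  st <- rep(NA_integer_, length(tree$tip.label))
  hit <- tree$tip.label %in% names(traits)
  st[hit] <- as.integer(traits[tree$tip.label[hit]])
  st[is.na(st)] <- -1L
  list(edge = po$edge, len = po$edge.length, n_tip = length(tree$tip.label),
       states = st)
}

#' BiSSE log-likelihood
#'
#' Likelihood of a binary time-calibrated tree and a two-state tip character
#' under state-dependent speciation, extinction and transition rates, with
#' state-specific sampling fractions entering the tip initial conditions
#' (`D_i = f_i`, `E_i = 1 - f_i`; missing-state tips get `D_i = f_i` for
#' both states).
#'
#' @param tree a binary `time_tree`.
#' @param traits a [trait_table] (0/1/NA) named by tip label; tips absent
#'   from the table are treated as missing.
#' @param pars a [bisse_params] (or coercible).
#' @param sampling `c(f0, f1)` sampling fractions in (0, 1].
#' @param root `"obs"` (weight root states by their relative D values, the
#'   default), `"flat"` (equal weights), or a numeric vector of two weights.
#' @param condition_surv condition on survival of the two root lineages
#'   (divides each `D_i` by `lambda_i (1 - E_i)^2` before root weighting).
#'   Off by default so the likelihood is the plain density of tree +
#'   character.
#' @param rtol relative ODE tolerance per branch.
#' @return log-likelihood; `-Inf` (with a warning) if the integrator fails
#'   at both the requested and a 100-fold tighter tolerance.
#' @export
bisse_lnl <- function(tree, traits, pars, sampling = c(1, 1), root = "obs",
                      condition_surv = FALSE, rtol = 1e-8) {
  prep <- .bisse_prep(tree, traits)
  .bisse_lnl_prepped(prep, pars, sampling, root, condition_surv, rtol)
}

.bisse_lnl_prepped <- function(prep, pars, sampling, root = "obs",
                               condition_surv = FALSE, rtol = 1e-8) {
  pars <- as_bisse_params(pars)
  stopifnot(length(sampling) == 2L, all(sampling > 0), all(sampling <= 1))
  if (is.character(root)) {
    mode <- match(match.arg(root, c("obs", "flat")), c("obs", "flat")) - 1L
    rp <- c(0.5, 0.5)
  } else {
    stopifnot(length(root) == 2L, all(root >= 0), sum(root) > 0)
    mode <- 2L
    rp <- root / sum(root)
  }
  res <- .bisse_lnl_cpp(prep$edge, prep$len, prep$n_tip, prep$states,
                        as.numeric(pars), as.numeric(sampling), mode, rp,
                        condition_surv, rtol)
  if (isTRUE(res$failed)) {
    warning("BiSSE ODE integration failed; returning -Inf")
    return(-Inf)
  }
  if (res$n_clamped > 0)
    attr(res$lnl, "n_clamped") <- res$n_clamped
  res$lnl
}

#' Maximum-likelihood BiSSE fit
#'
#' Bounded multi-start optimization of the six rates (or five with the
#' equal-speciation constraint `lambda0 = lambda1`) on the log scale.
#'
#' @inheritParams bisse_lnl
#' @param constraint `"none"` (full model, k = 6) or `"equal_lambda"`
#'   (k = 5).
#' @param extinction `"free"` (the default: `mu0`, `mu1` estimated) or
#'   `"none"` (state-dependent pure-birth model, `mu0 = mu1 = 0`; k drops
#'   by 2).  The pure-birth variant keeps every estimated parameter away
#'   from the zero boundary, which matters for calibration studies:
#'   extinction rates estimated from ~100-tip reconstructed trees collapse
#'   to zero in a large fraction of replicates, and a boundary nuisance
#'   parameter distorts the null distribution of likelihood-ratio
#'   statistics.
#' @param n_starts number of optimizer starts (the first is a
#'   character-independent heuristic; extras are lognormal jitters of it).
#' @param maxit optimizer (quasi-Newton, bounded, log scale) iteration cap
#'   per start.
#' @param init optional starting rates (named like a [bisse_params] or a
#'   full fit's `pars`), used as an additional start: e.g. start the full
#'   model from the constrained optimum when computing a likelihood-ratio
#'   test, which guarantees the nested ordering of the two maxima.
#' @return list with `pars` ([bisse_params]), `lnl`, `k`, `AIC`,
#'   `convergence` (TRUE if any start converged) and `counts`.
#' @export
bisse_ml <- function(tree, traits, sampling = c(1, 1),
                     constraint = c("none", "equal_lambda"),
                     root = "obs", condition_surv = FALSE, rtol = 1e-8,
                     n_starts = 1L, maxit = 500L, init = NULL,
                     extinction = c("free", "none")) {
  constraint <- match.arg(constraint)
  extinction <- match.arg(extinction)
  prep <- .bisse_prep(tree, traits)
  ## character-independent starting heuristic
  nt <- prep$n_tip
  ra <- root_age(tree)
  r0 <- max(log(nt / 2) / ra, 1e-3)
  start_full <- c(1.5 * r0, 1.5 * r0, 0.5 * r0, 0.5 * r0, 0.1 * r0, 0.1 * r0)
  ## free-parameter layout: lambdas, then (optionally) mus, then qs
  expand <- function(p) {
    lam <- if (constraint == "equal_lambda") c(p[1L], p[1L]) else p[1:2]
    rest <- p[-seq_len(if (constraint == "equal_lambda") 1L else 2L)]
    if (extinction == "free") c(lam, rest) else c(lam, 0, 0, rest)
  }
  collapse <- function(p6) {
    lam <- if (constraint == "equal_lambda") p6[1L] else p6[1:2]
    if (extinction == "free") c(lam, p6[3:6]) else c(lam, p6[5:6])
  }
  neg <- function(lp) {
    v <- -.bisse_lnl_prepped(prep, as_bisse_params(
      stats::setNames(expand(exp(lp)),
                      c("lambda0", "lambda1", "mu0", "mu1", "q01", "q10"))),
      sampling, root, condition_surv, rtol)
    if (!is.finite(v)) 1e10 else v
  }
  starts <- list(log(pmax(collapse(start_full), 1e-6)))
  if (!is.null(init)) {
    iv <- as.numeric(as_bisse_params(init))
    starts[[length(starts) + 1L]] <- log(pmax(collapse(iv), 1e-8))
  }
  if (n_starts > 1L) {
    for (i in seq_len(n_starts - 1L))
      starts[[length(starts) + 1L]] <-
        starts[[1L]] + stats::rnorm(length(starts[[1L]]), 0, 1)
  }
  best <- NULL; conv <- FALSE; counts <- 0L
  for (s in starts) {
    op <- stats::nlminb(s, neg,
                        lower = rep(-20, length(s)), upper = rep(5, length(s)),
                        control = list(iter.max = maxit, eval.max = 4L * maxit,
                                       rel.tol = 1e-12))
    counts <- counts + op$evaluations[1L]
    if (is.null(best) || op$objective < best$objective) best <- op
    if (op$convergence == 0) conv <- TRUE
  }
  pars <- as_bisse_params(stats::setNames(
    expand(exp(best$par)), c("lambda0", "lambda1", "mu0", "mu1", "q01", "q10")))
  k <- (if (constraint == "equal_lambda") 5L else 6L) -
    (if (extinction == "none") 2L else 0L)
  lnl <- -best$objective
  list(pars = pars, lnl = lnl, k = k, AIC = aic_score(lnl, k),
       convergence = conv, counts = counts, constraint = constraint)
}

#' Likelihood-ratio test of nested BiSSE fits
#'
#' `chi2 = 2 (lnL_full - lnL_constrained)`, `df = k_full - k_constrained`,
#' p from the upper chi-square tail.  A chi2 below `-tol` signals an
#' optimization failure upstream and is an error; small negative values from
#' optimizer noise are clamped to zero.
#'
#' @param full,constrained fit lists from [bisse_ml] (or any lists with
#'   `lnl` and `k`).
#' @param tol tolerance for negative chi2.
#' @return list with `chi2`, `df`, `p`.
#' @export
bisse_lrt <- function(full, constrained, tol = 1e-3) {
  df <- full$k - constrained$k
  if (df <= 0) stop("'constrained' must have fewer parameters than 'full'")
  chi2 <- 2 * (full$lnl - constrained$lnl)
  if (chi2 < -tol)
    stop("constrained fit beats full fit (chi2 = ", format(chi2),
         "): optimization failure upstream")
  chi2 <- max(chi2, 0)
  list(chi2 = chi2, df = df, p = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Posterior sampling of BiSSE rates by slice sampling
#'
#' Univariate slice sampling (stepping-out and shrinkage) applied to each
#' rate in turn, under independent exponential priors.  The prior mean
#' defaults to twice a crude whole-tree net diversification estimate.
#' Seeded and reproducible; the caller's RNG state is restored.
#'
#' @inheritParams bisse_lnl
#' @param steps total MCMC generations.
#' @param burnin generations discarded by summaries (kept in the chain,
#'   flagged by the `generation` column; must be < `steps`).
#' @param prior_mean exponential prior mean for every rate (scalar or
#'   6-vector); default `2 * log(n_tip/2) / root_age`.
#' @param init starting parameter vector; defaults to the prior mean.
#' @param w slice width (scalar or 6-vector).
#' @param seed integer seed.
#' @return a `bisse_chain` data.frame: `generation`, `lnpost`, `lnl`, the
#'   six rates, `r0`, `r1`, with attributes `burnin`, `steps`, `prior_mean`.
#' @export
bisse_mcmc <- function(tree, traits, sampling = c(1, 1), steps = 10000L,
                       burnin = 7500L, prior_mean = NULL, init = NULL,
                       w = NULL, root = "obs", condition_surv = FALSE,
                       rtol = 1e-8, seed = NULL) {
  stopifnot(burnin < steps)
  prep <- .bisse_prep(tree, traits)
  if (is.null(prior_mean))
    prior_mean <- 2 * max(log(prep$n_tip / 2) / root_age(tree), 1e-3)
  prior_mean <- rep_len(prior_mean, 6L)
  if (is.null(init)) init <- prior_mean
  init <- rep_len(init, 6L)
  if (is.null(w)) w <- pmax(prior_mean, 0.05)
  w <- rep_len(w, 6L)
  nm <- c("lambda0", "lambda1", "mu0", "mu1", "q01", "q10")
  lnpost <- function(p) {
    if (any(p < 0)) return(-Inf)
    ll <- .bisse_lnl_prepped(prep, as_bisse_params(stats::setNames(p, nm)),
                             sampling, root, condition_surv, rtol)
    if (!is.finite(ll)) return(-Inf)
    ll + sum(stats::dexp(p, rate = 1 / prior_mean, log = TRUE))
  }
  .with_seed(seed, {
    p <- init
    lp <- lnpost(p)
    if (!is.finite(lp)) stop("non-finite posterior at the initial point")
    out <- matrix(NA_real_, steps, 8L)
    for (g in seq_len(steps)) {
      for (j in 1:6) {
        sl <- .slice1(function(x) { q <- p; q[j] <- x; lnpost(q) },
                      p[j], lp, w[j])
        p[j] <- sl$x; lp <- sl$lp
      }
      if (!is.finite(lp)) stop("chain diverged at generation ", g,
                               "; state: ", paste(format(p), collapse = ", "))
      out[g, ] <- c(lp, lp - sum(stats::dexp(p, 1 / prior_mean, log = TRUE)), p)
    }
    chain <- data.frame(generation = seq_len(steps), lnpost = out[, 1L],
                        lnl = out[, 2L], out[, 3:8])
    names(chain)[4:9] <- nm
    chain$r0 <- chain$lambda0 - chain$mu0
    chain$r1 <- chain$lambda1 - chain$mu1
    structure(chain, class = c("bisse_chain", "data.frame"),
              burnin = burnin, steps = steps, prior_mean = prior_mean)
  })
}

## one univariate slice-sampling update (Neal 2003), domain x >= 0
.slice1 <- function(f, x0, lp0, w, max_steps = 50L) {
  z <- lp0 - stats::rexp(1L)
  u <- stats::runif(1L)
  L <- x0 - u * w
  R <- L + w
  j <- floor(max_steps * stats::runif(1L)); k <- max_steps - 1L - j
  while (j > 0 && L > 0 && f(L) > z) { L <- L - w; j <- j - 1L }
  while (k > 0 && f(R) > z) { R <- R + w; k <- k - 1L }
  L <- max(L, 0)
  repeat {
    x1 <- stats::runif(1L, L, R)
    lp1 <- f(x1)
    if (lp1 >= z) return(list(x = x1, lp = lp1))
    if (x1 < x0) L <- x1 else R <- x1
    if (R - L < 1e-12) return(list(x = x0, lp = lp0))
  }
}

#' Pool post-burnin draws from several chains
#'
#' Concatenates the post-burnin generations of chains run on different
#' trees (e.g. a posterior tree subsample), retaining per-draw provenance.
#'
#' @param chains list of `bisse_chain` objects with identical columns and
#'   prior settings.
#' @param ids optional identifiers (default: list index).
#' @return a `bisse_chain` data.frame with an extra `tree` column; its
#'   `burnin` attribute is 0 (burnin already removed).
#' @export
pool_chains <- function(chains, ids = seq_along(chains)) {
  stopifnot(length(chains) >= 1L)
  cols <- names(chains[[1L]])
  pm <- attr(chains[[1L]], "prior_mean")
  pooled <- lapply(seq_along(chains), function(i) {
    ch <- chains[[i]]
    if (!identical(names(ch), cols)) stop("chain ", i, ": mismatched columns")
    if (!isTRUE(all.equal(attr(ch, "prior_mean"), pm)))
      stop("chain ", i, ": mismatched prior parameterization")
    keep <- ch$generation > attr(ch, "burnin")
    cbind(tree = ids[i], ch[keep, , drop = FALSE])
  })
  structure(do.call(rbind, pooled), class = c("bisse_chain", "data.frame"),
            burnin = 0L, steps = NA_integer_, prior_mean = pm)
}

#' Posterior summary of a chain
#'
#' @param object a `bisse_chain`.
#' @param probs credible-interval quantiles.
#' @param ... unused.
#' @return data.frame with mean and quantiles per parameter (post-burnin
#'   draws only).
#' @export
summary.bisse_chain <- function(object, probs = c(0.025, 0.5, 0.975), ...) {
  keep <- object$generation > (attr(object, "burnin") %||% 0L)
  pars <- c("lambda0", "lambda1", "mu0", "mu1", "q01", "q10", "r0", "r1")
  out <- t(vapply(pars, function(p) {
    x <- object[[p]][keep]
    c(mean = mean(x), stats::quantile(x, probs))
  }, numeric(1L + length(probs))))
  as.data.frame(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
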