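#' Configuration for the stepwise shift search
#'
#' @param aicc_threshold improvement (AICc units) a candidate breakpoint must
#'   exceed to be accepted.  7.8 is the conventional value for
#'   genus-level trees of a few hundred terminals; see
#'   [aicc_threshold_for].
#' @param max_shifts hard cap on accepted breakpoints (runtime bound).
#' @param flavors model flavors tried for every piece; the better AICc
#'   contribution wins per piece.
#' @param cut_convention `"stem"` (default: a shift claims the branch
#'   subtending its node plus the subtree, so single-tip genus shifts are
#'   possible) or `"node"`.
#' @param n_starts optimizer restarts per bd fit.
#' @return a `shift_config` list.
#' @export
shift_config <- function(aicc_threshold = 7.8, max_shifts = 30L,
                         flavors = c("yule", "bd"),
                         cut_convention = c("stem", "node"),
                         n_starts = 1L) {
  stopifnot(aicc_threshold > 0, max_shifts >= 0)
  flavors <- match.arg(flavors, several.ok = TRUE)
  structure(list(aicc_threshold = aicc_threshold,
                 max_shifts = as.integer(max_shifts),
                 flavors = flavors,
                 cut_convention = match.arg(cut_convention),
                 n_starts = as.integer(n_starts)),
            class = "shift_config")
}

#' Size-dependent AICc acceptance threshold
#'
#' The stepwise cutoff depends on the number of terminals.  This package
#' does not re-derive the calibration formula of the original method
#' implementations; supply either an explicit `override` or a lookup `table`
#' (data.frame with columns `n_tips`, `threshold`, thresholds non-decreasing
#' in `n_tips`; the largest `n_tips <= n` row applies).  Missing both is an
#' error, never a silent default.
#'
#' @param n_tips number of terminal taxa (>= 3).
#' @param override explicit threshold in AICc units.
#' @param table lookup table as described above.
#' @return threshold in AICc units.
#' @export
aicc_threshold_for <- function(n_tips, override = NULL, table = NULL) {
  stopifnot(n_tips >= 3)
  if (!is.null(override)) {
    stopifnot(is.numeric(override), override > 0)
    return(override)
  }
  if (is.null(table))
    stop("no AICc threshold available for n_tips = ", n_tips,
         ": supply 'override' or a calibration 'table'")
  stopifnot(all(c("n_tips", "threshold") %in% names(table)))
  tab <- table[order(table$n_tips), , drop = FALSE]
  if (is.unsorted(tab$threshold))
    stop("threshold table must be non-decreasing in n_tips")
  ok <- tab$n_tips <= n_tips
  if (!any(ok))
    stop("no table entry for n_tips = ", n_tips)
  tab$threshold[max(which(ok))]
}

## fit a piece under every configured flavor, keep the best AICc contribution
.fit_piece_best <- function(piece, config) {
  best <- NULL
  for (fl in config$flavors) {
    ft <- .fit_piece(piece, fl, n_starts = config$n_starts)
    ft$k <- if (fl == "yule") 1L else 2L
    ## compare flavors by their AIC contribution (lnl penalised by k); the
    ## piece-count part of AICc is common to both so AIC ordering suffices
    score <- -2 * ft$lnl + 2 * ft$k
    if (is.null(best) || score < best$score - 1e-12) { ft$score <- score; best <- ft }
  }
  best
}

## total k of a model given per-piece fits
.model_k <- function(fits, n_shifts) sum(vapply(fits, `[[`, 0L, "k")) + n_shifts

#' Stepwise AICc search for diversification-rate shifts
#'
#' Grows a piecewise birth-death model one breakpoint at a time.  The
#' one-piece model is fitted first (both flavors); then every candidate node
#' is tentatively cut, only the new piece and its donor piece are refitted
#' (the likelihood is decomposable), and the best candidate is accepted iff
#' it improves AICc by more than the threshold.  Ties are broken by older
#' shift-node age, then lexicographic clade key, so results are stable under
#' tip reordering.
#'
#' @param tree a binary `time_tree`.
#' @param richness a [richness_table]; defaults to 1 species per tip.
#' @param config a [shift_config].
#' @return a `shift_model`: list with `shifts` (data.frame of accepted
#'   breakpoints: node, flavor, b, d, r, epsilon, piece lnL), `background`
#'   (the root piece's row), `clade_keys` (list of [clade_key]s per shift),
#'   `fit` (lnL, k, AIC, AICc, n_obs), `trajectory` (AICc after each
#'   accepted step, starting with the one-piece model), plus the inputs.
#' @export
stepwise_search <- function(tree, richness = NULL, config = shift_config()) {
  idx <- .tree_index(tree, richness)
  n_obs <- idx$nt
  conv <- config$cut_convention
  ## 1-piece model
  fs <- .first_shift_above(idx, integer(0))
  pieces <- .build_pieces(idx, fs, conv)
  fits <- list()
  fits[[as.character(idx$root)]] <- .fit_piece_best(pieces[[1L]], config)
  if (!is.finite(fits[[1L]]$lnl) || fits[[1L]]$lnl <= .LNL_FLOOR)
    stop("one-piece model failed to converge; cannot start the search")
  shifts <- integer(0)
  total_lnl <- fits[[1L]]$lnl
  k <- .model_k(fits, 0L)
  cur_aicc <- aicc_score(total_lnl, k, n_obs)
  trajectory <- cur_aicc
  ## candidate bookkeeping: piece membership version for cache invalidation
  version <- c(stats::setNames(1L, as.character(idx$root)))
  cache <- new.env(parent = emptyenv())
  candidates <- if (conv == "stem") setdiff(seq_len(idx$nn), idx$root)
                else setdiff((idx$nt + 1L):idx$nn, idx$root)
  repeat {
    if (length(shifts) >= config$max_shifts) break
    best <- NULL
    for (v in setdiff(candidates, shifts)) {
      donor <- fs[[v]]
      if (conv == "node") donor <- fs[[v]]  # v not a shift, so fs[v] is its owner
      keyc <- as.character(v)
      hit <- if (exists(keyc, cache)) get(keyc, cache) else NULL
      if (is.null(hit) || hit$donor != donor ||
          hit$version != version[[as.character(donor)]]) {
        fs2 <- fs
        ## mark v and its current-piece descendants as the new piece
        sub <- .subtree_nodes(idx, v)
        fs2[sub[fs[sub] == donor]] <- v
        two <- .build_pieces(idx, fs2, conv, only = c(donor, v))
        dp <- two[[as.character(donor)]]
        np <- two[[as.character(v)]]
        if (is.null(np) || (np$n_b == 0 && !length(np$int_s) && !length(np$tip_s))) {
          hit <- list(donor = donor, version = version[[as.character(donor)]],
                      ok = FALSE)
        } else if (is.null(dp) ||
                   (dp$n_b == 0 && !length(dp$int_s) && !length(dp$tip_s))) {
          hit <- list(donor = donor, version = version[[as.character(donor)]],
                      ok = FALSE)
        } else {
          f_new <- .fit_piece_best(np, config)
          f_don <- .fit_piece_best(dp, config)
          hit <- list(donor = donor, version = version[[as.character(donor)]],
                      ok = TRUE, f_new = f_new, f_don = f_don)
        }
        assign(keyc, hit, cache)
      }
      if (!hit$ok) next
      dkey <- as.character(hit$donor)
      lnl2 <- total_lnl - fits[[dkey]]$lnl + hit$f_don$lnl + hit$f_new$lnl
      k2 <- k - fits[[dkey]]$k + hit$f_don$k + hit$f_new$k + 1L
      aicc2 <- aicc_score(lnl2, k2, n_obs)
      if (!is.finite(aicc2)) next   # too many parameters for this tree size
      if (is.null(best) || aicc2 < best$aicc - 1e-9 ||
          (abs(aicc2 - best$aicc) <= 1e-9 && .older_candidate(idx, v, best$v))) {
        best <- list(v = v, aicc = aicc2, lnl = lnl2, k = k2, hit = hit)
      }
    }
    if (is.null(best) || !(cur_aicc - best$aicc > config$aicc_threshold)) break
    ## accept: a superset model must never lose likelihood
    stopifnot(best$lnl >= total_lnl - 1e-6)
    v <- best$v; donor <- best$hit$donor
    shifts <- c(shifts, v)
    fs <- local({
      sub <- .subtree_nodes(idx, v)
      fs[sub[fs[sub] == donor]] <- v
      fs
    })
    fits[[as.character(donor)]] <- best$hit$f_don
    fits[[as.character(v)]] <- best$hit$f_new
    total_lnl <- best$lnl; k <- best$k; cur_aicc <- best$aicc
    version[[as.character(donor)]] <- version[[as.character(donor)]] + 1L
    version[[as.character(v)]] <- 1L
    trajectory <- c(trajectory, cur_aicc)
  }
  .shift_model(tree, richness, idx, shifts, fits, conv, total_lnl, k, n_obs,
               trajectory, config)
}

## nodes in the subtree rooted at v (self included); for stem convention the
## stem edge is implied by membership of v itself
.subtree_nodes <- function(idx, v) {
  sub <- integer(0); stack <- v
  while (length(stack)) {
    x <- stack[length(stack)]; stack <- stack[-length(stack)]
    sub <- c(sub, x)
    if (x > idx$nt) stack <- c(stack, idx$children[[x]])
  }
  sub
}

## tie-break: older node age wins; equal ages -> lexicographically smaller key
.older_candidate <- function(idx, v, w) {
  av <- idx$ages[v]; aw <- idx$ages[w]
  if (abs(av - aw) > 1e-12) return(av > aw)
  kv <- format(clade_key_of_node(idx$tree, v))
  kw <- format(clade_key_of_node(idx$tree, w))
  kv < kw
}

.shift_model <- function(tree, richness, idx, shifts, fits, conv,
                         total_lnl, k, n_obs, trajectory, config) {
  row_of <- function(id) {
    f <- fits[[as.character(id)]]
    data.frame(node = id,
               flavor = f$rates$flavor,
               b = f$rates$b, d = f$rates$d,
               r = f$rates$r, epsilon = f$rates$epsilon,
               lnl = f$lnl, k = f$k,
               converged = f$convergence)
  }
  shift_df <- if (length(shifts)) do.call(rbind, lapply(shifts, row_of))
              else row_of(idx$root)[0, ]
  structure(list(
    tree = tree,
    richness = idx$richness,
    convention = conv,
    shifts = shift_df,
    background = row_of(idx$root),
    clade_keys = lapply(shifts, function(v) clade_key_of_node(tree, v)),
    fit = list(lnl = total_lnl, k = k,
               AIC = aic_score(total_lnl, k),
               AICc = aicc_score(total_lnl, k, n_obs),
               n_obs = n_obs),
    trajectory = trajectory,
    config = config), class = "shift_model")
}

#' @export
print.shift_model <- function(x, ...) {
  cat("shift_model:", nrow(x$shifts), "accepted shift(s);",
      "background r =", format(x$background$r, digits = 4),
      "(", x$background$flavor, ")\n")
  cat("lnL =", format(x$fit$lnl, digits = 8),
      " k =", x$fit$k,
      " AICc =", format(x$fit$AICc, digits = 8), "\n")
  if (nrow(x$shifts)) {
    df <- x$shifts
    df$clade <- vapply(x$clade_keys, function(k)
      paste0(utils::head(unclass(k), 3), collapse = ","), character(1))
    print(df[, c("node", "flavor", "r", "epsilon", "lnl", "clade")],
          row.names = FALSE)
  }
  invisible(x)
}

#' Rank all candidate breakpoints of the current model
#'
#' Evaluates every admissible candidate cut of a fitted model (as the search
#' does internally) and returns them ranked by the AICc of the resulting
#' model, with the deterministic tie-break (older node age, then
#' lexicographic clade key).  Accepted shifts are never re-proposed.
#'
#' @param model a `shift_model`.
#' @return data.frame with columns `node`, `aicc`, `delta_aicc`
#'   (improvement over the current model; positive is better), `age`.
#' @export
candidate_scan <- function(model) {
  idx <- .tree_index(model$tree,
                     stats::setNames(model$richness, model$tree$tip.label))
  config <- model$config
  conv <- model$convention
  shifts <- model$shifts$node
  fs <- .first_shift_above(idx, shifts)
  pieces <- .build_pieces(idx, fs, conv)
  fits <- lapply(pieces, .fit_piece_best, config = config)
  total_lnl <- sum(vapply(fits, `[[`, 0, "lnl"))
  k <- .model_k(fits, length(shifts))
  candidates <- if (conv == "stem") setdiff(seq_len(idx$nn), idx$root)
                else setdiff((idx$nt + 1L):idx$nn, idx$root)
  candidates <- setdiff(candidates, shifts)
  rows <- lapply(candidates, function(v) {
    donor <- fs[[v]]
    fs2 <- fs
    sub <- .subtree_nodes(idx, v)
    fs2[sub[fs[sub] == donor]] <- v
    two <- .build_pieces(idx, fs2, conv, only = c(donor, v))
    dp <- two[[as.character(donor)]]; np <- two[[as.character(v)]]
    empty <- function(p) is.null(p) || (p$n_b == 0 && !length(p$int_s) && !length(p$tip_s))
    if (empty(dp) || empty(np)) return(NULL)
    f_new <- .fit_piece_best(np, config); f_don <- .fit_piece_best(dp, config)
    lnl2 <- total_lnl - fits[[as.character(donor)]]$lnl + f_don$lnl + f_new$lnl
    k2 <- k - fits[[as.character(donor)]]$k + f_don$k + f_new$k + 1L
    data.frame(node = v, aicc = aicc_score(lnl2, k2, idx$nt),
               lnl = lnl2, age = idx$ages[v])
  })
  rows <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  cur <- aicc_score(total_lnl, k, idx$nt)
  rows$delta_aicc <- cur - rows$aicc
  keys <- vapply(rows$node, function(v) format(clade_key_of_node(model$tree, v)),
                 character(1))
  rows[order(rows$aicc, -rows$age, keys), c("node", "aicc", "delta_aicc", "age")]
}
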