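#' Run the stepwise shift search over a tree sample
#'
#' Applies [stepwise_search] independently to every tree of a posterior
#' sample.  Per-tree failures are caught, logged and excluded (the run
#' aborts if more than `max_fail_frac` of trees fail).  Results can be
#' cached to disk per tree so long runs are resumable.
#'
#' @param sample a `tree_sample` (all trees must share the tip set).
#' @param richness a [richness_table] covering the shared tip set.
#' @param config a [shift_config].
#' @param cache_dir optional directory; per-tree results are stored as
#'   `tree_<i>.rds` and reused on rerun.
#' @param max_fail_frac abort when the failed fraction exceeds this.
#' @param progress print one line per 25 trees.
#' @return a `multitree_result`: list with `models` (per-tree
#'   `shift_model` or `NULL` for failures), `failures` (data.frame of index
#'   + message), `sample`, `config`.
#' @export
run_over_sample <- function(sample, richness = NULL, config = shift_config(),
                            cache_dir = NULL, max_fail_frac = 0.05,
                            progress = FALSE) {
  if (length(attr(sample, "tip_mismatch")))
    stop("trees do not share a tip set: ",
         paste(attr(sample, "tip_mismatch"), collapse = "; "))
  if (!is.null(cache_dir) && !dir.exists(cache_dir))
    dir.create(cache_dir, recursive = TRUE)
  models <- vector("list", length(sample))
  fails <- list()
  for (i in seq_along(sample)) {
    cache_file <- if (!is.null(cache_dir))
      file.path(cache_dir, sprintf("tree_%d.rds", i)) else NULL
    if (!is.null(cache_file) && file.exists(cache_file)) {
      models[[i]] <- readRDS(cache_file)
    } else {
      m <- tryCatch(stepwise_search(sample[[i]], richness, config),
                    error = function(e) e)
      if (inherits(m, "error")) {
        fails[[length(fails) + 1L]] <-
          data.frame(tree = i, message = conditionMessage(m))
        models[i] <- list(NULL)
      } else {
        models[[i]] <- m
        if (!is.null(cache_file)) saveRDS(m, cache_file)
      }
    }
    if (progress && i %% 25L == 0L)
      message("analysed ", i, "/", length(sample), " trees")
  }
  failures <- if (length(fails)) do.call(rbind, fails)
              else data.frame(tree = integer(0), message = character(0))
  if (nrow(failures) > max_fail_frac * length(sample))
    stop("too many per-tree failures (", nrow(failures), "/", length(sample),
         "); first: ", failures$message[1L])
  structure(list(models = models, failures = failures, sample = sample,
                 config = config), class = "multitree_result")
}

#' Match shifts across trees and summarize recovery
#'
#' For each reference clade S (from a shift model fitted to an MCC or other
#' reference tree) and each sampled tree T, a shift in T matches S iff the
#' shift node of T equals `mrca(T, S)`.  This recovers shifts even when the
#' reference clade is not monophyletic in T, which is what makes recovery
#' frequencies near 1 possible for clades present in only a fraction of the
#' sample.  `sum_prop` is the matched fraction over all analysed trees;
#' conditional frequencies given clade monophyly are also reported.
#'
#' @param result a `multitree_result`.
#' @param reference either a `shift_model` (its accepted shift clades are
#'   used) or a list of [clade_key]s.
#' @return a `shift_summary` data.frame, one row per reference clade:
#'   `clade`, `sum_prop`, `n_trees_matched`, `n_trees_analysed`,
#'   `n_trees_with_clade`, `sum_prop_conditional`, `median_r`, `mean_r`,
#'   `sd_r`, `median_epsilon`.  The matched per-tree rates are attached as
#'   attribute `rates` (list of numeric vectors, one per clade), and shifts
#'   matching no reference clade as attribute `unanchored` (data.frame
#'   tree/node/r).
#' @export
match_shifts <- function(result, reference) {
  keys <- if (inherits(reference, "shift_model")) reference$clade_keys
          else lapply(reference, clade_key)
  if (!length(keys)) stop("no reference clades")
  models <- result$models
  ok <- !vapply(models, is.null, TRUE)
  rows <- vector("list", length(keys))
  rates <- vector("list", length(keys))
  matched_any <- lapply(models, function(m)
    if (is.null(m)) logical(0) else rep(FALSE, nrow(m$shifts)))
  for (k in seq_along(keys)) {
    key <- keys[[k]]
    rs <- numeric(0); eps <- numeric(0)
    n_match <- 0L; n_clade <- 0L; n_match_given_clade <- 0L
    for (i in which(ok)) {
      m <- models[[i]]
      node <- mrca_node(m$tree, key)
      mono <- is_monophyletic_key(m$tree, key)
      if (mono) n_clade <- n_clade + 1L
      hit <- which(m$shifts$node == node)
      if (length(hit)) {
        n_match <- n_match + 1L
        if (mono) n_match_given_clade <- n_match_given_clade + 1L
        rs <- c(rs, m$shifts$r[hit[1L]])
        eps <- c(eps, m$shifts$epsilon[hit[1L]])
        matched_any[[i]][hit[1L]] <- TRUE
      }
    }
    n_an <- sum(ok)
    rows[[k]] <- data.frame(
      clade = format(key),
      sum_prop = n_match / n_an,
      n_trees_matched = n_match,
      n_trees_analysed = n_an,
      n_trees_with_clade = n_clade,
      sum_prop_conditional = if (n_clade) n_match_given_clade / n_clade else NA_real_,
      median_r = if (n_match) stats::median(rs) else NA_real_,
      mean_r = if (n_match) mean(rs) else NA_real_,
      sd_r = if (n_match) stats::sd(rs) else NA_real_,
      median_epsilon = if (n_match) stats::median(eps) else NA_real_)
    rates[[k]] <- rs
  }
  un <- list()
  for (i in which(ok)) {
    m <- models[[i]]
    for (j in seq_len(nrow(m$shifts))) {
      if (!matched_any[[i]][j])
        un[[length(un) + 1L]] <- data.frame(
          tree = i, node = m$shifts$node[j], r = m$shifts$r[j],
          clade = format(m$clade_keys[[j]]))
    }
  }
  unanchored <- if (length(un)) do.call(rbind, un)
                else data.frame(tree = integer(0), node = integer(0),
                                r = numeric(0), clade = character(0))
  names(rates) <- vapply(keys, format, character(1))
  structure(do.call(rbind, rows), class = c("shift_summary", "data.frame"),
            rates = rates, unanchored = unanchored, keys = keys)
}

#' Significant shifts and a rate matrix across trees
#'
#' Applies the recovery-frequency significance rule: a reference shift is
#' significant iff `sum_prop >= cutoff` (0.90 by convention).
#' Also returns a boxplot-ready rate matrix: one row per reference clade,
#' entries are the matched per-tree net diversification rates.
#'
#' @param summary a `shift_summary` from [match_shifts].
#' @param cutoff recovery-frequency threshold in `[0, 1]` (values > 1 make
#'   nothing significant).
#' @return list with `table` (the summary plus a `significant` column) and
#'   `rates` (matrix, rows = clades, columns padded with NA to the longest
#'   match vector).
#' @export
summarize_shifts <- function(summary, cutoff = 0.90) {
  tab <- as.data.frame(summary)
  tab$significant <- tab$sum_prop >= cutoff
  rates <- attr(summary, "rates")
  width <- max(1L, vapply(rates, length, 0L))
  mat <- t(vapply(rates, function(r) c(r, rep(NA_real_, width - length(r))),
                  numeric(width)))
  rownames(mat) <- names(rates)
  list(table = tab, rates = mat, cutoff = cutoff)
}
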