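#' Write a fitted shift model as a CSV table
#'
#' One row per piece (background first), mirroring the usual published
#' layout: shift number, shift node, model flavor, net diversification
#' rate, per-piece log-likelihood, model AICc (last row only) and the
#' clade's tip labels.  Floats are written at 6 decimals.
#'
#' @param model a `shift_model`.
#' @param path output CSV path.
#' @return the data.frame written, invisibly.
#' @export
write_shift_table <- function(model, path) {
  all_rows <- rbind(model$background, model$shifts)
  n <- nrow(all_rows)
  taxa <- c("(root)", vapply(model$clade_keys, function(k)
    paste(unclass(k), collapse = " "), character(1)))
  df <- data.frame(
    shift = seq_len(n),
    shift_node = all_rows$node,
    model = all_rows$flavor,
    r = round(all_rows$r, 6),
    lnlik_part = round(all_rows$lnl, 6),
    AICc = c(rep(NA_real_, n - 1L), round(model$fit$AICc, 6)),
    taxa = taxa)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(df)
}

#' Write a cross-tree shift summary as a CSV table
#'
#' One row per reference shift: the reference (single-tree) rate, the
#' median rate across matched trees, and the probability of the shift being
#' recovered (`sum_prop`).
#'
#' @param summary a `shift_summary` from [match_shifts].
#' @param reference optional reference `shift_model` supplying the
#'   single-tree rates (matched by clade).
#' @param path output CSV path.
#' @return the data.frame written, invisibly.
#' @export
write_shift_summary <- function(summary, path, reference = NULL) {
  tab <- as.data.frame(summary)
  ref_r <- rep(NA_real_, nrow(tab))
  if (!is.null(reference)) {
    ref_keys <- vapply(reference$clade_keys, format, character(1))
    hit <- match(tab$clade, ref_keys)
    ref_r[!is.na(hit)] <- reference$shifts$r[hit[!is.na(hit)]]
  }
  df <- data.frame(
    shift_node = tab$clade,
    rate_reference = round(ref_r, 6),
    median_rate = round(tab$median_r, 6),
    prob_recovered = round(tab$sum_prop, 6))
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(df)
}

#' Serialize a shift model to JSON and back
#'
#' Round-trips the fitted pieces (node, flavor, b, d, r, epsilon, lnl),
#' clade keys, total fit and the acceptance trajectory.  The tree itself is
#' stored as a newick string.
#'
#' @param model a `shift_model`.
#' @param path JSON file path.
#' @return `model_to_json` returns `path` invisibly; `model_from_json`
#'   returns a list with the same components as a `shift_model` (class
#'   `shift_model`).
#' @export
model_to_json <- function(model, path) {
  obj <- list(
    newick = ape::write.tree(model$tree),
    richness = stats::setNames(as.list(model$richness), model$tree$tip.label),
    convention = model$convention,
    background = model$background,
    shifts = model$shifts,
    clade_keys = vapply(model$clade_keys, format, character(1)),
    fit = model$fit,
    trajectory = model$trajectory,
    config = unclass(model$config))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname model_to_json
#' @export
model_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  tree <- as_time_tree(ape::read.tree(text = obj$newick))
  cfg <- do.call(shift_config, obj$config[c("aicc_threshold", "max_shifts",
                                            "flavors", "cut_convention",
                                            "n_starts")])
  keys <- lapply(strsplit(unlist(obj$clade_keys), "|", fixed = TRUE), clade_key)
  if (length(obj$clade_keys) == 0L) keys <- list()
  structure(list(
    tree = tree,
    richness = unlist(obj$richness),
    convention = obj$convention,
    shifts = as.data.frame(obj$shifts),
    background = as.data.frame(obj$background),
    clade_keys = keys,
    fit = obj$fit,
    trajectory = obj$trajectory,
    config = cfg), class = "shift_model")
}

#' Write an MCMC chain as CSV
#'
#' @param chain a `bisse_chain`.
#' @param path output CSV path.
#' @return the chain invisibly.
#' @export
write_chain <- function(chain, path) {
  utils::write.csv(as.data.frame(chain), path, row.names = FALSE)
  invisible(chain)
}
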