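#' Time-calibrated ultrametric trees
#'
#' A `time_tree` is an [ape::ape-package] `"phylo"` object that has passed
#' validation for use in diversification analyses: rooted, binary tip labels
#' unique, branch lengths in millions of years (My), and ultrametric within a
#' relative tolerance of the root age.  Node ages (My before present) are
#' cached in the `"node_ages"` attribute, rebuilt from branch lengths by
#' maximum root-to-node path length so that rounding noise in dated Bayesian
#' trees does not propagate.
#'
#' @param phy an object of class `"phylo"`.
#' @param tol relative ultrametricity tolerance, as a fraction of root age.
#'   Trees violating it are flagged (`attr(x, "is_ultrametric")` is `FALSE`)
#'   with a warning, not rejected.
#' @return an object of classes `c("time_tree", "phylo")` with attributes
#'   `node_ages` (numeric, length `Nnode + Ntip`) and `is_ultrametric`.
#' @examples
#' tr <- as_time_tree(ape::read.tree(text = "((A:1,B:1):1,C:2);"))
#' node_ages(tr)
#' @export
as_time_tree <- function(phy, tol = 1e-3) {
  if (!inherits(phy, "phylo")) stop("'phy' must be a \"phylo\" object")
  if (is.null(phy$edge.length)) stop("tree has no branch lengths")
  if (any(duplicated(phy$tip.label))) stop("duplicate tip labels: ",
    paste(unique(phy$tip.label[duplicated(phy$tip.label)]), collapse = ", "))
  if (!ape::is.rooted(phy)) stop("tree must be rooted")
  if (any(phy$edge.length < 0)) stop("negative branch lengths")
  nt <- length(phy$tip.label)
  if (nt < 2L) stop("tree must have at least 2 tips")
  ages <- .node_ages_from_lengths(phy)
  root_age <- max(ages)
  tip_ages <- ages[seq_len(nt)]
  ultra <- all(abs(tip_ages) <= tol * root_age)
  if (!ultra) {
    warning("tree is not ultrametric within tolerance (max tip age ",
            format(max(abs(tip_ages))), " vs root age ", format(root_age), ")")
  } else {
    # snap tips to the present so downstream age arithmetic is exact
    ages[seq_len(nt)] <- 0
  }
  structure(phy,
            class = c("time_tree", "phylo"),
            node_ages = ages,
            is_ultrametric = ultra)
}

## ages = max path length to any descendant tip; robust to rounding noise
.node_ages_from_lengths <- function(phy) {
  nt <- length(phy$tip.label)
  nn <- nt + phy$Nnode
  ages <- numeric(nn)
  po <- ape::reorder.phylo(phy, "postorder")
  for (i in seq_len(nrow(po$edge))) {
    p <- po$edge[i, 1L]; ch <- po$edge[i, 2L]
    cand <- ages[ch] + po$edge.length[i]
    if (cand > ages[p]) ages[p] <- cand
  }
  ## shift so tips sit at (near) zero: ages are depths below root; convert
  depth <- numeric(nn)
  pr <- rev(seq_len(nrow(po$edge)))
  for (i in pr) {
    p <- po$edge[i, 1L]; ch <- po$edge[i, 2L]
    depth[ch] <- depth[p] + po$edge.length[i]
  }
  max(depth) - depth
}

#' @rdname as_time_tree
#' @param x a `time_tree`.
#' @export
node_ages <- function(x) {
  a <- attr(x, "node_ages")
  if (is.null(a)) a <- .node_ages_from_lengths(x)
  a
}

#' @rdname as_time_tree
#' @export
root_age <- function(x) max(node_ages(x))

#' @export
print.time_tree <- function(x, ...) {
  cat("time_tree: ", length(x$tip.label), " tips, root age ",
      format(root_age(x), digits = 6), " My",
      if (!attr(x, "is_ultrametric")) " [NOT ultrametric]", "\n", sep = "")
  invisible(x)
}

#' Validate time-tree invariants
#'
#' Checks the structural invariants required by the likelihood machinery:
#' single root, all internal nodes with >= 2 children, unique tip labels,
#' tips at the present within tolerance, and age additivity along edges.
#'
#' @param x a `time_tree`.
#' @param tol relative tolerance (fraction of root age).
#' @param require_binary fail on polytomies (the birth-death likelihood
#'   assumes binary branching; polytomies are accepted on input but rejected
#'   here when a likelihood module asks for a binary tree).
#' @return `TRUE` invisibly; errors describe the first violated invariant.
#' @export
validate_time_tree <- function(x, tol = 1e-3, require_binary = FALSE) {
  stopifnot(inherits(x, "phylo"))
  nt <- length(x$tip.label)
  if (any(duplicated(x$tip.label))) stop("duplicate tip labels")
  if (!ape::is.rooted(x)) stop("tree is not rooted")
  tab <- tabulate(x$edge[, 1L], nbins = nt + x$Nnode)
  if (any(tab[seq_len(nt)] > 0)) stop("a tip is also an internal node")
  internal <- tab[(nt + 1L):(nt + x$Nnode)]
  if (any(internal < 2L)) stop("internal node with fewer than 2 children")
  if (require_binary && any(internal > 2L))
    stop("tree contains polytomies; the likelihood assumes binary branching")
  ages <- node_ages(x)
  ra <- max(ages)
  if (any(abs(ages[seq_len(nt)]) > tol * ra))
    stop("tip ages deviate from the present beyond tolerance")
  ## age additivity: parent age = child age + edge length (up to tolerance,
  ## except where tips were snapped to zero)
  dev <- abs(ages[x$edge[, 1L]] - ages[x$edge[, 2L]] - x$edge.length)
  if (max(dev) > max(tol * ra, 1e-8))
    stop("node ages inconsistent with branch lengths (max deviation ",
         format(max(dev)), ")")
  invisible(TRUE)
}

#' Read a sample of time-calibrated trees
#'
#' Reads one or more trees from a newick or NEXUS file (NEXUS translate
#' tables are honoured via [ape::read.nexus]) and validates each as a
#' [as_time_tree] `time_tree`.  Parse or validation failures identify the
#' offending tree index.
#'
#' @param path file path.
#' @param format `"newick"` or `"nexus"`; default guesses from the first
#'   non-blank character (`#` starts a NEXUS file).
#' @param tol ultrametricity tolerance passed to [as_time_tree].
#' @return a `tree_sample`: a list of `time_tree`s with attributes `source`
#'   (the path) and `tip_mismatch` (character vector of messages for trees
#'   whose tip set differs from the first tree's; reported, never fixed).
#' @export
read_trees <- function(path, format = c("auto", "newick", "nexus"), tol = 1e-3) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    first <- readLines(path, n = 1L, warn = FALSE)
    format <- if (grepl("^\\s*#", first)) "nexus" else "newick"
  }
  trees <- if (format == "nexus") ape::read.nexus(path) else ape::read.tree(path)
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (length(trees) == 0L) stop("no trees in file: ", path)
  out <- vector("list", length(trees))
  for (i in seq_along(trees)) {
    out[[i]] <- tryCatch(as_time_tree(trees[[i]], tol = tol),
                         error = function(e)
                           stop("tree ", i, " in ", path, ": ",
                                conditionMessage(e), call. = FALSE))
  }
  tree_sample(out, source = path)
}

#' @rdname read_trees
#' @param trees a non-empty list of `time_tree`s.
#' @param source provenance string.
#' @export
tree_sample <- function(trees, source = "<memory>") {
  if (length(trees) == 0L) stop("empty tree sample")
  ref <- sort(trees[[1L]]$tip.label)
  mism <- character(0)
  for (i in seq_along(trees)) {
    if (!identical(sort(trees[[i]]$tip.label), ref))
      mism <- c(mism, paste0("tree ", i, " tip set differs from tree 1"))
  }
  structure(trees, class = "tree_sample", source = source,
            tip_mismatch = mism)
}

#' @export
print.tree_sample <- function(x, ...) {
  cat("tree_sample:", length(x), "trees from", attr(x, "source"), "\n")
  mm <- attr(x, "tip_mismatch")
  if (length(mm)) cat("tip-set mismatches:", length(mm), "\n")
  invisible(x)
}

#' Prune outgroup taxa
#'
#' Drops the given tip labels, suppresses the resulting degree-2 nodes
#' (branch lengths summed, as in [ape::drop.tip]) and recomputes the ingroup
#' root age.
#'
#' @param tree a `time_tree`.
#' @param labels tip labels to remove; all must be present.
#' @return the pruned `time_tree`.
#' @export
prune_outgroup <- function(tree, labels) {
  if (length(labels) == 0L) return(tree)
  missing <- setdiff(labels, tree$tip.label)
  if (length(missing))
    stop("labels not in tree: ", paste(missing, collapse = ", "))
  if (length(tree$tip.label) - length(labels) < 2L)
    stop("pruning would leave fewer than 2 tips")
  as_time_tree(ape::drop.tip(tree, labels))
}

#' Canonical clade identity
#'
#' A `clade_key` names a clade by its sorted tip-label set, so that "the same
#' shift node" is well-defined across trees that differ in topology: two
#' shifts match when each tree's shift node is the MRCA of the same tip set.
#'
#' @param labels character vector of tip labels (non-empty).
#' @return a `clade_key`: sorted unique labels with a canonical string form.
#' @export
clade_key <- function(labels) {
  labels <- sort(unique(as.character(labels)))
  if (length(labels) == 0L) stop("empty clade key")
  structure(labels, class = "clade_key")
}

#' @rdname clade_key
#' @param x a `clade_key`.
#' @export
format.clade_key <- function(x, ...) paste(unclass(x), collapse = "|")

#' @export
print.clade_key <- function(x, ...) {
  cat("clade_key:", format(x), "\n")
  invisible(x)
}

#' @rdname clade_key
#' @param tree a `time_tree`.
#' @param node node number (ape numbering).
#' @export
clade_key_of_node <- function(tree, node) {
  nt <- length(tree$tip.label)
  if (node <= nt) return(clade_key(tree$tip.label[node]))
  clade_key(tree$tip.label[.desc_tips(tree, node)])
}

.desc_tips <- function(tree, node) {
  nt <- length(tree$tip.label)
  if (node <= nt) return(node)
  po <- ape::reorder.phylo(tree, "postorder")
  keep <- logical(nt + tree$Nnode)
  keep[node] <- TRUE
  for (i in rev(seq_len(nrow(po$edge)))) {
    if (keep[po$edge[i, 1L]]) keep[po$edge[i, 2L]] <- TRUE
  }
  which(keep[seq_len(nt)])
}

#' Most recent common ancestor of a clade key
#'
#' @param tree a `time_tree`.
#' @param key a `clade_key` or character vector of tip labels.
#' @return node number of the MRCA; the MRCA of a single tip is that tip.
#' @export
mrca_node <- function(tree, key) {
  labels <- unclass(clade_key(key))
  idx <- match(labels, tree$tip.label)
  if (anyNA(idx))
    stop("labels not in tree: ", paste(labels[is.na(idx)], collapse = ", "))
  if (length(idx) == 1L) return(idx)
  ape::getMRCA(tree, idx)
}

#' Is a clade key monophyletic in a tree?
#'
#' @inheritParams mrca_node
#' @return `TRUE` iff the MRCA's descendant tip set equals the key.
#' @export
is_monophyletic_key <- function(tree, key) {
  key <- clade_key(key)
  m <- mrca_node(tree, key)
  identical(sort(tree$tip.label[.desc_tips(tree, m)]), unclass(key))
}
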