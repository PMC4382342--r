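#' Read and validate a genus richness table
#'
#' The richness table maps each tip label (genus) to its number of described
#' extant species.  Species numbers of genera absent from the tree are
#' assumed to have been folded into their closest included relative upstream;
#' this loader only validates, it never reassigns.
#'
#' @param path CSV file with header columns `taxon,richness`.
#' @return named integer vector (names = taxa), all values >= 1.
#' @export
read_richness <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("taxon", "richness") %in% names(df)))
    stop("richness CSV must have columns 'taxon' and 'richness'")
  richness_table(stats::setNames(df$richness, df$taxon))
}

#' @rdname read_richness
#' @param x named numeric vector of species counts.
#' @export
richness_table <- function(x) {
  if (is.null(names(x)) || any(!nzchar(names(x)))) stop("richness must be named")
  if (any(duplicated(names(x)))) stop("duplicated taxa in richness table")
  v <- as.integer(round(x))
  if (any(abs(x - v) > 1e-8)) stop("non-integer richness values")
  if (any(v < 1L)) stop("richness values must be >= 1")
  stats::setNames(v, names(x))
}

#' Check that every tree tip has a richness entry
#'
#' @param tree a `time_tree`.
#' @param richness a [richness_table].
#' @return the richness vector aligned to `tree$tip.label`, invisibly
#'   error if any tip is missing.
#' @export
check_richness <- function(tree, richness) {
  richness <- richness_table(richness)
  miss <- setdiff(tree$tip.label, names(richness))
  if (length(miss))
    stop("tips without richness entries: ", paste(miss, collapse = ", "))
  richness[tree$tip.label]
}

#' Read a binary trait table
#'
#' States are 0/1; anything else (empty, NA, "?") is treated as missing and
#' reported in the coverage attribute.
#'
#' @param path CSV file with header columns `taxon,state`.
#' @return named integer vector with values 0, 1 or NA and attribute
#'   `coverage` (fraction of non-missing states).
#' @export
read_traits <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("taxon", "state") %in% names(df)))
    stop("trait CSV must have columns 'taxon' and 'state'")
  trait_table(stats::setNames(df$state, df$taxon))
}

#' @rdname read_traits
#' @param x named vector coercible to 0/1/NA.
#' @export
trait_table <- function(x) {
  if (is.null(names(x))) stop("trait states must be named")
  if (any(duplicated(names(x)))) stop("duplicated taxa in trait table")
  s <- suppressWarnings(as.integer(as.character(x)))
  s[!(s %in% c(0L, 1L))] <- NA_integer_
  out <- stats::setNames(s, names(x))
  attr(out, "coverage") <- mean(!is.na(s))
  out
}

#' Read a hostplant records table
#'
#' @param path CSV with header columns
#'   `butterfly_genus,plant_family,plant_genus,reference` (the last two are
#'   optional).
#' @return data.frame of records.
#' @export
read_hostplants <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("butterfly_genus", "plant_family")
  if (!all(need %in% names(df)))
    stop("hostplant CSV must have columns ", paste(need, collapse = ", "))
  if (nrow(df) == 0L) stop("empty hostplant record table")
  df
}

#' Code a binary hostplant-use character from feeding records
#'
#' A genus is coded 1 ("feeds on `target_family`") iff at least one record
#' links it to that plant family; genera present in the records but never
#' linked to the family are coded 0; genera absent from the records are
#' missing (NA).  `recode_absent` lists genera to force to state 0
#' regardless of records - the sensitivity re-coding used for taxa whose
#' literature records are considered dubious.
#'
#' @param records data.frame from [read_hostplants].
#' @param target_family plant family name, e.g. `"Solanaceae"`.
#' @param recode_absent character vector of butterfly genera to force to 0.
#' @param all_genera optional character vector of genera that should appear
#'   in the output (those without records become missing).
#' @param missing_as_absent code genera without any feeding record as 0
#'   instead of missing.  Missing is the default: downstream, the
#'   state-dependent likelihood then marginalises over their state instead
#'   of asserting absence.
#' @return a [trait_table] named by butterfly genus.
#' @export
code_binary_trait <- function(records, target_family, recode_absent = character(0),
                              all_genera = NULL, missing_as_absent = FALSE) {
  if (nrow(records) == 0L) stop("empty hostplant record table")
  genera <- unique(records$butterfly_genus)
  st <- as.integer(vapply(genera, function(g)
    any(records$plant_family[records$butterfly_genus == g] == target_family,
        na.rm = TRUE), logical(1)))
  names(st) <- genera
  st[names(st) %in% recode_absent] <- 0L
  if (!is.null(all_genera)) {
    fill <- if (missing_as_absent) 0L else NA_integer_
    full <- stats::setNames(rep(fill, length(all_genera)), all_genera)
    full[intersect(names(st), all_genera)] <- st[intersect(names(st), all_genera)]
    st <- full
  }
  trait_table(st)
}

#' Count how many genera use one vs more than one plant family
#'
#' @param records data.frame from [read_hostplants].
#' @return named integer vector `c(one_family = , multiple_families = )`.
#' @export
plant_family_breadth <- function(records) {
  fams <- tapply(records$plant_family, records$butterfly_genus,
                 function(x) length(unique(x[!is.na(x) & nzchar(x)])))
  c(one_family = sum(fams == 1L), multiple_families = sum(fams > 1L))
}
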