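#' Construct and validate a focus-set family
#'
#' A focus family is a collection of `m` prespecified feature sets
#' \eqn{F_1, \dots, F_m} over a feature universe \eqn{W}. Focus sets carry the
#' partial true discovery guarantee procedures that [focusct()] combines; they
#' must be chosen independently of the data. Sets may overlap.
#'
#' @param sets a named list of feature-id vectors (character or integer), one
#'   per focus set. Unnamed lists get names `F1, F2, ...`.
#' @param universe the full feature universe, as a vector of unique ids. When
#'   `NULL`, the union of `sets` (in order of first appearance) is used.
#' @return An object of class `focus_family` with elements `universe`
#'   (character ids), `w`, `m`, `sets` (list of integer index vectors into the
#'   universe), `names`, and an `overlap` matrix of pairwise intersection
#'   sizes.
#' @examples
#' fam <- focus_family(list(F1 = c(1, 2), F2 = c(2, 4)), universe = 1:4)
#' fam$overlap
#' @export
focus_family <- function(sets, universe = NULL) {
  if (!is.list(sets) || length(sets) == 0L)
    stop("'sets' must be a nonempty list of feature-id vectors")
  nm <- names(sets)
  if (is.null(nm) || any(nm == ""))
    names(sets) <- nm <- paste0("F", seq_along(sets))
  if (anyDuplicated(nm))
    stop("duplicate focus-set names: ", paste(unique(nm[duplicated(nm)]), collapse = ", "))
  sets <- lapply(sets, as.character)
  if (is.null(universe)) universe <- unique(unlist(sets, use.names = FALSE))
  universe <- as.character(universe)
  if (anyDuplicated(universe)) stop("feature ids in the universe must be unique")
  if (length(universe) < 1L) stop("universe must contain at least one feature")
  idx <- lapply(seq_along(sets), function(i) {
    s <- unique(sets[[i]])
    if (length(s) == 0L) stop("focus set '", nm[i], "' is empty")
    j <- match(s, universe)
    if (anyNA(j))
      stop("feature ", paste(s[is.na(j)], collapse = ", "),
           " not in universe (focus set '", nm[i], "')")
    sort(j)
  })
  m <- length(idx)
  ov <- matrix(0L, m, m, dimnames = list(nm, nm))
  for (i in seq_len(m)) for (j in seq_len(m))
    ov[i, j] <- length(intersect(idx[[i]], idx[[j]]))
  structure(list(universe = universe, w = length(universe), m = m,
                 sets = idx, names = nm, overlap = ov),
            class = "focus_family")
}

#' @export
print.focus_family <- function(x, ...) {
  cat("Focus family: m =", x$m, "sets over w =", x$w, "features\n")
  sizes <- lengths(x$sets)
  cat("  set sizes:", paste(sizes, collapse = ", "), "\n")
  off <- x$overlap; diag(off) <- 0L
  if (any(off > 0)) cat("  overlapping pairs:", sum(off[upper.tri(off)] > 0), "\n")
  else cat("  sets are pairwise disjoint\n")
  invisible(x)
}

# resolve a query set (feature ids or integer indices) to universe indices
resolve_set <- function(family, set) {
  if (length(set) == 0L) return(integer(0))
  if (is.numeric(set) && all(set == as.integer(set)) &&
      all(set >= 1) && all(set <= family$w) && !is.character(set)) {
    return(sort(unique(as.integer(set))))
  }
  j <- match(as.character(set), family$universe)
  if (anyNA(j))
    stop("feature ", paste(set[is.na(j)], collapse = ", "), " not in universe")
  sort(unique(j))
}

#' Partial bound oracle backed by a table of precomputed bounds
#'
#' A partial bound oracle for focus set \eqn{F_i} answers queries
#' `evaluate(level, subset)` with an integer lower bound on the true
#' discoveries in `subset` \eqn{\subseteq F_i}, valid at the given level.
#' The table oracle serves tabulated full-set values \eqn{d_i(F_i)} and
#' answers proper subsets by the interpolation floor
#' \eqn{\max(0, d_i - |F_i \setminus S|)}, which preserves the oracle
#' contract. This lets the combination machinery run (and be tested) without
#' any p-values.
#'
#' @param family a [focus_family()].
#' @param bounds either a numeric vector of length `m` (level-independent
#'   bounds) or an `m x L` matrix with one column per tabulated level.
#' @param levels increasing vector of `L` tabulated levels matching the
#'   columns of `bounds`; a query at level `gamma` uses the largest tabulated
#'   level `<= gamma` (a valid, conservative fallback by monotonicity).
#'   Required when `bounds` is a matrix.
#' @return A list of `m` objects of class `partial_oracle`, each with fields
#'   `i`, `size` and a function `evaluate(level, sub)` taking local indices
#'   `sub` within \eqn{F_i}.
#' @examples
#' fam <- focus_family(list(F1 = c(1, 2), F2 = c(2, 4)), universe = 1:4)
#' oc <- oracle_table(fam, c(1, 2))
#' oc[[2]]$evaluate(0.05, 1:2)  # full F2 -> 2
#' oc[[2]]$evaluate(0.05, 1)    # {2} subset of F2 -> 1
#' @export
oracle_table <- function(family, bounds, levels = NULL) {
  m <- family$m
  sizes <- lengths(family$sets)
  if (is.matrix(bounds)) {
    if (is.null(levels) || length(levels) != ncol(bounds))
      stop("'levels' must match the columns of 'bounds'")
    if (is.unsorted(levels, strictly = TRUE)) stop("'levels' must be strictly increasing")
    if (nrow(bounds) != m) stop("'bounds' must have one row per focus set")
    if (any(apply(bounds, 1, is.unsorted)))
      stop("bounds must be nondecreasing in the level")
  } else {
    if (length(bounds) != m) stop("'bounds' must have one entry per focus set")
    bounds <- matrix(as.numeric(bounds), m, 1)
    levels <- NA_real_
  }
  if (any(bounds < 0) || any(bounds > sizes))
    stop("bounds must lie in [0, |F_i|]")
  lapply(seq_len(m), function(i) {
    bi <- as.integer(bounds[i, ])
    size <- sizes[i]
    evaluate <- function(level, sub = seq_len(size)) {
      sub <- unique(as.integer(sub))
      if (length(sub) == 0L) return(0L)
      if (any(sub < 1L | sub > size)) stop("subset indices outside focus set ", i)
      if (length(levels) == 1L && is.na(levels)) d <- bi[1]
      else {
        k <- findInterval(level + 1e-12, levels)
        if (k == 0L) stop("level ", level, " below all tabulated levels for focus set ", i)
        d <- bi[k]
      }
      max(0L, d - (size - length(sub)))
    }
    structure(list(i = i, size = size, evaluate = evaluate),
              class = "partial_oracle")
  })
}

#' @export
print.partial_oracle <- function(x, ...) {
  cat("Partial bound oracle for focus set", x$i, "(size", x$size, ")\n")
  invisible(x)
}
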