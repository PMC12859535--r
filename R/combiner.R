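# Combining the per-focus bounds into a simultaneous procedure: the trivial
# base procedure, interpolation to coherence (exact, small universes), and
# the greedy shortcut for arbitrary universes.

#' Trivial combined procedure
#'
#' The base bound function \eqn{d^{(0)}}: a query set gets its focus set's
#' bound when it coincides with a focus set (ties between duplicated focus
#' sets take the maximum), and 0 otherwise.
#'
#' @param family a [focus_family()].
#' @param d_focus integer vector of per-focus full-set bounds (e.g.
#'   `holm_partial_bounds(...)$bounds`).
#' @return A function `(set) -> integer` accepting feature ids or indices.
#' @export
trivial_bounds <- function(family, d_focus) {
  stopifnot(length(d_focus) == family$m)
  keys <- vapply(family$sets, paste, "", collapse = ",")
  function(set) {
    s <- resolve_set(family, set)
    if (length(s) == 0L) return(0L)
    hit <- keys == paste(s, collapse = ",")
    if (any(hit)) as.integer(max(d_focus[hit])) else 0L
  }
}

# d^(0) over the whole subset lattice as an integer vector indexed by
# bitmask + 1 (w <= cap)
trivial_lattice <- function(family, d_focus, cap = 16) {
  w <- family$w
  if (w > cap) stop("universe of size ", w, " exceeds the exact cap (", cap,
                    "); use greedy_bound()")
  d <- integer(bitwShiftL(1L, w))
  for (i in seq_len(family$m)) {
    k <- mask_of(family$sets[[i]]) + 1L
    d[k] <- max(d[k], as.integer(d_focus[i]))
  }
  d
}

# one full interpolation sweep over the lattice:
# d'(S) = max_U { d(U) - |U \ S| + d(S \ U) }
interpolation_sweep <- function(d, w) {
  N <- bitwShiftL(1L, w)
  pc <- popcount_table(w)
  U <- 0:(N - 1L)
  dn <- integer(N)
  for (S in 0:(N - 1L)) {
    notS <- bitwAnd(U, bitwNot(S))       # U \ S, as masks
    rest <- bitwAnd(S, bitwNot(U))       # S \ U
    dn[S + 1L] <- max(d[U + 1L] - pc[notS + 1L] + d[rest + 1L])
  }
  dn
}

#' One round of interpolation at a query set
#'
#' Applies one interpolation step to a bound function: the improved bound for
#' `S` is \eqn{\max_{U \subseteq W} d(U) - |U \setminus S| + d(S \setminus U)}
#' — if `U` holds more discoveries than it has elements outside `S`, the
#' surplus must sit inside `S`. Exact mode enumerates all `U`; the universe
#' must satisfy `w <= cap`.
#'
#' @param family a [focus_family()].
#' @param d the current bound function, either an integer lattice vector of
#'   length `2^w` (see [coherent_bounds()]) or a per-focus bound vector of
#'   length `m` (interpreted through [trivial_bounds()]).
#' @param set the query set (feature ids or indices).
#' @param cap maximum exact universe size.
#' @return Integer bound for `set` after one round.
#' @examples
#' fam <- focus_family(list(F1 = c(1, 2), F2 = c(2, 4)), universe = 1:4)
#' interpolate_once(fam, c(1, 2), c(2, 3))  # 1, credited through F2
#' @export
interpolate_once <- function(family, d, set, cap = 16) {
  w <- family$w
  if (w > cap) stop("universe of size ", w, " exceeds the exact cap (", cap,
                    "); use greedy_bound()")
  if (length(d) == family$m && length(d) != bitwShiftL(1L, w))
    d <- trivial_lattice(family, d, cap)
  if (length(d) != bitwShiftL(1L, w)) stop("'d' must be a lattice vector or per-focus bounds")
  S <- mask_of(resolve_set(family, set))
  pc <- popcount_table(w)
  U <- 0:(bitwShiftL(1L, w) - 1L)
  max(d[U + 1L] - pc[bitwAnd(U, bitwNot(S)) + 1L] + d[bitwAnd(S, bitwNot(U)) + 1L])
}

#' Coherent (fully interpolated) bounds, exact mode
#'
#' Iterates interpolation sweeps over the whole subset lattice until a sweep
#' changes nothing; the fixpoint is the coherent procedure \eqn{d^{(r)}},
#' which cannot be improved by further interpolation and coincides with the
#' Holm-shortcut closed testing bound ([ct_bound()] with the Holm-level local
#' test). Exponential in `w`; use [greedy_bound()] beyond `cap` features.
#'
#' @inheritParams interpolate_once
#' @param d_focus per-focus full-set bounds.
#' @param queries optional list of query sets (feature ids or indices); when
#'   `NULL`, all `2^w` subsets are returned.
#' @param history keep the lattice after every sweep (`$history`).
#' @return An object of class `bound_table`: a data.frame with columns
#'   `set`, `size`, `bound`, `tdp`; attributes `sweeps` (number of sweeps
#'   until the fixpoint was confirmed) and optionally `history`.
#' @export
coherent_bounds <- function(family, d_focus, queries = NULL, cap = 16,
                            history = FALSE) {
  w <- family$w
  d <- trivial_lattice(family, d_focus, cap)
  hist <- list(d)
  sweeps <- 0L
  repeat {
    dn <- interpolation_sweep(d, w)
    sweeps <- sweeps + 1L
    if (history) hist[[sweeps + 1L]] <- dn
    if (identical(dn, d)) break
    d <- dn
  }
  if (is.null(queries)) {
    masks <- 0:(bitwShiftL(1L, w) - 1L)
    sets <- lapply(masks, function(mk) family$universe[idx_of(mk, w)])
    nmv <- vapply(sets, function(s) paste0("{", paste(s, collapse = ","), "}"), "")
    bounds <- d[masks + 1L]
  } else {
    idx <- lapply(queries, resolve_set, family = family)
    nmv <- names(queries) %||%
      vapply(idx, function(s) paste0("{", paste(family$universe[s], collapse = ","), "}"), "")
    sets <- lapply(idx, function(s) family$universe[s])
    bounds <- vapply(idx, function(s) d[mask_of(s) + 1L], integer(1))
  }
  sizes <- lengths(sets)
  out <- data.frame(set = nmv, size = sizes, bound = as.integer(bounds),
                    tdp = ifelse(sizes > 0, bounds / sizes, 0),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "sweeps") <- sweeps
  attr(out, "method") <- "coherent"
  if (history) attr(out, "history") <- hist
  class(out) <- c("bound_table", "data.frame")
  out
}

#' Greedy interpolation shortcut for one query set
#'
#' Conservative fast bound for an arbitrary query set `S`: repeatedly pick
#' the focus set with the largest incremental contribution
#' \eqn{c_i = \max(0, d_i - |F_i \setminus S'|)} where `S'` is the part of
#' `S` not yet credited; credit \eqn{c_i} discoveries, remove
#' \eqn{F_i \cap S'} from `S'`, retire \eqn{F_i}, and stop when no positive
#' contribution remains. Each step is an interpolation through \eqn{F_i}, so
#' the total never exceeds the coherent bound. Ties are broken by the larger
#' overlap \eqn{|F_i \cap S'|}, then the lower focus index. Runs in
#' \eqn{O(m^2)} set operations for any universe size.
#'
#' @inheritParams coherent_bounds
#' @param set the query set (feature ids or indices).
#' @return Integer bound in `[0, |set|]`.
#' @export
greedy_bound <- function(family, d_focus, set) {
  stopifnot(length(d_focus) == family$m)
  Sp <- resolve_set(family, set)
  cand <- seq_len(family$m)
  total <- 0L
  while (length(cand) > 0L && length(Sp) > 0L) {
    inter <- vapply(family$sets[cand], function(f) length(intersect(f, Sp)), integer(1))
    contrib <- pmax(0L, as.integer(d_focus[cand]) - (lengths(family$sets[cand]) - inter))
    if (all(contrib <= 0L)) break
    pick <- which(contrib == max(contrib))
    if (length(pick) > 1L) pick <- pick[inter[pick] == max(inter[pick])]
    pick <- pick[1L]
    total <- total + contrib[pick]
    Sp <- setdiff(Sp, family$sets[[cand[pick]]])
    cand <- cand[-pick]
  }
  total
}

#' @export
print.bound_table <- function(x, ...) {
  cat("True discovery bounds (", attr(x, "method") %||% "combined", ")\n", sep = "")
  print.data.frame(x, ...)
  invisible(x)
}
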