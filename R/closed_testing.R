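# The explicit closed-testing construction behind the combined procedure.
# Three local-test variants of decreasing power and cost:
#   phi       — some focus set reports discoveries inside S at level alpha/m_S
#               (needs subset-capable partial oracles);
#   phi_tilde — some focus set's full-set bound at alpha/m_S exceeds |F_i \ S|;
#   phi_bar   — same condition with the converged Holm factor h instead of m_S.
# Used to verify the shortcut chain and quantify its power gaps.

#' Number of focus sets intersecting a set
#'
#' @param family a [focus_family()].
#' @param set feature ids or indices.
#' @return Integer count \eqn{m_S = \#\{i : F_i \cap S \neq \emptyset\}}.
#' @export
m_S <- function(family, set) {
  s <- resolve_set(family, set)
  if (length(s) == 0L) return(0L)
  sum(vapply(family$sets, function(f) length(intersect(f, s)) > 0L, logical(1)))
}

#' Closed-testing local test variants
#'
#' Evaluates one of the three local tests at a set `S`. Rejection (`1`)
#' requires the variant's condition to hold for at least one focus set;
#' sets intersecting no focus set are never rejected.
#'
#' @param family a [focus_family()].
#' @param oracles list of partial bound oracles; the `"phi"` variant queries
#'   proper subsets \eqn{F_i \cap S}, the others only full sets.
#' @param alpha level.
#' @param set the set `S` (feature ids or indices).
#' @param variant `"phi"`, `"phi_tilde"` or `"phi_bar"`.
#' @param holm for `"phi_bar"`: a converged [holm_partial_bounds()] state.
#' @return `0L` or `1L`.
#' @export
ct_local_test <- function(family, oracles, alpha, set,
                          variant = c("phi", "phi_tilde", "phi_bar"),
                          holm = NULL) {
  variant <- match.arg(variant)
  s <- resolve_set(family, set)
  if (length(s) == 0L) return(0L)
  mS <- m_S(family, s)
  if (mS == 0L) return(0L)
  if (variant == "phi_bar") {
    if (is.null(holm) || !inherits(holm, "holm_state"))
      stop("'phi_bar' requires a converged holm_state in 'holm'")
    d <- holm$bounds
    for (i in seq_len(family$m)) {
      if (d[i] > length(setdiff(family$sets[[i]], s))) return(1L)
    }
    return(0L)
  }
  level <- alpha / mS
  for (i in seq_len(family$m)) {
    Fi <- family$sets[[i]]
    inter <- intersect(Fi, s)
    if (length(inter) == 0L) next
    if (variant == "phi") {
      sub <- match(inter, Fi)
      if (oracles[[i]]$evaluate(level, sub) > 0L) return(1L)
    } else {
      if (oracles[[i]]$evaluate(level) > length(Fi) - length(inter)) return(1L)
    }
  }
  0L
}

# Evaluate a local-test variant on every mask of the lattice, then run the
# downward dynamic programmes for psi (superset minimum) and for the largest
# non-rejected-by-psi subset inside each mask.
ct_lattice <- function(family, oracles, alpha,
                       variant = c("phi", "phi_tilde", "phi_bar"),
                       holm = NULL, cap = 16) {
  variant <- match.arg(variant)
  w <- family$w
  if (w > cap) stop("universe of size ", w, " exceeds the enumeration cap (", cap, ")")
  N <- bitwShiftL(1L, w)
  pc <- popcount_table(w)
  fmask <- vapply(family$sets, mask_of, integer(1))
  fsize <- lengths(family$sets)
  m <- family$m
  phi <- integer(N)
  if (variant == "phi_bar") {
    if (is.null(holm)) stop("'phi_bar' requires 'holm'")
    d <- holm$bounds
    for (K in 1:(N - 1L)) {
      inter <- pc[bitwAnd(fmask, K) + 1L]
      phi[K + 1L] <- as.integer(any(d > fsize - inter))
    }
  } else {
    # memoised full-set bounds per (i, level) for phi_tilde; per-subset for phi
    cacheF <- new.env(parent = emptyenv())
    for (K in 1:(N - 1L)) {
      inter <- pc[bitwAnd(fmask, K) + 1L]
      mK <- sum(inter > 0L)
      if (mK == 0L) next
      level <- alpha / mK
      rej <- 0L
      for (i in seq_len(m)) {
        if (inter[i] == 0L) next
        if (variant == "phi_tilde") {
          key <- paste0(i, "@", signif(level, 12))
          di <- cacheF[[key]]
          if (is.null(di)) { di <- oracles[[i]]$evaluate(level); cacheF[[key]] <- di }
          if (di > fsize[i] - inter[i]) { rej <- 1L; break }
        } else {
          sub <- match(intersect(idx_of(K, w), family$sets[[i]]), family$sets[[i]])
          if (oracles[[i]]$evaluate(level, sub) > 0L) { rej <- 1L; break }
        }
      }
      phi[K + 1L] <- rej
    }
  }
  # psi(J) = min over supersets K >= J of phi(K); downward DP by popcount
  psi <- phi
  ord <- order(pc, decreasing = TRUE)
  for (Jp in ord) {
    J <- Jp - 1L
    if (psi[Jp] == 0L) next
    free <- which(bitwAnd(J, bitwShiftL(1L, 0:(w - 1L))) == 0L)
    for (b in free) {
      if (psi[bitwOr(J, bitwShiftL(1L, b - 1L)) + 1L] == 0L) { psi[Jp] <- 0L; break }
    }
  }
  # g(S) = max |J|, J subset of S with psi(J) = 0 (upward DP)
  g <- ifelse(psi == 0L, pc, -1L)
  ord2 <- order(pc)
  for (Sp in ord2) {
    S <- Sp - 1L
    if (S == 0L) next
    inb <- which(bitwAnd(S, bitwShiftL(1L, 0:(w - 1L))) != 0L)
    for (b in inb) {
      sub <- bitwAnd(S, bitwNot(bitwShiftL(1L, b - 1L)))
      if (g[sub + 1L] > g[Sp]) g[Sp] <- g[sub + 1L]
    }
  }
  list(phi = phi, psi = psi, g = g, pc = pc, w = w)
}

#' Closed-testing true-discovery bound
#'
#' The bound \eqn{d(S) = \min_{J \subseteq S} \{|S \setminus J| : \psi(J) =
#' 0\}} of the closed testing procedure built from the chosen local-test
#' variant, where \eqn{\psi(J) = \min\{\phi(K) : J \subseteq K \subseteq W\}}
#' is the effective (superset-minimum) local test. Enumerates the subset
#' lattice, so the universe must be small (`w <= cap`); this is verification
#' machinery, not the user path. For `"phi_bar"`, \eqn{\psi} equals
#' \eqn{\phi} itself (no superset search) and the resulting bound coincides
#' with the coherent interpolated procedure.
#'
#' @inheritParams ct_local_test
#' @param cap enumeration cap on the universe size.
#' @return Integer bound for `set`.
#' @export
ct_bound <- function(family, oracles, alpha, set,
                     variant = c("phi", "phi_tilde", "phi_bar"),
                     holm = NULL, cap = 16) {
  variant <- match.arg(variant)
  lat <- ct_lattice(family, oracles, alpha, variant, holm, cap)
  s <- resolve_set(family, set)
  mk <- mask_of(s)
  length(s) - max(0L, lat$g[mk + 1L])
}

#' Holm-shortcut closed-testing bound without lattice enumeration
#'
#' Direct evaluation of the `"phi_bar"` closed-testing bound for one query
#' set: since the effective local test equals \eqn{\bar\phi} itself, the
#' bound is \eqn{|S| - \max\{|J| : J \subseteq S,\ \bar\phi(J) = 0\}}, and
#' \eqn{\bar\phi(J) = 0} iff \eqn{|F_i \cap J| \le |F_i| - d_i} for every
#' focus set. Enumerates subsets of `S` only (cap on `|S|`, not `w`).
#'
#' @param family a [focus_family()].
#' @param holm a converged [holm_partial_bounds()] (or Bonferroni) state.
#' @param set the query set.
#' @param cap maximum query-set size for enumeration.
#' @return Integer bound for `set`.
#' @export
ct_bound_phibar <- function(family, holm, set, cap = 22) {
  s <- resolve_set(family, set)
  ns <- length(s)
  if (ns == 0L) return(0L)
  if (ns > cap) stop("query set of size ", ns, " exceeds the enumeration cap (", cap, ")")
  d <- holm$bounds
  caps <- lengths(family$sets) - d   # max allowed |F_i cap J|
  # membership of each element of S in each focus set
  memb <- vapply(family$sets, function(f) s %in% f, logical(ns))
  memb <- matrix(memb, nrow = ns)
  pc <- popcount_table(ns)
  best <- 0L
  for (J in 0:(bitwShiftL(1L, ns) - 1L)) {
    if (pc[J + 1L] <= best) next
    take <- bitwAnd(J, bitwShiftL(1L, 0:(ns - 1L))) != 0L
    if (all(colSums(memb[take, , drop = FALSE]) <= caps)) best <- pc[J + 1L]
  }
  ns - best
}
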