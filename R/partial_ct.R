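# Partial closed testing within one focus set: exact true-discovery bounds
# d_i^gamma(S) for S inside F_i, plus the Bonferroni / Holm combination of
# the per-focus full-set bounds.

#' Exact Fisher closed-testing bound for a subset, by suffix scan
#'
#' Computes the closed-testing lower bound on true discoveries in a query set
#' with p-values `p_in`, where the closed testing runs over the family formed
#' by `p_in` together with `p_out` (the rest of the focus set, or the rest of
#' the universe for full closed testing), using Fisher combination local
#' tests at the given `level`.
#'
#' For a sum-based statistic whose rejection threshold depends only on the
#' subset size, the hardest-to-reject subset of a given size is the one
#' holding the largest p-values, so the minimum over all
#' \eqn{2^{|F|}} subsets reduces to a scan over (number taken from the query
#' set, number taken from outside) with suffix sums: the bound is
#' \eqn{|S| - \max\{k_1 : \exists k_0,\;}the \eqn{k_1} largest p-values in S
#' plus the \eqn{k_0} largest outside are not rejected\eqn{\}}. This is exact
#' and runs in \eqn{O(|S| \cdot |out|)} after sorting.
#'
#' @param p_in p-values of the query set.
#' @param p_out p-values of the remaining features in the closed family
#'   (use `numeric(0)` when the query set is the whole family).
#' @param level local-test level in `(0, 1)`.
#' @param floor clamp for zero p-values.
#' @return Integer bound in `[0, length(p_in)]`.
#' @seealso [partial_bound_bruteforce()] for the enumeration reference.
#' @export
fisher_subset_bound <- function(p_in, p_out = numeric(0), level = 0.05,
                                floor = 1e-300) {
  n_in <- length(p_in)
  if (n_in == 0L) return(0L)
  if (length(level) != 1L || level <= 0 || level >= 1) stop("'level' must lie in (0,1)")
  p_in <- pmax(p_in, floor); p_out <- pmax(p_out, floor)
  n_out <- length(p_out)
  # cumulative statistic of the k largest p-values (smallest Fisher statistic)
  cum_in <- c(0, cumsum(-2 * log(sort(p_in, decreasing = TRUE))))
  cum_out <- c(0, cumsum(-2 * log(sort(p_out, decreasing = TRUE))))
  thr <- c(Inf, stats::qchisq(1 - level, df = 2 * seq_len(n_in + n_out)))
  # thr[k+1] is the rejection threshold for a set of size k; size 0 never rejected
  k0 <- 0:n_out
  for (k1 in n_in:0) {
    if (k1 == 0L) return(n_in)
    tot <- cum_in[k1 + 1L] + cum_out[k0 + 1L]
    if (any(tot < thr[k1 + k0 + 1L])) return(n_in - k1)
  }
}

#' Brute-force partial closed-testing bound
#'
#' Reference implementation of the partial true-discovery bound
#' \eqn{d_i^{level}(S)} for \eqn{S \subseteq F_i}: enumerates every subset
#' \eqn{K \subseteq F_i}, applies the local test, and returns
#' \eqn{|S| - \max\{|K \cap S| : K \text{ not rejected}\}}. Exponential in
#' `length(p)`; intended as the trust anchor for the fast paths.
#'
#' @param p p-values of the whole focus set \eqn{F_i}.
#' @param level local-test level.
#' @param subset indices (within `p`) of the query set `S`; defaults to all
#'   of \eqn{F_i}.
#' @param local local test: a function `(p-values) -> combined p-value`;
#'   rejection is `local(p[K]) <= level`. Default [fisher_pvalue()].
#' @param cap refuse enumeration beyond this focus-set size.
#' @return Integer bound in `[0, length(subset)]`.
#' @export
partial_bound_bruteforce <- function(p, level, subset = seq_along(p),
                                     local = fisher_pvalue, cap = 20) {
  n <- length(p)
  if (n > cap)
    stop("focus set of size ", n, " exceeds the brute-force cap (", cap,
         "); use fisher_subset_bound() / partial_bound_fullset()")
  subset <- unique(as.integer(subset))
  if (length(subset) == 0L) return(0L)
  if (any(subset < 1L | subset > n)) stop("'subset' indices outside the focus set")
  smask <- mask_of(subset)
  pc <- popcount_table(n)
  best <- 0L  # K = empty set is never rejected
  for (K in seq_len(bitwShiftL(1L, n) - 1L)) {
    inter <- pc[bitwAnd(K, smask) + 1L]
    if (inter <= best) next
    if (local(p[idx_of(K, n)]) > level) best <- inter
  }
  length(subset) - best
}

#' Full-set partial bound via the sorted-suffix fast path
#'
#' The bound \eqn{d_i^{level}(F_i)} for the whole focus set under Fisher
#' combination local tests: \eqn{|F_i| - \max\{k\}} such that the `k` largest
#' p-values are not rejected as an intersection. Runs in
#' \eqn{O(|F_i| \log |F_i|)} and agrees with [partial_bound_bruteforce()].
#'
#' @inheritParams fisher_subset_bound
#' @param p p-values of the focus set.
#' @return Integer bound in `[0, length(p)]`.
#' @export
partial_bound_fullset <- function(p, level, floor = 1e-300) {
  fisher_subset_bound(p, numeric(0), level, floor)
}

#' Fisher partial closed-testing oracles for a focus family
#'
#' Builds one [oracle_table()]-style partial bound oracle per focus set, whose
#' `evaluate(level, sub)` runs exact partial closed testing with Fisher
#' combination local tests over \eqn{2^{F_i}} via the suffix scan of
#' [fisher_subset_bound()]. Evaluations are memoised per (level, subset).
#'
#' @param family a [focus_family()].
#' @param p named p-value vector aligned with (or covering) the family's
#'   universe.
#' @param floor clamp for zero p-values.
#' @return List of `m` `partial_oracle` objects.
#' @export
oracle_fisher <- function(family, p, floor = 1e-300) {
  p <- align_pvalues(family, p)
  lapply(seq_len(family$m), function(i) {
    pF <- p[family$sets[[i]]]
    size <- length(pF)
    cache <- new.env(parent = emptyenv())
    evaluate <- function(level, sub = seq_len(size)) {
      sub <- unique(as.integer(sub))
      if (length(sub) == 0L) return(0L)
      if (any(sub < 1L | sub > size)) stop("subset indices outside focus set ", i)
      key <- paste(signif(level, 12), paste(sort(sub), collapse = ","))
      hit <- cache[[key]]
      if (!is.null(hit)) return(hit)
      val <- fisher_subset_bound(pF[sub], pF[-sub], level, floor)
      cache[[key]] <- val
      val
    }
    structure(list(i = i, size = size, evaluate = evaluate),
              class = "partial_oracle")
  })
}

# align a p-value vector with the family universe (by name when available)
align_pvalues <- function(family, p) {
  if (!is.null(names(p))) {
    j <- match(family$universe, names(p))
    if (anyNA(j))
      stop("p-values missing for feature(s): ",
           paste(utils::head(family$universe[is.na(j)], 5), collapse = ", "))
    p <- unname(p[j])
  } else if (length(p) != family$w) {
    stop("unnamed p-value vector must have length w = ", family$w)
  }
  if (anyNA(p) || any(p < 0) || any(p > 1)) stop("p-values must lie in [0, 1]")
  p
}

#' Combine partial procedures at Bonferroni level alpha/m
#'
#' Evaluates each focus set's full-set bound at level `alpha/m`.
#'
#' @param oracles list of partial bound oracles (e.g. [oracle_fisher()]).
#' @param family the [focus_family()].
#' @param alpha overall confidence level parameter.
#' @return An object of class `holm_state` with `h = m`, per-focus `bounds`,
#'   and `fully_rejected` flags.
#' @export
bonferroni_partial_bounds <- function(oracles, family, alpha) {
  m <- family$m
  b <- vapply(seq_len(m), function(i) as.integer(oracles[[i]]$evaluate(alpha / m)),
              integer(1))
  structure(list(h = m, bounds = b, fully_rejected = b == lengths(family$sets),
                 rounds = 1L, alpha = alpha, method = "bonferroni",
                 names = family$names),
            class = "holm_state")
}

#' Combine partial procedures with Holm alpha-recycling
#'
#' Holm's factor `h` starts at `m`. Each sweep evaluates
#' \eqn{d_i^{\alpha/h}(F_i)} for every focus set not yet fully rejected;
#' every set whose bound reaches \eqn{|F_i|} is moved to the fully rejected
#' pool (its bound frozen there), `h` is reduced by the number of newly fully
#' rejected sets, and the sweep repeats until a sweep rejects nothing new.
#' Early stopping after `max_rounds` sweeps retains error control, at some
#' power cost.
#'
#' @inheritParams bonferroni_partial_bounds
#' @param max_rounds stop after this many sweeps even if not converged.
#' @return An object of class `holm_state`: final Holm factor `h`
#'   (floored at 1), per-focus `bounds`, `fully_rejected`, sweep count
#'   `rounds`.
#' @export
holm_partial_bounds <- function(oracles, family, alpha, max_rounds = Inf) {
  m <- family$m
  sizes <- lengths(family$sets)
  full <- rep(FALSE, m)
  b <- integer(m)
  rounds <- 0L
  repeat {
    rounds <- rounds + 1L
    h <- max(1L, m - sum(full))
    active <- which(!full)
    for (i in active) b[i] <- as.integer(oracles[[i]]$evaluate(alpha / h))
    newly <- active[b[active] == sizes[active]]
    full[newly] <- TRUE
    if (length(newly) == 0L || all(full) || rounds >= max_rounds) break
  }
  b[full] <- sizes[full]
  structure(list(h = max(1L, m - sum(full)), bounds = b, fully_rejected = full,
                 rounds = rounds, alpha = alpha, method = "holm",
                 names = family$names),
            class = "holm_state")
}

#' @export
print.holm_state <- function(x, ...) {
  cat(sprintf("%s combination: h = %d, %d/%d focus sets fully rejected (%d sweep%s)\n",
              x$method, x$h, sum(x$fully_rejected), length(x$bounds), x$rounds,
              if (x$rounds == 1L) "" else "s"))
  print(stats::setNames(x$bounds, x$names))
  invisible(x)
}
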