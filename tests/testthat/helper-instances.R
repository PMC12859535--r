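# Shared generators for randomised property tests.

# random focus family over a small universe
rand_family <- function(w_range = 4:8, m_range = 1:4, disjoint = FALSE,
                        max_size = 5) {
  w <- sample(w_range, 1)
  m <- sample(m_range, 1)
  if (disjoint) {
    perm <- sample(w)
    cuts <- sort(sample(seq_len(w - 1), min(m - 1, w - 1)))
    pieces <- split(perm, findInterval(seq_len(w), c(0, cuts) + 1))
    sets <- lapply(pieces[seq_len(min(m, length(pieces)))], sort)
  } else {
    sets <- lapply(seq_len(m), function(i)
      sort(sample(w, sample(2:min(max_size, w), 1))))
  }
  focus_family(stats::setNames(lapply(sets, as.character),
                               paste0("F", seq_along(sets))),
               universe = as.character(seq_len(w)))
}

# random level-tabulated table oracles respecting the oracle invariants
rand_table_oracle <- function(fam, alpha = 0.05) {
  sizes <- lengths(fam$sets)
  lo <- vapply(sizes, function(s) sample(0:s, 1), integer(1))
  mid <- pmin(sizes, lo + vapply(sizes, function(s) sample(0:2, 1), integer(1)))
  hi <- pmin(sizes, mid + vapply(sizes, function(s) sample(0:2, 1), integer(1)))
  oracle_table(fam, cbind(lo, mid, hi),
               levels = c(alpha / 4, alpha / 2, alpha))
}

# random Fisher partial-CT instance (p-values with occasional signal)
rand_fisher_instance <- function(w_range = 4:8, m_range = 1:4) {
  fam <- rand_family(w_range, m_range)
  p <- stats::runif(fam$w)^sample(c(1, 4), 1)
  names(p) <- fam$universe
  list(fam = fam, p = p, oracles = oracle_fisher(fam, p))
}

# all subsets of 1..w as index vectors, in mask order
lattice_sets <- function(w) {
  lapply(0:(2^w - 1), function(mk) which(bitwAnd(mk, bitwShiftL(1L, 0:(w - 1L))) != 0L))
}

mc_limit <- function(p0, reps, k = 3) p0 + k * sqrt(p0 * (1 - p0) / reps)

# a union of focus sets that cuts no focus set partially (the condition under
# which the full and full-set-only local tests coincide)
closed_union <- function(fam) {
  S <- sort(unique(unlist(fam$sets[sample(fam$m, sample(fam$m, 1))])))
  repeat {
    part <- which(vapply(fam$sets, function(f) {
      k <- length(intersect(f, S)); k > 0L && k < length(f)
    }, logical(1)))
    if (length(part) == 0L) break
    S <- sort(unique(c(S, unlist(fam$sets[part]))))
  }
  S
}
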