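# Seeded generators for the simulation designs every stage of the package is
# tested against: two-group normal features, focus/nonfocus sets with
# prescribed TDP, Beta-vs-Uniform replicability p-value matrices, and
# dyadic-tree structured hypotheses.

#' Two-group normal feature data
#'
#' `n` samples of `w` independent standard-normal features with a Bernoulli(0.5)
#' binary response; truly associated features have their mean shifted by `mu`
#' in the `y = 1` group (the shift applies to one group only, which yields
#' the stated association strength and keeps both group variances at
#' `sigma`).
#'
#' @param n samples (default 100).
#' @param w features (default 1000).
#' @param prop_signal proportion of truly associated features.
#' @param mu mean shift of associated features (default 0.7).
#' @param sigma common feature standard deviation (default 1).
#' @param seed optional RNG seed; the generator is a pure function of
#'   (arguments, seed) and leaves the caller's RNG stream untouched.
#' @return List: `x` (`n x w` matrix), `y` (0/1 response), `signal` (logical
#'   length-`w` truth assignment, `TRUE` = false null), `config`.
#' @export
sim_two_group <- function(n = 100, w = 1000, prop_signal = 0.2, mu = 0.7,
                          sigma = 1, seed = NULL) {
  stopifnot(n >= 4, w >= 1, prop_signal >= 0, prop_signal <= 1, sigma > 0)
  with_local_seed(seed, {
    repeat {
      y <- stats::rbinom(n, 1L, 0.5)
      if (length(unique(y)) == 2L) break
    }
    n_sig <- round(prop_signal * w)
    signal <- rep(FALSE, w)
    if (n_sig > 0) signal[sample.int(w, n_sig)] <- TRUE
    x <- matrix(stats::rnorm(n * w, sd = sigma), n, w)
    if (n_sig > 0) x[y == 1L, signal] <- x[y == 1L, signal] + mu
    colnames(x) <- paste0("f", seq_len(w))
    list(x = x, y = y, signal = signal,
         config = list(n = n, w = w, prop_signal = prop_signal, mu = mu,
                       sigma = sigma, seed = seed))
  })
}

#' Focus and nonfocus sets with prescribed true discovery proportions
#'
#' Builds `n_focus` focus sets and `n_nonfocus` post hoc (nonfocus) query
#' sets of size `set_size`, one per value of `tdp_grid`, whose realised TDP
#' (fraction of truly associated members) equals the grid value exactly.
#' A fraction `overlap` of each set's signal and null members is drawn from
#' small shared pools, so focus sets overlap each other and the nonfocus
#' sets.
#'
#' @param signal logical truth assignment over the universe (from
#'   [sim_two_group()]).
#' @param n_focus,n_nonfocus number of sets of each kind (default 11 each).
#' @param tdp_grid target TDP per set (recycled to each kind); every
#'   `tdp * set_size` must be an integer.
#' @param set_size members per set (default 20).
#' @param overlap fraction of members drawn from shared pools, in `[0, 1]`.
#' @param seed optional RNG seed.
#' @return List: `focus` (a [focus_family()]), `nonfocus` (named list of id
#'   vectors), `tdp` (the grid), `universe`.
#' @export
sim_focus_structure <- function(signal, n_focus = 11, n_nonfocus = 11,
                                tdp_grid = seq(0, 1, 0.1), set_size = 20,
                                overlap = 0.5, seed = NULL) {
  w <- length(signal)
  universe <- paste0("f", seq_len(w))
  tdp_f <- rep_len(tdp_grid, n_focus)
  tdp_n <- rep_len(tdp_grid, n_nonfocus)
  k_sig <- round(c(tdp_f, tdp_n) * set_size)
  if (any(abs(k_sig - c(tdp_f, tdp_n) * set_size) > 1e-9))
    stop("tdp * set_size must be an integer for every set")
  sig_ids <- which(signal); null_ids <- which(!signal)
  if (max(k_sig) > length(sig_ids) || max(set_size - k_sig) > length(null_ids))
    stop("not enough signal or null features to realise the requested TDPs")
  with_local_seed(seed, {
    pool_sig <- sample(sig_ids, min(length(sig_ids), set_size))
    pool_null <- sample(null_ids, min(length(null_ids), set_size))
    draw_set <- function(ks) {
      kn <- set_size - ks
      pick <- function(k, pool, all_ids) {
        k_pool <- min(round(overlap * k), length(pool))
        from_pool <- if (k_pool > 0) sample(pool, k_pool) else integer(0)
        rest <- setdiff(all_ids, from_pool)
        c(from_pool, if (k - k_pool > 0) sample(rest, k - k_pool) else integer(0))
      }
      sort(c(pick(ks, pool_sig, sig_ids), pick(kn, pool_null, null_ids)))
    }
    fsets <- lapply(k_sig[seq_len(n_focus)], draw_set)
    nsets <- lapply(k_sig[n_focus + seq_len(n_nonfocus)], draw_set)
    names(fsets) <- paste0("focus_tdp", format(tdp_f))
    names(nsets) <- paste0("nonfocus_tdp", format(tdp_n))
    list(focus = focus_family(lapply(fsets, function(s) universe[s]),
                              universe = universe),
         nonfocus = lapply(nsets, function(s) universe[s]),
         tdp = list(focus = tdp_f, nonfocus = tdp_n),
         universe = universe)
  })
}

#' Replicability p-value matrix (Beta signal vs Uniform null)
#'
#' `m x v` matrix of independent study p-values: signal entries follow
#' Beta(`beta_shape`, 1) (stochastically smaller than uniform for shape < 1),
#' null entries Uniform(0,1). With scalar `v1`, the first half of the
#' features get `v1` signal studies and the second half none (the design the
#' replicability comparison tabulates); a vector `v1` gives per-feature
#' counts.
#'
#' @param m features (default 10).
#' @param v studies (default 10).
#' @param v1 number of signal studies: scalar (first-half design) or length-`m`
#'   vector.
#' @param beta_shape Beta shape parameter of signal p-values (default 0.05).
#' @param seed optional RNG seed.
#' @return List: `p` (`m x v` matrix), `v1` (per-feature signal-study counts),
#'   `config`.
#' @export
sim_pc_matrix <- function(m = 10, v = 10, v1 = 0, beta_shape = 0.05,
                          seed = NULL) {
  if (length(v1) == 1L) {
    v1 <- c(rep(as.integer(v1), ceiling(m / 2)), rep(0L, floor(m / 2)))
  }
  stopifnot(length(v1) == m, all(v1 >= 0), all(v1 <= v), beta_shape > 0)
  with_local_seed(seed, {
    p <- matrix(stats::runif(m * v), m, v)
    for (i in seq_len(m)) {
      if (v1[i] > 0)
        p[i, seq_len(v1[i])] <- stats::rbeta(v1[i], beta_shape, 1)
    }
    rownames(p) <- paste0("feature", seq_len(m))
    colnames(p) <- paste0("study", seq_len(v))
    list(p = p, v1 = v1,
         config = list(m = m, v = v, beta_shape = beta_shape, seed = seed))
  })
}

#' Dyadic-tree structured hypotheses
#'
#' Leaf-level z-scores Normal(`mu` * signal, 1) converted to one-sided
#' p-values, with the internal nodes of a complete dyadic tree as candidate
#' focus families. Signals are either grouped (a contiguous block of leaves,
#' one branch when the count is a power of two) or randomly placed. A
#' complete dyadic tree with `layers` layers has `2^(layers-1)` leaves;
#' `truncate` keeps only the first so-many leaves (and trims node sets
#' accordingly) for non-dyadic element counts.
#'
#' @param n_leaves leaves (default 128 = 2^7, eight layers).
#' @param layers tree depth including the root layer.
#' @param prop_signal proportion of true nonnull leaves.
#' @param placement `"grouped"` or `"random"`.
#' @param mu signal strength (z-score mean).
#' @param truncate optional element count to truncate the leaves to.
#' @param seed optional RNG seed.
#' @return List: `p` (leaf p-values), `signal` (truth), `layers` (list of
#'   per-layer node families, each a named list of leaf-id vectors),
#'   `all_nodes` (every node of every layer).
#' @export
sim_dyadic_tree <- function(n_leaves = 128, layers = 8, prop_signal = 0.5,
                            placement = c("grouped", "random"), mu = 1,
                            truncate = NULL, seed = NULL) {
  placement <- match.arg(placement)
  if (bitwAnd(n_leaves, n_leaves - 1L) != 0L)
    stop("'n_leaves' must be a power of two")
  if (n_leaves != 2^(layers - 1L))
    stop("a complete dyadic tree with ", layers, " layers has ",
         2^(layers - 1L), " leaves")
  keep <- if (is.null(truncate)) n_leaves else min(truncate, n_leaves)
  with_local_seed(seed, {
    n_sig <- round(prop_signal * keep)
    signal <- rep(FALSE, keep)
    if (n_sig > 0) {
      sig_idx <- if (placement == "grouped") seq_len(n_sig)
                 else sample.int(keep, n_sig)
      signal[sig_idx] <- TRUE
    }
    z <- stats::rnorm(keep, mean = mu * signal)
    p <- stats::pnorm(z, lower.tail = FALSE)
    names(p) <- paste0("leaf", seq_len(keep))
    layer_fams <- lapply(seq_len(layers), function(l) {
      blk <- n_leaves / 2^(l - 1L)
      starts <- seq(1L, n_leaves, by = blk)
      nodes <- lapply(starts, function(s) {
        ids <- intersect(s:(s + blk - 1L), seq_len(keep))
        if (length(ids)) paste0("leaf", ids) else NULL
      })
      nodes <- Filter(Negate(is.null), nodes)
      stats::setNames(nodes, paste0("L", l, "n", seq_along(nodes)))
    })
    list(p = p, signal = signal, layers = layer_fams,
         all_nodes = unlist(layer_fams, recursive = FALSE),
         config = list(n_leaves = n_leaves, layers = layers,
                       prop_signal = prop_signal, placement = placement,
                       mu = mu, truncate = truncate, seed = seed))
  })
}

#' Replicability simulation table: partial closed testing vs AdaFilter
#'
#' For each number of signal studies `v1 = 0..v` (first half of features at
#' `v1`, second half null), averages the per-feature replication lower bound
#' over features and replications, for partial conjunction closed testing at
#' level `alpha/m` and AdaFilter-`r` for each `r` in `r_values`. The first
#' row is the analytic truth `v1/2` (mean signal-study count over features).
#'
#' @param reps replications per `v1` (default 1000).
#' @param alpha level (default 0.05).
#' @param m,v features and studies (default 10 each).
#' @param beta_shape signal p-value Beta shape (default 0.05).
#' @param r_values AdaFilter replication targets (default `2:v`).
#' @param seed optional RNG seed.
#' @return Numeric matrix, rows `true mean`, `partial_ct`, `adafilter-r`;
#'   columns `v1 = 0..v`.
#' @export
run_table2 <- function(reps = 1000, alpha = 0.05, m = 10, v = 10,
                       beta_shape = 0.05, r_values = 2:v, seed = NULL) {
  with_local_seed(seed, {
    cols <- 0:v
    out <- matrix(0, nrow = 2 + length(r_values), ncol = length(cols),
                  dimnames = list(c("true mean", "partial_ct",
                                    paste0("adafilter-", r_values)),
                                  paste0("v1=", cols)))
    for (ci in seq_along(cols)) {
      v1 <- cols[ci]
      acc <- numeric(1 + length(r_values))
      for (b in seq_len(reps)) {
        sim <- sim_pc_matrix(m = m, v = v, v1 = v1, beta_shape = beta_shape)
        pct <- vapply(seq_len(m),
                      function(i) pc_feature_bound(sim$p[i, ], alpha / m),
                      integer(1))
        acc[1] <- acc[1] + mean(pct)
        for (k in seq_along(r_values))
          acc[1 + k] <- acc[1 + k] + mean(adafilter(sim$p, r_values[k], alpha)$bounds)
      }
      out["true mean", ci] <- mean(c(rep(v1, ceiling(m / 2)), rep(0, floor(m / 2))))
      out[-1, ci] <- acc / reps
    }
    out
  })
}
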