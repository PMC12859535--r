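# Replicability analysis: per-feature lower bounds on the number of studies
# showing a true effect, via partial-conjunction closed testing with Fisher
# combination, and the AdaFilter comparator.

#' Partial conjunction p-value (Fisher combination)
#'
#' P-value for the partial conjunction hypothesis "fewer than `r` of the `v`
#' studies have a true effect": Fisher's combination of the `v - r + 1`
#' largest p-values in the row. `r = 0` returns 0 by convention (the
#' hypothesis "fewer than 0 effects" is always false, hence always rejected).
#'
#' @param p the feature's p-values across `v` studies.
#' @param r replication target, `0 <= r <= v`.
#' @param floor clamp for zero p-values.
#' @return The partial conjunction p-value.
#' @examples
#' pc_pvalue(c(0.01, 0.2, 0.9), 2)  # Fisher of {0.2, 0.9} = 0.48866
#' @export
pc_pvalue <- function(p, r, floor = 1e-300) {
  v <- length(p)
  if (v == 0L) stop("empty p-value row")
  if (r > v) stop("'r' cannot exceed the number of studies (", v, ")")
  if (r < 0L) stop("'r' must be nonnegative")
  if (r == 0L) return(0)
  fisher_pvalue(sort(p)[r:v], floor = floor)
}

#' Per-feature replication lower bound by partial conjunction closed testing
#'
#' The largest `r` such that every partial conjunction hypothesis up to `r`
#' is rejected: \eqn{d = \max\{r : p^{u/v} \le} `level` for all
#' \eqn{u = 0, \dots, r\}}. Equivalent to closed testing over the feature's
#' `v` study hypotheses with Fisher combination local tests, evaluated at the
#' full row.
#'
#' @param p the feature's p-values across `v` studies.
#' @param level per-feature level (e.g. `alpha / m`).
#' @param floor clamp for zero p-values.
#' @return Integer bound in `[0, v]`: with the stated confidence, at least
#'   this many studies carry a true effect.
#' @export
pc_feature_bound <- function(p, level, floor = 1e-300) {
  v <- length(p)
  ps <- sort(p)
  d <- 0L
  for (r in seq_len(v)) {
    if (fisher_pvalue(ps[r:v], floor = floor) <= level) d <- r else break
  }
  d
}

#' AdaFilter partial conjunction testing
#'
#' AdaFilter tests the fixed-`r` partial conjunction hypothesis for every
#' feature, filtering by \eqn{R_i = (v-r+1)\,p_{i(r-1)}} and selecting by
#' \eqn{S_i = (v-r+1)\,p_{i(r)} < \hat\alpha}, with the adaptive level
#' \eqn{\hat\alpha = \sup\{\gamma \in [0,\alpha] : \gamma \sum_i 1\{R_i <
#' \gamma\} \le \alpha\}}. The constraint is a right-continuous step-linear
#' function of \eqn{\gamma}, so the supremum is attained at one of the
#' candidate points \eqn{\{\alpha\} \cup \{\alpha/k\}_{k=1}^m \cup \{R_i\}}
#' (clipped to \eqn{[0,\alpha]}); all inequalities are strict as written.
#' Controls FWER at `alpha` for independent p-values. The implied
#' replication lower bound is `r` for rejected features, 0 otherwise.
#'
#' @param pmat `m x v` p-value matrix (rows = features, columns = studies).
#' @param r replication target, `2 <= r <= v`.
#' @param alpha FWER level.
#' @return An object of class `adafilter`: list with `bounds` (length-`m`
#'   integer vector), `rejected`, `alpha_hat`, `R`, `S`, `r`, `alpha`.
#' @examples
#' pm <- rbind(c(0.001, 0.002), c(0.01, 0.5), c(0.8, 0.9))
#' adafilter(pm, r = 2, alpha = 0.05)$alpha_hat  # 0.025
#' @export
adafilter <- function(pmat, r, alpha = 0.05) {
  pmat <- as.matrix(pmat)
  m <- nrow(pmat); v <- ncol(pmat)
  if (r < 2L || r > v) stop("'r' must lie in [2, v]")
  if (anyNA(pmat) || any(pmat < 0) || any(pmat > 1)) stop("p-values must lie in [0, 1]")
  ps <- t(apply(pmat, 1L, sort))
  R <- (v - r + 1) * ps[, r - 1L]
  S <- (v - r + 1) * ps[, r]
  cand <- unique(c(alpha, alpha / seq_len(m), R))
  cand <- cand[cand >= 0 & cand <= alpha]
  # tolerance absorbs rounding in candidates of the form (alpha/k) * k
  feas <- vapply(cand, function(g) g * sum(R < g) <= alpha * (1 + 1e-9),
                 logical(1))
  alpha_hat <- if (any(feas)) max(cand[feas]) else 0
  rejected <- S < alpha_hat
  structure(list(bounds = ifelse(rejected, r, 0L), rejected = rejected,
                 alpha_hat = alpha_hat, R = R, S = S, r = as.integer(r),
                 alpha = alpha),
            class = "adafilter")
}

#' @export
print.adafilter <- function(x, ...) {
  cat(sprintf("AdaFilter-%d: %d/%d features rejected (alpha_hat = %g)\n",
              x$r, sum(x$rejected), length(x$S), x$alpha_hat))
  invisible(x)
}

#' Replicability lower bounds for a p-value matrix
#'
#' Treats each feature's row of study p-values as one focus set of a disjoint
#' partition and reports, per feature, a lower confidence bound on the number
#' of studies with a true effect, simultaneous over all features at level
#' `alpha`.
#'
#' `method = "partial_ct"` runs partial conjunction closed testing per row at
#' level `alpha/m` (`adjust = "bonferroni"`, the default) or with Holm
#' alpha-recycling across rows (`adjust = "holm"`, never worse).
#' `method = "adafilter"` runs [adafilter()] at the supplied `r` and reports
#' bound `r` for rejected features, 0 otherwise.
#'
#' @param pmat `m x v` p-value matrix.
#' @param alpha simultaneous level.
#' @param method `"partial_ct"` or `"adafilter"`.
#' @param r replication target for AdaFilter.
#' @param adjust across-feature multiplicity for `"partial_ct"`.
#' @return A data.frame of class `replicability_result`: `feature`, `bound`;
#'   attributes `alpha`, `method` (and `alpha_hat`, `r` for AdaFilter).
#' @export
replicability <- function(pmat, alpha = 0.05,
                          method = c("partial_ct", "adafilter"), r = NULL,
                          adjust = c("bonferroni", "holm")) {
  method <- match.arg(method)
  adjust <- match.arg(adjust)
  pmat <- as.matrix(pmat)
  m <- nrow(pmat); v <- ncol(pmat)
  feat <- rownames(pmat) %||% as.character(seq_len(m))
  if (method == "adafilter") {
    if (is.null(r)) stop("supply 'r' for method = 'adafilter'")
    af <- adafilter(pmat, r, alpha)
    out <- data.frame(feature = feat, bound = as.integer(af$bounds))
    attr(out, "alpha_hat") <- af$alpha_hat
    attr(out, "r") <- af$r
  } else {
    if (adjust == "bonferroni") {
      b <- vapply(seq_len(m), function(i) pc_feature_bound(pmat[i, ], alpha / m),
                  integer(1))
    } else {
      # Holm over the disjoint row partition
      full <- rep(FALSE, m)
      b <- integer(m)
      repeat {
        h <- max(1L, m - sum(full))
        active <- which(!full)
        for (i in active) b[i] <- pc_feature_bound(pmat[i, ], alpha / h)
        newly <- active[b[active] == v]
        full[newly] <- TRUE
        if (length(newly) == 0L || all(full)) break
      }
      b[full] <- v
    }
    out <- data.frame(feature = feat, bound = b)
  }
  attr(out, "alpha") <- alpha
  attr(out, "method") <- method
  class(out) <- c("replicability_result", "data.frame")
  out
}
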