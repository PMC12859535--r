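#' Fit a focused true-discovery guarantee procedure
#'
#' Combines partial true discovery guarantee procedures on prespecified focus
#' sets into a single procedure giving simultaneous \eqn{1-\alpha} lower
#' confidence bounds on the number of true discoveries in *any* feature set:
#' with probability at least \eqn{1-\alpha}, every bound the fitted object
#' ever reports is below the true discovery count of its set. Focus sets get
#' the full power of their partial procedure (closed testing with Fisher
#' combination local tests by default), combined across sets by Holm
#' alpha-recycling or plain Bonferroni; post hoc query sets are served by
#' interpolation ([predict.focusct()]).
#'
#' Supply either per-feature p-values `p`, or a feature matrix `x` with
#' binary response `y` (two-sample t-test p-values are computed), or
#' ready-made bound `oracles`.
#'
#' @param focus the focus sets: a [focus_family()], or a named list of
#'   feature-id vectors.
#' @param p named per-feature p-values covering the universe.
#' @param x,y alternatively, an `n x w` feature matrix and binary response;
#'   p-values from [two_sample_t_pvalues()].
#' @param oracles alternatively, a list of `m` partial bound oracles
#'   ([oracle_fisher()], [oracle_table()]).
#' @param alpha simultaneous confidence level parameter, default `0.05`.
#' @param method `"holm"` (default) or `"bonferroni"` combination.
#' @param universe feature universe when `focus` is a plain list; defaults to
#'   `names(p)` / `colnames(x)` when available.
#' @param max_rounds optional early stop for the Holm sweeps.
#' @return An object of class `focusct` with components `family`, `alpha`,
#'   `method`, `state` (the converged [holm_partial_bounds()] /
#'   [bonferroni_partial_bounds()] state), `d_focus`, `oracles`, `p`.
#' @examples
#' fam <- focus_family(list(F1 = c("a", "b"), F2 = c("b", "d")),
#'                     universe = c("a", "b", "c", "d"))
#' p <- c(a = 0.2, b = 1e-6, d = 1e-5, c = 0.8)
#' fit <- focusct(fam, p = p, alpha = 0.05)
#' coef(fit)
#' predict(fit, list(post_hoc = c("b", "c")))
#' @export
focusct <- function(focus, p = NULL, x = NULL, y = NULL, oracles = NULL,
                    alpha = 0.05, method = c("holm", "bonferroni"),
                    universe = NULL, max_rounds = Inf) {
  method <- match.arg(method)
  if (length(alpha) != 1L || is.na(alpha) || alpha <= 0 || alpha >= 1)
    stop("'alpha' must lie in (0, 1)")
  if (!is.null(x)) {
    if (is.null(y)) stop("supply 'y' with 'x'")
    p <- two_sample_t_pvalues(x, y)
    if (is.null(names(p))) names(p) <- as.character(seq_along(p))
  }
  if (!inherits(focus, "focus_family")) {
    if (is.null(universe) && !is.null(p) && !is.null(names(p))) universe <- names(p)
    focus <- focus_family(focus, universe = universe)
  }
  if (is.null(oracles)) {
    if (is.null(p)) stop("supply 'p', 'x'/'y', or 'oracles'")
    oracles <- oracle_fisher(focus, p)
  } else if (length(oracles) != focus$m) {
    stop("'oracles' must have one entry per focus set")
  }
  state <- switch(method,
    holm = holm_partial_bounds(oracles, focus, alpha, max_rounds),
    bonferroni = bonferroni_partial_bounds(oracles, focus, alpha))
  structure(list(family = focus, alpha = alpha, method = method,
                 state = state, d_focus = state$bounds, oracles = oracles,
                 p = p, call = match.call()),
            class = "focusct")
}

#' @export
print.focusct <- function(x, ...) {
  cat("Focused true discovery guarantee procedure\n")
  cat(sprintf("  %d focus sets over %d features; alpha = %g, %s combination (h = %d)\n",
              x$family$m, x$family$w, x$alpha, x$method, x$state$h))
  sizes <- lengths(x$family$sets)
  cat(sprintf("  focus-set discoveries: %d of %d features bounded below\n",
              sum(x$d_focus), sum(sizes)))
  invisible(x)
}

#' Per-focus-set discovery bounds
#'
#' @param object a fitted [focusct()] object.
#' @param ... unused.
#' @return Named integer vector of \eqn{d_i(F_i)}.
#' @export
coef.focusct <- function(object, ...) {
  stats::setNames(object$d_focus, object$family$names)
}

#' @export
summary.focusct <- function(object, ...) {
  sizes <- lengths(object$family$sets)
  tab <- data.frame(set = object$family$names, size = sizes,
                    bound = object$d_focus, tdp = object$d_focus / sizes,
                    fully_rejected = object$state$fully_rejected,
                    row.names = NULL)
  out <- list(table = tab, alpha = object$alpha, method = object$method,
              h = object$state$h, rounds = object$state$rounds)
  class(out) <- "summary.focusct"
  out
}

#' @export
print.summary.focusct <- function(x, ...) {
  cat(sprintf("Focused TDP bounds at alpha = %g (%s, h = %d, %d sweep%s)\n",
              x$alpha, x$method, x$h, x$rounds, if (x$rounds == 1L) "" else "s"))
  print(x$table, digits = 3)
  invisible(x)
}

#' Simultaneous bounds for post hoc query sets
#'
#' Evaluates the fitted combined procedure on arbitrary feature sets.
#' `mode = "greedy"` (default) uses the greedy interpolation shortcut, valid
#' for any universe size; `mode = "exact"` computes the coherent
#' (fully interpolated) bound, requiring `w <=` `cap`.
#'
#' @param object a fitted [focusct()] object.
#' @param sets a list of query sets (feature ids or indices), a single
#'   vector, or `NULL` for the focus sets themselves.
#' @param mode `"greedy"` or `"exact"`.
#' @param cap exact-mode universe cap.
#' @param ... unused.
#' @return A `bound_table` data.frame: `set`, `size`, `bound`, `tdp`.
#' @export
predict.focusct <- function(object, sets = NULL, mode = c("greedy", "exact"),
                            cap = 16, ...) {
  mode <- match.arg(mode)
  fam <- object$family
  if (is.null(sets))
    sets <- stats::setNames(lapply(fam$sets, function(s) fam$universe[s]), fam$names)
  if (!is.list(sets)) sets <- list(query = sets)
  if (mode == "exact")
    return(coherent_bounds(fam, object$d_focus, queries = sets, cap = cap))
  idx <- lapply(sets, resolve_set, family = fam)
  b <- vapply(idx, function(s) as.integer(greedy_bound(fam, object$d_focus, s)),
              integer(1))
  sizes <- lengths(idx)
  nmv <- names(sets) %||%
    vapply(idx, function(s) paste0("{", paste(fam$universe[s], collapse = ","), "}"), "")
  out <- data.frame(set = nmv, size = sizes, bound = b,
                    tdp = ifelse(sizes > 0, b / sizes, 0), row.names = NULL)
  attr(out, "method") <- "greedy"
  class(out) <- c("bound_table", "data.frame")
  out
}

#' Plot per-focus-set TDP bounds
#'
#' @param x a fitted [focusct()] object.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.focusct <- function(x, ...) {
  sizes <- lengths(x$family$sets)
  graphics::barplot(x$d_focus / sizes, names.arg = x$family$names,
                    ylab = "TDP lower bound", ylim = c(0, 1), las = 2, ...)
  invisible(x)
}
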