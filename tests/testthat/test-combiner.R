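toy_family <- function() {
  focus_family(list(F1 = c("1", "2"), F2 = c("2", "4")),
               universe = as.character(1:4))
}

test_that("trivial procedure is supported on focus sets only", {
  fam <- toy_family()
  d0 <- trivial_bounds(fam, c(1, 2))
  expect_equal(d0(c("2", "4")), 2L)
  expect_equal(d0(c("1", "2")), 1L)
  expect_equal(d0(c("2", "3")), 0L)
  expect_equal(d0(character(0)), 0L)
  # duplicated focus set takes the larger bound
  fam2 <- focus_family(list(A = c("1", "2"), B = c("1", "2")),
                       universe = as.character(1:3))
  expect_equal(trivial_bounds(fam2, c(1, 2))(c("1", "2")), 2L)
})

test_that("one interpolation round reproduces the worked derivations", {
  fam <- toy_family()
  expect_equal(interpolate_once(fam, c(1, 2), c("2", "3")), 1L)
  expect_equal(interpolate_once(fam, c(1, 2), c("1", "3")), 0L)
  # S containing a fully rejected focus set keeps at least its bound
  fam3 <- focus_family(list(F1 = c("1", "2")), universe = as.character(1:3))
  expect_gte(interpolate_once(fam3, 2L, c("1", "2", "3")), 2L)
})

test_that("interpolation never decreases and converges to a coherent fixpoint", {
  set.seed(31)
  for (b in 1:30) {
    fam <- rand_family(w_range = 4:7)
    d <- vapply(lengths(fam$sets), function(s) sample(0:s, 1), integer(1))
    cb <- coherent_bounds(fam, d, history = TRUE)
    h <- attr(cb, "history")
    for (k in seq_len(length(h) - 1))
      expect_true(all(h[[k + 1]] >= h[[k]]))
    expect_identical(h[[length(h)]], h[[length(h) - 1]])
    # coherence: for S subset of T, d(S) <= d(T) <= d(S) + |T \ S|
    w <- fam$w
    subs <- lattice_sets(w)
    dv <- cb$bound
    for (ti in seq_along(subs)) {
      Tm <- ti - 1L
      for (e in subs[[ti]]) {
        Sm <- bitwAnd(Tm, bitwNot(bitwShiftL(1L, e - 1L)))
        expect_lte(dv[Sm + 1L], dv[ti])
        expect_lte(dv[ti], dv[Sm + 1L] + 1L)
      }
    }
  }
})

test_that("single focus set equal to the universe interpolates to the linear floor", {
  fam <- focus_family(list(all = as.character(1:5)), universe = as.character(1:5))
  b <- 3L
  cb <- coherent_bounds(fam, b)
  subs <- lattice_sets(5)
  expect_equal(cb$bound, vapply(subs, function(s) max(0L, b - (5L - length(s))), integer(1)))
})

test_that("greedy shortcut matches the toy example and stays conservative", {
  fam <- toy_family()
  expect_equal(greedy_bound(fam, c(1, 2), c("2", "3")), 1L)
  expect_equal(greedy_bound(fam, c(1, 2), "3"), 0L)
  set.seed(32)
  for (b in 1:200) {
    fam <- rand_family(w_range = 4:8)
    d <- vapply(lengths(fam$sets), function(s) sample(0:s, 1), integer(1))
    cb <- coherent_bounds(fam, d)
    subs <- lattice_sets(fam$w)
    g <- vapply(subs, function(s) greedy_bound(fam, d, s), integer(1))
    expect_true(all(g <= cb$bound))
    # picking F_i first is always available: greedy(F_i) >= d_i
    for (i in seq_len(fam$m))
      expect_gte(greedy_bound(fam, d, fam$sets[[i]]), d[i])
  }
})

test_that("fit object methods expose the combined procedure", {
  fam <- toy_family()
  p <- c("1" = 0.2, "2" = 1e-8, "4" = 1e-7, "3" = 0.9)
  fit <- focusct(fam, p = p, alpha = 0.05)
  expect_s3_class(fit, "focusct")
  expect_named(coef(fit), c("F1", "F2"))
  pred <- predict(fit, list(q1 = c("2", "3"), q2 = "3"))
  expect_equal(pred$size, c(2L, 1L))
  expect_true(all(pred$bound <= pred$size))
  expect_equal(pred$tdp, pred$bound / pred$size)
  # focus-set predictions never fall below the fitted per-focus bounds
  pf <- predict(fit)
  expect_true(all(pf$bound >= unname(coef(fit))))
  ex <- predict(fit, list(q1 = c("2", "3")), mode = "exact")
  expect_gte(ex$bound, pred$bound[1])
  s <- summary(fit)
  expect_equal(s$table$bound, unname(coef(fit)))
  expect_output(print(fit), "focus sets")
  # matrix + response interface
  set.seed(33)
  sim <- sim_two_group(n = 40, w = 8, prop_signal = 0.5, mu = 2, seed = 1)
  fit2 <- focusct(list(A = c("f1", "f2", "f3")), x = sim$x, y = sim$y)
  expect_equal(fit2$family$w, 8L)
  expect_error(focusct(fam, alpha = 0.05), "supply")
  expect_error(focusct(fam, p = p, alpha = 2), "alpha")
})
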