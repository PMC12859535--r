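test_that("brute-force partial bound handles the worked cases", {
  expect_equal(partial_bound_bruteforce(rep(1, 4), 0.05), 0L)
  # p = (1e-8, 1e-8, 0.5): only {3} survives as an intersection at 0.05
  expect_equal(partial_bound_bruteforce(c(1e-8, 1e-8, 0.5), 0.05), 2L)
  expect_equal(partial_bound_bruteforce(c(1e-8, 1e-8, 0.5), 0.05, integer(0)), 0L)
  expect_error(partial_bound_bruteforce(runif(25), 0.05), "cap")
})

test_that("suffix-scan fast path agrees with brute force on random instances", {
  set.seed(21)
  for (b in 1:400) {
    n <- sample(2:10, 1)
    p <- runif(n)^sample(c(1, 3, 6), 1)
    lev <- runif(1, 0.005, 0.2)
    sub <- sort(sample(n, sample(seq_len(n), 1)))
    expect_equal(fisher_subset_bound(p[sub], p[-sub], lev),
                 partial_bound_bruteforce(p, lev, sub))
  }
  # full-set queries
  for (b in 1:200) {
    n <- sample(2:12, 1)
    p <- runif(n)^sample(c(1, 4), 1)
    lev <- runif(1, 0.005, 0.2)
    expect_equal(partial_bound_fullset(p, lev),
                 partial_bound_bruteforce(p, lev))
  }
})

test_that("full-set fast path endpoints", {
  expect_equal(partial_bound_fullset(rep(1, 5), 0.05), 0L)
  expect_equal(partial_bound_fullset(rep(1e-12, 5), 0.05), 5L)
})

test_that("partial bounds are monotone in the level and capped by set size", {
  set.seed(22)
  for (b in 1:50) {
    n <- sample(3:10, 1)
    p <- runif(n)^2
    levels <- sort(runif(3, 0.001, 0.3))
    vals <- vapply(levels, function(l) partial_bound_fullset(p, l), integer(1))
    expect_true(all(diff(vals) >= 0))
    sub <- sort(sample(n, sample(seq_len(n), 1)))
    expect_lte(fisher_subset_bound(p[sub], p[-sub], levels[2]), length(sub))
    expect_lte(fisher_subset_bound(p[sub], p[-sub], levels[2]),
               partial_bound_fullset(p, levels[2]) + (n - length(sub)))
  }
})

test_that("Holm combination follows the sweep semantics", {
  fam3 <- focus_family(list(F1 = c("1", "2"), F2 = c("3", "4", "5"),
                            F3 = c("6", "7", "8")),
                       universe = as.character(1:8))
  # tabulated: at alpha/3 bounds (2,0,1); at alpha/2 (2,1,1); at alpha (2,1,2)
  oc <- oracle_table(fam3, rbind(c(2, 2, 2), c(0, 1, 1), c(1, 1, 2)),
                     levels = c(0.05 / 3, 0.05 / 2, 0.05))
  hs <- holm_partial_bounds(oc, fam3, 0.05)
  expect_equal(hs$h, 2L)
  expect_equal(hs$bounds, c(2L, 1L, 1L))
  expect_equal(hs$fully_rejected, c(TRUE, FALSE, FALSE))

  # m = 1: single pass at level alpha
  fam1 <- focus_family(list(F1 = c("1", "2")), universe = as.character(1:2))
  oc1 <- oracle_table(fam1, matrix(c(0, 1), 1), levels = c(0.025, 0.05))
  h1 <- holm_partial_bounds(oc1, fam1, 0.05)
  expect_equal(h1$h, 1L)
  expect_equal(h1$bounds, 1L)
  expect_equal(h1$rounds, 1L)

  # nothing fully rejected: fixpoint after one sweep, equals Bonferroni
  set.seed(23)
  for (b in 1:30) {
    ins <- rand_fisher_instance()
    hs <- holm_partial_bounds(ins$oracles, ins$fam, 0.05)
    bf <- bonferroni_partial_bounds(ins$oracles, ins$fam, 0.05)
    if (!any(hs$fully_rejected)) {
      expect_equal(hs$bounds, bf$bounds)
      expect_equal(hs$rounds, 1L)
    }
    expect_true(all(hs$bounds >= bf$bounds))  # Holm never worse
  }
})

test_that("early-stopped Holm still dominates Bonferroni", {
  set.seed(24)
  fam <- focus_family(list(F1 = c("1", "2"), F2 = c("3", "4"), F3 = c("5", "6")),
                      universe = as.character(1:6))
  p <- c(1e-9, 1e-9, 1e-4, 2e-4, 0.2, 0.9)
  names(p) <- fam$universe
  oc <- oracle_fisher(fam, p)
  h1 <- holm_partial_bounds(oc, fam, 0.05, max_rounds = 1)
  hfull <- holm_partial_bounds(oc, fam, 0.05)
  bf <- bonferroni_partial_bounds(oc, fam, 0.05)
  expect_true(all(h1$bounds >= bf$bounds))
  expect_true(all(hfull$bounds >= h1$bounds))
})

test_that("partial closed testing keeps its coverage under the null", {
  set.seed(25)
  reps <- 2000
  viol <- mean(replicate(reps, partial_bound_fullset(runif(8), 0.05) > 0))
  expect_lte(viol, mc_limit(0.05, reps))
})
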