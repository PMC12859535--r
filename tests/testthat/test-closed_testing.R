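toy_setup <- function() {
  fam <- focus_family(list(F1 = c("1", "2"), F2 = c("2", "4")),
                      universe = as.character(1:4))
  list(fam = fam, oc = oracle_table(fam, c(1, 2)))
}

test_that("m_S counts intersecting focus sets", {
  fam <- toy_setup()$fam
  expect_equal(m_S(fam, "2"), 2L)
  expect_equal(m_S(fam, "3"), 0L)
  expect_equal(m_S(fam, as.character(1:4)), 2L)
  expect_equal(m_S(fam, character(0)), 0L)
})

test_that("local test variants follow their defining conditions", {
  ts <- toy_setup()
  # phi_tilde at S = {2,3}: d2 = 2 > |F2 \ S| = 1
  expect_equal(ct_local_test(ts$fam, ts$oc, 0.05, c("2", "3"), "phi_tilde"), 1L)
  # no intersecting focus set: never rejected
  for (v in c("phi", "phi_tilde"))
    expect_equal(ct_local_test(ts$fam, ts$oc, 0.05, "3", v), 0L)
  hs <- holm_partial_bounds(ts$oc, ts$fam, 0.05)
  expect_equal(ct_local_test(ts$fam, ts$oc, 0.05, "3", "phi_bar", holm = hs), 0L)
  expect_error(ct_local_test(ts$fam, ts$oc, 0.05, "2", "phi_bar"), "holm_state")
})

test_that("local test shortcut ordering and union equality hold", {
  set.seed(41)
  for (b in 1:60) {
    ins <- if (b %% 3 == 0) {
      fam <- rand_family(w_range = 4:7)
      list(fam = fam, oracles = rand_table_oracle(fam))
    } else rand_fisher_instance(w_range = 4:7)
    fam <- ins$fam; oc <- ins$oracles
    hs <- holm_partial_bounds(oc, fam, 0.05)
    subs <- lattice_sets(fam$w)
    pick <- sample(seq_along(subs), min(8, length(subs)))
    for (si in pick) {
      S <- subs[[si]]
      pb <- ct_local_test(fam, oc, 0.05, S, "phi_bar", holm = hs)
      pt <- ct_local_test(fam, oc, 0.05, S, "phi_tilde")
      pp <- ct_local_test(fam, oc, 0.05, S, "phi")
      expect_lte(pb, pt)
      expect_lte(pt, pp)
    }
    # unions of focus sets cutting none partially: phi and phi_tilde coincide
    un <- closed_union(fam)
    expect_equal(ct_local_test(fam, oc, 0.05, un, "phi_tilde"),
                 ct_local_test(fam, oc, 0.05, un, "phi"))
  }
})

test_that("effective local test psi is monotone and bounds are ordered", {
  set.seed(42)
  for (b in 1:20) {
    ins <- rand_fisher_instance(w_range = 4:6, m_range = 1:3)
    fam <- ins$fam; oc <- ins$oracles
    hs <- holm_partial_bounds(oc, fam, 0.05)
    latp <- focusct:::ct_lattice(fam, oc, 0.05, "phi")
    latt <- focusct:::ct_lattice(fam, oc, 0.05, "phi_tilde")
    latb <- focusct:::ct_lattice(fam, oc, 0.05, "phi_bar", holm = hs)
    w <- fam$w
    for (Jp in seq_along(latp$psi)) {
      J <- Jp - 1L
      for (bbit in 0:(w - 1L)) {
        if (bitwAnd(J, bitwShiftL(1L, bbit)) != 0L) next
        Jext <- bitwOr(J, bitwShiftL(1L, bbit))
        expect_lte(latp$psi[Jp], latp$psi[Jext + 1L])
      }
    }
    # psi_bar equals phi_bar (monotone local test needs no superset search)
    expect_equal(latb$psi, latb$phi)
    # bound ordering across the shortcut chain, and direct phi_bar route
    subs <- lattice_sets(w)
    dphi <- lengths(subs) - pmax(0L, latp$g[seq_along(subs)])
    dtil <- lengths(subs) - pmax(0L, latt$g[seq_along(subs)])
    dbar <- lengths(subs) - pmax(0L, latb$g[seq_along(subs)])
    expect_true(all(dphi >= dtil))
    expect_true(all(dtil >= dbar))
    direct <- vapply(subs, function(s) ct_bound_phibar(fam, hs, s), integer(1))
    expect_equal(dbar, direct)
  }
})

test_that("interpolation fixpoint is a conservative shortcut to closed testing", {
  # The coherent interpolated procedure never exceeds the Holm-shortcut
  # closed testing bound, with equality for disjoint focus families; for
  # overlapping families closed testing can be strictly sharper, since
  # pairwise interpolation cannot express joint covering arguments across
  # three or more mutually overlapping focus sets.
  set.seed(43)
  for (b in 1:80) {
    fam <- rand_family(w_range = 4:7, disjoint = b %% 2 == 0)
    d <- vapply(lengths(fam$sets), function(s) sample(0:s, 1), integer(1))
    hs <- structure(list(h = fam$m, bounds = d,
                         fully_rejected = d == lengths(fam$sets),
                         rounds = 1L, alpha = 0.05, method = "bonferroni",
                         names = fam$names), class = "holm_state")
    cb <- coherent_bounds(fam, d)
    dbar <- vapply(lattice_sets(fam$w),
                   function(s) ct_bound_phibar(fam, hs, s), integer(1))
    expect_true(all(cb$bound <= dbar))
    if (b %% 2 == 0) expect_equal(cb$bound, dbar)  # disjoint: exact
  }
  # the gap is real: three mutually overlapping triples + a pair
  fam <- focus_family(list(F1 = c("1", "2", "4"), F2 = c("1", "2", "3"),
                           F3 = c("1", "3", "4"), F4 = c("2", "3")),
                      universe = as.character(1:4))
  d <- c(2L, 2L, 2L, 1L)
  hs <- structure(list(h = 4L, bounds = d, fully_rejected = rep(FALSE, 4),
                       rounds = 1L, alpha = 0.05, method = "bonferroni",
                       names = fam$names), class = "holm_state")
  expect_equal(coherent_bounds(fam, d, queries = list(as.character(1:4)))$bound, 2L)
  expect_equal(ct_bound_phibar(fam, hs, as.character(1:4)), 3L)
})

test_that("the explicit local test controls type I error on a true null set", {
  set.seed(44)
  reps <- 2000
  fam <- focus_family(list(F1 = c("1", "2", "3"), F2 = c("3", "4", "5")),
                      universe = as.character(1:6))
  S <- c("1", "3", "4")  # all-null under the simulation
  rej <- replicate(reps, {
    p <- runif(6); names(p) <- fam$universe
    ct_local_test(fam, oracle_fisher(fam, p), 0.05, S, "phi")
  })
  expect_lte(mean(rej), mc_limit(0.05, reps))
})
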