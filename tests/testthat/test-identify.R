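# Independent enumeration oracle: plain dmultinom loop, no shared code with
# the vectorized implementation.
oracle_plurality <- function(p, n, tie_credit = TRUE) {
  tot <- 0
  for (n1 in 0:n) {
    for (n2 in 0:(n - n1)) {
      n3 <- n - n1 - n2
      pr <- dmultinom(c(n1, n2, n3), prob = p)
      m <- max(n1, n2, n3)
      if (n1 == m) {
        k <- sum(c(n1, n2, n3) == m)
        if (k == 1) tot <- tot + pr else if (tie_credit) tot <- tot + pr / k
      }
    }
  }
  tot
}

test_that("majority vote picks the plurality class and honors tie rules", {
  v <- majority_vote(c("DA", "DA", "NE"))
  expect_equal(v$winner, "DA")
  expect_false(v$tie)
  expect_equal(v$n_signals, 3)
  expect_equal(sum(tidy(v)$count), 3)

  expect_error(majority_vote(c("DA", "NE"), tie_rule = "error"),
    class = "nanosig_tie_error")
  expect_equal(majority_vote(c("NE", "DA"), tie_rule = "lexicographic")$winner,
    "DA")
  r1 <- majority_vote(c("DA", "NE"), tie_rule = "random", seed = 5)
  r2 <- majority_vote(c("DA", "NE"), tie_rule = "random", seed = 5)
  expect_identical(r1$winner, r2$winner)
  expect_true(r1$tie)
  expect_error(majority_vote(character()), class = "nanosig_domain_error")
})

test_that("exact plurality accuracy matches an independent enumeration oracle", {
  cases <- list(
    list(p = c(0.5, 0.3, 0.2), n = 7),
    list(p = c(0.5, 0.3, 0.2), n = 20),
    list(p = c(0.45, 0.35, 0.2), n = 13),
    list(p = c(0.7, 0.2, 0.1), n = 9)
  )
  for (cs in cases) {
    for (tc in c(TRUE, FALSE)) {
      expect_equal(plurality_accuracy_exact(cs$p, cs$n, tie_credit = tc),
        oracle_plurality(cs$p, cs$n, tie_credit = tc), tolerance = 1e-12)
    }
  }
  expect_equal(plurality_accuracy_exact(c(1, 0, 0), 15), 1)
  expect_equal(plurality_accuracy_exact(rep(1 / 3, 3), 11, tie_credit = TRUE),
    1 / 3, tolerance = 1e-12)
  expect_error(plurality_accuracy_exact(c(0.5, 0.5, 0.5), 10),
    class = "nanosig_domain_error")
})

test_that("Monte-Carlo vote accuracy agrees with exact enumeration", {
  p <- c(0.5, 0.3, 0.2)
  for (n in c(20, 40, 110)) {
    mc <- plurality_accuracy_mc(p, n, reps = 2e4, seed = 11)
    expect_lt(abs(mc$estimate - plurality_accuracy_exact(p, n)), 3 * mc$se)
  }
  exact1 <- plurality_accuracy_mc(c(1, 0, 0), 10, reps = 1000, seed = 1)
  expect_equal(exact1$estimate, 1)
  m1 <- plurality_accuracy_mc(p, 20, reps = 1000, seed = 2)
  m2 <- plurality_accuracy_mc(p, 20, reps = 1000, seed = 2)
  expect_identical(m1$estimate, m2$estimate)
})

test_that("vote accuracy grows with accumulated signals", {
  p <- c(0.5, 0.3, 0.2)
  expect_gt(plurality_accuracy_exact(p, 110), plurality_accuracy_exact(p, 20))
  expect_gt(plurality_accuracy_exact(p, 400), 0.999)
})

test_that("signals_needed finds the smallest sufficient count", {
  p <- c(0.5, 0.3, 0.2)
  n99 <- signals_needed(p, 0.99)
  expect_lte(n99, 110)
  expect_gte(plurality_accuracy_exact(p, n99), 0.99)
  expect_lt(plurality_accuracy_exact(p, n99 - 1), 0.99)

  n_easy <- signals_needed(c(0.9, 0.05, 0.05), 0.9)
  expect_lte(n_easy, 5)
  expect_equal(signals_needed(c(0.5, 0.3, 0.2), 0.5), 1)
  expect_error(signals_needed(c(0.4, 0.4, 0.2), 0.9),
    class = "nanosig_domain_error")
})

test_that("mixture estimates normalize counts with simultaneous CIs", {
  m <- estimate_mixture(c(DA = 1829, NE = 740, `5HT` = 137))
  comp <- tidy(m)
  expect_equal(comp$ratio, c(0.676, 0.273, 0.051), tolerance = 0.001)
  expect_equal(sum(comp$ratio), 1, tolerance = 1e-9)
  expect_true(all(comp$conf_low <= comp$ratio & comp$ratio <= comp$conf_high))
  expect_equal(m$winner, "DA")
  expect_equal(m$n_signals, 2706)

  design <- estimate_mixture(c(DA = 100, NE = 200, `5HT` = 400))
  expect_equal(tidy(design)$ratio, c(1, 2, 4) / 7, tolerance = 1e-9)

  solo <- estimate_mixture(rep("NE", 25), classes = nanosig_classes())
  expect_equal(tidy(solo)$ratio, c(0, 1, 0))
  expect_error(estimate_mixture(character()), class = "nanosig_domain_error")
})

test_that("ternary coordinates map the simplex affinely onto the triangle", {
  expect_equal(unlist(ternary_coordinates(c(1, 0, 0))), c(x = 0, y = 0))
  expect_equal(unlist(ternary_coordinates(c(0, 1, 0))), c(x = 1, y = 0))
  expect_equal(unlist(ternary_coordinates(c(0, 0, 1))),
    c(x = 0.5, y = sqrt(3) / 2))
  expect_equal(unlist(ternary_coordinates(rep(1 / 3, 3))),
    c(x = 0.5, y = sqrt(3) / 6))

  a <- c(0.6, 0.3, 0.1)
  b <- c(0.1, 0.2, 0.7)
  mid <- ternary_coordinates((a + b) / 2)
  pa <- ternary_coordinates(a)
  pb <- ternary_coordinates(b)
  expect_equal(mid$x, (pa$x + pb$x) / 2)
  expect_equal(mid$y, (pa$y + pb$y) / 2)

  expect_error(ternary_coordinates(c(0.5, 0.5, 0.5)),
    class = "nanosig_domain_error")
})
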