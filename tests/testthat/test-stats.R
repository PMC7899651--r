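test_that("fisherExact2x2 reproduces closed-form tables", {
  expect_equal(fisherExact2x2(3, 7, 3, 7), 1)
  expect_equal(fisherExact2x2(5, 0, 0, 5), 2 / choose(10, 5), tolerance = 1e-12)
  expect_equal(fisherExact2x2(1, 0, 0, 0), 1)
  expect_equal(fisherExact2x2(10, 0, 0, 10), 2 / choose(20, 10),
               tolerance = 1e-12)
  expect_error(fisherExact2x2(0, 0, 0, 0), "all-zero")
  expect_error(fisherExact2x2(-1, 2, 3, 4), "nonnegative")
})

test_that("fisherExact2x2 agrees with enumeration and fisher.test", {
  set.seed(7)
  for (rep in 1:200) {
    tab <- sample(0:12, 4, replace = TRUE)
    if (sum(tab) == 0) next
    p <- fisherExact2x2(tab[1], tab[2], tab[3], tab[4])
    expect_equal(p, fisherOracle(tab[1], tab[2], tab[3], tab[4]),
                 tolerance = 1e-12)
    expect_equal(p, fisher.test(matrix(tab, 2, byrow = TRUE))$p.value,
                 tolerance = 1e-7)
  }
})

test_that("p is invariant to transposition and row+column swaps", {
  set.seed(11)
  for (rep in 1:50) {
    t4 <- sample(0:15, 4, replace = TRUE)
    if (sum(t4) == 0) next
    a <- t4[1]; b <- t4[2]; c <- t4[3]; d <- t4[4]
    p <- fisherExact2x2(a, b, c, d)
    expect_equal(fisherExact2x2(a, c, b, d), p, tolerance = 1e-12) # transpose
    expect_equal(fisherExact2x2(d, c, b, a), p, tolerance = 1e-12) # both swaps
  }
})

test_that("exact test is conservative under the null", {
  set.seed(1234)
  n <- 2000
  rej <- 0L
  for (i in seq_len(n)) {
    x <- rbinom(2L, 25L, 0.3)
    if (fisherExact2x2(x[1], 25 - x[1], x[2], 25 - x[2]) < 0.05)
      rej <- rej + 1L
  }
  rate <- rej / n
  expect_lte(rate, 0.05 + 3 * sqrt(0.05 * 0.95 / n))
})

test_that("pairedT matches the closed form and a density-integration oracle", {
  r <- pairedT(baseline = c(0, 0, 0), post = c(2, 4, 6))
  expect_equal(r$t, 4 / (2 / sqrt(3)), tolerance = 1e-12)
  expect_equal(r$t, 3.4641016, tolerance = 1e-6)
  expect_equal(r$df, 2L)
  # two-sided p from high-resolution numerical integration of the t density
  tdens <- function(x, v) gamma((v + 1) / 2) / (sqrt(v * pi) * gamma(v / 2)) *
    (1 + x^2 / v)^(-(v + 1) / 2)
  pOracle <- 2 * integrate(tdens, r$t, Inf, v = 2, rel.tol = 1e-12)$value
  expect_equal(r$p, pOracle, tolerance = 1e-9)

  # symmetry: alternating differences give t = 0, p = 1
  r2 <- pairedT(c(0, 0, 0, 0), c(1, -1, 1, -1))
  expect_equal(r2$t, 0)
  expect_equal(r2$p, 1)

  # constant differences are degenerate: flagged, no p
  r3 <- pairedT(c(1, 2, 3, 4), c(2, 3, 4, 5))
  expect_true(r3$degenerate)
  expect_true(is.na(r3$p))

  expect_error(pairedT(1, c(1, 2)), "pair")
  expect_error(pairedT(1, 2), "at least 2")
})

test_that("pairedT is invariant to shifting both members of every pair", {
  set.seed(5)
  b <- rnorm(12); p <- rnorm(12, 0.8)
  r1 <- pairedT(b, p)
  r2 <- pairedT(b + 3.7, p + 3.7)
  expect_equal(r1$t, r2$t)
  expect_equal(r1$p, r2$p)
  # cross-check against the reference implementation
  expect_equal(r1$p, t.test(p, b, paired = TRUE)$p.value, tolerance = 1e-12)
})

test_that("summarizeGroups tabulates proportions and pairwise exact tests", {
  mkCalls <- function(ids, resp) data.frame(
    unit_id = ids, event_label = "CS_ON", responsive = resp, excluded = FALSE)
  ids <- sprintf("u%02d", 1:20)
  gm <- data.frame(unit_id = ids, group = rep(c("g1", "g2"), each = 10))

  # 4/10 vs 4/10: identical percentages, p = 1
  res <- summarizeGroups(mkCalls(ids, rep(c(rep(TRUE, 4), rep(FALSE, 6)), 2)), gm)
  expect_equal(res$summary$percent, c(40, 40))
  expect_equal(res$comparisons$p_two_sided, 1)

  # 10/10 vs 0/10: the extreme table
  res2 <- summarizeGroups(mkCalls(ids, rep(c(TRUE, FALSE), each = 10)), gm)
  expect_equal(res2$comparisons$p_two_sided, 2 / choose(20, 10),
               tolerance = 1e-12)
  expect_equal(res2$comparisons[, c("a", "b", "c", "d")],
               data.frame(a = 10L, b = 0L, c = 0L, d = 10L),
               ignore_attr = TRUE)

  # single group: percentages only, no tests
  res3 <- summarizeGroups(mkCalls(ids[1:10], rep(c(TRUE, FALSE), 5)),
                          gm[1:10, ])
  expect_null(res3$comparisons)
  expect_equal(res3$summary$percent, 50)

  # excluded units never enter the denominators
  calls <- mkCalls(ids, rep(TRUE, 20))
  calls$excluded[1:5] <- TRUE
  calls$responsive[1:5] <- NA
  res4 <- summarizeGroups(calls, gm)
  expect_equal(res4$summary$n_total[res4$summary$group == "g1"], 5L)

  expect_error(summarizeGroups(mkCalls(ids, rep(NA, 20)), gm), "no classified")
})

test_that("baselineVsResponse pairs mean baseline z with mean response z", {
  profs <- lapply(1:6, function(i)
    profileFromZ(zResp = rep(i / 2, 5), zBase = rep(0, 10)))
  r <- baselineVsResponse(profs)
  expect_equal(r$pairs$baseline, rep(0, 6))
  expect_equal(r$pairs$response, (1:6) / 2)
  expect_false(r$degenerate)
  expect_lt(r$p, 0.01)
})
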