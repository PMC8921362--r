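# Exact small-sample behaviour of the nonparametric tests.

test_that("Mann-Whitney matches enumeration and known exact values", {
  r <- mannWhitneyU(c(1, 2), c(3, 4))
  expect_equal(r$U, 0)
  expect_equal(r$p, 2 / 6)
  expect_equal(mannWhitneyU(c(1, 2, 3), c(1, 2, 3))$p, 1)

  # complete separation at the published group sizes: p = 2 / C(19,9)
  rc <- loadRCTable()
  par <- rc$rc_percent[rc$kind == "whole-parenchyma" & rc$iterations == 72 &
                       rc$tbr == "infinity"]
  cor <- rc$rc_percent[rc$kind == "cortex-only" & rc$iterations == 72 &
                       rc$tbr == "infinity"]
  r2 <- mannWhitneyU(par, cor)
  expect_equal(r2$U, 0)
  expect_equal(r2$p, 2 / choose(19, 9))
  expect_lt(r2$p, 0.01)
})

test_that("exact Mann-Whitney equals brute force for all sizes <= 8", {
  set.seed(31)
  for (na in 2:4) for (nb in 2:4) {
    a <- sample(1:6, na, replace = TRUE)   # ties likely
    b <- sample(1:6, nb, replace = TRUE)
    expect_equal(mannWhitneyU(a, b)$p, bruteMW(a, b),
                 info = sprintf("na=%d nb=%d", na, nb))
  }
  # tie-free case cross-checked against the base distribution machinery
  a <- c(1.2, 3.4, 5.1, 7.9); b <- c(2.2, 4.4, 6.1)
  expect_equal(mannWhitneyU(a, b)$p,
               wilcox.test(a, b, exact = TRUE)$p.value)
})

test_that("Wilcoxon signed-rank matches enumeration and known exact values", {
  r <- wilcoxonSignedRank(c(1, 2, 3))
  expect_equal(r$W, 0)
  expect_equal(r$p, 2 / 8)
  expect_equal(wilcoxonSignedRank(c(-1, 1))$p, 1)
  expect_error(wilcoxonSignedRank(c(0, 0)), "zero")

  # the 19 kidney 5:1-minus-infinity differences (72 it) are all positive
  rc <- loadRCTable()
  kid <- rc[rc$kind != "ellipsoid" & rc$iterations == 72, ]
  w <- reshape(kid[, c("id", "tbr", "rc_percent")], idvar = "id",
               timevar = "tbr", direction = "wide")
  d <- w[["rc_percent.5:1"]] - w[["rc_percent.infinity"]]
  expect_true(all(d > 0))
  r2 <- wilcoxonSignedRank(d)
  expect_equal(r2$W, 0)
  expect_equal(r2$p, 2 / 2^19)
  expect_lt(r2$p, 0.01)
})

test_that("exact Wilcoxon equals brute force for all sizes <= 8", {
  set.seed(41)
  for (n in c(3, 5, 8)) {
    d <- sample(c(-4:-1, 1:4), n, replace = TRUE)  # ties likely, no zeros
    expect_equal(wilcoxonSignedRank(d)$p, bruteWilcoxon(d),
                 info = sprintf("n=%d", n))
  }
  # tie-free cross-check against the base signed-rank distribution
  d <- c(1.3, -2.4, 3.1, 4.9, -0.7, 6.2)
  expect_equal(wilcoxonSignedRank(d)$p,
               wilcox.test(d, exact = TRUE)$p.value)
})

test_that("Levene test flags the published variance contrast", {
  expect_equal(leveneVarTest(c(1, 2, 3), c(1, 2, 3))$statistic, 0)
  rc <- loadRCTable()
  cor <- rc$rc_percent[rc$kind == "cortex-only" & rc$iterations == 72 &
                       rc$tbr == "10:1"]
  par <- rc$rc_percent[rc$kind == "whole-parenchyma" & rc$iterations == 72 &
                       rc$tbr == "10:1"]
  r <- leveneVarTest(cor, par)
  expect_lt(r$p, 0.01)
  # cross-check against the established implementation
  cr <- car::leveneTest(c(cor, par),
                        factor(rep(c("c", "p"), c(length(cor), length(par)))),
                        center = mean)
  expect_equal(r$statistic, cr[["F value"]][1])
  expect_equal(r$p, cr[["Pr(>F)"]][1])
  # scale property: inflating one group's spread raises the statistic
  set.seed(5)
  a <- rnorm(12)
  r2 <- leveneVarTest(a, 10 * a)
  expect_gt(r2$statistic, 0)
  expect_lt(r2$p, 0.05)
})
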