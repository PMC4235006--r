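test_that("modulation index matches its definition and symmetry", {
  expect_equal(modulationIndex(100, 100), 0)
  expect_equal(modulationIndex(50, 150), 0.5)
  expect_equal(modulationIndex(40, 0), -1)
  expect_true(is.na(modulationIndex(0, 0)))
  set.seed(1)
  a <- runif(50, 0, 10); b <- runif(50, 0, 10)
  expect_equal(modulationIndex(a, b), -modulationIndex(b, a))
  expect_true(all(abs(modulationIndex(a, b)) <= 1))
})

test_that("20% change classification is boundary-inclusive", {
  expect_equal(classifyChange(100, 119), "none")
  expect_equal(classifyChange(100, 121), "increase")
  expect_equal(classifyChange(100, 80), "decrease")
  expect_equal(classifyChange(100, 120), "increase")
  expect_equal(classifyChange(0, 5), "increase")
  expect_equal(classifyChange(0, 0), "none")
})

test_that("KS test matches a brute-force ECDF sweep", {
  expect_equal(ksTwoSample(1:5, 1:5)$statistic, 0)
  expect_equal(ksTwoSample(c(1, 2, 3), c(4, 5, 6))$statistic, 1)

  ksOracle <- function(x, y) {
    pts <- sort(unique(c(x, y)))
    max(abs(ecdf(x)(pts) - ecdf(y)(pts)))
  }
  expect_equal(ksTwoSample(c(1, 3, 5), c(2, 4, 6))$statistic,
               ksOracle(c(1, 3, 5), c(2, 4, 6)))
  set.seed(7)
  for (i in 1:25) {
    x <- rnorm(sample(3:12, 1)); y <- rnorm(sample(3:12, 1), sd = 2)
    r <- ksTwoSample(x, y)
    expect_equal(r$statistic, ksOracle(x, y))
    expect_true(r$p > 0 && r$p <= 1)
  }
  expect_error(ksTwoSample(numeric(0), 1:3), "non-empty")
})

test_that("Friedman test matches the rank-sum formula", {
  const <- matrix(5, nrow = 6, ncol = 3)
  expect_equal(friedmanTest(const)$statistic, 0)

  ## 10 subjects, strictly increasing conditions: ranks 1,2,3 every row
  m <- t(replicate(10, c(1, 2, 3) + runif(3, 0, 0.1)))
  m <- m[, order(colMeans(m))]
  r <- friedmanTest(m)
  n <- 10; k <- 3; R <- c(1, 2, 3) * n
  chi2 <- 12 / (n * k * (k + 1)) * sum(R^2) - 3 * n * (k + 1)
  expect_equal(unname(r$statistic), chi2)   # 20
  expect_equal(r$df, 2)

  ## permuting condition columns leaves the statistic unchanged
  set.seed(3)
  mm <- matrix(rnorm(30), 10, 3)
  expect_equal(friedmanTest(mm[, c(3, 1, 2)])$statistic,
               friedmanTest(mm)$statistic)
  expect_error(friedmanTest(cbind(1:4, 2:5)), "k >= 3")
  expect_error(friedmanTest(cbind(c(1, NA, 3), 1:3, 2:4)), "complete")
})

test_that("Wilcoxon signed-rank p-values are exact for small n", {
  ## n = 5, all positive differences: 2/32 by sign enumeration
  x <- c(1, 2, 3, 4, 5); y <- rep(0, 5)
  r <- wilcoxonSignedRank(x, y)
  expect_equal(r$p, 0.0625)
  expect_true(r$exact)
  expect_equal(wilcoxonSignedRank(y, x)$p, r$p)  # swap symmetry
  expect_error(wilcoxonSignedRank(x, x), "zero")

  ## exact path agrees with explicit enumeration of sign assignments
  set.seed(11)
  for (i in 1:10) {
    d <- round(runif(6, 0.5, 9), 3) * sample(c(-1, 1), 6, replace = TRUE)
    r <- wilcoxonSignedRank(d, rep(0, 6))
    rk <- rank(abs(d))
    W <- sum(rk[d > 0])
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), 6)))
    Wall <- signs %*% rk
    pEnum <- mean(abs(Wall - sum(rk) / 2) >= abs(W - sum(rk) / 2))
    expect_equal(r$p, pEnum)
  }
})

test_that("Sidak correction reproduces the printed per-test alpha", {
  expect_equal(round(sidakAlpha(0.05, 2), 4), 0.0253)
  expect_equal(sidakAlpha(0.05, 1), 0.05)
  expect_equal(sidakAlpha(0.05, 3), 1 - (1 - 0.05)^(1 / 3))
  expect_error(sidakAlpha(0.05, 0), ">= 1")
  expect_error(sidakAlpha(1.2, 2), "in \\(0, 1\\)")
})

test_that("Spearman correlation equals Pearson on ranks", {
  expect_equal(spearmanCorrelation(1:8, (1:8)^2)$statistic, 1)
  expect_equal(spearmanCorrelation(1:8, -(1:8)^3)$statistic, -1)
  x <- c(1, 2, 3, 4); y <- c(2, 1, 4, 3)
  expect_equal(spearmanCorrelation(x, y)$statistic,
               cor(rank(x), rank(y)))
  expect_error(spearmanCorrelation(1:5, rep(2, 5)), "zero")
})

test_that("Fisher r x 2 equals closed-form and enumeration oracles", {
  ## only one table has these margins
  expect_equal(fisherExactRx2(rbind(c(3, 0), c(2, 0)))$p, 1)

  ## 2 x 2: hypergeometric probability-ordering closed form
  hyper2x2 <- function(tab) {
    m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
    xs <- max(0, k - n):min(k, m)
    ps <- dhyper(xs, m, n, k)
    sum(ps[ps <= dhyper(tab[1, 1], m, n, k) * (1 + 1e-7)])
  }
  set.seed(13)
  for (i in 1:50) {
    tab <- matrix(rpois(4, 4), 2, 2)
    if (any(colSums(tab) == 0)) next
    expect_equal(fisherExactRx2(tab)$p, hyper2x2(tab), tolerance = 1e-8)
  }

  ## r x 2: exhaustive enumeration over all margin-consistent tables
  enumP <- function(tab) {
    rs <- rowSums(tab); c1 <- sum(tab[, 1])
    prob <- function(firstCol) {
      t2 <- cbind(firstCol, rs - firstCol)
      exp(sum(lgamma(rs + 1)) + lgamma(c1 + 1) +
            lgamma(sum(rs) - c1 + 1) - lgamma(sum(rs) + 1) -
            sum(lgamma(t2 + 1)))
    }
    grids <- do.call(expand.grid, lapply(rs, function(r) 0:r))
    ok <- rowSums(grids) == c1
    ps <- apply(grids[ok, , drop = FALSE], 1, prob)
    pObs <- prob(tab[, 1])
    sum(ps[ps <= pObs * (1 + 1e-7)])
  }
  expect_equal(fisherExactRx2(rbind(c(2, 0), c(0, 2), c(1, 1)))$p,
               enumP(rbind(c(2, 0), c(0, 2), c(1, 1))), tolerance = 1e-8)
  set.seed(17)
  for (i in 1:20) {
    r <- sample(c(3, 5), 1)
    tab <- matrix(rpois(2 * r, 1.2), r, 2)
    if (sum(tab) > 20 || any(colSums(tab) == 0)) next
    expect_equal(fisherExactRx2(tab)$p, enumP(tab), tolerance = 1e-7)
  }
  expect_error(fisherExactRx2(matrix(1, 2, 3)), "r x 2")
  expect_error(fisherExactRx2(rbind(c(1.5, 1), c(1, 1))), "integers")
})

test_that("bootstrap median CI is seeded and covers", {
  same <- bootstrapMedianCI(rep(4, 10), seed = 2)
  expect_equal(same$lo, 4)
  expect_equal(same$hi, 4)

  x <- rnorm(40)
  a <- bootstrapMedianCI(x, nBoot = 500, seed = 3)
  b <- bootstrapMedianCI(x, nBoot = 500, seed = 3)
  expect_identical(a, b)
  expect_true(a$lo <= a$median && a$median <= a$hi)

  ## coverage of the true median on large symmetric samples
  set.seed(29)
  hits <- vapply(1:200, function(i) {
    x <- rnorm(101)
    ci <- bootstrapMedianCI(x, nBoot = 400, seed = i)
    ci$lo <= 0 && 0 <= ci$hi
  }, logical(1))
  expect_gte(mean(hits), 0.93)
})
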