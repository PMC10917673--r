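test_that("null data produce no significant clusters", {
  x <- matrix(0, 10, 30)
  r <- clusterTest(x, nSurrogates = 101, seed = 1)
  expect_equal(nrow(r$clusters), 0L)
})

test_that("a planted contiguous shift is recovered with high power", {
  set.seed(4)
  hits <- replicate(100, {
    x <- matrix(rnorm(30 * 40), 30, 40)
    x[, 15:25] <- x[, 15:25] + 1
    r <- clusterTest(x, nSurrogates = 201, seed = sample.int(1e6, 1))
    sig <- r$clusters[r$clusters$significant, , drop = FALSE]
    nrow(sig) > 0 && any(r$labels[15:25] %in% sig$id)
  })
  expect_gte(mean(hits), 0.9)
})

test_that("the permutation test is calibrated at alpha = 0.05", {
  set.seed(1)
  hits <- replicate(200, {
    x <- matrix(rnorm(20 * 40), 20, 40)
    any(clusterTest(x, nSurrogates = 201,
                    seed = sample.int(1e6, 1))$clusters$significant)
  })
  expect_gte(mean(hits), 0.02); expect_lte(mean(hits), 0.08)
})

test_that("two-sample schemes detect group differences and respect exchangeability", {
  set.seed(2)
  x <- matrix(rnorm(15 * 50), 15, 50); x[, 20:30] <- x[, 20:30] + 1.2
  y <- matrix(rnorm(15 * 50), 15, 50)
  r <- clusterTest(x, y, test = "two_sample", scheme = "label_reassign",
                   nSurrogates = 201, seed = 3)
  expect_true(any(r$clusters$significant))
  rs <- clusterTest(x, y, test = "two_sample", scheme = "set_swap",
                    nSurrogates = 201, seed = 3)
  expect_true(any(rs$clusters$significant))
  ## identical sets: significance at about the alpha rate
  hits <- replicate(60, {
    z <- matrix(rnorm(12 * 30), 12, 30)
    z2 <- z[sample(12), ]
    any(clusterTest(z, z2, test = "two_sample",
                    nSurrogates = 101,
                    seed = sample.int(1e6, 1))$clusters$significant)
  })
  expect_lte(mean(hits), 0.15)
})

test_that("results are invariant to observation order and handle 2D grids", {
  set.seed(5)
  x <- matrix(rnorm(12 * 225), 12, 225)
  x[, 100:120] <- x[, 100:120] + 1.5
  r1 <- clusterTest(x, dims = c(15, 15), nSurrogates = 101, seed = 7)
  r2 <- clusterTest(x[sample(12), ], dims = c(15, 15), nSurrogates = 101,
                    seed = 7)
  expect_equal(r1$t, r2$t)
  expect_equal(r1$clusters$sumT, r2$clusters$sumT)
})

test_that("two-sided tests find negative clusters at alpha = 0.025", {
  set.seed(6)
  x <- matrix(rnorm(20 * 40), 20, 40)
  x[, 5:15] <- x[, 5:15] - 1.2
  r <- clusterTest(x, alternative = "two_sided", nSurrogates = 201,
                   seed = 8)
  sig <- r$clusters[r$clusters$significant, ]
  expect_true(any(sig$sign == -1))
})

test_that("circular statistics behave at the reference points", {
  ## concentrated phases: p below 1e-6 at n = 50
  r <- rayleighTest(rep(1.2, 50))
  expect_lt(r$p, 1e-6)
  expect_equal(r$meanDirection, 1.2)
  expect_equal(r$z, 50)
  ## uniform phases keep p above alpha in about 95% of draws
  set.seed(9)
  ps <- replicate(200, rayleighTest(runif(40, 0, 2 * pi))$p)
  expect_gt(mean(ps > 0.05), 0.88)
  ## Kuiper: a sample against itself shows no difference
  a <- runif(50, 0, 2 * pi)
  expect_gt(kuiperTwoSample(a, a)$p, 0.5)
  ## shifted distributions are detected
  set.seed(10)
  b <- (rnorm(300, 0, 0.4)) %% (2 * pi)
  cshift <- (rnorm(300, pi, 0.4)) %% (2 * pi)
  expect_lt(kuiperTwoSample(b, cshift)$p, 0.01)
})
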