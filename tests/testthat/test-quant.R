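test_that("gel percentage follows the bounded reading of the area formula", {
  expect_equal(percent_capped(0, 50), 100)
  expect_equal(percent_capped(10, 10), 50)
  expect_equal(percent_capped(30, 70), 70)
  expect_error(percent_capped(0, 0), "zero")
  # invariant under common rescaling, bounded in [0, 100]
  set.seed(3)
  for (i in 1:20) {
    p <- runif(1, 1, 100); cc <- runif(1, 1, 100); s <- runif(1, 0.1, 50)
    v <- percent_capped(p, cc)
    expect_equal(percent_capped(s * p, s * cc), v, tolerance = 1e-12)
    expect_gte(v, 0); expect_lte(v, 100)
  }
})

test_that("standard addition is exact on noiseless affine series", {
  fit <- standard_addition(c(0, 1, 2, 4), c(2, 4, 6, 10))
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 2)
  expect_equal(fit$c0, 1)
  set.seed(5)
  for (i in 1:10) {
    a <- runif(1, 0.1, 100); c0 <- runif(1, 1, 2000)
    x <- c0 * c(0, 0.5, 1, 2)
    fit <- standard_addition(x, a * (x + c0))
    expect_equal(fit$c0, c0, tolerance = 1e-9)
  }
  expect_error(standard_addition(c(0, 1), c(1, 2)), "3 distinct")
  expect_error(standard_addition(c(0, 1, 2), c(3, 2, 1)), "no response")
})

test_that("standard addition recovers truth within 5% under 5% area noise", {
  truth <- synth_truth()
  for (sp in c("Ap3A", "2mGp4G", "NAD")) {
    est <- vapply(1:100, function(r) {
      tab <- simulate_assays(truth, seed = 1000 + r)$standard_addition
      tab <- tab[tab$species == sp, ]
      standard_addition(tab$spike, tab$area)$c0
    }, numeric(1))
    expect_equal(mean(est), truth$c0[[sp]],
                 tolerance = 0.05 * truth$c0[[sp]])
  }
})

test_that("relative abundance reports both fold conventions", {
  expect_equal(relative_abundance(10, 10)$fold, 1)
  r <- relative_abundance(c(1, 1, 1), c(2, 2, 2))
  expect_equal(r$fold, 2)
  expect_equal(r$fold_paired$mean, 2)
  expect_equal(r$fold_paired$sd, 0)
  expect_error(relative_abundance(0, 1), "area_a > 0")
})

test_that("decapping classes follow the two-enzyme truth table", {
  expect_equal(classify_decapping(100, 5, 5)$class, "RppH-sensitive")
  expect_equal(classify_decapping(100, 98, 3)$class,
               "RppH-resistant/ApaH-sensitive")
  expect_equal(classify_decapping(100, 100, 100)$class, "resistant-to-both")
})

test_that("raising the threshold never moves a species toward sensitive", {
  rank_of <- function(cls) match(cls, c("resistant-to-both",
                                        "RppH-resistant/ApaH-sensitive",
                                        "RppH-sensitive"))
  set.seed(9)
  for (i in 1:20) {
    before <- 100
    ar <- runif(1, 0, 100); aa <- runif(1, 0, 100)
    ths <- sort(runif(3, 0.05, 0.95))
    ranks <- vapply(ths, function(th)
      rank_of(classify_decapping(before, ar, aa, threshold = th)$class),
      numeric(1))
    expect_false(is.unsorted(rev(ranks)))
  }
})

test_that("kinetics normalisation and rate fitting behave", {
  flat <- kinetics_curve(c(0, 1, 5, 10), c(500, 500, 500, 500))
  expect_equal(flat$k, 0)
  expect_equal(flat$curve$percent_remaining, rep(100, 4))
  expect_equal(flat$half_life, Inf)

  tt <- c(0, 0.5, 1, 2, 5, 10, 20, 40)
  exact <- kinetics_curve(tt, 1234 * exp(-0.32 * tt))
  expect_equal(exact$k, 0.32, tolerance = 1e-9)
  expect_equal(exact$half_life, log(2) / 0.32, tolerance = 1e-9)

  # normalisation removes multiplicative area scaling
  a <- 77 * exp(-0.1 * tt)
  expect_equal(kinetics_curve(tt, a)$curve$percent_remaining,
               kinetics_curve(tt, 13 * a)$curve$percent_remaining)

  # a substrate at 50% after 40 min fits k = ln2/40
  slow <- kinetics_curve(tt, 100 * exp(-log(2) / 40 * tt))
  expect_equal(100 * exp(-slow$k * 40), 50, tolerance = 1e-6)

  expect_error(kinetics_curve(c(1, 2), c(1, 1)), "t = 0")
  expect_error(kinetics_curve(c(0, 2), c(0, 1)), "positive")
})

test_that("kinetics rate is recovered within 5% at 5% area noise", {
  truth <- synth_truth()
  est <- vapply(1:100, function(r) {
    kin <- simulate_assays(truth, seed = 2000 + r)$kinetics
    kin <- kin[kin$species == "Ap4A-RNA", ]
    kinetics_curve(kin$time, kin$area)$k
  }, numeric(1))
  expect_equal(mean(est), 0.32, tolerance = 0.05 * 0.32)
})
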