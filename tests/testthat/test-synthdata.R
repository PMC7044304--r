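test_that("generation is deterministic in (config, seed)", {
  truth <- synth_truth()
  a <- simulate_run(truth, seed = 5)
  b <- simulate_run(truth, seed = 5)
  expect_identical(a, b)
  d <- simulate_run(truth, seed = 6)
  expect_false(identical(a$sample$peaks, d$sample$peaks))
  expect_identical(simulate_assays(truth, 5), simulate_assays(truth, 5))
})

test_that("the generator does not disturb the caller's RNG stream", {
  set.seed(123)
  x1 <- runif(3)
  set.seed(123)
  invisible(simulate_run(synth_truth(), seed = 99))
  x2 <- runif(3)
  expect_identical(x1, x2)
})

test_that("an empty truth yields mononucleotide-only sample runs", {
  truth <- synth_truth(caps = list(), n_background = 0)
  runs <- simulate_run(truth, seed = 1)
  expect_equal(nrow(runs$sample$peaks), 4L)  # AMP, GMP, CMP, UMP
  expect_equal(nrow(runs$control$peaks), 0L)
  expect_true(runs$control$control)
})

test_that("15N runs shift nitrogenous peaks by N x 0.9970349 / z", {
  truth <- synth_truth(ppm_sigma = 0, n_background = 0)
  runs <- simulate_run(truth, seed = 2)
  gt <- runs$ground_truth
  expect_equal(gt$mz15 - gt$mz14,
               10 * delta_15n() / ifelse(gt$adduct == "[M-2H]2-", 2, 1),
               tolerance = 1e-9)
})

test_that("noise-free assay tables return every truth parameter exactly", {
  truth <- synth_truth(area_cv = 0)
  assays <- simulate_assays(truth, seed = 3)
  for (sp in names(truth$c0)) {
    tab <- assays$standard_addition[assays$standard_addition$species == sp, ]
    expect_equal(standard_addition(tab$spike, tab$area)$c0, truth$c0[[sp]],
                 tolerance = 1e-9)
  }
  for (i in seq_len(nrow(truth$kinetics))) {
    kin <- assays$kinetics[assays$kinetics$species ==
                             truth$kinetics$species[i], ]
    expect_equal(kinetics_curve(kin$time, kin$area)$k, truth$kinetics$k[i],
                 tolerance = 1e-9)
  }
  for (i in seq_len(nrow(assays$gel))) {
    expect_equal(percent_capped(assays$gel$ar_p[i], assays$gel$ar_cap[i]),
                 100 * truth$gel_fractions[[assays$gel$species[i]]],
                 tolerance = 1e-9)
  }
  rel <- assays$relative
  expect_equal(relative_abundance(rel$area[rel$condition == "EXP"],
                                  rel$area[rel$condition == "STA"])$fold,
               truth$fold_sta_exp, tolerance = 1e-9)
})

test_that("decapping tables reproduce the methylation signature", {
  truth <- synth_truth()
  dcp <- simulate_assays(truth, seed = 4)$decapping
  cls <- vapply(seq_len(nrow(dcp)), function(i)
    classify_decapping(dcp$before[i], dcp$after_rpph[i],
                       dcp$after_apah[i])$class, character(1))
  expect_equal(cls[dcp$species == "Gp4G"], "RppH-sensitive")
  expect_equal(cls[dcp$species == "2mGp4G"],
               "RppH-resistant/ApaH-sensitive")
  expect_equal(cls[dcp$species == "uncapped-control"], "resistant-to-both")
})

test_that("the STA/EXP fold change is recovered at the configured ratio", {
  truth <- synth_truth()
  folds <- vapply(1:50, function(r) {
    rel <- simulate_assays(truth, seed = 3000 + r)$relative
    relative_abundance(rel$area[rel$condition == "EXP"],
                       rel$area[rel$condition == "STA"])$fold
  }, numeric(1))
  expect_equal(mean(folds), truth$fold_sta_exp,
               tolerance = 0.05 * truth$fold_sta_exp)
})
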