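make_run <- function(mz, intensity = 1000, rt = 5, ...) {
  ms_run(data.frame(mz = mz, intensity = intensity, rt = rt), ...)
}

test_that("exact peaks annotate with zero ppm error", {
  lib <- enumerate_candidates(bases = "A", n_range = 3, max_methyls = 0,
                              ions = list("[M-H]-"))
  theo <- lib$mz[lib$label == "14N"]
  ann <- match_peaks(make_run(theo), lib)
  expect_equal(nrow(ann), 1L)
  expect_equal(ann$ppm, 0)
  expect_equal(ann$cap_id, "Ap3A")
})

test_that("the printed Ap3A detection is assigned at ~3 ppm", {
  ann <- match_peaks(make_run(755.077), default_cap_library(), tol_ppm = 10)
  hit <- ann[ann$adduct == "[M-H]-", ]
  expect_equal(hit$cap_id, "Ap3A")
  expect_lt(abs(hit$ppm), 4)
})

test_that("ppm ties break to the more intense peak", {
  lib <- enumerate_candidates(bases = "A", n_range = 3, max_methyls = 0,
                              ions = list("[M-H]-"))
  theo <- lib$mz[lib$label == "14N"]
  d <- theo * 5e-6
  run <- make_run(c(theo - d, theo + d), intensity = c(100, 900))
  ann <- match_peaks(run, lib, tol_ppm = 10)
  expect_equal(ann$observed_mz, theo + d)
})

test_that("sub-threshold peaks are ignored and empty runs error", {
  lib <- enumerate_candidates(bases = "A", n_range = 3, max_methyls = 0,
                              ions = list("[M-H]-"))
  theo <- lib$mz[lib$label == "14N"]
  expect_equal(nrow(match_peaks(make_run(theo, intensity = 10), lib)), 0L)
  expect_error(match_peaks(make_run(numeric(0), numeric(0), numeric(0)), lib),
               "no peaks")
})

test_that("enlarging the tolerance never removes an annotation", {
  lib <- default_cap_library()
  set.seed(7)
  for (i in 1:5) {
    truth <- synth_truth()
    run <- simulate_run(truth, seed = 100 + i)$sample
    tols <- c(5, 10, 20, 40)
    found <- lapply(tols, function(tp) {
      a <- match_peaks(run, lib, tol_ppm = tp)
      paste(a$cap_id, a$adduct)
    })
    for (j in seq_len(length(tols) - 1)) {
      expect_true(all(found[[j]] %in% found[[j + 1]]))
    }
  }
})

test_that("EIC areas sum the peaks inside the window", {
  run <- make_run(c(500, 500.001, 500.002, 600),
                  intensity = c(100, 200, 300, 999))
  expect_equal(eic_area(run, 500.001, tol_ppm = 5), 600)
  expect_equal(eic_area(run, 700, tol_ppm = 5), 0)
  expect_equal(eic_area(run, 600, tol_ppm = 5, rt_window = c(6, 7)), 0)
  expect_equal(eic_area(run, 600, tol_ppm = 5, rt_window = c(4, 6)), 999)
})

test_that("the negative-control filter rejects shared contamination", {
  lib <- enumerate_candidates(bases = "A", n_range = 3, max_methyls = 0,
                              ions = list("[M-H]-"))
  theo <- lib$mz[lib$label == "14N"]
  sample <- make_run(theo, intensity = 1000)
  ann <- match_peaks(sample, lib)

  clean <- make_run(200, intensity = 1000, control = TRUE)
  out <- control_filter(ann, clean, sample)
  expect_true(out$accepted)
  expect_equal(out$control_area, 0)

  dirty <- make_run(theo, intensity = 1000, control = TRUE)
  out2 <- control_filter(ann, dirty, sample)
  expect_false(out2$accepted)

  expect_error(control_filter(ann, sample, sample), "not flagged")
  sta_ctrl <- make_run(200, control = TRUE, condition = "STA")
  expect_error(control_filter(ann, sta_ctrl, sample), "mismatched conditions")
})

test_that("peak CSV round-trips through the documented dialect", {
  run <- make_run(c(300.1, 500.5), intensity = c(10, 20), rt = c(1, 2))
  path <- withr::local_tempfile(fileext = ".csv")
  write_peak_csv(run, path)
  expect_identical(readLines(path)[1], "mz,intensity,rt")
  back <- read_peak_csv(path, label = "14N")
  expect_equal(back$peaks, run$peaks)
})
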