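test_that("internal-bridge caps are in-source stable, terminal isomers labile", {
  g4g <- cap_structure("G", "G", 4)
  stable <- insource_stability(g4g, "internal")
  expect_equal(stable$stability, "stable")
  expect_equal(nrow(stable$fragments), 0L)

  labile <- insource_stability(g4g, "terminal")  # p3GpG, the Gp4G isomer
  expect_equal(labile$stability, "labile")
  expect_true("p2GpG" %in% labile$fragments$label)
  # ladder steps are spaced by exactly one HPO3 at z = 1
  parent_mz <- mz_of(cap_formula(g4g), "[M-H]-")
  mzs <- c(parent_mz, labile$fragments$mz)
  expect_equal(diff(mzs), rep(-79.96633, length(mzs) - 1), tolerance = 1e-5)
})

test_that("the shortest terminal isomer shows a single HPO3 loss", {
  lab <- insource_stability(cap_structure("A", "A", 3), "terminal")  # p2NpN
  expect_equal(nrow(lab$fragments), 1L)
})

test_that("MSn fragment set contains the diagnostic dehydrated species", {
  fr <- predict_msn_fragments(cap_structure("A", "A", 3))
  atp <- fr[fr$label == "ATP-H2O", ]
  expect_equal(nrow(atp), 2L)  # both sides of the symmetric cap
  expect_equal(atp$mz[1], 487.98, tolerance = 1e-3)
  expect_lt(abs(atp$mz[1] - 487.8), 0.5)  # unit-resolution selection window

  m6 <- predict_msn_fragments(cap_structure("A", "A", 3, methyl1 = 1,
                                            pos1 = "N6"))
  mamp <- m6[m6$label == "mAMP-H2O", ]
  expect_equal(mamp$mz, 342.06, tolerance = 1e-3)
  expect_lt(abs(mamp$mz - 341.8), 0.5)
})

test_that("fragments never exceed the parent composition", {
  caps <- list(cap_structure("A", "G", 4, methyl1 = 1),
               cap_structure("G", "G", 5, methyl1 = 2),
               cap_structure("A", "A", 2))
  for (cap in caps) {
    parent <- cap_formula(cap)
    fr <- predict_msn_fragments(cap)
    for (i in seq_len(nrow(fr))) {
      # subtraction errors out if any element count would go negative
      expect_silent(parent - parse_formula(fr$formula[i]))
      expect_lt(monoisotopic_mass(parse_formula(fr$formula[i])),
                monoisotopic_mass(parent))
    }
  }
})

test_that("a symmetric cap yields identical per-side fragment sets", {
  fr <- predict_msn_fragments(cap_structure("A", "A", 3))
  s1 <- fr[fr$side == 1, c("label", "formula", "mz")]
  s2 <- fr[fr$side == 2, c("label", "formula", "mz")]
  rownames(s1) <- rownames(s2) <- NULL
  expect_equal(s1, s2)
  # methyls stay on their own side, breaking the symmetry
  fr2 <- predict_msn_fragments(cap_structure("A", "A", 3, methyl1 = 1))
  expect_false(identical(sort(fr2$label[fr2$side == 1]),
                         sort(fr2$label[fr2$side == 2])))
})

test_that("phosphorylation depth is bounded by the bridge length", {
  fr <- predict_msn_fragments(cap_structure("A", "A", 2))
  expect_false(any(grepl("^ATP", fr$label)))
  expect_true(any(grepl("^ADP", fr$label)))
})
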