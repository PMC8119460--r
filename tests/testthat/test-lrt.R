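test_that("chi-square arithmetic reproduces published statistics", {
  # values printed in the reference selection table (df = 1 throughout)
  expect_equal(lrtPvalue(-1000, -1000 - 74.72 / 2)@p, 5.424e-18,
               tolerance = 1e-3)
  expect_equal(lrtPvalue(-500, -500 - 25.78 / 2)@p, 3.826e-07,
               tolerance = 1e-3)
  expect_equal(lrtPvalue(-10, -10)@p, 1)
  expect_equal(lrtPvalue(-10, -10)@stat, 0)
})

test_that("negative statistics within tolerance are clamped with a warning", {
  expect_warning(res <- lrtPvalue(-100.001, -100), "clamped")
  expect_equal(res@stat, 0)
  expect_equal(res@p, 1)
  expect_silent(lrtPvalue(-100, -100.000000001))
})

test_that("Bonferroni adjustment multiplies and caps", {
  expect_equal(bonferroniAdjust(5.424e-18, 2), 1.0848e-17)
  expect_equal(bonferroniAdjust(0.021, 2), 0.042)
  expect_equal(bonferroniAdjust(0.7, 2), 1)
  expect_error(bonferroniAdjust(1.2, 2), "\\[0, 1\\]")
  lrt <- lrtPvalue(-100, -102, nTests = 2)
  expect_equal(lrt@pAdjusted, min(1, lrt@p * 2))
})

test_that("the printed-precision comparator accepts rounding and truncation", {
  expect_true(phylotroph:::.matchesPrinted(0.021082, "0.021"))
  expect_true(phylotroph:::.matchesPrinted(1.084876e-17, "1.084E-17"))
  expect_true(phylotroph:::.matchesPrinted(1.39e-4, "0.000"))
  expect_false(phylotroph:::.matchesPrinted(0.0523, "0.026"))
})
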