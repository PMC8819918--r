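test_that("standard-curve fitting recovers slope, efficiency and R^2", {
  # points constructed on an exact line: slope = -delta cq / delta log10
  curve <- fitStandardCurve(c(1e3, 1e5, 1e7),
                            c(28.035, 21.3912, 14.7474))
  expect_equal(curve@slope, -3.3219, tolerance = 1e-4)
  expect_equal(amplificationEfficiency(curve), 1.00, tolerance = 1e-3)

  exact <- fitStandardCurve(c(1e3, 1e5, 1e7), 30 - 3 * c(3, 5, 7))
  expect_equal(exact@slope, -3, tolerance = 1e-12)
  expect_equal(exact@intercept, 30, tolerance = 1e-12)
  expect_equal(exact@rSquared, 1, tolerance = 1e-12)

  # perturbing one point by +0.5 Cq: hand OLS on x = (3,5,7),
  # y = (21.5,15,9) gives slope -25/8 = -3.125
  bent <- fitStandardCurve(c(1e3, 1e5, 1e7), c(21.5, 15, 9))
  expect_equal(bent@slope, -3.125, tolerance = 1e-12)
  expect_lt(abs(bent@slope - (-3)), 0.25)
  expect_lt(bent@rSquared, 1)

  expect_error(fitStandardCurve(c(1e3, 1e5), c(28, 21)), "at least 3")
  expect_error(fitStandardCurve(rep(1e5, 3), c(1, 2, 3) + 20), "span")
})

test_that("single reactions quantify through the curve with censoring", {
  curve <- defaultStandardCurve()

  expect_true(is.na(quantifyReaction(24.7123, curve, flagged = TRUE)))
  # cq = intercept corresponds to 1 copy/ul: below the 800 cutoff
  expect_true(is.na(quantifyReaction(curve@intercept, curve)))
  expect_true(is.na(quantifyReaction(NA_real_, curve)))
  # invert the line by hand: 38 - 3.3219 * 4 = 24.7123 -> 1e4 copies/ul
  expect_equal(quantifyReaction(24.7123, curve), 1e4, tolerance = 1e-3)

  # round trip is the identity within the calibrated range
  copies <- 10^seq(3, 7, by = 0.25)
  back <- quantifyReaction(cqFromCopies(copies, curve), curve)
  expect_equal(back, copies, tolerance = 1e-9)

  expect_warning(quantifyReaction(cqFromCopies(1e8, curve), curve),
                 "extrapolating")
})

test_that("triplicate aggregation applies the 2-of-3 / 800 copies rule", {
  pos <- aggregateTriplicates(c(1000, 900, NA))
  expect_equal(pos$copies, 950)
  expect_equal(pos$nPositive, 2L)

  # only one reaction at or above 800 copies/ul -> negative call
  one <- aggregateTriplicates(c(700, 750, 900))
  expect_true(is.na(one$copies))
  expect_equal(one$nPositive, 1L)

  none <- aggregateTriplicates(c(NA, NA, NA))
  expect_true(is.na(none$copies))
  expect_equal(none$nPositive, 0L)

  expect_error(aggregateTriplicates(c(1000, 900)), "exactly 3")
  expect_equal(aggregateTriplicates(c(1000, 900),
                                    allowIncomplete = TRUE)$copies, 950)
})

test_that("aggregation is permutation-invariant and monotone", {
  set.seed(41)
  for (i in 1:50) {
    x <- stats::runif(3, 0, 2000)
    x[stats::runif(3) < 0.3] <- NA
    base <- aggregateTriplicates(x)
    perm <- aggregateTriplicates(sample(x))
    expect_identical(base$nPositive, perm$nPositive)
    expect_equal(base$copies, perm$copies)
    # raising one replicate never flips positive -> negative
    j <- sample.int(3, 1)
    y <- x
    y[j] <- if (is.na(y[j])) 2500 else y[j] + 1500
    raised <- aggregateTriplicates(y)
    if (!is.na(base$copies)) expect_false(is.na(raised$copies))
    expect_gte(raised$nPositive, base$nPositive)
  }
})

test_that("a full reaction table quantifies to a copies table", {
  curve <- defaultStandardCurve()
  reactions <- data.frame(
    sample = rep(c("S01", "S02"), each = 6),
    assay = rep(rep(c("A", "B"), each = 3), 2),
    replicate = rep(1:3, 4),
    cq = c(cqFromCopies(c(1000, 1000, 1000), curve),   # S01 A: positive
           cqFromCopies(c(900, 700, 700), curve),      # S01 B: 1 positive
           cqFromCopies(c(2e4, 2e4, 2e4), curve),      # S02 A
           NA, NA, NA))                                # S02 B: no amp
  tab <- quantifyReactions(reactions, curve)
  v <- abundValues(tab)
  expect_equal(abundUnit(tab), "copies_per_ul")
  expect_equal(v["S01", "A"], 1000, tolerance = 1e-9)
  expect_true(is.na(v["S01", "B"]))
  expect_equal(v["S02", "A"], 2e4, tolerance = 1e-9)
  expect_true(is.na(v["S02", "B"]))
  expect_error(quantifyReactions(reactions[, -4], curve), "columns")
})

test_that("subspecies assays pool into species groups", {
  m <- matrix(c(30000, 2000, 5000, NA, NA, NA), nrow = 3, byrow = TRUE)
  tab <- mkTable(m, unit = "copies_per_ul",
                 taxa = c("lactis", "cremoris"))
  pooled <- poolSubspecies(tab, c(lactis = "Lc. lactis",
                                  cremoris = "Lc. lactis"))
  v <- abundValues(pooled)
  expect_equal(colnames(v), "Lc. lactis")
  expect_equal(unname(v[1L, ]), 32000)   # sum of members
  expect_equal(unname(v[2L, ]), 5000)    # positive + negative
  expect_true(is.na(v[3L, ]))            # all members negative

  # identity map leaves values unchanged
  ident <- poolSubspecies(tab, c(lactis = "lactis",
                                 cremoris = "cremoris"))
  expect_equal(abundValues(ident)[, c("lactis", "cremoris")],
               abundValues(tab))

  wide <- mkTable(matrix(1:4 * 1000, 1), unit = "copies_per_ul",
                  taxa = c("a", "b", "c", "d"))
  expect_error(poolSubspecies(wide, c(a = "c")), "collides")
})
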