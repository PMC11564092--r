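test_that("cohort split uses strict thresholds and partitions the table", {
  tab <- data.frame(spacer = replicate(4, strrep("A", 30)),
                    efficiency = c(95, 92, 70, 40))
  co <- splitCohorts(tab)
  expect_equal(sort(co$potent$efficiency), c(92, 95))
  expect_equal(co$ineffective$efficiency, 40)
  expect_equal(co$excluded$efficiency, 70)

  # boundaries are excluded (strict inequalities)
  bound <- data.frame(spacer = c("A", "A"), efficiency = c(90, 50))
  cb <- splitCohorts(bound)
  expect_equal(nrow(cb$potent), 0L)
  expect_equal(nrow(cb$ineffective), 0L)
  expect_equal(nrow(cb$excluded), 2L)

  empty <- splitCohorts(data.frame(spacer = character(0),
                                   efficiency = numeric(0)))
  expect_true(all(vapply(empty, nrow, integer(1)) == 0L))
  expect_error(splitCohorts(data.frame(spacer = "A", efficiency = 105)),
               "\\[0, 100\\]")
})

test_that("cohort partition is exhaustive and disjoint on random tables", {
  withr::with_seed(61, {
    tab <- data.frame(spacer = replicate(50, rand_spacer()),
                      efficiency = runif(50, 0, 100))
    co <- splitCohorts(tab)
    expect_equal(sum(vapply(co, nrow, integer(1))), nrow(tab))
    all_eff <- sort(unname(unlist(lapply(co, function(d) d$efficiency))))
    expect_equal(all_eff, sort(tab$efficiency))
  })
})

test_that("pwm matches hand-counted frequencies and sums to one", {
  ident <- pwm(rep("GGAU", 5))
  expect_equal(unname(colSums(matrixValues(ident))), rep(1, 4))
  expect_true(all(matrixValues(ident) %in% c(0, 1)))
  expect_equal(unname(matrixValues(ident)["G", 1]), 1)

  four <- pwm(c(strrep("A", 6), strrep("C", 6), strrep("G", 6),
                strrep("U", 6)))
  expect_true(all(matrixValues(four) == 0.25))

  withr::with_seed(62, {
    sps <- replicate(40, rand_spacer())
    m <- matrixValues(pwm(sps))
    # hand-count a few cells
    chm <- do.call(rbind, strsplit(sps, ""))
    for (i in c(1, 15, 30)) for (b in c("A", "C", "G", "U"))
      expect_equal(unname(m[b, i]), mean(chm[, i] == b))
    expect_equal(unname(colSums(m)), rep(1, 30))
  })
  expect_error(pwm(c("AAA", "AAAA")), "same length")
  expect_error(pwm(character(0)), "empty")
})

test_that("delta probabilities subtract the baseline and sum to zero", {
  # uniform cohort with cohort-mean baseline: all-zero matrix
  uni <- deltaProbabilities(c(strrep("A", 8), strrep("C", 8), strrep("G", 8),
                              strrep("U", 8)))
  expect_true(all(abs(matrixValues(uni)) < 1e-12))

  # all-G cohort against the uniform baseline: +0.75 G, -0.25 others
  allg <- deltaProbabilities(rep(strrep("G", 10), 3), baseline = "uniform")
  expect_true(all(matrixValues(allg)["G", ] == 0.75))
  expect_true(all(matrixValues(allg)[c("A", "C", "U"), ] == -0.25))

  withr::with_seed(63, {
    sps <- replicate(30, rand_spacer())
    for (bl in list("cohort_mean", "uniform", c(0.4, 0.3, 0.2, 0.1))) {
      d <- deltaProbabilities(sps, baseline = bl)
      expect_true(all(abs(colSums(matrixValues(d))) < 1e-9))
    }
  })
  expect_error(deltaProbabilities(strrep("A", 30),
                                  baseline = c(0.5, 0.5, 0.5, 0.5)),
               "summing to 1")
})

test_that("PFS matrices use only records with complete flanks", {
  recs <- data.frame(spacer = replicate(6, strrep("A", 30)),
                     flank_up = c("ACGU", "GGGG", "ACGU", "AC", NA, "UUUU"),
                     flank_down = c("UUUU", "CCCC", "ACGU", "ACGU", "ACGU",
                                    "GG"))
  expect_warning(pfs <- pfsMatrices(recs), "skipped")
  expect_equal(cohortSize(pfs$upstream), 3L)
  expect_equal(dim(matrixValues(pfs$upstream)), c(4L, 4L))
  expect_equal(unname(colSums(matrixValues(pfs$downstream))), rep(1, 4))

  ident <- suppressWarnings(pfsMatrices(
    data.frame(flank_up = rep("GGCC", 4), flank_down = rep("AAUU", 4))))
  expect_true(all(matrixValues(ident$upstream) %in% c(0, 1)))
  expect_error(pfsMatrices(data.frame(flank_up = "AC", flank_down = "A")),
               "flanks")
})

test_that("randomised flanks approach the no-PFS-bias null", {
  withr::with_seed(64, {
    n <- 4000
    recs <- data.frame(
      flank_up = replicate(n, rand_seq(4)),
      flank_down = replicate(n, rand_seq(4)))
    pfs <- pfsMatrices(recs)
    expect_true(all(abs(matrixValues(pfs$upstream) - 0.25) < 0.03))
    expect_true(all(abs(matrixValues(pfs$downstream) - 0.25) < 0.03))
  })
})

test_that("prediction evaluation reports cohort-conditional accuracy", {
  # all predicted-potent records at 95% efficiency: accuracy 1
  pot <- data.frame(spacer = rep(paste0("GG", strrep("A", 28)), 5),
                    efficiency = rep(95, 5))
  ev <- evaluatePredictions(pot)
  expect_equal(ev$potent_accuracy, 1)
  expect_equal(ev$n_predicted_potent, 5L)

  # 21 predicted-potent records, 20 above threshold: 20/21
  tab21 <- data.frame(spacer = rep(paste0("GG", strrep("A", 28)), 21),
                      efficiency = c(rep(95, 20), 60))
  expect_equal(evaluatePredictions(tab21)$potent_accuracy, 20 / 21)

  # order permutation invariance
  withr::with_seed(65, {
    tab <- makeEfficiencyTable(n = 60, seed = 8)
    a <- evaluatePredictions(tab)
    b <- evaluatePredictions(tab[sample(nrow(tab)), ])
    expect_equal(a$potent_accuracy, b$potent_accuracy)
    expect_equal(a$ineffective_accuracy, b$ineffective_accuracy)
  })
  expect_error(evaluatePredictions(data.frame(spacer = character(0),
                                              efficiency = numeric(0))),
               "no records")
})

test_that("planted positional bias is recovered in the potent delta matrix", {
  tab <- makeEfficiencyTable(n = 201, seed = 17)
  co <- splitCohorts(tab)
  expect_gt(nrow(co$potent), 20)
  d_pot <- matrixValues(deltaProbabilities(co$potent$spacer))
  # potent records were forced to G at positions 1-2
  expect_gt(d_pot["G", 1], 0.3)
  expect_gt(d_pot["G", 2], 0.3)
  expect_lt(d_pot["C", 1], 0)
  d_ineff <- matrixValues(deltaProbabilities(co$ineffective$spacer))
  expect_gt(d_ineff["C", 1], 0.3)
  expect_lt(d_ineff["G", 1], 0)
})

test_that("covariate correlation wraps Pearson's test", {
  withr::with_seed(66, {
    eff <- runif(40, 0, 100)
    recs <- data.frame(spacer = replicate(40, rand_spacer()),
                       efficiency = eff,
                       mfe = -0.5 * eff + rnorm(40, 0, 5))
    cc <- covariateCorrelation(recs, "mfe")
    expect_equal(cc$r, unname(cor(eff, recs$mfe)))
    expect_lt(cc$p_value, 0.001)
  })
  expect_error(covariateCorrelation(data.frame(efficiency = 1), "mfe"),
               "no column")
})
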