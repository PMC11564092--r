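test_that("single-feature spacers reproduce the published weights", {
  A29 <- strrep("A", 29)
  expect_equal(scoreTotal(scoreSpacer(paste0("G", A29))), 60)
  expect_equal(scoreTotal(scoreSpacer(paste0("AG", strrep("A", 28)))), 60)
  expect_equal(scoreTotal(scoreSpacer(strrep("A", 30))), 0)
  expect_equal(scoreTotal(scoreSpacer(paste0("GG", strrep("A", 28)))), 120)
  expect_equal(scoreTotal(scoreSpacer(paste0("C", A29))), -60)
  expect_equal(scoreTotal(scoreSpacer(paste0("AC", strrep("A", 28)))), -60)
  expect_equal(scoreTotal(scoreSpacer(paste0("AAC", strrep("A", 27)))), -50)
  expect_equal(scoreTotal(scoreSpacer(paste0("AAAC", strrep("A", 26)))), -40)
  for (p in c(11, 12, 15, 16, 17)) {
    s <- strsplit(strrep("A", 30), "")[[1]]
    s[p] <- "C"
    expect_equal(scoreTotal(scoreSpacer(paste(s, collapse = ""))), -5)
  }
  expect_equal(scoreTotal(scoreSpacer(strrep("C", 30))), -235)
})

test_that("scores agree with the brute-force oracle and stay in bounds", {
  withr::with_seed(31, {
    sps <- vapply(1:500, function(i) rand_spacer(), character(1))
    got <- scoreSpacers(sps)
    want <- vapply(sps, oracle_score, numeric(1), USE.NAMES = FALSE)
    expect_equal(got, want)
    expect_true(all(got >= -235 & got <= 120))
    # breakdown totals match the vectorised path
    for (s in sps[1:20])
      expect_equal(scoreTotal(scoreSpacer(s)), oracle_score(s))
  })
  expect_error(scoreSpacer(strrep("A", 29)), "nt")
  expect_error(scoreSpacers(paste0("N", strrep("A", 29))), "N")
})

test_that("consensus classification follows the potent/ineffective motifs", {
  expect_equal(classifySpacer(paste0("GG", strrep("A", 28))),
               "predicted_potent")
  expect_equal(classifySpacer(paste0("CCCC", "AAAAAA", "CC", "AA", "CCC",
                                     strrep("A", 13))),
               "predicted_ineffective")
  expect_equal(classifySpacer(paste0("GA", strrep("A", 28))),
               "indeterminate")
  # a G-G start with a central C violates the potent consensus
  expect_equal(classifySpacer(paste0("GG", strrep("A", 8), "C",
                                     strrep("A", 19))), "indeterminate")
  # C at a -60 position alone is predicted ineffective
  expect_equal(classifySpacer(paste0("CA", strrep("G", 28))),
               "predicted_ineffective")
})

test_that("predicted-potent spacers always score at least +30", {
  # G at 1-2 (+120) and no central C leaves at worst C at 3 and 4 (-90)
  withr::with_seed(32, {
    for (i in 1:300) {
      s <- rand_spacer()
      if (classifySpacer(s) == "predicted_potent")
        expect_gte(scoreTotal(scoreSpacer(s)), 30)
    }
  })
})

test_that("ranking is stable, score-descending, start-ascending on ties", {
  cand <- data.frame(
    spacer = c(paste0("GG", strrep("A", 28)),   # +120
               strrep("A", 30),                 # 0
               strrep("U", 30),                 # 0, earlier start wins
               paste0("C", strrep("A", 29))),   # -60
    start = c(7L, 10L, 3L, 1L))
  rk <- rankSpacers(cand)
  expect_equal(rk$score, c(120, 0, 0, -60))
  expect_equal(rk$start_1based, c(7L, 3L, 10L, 1L))
  expect_equal(rk$rank, 1:4)

  withr::with_seed(33, {
    sps <- vapply(1:200, function(i) rand_spacer(), character(1))
    cand <- data.frame(spacer = sps, start = sample(1000, 200))
    rk <- rankSpacers(cand)
    sc <- scoreSpacers(sps)
    ord <- order(-sc, cand$start)
    expect_equal(rk$spacer_seq, sps[ord])
    expect_equal(rk$score, sc[ord])
  })

  expect_warning(out <- rankSpacers(data.frame(spacer = character(0),
                                               start = integer(0))),
                 "no retained")
  expect_equal(nrow(out), 0L)
})

test_that("rescue variants follow the insertion/substitution scheme", {
  X28 <- strrep("U", 28)
  v <- rescueSpacer(paste0("CA", X28))
  expect_setequal(v$variant, c("INS_G", "SUB_1G", "SUB_12GG"))
  expect_equal(v$spacer_seq[v$variant == "INS_G"], paste0("GCA", X28))
  expect_equal(nchar(v$spacer_seq[v$variant == "INS_G"]), 31L)
  expect_equal(v$spacer_seq[v$variant == "SUB_1G"], paste0("GA", X28))
  expect_equal(v$spacer_seq[v$variant == "SUB_12GG"], paste0("GG", X28))
  expect_equal(v$introduced_mismatches[v$variant == "INS_G"], 1L)
  expect_equal(v$introduced_mismatches[v$variant == "SUB_12GG"], 2L)

  # variants identical to the input are omitted
  v2 <- rescueSpacer(paste0("GG", X28))
  expect_equal(v2$variant, "INS_G")

  # 31-nt insertion variants score 5'-anchored: position 1 G earns +60
  expect_equal(scoreTotal(scoreSpacer(paste0("G", strrep("A", 30)))), 60)
})

test_that("SUB_12GG never scores below the original spacer", {
  # exhaustive over position-1/2 base combinations
  tail28 <- strrep("A", 28)
  for (b1 in c("A", "C", "G", "U")) for (b2 in c("A", "C", "G", "U")) {
    s <- paste0(b1, b2, tail28)
    v <- rescueSpacer(s)
    gg <- v$spacer_seq[v$variant == "SUB_12GG"]
    if (length(gg))
      expect_gte(scoreTotal(scoreSpacer(gg)), scoreTotal(scoreSpacer(s)))
  }
})

test_that("scoring config round-trips and reproduces the defaults", {
  cfg <- system.file("extdata", "scoring_weights.yaml",
                     package = "cas13design")
  fromCfg <- readScoringConfig(cfg)
  expect_equal(scoringWeights(fromCfg), scoringWeights(scoringParams()))

  dir <- withr::local_tempdir()
  path <- file.path(dir, "w.yaml")
  custom <- scoringParams(gBonus = c("1" = 10), cPenalty = c("5" = -7))
  writeScoringConfig(custom, path)
  expect_equal(scoringWeights(readScoringConfig(path)),
               scoringWeights(custom))
  expect_equal(scoreTotal(scoreSpacer(paste0("G", strrep("A", 29)),
                                      custom)), 10)
})
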