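test_that("mismatch counting is positionwise complementarity", {
  withr::with_seed(51, {
    sp <- rand_spacer()
    win <- revComp(sp, "RNA")
    expect_equal(countMismatches(sp, win)$count, 0L)

    # plant mismatches at known spacer positions via the fixture generator
    tx <- NucleotideSeq(rand_seq(100), id = "t")
    planted <- c(3L, 7L, 12L, 20L, 25L)
    pl <- plantOffTarget(tx, sp, planted, insertAt = 40L)
    cm <- countMismatches(sp, substr(residues(pl$transcript), 40, 69))
    expect_equal(cm$count, 5L)
    expect_equal(cm$positions, planted)
  })
  expect_equal(countMismatches(strrep("A", 30), strrep("A", 30))$count, 30L)
  expect_error(countMismatches(strrep("A", 30), strrep("A", 29)), "length")
})

test_that("category thresholds encode the 4 / 15 mismatch cut-offs", {
  expect_equal(categorizeMismatches(c(0, 4, 5, 15, 16)),
               c("likely_silenced", "likely_silenced", "unlikely_silenced",
                 "unlikely_silenced", "nonexistent"))
  expect_error(categorizeMismatches(-1), ">= 0")
  expect_error(offTargetThresholds(17, 16), "<=")
})

test_that("planted sites are recovered with exact counts; 16-mm suppressed", {
  withr::with_seed(52, {
    sp <- rand_spacer()
    txs <- makeTranscriptome(6, c(300, 500), 0.5, seed = 99)
    mm_counts <- c(0L, 3L, 5L, 15L, 16L)
    sites <- list()
    for (i in seq_along(mm_counts)) {
      pos <- sort(sample(30, mm_counts[i]))
      pl <- plantOffTarget(txs[[i]], sp, pos, insertAt = 100L)
      txs[[i]] <- pl$transcript
      sites[[i]] <- pl$site
    }
    hits <- as.data.frame(scanOffTargets(sp, txs, maxReportMm = 15,
                                         method = "brute"))
    for (i in which(mm_counts <= 15L)) {
      h <- hits[hits$transcript_id == sprintf("tx_%03d", i) &
                  hits$start == 100L, ]
      expect_equal(nrow(h), 1L)
      expect_equal(h$mismatch_count, mm_counts[i])
      expect_equal(h$percent_match, (30 - mm_counts[i]) / 30)
    }
    expect_false(any(hits$transcript_id == "tx_005" & hits$start == 100L))
  })
})

test_that("seeded scan equals the brute-force oracle on random fixtures", {
  withr::with_seed(53, {
    sp <- rand_spacer()
    txs <- makeTranscriptome(8, c(200, 600), 0.45, seed = 7)
    # plant a couple of low-mismatch sites so the hit set is non-trivial
    pl1 <- plantOffTarget(txs[[2]], sp, c(5L, 17L), insertAt = 50L)
    pl2 <- plantOffTarget(txs[[4]], sp, integer(0), insertAt = 120L)
    txs[[2]] <- pl1$transcript
    txs[[4]] <- pl2$transcript
    chr <- setNames(vapply(txs, function(x) residues(x), character(1)),
                    vapply(txs, seqId, character(1)))
    for (cap in c(2L, 4L)) {
      seeded <- as.data.frame(scanOffTargets(sp, txs, maxReportMm = cap,
                                             method = "seed"))
      brute <- as.data.frame(scanOffTargets(sp, txs, maxReportMm = cap,
                                            method = "brute"))
      expect_equal(seeded, brute)
      ora <- oracle_scan(sp, chr, cap)
      expect_equal(seeded$transcript_id, ora$transcript_id)
      expect_equal(seeded$start, ora$start)
      expect_equal(seeded$mismatch_count, ora$mismatch_count)
    }
  })
})

test_that("report cap is monotone and N windows are skipped", {
  withr::with_seed(54, {
    sp <- rand_spacer()
    txs <- makeTranscriptome(4, c(200, 400), 0.5, seed = 13)
    pl <- plantOffTarget(txs[[1]], sp, c(4L, 9L, 22L), insertAt = 30L)
    txs[[1]] <- pl$transcript
    h15 <- as.data.frame(scanOffTargets(sp, txs, maxReportMm = 15,
                                        method = "brute"))
    h8 <- as.data.frame(scanOffTargets(sp, txs, maxReportMm = 8,
                                       method = "brute"))
    key <- function(h) paste(h$transcript_id, h$start)
    expect_true(all(key(h8) %in% key(h15)))
    expect_true(all(h8$mismatch_count <= 8))

    # a perfect site disrupted by N must not be reported
    res <- residues(txs[[2]])
    rc <- revComp(sp, "RNA")
    broken <- paste0(substr(res, 1, 49), chartr("U", "T",
                                                paste0(substr(rc, 1, 10), "N",
                                                       substr(rc, 12, 30))),
                     substr(res, 80, nchar(res)))
    tx_n <- NucleotideSeq(broken, id = "nx")
    hn <- as.data.frame(scanOffTargets(sp, list(tx_n), maxReportMm = 15,
                                       method = "brute"))
    expect_false(any(hn$start == 50L))
  })
})

test_that("likely-silenced hits carry a mismatch-tolerance annotation", {
  withr::with_seed(55, {
    sp <- rand_spacer()
    tx <- makeTranscriptome(1, c(300, 300), 0.5, seed = 5)[[1]]
    pl <- plantOffTarget(tx, sp, c(6L, 13L, 20L, 27L), insertAt = 80L)
    hits <- as.data.frame(scanOffTargets(sp, list(pl$transcript),
                                         maxReportMm = 15, method = "brute"))
    h <- hits[hits$start == 80L, ]
    expect_equal(h$category, "likely_silenced")
    expect_equal(h$tolerance_label, "TOLERATED")
    expect_true(all(is.na(hits$tolerance_label[
      hits$category != "likely_silenced"])))
  })
})

test_that("degenerate inputs are handled", {
  expect_warning(h <- scanOffTargets(strrep("A", 30), list()), "empty")
  expect_equal(nrow(h), 0L)
  expect_error(scanOffTargets(strrep("A", 29), list(NucleotideSeq("ACGU"))),
               "30-nt")
  expect_error(scanOffTargets(strrep("A", 30),
                              list(NucleotideSeq(strrep("ACGU", 20))),
                              maxReportMm = 15, method = "seed"),
               "seed")
})
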