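# Independent character-level oracles and small generators used across the
# suite. The oracles deliberately avoid the package's own code paths.

# character-by-character reverse complement (RNA alphabet)
oracle_revcomp <- function(x) {
  comp <- c(A = "U", C = "G", G = "C", U = "A", N = "N")
  paste(rev(comp[strsplit(x, "", fixed = TRUE)[[1L]]]), collapse = "")
}

# brute-force positional score: walk the spacer summing table lookups
oracle_score <- function(spacer, g_bonus = c(60, 60),
                         c_pen = c(`1` = -60, `2` = -60, `3` = -50,
                                   `4` = -40, `11` = -5, `12` = -5,
                                   `15` = -5, `16` = -5, `17` = -5)) {
  ch <- strsplit(chartr("T", "U", toupper(spacer)), "", fixed = TRUE)[[1L]]
  total <- 0
  for (i in seq_along(ch)) {
    if (ch[i] == "G" && i <= 2L) total <- total + g_bonus[i]
    key <- as.character(i)
    if (ch[i] == "C" && key %in% names(c_pen)) total <- total + c_pen[[key]]
  }
  total
}

rand_seq <- function(len, bases = c("A", "C", "G", "U")) {
  paste(sample(bases, len, replace = TRUE), collapse = "")
}

rand_spacer <- function() rand_seq(30L)

# all-windows Hamming off-target oracle (sense strand, windows with N skipped)
oracle_scan <- function(spacer, txs, max_mm) {
  rc <- oracle_revcomp(chartr("T", "U", toupper(spacer)))
  rcv <- strsplit(rc, "", fixed = TRUE)[[1L]]
  out <- NULL
  for (id in names(txs)) {
    tv <- strsplit(chartr("T", "U", toupper(txs[[id]])), "",
                   fixed = TRUE)[[1L]]
    n <- length(tv)
    if (n < 30L) next
    for (s in seq_len(n - 29L)) {
      win <- tv[s:(s + 29L)]
      if (any(win == "N")) next
      mm <- sum(win != rcv)
      if (mm <= max_mm)
        out <- rbind(out, data.frame(transcript_id = id, start = s,
                                     mismatch_count = mm,
                                     stringsAsFactors = FALSE))
    }
  }
  if (is.null(out))
    out <- data.frame(transcript_id = character(0), start = integer(0),
                      mismatch_count = integer(0))
  out[order(out$mismatch_count, out$transcript_id, out$start), ,
      drop = FALSE]
}

write_tmp_fasta <- function(records, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "tmp.fasta")
  writeLines(unlist(lapply(names(records), function(id)
    c(paste0(">", id), records[[id]]))), path)
  path
}
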