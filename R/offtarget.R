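#' Off-target categorisation thresholds
#'
#' Mismatch-count cut-offs for categorising complementary windows found in a
#' transcriptome. With up to four mismatches a window is likely silenced
#' (mismatch tolerance extends to four scattered mismatches); with five or
#' more the guide is likely to lose silencing activity; above fifteen the
#' off-target effect is considered nonexistent and the window is not
#' reported by default.
#'
#' @slot silencingLossMinMm integer(1): smallest mismatch count at which
#'   silencing is likely lost (default 5).
#' @slot nonexistentMinMm integer(1): smallest mismatch count considered a
#'   nonexistent off-target (default 16, i.e. "greater than 15").
#' @export
setClass("OffTargetThresholds",
         representation(silencingLossMinMm = "integer",
                        nonexistentMinMm = "integer"))

setValidity("OffTargetThresholds", function(object) {
  a <- object@silencingLossMinMm
  b <- object@nonexistentMinMm
  if (a <= 0L || a > b)
    return("need 0 < silencingLossMinMm <= nonexistentMinMm")
  TRUE
})

#' @rdname OffTargetThresholds-class
#' @param silencingLossMinMm,nonexistentMinMm see slot documentation.
#' @return \code{offTargetThresholds} returns an
#'   \linkS4class{OffTargetThresholds}.
#' @export
offTargetThresholds <- function(silencingLossMinMm = 5L,
                                nonexistentMinMm = 16L) {
  new("OffTargetThresholds",
      silencingLossMinMm = as.integer(silencingLossMinMm),
      nonexistentMinMm = as.integer(nonexistentMinMm))
}

setMethod("show", "OffTargetThresholds", function(object) {
  cat(sprintf(
    "OffTargetThresholds: likely_silenced <= %d mm, unlikely %d-%d mm, nonexistent > %d mm\n",
    object@silencingLossMinMm - 1L, object@silencingLossMinMm,
    object@nonexistentMinMm - 1L, object@nonexistentMinMm - 1L))
})

#' Categorise an off-target window by mismatch count
#'
#' @param mm integer vector of mismatch counts (>= 0).
#' @param thresholds An \linkS4class{OffTargetThresholds}.
#' @return character vector in \code{likely_silenced},
#'   \code{unlikely_silenced}, \code{nonexistent}.
#' @examples
#' categorizeMismatches(c(0, 4, 5, 15, 16))
#' @export
categorizeMismatches <- function(mm, thresholds = offTargetThresholds()) {
  mm <- as.integer(mm)
  if (anyNA(mm) || any(mm < 0L)) stop("mismatch counts must be >= 0")
  ifelse(mm < thresholds@silencingLossMinMm, "likely_silenced",
         ifelse(mm < thresholds@nonexistentMinMm, "unlikely_silenced",
                "nonexistent"))
}

#' Count spacer-target mismatches in one window
#'
#' A transcript window (sense orientation) is a perfect target when it
#' equals the reverse complement of the spacer; spacer position i (1 = 5'
#' end) pairs with window position L - i + 1. Mismatch positions are
#' reported in spacer coordinates. N in the window never pairs.
#'
#' @param spacer character(1) or \linkS4class{NucleotideSeq}.
#' @param window character(1) or \linkS4class{NucleotideSeq} of the same
#'   length, sense strand of the transcript.
#' @return list with \code{count} (integer) and \code{positions} (sorted
#'   integer vector, spacer coordinates).
#' @examples
#' sp <- strrep("A", 30)
#' countMismatches(sp, revComp(sp))$count       # 0
#' countMismatches(sp, strrep("A", 30))$count   # 30 (A cannot pair A)
#' @export
countMismatches <- function(spacer, window) {
  sp <- toRNA(if (is(spacer, "NucleotideSeq")) residues(spacer) else spacer)
  win <- toRNA(if (is(window, "NucleotideSeq")) residues(window) else window)
  L <- nchar(sp)
  if (nchar(win) != L)
    stop("spacer (", L, " nt) and window (", nchar(win),
         " nt) must have equal length")
  rc <- .revcomp_chr(sp, "RNA")
  a <- strsplit(rc, "", fixed = TRUE)[[1L]]
  b <- strsplit(win, "", fixed = TRUE)[[1L]]
  miss_win <- which(a != b | b == "N")
  positions <- sort(L - miss_win + 1L)
  list(count = length(positions), positions = positions)
}

## normalise a transcriptome argument to a named character vector (RNA)
.as_transcriptome <- function(transcriptome) {
  if (is(transcriptome, "NucleotideSeq")) transcriptome <- list(transcriptome)
  if (is.list(transcriptome)) {
    stats::setNames(vapply(transcriptome, function(s) .to_rna_chr(residues(s)),
                           character(1)),
                    vapply(transcriptome, seqId, character(1)))
  } else if (is.character(transcriptome)) {
    if (is.null(names(transcriptome)))
      names(transcriptome) <- sprintf("tx%d", seq_along(transcriptome))
    vapply(transcriptome, function(x) .to_rna_chr(toupper(x)), character(1))
  } else {
    stop("transcriptome must be a list of NucleotideSeq or a named character vector")
  }
}

## mismatch count of rc (length L) against every window of tx; windows
## containing N get NA_integer_
.window_mismatch_profile <- function(rc_chars, tx) {
  L <- length(rc_chars)
  tv <- strsplit(tx, "", fixed = TRUE)[[1L]]
  n <- length(tv)
  if (n < L) return(integer(0))
  W <- n - L + 1L
  mm <- integer(W)
  for (k in seq_len(L))
    mm <- mm + (tv[k:(W + k - 1L)] != rc_chars[k])
  isN <- cumsum(tv == "N")
  hasN <- (isN[L:n] - c(0L, isN[seq_len(W - 1L)])) > 0L
  mm[hasN] <- NA_integer_
  mm
}

.empty_hits <- function() {
  S4Vectors::DataFrame(transcript_id = character(0), start = integer(0),
                       end = integer(0), mismatch_count = integer(0),
                       mismatch_positions = character(0),
                       percent_match = numeric(0), category = character(0),
                       tolerance_label = character(0))
}

#' Scan a transcriptome for off-target windows of a spacer
#'
#' Ungapped (Hamming) scan of the sense strand of every transcript for
#' windows complementary to the spacer with at most \code{maxReportMm}
#' mismatches. Windows above the cap form the "nonexistent" class and are
#' suppressed. Two equivalent search paths are provided: a pigeonhole-seeded
#' scan (the reverse complement of the spacer is partitioned into
#' \code{maxReportMm + 1} exact seeds looked up across the transcripts, so
#' any window within the cap must contain one seed exactly) and a full
#' sliding-window count. Seeding requires seeds of at least 3 nt
#' (\code{maxReportMm <= 9} for a 30-nt spacer); \code{method = "auto"}
#' uses seeding for caps up to 4 and the sliding window otherwise.
#'
#' Hits with up to 4 mismatches are additionally annotated with the
#' mismatch-tolerance class of their mismatch pattern
#' (\code{\link{classifyMismatchPattern}}), refining 3-4-mismatch hits into
#' tolerated / partial / lost.
#'
#' @param spacer character(1) or \linkS4class{NucleotideSeq}, 30 nt, no N.
#' @param transcriptome list of \linkS4class{NucleotideSeq} (e.g. from
#'   \code{\link{readFasta}}) or a named character vector, sense strand.
#' @param thresholds An \linkS4class{OffTargetThresholds}.
#' @param maxReportMm report windows with at most this many mismatches
#'   (default 15; use 4 for a fast scan of the biologically actionable
#'   class).
#' @param method \code{"auto"}, \code{"seed"} or \code{"brute"}.
#' @return \linkS4class{DataFrame} with one row per reported window:
#'   \code{transcript_id}, \code{start}/\code{end} (1-based inclusive on
#'   the transcript), \code{mismatch_count}, \code{mismatch_positions}
#'   (comma-separated, spacer coordinates), \code{percent_match},
#'   \code{category}, \code{tolerance_label} (NA unless likely_silenced).
#'   Sorted by mismatch count, transcript id, then position.
#' @export
scanOffTargets <- function(spacer, transcriptome,
                           thresholds = offTargetThresholds(),
                           maxReportMm = 15L,
                           method = c("auto", "seed", "brute")) {
  method <- match.arg(method)
  sp <- toRNA(if (is(spacer, "NucleotideSeq")) residues(spacer) else spacer)
  L <- nchar(sp)
  if (L != 30L) stop("off-target scanning expects a 30-nt spacer")
  if (grepl("N", sp, fixed = TRUE)) stop("spacer must not contain N")
  maxReportMm <- as.integer(maxReportMm)
  txs <- .as_transcriptome(transcriptome)
  if (!length(txs)) {
    warning("empty transcriptome: no off-target windows to report")
    return(.empty_hits())
  }
  if (method == "auto")
    method <- if (maxReportMm <= 4L) "seed" else "brute"
  if (method == "seed" && L %/% (maxReportMm + 1L) < 3L)
    stop("seeded scan needs seeds of >= 3 nt (maxReportMm <= ",
         L %/% 3L - 1L, "); use method = \"brute\"")
  rc <- .revcomp_chr(sp, "RNA")
  rc_chars <- strsplit(rc, "", fixed = TRUE)[[1L]]

  hit_tx <- character(0); hit_start <- integer(0); hit_mm <- integer(0)
  if (method == "brute") {
    for (id in names(txs)) {
      mm <- .window_mismatch_profile(rc_chars, txs[[id]])
      keep <- which(!is.na(mm) & mm <= maxReportMm)
      hit_tx <- c(hit_tx, rep(id, length(keep)))
      hit_start <- c(hit_start, keep)
      hit_mm <- c(hit_mm, mm[keep])
    }
  } else {
    ## pigeonhole: cut rc into maxReportMm + 1 contiguous seeds; a window
    ## with <= maxReportMm mismatches matches at least one seed exactly
    nseed <- maxReportMm + 1L
    bounds <- floor(seq(0L, L, length.out = nseed + 1L))
    seed_start <- as.integer(bounds[-length(bounds)] + 1L)
    seed_end <- as.integer(bounds[-1L])
    for (id in names(txs)) {
      tx <- txs[[id]]
      n <- nchar(tx)
      if (n < L) next
      subj <- Biostrings::RNAString(tx)
      cand <- integer(0)
      for (j in seq_len(nseed)) {
        seed <- substr(rc, seed_start[j], seed_end[j])
        m <- Biostrings::start(Biostrings::matchPattern(seed, subj))
        cand <- c(cand, m - seed_start[j] + 1L)
      }
      cand <- sort(unique(cand[cand >= 1L & cand <= n - L + 1L]))
      if (!length(cand)) next
      tv <- strsplit(tx, "", fixed = TRUE)[[1L]]
      for (s0 in cand) {
        win <- tv[s0:(s0 + L - 1L)]
        if (any(win == "N")) next
        mm <- sum(win != rc_chars)
        if (mm <= maxReportMm) {
          hit_tx <- c(hit_tx, id)
          hit_start <- c(hit_start, s0)
          hit_mm <- c(hit_mm, mm)
        }
      }
    }
  }
  if (!length(hit_start)) return(.empty_hits())

  ord <- order(hit_mm, hit_tx, hit_start)
  hit_tx <- hit_tx[ord]; hit_start <- hit_start[ord]; hit_mm <- hit_mm[ord]
  pos_str <- character(length(hit_start))
  tol <- rep(NA_character_, length(hit_start))
  category <- categorizeMismatches(hit_mm, thresholds)
  for (i in seq_along(hit_start)) {
    win <- substr(txs[[hit_tx[i]]], hit_start[i], hit_start[i] + L - 1L)
    cm <- countMismatches(sp, win)
    pos_str[i] <- paste(cm$positions, collapse = ",")
    if (category[i] == "likely_silenced")
      tol[i] <- activityLabel(classifyMismatchPattern(cm$positions, L))
  }
  S4Vectors::DataFrame(transcript_id = hit_tx, start = hit_start,
                       end = hit_start + L - 1L, mismatch_count = hit_mm,
                       mismatch_positions = pos_str,
                       percent_match = (L - hit_mm) / L,
                       category = category, tolerance_label = tol)
}
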