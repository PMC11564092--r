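#' Activity call returned by the mismatch-tolerance classifier
#'
#' @slot label one of \code{TOLERATED}, \code{PARTIAL_LOSS}, \code{LOST}.
#' @slot ruleId name of the rule that produced the label.
#' @export
setClass("ActivityCall",
         representation(label = "character", ruleId = "character"))

setValidity("ActivityCall", function(object) {
  if (!(object@label %in% c("TOLERATED", "PARTIAL_LOSS", "LOST")))
    return("label must be TOLERATED, PARTIAL_LOSS or LOST")
  TRUE
})

.activity <- function(label, ruleId)
  new("ActivityCall", label = label, ruleId = ruleId)

#' @rdname ActivityCall-accessors
#' @export
setGeneric("activityLabel", function(x) standardGeneric("activityLabel"))
#' @rdname ActivityCall-accessors
#' @export
setGeneric("ruleId", function(x) standardGeneric("ruleId"))

#' Accessors for ActivityCall
#'
#' @param x An \linkS4class{ActivityCall}.
#' @return character(1).
#' @name ActivityCall-accessors
NULL

#' @rdname ActivityCall-accessors
#' @export
setMethod("activityLabel", "ActivityCall", function(x) x@label)
#' @rdname ActivityCall-accessors
#' @export
setMethod("ruleId", "ActivityCall", function(x) x@ruleId)

setMethod("show", "ActivityCall", function(object)
  cat(sprintf("%s (rule: %s)\n", object@label, object@ruleId)))

#' Consecutive-block tolerance rules
#'
#' Human-readable rule table for single consecutive mismatch blocks,
#' derived from the spacer-target mutagenesis outcomes. A block matches the
#' first row whose length range contains its length and whose positional
#' constraints (block start within [start_min, start_max], block end at most
#' end_max) hold. Rule ids carry the mutagenesis panel they encode;
#' \code{interp} marks placements not directly assayed, which inherit the
#' label of the tested span they fall inside (conservatively the worse label
#' when straddling two spans).
#'
#' The 30-nt table encodes: 3-nt blocks tolerated everywhere except
#' positions 1-3 (where loss tracks removal of the 5' G-G-G motif rather
#' than the mismatch itself); 4-nt blocks starting at positions 9-17 give
#' partial loss, elsewhere complete loss; 5-nt blocks within 6-15 or 26-30
#' give partial loss, elsewhere complete loss; blocks of 6 or more always
#' lose activity. The stricter 27-nt table reflects the exacerbated
#' intolerance of shortened spacers.
#'
#' @param spacerLen 30 (default rule set) or 27 (stricter short-spacer set).
#' @return data.frame with columns \code{rule_id}, \code{len_min},
#'   \code{len_max}, \code{start_min}, \code{start_max}, \code{end_max},
#'   \code{label}, \code{panel}.
#' @export
toleranceRules <- function(spacerLen = 30L) {
  spacerLen <- as.integer(spacerLen)
  if (spacerLen == 30L) {
    data.frame(
      rule_id = c("block_1_2", "block3_5prime", "block3_any",
                  "block4_central", "block4_other",
                  "block5_mid", "block5_3prime", "block5_other",
                  "block6_plus"),
      len_min = c(1L, 3L, 3L, 4L, 4L, 5L, 5L, 5L, 6L),
      len_max = c(2L, 3L, 3L, 4L, 4L, 5L, 5L, 5L, 30L),
      start_min = c(1L, 1L, 1L, 9L, 1L, 6L, 26L, 1L, 1L),
      start_max = c(30L, 1L, 30L, 17L, 30L, 11L, 26L, 30L, 30L),
      end_max = c(30L, 3L, 30L, 30L, 30L, 15L, 30L, 30L, 30L),
      label = c("TOLERATED", "LOST", "TOLERATED",
                "PARTIAL_LOSS", "LOST",
                "PARTIAL_LOSS", "PARTIAL_LOSS", "LOST", "LOST"),
      panel = c("single-substitution/interp", "5prime-3nt", "3nt-tiling",
                "4nt-tiling", "4nt-tiling",
                "5nt-tiling", "5nt-tiling", "5nt-tiling", "6nt-tiling"),
      stringsAsFactors = FALSE)
  } else if (spacerLen == 27L) {
    data.frame(
      rule_id = c("short_single_21", "short_single", "short_block3_22_24",
                  "short_block3_mid", "short_block3_central",
                  "short_block3_straddle", "short_block_other"),
      len_min = c(1L, 1L, 3L, 3L, 3L, 3L, 2L),
      len_max = c(1L, 1L, 3L, 3L, 3L, 3L, 27L),
      start_min = c(21L, 1L, 22L, 4L, 13L, 11L, 1L),
      start_max = c(21L, 27L, 22L, 10L, 19L, 12L, 27L),
      end_max = c(21L, 27L, 24L, 12L, 21L, 14L, 27L),
      label = c("PARTIAL_LOSS", "TOLERATED", "LOST",
                "PARTIAL_LOSS", "TOLERATED", "PARTIAL_LOSS", "LOST"),
      panel = c("27nt-single", "27nt-single/interp", "27nt-3nt",
                "27nt-3nt", "27nt-3nt", "27nt-interp", "27nt-interp"),
      stringsAsFactors = FALSE)
  } else {
    stop("no tolerance rule set for spacer length ", spacerLen,
         " (available: 30, 27)")
  }
}

#' @rdname toleranceRules
#' @param rules rule table as returned by \code{toleranceRules}.
#' @param path TSV path for serialisation.
#' @export
writeToleranceRules <- function(rules, path) {
  utils::write.table(rules, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname toleranceRules
#' @export
readToleranceRules <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    colClasses = c(rule_id = "character", len_min = "integer",
                                   len_max = "integer", start_min = "integer",
                                   start_max = "integer", end_max = "integer",
                                   label = "character", panel = "character"),
                    stringsAsFactors = FALSE)
}

## maximal runs of consecutive positions; returns list(start, end, len)
.mismatch_runs <- function(positions) {
  p <- sort(unique(as.integer(positions)))
  brk <- c(0L, which(diff(p) > 1L), length(p))
  starts <- p[brk[-length(brk)] + 1L]
  ends <- p[brk[-1L]]
  list(start = starts, end = ends, len = ends - starts + 1L)
}

.match_block_rule <- function(len, start, end, rules) {
  hit <- rules$len_min <= len & len <= rules$len_max &
    rules$start_min <= start & start <= rules$start_max &
    end <= rules$end_max
  if (!any(hit)) return(NULL)
  rules[which(hit)[1L], , drop = FALSE]
}

#' Classify a spacer-target mismatch pattern
#'
#' Maps a set of mismatched spacer positions (1 = 5' end) to a predicted
#' activity class, encoding the spacer mutagenesis outcomes. Rules are
#' applied in priority order:
#' \enumerate{
#'   \item no mismatch: \code{TOLERATED};
#'   \item a single consecutive block: looked up in the block rule table
#'     (\code{\link{toleranceRules}});
#'   \item scattered patterns (two or more maximal runs): up to four
#'     mismatches in runs of at most two, with no run of two or more
#'     touching positions 1-3, are \code{TOLERATED} (a single mismatch at
#'     positions 1-3 is permitted, as single 5' substitutions do not impair
#'     silencing); two or more runs of length 2-3 are \code{LOST}; five or
#'     more total mismatches are \code{LOST};
#'   \item anything else falls back to \code{LOST} (conservative default,
#'     \code{rule_id = "fallback"}).
#' }
#'
#' @param positions integer vector of mismatched spacer positions (may be
#'   empty), 1-based from the 5' end.
#' @param spacerLen spacer length (30, or 27 for the stricter short-spacer
#'   rule set where any scattered pattern of two or more mismatches loses
#'   activity).
#' @param rules block rule table; defaults to
#'   \code{toleranceRules(spacerLen)}.
#' @return An \linkS4class{ActivityCall}.
#' @examples
#' activityLabel(classifyMismatchPattern(c(28, 29, 30)))  # TOLERATED
#' activityLabel(classifyMismatchPattern(c(5, 6, 7, 8)))  # LOST
#' activityLabel(classifyMismatchPattern(c(9, 10, 11, 12)))  # PARTIAL_LOSS
## rule-engine core shared by the exported classifier and the enumerators;
## returns list(label, rule_id) without S4 overhead
.classify_pattern <- function(positions, spacerLen, rules) {
  if (!length(positions)) return(list(label = "TOLERATED", rule_id = "empty"))
  runs <- .mismatch_runs(positions)
  if (length(runs$start) == 1L) {
    m <- .match_block_rule(runs$len, runs$start, runs$end, rules)
    if (is.null(m)) return(list(label = "LOST", rule_id = "fallback"))
    return(list(label = m$label, rule_id = m$rule_id))
  }
  ## scattered: two or more maximal runs
  k <- length(positions)
  if (spacerLen == 27L)
    return(list(label = "LOST", rule_id = "short_scattered"))
  run2_touching_5prime <- any(runs$len >= 2L & runs$start <= 3L)
  if (k <= 4L && all(runs$len <= 2L) && !run2_touching_5prime)
    return(list(label = "TOLERATED", rule_id = "scattered_le4"))
  if (sum(runs$len >= 2L & runs$len <= 3L) >= 2L)
    return(list(label = "LOST", rule_id = "scattered_multi_runs"))
  if (k >= 5L)
    return(list(label = "LOST", rule_id = "scattered_ge5"))
  list(label = "LOST", rule_id = "fallback")
}

#' @export
classifyMismatchPattern <- function(positions, spacerLen = 30L,
                                    rules = toleranceRules(spacerLen)) {
  spacerLen <- as.integer(spacerLen)
  positions <- as.integer(positions)
  if (anyNA(positions)) stop("mismatch positions must be integers")
  if (anyDuplicated(positions)) stop("mismatch positions must be distinct")
  if (length(positions) && (min(positions) < 1L || max(positions) > spacerLen))
    stop("mismatch positions must lie in [1, ", spacerLen, "]")
  if (is.null(rules) || !nrow(rules))
    stop("empty tolerance rule table: the classifier is misconfigured")
  res <- .classify_pattern(positions, spacerLen, rules)
  .activity(res$label, res$rule_id)
}

#' Maximum number of tolerated scattered mismatches
#'
#' Enumerates scattered mismatch patterns (maximal runs of at most two,
#' avoiding the 5' positions 1-3) of increasing size and reports the largest
#' size for which at least one pattern is classified \code{TOLERATED} by the
#' rule engine. The answer is computed by enumeration, not read off a
#' constant.
#'
#' @inheritParams classifyMismatchPattern
#' @param maxK upper bound on the enumeration (enumeration stops at the
#'   first size with no tolerated pattern).
#' @return integer(1); 4 for the default 30-nt rules.
#' @export
maxToleratedScattered <- function(spacerLen = 30L,
                                  rules = toleranceRules(spacerLen),
                                  maxK = 6L) {
  if (is.null(rules) || !nrow(rules))
    stop("empty tolerance rule table: the classifier is misconfigured")
  spacerLen <- as.integer(spacerLen)
  pool <- 4:spacerLen
  best <- 0L
  for (k in seq_len(min(maxK, length(pool)))) {
    cmb <- utils::combn(pool, k)
    tol <- FALSE
    for (j in seq_len(ncol(cmb))) {
      p <- cmb[, j]
      ## runs <= 2 iff no three consecutive positions
      if (k >= 3L && any(p[-(1:2)] - p[seq_len(k - 2L)] == 2L)) next
      if (.classify_pattern(p, spacerLen, rules)$label == "TOLERATED") {
        tol <- TRUE
        break
      }
    }
    if (!tol) return(best)
    best <- k
  }
  best
}

#' Minimum spacer-target base pairing required for activity
#'
#' The spacer length minus the maximum number of tolerated scattered
#' mismatches: the number of paired bases the nuclease needs to activate.
#' For the 30-nt spacer this is 26.
#'
#' @inheritParams maxToleratedScattered
#' @return integer(1).
#' @export
minRequiredPairing <- function(spacerLen = 30L,
                               rules = toleranceRules(spacerLen)) {
  as.integer(spacerLen) - maxToleratedScattered(spacerLen, rules)
}

#' Classify a spacer truncation
#'
#' Truncations behave differently from mismatches: removing three or more
#' nucleotides from the 5' end abolishes silencing, whereas a 3-nt 3'
#' truncation is tolerated and longer 3' truncations (up to 15 nt) lose
#' activity gradually.
#'
#' @param end \code{"5prime"} or \code{"3prime"}.
#' @param nRemoved number of nucleotides removed (0 or more).
#' @param spacerLen spacer length before truncation.
#' @return An \linkS4class{ActivityCall}.
#' @examples
#' activityLabel(classifyTruncation("3prime", 3))  # TOLERATED
#' activityLabel(classifyTruncation("5prime", 3))  # LOST
#' @export
classifyTruncation <- function(end = c("5prime", "3prime"), nRemoved,
                               spacerLen = 30L) {
  end <- match.arg(end)
  nRemoved <- as.integer(nRemoved)
  if (is.na(nRemoved) || nRemoved < 0L || nRemoved > spacerLen)
    stop("nRemoved must be an integer in [0, ", spacerLen, "]")
  if (nRemoved == 0L) return(.activity("TOLERATED", "no_truncation"))
  if (end == "5prime") {
    if (nRemoved >= 3L) return(.activity("LOST", "trunc_5prime_ge3"))
    return(.activity("TOLERATED", "trunc_5prime_lt3"))
  }
  if (nRemoved <= 3L) return(.activity("TOLERATED", "trunc_3prime_le3"))
  if (nRemoved <= 15L) return(.activity("PARTIAL_LOSS", "trunc_3prime_gradual"))
  .activity("LOST", "trunc_3prime_gt15")
}
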