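#' Single-nucleotide tiled spacer candidates for one target
#'
#' Every 30-nt window of the sense target is tiled with step 1; the candidate
#' spacer is the reverse complement of the window (the spacer base-pairs the
#' transcript), so spacer position 1 (its 5' end) pairs with the last base of
#' the window. Windows containing N and spacers carrying a poly-T
#' transcription-termination signal are flagged as not retained.
#'
#' @slot targetId character(1), id of the tiled target.
#' @slot targetSeq character(1), target sequence in the RNA alphabet.
#' @slot spacerLen integer(1), spacer length (30 by default).
#' @slot candidates \linkS4class{DataFrame} with columns \code{start}
#'   (1-based window start on the target), \code{end} (1-based inclusive),
#'   \code{spacer} (RNA), \code{retained} (logical) and \code{filterReason}
#'   (\code{"none"}, \code{"polyT"} or \code{"ambiguous_base"}).
#' @export
setClass("SpacerCandidates",
         representation(targetId = "character", targetSeq = "character",
                        spacerLen = "integer", candidates = "DataFrame"))

setValidity("SpacerCandidates", function(object) {
  need <- c("start", "end", "spacer", "retained", "filterReason")
  if (!all(need %in% colnames(object@candidates)))
    return(paste("candidates must have columns:", paste(need, collapse = ", ")))
  cd <- object@candidates
  if (nrow(cd) && any(cd$end - cd$start + 1L != object@spacerLen))
    return("window width must equal spacerLen")
  TRUE
})

#' @rdname SpacerCandidates-accessors
#' @export
setGeneric("candidates", function(x) standardGeneric("candidates"))
#' @rdname SpacerCandidates-accessors
#' @export
setGeneric("retainedCandidates", function(x) standardGeneric("retainedCandidates"))
#' @rdname SpacerCandidates-accessors
#' @export
setGeneric("spacerLen", function(x) standardGeneric("spacerLen"))
#' @rdname SpacerCandidates-accessors
#' @export
setGeneric("targetId", function(x) standardGeneric("targetId"))

#' Accessors for SpacerCandidates
#'
#' @param x A \linkS4class{SpacerCandidates}.
#' @return \code{candidates} returns the full candidate table,
#'   \code{retainedCandidates} the rows passing all filters, \code{spacerLen}
#'   and \code{targetId} the corresponding slots, \code{length} the number of
#'   candidates.
#' @name SpacerCandidates-accessors
NULL

#' @rdname SpacerCandidates-accessors
#' @export
setMethod("candidates", "SpacerCandidates", function(x) x@candidates)
#' @rdname SpacerCandidates-accessors
#' @export
setMethod("retainedCandidates", "SpacerCandidates",
          function(x) x@candidates[x@candidates$retained, , drop = FALSE])
#' @rdname SpacerCandidates-accessors
#' @export
setMethod("spacerLen", "SpacerCandidates", function(x) x@spacerLen)
#' @rdname SpacerCandidates-accessors
#' @export
setMethod("targetId", "SpacerCandidates", function(x) x@targetId)
#' @rdname SpacerCandidates-accessors
#' @export
setMethod("length", "SpacerCandidates", function(x) nrow(x@candidates))

setMethod("show", "SpacerCandidates", function(object) {
  cd <- object@candidates
  cat(sprintf("SpacerCandidates for '%s' (%d nt target)\n",
              object@targetId, nchar(object@targetSeq)))
  cat(sprintf("  %d candidates of %d nt: %d retained, %d polyT, %d ambiguous\n",
              nrow(cd), object@spacerLen, sum(cd$retained),
              sum(cd$filterReason == "polyT"),
              sum(cd$filterReason == "ambiguous_base")))
})

#' Poly-T transcription-termination filter
#'
#' A spacer is removed when, written in the DNA alphabet, it contains a run
#' of four or more consecutive T bases: transcribed from a U6 cassette such a
#' run acts as an RNA polymerase III termination signal and would yield a
#' premature crRNA. Runs of exactly three T are permitted.
#'
#' @param spacer character vector of spacer sequences (DNA or RNA alphabet).
#' @return logical vector: \code{TRUE} where the spacer must be removed.
#' @examples
#' polyTFilter(c("AAAAUUUUAA", "AAAUUUAAAA"))  # TRUE, FALSE
#' @export
polyTFilter <- function(spacer) {
  grepl("TTTT", .to_dna_chr(toupper(spacer)), fixed = TRUE)
}

#' Generate all single-nucleotide tiled spacer candidates
#'
#' Tiles the sense strand of \code{target} with windows of \code{spacerLen}
#' at single-base steps; each candidate spacer is the reverse complement of
#' its window, reported 5' to 3' in the RNA alphabet. A target of length L
#' yields exactly L - spacerLen + 1 candidates, ordered by window start.
#' Windows containing N are flagged \code{ambiguous_base}; remaining spacers
#' go through \code{\link{polyTFilter}}.
#'
#' @param target A \linkS4class{NucleotideSeq} (DNA or RNA) or character(1).
#' @param spacerLen spacer length; 30 for PspCas13b.
#' @return A \linkS4class{SpacerCandidates}.
#' @examples
#' sc <- generateCandidates(NucleotideSeq(strrep("ACGG", 25), id = "t"))
#' length(sc)  # 100 - 30 + 1 = 71
#' @export
generateCandidates <- function(target, spacerLen = 30L) {
  if (!is(target, "NucleotideSeq")) target <- NucleotideSeq(target)
  spacerLen <- as.integer(spacerLen)
  rna <- .to_rna_chr(target@residues)
  L <- nchar(rna)
  if (L < spacerLen)
    stop(sprintf("target '%s' (%d nt) is shorter than the spacer length (%d nt)",
                 target@id, L, spacerLen))
  starts <- seq_len(L - spacerLen + 1L)
  ends <- starts + spacerLen - 1L
  windows <- substring(rna, starts, ends)
  ## spacer_i = revcomp(window_i) is a substring of the reverse-complemented
  ## target, which avoids reverse-complementing every window separately
  rc <- .revcomp_chr(rna, "RNA")
  spacers <- substring(rc, L - ends + 1L, L - starts + 1L)
  has_n <- grepl("N", windows, fixed = TRUE)
  polyt <- !has_n & polyTFilter(spacers)
  reason <- rep("none", length(starts))
  reason[polyt] <- "polyT"
  reason[has_n] <- "ambiguous_base"
  cd <- S4Vectors::DataFrame(start = starts, end = ends, spacer = spacers,
                             retained = !has_n & !polyt,
                             filterReason = reason)
  new("SpacerCandidates", targetId = target@id, targetSeq = rna,
      spacerLen = spacerLen, candidates = cd)
}

#' Candidate table as a plain data.frame
#'
#' Flattens a \linkS4class{SpacerCandidates} into the TSV dialect used by
#' the command-line layer. Coordinates are 1-based inclusive.
#'
#' @param x A \linkS4class{SpacerCandidates}.
#' @return data.frame with columns \code{target_id}, \code{start_1based},
#'   \code{end_1based}, \code{spacer_seq}, \code{retained},
#'   \code{filter_reason}.
#' @export
asCandidateTable <- function(x) {
  stopifnot(is(x, "SpacerCandidates"))
  cd <- x@candidates
  data.frame(target_id = rep(x@targetId, nrow(cd)),
             start_1based = cd$start, end_1based = cd$end,
             spacer_seq = cd$spacer, retained = cd$retained,
             filter_reason = cd$filterReason,
             stringsAsFactors = FALSE)
}

#' The bundled direct-repeat scaffold
#'
#' Returns the 36-nt direct-repeat sequence shipped with the package.
#' PspCas13b carries the direct repeat 3' of the spacer, so a full crRNA is
#' spacer + direct repeat (30 + 36 = 66 nt). The bundled sequence is a
#' synthetic stand-in of the correct length (see
#' \code{inst/extdata/direct_repeat_synthetic.fasta}); substitute the
#' repeat of your expression system for cloning-ready output.
#'
#' @return A \linkS4class{NucleotideSeq} of 36 nt (RNA).
#' @export
directRepeatSeq <- function() {
  path <- system.file("extdata", "direct_repeat_synthetic.fasta",
                      package = "cas13design", mustWork = TRUE)
  toRNA(readFasta(path)[[1L]])
}

#' Assemble a full crRNA from a spacer and a direct repeat
#'
#' Concatenates the spacer (5') with the direct repeat (3'), the PspCas13b
#' arrangement. With the default 30-nt spacer and 36-nt repeat the crRNA is
#' 66 nt; a 31-nt 5'-G insertion rescue variant yields 67 nt.
#'
#' @param spacer character(1) or \linkS4class{NucleotideSeq}, normally 30 nt.
#' @param directRepeat direct repeat sequence; defaults to the bundled
#'   scaffold. May be the empty string.
#' @param checkLength error when the spacer is not 30 nt. Set \code{FALSE}
#'   for insertion rescue variants (31 nt) or non-standard designs.
#' @return A \linkS4class{NucleotideSeq} (RNA) named after the spacer.
#' @export
assembleCrRNA <- function(spacer, directRepeat = directRepeatSeq(),
                          checkLength = TRUE) {
  sp_id <- if (is(spacer, "NucleotideSeq")) seqId(spacer) else "crRNA"
  sp <- toRNA(if (is(spacer, "NucleotideSeq")) residues(spacer) else spacer)
  dr <- toRNA(if (is(directRepeat, "NucleotideSeq"))
    residues(directRepeat) else as.character(directRepeat))
  if (checkLength && nchar(sp) != 30L)
    stop("spacer is ", nchar(sp),
         " nt, expected 30; use checkLength = FALSE to override")
  NucleotideSeq(paste0(sp, dr), id = sp_id, alphabet = "RNA")
}
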