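#' Position-specific scoring weights
#'
#' A 4 x L weight matrix (rows A, C, G, U; columns spacer positions 1..L from
#' the 5' end). The cumulative score of a spacer is the sum over positions of
#' the weight of the base observed there. The defaults encode the published
#' PspCas13b rules: a G at position 1 or 2 earns +60 each; a C at positions
#' 1-4 is penalised -60, -60, -50, -40; a C at the central positions 11, 12,
#' 15, 16 or 17 is penalised -5 each; everything else is 0. Under these
#' defaults the attainable score range is [-235, +120].
#'
#' @slot weights numeric matrix, 4 x spacerLength, rownames A/C/G/U.
#' @slot spacerLength integer(1).
#' @export
setClass("ScoringParams",
         representation(weights = "matrix", spacerLength = "integer"))

setValidity("ScoringParams", function(object) {
  if (!identical(rownames(object@weights), .RNA_BASES))
    return("weights must have rownames A, C, G, U")
  if (ncol(object@weights) != object@spacerLength)
    return("weights must have spacerLength columns")
  TRUE
})

#' Construct scoring parameters
#'
#' @param gBonus named numeric: position -> bonus for a G there.
#' @param cPenalty named numeric: position -> penalty for a C there.
#' @param spacerLength spacer length the weights apply to.
#' @return A \linkS4class{ScoringParams}.
#' @examples
#' scoringParams()  # published defaults
#' @export
scoringParams <- function(gBonus = c("1" = 60, "2" = 60),
                          cPenalty = c("1" = -60, "2" = -60, "3" = -50,
                                       "4" = -40, "11" = -5, "12" = -5,
                                       "15" = -5, "16" = -5, "17" = -5),
                          spacerLength = 30L) {
  spacerLength <- as.integer(spacerLength)
  w <- matrix(0, nrow = 4L, ncol = spacerLength,
              dimnames = list(.RNA_BASES, NULL))
  w["G", as.integer(names(gBonus))] <- gBonus
  w["C", as.integer(names(cPenalty))] <- cPenalty
  new("ScoringParams", weights = w, spacerLength = spacerLength)
}

#' @rdname scoringParams
#' @param x A \linkS4class{ScoringParams}.
#' @export
scoringWeights <- function(x) x@weights

setMethod("show", "ScoringParams", function(object) {
  nz <- which(object@weights != 0, arr.ind = TRUE)
  cat(sprintf("ScoringParams for %d-nt spacers (%d non-zero weights)\n",
              object@spacerLength, nrow(nz)))
  if (nrow(nz)) {
    ord <- order(nz[, "col"], nz[, "row"])
    nz <- nz[ord, , drop = FALSE]
    cat(paste(sprintf("  %s@%d: %+g", rownames(object@weights)[nz[, "row"]],
                      nz[, "col"], object@weights[nz]), collapse = "\n"), "\n")
  }
})

#' Read / write scoring weights as a YAML config
#'
#' The config has a \code{spacer_length} key and a \code{weights} mapping
#' base -> position -> weight; the bundled
#' \code{inst/extdata/scoring_weights.yaml} reproduces the defaults. Users
#' can override individual weights without touching code.
#'
#' @param path YAML file path.
#' @return \code{readScoringConfig} returns a \linkS4class{ScoringParams};
#'   \code{writeScoringConfig} returns \code{path} invisibly.
#' @export
readScoringConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  L <- as.integer(cfg$spacer_length %||% 30L)
  w <- matrix(0, nrow = 4L, ncol = L, dimnames = list(.RNA_BASES, NULL))
  for (base in names(cfg$weights)) {
    b <- toupper(chartr("T", "U", base))
    if (!b %in% .RNA_BASES) stop("unknown base in scoring config: ", base)
    ww <- cfg$weights[[base]]
    pos <- as.integer(names(ww))
    if (any(is.na(pos)) || any(pos < 1L) || any(pos > L))
      stop("scoring config positions must be integers in [1, ", L, "]")
    w[b, pos] <- as.numeric(unlist(ww))
  }
  new("ScoringParams", weights = w, spacerLength = L)
}

#' @rdname readScoringConfig
#' @param params A \linkS4class{ScoringParams}.
#' @export
writeScoringConfig <- function(params, path) {
  w <- params@weights
  by_base <- lapply(.RNA_BASES, function(b) {
    pos <- which(w[b, ] != 0)
    if (!length(pos)) return(NULL)
    stats::setNames(as.list(unname(w[b, pos])), as.character(pos))
  })
  names(by_base) <- .RNA_BASES
  by_base <- Filter(Negate(is.null), by_base)
  yaml::write_yaml(list(spacer_length = params@spacerLength,
                        weights = by_base), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-spacer score breakdown
#'
#' @slot spacer character(1), the scored spacer (RNA).
#' @slot perPosition \linkS4class{DataFrame} with \code{position},
#'   \code{base}, \code{contribution}.
#' @slot total numeric(1), cumulative score.
#' @slot motifClass consensus classification of the spacer (see
#'   \code{\link{classifySpacer}}).
#' @export
setClass("ScoreBreakdown",
         representation(spacer = "character", perPosition = "DataFrame",
                        total = "numeric", motifClass = "character"))

setValidity("ScoreBreakdown", function(object) {
  if (abs(object@total - sum(object@perPosition$contribution)) > 1e-9)
    return("total must equal the sum of per-position contributions")
  TRUE
})

#' @rdname ScoreBreakdown-accessors
#' @export
setGeneric("scoreTotal", function(x) standardGeneric("scoreTotal"))
#' @rdname ScoreBreakdown-accessors
#' @export
setGeneric("perPosition", function(x) standardGeneric("perPosition"))
#' @rdname ScoreBreakdown-accessors
#' @export
setGeneric("motifClass", function(x) standardGeneric("motifClass"))

#' Accessors for ScoreBreakdown
#'
#' @param x A \linkS4class{ScoreBreakdown}.
#' @return \code{scoreTotal}: numeric(1); \code{perPosition}: DataFrame;
#'   \code{motifClass}: character(1).
#' @name ScoreBreakdown-accessors
NULL

#' @rdname ScoreBreakdown-accessors
#' @export
setMethod("scoreTotal", "ScoreBreakdown", function(x) x@total)
#' @rdname ScoreBreakdown-accessors
#' @export
setMethod("perPosition", "ScoreBreakdown", function(x) x@perPosition)
#' @rdname ScoreBreakdown-accessors
#' @export
setMethod("motifClass", "ScoreBreakdown", function(x) x@motifClass)

setMethod("show", "ScoreBreakdown", function(object) {
  cat(sprintf("ScoreBreakdown: %s\n  total %+g (%s)\n", object@spacer,
              object@total, object@motifClass))
  nz <- object@perPosition[object@perPosition$contribution != 0, , drop = FALSE]
  if (nrow(nz))
    cat(paste(sprintf("  pos %d (%s): %+g", nz$position, nz$base,
                      nz$contribution), collapse = "\n"), "\n")
})

.spacer_char_matrix <- function(spacers) {
  L <- unique(nchar(spacers))
  if (length(L) != 1L) stop("spacers must all have the same length")
  matrix(unlist(strsplit(spacers, "", fixed = TRUE), use.names = FALSE),
         nrow = L)
}

#' Cumulative scores for many spacers
#'
#' Vectorised scoring: each spacer's score is the sum of the positional
#' weights of its bases, 5'-anchored (weight column i applies to spacer
#' position i; positions beyond the weight table, e.g. position 31 of an
#' insertion rescue variant, contribute 0).
#'
#' @param spacers character vector of spacers (DNA or RNA; no N).
#' @param params A \linkS4class{ScoringParams}.
#' @return numeric vector of cumulative scores.
#' @export
scoreSpacers <- function(spacers, params = scoringParams()) {
  if (!length(spacers)) return(numeric(0))
  spacers <- .to_rna_chr(toupper(spacers))
  if (any(grepl("N", spacers, fixed = TRUE)))
    stop("spacers containing N cannot be scored")
  chm <- .spacer_char_matrix(spacers)
  L <- nrow(chm)
  bi <- match(chm, .RNA_BASES)
  if (anyNA(bi)) stop("spacers contain non-ACGT/U characters")
  Lw <- min(L, ncol(params@weights))
  bi <- matrix(bi, nrow = L)[seq_len(Lw), , drop = FALSE]
  idx <- cbind(as.vector(bi), rep(seq_len(Lw), times = ncol(bi)))
  colSums(matrix(params@weights[idx], nrow = Lw))
}

#' Score a single spacer with a per-position breakdown
#'
#' @param spacer character(1) or \linkS4class{NucleotideSeq}; normally 30 nt
#'   (31-nt insertion rescue variants are allowed and scored 5'-anchored).
#' @param params A \linkS4class{ScoringParams}.
#' @return A \linkS4class{ScoreBreakdown}.
#' @examples
#' scoreTotal(scoreSpacer(paste0("G", strrep("A", 29))))   # +60
#' scoreTotal(scoreSpacer(strrep("C", 30)))                # -235
#' @export
scoreSpacer <- function(spacer, params = scoringParams()) {
  sp <- .to_rna_chr(toupper(
    if (is(spacer, "NucleotideSeq")) residues(spacer) else spacer))
  if (length(sp) != 1L) stop("scoreSpacer() takes one spacer; see scoreSpacers()")
  L <- nchar(sp)
  if (L != params@spacerLength && L != params@spacerLength + 1L)
    stop("spacer is ", L, " nt; expected ", params@spacerLength,
         " (or +1 for an insertion variant)")
  chars <- strsplit(sp, "", fixed = TRUE)[[1L]]
  bi <- match(chars, .RNA_BASES)
  if (anyNA(bi)) stop("spacer contains characters outside A/C/G/U (N not allowed)")
  Lw <- min(L, ncol(params@weights))
  contrib <- numeric(L)
  contrib[seq_len(Lw)] <- params@weights[cbind(bi[seq_len(Lw)], seq_len(Lw))]
  new("ScoreBreakdown", spacer = sp,
      perPosition = S4Vectors::DataFrame(position = seq_len(L), base = chars,
                                         contribution = contrib),
      total = sum(contrib), motifClass = classifySpacer(sp))
}

#' Classify a spacer against the consensus motifs
#'
#' Potent spacers match the consensus G-G at positions 1-2 with no C at the
#' central positions 11, 12, 15, 16, 17. Ineffective spacers carry a C at
#' position 1 or 2 (the strongest penalties), or a C at six or more of the
#' nine penalised positions \{1, 2, 3, 4, 11, 12, 15, 16, 17\},
#' approximating the C-rich ineffective consensus. Everything else is
#' \code{indeterminate}; the numeric score lets users apply their own cut.
#'
#' @param spacer character vector of spacers (length >= 17 nt each).
#' @return character vector in \code{predicted_potent},
#'   \code{predicted_ineffective}, \code{indeterminate}.
#' @examples
#' classifySpacer(paste0("GG", strrep("A", 28)))  # predicted_potent
#' @export
classifySpacer <- function(spacer) {
  s <- .to_rna_chr(toupper(
    if (is(spacer, "NucleotideSeq")) residues(spacer) else spacer))
  if (any(nchar(s) < 17L)) stop("spacers must be at least 17 nt to classify")
  at <- function(p) substr(s, p, p)
  central <- c(11L, 12L, 15L, 16L, 17L)
  nine <- c(1L, 2L, 3L, 4L, central)
  c_central <- Reduce(`+`, lapply(central, function(p) at(p) == "C"))
  c_nine <- Reduce(`+`, lapply(nine, function(p) at(p) == "C"))
  potent <- at(1L) == "G" & at(2L) == "G" & c_central == 0L
  ineff <- at(1L) == "C" | at(2L) == "C" | c_nine >= 6L
  ifelse(potent, "predicted_potent",
         ifelse(ineff, "predicted_ineffective", "indeterminate"))
}

#' Rank retained spacer candidates by cumulative score
#'
#' Stable sort by score descending; ties are broken by window start
#' ascending, so among equally scored spacers the 5'-most design comes
#' first. Ranks are 1-based.
#'
#' @param x A \linkS4class{SpacerCandidates}, or a data.frame with columns
#'   \code{spacer} and \code{start} (plus optional \code{target_id}).
#' @param params A \linkS4class{ScoringParams}.
#' @return data.frame with columns \code{rank}, \code{target_id},
#'   \code{spacer_seq}, \code{start_1based}, \code{end_1based}, \code{score},
#'   \code{motif_class}. Empty (with a warning) when no candidate is retained.
#' @export
rankSpacers <- function(x, params = scoringParams()) {
  if (is(x, "SpacerCandidates")) {
    cd <- as.data.frame(retainedCandidates(x))
    cd$target_id <- rep(targetId(x), nrow(cd))
  } else {
    cd <- as.data.frame(x)
    if (is.null(cd$target_id)) cd$target_id <- rep("target", nrow(cd))
    if (is.null(cd$end)) cd$end <- cd$start + nchar(cd$spacer) - 1L
  }
  empty <- data.frame(rank = integer(0), target_id = character(0),
                      spacer_seq = character(0), start_1based = integer(0),
                      end_1based = integer(0), score = numeric(0),
                      motif_class = character(0), stringsAsFactors = FALSE)
  if (!nrow(cd)) {
    warning("no retained spacer candidates to rank")
    return(empty)
  }
  score <- scoreSpacers(cd$spacer, params)
  ord <- order(-score, cd$start)
  data.frame(rank = seq_along(ord), target_id = cd$target_id[ord],
             spacer_seq = cd$spacer[ord], start_1based = cd$start[ord],
             end_1based = cd$end[ord], score = score[ord],
             motif_class = classifySpacer(cd$spacer[ord]),
             stringsAsFactors = FALSE)
}

#' Design 5' G rescue variants of a spacer
#'
#' Ineffective spacers lacking a 5' G-rich motif can be rescued by forcing G
#' bases at the 5' end, at the cost of deliberate mismatches with the
#' target: \code{INS_G} prepends a G (31-nt spacer, one unpaired 5' base;
#' full 30-nt complementarity retained), \code{SUB_1G} substitutes position
#' 1 by G, and \code{SUB_12GG} substitutes positions 1-2 by G-G. Variants
#' identical to the input are omitted.
#'
#' @param spacer character(1) or \linkS4class{NucleotideSeq}, 30 nt.
#' @return data.frame with columns \code{variant}, \code{spacer_seq},
#'   \code{introduced_mismatches}.
#' @examples
#' rescueSpacer(paste0("CA", strrep("U", 28)))
#' @export
rescueSpacer <- function(spacer) {
  s <- .to_rna_chr(toupper(
    if (is(spacer, "NucleotideSeq")) residues(spacer) else spacer))
  if (nchar(s) != 30L) stop("rescue variants are defined for 30-nt spacers")
  tail28 <- substr(s, 3L, 30L)
  out <- data.frame(
    variant = c("INS_G", "SUB_1G", "SUB_12GG"),
    spacer_seq = c(paste0("G", s),
                   paste0("G", substr(s, 2L, 30L)),
                   paste0("GG", tail28)),
    introduced_mismatches = c(
      1L,
      as.integer(substr(s, 1L, 1L) != "G"),
      (substr(s, 1L, 1L) != "G") + (substr(s, 2L, 2L) != "G")),
    stringsAsFactors = FALSE)
  out[out$spacer_seq != s, , drop = FALSE]
}
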