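#' Positional nucleotide matrix for a spacer cohort
#'
#' A 4 x L matrix (rows A, C, G, U) of per-position nucleotide probabilities
#' (\code{kind = "probability"}: columns sum to 1) or of differences from a
#' baseline composition (\code{kind = "delta"}: columns sum to 0).
#'
#' @slot values numeric 4 x L matrix, rownames A/C/G/U.
#' @slot kind \code{"probability"} or \code{"delta"}.
#' @slot n integer(1), cohort size the matrix was computed from.
#' @slot baseline numeric(4) baseline composition used for delta matrices
#'   (NA for probability matrices).
#' @export
setClass("PositionMatrix",
         representation(values = "matrix", kind = "character", n = "integer",
                        baseline = "numeric"))

setValidity("PositionMatrix", function(object) {
  if (!identical(rownames(object@values), .RNA_BASES))
    return("values must have rownames A, C, G, U")
  if (!(object@kind %in% c("probability", "delta")))
    return("kind must be \"probability\" or \"delta\"")
  cs <- colSums(object@values)
  if (object@kind == "probability") {
    if (any(abs(cs - 1) > 1e-9)) return("probability columns must sum to 1")
    if (any(object@values < -1e-12)) return("probabilities must be >= 0")
  } else if (any(abs(cs) > 1e-9)) {
    return("delta columns must sum to 0")
  }
  TRUE
})

#' @rdname PositionMatrix-accessors
#' @export
setGeneric("matrixValues", function(x) standardGeneric("matrixValues"))
#' @rdname PositionMatrix-accessors
#' @export
setGeneric("matrixKind", function(x) standardGeneric("matrixKind"))
#' @rdname PositionMatrix-accessors
#' @export
setGeneric("cohortSize", function(x) standardGeneric("cohortSize"))

#' Accessors for PositionMatrix
#'
#' @param x A \linkS4class{PositionMatrix}.
#' @return \code{matrixValues}: the 4 x L numeric matrix;
#'   \code{matrixKind}: character(1); \code{cohortSize}: integer(1).
#' @name PositionMatrix-accessors
NULL

#' @rdname PositionMatrix-accessors
#' @export
setMethod("matrixValues", "PositionMatrix", function(x) x@values)
#' @rdname PositionMatrix-accessors
#' @export
setMethod("matrixKind", "PositionMatrix", function(x) x@kind)
#' @rdname PositionMatrix-accessors
#' @export
setMethod("cohortSize", "PositionMatrix", function(x) x@n)

setMethod("show", "PositionMatrix", function(object) {
  cat(sprintf("PositionMatrix (%s, n = %d, %d positions)\n", object@kind,
              object@n, ncol(object@values)))
  print(round(object@values[, seq_len(min(8L, ncol(object@values))),
                            drop = FALSE], 3))
  if (ncol(object@values) > 8L) cat("  ...\n")
})

.cohort_spacers <- function(spacers) {
  s <- .to_rna_chr(toupper(
    if (is.data.frame(spacers)) spacers$spacer else spacers))
  if (!length(s)) stop("cohort is empty: need at least one spacer")
  if (length(unique(nchar(s))) != 1L)
    stop("cohort spacers must all have the same length")
  s
}

#' Position weight matrix of a spacer cohort
#'
#' Entry (b, i) is the fraction of cohort members carrying base b at
#' position i.
#'
#' @param spacers character vector of equal-length sequences (or a
#'   data.frame with a \code{spacer} column).
#' @return A \linkS4class{PositionMatrix} of kind \code{"probability"}.
#' @examples
#' pwm(c("GGAA", "GGCA", "GGAU"))
#' @export
pwm <- function(spacers) {
  s <- .cohort_spacers(spacers)
  chm <- .spacer_char_matrix(s)
  n <- length(s)
  vals <- vapply(seq_len(nrow(chm)), function(i)
    tabulate(match(chm[i, ], .RNA_BASES), nbins = 4L), numeric(4L)) / n
  rownames(vals) <- .RNA_BASES
  new("PositionMatrix", values = vals, kind = "probability", n = n,
      baseline = rep(NA_real_, 4L))
}

#' Delta nucleotide probabilities of a cohort
#'
#' Per-position nucleotide probability minus a baseline composition, so a
#' positive entry marks enrichment of that base at that position relative
#' to baseline. The default baseline is the cohort's own pooled nucleotide
#' frequency over all positions; \code{"uniform"} uses 0.25 everywhere; a
#' custom baseline is a numeric vector of 4 probabilities (A, C, G, U)
#' summing to 1.
#'
#' @inheritParams pwm
#' @param baseline \code{"cohort_mean"}, \code{"uniform"}, or numeric(4).
#' @return A \linkS4class{PositionMatrix} of kind \code{"delta"} whose
#'   columns sum to 0; the baseline used is stored in the \code{baseline}
#'   slot.
#' @export
deltaProbabilities <- function(spacers, baseline = "cohort_mean") {
  p <- pwm(spacers)
  if (is.character(baseline)) {
    baseline <- match.arg(baseline, c("cohort_mean", "uniform"))
    b <- if (baseline == "uniform") rep(0.25, 4L) else rowMeans(p@values)
  } else {
    b <- as.numeric(baseline)
    if (length(b) != 4L || abs(sum(b) - 1) > 1e-9)
      stop("custom baseline must be 4 probabilities (A, C, G, U) summing to 1")
  }
  names(b) <- .RNA_BASES
  new("PositionMatrix", values = p@values - b, kind = "delta", n = p@n,
      baseline = b)
}

#' Split an efficiency table into potency cohorts
#'
#' Records with silencing efficiency strictly above \code{potentThr} (90\%)
#' are the potent cohort; records strictly below \code{ineffectiveThr}
#' (50\%) are the ineffective cohort; records in between (boundaries
#' included) are excluded from analysis.
#'
#' @param records data.frame with at least \code{spacer} and
#'   \code{efficiency} (percent, in [0, 100]) columns.
#' @param potentThr,ineffectiveThr percent thresholds.
#' @return named list of data.frames: \code{potent}, \code{ineffective},
#'   \code{excluded} (an exhaustive, disjoint partition of the rows).
#' @examples
#' tab <- data.frame(spacer = strrep("A", 30), efficiency = c(95, 92, 70, 40))
#' vapply(splitCohorts(tab), nrow, integer(1))  # 2, 1, 1
#' @export
splitCohorts <- function(records, potentThr = 90, ineffectiveThr = 50) {
  eff <- records$efficiency
  if (is.null(eff)) stop("records must have an 'efficiency' column")
  if (anyNA(eff) || any(eff < 0 | eff > 100))
    stop("efficiencies must lie in [0, 100]")
  list(potent = records[eff > potentThr, , drop = FALSE],
       ineffective = records[eff < ineffectiveThr, , drop = FALSE],
       excluded = records[eff >= ineffectiveThr & eff <= potentThr, ,
                          drop = FALSE])
}

#' Nucleotide composition of protospacer-flanking sequences
#'
#' Positional nucleotide probabilities of the 4-nt target regions
#' immediately upstream and downstream of the protospacer, used to test for
#' a protospacer-flanking sequence (PFS) requirement. Records without both
#' flanks of the expected length are skipped with a warning.
#'
#' @param records data.frame with \code{flank_up} and \code{flank_down}
#'   columns.
#' @param flankLen expected flank length (4).
#' @return list of two \linkS4class{PositionMatrix} objects,
#'   \code{upstream} and \code{downstream}; \code{cohortSize} reports the
#'   number of records used.
#' @export
pfsMatrices <- function(records, flankLen = 4L) {
  up <- as.character(records$flank_up %||% character(0))
  dn <- as.character(records$flank_down %||% character(0))
  ok <- !is.na(up) & !is.na(dn) & nchar(up) == flankLen &
    nchar(dn) == flankLen
  if (!any(ok)) stop("no records with both ", flankLen, "-nt flanks")
  if (any(!ok))
    warning(sum(!ok), " record(s) without complete flanks skipped")
  list(upstream = pwm(up[ok]), downstream = pwm(dn[ok]))
}

#' Evaluate consensus-motif predictions against measured efficiencies
#'
#' Classifies every spacer with \code{classifier} and reports, for the
#' spacers predicted potent, the fraction whose measured efficiency exceeds
#' \code{potentThr} (and conversely, for those predicted ineffective, the
#' fraction below \code{ineffectiveThr}), together with a confusion table
#' of predicted class against measured cohort.
#'
#' @param records data.frame with \code{spacer} and \code{efficiency}.
#' @param potentThr,ineffectiveThr percent thresholds (as in
#'   \code{\link{splitCohorts}}).
#' @param classifier vectorised function spacer -> class label (default
#'   \code{\link{classifySpacer}}).
#' @return list with \code{potent_accuracy}, \code{ineffective_accuracy},
#'   \code{n_predicted_potent}, \code{n_predicted_ineffective} and
#'   \code{confusion} (predicted x measured table).
#' @export
evaluatePredictions <- function(records, potentThr = 90,
                                ineffectiveThr = 50,
                                classifier = classifySpacer) {
  if (!NROW(records)) stop("no records to evaluate")
  eff <- records$efficiency
  if (is.null(eff) || anyNA(eff) || any(eff < 0 | eff > 100))
    stop("records must carry efficiencies in [0, 100]")
  pred <- classifier(records$spacer)
  measured <- ifelse(eff > potentThr, "potent",
                     ifelse(eff < ineffectiveThr, "ineffective", "excluded"))
  is_pp <- pred == "predicted_potent"
  is_pi <- pred == "predicted_ineffective"
  list(potent_accuracy = if (any(is_pp)) mean(eff[is_pp] > potentThr)
       else NA_real_,
       ineffective_accuracy = if (any(is_pi)) mean(eff[is_pi] < ineffectiveThr)
       else NA_real_,
       n_predicted_potent = sum(is_pp),
       n_predicted_ineffective = sum(is_pi),
       confusion = table(predicted = pred, measured = measured))
}

#' Pearson correlation of efficiency against a precomputed covariate
#'
#' Convenience wrapper for correlating measured silencing efficiency with a
#' per-spacer covariate column (for example a folding energy or nucleotide
#' content computed elsewhere).
#'
#' @param records data.frame with \code{efficiency} and the covariate.
#' @param column covariate column name.
#' @return list with \code{r}, \code{p_value} and \code{n}.
#' @export
covariateCorrelation <- function(records, column) {
  x <- records[[column]]
  if (is.null(x)) stop("no column '", column, "' in records")
  ct <- stats::cor.test(records$efficiency, x, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value,
       n = sum(stats::complete.cases(records$efficiency, x)))
}

#' Write a PositionMatrix as TSV
#'
#' Base-labelled rows, one column per position.
#'
#' @param pm A \linkS4class{PositionMatrix}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writePositionMatrix <- function(pm, path) {
  m <- matrixValues(pm)
  df <- data.frame(base = rownames(m), m, check.names = FALSE)
  colnames(df) <- c("base", sprintf("pos%d", seq_len(ncol(m))))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
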