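#' Deterministic synthetic transcriptome
#'
#' Generates random transcripts at a requested GC fraction for testing the
#' design and off-target pipeline without downloads. All randomness is
#' driven by the explicit \code{seed} through a local RNG scope, so the
#' same arguments always produce byte-identical output and the caller's
#' random state is untouched.
#'
#' @param nTranscripts number of transcripts.
#' @param lengthRange integer(2), inclusive range of transcript lengths.
#' @param gcFraction target GC content in [0, 1].
#' @param seed integer seed.
#' @param alphabet \code{"DNA"} (default, as transcriptome FASTA usually
#'   ships) or \code{"RNA"}.
#' @param path optional FASTA path to write.
#' @return list of \linkS4class{NucleotideSeq} (ids \code{tx_001}, ...).
#' @examples
#' txs <- makeTranscriptome(3, c(100, 200), 0.5, seed = 1)
#' @export
makeTranscriptome <- function(nTranscripts = 50L,
                              lengthRange = c(500L, 3000L),
                              gcFraction = 0.5, seed = 1L,
                              alphabet = c("DNA", "RNA"), path = NULL) {
  alphabet <- match.arg(alphabet)
  nTranscripts <- as.integer(nTranscripts)
  if (gcFraction < 0 || gcFraction > 1)
    stop("gcFraction must lie in [0, 1]")
  if (lengthRange[1L] > lengthRange[2L] || lengthRange[1L] < 1L)
    stop("impossible length range")
  bases <- if (alphabet == "DNA") .DNA_BASES else .RNA_BASES
  probs <- c((1 - gcFraction) / 2, gcFraction / 2, gcFraction / 2,
             (1 - gcFraction) / 2)
  seqs <- withr::with_seed(as.integer(seed), {
    rng <- seq.int(lengthRange[1L], lengthRange[2L])
    lens <- if (!nTranscripts) integer(0)
    else if (length(rng) == 1L) rep(rng, nTranscripts)
    else sample(rng, nTranscripts, replace = TRUE)
    lapply(seq_len(nTranscripts), function(i)
      NucleotideSeq(paste(sample(bases, lens[i], replace = TRUE,
                                 prob = probs), collapse = ""),
                    id = sprintf("tx_%03d", i), alphabet = alphabet))
  })
  if (!is.null(path)) writeFasta(seqs, path)
  seqs
}

#' Plant an off-target site into a transcript
#'
#' Overwrites the transcript at \code{insertAt} with the reverse complement
#' of the spacer, mutated at the stated spacer positions so that the
#' resulting window's mismatch count is exactly
#' \code{length(mismatchPositions)}. Each mutated base is chosen
#' deterministically (the next base in A->C->G->U/T cyclic order after the
#' complementary base), so planting is a pure function of its arguments.
#'
#' @param transcript A \linkS4class{NucleotideSeq}.
#' @param spacer character(1) or \linkS4class{NucleotideSeq}, the spacer
#'   whose target site is planted.
#' @param mismatchPositions integer vector of spacer positions (1 = 5' end)
#'   to leave unpaired; may be empty for a perfect site.
#' @param insertAt 1-based start of the planted window on the transcript.
#' @param plantedSites optional data.frame with \code{start}/\code{end}
#'   columns of previously planted sites on this transcript; overlap is an
#'   error so each planted window keeps its exact mismatch count.
#' @return list with \code{transcript} (modified
#'   \linkS4class{NucleotideSeq}) and \code{site} (one-row data.frame:
#'   \code{start}, \code{end}, \code{n_mismatches}).
#' @export
plantOffTarget <- function(transcript, spacer, mismatchPositions = integer(0),
                           insertAt, plantedSites = NULL) {
  stopifnot(is(transcript, "NucleotideSeq"))
  sp <- toRNA(if (is(spacer, "NucleotideSeq")) residues(spacer) else spacer)
  L <- nchar(sp)
  insertAt <- as.integer(insertAt)
  n <- length(transcript)
  if (insertAt < 1L || insertAt + L - 1L > n)
    stop("planted window [", insertAt, ", ", insertAt + L - 1L,
         "] does not fit a ", n, "-nt transcript")
  mismatchPositions <- as.integer(mismatchPositions)
  if (length(mismatchPositions) &&
      (anyDuplicated(mismatchPositions) || min(mismatchPositions) < 1L ||
       max(mismatchPositions) > L))
    stop("mismatch positions must be distinct and in [1, ", L, "]")
  if (!is.null(plantedSites) && nrow(plantedSites)) {
    if (any(insertAt <= plantedSites$end &
            insertAt + L - 1L >= plantedSites$start))
      stop("planted site at ", insertAt, " overlaps an existing planted site")
  }
  win <- strsplit(.revcomp_chr(sp, "RNA"), "", fixed = TRUE)[[1L]]
  cyc <- c(A = "C", C = "G", G = "U", U = "A")
  for (i in mismatchPositions) {
    j <- L - i + 1L  # spacer position i pairs window position L - i + 1
    win[j] <- cyc[[win[j]]]
  }
  win <- paste(win, collapse = "")
  if (alphabet(transcript) == "DNA") win <- .to_dna_chr(win)
  res <- residues(transcript)
  out <- paste0(substr(res, 1L, insertAt - 1L), win,
                substr(res, insertAt + L, n))
  list(transcript = NucleotideSeq(out, id = seqId(transcript),
                                  alphabet = alphabet(transcript)),
       site = data.frame(start = insertAt, end = insertAt + L - 1L,
                         n_mismatches = length(mismatchPositions)))
}

#' Synthetic crRNA efficiency table
#'
#' Emulates the structure of a tiled-screen efficiency dataset: n records of
#' one 30-nt spacer plus a measured silencing efficiency in percent, with
#' 4-nt target flanks. When \code{bias = TRUE}, a planted compositional
#' signal ties sequence to potency the way the real design rules do: potent
#' records are forced to G at spacer positions 1-2 with no C at positions
#' 11, 12, 15, 16, 17 and draw efficiencies around \code{potentMean};
#' ineffective records are forced to C at positions 1-2 and draw around
#' \code{ineffectiveMean}; the rest stay unconstrained around
#' \code{midMean}. Efficiencies are Gaussian with sd \code{noiseSd},
#' truncated to [0, 100]. Defaults (201 records, class means 95/70/30, sd
#' 5) mirror a cohort in which the potent/ineffective split at >90 / <50
#' percent cleanly recovers the planted classes.
#'
#' @param n number of records.
#' @param potentFrac,ineffectiveFrac fractions of records in the potent and
#'   ineffective classes (the remainder is intermediate).
#' @param potentMean,midMean,ineffectiveMean class mean efficiencies (percent).
#' @param noiseSd Gaussian sd of efficiencies (percent); 0 gives the exact
#'   class means.
#' @param bias plant the compositional signal (see above).
#' @param spacerLen spacer length.
#' @param seed integer seed.
#' @return data.frame with columns \code{spacer}, \code{efficiency},
#'   \code{flank_up}, \code{flank_down}, \code{class}.
#' @export
makeEfficiencyTable <- function(n = 201L, potentFrac = 0.3,
                                ineffectiveFrac = 0.35, potentMean = 95,
                                midMean = 70, ineffectiveMean = 30,
                                noiseSd = 5, bias = TRUE, spacerLen = 30L,
                                seed = 1L) {
  n <- as.integer(n)
  spacerLen <- as.integer(spacerLen)
  n_pot <- round(n * potentFrac)
  n_ineff <- round(n * ineffectiveFrac)
  if (n_pot + n_ineff > n) stop("class fractions exceed 1")
  cls <- rep(c("potent", "intermediate", "ineffective"),
             c(n_pot, n - n_pot - n_ineff, n_ineff))
  withr::with_seed(as.integer(seed), {
    rand_seq <- function(k, len)
      vapply(seq_len(k), function(i)
        paste(sample(.RNA_BASES, len, replace = TRUE), collapse = ""),
        character(1))
    spacers <- rand_seq(n, spacerLen)
    if (bias) {
      pot <- which(cls == "potent")
      for (i in pot) {
        ch <- strsplit(spacers[i], "", fixed = TRUE)[[1L]]
        ch[1:2] <- "G"
        central <- c(11L, 12L, 15L, 16L, 17L)
        ch[central][ch[central] == "C"] <- "A"
        spacers[i] <- paste(ch, collapse = "")
      }
      ineff <- which(cls == "ineffective")
      for (i in ineff) {
        ch <- strsplit(spacers[i], "", fixed = TRUE)[[1L]]
        ch[1:2] <- "C"
        spacers[i] <- paste(ch, collapse = "")
      }
    }
    mu <- c(potent = potentMean, intermediate = midMean,
            ineffective = ineffectiveMean)[cls]
    eff <- pmin(100, pmax(0, mu + stats::rnorm(n, 0, noiseSd)))
    data.frame(spacer = spacers, efficiency = unname(eff),
               flank_up = rand_seq(n, 4L), flank_down = rand_seq(n, 4L),
               class = cls, stringsAsFactors = FALSE)
  })
}
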