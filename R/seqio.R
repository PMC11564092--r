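#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importClassesFrom S4Vectors DataFrame
NULL

.RNA_BASES <- c("A", "C", "G", "U")
.DNA_BASES <- c("A", "C", "G", "T")

#' Single nucleotide sequence with a declared alphabet
#'
#' Lightweight container for one DNA or RNA sequence. Residues are stored
#' uppercase and restricted to the declared alphabet plus \code{N}; a record
#' may never mix \code{T} and \code{U}. Spacers and targets are handled
#' internally in the RNA alphabet; transcriptomes are typically read as DNA.
#'
#' @slot id character(1), sequence label.
#' @slot residues character(1), the sequence itself (uppercase).
#' @slot alphabet \code{"DNA"} or \code{"RNA"}.
#' @export
setClass("NucleotideSeq",
         representation(id = "character", residues = "character",
                        alphabet = "character"))

setValidity("NucleotideSeq", function(object) {
  msgs <- character()
  if (length(object@id) != 1L) msgs <- c(msgs, "'id' must be length 1")
  if (length(object@residues) != 1L)
    msgs <- c(msgs, "'residues' must be a single string")
  if (!(object@alphabet %in% c("DNA", "RNA")))
    msgs <- c(msgs, "'alphabet' must be \"DNA\" or \"RNA\"")
  else {
    allowed <- if (object@alphabet == "RNA") "^[ACGUN]*$" else "^[ACGTN]*$"
    if (!grepl(allowed, object@residues))
      msgs <- c(msgs, sprintf("residues contain symbols outside the %s alphabet (A/C/G/%s/N)",
                              object@alphabet,
                              if (object@alphabet == "RNA") "U" else "T"))
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a NucleotideSeq
#'
#' Residues are uppercased; the alphabet is auto-detected when not given
#' (presence of \code{U} implies RNA, otherwise DNA). A sequence containing
#' both \code{T} and \code{U} is rejected.
#'
#' @param residues character(1) sequence (case-insensitive).
#' @param id sequence label.
#' @param alphabet \code{"DNA"}, \code{"RNA"} or \code{NULL} (auto-detect).
#' @return A \linkS4class{NucleotideSeq}.
#' @examples
#' NucleotideSeq("acgu", id = "x")    # RNA
#' NucleotideSeq("ACGT", id = "y")    # DNA
#' @export
NucleotideSeq <- function(residues, id = "seq", alphabet = NULL) {
  residues <- toupper(as.character(residues))
  has_t <- grepl("T", residues, fixed = TRUE)
  has_u <- grepl("U", residues, fixed = TRUE)
  if (has_t && has_u)
    stop("sequence '", id, "' mixes T and U bases")
  if (is.null(alphabet))
    alphabet <- if (has_u) "RNA" else "DNA"
  new("NucleotideSeq", id = id, residues = residues, alphabet = alphabet)
}

#' @rdname NucleotideSeq-accessors
#' @export
setGeneric("seqId", function(x) standardGeneric("seqId"))
#' @rdname NucleotideSeq-accessors
#' @export
setGeneric("residues", function(x) standardGeneric("residues"))
#' @rdname NucleotideSeq-accessors
#' @export
setGeneric("alphabet", function(x) standardGeneric("alphabet"))

#' Accessors for NucleotideSeq
#'
#' @param x A \linkS4class{NucleotideSeq}.
#' @return \code{seqId}/\code{residues}/\code{alphabet} return character(1);
#'   \code{length} returns the number of residues.
#' @name NucleotideSeq-accessors
NULL

#' @rdname NucleotideSeq-accessors
#' @export
setMethod("seqId", "NucleotideSeq", function(x) x@id)
#' @rdname NucleotideSeq-accessors
#' @export
setMethod("residues", "NucleotideSeq", function(x) x@residues)
#' @rdname NucleotideSeq-accessors
#' @export
setMethod("alphabet", "NucleotideSeq", function(x) x@alphabet)
#' @rdname NucleotideSeq-accessors
#' @export
setMethod("length", "NucleotideSeq", function(x) nchar(x@residues))

setMethod("show", "NucleotideSeq", function(object) {
  n <- nchar(object@residues)
  preview <- if (n > 60)
    paste0(substr(object@residues, 1, 57), "...") else object@residues
  cat(sprintf("NucleotideSeq '%s' (%s, %d nt)\n  %s\n",
              object@id, object@alphabet, n, preview))
})

## character-level helpers shared across modules (inputs assumed uppercase)
.to_rna_chr <- function(x) chartr("T", "U", x)
.to_dna_chr <- function(x) chartr("U", "T", x)

.revcomp_chr <- function(x, alphabet = c("RNA", "DNA")) {
  alphabet <- match.arg(alphabet)
  xs <- if (alphabet == "RNA")
    Biostrings::RNAStringSet(x) else Biostrings::DNAStringSet(x)
  as.character(Biostrings::reverseComplement(xs))
}

#' Reverse complement
#'
#' Watson-Crick reverse complement in the sequence's own alphabet.
#' \code{N} maps to \code{N}. The operation is an involution.
#'
#' @param x A \linkS4class{NucleotideSeq}, or a character vector together
#'   with \code{alphabet}.
#' @param alphabet alphabet for character input; ignored for
#'   \code{NucleotideSeq} input.
#' @return Same type as the input.
#' @examples
#' revComp(NucleotideSeq("AAAA", alphabet = "DNA"))  # TTTT
#' revComp("ACGU", alphabet = "RNA")                 # "ACGU"
#' @export
setGeneric("revComp", function(x, alphabet = "RNA") standardGeneric("revComp"))

#' @rdname revComp
#' @export
setMethod("revComp", "NucleotideSeq", function(x, alphabet = "RNA") {
  NucleotideSeq(.revcomp_chr(x@residues, x@alphabet),
                id = x@id, alphabet = x@alphabet)
})

#' @rdname revComp
#' @export
setMethod("revComp", "character", function(x, alphabet = "RNA") {
  unname(.revcomp_chr(toupper(x), alphabet))
})

#' Convert between DNA and RNA alphabets
#'
#' \code{toRNA} substitutes T by U, \code{toDNA} substitutes U by T.
#'
#' @param x A \linkS4class{NucleotideSeq} or character vector.
#' @return Same type as the input, in the requested alphabet.
#' @export
toRNA <- function(x) {
  if (is(x, "NucleotideSeq"))
    NucleotideSeq(.to_rna_chr(x@residues), id = x@id, alphabet = "RNA")
  else .to_rna_chr(toupper(x))
}

#' @rdname toRNA
#' @export
toDNA <- function(x) {
  if (is(x, "NucleotideSeq"))
    NucleotideSeq(.to_dna_chr(x@residues), id = x@id, alphabet = "DNA")
  else .to_dna_chr(toupper(x))
}

#' Read a FASTA file
#'
#' Parses a (possibly line-wrapped) multi-record FASTA file into a list of
#' \linkS4class{NucleotideSeq}. Record ids are the first whitespace-delimited
#' token of each header. Sequences are uppercased and the alphabet of each
#' record is auto-detected (a record containing U is RNA, otherwise DNA);
#' a record mixing T and U is an error.
#'
#' @param path path to a FASTA file.
#' @return list of \linkS4class{NucleotideSeq}, in file order.
#' @export
readFasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (!length(nonblank)) stop("empty FASTA file: ", path)
  first <- nonblank[1L]
  if (!startsWith(trimws(lines[first]), ">"))
    stop(sprintf("malformed FASTA at line %d of '%s': expected '>' header",
                 first, path))
  set <- Biostrings::readBStringSet(path)
  if (!length(set)) stop("no records in FASTA file: ", path)
  if (any(Biostrings::width(set) == 0L))
    stop("empty sequence record in '", path, "': ",
         names(set)[Biostrings::width(set) == 0L][1L])
  ids <- vapply(strsplit(names(set), "[ \t]+"), `[`, character(1), 1L)
  lapply(seq_along(set), function(i)
    NucleotideSeq(as.character(set[[i]]), id = ids[i]))
}

#' Write sequences to a FASTA file
#'
#' @param seqs list of \linkS4class{NucleotideSeq} (or a single one).
#' @param path output path.
#' @param width line-wrap width.
#' @return \code{path}, invisibly.
#' @export
writeFasta <- function(seqs, path, width = 60L) {
  if (is(seqs, "NucleotideSeq")) seqs <- list(seqs)
  set <- Biostrings::BStringSet(
    stats::setNames(vapply(seqs, residues, character(1)),
                    vapply(seqs, seqId, character(1))))
  Biostrings::writeXStringSet(set, path, width = as.integer(width))
  invisible(path)
}
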