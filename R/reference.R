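# Reference gene loading and sequence-context annotation.
#
# Coordinates are 1-based on the coding strand throughout; position 1 is the
# first nucleotide of the reporter coding sequence. CpG membership is
# strand-symmetric (both the C and the G of a CG dinucleotide are CpG
# positions, covering the mutated G:C pair on either strand); GpG context is
# the 3' G of 5'-GpG-3' on the coding strand only, matching how oxidative
# G-to-A hotspots are reported.

annotateRuns <- function(bases, minLength) {
  r <- rle(bases)
  end <- cumsum(r$lengths)
  start <- end - r$lengths + 1L
  keep <- r$lengths >= minLength
  data.frame(base = r$values[keep], start = start[keep], end = end[keep],
             length = r$lengths[keep], stringsAsFactors = FALSE)
}

annotateCpg <- function(bases) {
  n <- length(bases)
  if (n < 2L) return(integer())
  isC <- bases[-n] == "C" & bases[-1L] == "G"
  sort(unique(c(which(isC), which(isC) + 1L)))
}

newReferenceGene <- function(name, sequence, numberingOffset = 0L,
                             runMinLength = 3L) {
  sequence <- toupper(sequence)
  b <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  bad <- which(!b %in% c("A", "C", "G", "T"))
  if (length(bad))
    stop(sprintf("non-ACGT character '%s' at position %d of '%s'",
                 b[bad[1L]], bad[1L], name))
  numberingOffset <- as.integer(numberingOffset)
  if (numberingOffset < 0L || numberingOffset >= length(b))
    stop("numbering_offset outside sequence bounds")
  nb <- b[(numberingOffset + 1L):length(b)]
  new("ReferenceGene", name = name, sequence = sequence,
      numberingOffset = numberingOffset,
      cpgPositions = annotateCpg(nb),
      runs = annotateRuns(nb, as.integer(runMinLength)),
      runMinLength = as.integer(runMinLength))
}

#' Load a reference gene from a single-record FASTA file
#'
#' Reads the coding-strand reference sequence and eagerly computes the
#' CpG-site and mononucleotide-run annotations used by all downstream
#' context calls.
#'
#' @param fastaPath Path to a FASTA file containing exactly one record.
#' @param numberingOffset 0-based index into the record of the nucleotide to
#'   report as position 1 (default 0: the record starts at position 1).
#' @param runMinLength Minimum mononucleotide-run length to annotate
#'   (default 3, the shortest run reported as an A-run).
#' @return A [ReferenceGene-class] object.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">toy", "ATGACGTAAAAACGCGT"), fa)
#' ref <- loadReference(fa)
#' cpgSites(ref)
#' nucRuns(ref)
#' @export
loadReference <- function(fastaPath, numberingOffset = 0L,
                          runMinLength = 3L) {
  dss <- Biostrings::readDNAStringSet(fastaPath)
  if (length(dss) != 1L)
    stop("expected a single-record FASTA, found ", length(dss), " records")
  newReferenceGene(names(dss)[1L], as.character(dss[[1L]]),
                   numberingOffset, runMinLength)
}

#' The packaged gpt reporter reference
#'
#' Returns the annotated 456-nt E. coli gpt coding sequence shipped with the
#' package (the reporter carried by lambda EG10 in gpt delta rodents).
#' Loading runs a calibration self-test: the coordinate convention is only
#' correct if positions 110 and 115 fall in CpG dinucleotides and positions
#' 92 and 113 are the 3' G of 5'-GpG-3'; the function fails loudly
#' otherwise, so a wrong bundled sequence or offset cannot go unnoticed.
#'
#' @param runMinLength Minimum annotated run length (default 3).
#' @return A [ReferenceGene-class] object for gpt.
#' @examples
#' ref <- gptReference()
#' refLength(ref)            # 456
#' 110 %in% cpgSites(ref)    # TRUE
#' @export
gptReference <- function(runMinLength = 3L) {
  fa <- system.file("extdata", "gpt_reporter.fasta", package = "gptSpectra",
                    mustWork = TRUE)
  ref <- loadReference(fa, 0L, runMinLength)
  ok <- all(c(110L, 115L) %in% ref@cpgPositions) &&
    isGpgContext(ref, 92L) && isGpgContext(ref, 113L) &&
    any(ref@runs$start == 8L & ref@runs$end == 12L & ref@runs$base == "A")
  if (!ok)
    stop("gpt reference calibration failed: bundled sequence or numbering ",
         "offset is wrong (expected CpG at 110/115, GpG at 92/113, ",
         "A-run 8-12)")
  ref
}

#' @describeIn refLength Length of the numbered reference region.
#' @export
setGeneric("refLength", function(x) standardGeneric("refLength"))

#' Reference accessors
#'
#' @param x A [ReferenceGene-class] object.
#' @return \code{refLength}: integer length of the numbered region;
#'   \code{refBases}: character vector of single bases indexed by reported
#'   position; \code{refSequence}: the numbered region as one string;
#'   \code{cpgSites}: integer vector of CpG-participating positions;
#'   \code{nucRuns}: data.frame of maximal runs; \code{arunSites}: the
#'   subset of runs at A:T base pairs (base A or T on the coding strand).
#' @name refLength
#' @aliases refBases refSequence cpgSites nucRuns arunSites
#' @examples
#' ref <- gptReference()
#' head(refBases(ref))
#' arunSites(ref)
#' @export
setMethod("refLength", "ReferenceGene", function(x)
  nchar(x@sequence) - x@numberingOffset)

#' @rdname refLength
#' @export
refBases <- function(x) {
  b <- strsplit(x@sequence, "", fixed = TRUE)[[1L]]
  b[(x@numberingOffset + 1L):length(b)]
}

#' @rdname refLength
#' @export
refSequence <- function(x) paste(refBases(x), collapse = "")

#' @rdname refLength
#' @export
cpgSites <- function(x) x@cpgPositions

#' @rdname refLength
#' @export
nucRuns <- function(x) x@runs

#' @rdname refLength
#' @export
arunSites <- function(x) x@runs[x@runs$base %in% c("A", "T"), , drop = FALSE]

#' Is a position the 3' G of a coding-strand 5'-GpG-3' dinucleotide?
#'
#' @param ref A [ReferenceGene-class] object.
#' @param position 1-based position(s) in reference numbering.
#' @return Logical vector: TRUE where the base is G and the 5' neighbour is
#'   G. Position 1 is always FALSE (no 5' neighbour).
#' @examples
#' ref <- gptReference()
#' isGpgContext(ref, c(92, 113))
#' @export
isGpgContext <- function(ref, position) {
  b <- refBases(ref)
  position <- as.integer(position)
  if (any(position < 1L | position > length(b)))
    stop("position out of reference range")
  position > 1L & b[position] == "G" & b[pmax(position - 1L, 1L)] == "G"
}

#' @export
setMethod("show", "ReferenceGene", function(object) {
  cat("ReferenceGene:", object@name, "\n",
      " length:", refLength(object), "nt (offset",
      object@numberingOffset, ")\n",
      " CpG positions:", length(object@cpgPositions), "\n",
      " runs >=", object@runMinLength, "nt:", nrow(object@runs),
      sprintf("(%d at A:T pairs)", nrow(arunSites(object))), "\n")
})
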