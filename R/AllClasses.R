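#' ReferenceGene: an annotated reporter coding sequence
#'
#' Holds the coding-strand sequence of the reporter gene together with the
#' derived annotations every downstream context call relies on: the set of
#' 1-based positions participating in a 5'-CG-3' dinucleotide, and the
#' maximal mononucleotide runs of length >= \code{runMinLength}. Position 1
#' is the first nucleotide of the coding sequence (an arbitrary
#' \code{numberingOffset} into the stored sequence is supported for
#' references embedded in a longer record).
#'
#' @slot name Record name from the FASTA header.
#' @slot sequence Uppercase coding-strand sequence (A/C/G/T only).
#' @slot numberingOffset 0-based index into \code{sequence} of the
#'   nucleotide reported as position 1.
#' @slot cpgPositions Integer vector of 1-based positions whose base is the
#'   C or the G of a CG dinucleotide.
#' @slot runs data.frame with columns \code{base}, \code{start}, \code{end},
#'   \code{length}: maximal single-base runs of length >= runMinLength,
#'   sorted and non-overlapping.
#' @slot runMinLength Minimum run length retained (default 3).
#'
#' @seealso [loadReference()], [gptReference()], [cpgSites()], [nucRuns()]
#' @export
setClass("ReferenceGene",
  representation(name = "character", sequence = "character",
                 numberingOffset = "integer", cpgPositions = "integer",
                 runs = "data.frame", runMinLength = "integer"))

setValidity("ReferenceGene", function(object) {
  msg <- character()
  if (length(object@sequence) != 1L || nchar(object@sequence) == 0L)
    msg <- c(msg, "sequence must be a single non-empty string")
  else {
    b <- strsplit(object@sequence, "", fixed = TRUE)[[1L]]
    bad <- which(!b %in% c("A", "C", "G", "T"))
    if (length(bad))
      msg <- c(msg, sprintf("non-ACGT character '%s' at sequence index %d",
                            b[bad[1L]], bad[1L]))
    n <- length(b) - object@numberingOffset
    p <- object@cpgPositions
    if (any(p < 1L | p > n))
      msg <- c(msg, "cpgPositions out of numbering range")
    else if (length(p)) {
      i <- p + object@numberingOffset
      ok <- (b[i] == "C" & i < length(b) & c(b[-1L], "")[i] == "G") |
            (b[i] == "G" & i > 1L & c("", b[-length(b)])[i] == "C")
      if (!all(ok)) msg <- c(msg, "cpgPositions contain a non-CpG position")
    }
    r <- object@runs
    if (nrow(r)) {
      if (is.unsorted(r$start, strictly = TRUE))
        msg <- c(msg, "runs must be sorted by start")
      if (any(r$end - r$start + 1L != r$length) ||
          any(r$length < object@runMinLength))
        msg <- c(msg, "run length inconsistent or below runMinLength")
      if (any(r$start[-1L] <= r$end[-nrow(r)]))
        msg <- c(msg, "runs overlap")
    }
  }
  if (length(msg)) msg else TRUE
})

#' GptAssaySet: a complete multi-animal reporter-gene assay
#'
#' Container for one study: the annotated reference, a per-animal metadata
#' table (group, genotype, dose, sex, titer and total mutant-colony count)
#' and a per-colony event table. Events are classified eagerly at
#' construction (category, CpG/GpG flags, run context), so accessors always
#' return annotated tables.
#'
#' The event table has one row per mutation event with columns
#' \code{animal_id}, \code{colony_id}, \code{position}, \code{kind}
#' (substitution/deletion/insertion/complex), \code{ref_allele},
#' \code{alt_allele}, \code{size}, plus the derived columns \code{class},
#' \code{is_cpg}, \code{is_gpg}, \code{run_start}, \code{run_end},
#' \code{run_base}. Colonies with no detectable event may be listed in
#' \code{animals$mutant_count} without event rows; they count toward mutant
#' frequency but not toward spectra.
#'
#' @slot reference A [ReferenceGene-class] object.
#' @slot animals data.frame: \code{animal_id}, \code{group_id},
#'   \code{genotype}, \code{dose_g_per_L}, \code{sex}, \code{titer},
#'   \code{mutant_count}.
#' @slot events data.frame of classified events (see Details).
#'
#' @seealso [GptAssaySet()], [assayAnimals()], [assayEvents()],
#'   [spectrumTable()], [groupSummary()]
#' @export
setClass("GptAssaySet",
  representation(reference = "ReferenceGene", animals = "data.frame",
                 events = "data.frame"))

setValidity("GptAssaySet", function(object) {
  msg <- character()
  a <- object@animals
  need <- c("animal_id", "group_id", "titer", "mutant_count")
  if (!all(need %in% names(a)))
    msg <- c(msg, paste("animals table must contain:",
                        paste(need, collapse = ", ")))
  else {
    if (anyDuplicated(a$animal_id))
      msg <- c(msg, "duplicated animal_id in animals table")
    if (any(a$titer <= 0)) msg <- c(msg, "titer must be positive")
    if (any(a$mutant_count < 0)) msg <- c(msg, "mutant_count must be >= 0")
  }
  e <- object@events
  if (nrow(e)) {
    if (!all(EVENT_COLS %in% names(e)))
      msg <- c(msg, paste("events table must contain:",
                          paste(EVENT_COLS, collapse = ", ")))
    else {
      if (!all(e$animal_id %in% a$animal_id))
        msg <- c(msg, "events refer to animals absent from animals table")
      n <- refLength(object@reference)
      if (any(e$position < 0L | e$position > n))
        msg <- c(msg, "event position outside reference bounds")
      # colonies per animal must not exceed the recorded mutant count
      ncol_by_animal <- tapply(e$colony_id, e$animal_id,
                               function(x) length(unique(x)))
      mc <- setNames(a$mutant_count, a$animal_id)
      over <- names(ncol_by_animal)[ncol_by_animal >
                                    mc[names(ncol_by_animal)]]
      if (length(over))
        msg <- c(msg, sprintf(
          "animal '%s' has more sequenced colonies than mutant_count",
          over[1L]))
    }
  }
  if (length(msg)) msg else TRUE
})
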