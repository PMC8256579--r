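# Mutation calling: optimal global pairwise alignment of a colony sequence
# against the reference, event extraction with merging of adjacent gap
# columns, and left-alignment of indels. The alignment itself is delegated
# to Biostrings::pairwiseAlignment (Needleman-Wunsch); unit-scale costs with
# gap extension below gap opening keep multi-base indels contiguous and make
# substitutions preferred over paired insertion+deletion.

callAlignment <- function(refSeq, mutant, flanked) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(refSeq),
    subject = Biostrings::DNAString(mutant),
    type = if (flanked) "global-local" else "global",
    substitutionMatrix = mat, gapOpening = 1.5, gapExtension = 1)
}

#' Call mutation events from a mutant colony sequence
#'
#' Globally aligns a colony sequence against the reference and extracts the
#' mutation events: substitutions at distinct positions as separate events,
#' adjacent gap columns of the same kind merged into one indel, and every
#' indel left-aligned with [normalizeIndel()]. Only events inside the
#' reference coordinate window are reported.
#'
#' @param ref A [ReferenceGene-class] object.
#' @param mutantSequence The colony sequence (A/C/G/T string).
#' @param flanked Set TRUE when the colony sequence is a longer amplicon
#'   containing the reference region (e.g. the 739-bp fragment sequenced in
#'   the assay): the alignment is then global in the reference and local in
#'   the colony sequence, and flanking sequence is ignored. Default
#'   (\code{NULL}) flags sequences more than 50 nt longer than the
#'   reference as flanked.
#' @param minIdentity Identity floor (fraction) below which the sequence is
#'   rejected as not a plausible mutant of this reference (default 0.9).
#' @return Event data.frame (possibly zero rows) sorted by position.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">toy", "ATGACGTAAAAACGCGT"), fa)
#' toy <- loadReference(fa)
#' callEvents(toy, "ATGACATAAAAACGCGT")   # G6>A
#' callEvents(toy, "ATGACGTAAAACGCGT")    # one A lost from the run: del at 8
#' @export
callEvents <- function(ref, mutantSequence, flanked = NULL,
                       minIdentity = 0.9) {
  mutantSequence <- toupper(mutantSequence)
  mb <- strsplit(mutantSequence, "", fixed = TRUE)[[1L]]
  bad <- which(!mb %in% c("A", "C", "G", "T"))
  if (length(bad))
    stop(sprintf("non-ACGT character '%s' at position %d of mutant sequence",
                 mb[bad[1L]], bad[1L]))
  refSeq <- refSequence(ref)
  if (is.null(flanked))
    flanked <- nchar(mutantSequence) > nchar(refSeq) + 50L
  aln <- callAlignment(refSeq, mutantSequence, flanked)
  if (Biostrings::pid(aln) < minIdentity * 100)
    stop(sprintf("alignment identity %.1f%% below %.0f%%: ",
                 Biostrings::pid(aln), minIdentity * 100),
         "not a plausible mutant of this reference")
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1L]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1L]]
  events <- emptyEventTable()
  refpos <- 0L
  i <- 1L
  while (i <= length(p)) {
    if (p[i] != "-" && s[i] != "-") {
      refpos <- refpos + 1L
      if (p[i] != s[i])
        events <- rbind(events, mutationEvent(refpos, "substitution",
                                              p[i], s[i]))
      i <- i + 1L
    } else if (s[i] == "-") {           # deletion of reference bases
      j <- i
      while (j <= length(p) && s[j] == "-" && p[j] != "-") j <- j + 1L
      delref <- paste(p[i:(j - 1L)], collapse = "")
      events <- rbind(events, mutationEvent(refpos + 1L, "deletion",
                                            ref = delref))
      refpos <- refpos + (j - i)
      i <- j
    } else {                            # insertion relative to reference
      j <- i
      while (j <= length(p) && p[j] == "-") j <- j + 1L
      insalt <- paste(s[i:(j - 1L)], collapse = "")
      events <- rbind(events, mutationEvent(refpos, "insertion",
                                            alt = insalt))
      i <- j
    }
  }
  normalizeEventTable(events, ref)
}

#' Read mutant colony sequences from FASTA and call their events
#'
#' Record IDs must encode the animal and colony as
#' \code{"animalID<delim>colonyID"}.
#'
#' @param fastaPath FASTA of colony sequences, one record per confirmed
#'   mutant colony.
#' @param ref A [ReferenceGene-class] object.
#' @param delim Delimiter between animal and colony ID (default "|").
#' @inheritParams callEvents
#' @return Event data.frame with \code{animal_id}/\code{colony_id} filled;
#'   colonies whose sequence is identical to the reference contribute zero
#'   rows but are returned in the \code{"colonies"} attribute (animal_id,
#'   colony_id, n_events) so no-mutation colonies remain visible.
#' @seealso [writeFixture()] for the emitting side, [GptAssaySet()] to
#'   assemble a full assay with metadata.
#' @export
readColonyFasta <- function(fastaPath, ref, delim = "|", flanked = NULL,
                            minIdentity = 0.9) {
  dss <- Biostrings::readDNAStringSet(fastaPath)
  ids <- strsplit(names(dss), delim, fixed = TRUE)
  bad <- which(lengths(ids) < 2L)
  if (length(bad))
    stop(sprintf("record '%s' does not match 'animal%scolony' ID format",
                 names(dss)[bad[1L]], delim))
  out <- vector("list", length(dss))
  for (k in seq_along(dss)) {
    ev <- callEvents(ref, as.character(dss[[k]]), flanked, minIdentity)
    if (nrow(ev)) {
      ev$animal_id <- ids[[k]][1L]
      ev$colony_id <- paste(ids[[k]][-1L], collapse = delim)
    }
    out[[k]] <- ev
  }
  events <- do.call(rbind, c(list(emptyEventTable()), out))
  events <- events[order(events$animal_id, events$colony_id,
                         events$position), , drop = FALSE]
  rownames(events) <- NULL
  attr(events, "colonies") <- data.frame(
    animal_id = vapply(ids, `[`, "", 1L),
    colony_id = vapply(ids, function(x) paste(x[-1L], collapse = delim), ""),
    n_events = vapply(out, nrow, 0L), stringsAsFactors = FALSE)
  events
}

#' Read a pre-called mutation table
#'
#' Ingests a TSV with columns \code{animal_id}, \code{colony_id},
#' \code{position}, \code{ref_allele}, \code{alt_allele}, \code{kind}.
#' Rows are validated against the reference (the stated reference allele
#' must match the reference bases), indels are left-aligned, and rows are
#' grouped into colonies by (animal_id, colony_id).
#'
#' @param tsvPath Path to the TSV file.
#' @param ref A [ReferenceGene-class] object.
#' @return Event data.frame sorted by animal, colony, position.
#' @export
readMutationTable <- function(tsvPath, ref) {
  tab <- read.delim(tsvPath, stringsAsFactors = FALSE,
                    colClasses = "character")
  need <- c("animal_id", "colony_id", "position", "ref_allele",
            "alt_allele", "kind")
  if (!all(need %in% names(tab)))
    stop("mutation table must contain columns: ",
         paste(need, collapse = ", "))
  b <- refBases(ref)
  rows <- lapply(seq_len(nrow(tab)), function(i) {
    r <- tab[i, ]
    if (!r$kind %in% c("substitution", "deletion", "insertion", "complex"))
      stop(sprintf("row %d: unknown kind '%s'", i, r$kind))
    pos <- as.integer(r$position)
    if (r$kind %in% c("substitution", "deletion")) {
      refseg <- paste(b[pos:(pos + max(nchar(r$ref_allele), 1L) - 1L)],
                      collapse = "")
      if (refseg != r$ref_allele)
        stop(sprintf(
          "row %d: ref_allele '%s' does not match reference '%s' at %d",
          i, r$ref_allele, refseg, pos))
    }
    mutationEvent(pos, r$kind, r$ref_allele, r$alt_allele,
                  animal = r$animal_id, colony = r$colony_id)
  })
  events <- do.call(rbind, c(list(emptyEventTable()), rows))
  events <- normalizeEventTable(events, ref)
  rownames(events) <- NULL
  events
}

#' Read an animal/assay metadata table
#'
#' @param tsvPath TSV with columns \code{animal_id}, \code{group_id},
#'   \code{genotype}, \code{dose_g_per_L}, \code{sex}, \code{titer},
#'   \code{mutant_count}.
#' @return data.frame suitable for the \code{animals} slot of
#'   [GptAssaySet()].
#' @export
readMetadata <- function(tsvPath) {
  a <- read.delim(tsvPath, stringsAsFactors = FALSE)
  need <- c("animal_id", "group_id", "titer", "mutant_count")
  if (!all(need %in% names(a)))
    stop("metadata must contain columns: ", paste(need, collapse = ", "))
  a$animal_id <- as.character(a$animal_id)
  a$titer <- as.numeric(a$titer)
  a$mutant_count <- as.integer(a$mutant_count)
  a
}

#' Assemble a classified assay set
#'
#' Combines the reference, the per-animal metadata and a per-colony event
#' table into a validated [GptAssaySet-class]. Events are classified
#' eagerly: each row receives its strand-normalized class and its
#' CpG/GpG/run context flags.
#'
#' @param reference A [ReferenceGene-class] object.
#' @param animals Metadata data.frame (see [readMetadata()]); missing
#'   optional columns (genotype, dose_g_per_L, sex) are filled with NA.
#' @param events Event data.frame (from [readColonyFasta()],
#'   [readMutationTable()] or built in code).
#' @param includeFlank Passed to the run-context rule: when TRUE a
#'   substitution at the base immediately flanking a run also receives run
#'   context (default FALSE).
#' @return A [GptAssaySet-class] object.
#' @export
GptAssaySet <- function(reference, animals, events = emptyEventTable(),
                        includeFlank = FALSE) {
  for (col in c("group_id", "genotype", "sex"))
    if (is.null(animals[[col]]))
      animals[[col]] <- rep(NA_character_, nrow(animals))
  if (is.null(animals[["dose_g_per_L"]]))
    animals[["dose_g_per_L"]] <- rep(NA_real_, nrow(animals))
  animals$animal_id <- as.character(animals$animal_id)
  if (nrow(events)) {
    events <- normalizeEventTable(events[, EVENT_COLS], reference)
    events <- classifyEvents(events, reference, includeFlank)
    rownames(events) <- NULL
  } else {
    events <- classifyEvents(emptyEventTable(), reference, includeFlank)
  }
  new("GptAssaySet", reference = reference, animals = animals,
      events = events)
}

#' @describeIn GptAssaySet Per-animal metadata table.
#' @param x A [GptAssaySet-class] object.
#' @export
assayAnimals <- function(x) x@animals

#' @describeIn GptAssaySet Classified event table.
#' @export
assayEvents <- function(x) x@events

#' @describeIn GptAssaySet The reference the assay was called against.
#' @export
assayReference <- function(x) x@reference

#' @describeIn GptAssaySet Restrict an assay set to selected animals or
#'   groups (metadata and events together).
#' @param animals_keep,groups_keep Character vectors of animal or group IDs.
#' @export
subsetAssay <- function(x, animals_keep = NULL, groups_keep = NULL) {
  a <- x@animals
  if (!is.null(groups_keep)) a <- a[a$group_id %in% groups_keep, ,
                                    drop = FALSE]
  if (!is.null(animals_keep)) a <- a[a$animal_id %in% animals_keep, ,
                                     drop = FALSE]
  e <- x@events[x@events$animal_id %in% a$animal_id, , drop = FALSE]
  new("GptAssaySet", reference = x@reference, animals = a, events = e)
}

#' @export
setMethod("show", "GptAssaySet", function(object) {
  a <- object@animals
  cat("GptAssaySet:", nrow(a), "animals in",
      length(unique(a$group_id)), "group(s);",
      nrow(object@events), "events in",
      nrow(unique(object@events[c("animal_id", "colony_id")])),
      "sequenced colonies\n")
  if (nrow(a)) {
    tf <- tapply(a$mutant_count / a$titer, a$group_id, mean)
    cat(" mean mutant frequency by group:\n")
    for (g in names(tf)) cat(sprintf("   %s: %.2e\n", g, tf[[g]]))
  }
})
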