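# Mutation events are rows of a plain data.frame (schema in EVENT_COLS).
# position semantics: substitution = the changed base; deletion = first
# deleted base after left alignment; insertion = the reference base
# immediately 5' of the inserted bases after left alignment (0 = before
# position 1).

#' Construct mutation event rows
#'
#' Builds one row of the canonical event table. Mostly useful in tests and
#' when encoding published mutation lists as fixtures; the calling and
#' simulation paths build event tables directly.
#'
#' @param position 1-based position (0 allowed for an insertion before
#'   position 1).
#' @param kind One of \code{"substitution"}, \code{"deletion"},
#'   \code{"insertion"}, \code{"complex"}.
#' @param ref Reference allele (empty string for insertions).
#' @param alt Alternate allele (empty string for deletions).
#' @param animal,colony Identifiers (default empty).
#' @return A one-row data.frame with the canonical event columns.
#' @examples
#' mutationEvent(110, "substitution", "G", "A")
#' @export
mutationEvent <- function(position, kind, ref = "", alt = "",
                          animal = "", colony = "") {
  kind <- match.arg(kind, c("substitution", "deletion", "insertion",
                            "complex"))
  size <- switch(kind,
                 substitution = 1L,
                 deletion = nchar(ref),
                 insertion = nchar(alt),
                 complex = max(nchar(ref), nchar(alt)))
  if (kind == "substitution" &&
      (nchar(ref) != 1L || nchar(alt) != 1L || ref == alt))
    stop("substitution requires single differing ref and alt bases")
  if (kind == "deletion" && (nchar(alt) != 0L || nchar(ref) < 1L))
    stop("deletion requires empty alt and non-empty ref")
  if (kind == "insertion" && (nchar(ref) != 0L || nchar(alt) < 1L))
    stop("insertion requires empty ref and non-empty alt")
  data.frame(animal_id = animal, colony_id = colony,
             position = as.integer(position), kind = kind,
             ref_allele = ref, alt_allele = alt, size = as.integer(size),
             stringsAsFactors = FALSE)
}

emptyEventTable <- function() {
  data.frame(animal_id = character(), colony_id = character(),
             position = integer(), kind = character(),
             ref_allele = character(), alt_allele = character(),
             size = integer(), stringsAsFactors = FALSE)
}

#' Left-align an indel to its 5'-most equivalent placement
#'
#' Deletions and insertions inside repetitive sequence have several
#' placements that yield an identical alternate sequence; run-level
#' bookkeeping needs one canonical choice. This shifts the event to its
#' left-most (5'-most, coding strand) equivalent placement; substitutions
#' and complex events are returned unchanged. The operation is idempotent
#' and preserves the alternate sequence.
#'
#' @param event One-row event data.frame (see [mutationEvent()]).
#' @param ref A [ReferenceGene-class] object.
#' @return The event row, possibly with shifted \code{position} (and, for
#'   insertions, rotated \code{alt_allele}).
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">toy", "ATGACGTAAAAACGCGT"), fa)
#' toy <- loadReference(fa)
#' normalizeIndel(mutationEvent(11, "deletion", ref = "A"), toy)$position  # 8
#' @export
normalizeIndel <- function(event, ref) {
  stopifnot(nrow(event) == 1L)
  b <- refBases(ref)
  if (event$kind == "deletion") {
    p <- event$position; k <- event$size
    while (p > 1L && b[p - 1L] == b[p + k - 1L]) p <- p - 1L
    event$position <- p
    event$ref_allele <- paste(b[p:(p + k - 1L)], collapse = "")
  } else if (event$kind == "insertion") {
    a <- event$position
    s <- strsplit(event$alt_allele, "", fixed = TRUE)[[1L]]
    k <- length(s)
    while (a >= 1L && s[k] == b[a]) {
      s <- c(b[a], s[-k])
      a <- a - 1L
    }
    event$position <- a
    event$alt_allele <- paste(s, collapse = "")
  }
  event
}

normalizeEventTable <- function(events, ref) {
  if (!nrow(events)) return(events)
  idx <- which(events$kind %in% c("deletion", "insertion"))
  for (i in idx) events[i, ] <- normalizeIndel(events[i, , drop = FALSE], ref)
  events[order(events$animal_id, events$colony_id, events$position), ,
         drop = FALSE]
}

#' Apply events to the reference to rebuild a mutant sequence
#'
#' Reconstructs the sequence of a mutant colony from its event list; the
#' inverse of [callEvents()] and the basis of the simulator's FASTA output.
#'
#' @param ref A [ReferenceGene-class] object.
#' @param events Event data.frame for one colony (positions must not
#'   overlap).
#' @return The mutant sequence as a single string.
#' @examples
#' ref <- gptReference()
#' substr(applyEvents(ref, mutationEvent(110, "substitution", "G", "A")),
#'        108, 112)
#' @export
applyEvents <- function(ref, events) {
  b <- refBases(ref)
  if (!nrow(events)) return(paste(b, collapse = ""))
  events <- events[order(events$position, decreasing = TRUE), , drop = FALSE]
  for (i in seq_len(nrow(events))) {
    e <- events[i, ]
    if (e$kind == "substitution") {
      if (b[e$position] != e$ref_allele)
        stop(sprintf("ref allele mismatch at position %d: expected %s",
                     e$position, b[e$position]))
      b[e$position] <- e$alt_allele
    } else if (e$kind == "deletion") {
      b <- b[-(e$position:(e$position + e$size - 1L))]
    } else if (e$kind == "insertion") {
      ins <- strsplit(e$alt_allele, "", fixed = TRUE)[[1L]]
      b <- append(b, ins, after = e$position)
    } else {
      stop("cannot apply events of kind 'complex'")
    }
  }
  paste(b, collapse = "")
}
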