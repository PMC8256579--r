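# Spectrum classification: strand-normalized substitution classes, colony
# categories, and CpG / GpG / run context flags.

COMP <- c(A = "T", C = "G", G = "C", T = "A")

#' Strand-normalized base-substitution class
#'
#' Maps an ordered (ref, alt) base pair onto one of the six base-pair
#' substitution classes used in mutation-spectrum tables. The class of a
#' substitution equals the class of its strand complement, so the twelve
#' ordered base pairs collapse onto six classes (two pairs each):
#' G>A and C>T are both \code{GC_to_AT}, and so on.
#'
#' @param ref,alt Single reference and alternate bases (vectorized).
#' @return Character vector of class labels (\code{"GC_to_AT"},
#'   \code{"AT_to_GC"}, \code{"GC_to_TA"}, \code{"GC_to_CG"},
#'   \code{"AT_to_TA"}, \code{"AT_to_CG"}).
#' @examples
#' classifySubstitution("G", "A")  # GC_to_AT
#' classifySubstitution("T", "C")  # AT_to_GC
#' @export
classifySubstitution <- function(ref, alt) {
  stopifnot(all(ref %in% names(COMP)), all(alt %in% names(COMP)))
  if (any(ref == alt)) stop("ref and alt bases must differ")
  flip <- ref %in% c("C", "T")     # normalize so ref is the purine (G or A)
  r <- ifelse(flip, COMP[ref], ref)
  a <- ifelse(flip, COMP[alt], alt)
  paste0(r, COMP[r], "_to_", a, COMP[a])
}

# run-context rule: a substitution inside an annotated run (optionally also
# at the immediately flanking base), or an indel whose inserted/deleted
# bases all match the run base and whose left-aligned placement touches the
# run interval.
runContext <- function(events, ref, includeFlank = FALSE) {
  runs <- nucRuns(ref)
  n <- nrow(events)
  out <- data.frame(run_start = rep(NA_integer_, n),
                    run_end = rep(NA_integer_, n),
                    run_base = rep(NA_character_, n))
  if (!n || !nrow(runs)) return(out)
  for (i in seq_len(n)) {
    e <- events[i, ]
    hit <- if (e$kind == "substitution") {
      lo <- runs$start - if (includeFlank) 1L else 0L
      hi <- runs$end + if (includeFlank) 1L else 0L
      e$position >= lo & e$position <= hi
    } else if (e$kind == "deletion") {
      allele <- strsplit(e$ref_allele, "", fixed = TRUE)[[1L]]
      del_end <- e$position + e$size - 1L
      vapply(seq_len(nrow(runs)), function(j)
        all(allele == runs$base[j]) &&
          e$position <= runs$end[j] && del_end >= runs$start[j],
        NA)
    } else if (e$kind == "insertion") {
      allele <- strsplit(e$alt_allele, "", fixed = TRUE)[[1L]]
      vapply(seq_len(nrow(runs)), function(j)
        all(allele == runs$base[j]) &&
          e$position >= runs$start[j] - 1L && e$position <= runs$end[j],
        NA)
    } else rep(FALSE, nrow(runs))
    j <- which(hit)
    if (length(j)) {
      j <- j[1L]
      out$run_start[i] <- runs$start[j]
      out$run_end[i] <- runs$end[j]
      out$run_base[i] <- runs$base[j]
    }
  }
  out
}

#' Annotate events with class and sequence context
#'
#' Adds to an event table the per-event columns \code{class} (substitution
#' class, or \code{deletion_1}/\code{deletion_ge2}/\code{insertion}/
#' \code{complex}), \code{is_cpg} and \code{is_gpg} (substitutions at G:C
#' pairs only: does the mutated pair participate in a CG dinucleotide on
#' either strand; is the base the 3' G of coding-strand 5'-GpG-3'), and the
#' run context columns \code{run_start}/\code{run_end}/\code{run_base}.
#'
#' @param events Event data.frame.
#' @param ref A [ReferenceGene-class] object.
#' @param includeFlank When TRUE, a substitution at the base immediately 5'
#'   or 3' of a run also receives that run's context (default FALSE).
#' @return The event table with annotation columns appended.
#' @export
classifyEvents <- function(events, ref, includeFlank = FALSE) {
  n <- nrow(events)
  cls <- character(n); cpg <- logical(n); gpg <- logical(n)
  if (n) {
    sub <- events$kind == "substitution"
    cls[sub] <- classifySubstitution(events$ref_allele[sub],
                                     events$alt_allele[sub])
    cls[events$kind == "deletion"] <-
      ifelse(events$size[events$kind == "deletion"] == 1L,
             "deletion_1", "deletion_ge2")
    cls[events$kind == "insertion"] <- "insertion"
    cls[events$kind == "complex"] <- "complex"
    gc_sub <- sub & events$ref_allele %in% c("G", "C")
    cpg[gc_sub] <- events$position[gc_sub] %in% cpgSites(ref)
    if (any(gc_sub))
      gpg[gc_sub] <- isGpgContext(ref, events$position[gc_sub])
  }
  events$class <- cls
  events$is_cpg <- cpg
  events$is_gpg <- gpg
  cbind(events, runContext(events, ref, includeFlank))
}

#' Colony-level mutation category
#'
#' Reduces the events of one colony to a single spectrum-table category:
#' a single substitution maps to its class; a single deletion to
#' \code{deletion_1} (size 1) or \code{deletion_ge2}; a single insertion of
#' any size to \code{insertion}; two or more events, or any complex event,
#' to \code{other}; no events to the sentinel \code{no_mutation} (excluded
#' from spectrum denominators).
#'
#' @param events Event rows of one colony (zero or more rows).
#' @return A single category label.
#' @export
categorizeColony <- function(events) {
  if (!nrow(events)) return("no_mutation")
  if (nrow(events) >= 2L || any(events$kind == "complex")) return("other")
  if (is.null(events$class))
    stop("events must be classified first (see classifyEvents)")
  events$class[1L]
}

#' Per-colony classified table
#'
#' One row per sequenced colony with its category and, for single-event
#' colonies, the event's context flags; multi-event colonies are category
#' \code{other} with NA context.
#'
#' @param x A [GptAssaySet-class] object.
#' @return data.frame: \code{animal_id}, \code{group_id}, \code{colony_id},
#'   \code{category}, \code{is_cpg}, \code{is_gpg}, \code{run_start},
#'   \code{run_end}, \code{run_base}.
#' @export
colonyTable <- function(x) {
  e <- assayEvents(x)
  if (!nrow(e))
    return(data.frame(animal_id = character(), group_id = character(),
                      colony_id = character(), category = character(),
                      is_cpg = logical(), is_gpg = logical(),
                      run_start = integer(), run_end = integer(),
                      run_base = character(), stringsAsFactors = FALSE))
  key <- paste(e$animal_id, e$colony_id, sep = "\r")
  rows <- lapply(split(seq_len(nrow(e)), key), function(idx) {
    ev <- e[idx, , drop = FALSE]
    single <- nrow(ev) == 1L && ev$kind[1L] != "complex"
    data.frame(animal_id = ev$animal_id[1L], colony_id = ev$colony_id[1L],
               category = categorizeColony(ev),
               is_cpg = if (single) ev$is_cpg[1L] else NA,
               is_gpg = if (single) ev$is_gpg[1L] else NA,
               run_start = if (single) ev$run_start[1L] else NA_integer_,
               run_end = if (single) ev$run_end[1L] else NA_integer_,
               run_base = if (single) ev$run_base[1L] else NA_character_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$group_id <- assayAnimals(x)$group_id[
    match(out$animal_id, assayAnimals(x)$animal_id)]
  out <- out[order(out$animal_id, out$colony_id),
             c("animal_id", "group_id", "colony_id", "category", "is_cpg",
               "is_gpg", "run_start", "run_end", "run_base")]
  rownames(out) <- NULL
  out
}
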