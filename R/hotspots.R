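# Hotspot calling by multi-animal support, the A-run mutation table, and
# the A-run enrichment contingency test.

#' Call mutation hotspots within one treatment group
#'
#' A position is a mutation hotspot when the same change is carried by at
#' least \code{minAnimals} distinct animals of one treatment group.
#' Support is counted on clonally corrected events, so duplicating a colony
#' within an animal can never change a call; hotspot identity is
#' (position, class), with different changes at one position reported
#' separately. Events from multi-event ("other") colonies contribute to the
#' tallies.
#'
#' @param x A [GptAssaySet-class] restricted to a single group (see
#'   [subsetAssay()]); spanning several groups is an error.
#' @param minAnimals Minimum number of supporting animals (default 3).
#' @return data.frame: \code{group_id}, \code{position}, \code{class},
#'   \code{kind}, \code{n_animals}, \code{animals} (comma-separated ids),
#'   \code{is_hotspot}, \code{is_cpg}, \code{is_gpg}, one row per
#'   (position, class) with at least one independent event.
#' @export
callHotspots <- function(x, minAnimals = 3L) {
  a <- assayAnimals(x)
  g <- unique(a$group_id)
  if (length(g) > 1L)
    stop("hotspots are called within one treatment group; got ",
         length(g), " groups (use subsetAssay)")
  ie <- independentEvents(x)
  if (!nrow(ie))
    return(data.frame(group_id = character(), position = integer(),
                      class = character(), kind = character(),
                      n_animals = integer(), animals = character(),
                      is_hotspot = logical(), is_cpg = logical(),
                      is_gpg = logical(), stringsAsFactors = FALSE))
  key <- paste(ie$position, ie$class, ie$kind, ie$ref_allele,
               ie$alt_allele, sep = "\r")
  rows <- lapply(split(seq_len(nrow(ie)), key), function(idx) {
    d <- ie[idx, , drop = FALSE]
    ani <- sort(unique(d$animal_id))
    data.frame(group_id = g, position = d$position[1L],
               class = d$class[1L], kind = d$kind[1L],
               n_animals = length(ani),
               animals = paste(ani, collapse = ","),
               is_cpg = d$is_cpg[1L], is_gpg = d$is_gpg[1L],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$is_hotspot <- out$n_animals >= minAnimals
  out <- out[order(out$position, out$class),
             c("group_id", "position", "class", "kind", "n_animals",
               "animals", "is_hotspot", "is_cpg", "is_gpg")]
  rownames(out) <- NULL
  out
}

#' A-run mutation table
#'
#' Tabulates, per treatment group, the mutant colonies whose single event
#' lies in an annotated A:T mononucleotide run (A-run): one row per
#' (run, specific change) with the colony count and the clonally corrected
#' independent count, plus per-group grand totals as the \code{"totals"}
#' attribute.
#'
#' @param x A [GptAssaySet-class] object (one or more groups).
#' @return data.frame: \code{run_start}, \code{run_end}, \code{run_base},
#'   \code{original}, \code{mutated}, \code{group_id}, \code{n_mutants},
#'   \code{n_independent}; \code{mutated} describes the change
#'   (\code{del1}, \code{insA}, \code{insAA}, \code{A345C}, ...).
#' @export
arunTable <- function(x) {
  e <- assayEvents(x)
  a <- assayAnimals(x)
  groups <- sort(unique(a$group_id))
  # single-event colonies only: multi-event colonies are category "other"
  ckey <- paste(e$animal_id, e$colony_id, sep = "\r")
  single <- ckey %in% names(which(table(ckey) == 1L))
  keep <- single & !is.na(e$run_base) & e$run_base %in% c("A", "T")
  e <- e[keep, , drop = FALSE]
  empty <- data.frame(run_start = integer(), run_end = integer(),
                      run_base = character(), original = character(),
                      mutated = character(), group_id = character(),
                      n_mutants = integer(), n_independent = integer(),
                      stringsAsFactors = FALSE)
  totals <- data.frame(group_id = groups,
                       n_mutants = rep(0L, length(groups)),
                       n_independent = rep(0L, length(groups)),
                       stringsAsFactors = FALSE)
  if (!nrow(e)) {
    attr(empty, "totals") <- totals
    return(empty)
  }
  e$group_id <- a$group_id[match(e$animal_id, a$animal_id)]
  lab <- ifelse(e$kind == "deletion", paste0("del", e$size),
         ifelse(e$kind == "insertion", paste0("ins", e$alt_allele),
                paste0(e$ref_allele, e$position, e$alt_allele)))
  key <- paste(e$run_start, e$run_end, lab, e$group_id, sep = "\r")
  rows <- lapply(split(seq_len(nrow(e)), key), function(idx) {
    d <- e[idx, , drop = FALSE]
    indep <- length(unique(paste(d$animal_id, d$position, d$kind,
                                 d$ref_allele, d$alt_allele)))
    data.frame(run_start = d$run_start[1L], run_end = d$run_end[1L],
               run_base = d$run_base[1L],
               original = strrep(d$run_base[1L],
                                 d$run_end[1L] - d$run_start[1L] + 1L),
               mutated = lab[idx[1L]], group_id = d$group_id[1L],
               n_mutants = nrow(d), n_independent = indep,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$run_start, out$mutated, out$group_id), , drop = FALSE]
  rownames(out) <- NULL
  agg <- lapply(groups, function(g) {
    d <- out[out$group_id == g, , drop = FALSE]
    data.frame(group_id = g, n_mutants = sum(d$n_mutants),
               n_independent = sum(d$n_independent),
               stringsAsFactors = FALSE)
  })
  attr(out, "totals") <- do.call(rbind, agg)
  out
}

#' Expand a per-run mutation count table into a colony-level assay
#'
#' Published A-run summaries report, per run and specific change, the
#' number of mutant colonies and the number of independent mutations per
#' group. This expands such a table into concrete colonies: each row's
#' \code{n_mutants} colonies are distributed round-robin over
#' \code{n_independent} animals of the group, so per-animal clonal
#' correction recovers exactly the stated independent count.
#'
#' @param counts data.frame or TSV path with columns \code{run_start},
#'   \code{run_end}, \code{run_base}, \code{kind}, \code{position},
#'   \code{ref_allele}, \code{alt_allele}, \code{group_id},
#'   \code{n_mutants}, \code{n_independent}.
#' @param ref A [ReferenceGene-class] object.
#' @param titer Titer assigned to every synthetic animal (default 5e5; the
#'   expansion is for spectrum/run bookkeeping, not frequency estimation).
#' @return A [GptAssaySet-class] object.
#' @examples
#' tsv <- system.file("extdata", "arun_mutations_by_group.tsv",
#'                    package = "gptSpectra")
#' fix <- expandRunCounts(tsv, gptReference())
#' attr(arunTable(fix), "totals")
#' @export
expandRunCounts <- function(counts, ref, titer = 5e5) {
  if (is.character(counts))
    counts <- read.delim(counts, stringsAsFactors = FALSE,
                         na.strings = NULL,
                         colClasses = c(ref_allele = "character",
                                        alt_allele = "character"))
  rows <- list()
  for (i in seq_len(nrow(counts))) {
    r <- counts[i, ]
    if (r$n_independent > r$n_mutants)
      stop(sprintf("row %d: independent count exceeds mutant count", i))
    animal <- paste0(r$group_id, "_a",
                     rep_len(seq_len(r$n_independent), r$n_mutants))
    for (j in seq_len(r$n_mutants))
      rows[[length(rows) + 1L]] <-
        mutationEvent(r$position, r$kind, r$ref_allele, r$alt_allele,
                      animal = animal[j],
                      colony = sprintf("row%d_c%d", i, j))
  }
  events <- do.call(rbind, c(list(emptyEventTable()), rows))
  ncolony <- table(events$animal_id)
  animals <- data.frame(
    animal_id = names(ncolony),
    group_id = sub("_a[0-9]+$", "", names(ncolony)),
    titer = titer, mutant_count = as.integer(ncolony),
    stringsAsFactors = FALSE)
  GptAssaySet(ref, animals, events)
}

#' Fisher's exact test of two proportions
#'
#' Builds the 2x2 table \code{[[countA, totalA-countA], [countB,
#' totalB-countB]]} and delegates to [fisherExact2x2()]. Used for the
#' A-run and indel enrichment comparisons between treatment groups.
#'
#' @param countA,totalA Count and total of the first group.
#' @param countB,totalB Count and total of the second group.
#' @return See [fisherExact2x2()].
#' @examples
#' proportionTest(38, 149, 2, 28)$p_two_sided
#' @export
proportionTest <- function(countA, totalA, countB, totalB) {
  v <- c(countA, totalA, countB, totalB)
  if (any(v < 0) || countA > totalA || countB > totalB)
    stop("counts must be non-negative and no larger than their totals")
  fisherExact2x2(matrix(c(countA, totalA - countA,
                          countB, totalB - countB),
                        nrow = 2L, byrow = TRUE))
}
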