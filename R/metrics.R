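# Assay metrics: mutant frequency, clonal correction, group summaries and
# the spectrum table.

#' Per-animal mutant frequency
#'
#' Mutant frequency is the number of 6-TG-resistant mutant colonies divided
#' by the titer (dilution-corrected colony count on non-selective plates)
#' of the same animal.
#'
#' @param x A [GptAssaySet-class] object.
#' @return Named numeric vector of frequencies, one per animal.
#' @examples
#' a <- data.frame(animal_id = "a1", group_id = "g", titer = 3e5,
#'                 mutant_count = 15)
#' mutantFrequency(GptAssaySet(gptReference(), a))  # 5e-05
#' @export
mutantFrequency <- function(x) {
  a <- assayAnimals(x)
  if (any(a$titer <= 0)) stop("titer must be positive")
  setNames(a$mutant_count / a$titer, a$animal_id)
}

#' Clonal correction: collapse within-animal duplicate events
#'
#' Within one animal, colonies carrying an identical event (same position,
#' kind and alleles) are presumed descendants of a single mutational event
#' in the tissue; they collapse to one independent event carrying a
#' \code{clonal_count}. Events in different animals never collapse.
#'
#' @param events Either a [GptAssaySet-class] (deduplicated within each
#'   animal) or an event data.frame from a single animal (rows from more
#'   than one animal are an error).
#' @return Event data.frame of independent events with a
#'   \code{clonal_count} column, ordered by animal and position.
#' @export
independentEvents <- function(events) {
  if (is(events, "GptAssaySet")) {
    e <- assayEvents(events)
    parts <- lapply(split(e, e$animal_id), independentEvents)
    out <- do.call(rbind, c(list(cbind(e[0, ], clonal_count = integer())),
                            unname(parts)))
    rownames(out) <- NULL
    return(out)
  }
  e <- events
  if (!nrow(e)) return(cbind(e, clonal_count = integer()))
  if (length(unique(e$animal_id)) > 1L)
    stop("independentEvents on a raw event table requires a single ",
         "animal; pass a GptAssaySet for per-animal correction")
  key <- paste(e$position, e$kind, e$ref_allele, e$alt_allele, sep = "\r")
  first <- !duplicated(key)
  out <- e[first, , drop = FALSE]
  out$clonal_count <- as.integer(table(key)[key[first]])
  out <- out[order(out$position), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Group-level frequency summary
#'
#' Computes per-animal frequencies (count / titer) and the group mean with
#' sample (n-1) standard deviation across animals. The count is, by
#' default, the animal's total mutant-colony count; with \code{category}
#' set, the number of colonies in that category (or, with
#' \code{independent = TRUE}, the number of clonally corrected events of
#' that class). Frequencies are averaged per animal, never pooled across
#' the group, so the SD reflects animal-to-animal variation; the pooled
#' alternative (group count sum / group titer sum) is also reported.
#'
#' @param x A [GptAssaySet-class] object.
#' @param category Optional category label ([mutationCategories()]) to
#'   restrict counts to one mutation type.
#' @param independent When TRUE, count clonally corrected independent
#'   events instead of colonies.
#' @return List with \code{per_animal} (animal_id, group_id, count, titer,
#'   frequency) and \code{groups} (group_id, n_animals, mean, sd, pooled).
#' @export
groupSummary <- function(x, category = NULL, independent = FALSE) {
  a <- assayAnimals(x)
  if (!nrow(a)) stop("empty assay set")
  counts <- setNames(rep(0L, nrow(a)), a$animal_id)
  if (is.null(category) && !independent) {
    counts[] <- a$mutant_count
  } else if (independent) {
    ie <- independentEvents(x)
    if (!is.null(category)) ie <- ie[ie$class == category, , drop = FALSE]
    if (nrow(ie)) {
      tab <- table(ie$animal_id)
      counts[names(tab)] <- as.integer(tab)
    }
  } else {
    ct <- colonyTable(x)
    ct <- ct[ct$category == category, , drop = FALSE]
    if (nrow(ct)) {
      tab <- table(ct$animal_id)
      counts[names(tab)] <- as.integer(tab)
    }
  }
  per <- data.frame(animal_id = a$animal_id, group_id = a$group_id,
                    count = as.integer(counts), titer = a$titer,
                    frequency = counts / a$titer,
                    stringsAsFactors = FALSE)
  groups <- do.call(rbind, lapply(split(per, per$group_id), function(d)
    data.frame(group_id = d$group_id[1L], n_animals = nrow(d),
               mean = mean(d$frequency),
               sd = if (nrow(d) >= 2L) sd(d$frequency) else NA_real_,
               pooled = sum(d$count) / sum(d$titer),
               stringsAsFactors = FALSE)))
  rownames(groups) <- NULL
  list(per_animal = per, groups = groups)
}

#' Mutation spectrum table
#'
#' Per-group counts and integer-rounded percentages by mutation category,
#' with the CpG sub-count reported under the G:C->A:T row. Column totals
#' equal the number of categorized (sequenced, mutation-bearing) colonies;
#' colonies without a detectable event are excluded.
#'
#' @param x A [GptAssaySet-class] object, or a numeric matrix of category
#'   counts (rows named by [mutationCategories()], optionally plus a
#'   \code{"GC_to_AT_CpG"} sub-count row; columns named by group).
#' @param ... Unused.
#' @return Long-format data.frame (\code{group_id}, \code{category},
#'   \code{n}, \code{pct}, \code{n_cpg}) with a \code{"totals"} attribute
#'   (categorized colonies per group).
#' @examples
#' m <- matrix(c(6, 1, 1, 0, 0, 0, 1, 0, 1, 0), ncol = 1,
#'             dimnames = list(mutationCategories(), "g1"))
#' spectrumTable(m)
#' @export
setGeneric("spectrumTable", function(x, ...) standardGeneric("spectrumTable"))

spectrumFromCounts <- function(counts, cpg = NULL) {
  groups <- colnames(counts)
  out <- do.call(rbind, lapply(groups, function(g) {
    n <- counts[, g]
    total <- sum(n)
    data.frame(group_id = g, category = rownames(counts),
               n = as.integer(n),
               pct = if (total > 0) as.integer(round(100 * n / total))
                     else rep(0L, length(n)),
               n_cpg = ifelse(rownames(counts) == "GC_to_AT" &
                                !is.null(cpg), cpg[g], NA_integer_),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "totals") <- colSums(counts)
  out
}

#' @rdname spectrumTable
#' @export
setMethod("spectrumTable", "GptAssaySet", function(x, ...) {
  ct <- colonyTable(x)
  ct <- ct[ct$category != "no_mutation", , drop = FALSE]
  groups <- sort(unique(assayAnimals(x)$group_id))
  counts <- matrix(0L, nrow = length(MUTATION_CATEGORIES),
                   ncol = length(groups),
                   dimnames = list(MUTATION_CATEGORIES, groups))
  cpg <- setNames(rep(0L, length(groups)), groups)
  for (g in groups) {
    d <- ct[ct$group_id == g, , drop = FALSE]
    tab <- table(factor(d$category, levels = MUTATION_CATEGORIES))
    counts[, g] <- as.integer(tab)
    cpg[g] <- sum(d$category == "GC_to_AT" & d$is_cpg, na.rm = TRUE)
  }
  spectrumFromCounts(counts, cpg)
})

#' @rdname spectrumTable
#' @export
setMethod("spectrumTable", "matrix", function(x, ...) {
  cpg <- NULL
  if ("GC_to_AT_CpG" %in% rownames(x)) {
    cpg <- x["GC_to_AT_CpG", ]
    x <- x[rownames(x) != "GC_to_AT_CpG", , drop = FALSE]
  }
  miss <- setdiff(rownames(x), MUTATION_CATEGORIES)
  if (length(miss)) stop("unknown category row: ", miss[1L])
  x <- x[intersect(MUTATION_CATEGORIES, rownames(x)), , drop = FALSE]
  if (!is.null(cpg) && any(cpg > x["GC_to_AT", ]))
    stop("CpG sub-count exceeds GC_to_AT count")
  spectrumFromCounts(x, cpg)
})
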