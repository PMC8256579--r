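# Synthetic-assay generator: emulates the statistical structure of a gpt
# delta study — group design, log-normal titers, Poisson counts of
# independent mutations drawn from a position-weighted spectrum (CpG,
# hotspot and A-run effects), geometric within-animal clonal expansion, and
# a fraction of resistant colonies without a detectable event.

#' Simulation configuration
#'
#' Bundles and validates the generator parameters. All rates are per-locus
#' (per rescued phage) rates of *independent* mutations; clonal expansion
#' multiplies them into colony counts.
#'
#' @param seed Integer seed; fully determines the output.
#' @param groups data.frame with columns \code{group_id}, \code{genotype},
#'   \code{dose_g_per_L}, \code{n_animals}.
#' @param rates Named list (by group_id) of named numeric vectors: per-locus
#'   independent-mutation rate per category (names from
#'   [mutationCategories()]).
#' @param titer_meanlog,titer_sdlog Log-normal titer parameters.
#' @param cpg_multiplier Weight multiplier (>= 1) for G:C->A:T events at
#'   CpG positions.
#' @param hotspot_multipliers Named numeric (names = positions): extra
#'   weight for G:C->A:T events at those positions.
#' @param arun_indel_rate Named numeric (by group_id): per-run per-locus
#'   rate of single-base slippage indels in A:T runs (deletion with
#'   probability \code{arun_del_share}, otherwise insertion of one or two
#'   run bases).
#' @param arun_del_share Deletion share of A-run slippage events
#'   (default 0.7).
#' @param clonal_p Geometric parameter: copies per independent mutation are
#'   \code{1 + Geometric(clonal_p)} (mean \code{1/clonal_p}).
#' @param no_mutation_fraction Probability that a resistant colony yields
#'   no detectable event.
#' @return A validated list of class \code{"gpt_sim_config"}.
#' @seealso [defaultStudyConfig()] for presets mirroring a four-group
#'   two-genotype by two-dose design.
#' @export
simulationConfig <- function(seed, groups, rates,
                             titer_meanlog = log(6e5), titer_sdlog = 0.3,
                             cpg_multiplier = 5,
                             hotspot_multipliers = numeric(),
                             arun_indel_rate = NULL,
                             arun_del_share = 0.7,
                             clonal_p = 0.65,
                             no_mutation_fraction = 0.05) {
  stopifnot(is.data.frame(groups),
            all(c("group_id", "n_animals") %in% names(groups)))
  if (is.null(groups$genotype)) groups$genotype <- NA_character_
  if (is.null(groups$dose_g_per_L)) groups$dose_g_per_L <- NA_real_
  if (!is.list(rates) || is.null(names(rates)))
    stop("rates must be a named list, one element per group_id")
  miss <- setdiff(groups$group_id, names(rates))
  if (length(miss)) stop("no rates for group: ", miss[1L])
  for (g in names(rates)) {
    r <- rates[[g]]
    if (any(r < 0)) stop("rates must be non-negative")
    bad <- setdiff(names(r), MUTATION_CATEGORIES)
    if (length(bad)) stop("unknown rate category: ", bad[1L])
  }
  if (is.null(arun_indel_rate))
    arun_indel_rate <- setNames(rep(0, nrow(groups)), groups$group_id)
  stopifnot(cpg_multiplier >= 1, all(hotspot_multipliers >= 1),
            clonal_p > 0, clonal_p <= 1,
            no_mutation_fraction >= 0, no_mutation_fraction < 1,
            arun_del_share >= 0, arun_del_share <= 1)
  structure(list(seed = as.integer(seed), groups = groups, rates = rates,
                 titer_meanlog = titer_meanlog, titer_sdlog = titer_sdlog,
                 cpg_multiplier = cpg_multiplier,
                 hotspot_multipliers = hotspot_multipliers,
                 arun_indel_rate = arun_indel_rate,
                 arun_del_share = arun_del_share,
                 clonal_p = clonal_p,
                 no_mutation_fraction = no_mutation_fraction),
            class = "gpt_sim_config")
}

#' Default four-group study configuration
#'
#' Presets emulating a two-genotype (mismatch-repair bearing vs knockout)
#' by two-dose (vehicle vs oxidant in drinking water) design with 3-5
#' animals per group: per-group independent-mutation rates proportioned
#' across categories like the spectra such studies report, CpG-weighted
#' G:C->A:T with four hotspot positions, and A-run slippage indels in the
#' knockout groups. The presets are documentation of a realistic regime,
#' not claims about any particular animal cohort.
#'
#' @param seed Integer seed.
#' @param ref Reference used to count A:T runs (default [gptReference()]).
#' @return A \code{"gpt_sim_config"} object (see [simulationConfig()]).
#' @export
defaultStudyConfig <- function(seed = 1L, ref = gptReference()) {
  groups <- data.frame(
    group_id = c("bearing_vehicle", "bearing_kbro3",
                 "ko_vehicle", "ko_kbro3"),
    genotype = c("Msh2_bearing", "Msh2_bearing", "Msh2_KO", "Msh2_KO"),
    dose_g_per_L = c(0, 1.5, 0, 1.5),
    n_animals = c(4L, 5L, 3L, 4L),
    stringsAsFactors = FALSE)
  # per-group total independent-mutation rates (per locus) and category
  # proportions of the regime being emulated
  totals <- c(bearing_vehicle = 0.40e-5, bearing_kbro3 = 0.64e-5,
              ko_vehicle = 3.14e-5, ko_kbro3 = 2.67e-5)
  counts <- exampleSpectrumCounts()
  cat10 <- counts[rownames(counts) != "GC_to_AT_CpG", ]
  nruns <- nrow(arunSites(ref))
  arunShare <- c(bearing_vehicle = 0, bearing_kbro3 = 0,
                 ko_vehicle = 0.5, ko_kbro3 = 0.7)
  rates <- list(); arun <- numeric()
  for (g in groups$group_id) {
    prop <- cat10[, g] / sum(cat10[, g])
    r <- totals[[g]] * prop
    # route part of the single-base indel mass through the A-run channel
    moved <- arunShare[[g]] * (r[["deletion_1"]] + r[["insertion"]])
    r[["deletion_1"]] <- r[["deletion_1"]] * (1 - arunShare[[g]])
    r[["insertion"]] <- r[["insertion"]] * (1 - arunShare[[g]])
    rates[[g]] <- r
    arun[[g]] <- moved / nruns
  }
  simulationConfig(seed = seed, groups = groups, rates = rates,
                   cpg_multiplier = 5,
                   hotspot_multipliers = c("92" = 120, "110" = 30,
                                           "113" = 120, "115" = 30),
                   arun_indel_rate = arun)
}

# position weights for one substitution class
classPositionWeights <- function(class, ref, config) {
  b <- refBases(ref)
  pair <- if (startsWith(class, "GC")) c("G", "C") else c("A", "T")
  pos <- which(b %in% pair)
  w <- rep(1, length(pos))
  if (class == "GC_to_AT") {
    w[pos %in% cpgSites(ref)] <- w[pos %in% cpgSites(ref)] *
      config$cpg_multiplier
    hm <- config$hotspot_multipliers
    hit <- match(pos, as.integer(names(hm)))
    w[!is.na(hit)] <- w[!is.na(hit)] * hm[hit[!is.na(hit)]]
  }
  list(pos = pos, w = w)
}

substitutionAlt <- function(class, refbase) {
  x <- substr(class, 1L, 1L); y <- substr(class, 2L, 2L)
  z <- substr(class, 7L, 7L); w <- substr(class, 8L, 8L)
  ifelse(refbase == x, z, w)
}

#' Simulate a complete synthetic assay
#'
#' Per animal: a log-normal titer is drawn; the number of independent
#' mutations per category is Poisson with mean titer x rate; positions are
#' drawn from the weighted spectrum (CpG / hotspot multipliers for
#' G:C->A:T, per-run slippage rates for A-run indels); each independent
#' mutation is replicated into 1 + Geometric(clonal_p) colonies; and
#' no-mutation colonies are added so a fraction \code{no_mutation_fraction}
#' of resistant colonies carries no detectable event. Deterministic under a
#' fixed seed.
#'
#' @param config A \code{"gpt_sim_config"} object.
#' @param ref A [ReferenceGene-class] object.
#' @return A [GptAssaySet-class] with attributes \code{"truth"} (the
#'   generated independent mutations, one row each, with \code{copies}),
#'   \code{"colonies"} (all colonies incl. no-mutation ones) and
#'   \code{"config"}.
#' @examples
#' cfg <- defaultStudyConfig(seed = 7)
#' sim <- simulateAssay(cfg, gptReference())
#' sim
#' @export
simulateAssay <- function(config, ref) {
  stopifnot(inherits(config, "gpt_sim_config"))
  set.seed(config$seed)
  b <- refBases(ref)
  L <- length(b)
  runs <- arunSites(ref)
  subClasses <- MUTATION_CATEGORIES[1:6]
  weights <- lapply(setNames(subClasses, subClasses),
                    classPositionWeights, ref = ref, config = config)
  meanCopies <- 1 / config$clonal_p
  ev <- list(); tr <- list(); animals <- list(); colonies <- list()
  for (gi in seq_len(nrow(config$groups))) {
    g <- config$groups$group_id[gi]
    r <- config$rates[[g]]
    totalRate <- sum(r) + config$arun_indel_rate[[g]] * nrow(runs)
    if (totalRate * meanCopies > 0.1)
      stop("rates imply expected mutants above titer/10; ",
           "not a realistic selection assay")
    for (ai in seq_len(config$groups$n_animals[gi])) {
      animal <- sprintf("%s_a%d", g, ai)
      titer <- max(1e4, round(rlnorm(1, config$titer_meanlog,
                                     config$titer_sdlog)))
      pos <- integer(); kind <- character()
      refa <- character(); alta <- character()
      multi <- list()   # "other" colonies: two substitutions each
      for (cls in names(r)) {
        n <- rpois(1L, titer * r[[cls]])
        if (!n) next
        if (cls %in% subClasses) {
          wt <- weights[[cls]]
          p <- wt$pos[sample.int(length(wt$pos), n, replace = TRUE,
                                 prob = wt$w)]
          pos <- c(pos, p); kind <- c(kind, rep("substitution", n))
          refa <- c(refa, b[p]); alta <- c(alta, substitutionAlt(cls, b[p]))
        } else if (cls == "deletion_1") {
          p <- sample.int(L, n, replace = TRUE)
          pos <- c(pos, p); kind <- c(kind, rep("deletion", n))
          refa <- c(refa, b[p]); alta <- c(alta, rep("", n))
        } else if (cls == "deletion_ge2") {
          p <- sample.int(L - 1L, n, replace = TRUE)
          pos <- c(pos, p); kind <- c(kind, rep("deletion", n))
          refa <- c(refa, paste0(b[p], b[p + 1L])); alta <- c(alta, rep("", n))
        } else if (cls == "insertion") {
          p <- sample.int(L, n, replace = TRUE)
          pos <- c(pos, p); kind <- c(kind, rep("insertion", n))
          refa <- c(refa, rep("", n)); alta <- c(alta, b[p])
        } else if (cls == "other") {
          for (j in seq_len(n)) {
            p2 <- sample.int(L, 2L)
            alt2 <- vapply(p2, function(q)
              sample(setdiff(c("A", "C", "G", "T"), b[q]), 1L), "")
            multi[[length(multi) + 1L]] <-
              data.frame(position = p2, kind = "substitution",
                         ref_allele = b[p2], alt_allele = alt2,
                         stringsAsFactors = FALSE)
          }
        }
      }
      if (nrow(runs) && config$arun_indel_rate[[g]] > 0) {
        for (ri in seq_len(nrow(runs))) {
          n <- rpois(1L, titer * config$arun_indel_rate[[g]])
          if (!n) next
          isdel <- runif(n) < config$arun_del_share
          base <- runs$base[ri]
          for (j in seq_len(n)) {
            if (isdel[j]) {
              pos <- c(pos, runs$start[ri]); kind <- c(kind, "deletion")
              refa <- c(refa, base); alta <- c(alta, "")
            } else {
              k <- if (runif(1) < 0.8) 1L else 2L
              pos <- c(pos, runs$start[ri] - 1L)
              kind <- c(kind, "insertion")
              refa <- c(refa, ""); alta <- c(alta, strrep(base, k))
            }
          }
        }
      }
      nIndep <- length(pos) + length(multi)
      copies <- 1L + rgeom(nIndep, config$clonal_p)
      # expand independent mutations into clonal colonies
      aev <- list(); acol <- 0L
      addColony <- function(events1) {
        acol <<- acol + 1L
        events1$animal_id <- animal
        events1$colony_id <- sprintf("c%03d", acol)
        aev[[length(aev) + 1L]] <<- events1
      }
      if (length(pos)) {
        single <- data.frame(position = pos, kind = kind,
                             ref_allele = refa, alt_allele = alta,
                             stringsAsFactors = FALSE)
        for (i in seq_len(nrow(single)))
          for (cc in seq_len(copies[i]))
            addColony(single[i, , drop = FALSE])
      }
      for (i in seq_along(multi))
        for (cc in seq_len(copies[length(pos) + i]))
          addColony(multi[[i]])
      nWithEvents <- acol
      f <- config$no_mutation_fraction
      n0 <- if (f > 0) rpois(1L, nWithEvents * f / (1 - f)) else 0L
      aevents <- do.call(rbind, aev)
      if (!is.null(aevents)) {
        aevents$size <- ifelse(aevents$kind == "deletion",
                               nchar(aevents$ref_allele),
                               pmax(nchar(aevents$alt_allele), 1L))
        ev[[length(ev) + 1L]] <- aevents[, EVENT_COLS]
      }
      tr[[length(tr) + 1L]] <- if (nIndep) data.frame(
        animal_id = animal, group_id = g,
        position = c(pos, vapply(multi, function(m) m$position[1L], 0L)),
        kind = c(kind, rep("other", length(multi))),
        ref_allele = c(refa, rep(NA, length(multi))),
        alt_allele = c(alta, rep(NA, length(multi))),
        copies = copies, stringsAsFactors = FALSE) else NULL
      animals[[length(animals) + 1L]] <- data.frame(
        animal_id = animal, group_id = g,
        genotype = config$groups$genotype[gi],
        dose_g_per_L = config$groups$dose_g_per_L[gi],
        sex = "unknown", titer = titer,
        mutant_count = nWithEvents + n0, stringsAsFactors = FALSE)
      extra <- if (n0) data.frame(
        animal_id = animal,
        colony_id = sprintf("c%03d", nWithEvents + seq_len(n0)),
        n_events = 0L, stringsAsFactors = FALSE) else NULL
      withev <- if (nWithEvents) data.frame(
        animal_id = animal, colony_id = sprintf("c%03d", seq_len(nWithEvents)),
        n_events = vapply(aev, nrow, 0L), stringsAsFactors = FALSE) else NULL
      colonies[[length(colonies) + 1L]] <- rbind(withev, extra)
    }
  }
  out <- GptAssaySet(ref, do.call(rbind, animals),
                     do.call(rbind, c(list(emptyEventTable()), ev)))
  attr(out, "truth") <- do.call(rbind, tr)
  attr(out, "colonies") <- do.call(rbind, colonies)
  attr(out, "config") <- config
  out
}

#' Write a simulated (or constructed) assay out as pipeline input files
#'
#' Emits the same files the analysis side consumes: a colony FASTA (mutant
#' sequences rebuilt by applying each colony's events to the reference;
#' no-mutation colonies as unmutated reference copies), a metadata TSV, and
#' — when present — the generating truth table and a YAML echo of the
#' configuration with its resolved seed.
#'
#' @param x A [GptAssaySet-class] object.
#' @param dir Output directory (created if needed).
#' @param delim Animal/colony delimiter in FASTA record IDs (default "|").
#' @return Named character vector of the written paths.
#' @export
writeFixture <- function(x, dir, delim = "|") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ref <- assayReference(x)
  e <- assayEvents(x)
  col <- attr(x, "colonies")
  if (is.null(col)) {
    col <- unique(e[, c("animal_id", "colony_id")])
    col$n_events <- NA_integer_
  }
  seqs <- character(nrow(col))
  for (i in seq_len(nrow(col))) {
    idx <- e$animal_id == col$animal_id[i] & e$colony_id == col$colony_id[i]
    seqs[i] <- applyEvents(ref, e[idx, , drop = FALSE])
  }
  dss <- Biostrings::DNAStringSet(seqs)
  names(dss) <- paste(col$animal_id, col$colony_id, sep = delim)
  paths <- c(fasta = file.path(dir, "colonies.fasta"),
             metadata = file.path(dir, "metadata.tsv"))
  Biostrings::writeXStringSet(dss, paths[["fasta"]])
  write.table(assayAnimals(x), paths[["metadata"]], sep = "\t",
              quote = FALSE, row.names = FALSE)
  truth <- attr(x, "truth")
  if (!is.null(truth)) {
    paths[["truth"]] <- file.path(dir, "truth.tsv")
    write.table(truth, paths[["truth"]], sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  config <- attr(x, "config")
  if (!is.null(config)) {
    paths[["config"]] <- file.path(dir, "config.yaml")
    cfg <- unclass(config)
    cfg$groups <- as.list(cfg$groups)
    cfg$rates <- lapply(cfg$rates, as.list)
    yaml::write_yaml(cfg, paths[["config"]])
  }
  paths
}

#' Category counts of an example four-group spectrum
#'
#' Loads the packaged example of a published-style spectrum table: category
#' counts (plus the CpG sub-count of G:C->A:T) for a two-genotype by
#' two-dose, four-group small-intestine study. Used as a worked example and
#' as the proportions behind [defaultStudyConfig()].
#'
#' @return Integer matrix, rows = categories (plus \code{"GC_to_AT_CpG"}),
#'   columns = groups.
#' @export
exampleSpectrumCounts <- function() {
  tsv <- system.file("extdata", "spectrum_counts_by_group.tsv",
                     package = "gptSpectra", mustWork = TRUE)
  tab <- read.delim(tsv, stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1L])
  rownames(m) <- tab$category
  storage.mode(m) <- "integer"
  m
}

#' The packaged example A-run mutation count table
#'
#' Per-run, per-change mutant and independent counts for the knockout
#' groups of the example study, with each change mapped to a concrete
#' left-aligned event on the packaged reporter reference. Expand with
#' [expandRunCounts()].
#'
#' @return data.frame (see [expandRunCounts()] for the columns).
#' @export
exampleArunCounts <- function() {
  tsv <- system.file("extdata", "arun_mutations_by_group.tsv",
                     package = "gptSpectra", mustWork = TRUE)
  read.delim(tsv, stringsAsFactors = FALSE, na.strings = NULL,
             colClasses = c(ref_allele = "character",
                            alt_allele = "character"))
}
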