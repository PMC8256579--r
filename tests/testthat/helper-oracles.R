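# Shared fixtures and independent oracles used across the suite.
# The oracles work on plain strings with base R only, so they stay
# independent of the code paths they check.

makeRef <- function(seq, name = "toy", runMinLength = 3) {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(paste0(">", name), seq), fa)
  loadReference(fa, runMinLength = runMinLength)
}

toyRef <- function() makeRef("ATGACGTAAAAACGCGT")

# apply a single edit to a sequence by plain string surgery
oracleApply <- function(refseq, pos, kind, refa = "", alta = "") {
  n <- nchar(refseq)
  if (kind == "substitution")
    return(paste0(substr(refseq, 1, pos - 1), alta,
                  substr(refseq, pos + 1, n)))
  if (kind == "deletion")
    return(paste0(substr(refseq, 1, pos - 1),
                  substr(refseq, pos + nchar(refa), n)))
  if (kind == "insertion")
    return(paste0(substr(refseq, 1, pos), alta,
                  substr(refseq, pos + 1, n)))
  stop("unsupported kind")
}

# every single-base edit of a sequence, with the mutant it produces
enumerateSingleEdits <- function(refseq) {
  n <- nchar(refseq)
  bases <- c("A", "C", "G", "T")
  rows <- list()
  add <- function(pos, kind, refa, alta)
    rows[[length(rows) + 1L]] <<- data.frame(
      pos = pos, kind = kind, refa = refa, alta = alta,
      mutant = oracleApply(refseq, pos, kind, refa, alta),
      stringsAsFactors = FALSE)
  for (p in seq_len(n)) {
    rb <- substr(refseq, p, p)
    for (a in setdiff(bases, rb)) add(p, "substitution", rb, a)
    add(p, "deletion", rb, "")
  }
  for (p in 0:n) for (a in bases) add(p, "insertion", "", a)
  do.call(rbind, rows)
}

# canonical (left-most) representative of a single edit: among all single
# edits of the same kind producing the same mutant, the smallest position
oracleCanonical <- function(edits, mutant, kind) {
  hits <- edits[edits$mutant == mutant & edits$kind == kind, , drop = FALSE]
  hits[which.min(hits$pos), , drop = FALSE]
}

# Fisher's exact test by full enumeration of margin-fixed tables, with
# point probabilities from binomial coefficients (no dhyper)
fisherOracle <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1]); c2 <- sum(tab[, 2])
  N <- r1 + r2
  support <- max(0, r1 - c2):min(r1, c1)
  pr <- choose(c1, support) * choose(c2, r1 - support) / choose(N, r1)
  obs <- pr[support == tab[1, 1]]
  list(p_two_sided = sum(pr[pr <= obs * (1 + 1e-7)]),
       p_one_sided = min(sum(pr[support <= tab[1, 1]]),
                         sum(pr[support >= tab[1, 1]])))
}

# small assay builder: one group, events described as list(animal, colony,
# pos, kind, ref, alt)
buildAssay <- function(ref, rows, group = "g1", titer = 5e5,
                       extraColonies = 0L) {
  ev <- do.call(rbind, lapply(rows, function(r)
    mutationEvent(r[[3]], r[[4]], r[[5]], r[[6]],
                  animal = r[[1]], colony = r[[2]])))
  ncol <- table(ev$animal_id)
  animals <- data.frame(animal_id = names(ncol), group_id = group,
                        titer = titer,
                        mutant_count = as.integer(ncol) + extraColonies,
                        stringsAsFactors = FALSE)
  GptAssaySet(ref, animals, ev)
}
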