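test_that("identity, substitution and run-deletion calls on the toy reference", {
  toy <- toyRef()
  expect_equal(nrow(callEvents(toy, "ATGACGTAAAAACGCGT")), 0L)
  ev <- callEvents(toy, "ATGACATAAAAACGCGT")
  expect_equal(ev$position, 6L)
  expect_equal(ev$kind, "substitution")
  expect_equal(ev$ref_allele, "G")
  expect_equal(ev$alt_allele, "A")
  ev <- callEvents(toy, "ATGACGTAAAACGCGT")  # one A lost from run 8-12
  expect_equal(ev$kind, "deletion")
  expect_equal(ev$position, 8L)
  expect_equal(ev$size, 1L)
  expect_equal(ev$ref_allele, "A")
})

test_that("calling equals exhaustive single-edit enumeration (with round trip)", {
  set.seed(21)
  refs <- c("ATGACGTAAAAACGCGT",
            paste(sample(c("A", "C", "G", "T"), 31, replace = TRUE,
                         prob = c(.35, .15, .15, .35)), collapse = ""),
            paste(sample(c("A", "C", "G", "T"), 50, replace = TRUE),
                  collapse = ""))
  for (s in refs) {
    ref <- makeRef(s)
    edits <- enumerateSingleEdits(s)
    for (i in seq_len(nrow(edits))) {
      e <- edits[i, ]
      ev <- callEvents(ref, e$mutant)
      expect_equal(nrow(ev), 1L, label = paste("one event for", e$kind,
                                               "at", e$pos))
      want <- oracleCanonical(edits, e$mutant, e$kind)
      expect_equal(ev$kind, want$kind)
      expect_equal(ev$position, want$pos)
      # round trip: re-applying the call reconstructs the mutant
      expect_identical(applyEvents(ref, ev), e$mutant)
    }
  }
})

test_that("indel left-alignment: examples, idempotence, sequence preservation", {
  toy <- toyRef()
  d <- normalizeIndel(mutationEvent(11, "deletion", ref = "A"), toy)
  expect_equal(d$position, 8L)
  i <- normalizeIndel(mutationEvent(10, "insertion", alt = "AA"), toy)
  expect_equal(i$position, 7L)
  expect_equal(i$alt_allele, "AA")
  u <- normalizeIndel(mutationEvent(3, "deletion", ref = "G"),
                      makeRef("ACGT"))
  expect_equal(u$position, 3L)
  # property: idempotent, never shifts right, preserves the alternate
  set.seed(22)
  for (k in 1:50) {
    s <- paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE,
                      prob = c(.4, .1, .1, .4)), collapse = "")
    ref <- makeRef(s)
    p <- sample(29, 1)
    ev <- if (runif(1) < .5)
      mutationEvent(p, "deletion",
                    ref = substr(s, p, p + sample(0:1, 1)))
    else mutationEvent(p, "insertion",
                       alt = paste(sample(c("A", "T"), sample(1:2, 1),
                                          replace = TRUE), collapse = ""))
    before <- applyEvents(ref, ev)
    norm <- normalizeIndel(ev, ref)
    expect_lte(norm$position, ev$position)
    expect_identical(applyEvents(ref, norm), before)
    expect_identical(normalizeIndel(norm, ref), norm)
  }
})

test_that("amplicon-flanked sequences are handled and bad input rejected", {
  ref <- gptReference()
  mut <- applyEvents(ref, mutationEvent(110, "substitution", "G", "A"))
  flankedSeq <- paste0("TTACCACTTTATCCCGCGTCAGGCA", mut, "ACCTGAGCGAAACCC")
  ev <- callEvents(ref, flankedSeq, flanked = TRUE)
  expect_equal(ev$position, 110L)
  expect_equal(ev$alt_allele, "A")
  expect_error(callEvents(ref, "ACGN"), "non-ACGT")
  expect_error(callEvents(ref, strrep("ACGT", 114)),
               "not a plausible mutant")
})

test_that("pre-called mutation tables are validated and grouped", {
  ref <- gptReference()
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("animal_id\tcolony_id\tposition\tref_allele\talt_allele\tkind",
               "a1\tc1\t110\tG\tA\tsubstitution",
               "a1\tc2\t8\tA\t\tdeletion",
               "a2\tc1\t92\tG\tA\tsubstitution",
               "a2\tc1\t345\tA\tC\tsubstitution"), tsv)
  ev <- readMutationTable(tsv, ref)
  expect_equal(nrow(ev), 4L)
  expect_equal(sum(ev$animal_id == "a2" & ev$colony_id == "c1"), 2L)
  # two events in one colony categorize as "other" downstream
  asy <- GptAssaySet(ref, data.frame(animal_id = c("a1", "a2"),
                                     group_id = "g", titer = 1e5,
                                     mutant_count = 2L), ev)
  ct <- colonyTable(asy)
  expect_equal(ct$category[ct$animal_id == "a2"], "other")

  writeLines(c("animal_id\tcolony_id\tposition\tref_allele\talt_allele\tkind",
               "a1\tc1\t110\tT\tA\tsubstitution"), tsv)
  expect_error(readMutationTable(tsv, ref), "does not match reference")
  writeLines(c("animal_id\tcolony_id\tposition\tref_allele\talt_allele\tkind",
               "a1\tc1\t110\tG\tA\tinversion"), tsv)
  expect_error(readMutationTable(tsv, ref), "unknown kind")
})
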