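hotspotFixture <- function(ref) {
  # independent G>A events at 92/110/113/115 in >=3 of 4 animals, other
  # positions in at most 2 animals; one position clonally inflated
  rows <- list()
  add <- function(animal, colony, pos)
    rows[[length(rows) + 1L]] <<- list(animal, colony, pos,
                                       "substitution", "G", "A")
  for (an in c("a1", "a2", "a3")) add(an, "h110", 110)
  for (an in c("a1", "a2", "a3", "a4")) add(an, "h115", 115)
  for (an in c("a2", "a3", "a4")) add(an, "h92", 92)
  for (an in c("a1", "a2", "a4")) add(an, "h113", 113)
  add("a1", "bg1", 64); add("a2", "bg1", 64)     # two animals only
  add("a3", "bg2", 26)
  for (k in 1:5) add("a4", paste0("cl", k), 26)  # clonal pile in one animal
  buildAssay(ref, rows)
}

test_that("the >=3-animal rule calls exactly the constructed hotspots", {
  ref <- gptReference()
  hs <- callHotspots(hotspotFixture(ref))
  called <- hs$position[hs$is_hotspot]
  expect_setequal(called, c(92L, 110L, 113L, 115L))
  # support counts animals, not colonies: 26 has 2 animals despite 6 colonies
  expect_equal(hs$n_animals[hs$position == 26], 2L)
  expect_false(hs$is_hotspot[hs$position == 26])
  # context flags are carried through
  expect_true(all(hs$is_cpg[hs$position %in% c(110, 115)]))
  expect_true(all(hs$is_gpg[hs$position %in% c(92, 113)]))
})

test_that("hotspot calls are invariant to clonal expansion", {
  ref <- gptReference()
  asy <- hotspotFixture(ref)
  base <- callHotspots(asy)
  e <- assayEvents(asy)
  set.seed(41)
  for (k in 1:5) {
    i <- sample(nrow(e), 1)
    dup <- e[i, ]
    dup$colony_id <- paste0(dup$colony_id, "_dup", k)
    e <- rbind(e, dup)
  }
  a <- assayAnimals(asy)
  a$mutant_count <- a$mutant_count + 5L   # generous upper bound
  again <- callHotspots(GptAssaySet(ref, a, e[, c("animal_id", "colony_id",
                                                  "position", "kind",
                                                  "ref_allele", "alt_allele",
                                                  "size")]))
  expect_equal(again[names(base)], base)
})

test_that("raising the support threshold shrinks the hotspot set", {
  asy <- hotspotFixture(gptReference())
  sets <- lapply(1:5, function(t) {
    hs <- callHotspots(asy, minAnimals = t)
    hs$position[hs$is_hotspot]
  })
  for (t in 1:4)
    expect_true(all(sets[[t + 1]] %in% sets[[t]]))
  expect_error(callHotspots(
    subsetAssay(simulateAssay(defaultStudyConfig(seed = 5),
                              gptReference()))), "one treatment group")
})

test_that("the A-run table reproduces encoded per-row and total counts", {
  ref <- gptReference()
  counts <- exampleArunCounts()
  fix <- expandRunCounts(counts, ref)
  at <- arunTable(fix)
  tot <- attr(at, "totals")
  expect_equal(tot$n_mutants[tot$group_id == "ko_kbro3"], 30L)
  expect_equal(tot$n_independent[tot$group_id == "ko_kbro3"], 21L)
  expect_equal(tot$n_mutants[tot$group_id == "ko_vehicle"], 12L)
  expect_equal(tot$n_independent[tot$group_id == "ko_vehicle"], 6L)
  # row-by-row: clonal correction reproduces every independent count
  expect_equal(nrow(at), nrow(counts))
  for (i in seq_len(nrow(counts))) {
    r <- counts[i, ]
    hit <- at$run_start == r$run_start & at$group_id == r$group_id &
      (if (r$kind == "deletion") at$mutated == "del1"
       else if (r$kind == "insertion")
         at$mutated == paste0("ins", r$alt_allele)
       else at$mutated == paste0(r$ref_allele, r$position, r$alt_allele))
    expect_equal(at$n_mutants[hit], r$n_mutants)
    expect_equal(at$n_independent[hit], r$n_independent)
  }
  # empty group: no rows, zero totals
  none <- arunTable(subsetAssay(fix, groups_keep = character()))
  expect_equal(nrow(none), 0L)
})

test_that("A-run totals equal colonies whose single event has run context", {
  sim <- simulateAssay(defaultStudyConfig(seed = 43), gptReference())
  at <- arunTable(sim)
  tot <- attr(at, "totals")
  ct <- colonyTable(sim)
  inRun <- ct[!is.na(ct$run_base) & ct$run_base %in% c("A", "T"), ]
  want <- table(factor(inRun$group_id, levels = tot$group_id))
  expect_equal(tot$n_mutants, as.integer(want))
})

test_that("proportion tests build the right table and bounds hold", {
  r <- proportionTest(38, 149, 2, 28)
  expect_equal(r$table, matrix(c(38, 111, 2, 26), 2, byrow = TRUE))
  expect_lt(r$p_two_sided, 0.05)
  expect_equal(proportionTest(0, 10, 0, 10)$p_two_sided, 1)
  # one- vs two-sided relation for the point-probability method
  r2 <- proportionTest(30, 149, 12, 107)
  orc <- fisherOracle(r2$table)
  expect_equal(r2$p_two_sided, orc$p_two_sided, tolerance = 1e-12)
  expect_equal(r2$p_one_sided, orc$p_one_sided, tolerance = 1e-12)
  expect_lte(r2$p_one_sided, r2$p_two_sided)
  expect_lte(r2$p_two_sided, min(1, 2 * r2$p_one_sided))
  expect_error(proportionTest(5, 3, 1, 10), "no larger than")
})
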