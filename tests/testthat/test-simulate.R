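test_that("the generator is deterministic under a fixed seed", {
  ref <- gptReference()
  cfg <- defaultStudyConfig(seed = 61)
  s1 <- simulateAssay(cfg, ref)
  s2 <- simulateAssay(cfg, ref)
  expect_identical(assayEvents(s1), assayEvents(s2))
  expect_identical(assayAnimals(s1), assayAnimals(s2))
  d1 <- tempfile(); d2 <- tempfile()
  p1 <- writeFixture(s1, d1); p2 <- writeFixture(s2, d2)
  for (f in c("fasta", "metadata", "truth"))
    expect_identical(readLines(p1[[f]]), readLines(p2[[f]]))
})

test_that("zero rates give empty spectra", {
  ref <- gptReference()
  cfg <- simulationConfig(seed = 62,
                          groups = data.frame(group_id = "g",
                                              n_animals = 3L),
                          rates = list(g = c(GC_to_AT = 0)),
                          no_mutation_fraction = 0)
  sim <- simulateAssay(cfg, ref)
  expect_equal(nrow(assayEvents(sim)), 0L)
  expect_true(all(assayAnimals(sim)$mutant_count == 0L))
})

test_that("unrealistically high rates are refused", {
  cfg <- simulationConfig(seed = 63,
                          groups = data.frame(group_id = "g",
                                              n_animals = 2L),
                          rates = list(g = c(GC_to_AT = 0.2)))
  expect_error(simulateAssay(cfg, gptReference()), "titer/10")
})

test_that("generated class proportions are recovered by the pipeline", {
  # GC_to_AT set to 0.45 of the total rate; pooled colony proportion must
  # come back within 3 binomial SE
  ref <- gptReference()
  total <- 3e-5
  cfg <- simulationConfig(seed = 64,
                          groups = data.frame(group_id = "g",
                                              n_animals = 50L),
                          rates = list(g = c(GC_to_AT = 0.45 * total,
                                             AT_to_GC = 0.25 * total,
                                             GC_to_TA = 0.20 * total,
                                             deletion_1 = 0.10 * total)),
                          clonal_p = 1, no_mutation_fraction = 0)
  sim <- simulateAssay(cfg, ref)
  ct <- colonyTable(sim)
  n <- nrow(ct)
  phat <- mean(ct$category == "GC_to_AT")
  expect_lt(abs(phat - 0.45), 3 * sqrt(0.45 * 0.55 / n))
})

test_that("written fixtures round-trip through alignment calling", {
  ref <- gptReference()
  groups <- data.frame(group_id = "g", n_animals = 3L)
  cfg <- simulationConfig(seed = 65, groups = groups,
                          rates = list(g = c(GC_to_AT = 6e-6,
                                             AT_to_GC = 3e-6,
                                             deletion_1 = 3e-6,
                                             insertion = 2e-6,
                                             deletion_ge2 = 2e-6)),
                          arun_indel_rate = c(g = 3e-7),
                          titer_meanlog = log(4e5),
                          no_mutation_fraction = 0.1)
  sim <- simulateAssay(cfg, ref)
  dir <- tempfile()
  paths <- writeFixture(sim, dir)
  expect_true(all(file.exists(paths)))
  called <- readColonyFasta(paths[["fasta"]], ref)
  meta <- readMetadata(paths[["metadata"]])
  rebuilt <- GptAssaySet(ref, meta, called)
  cols <- c("animal_id", "colony_id", "position", "kind",
            "ref_allele", "alt_allele", "size")
  want <- assayEvents(sim)[, cols]
  got <- assayEvents(rebuilt)[, cols]
  ord <- function(d) {
    d <- d[order(d$animal_id, d$colony_id, d$position, d$kind), ]
    rownames(d) <- NULL
    d
  }
  expect_equal(ord(got), ord(want))
  # no-mutation colonies surface in the FASTA but carry no events
  colonies <- attr(called, "colonies")
  expect_equal(sum(colonies$n_events == 0),
               sum(attr(sim, "colonies")$n_events == 0))
})

test_that("clonal correction recovers the generated independent mutations", {
  sim <- simulateAssay(defaultStudyConfig(seed = 66), gptReference())
  truth <- attr(sim, "truth")
  truth <- truth[truth$kind != "other", ]
  # pipeline side: drop multi-event ("other") colonies, then deduplicate
  e <- assayEvents(sim)
  ckey <- paste(e$animal_id, e$colony_id)
  e <- e[ckey %in% names(which(table(ckey) == 1L)), ]
  # truth side: two generated events are the same mutation iff they yield
  # the same alternate sequence (placement-equivalent indels collapse)
  refseq <- refSequence(assayReference(sim))
  for (an in unique(truth$animal_id)) {
    tg <- truth[truth$animal_id == an, ]
    alt <- vapply(seq_len(nrow(tg)), function(i)
      oracleApply(refseq, tg$position[i], tg$kind[i],
                  tg$ref_allele[i], tg$alt_allele[i]), "")
    ie <- independentEvents(e[e$animal_id == an, ])
    expect_equal(nrow(ie), length(unique(alt)))
  }
})

test_that("an engineered hotspot is called; without it calls are rare", {
  ref <- gptReference()
  groups <- data.frame(group_id = "g", n_animals = 4L)
  baseRate <- c(GC_to_AT = 8e-6)
  calledWith <- calledWithout <- logical(10)
  for (s in 1:10) {
    hot <- simulateAssay(simulationConfig(
      seed = 100 + s, groups = groups, rates = list(g = baseRate),
      cpg_multiplier = 1, titer_meanlog = log(5e5),
      hotspot_multipliers = c("110" = 150),
      no_mutation_fraction = 0), ref)
    hs <- callHotspots(hot)
    calledWith[s] <- any(hs$is_hotspot & hs$position == 110)
    flat <- simulateAssay(simulationConfig(
      seed = 200 + s, groups = groups, rates = list(g = baseRate),
      cpg_multiplier = 1, titer_meanlog = log(5e5),
      no_mutation_fraction = 0), ref)
    hsf <- callHotspots(flat)
    calledWithout[s] <- any(hsf$is_hotspot)
  }
  expect_gt(mean(calledWith), 0.5)
  expect_lt(mean(calledWithout), 0.5)
})
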