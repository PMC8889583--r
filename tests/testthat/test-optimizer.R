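# Optimizer behaviour is exercised on the small planted fixture (6 signal +
# 4 noise cavity atoms, 10 actives, 40 decoys, 2 poses each) so the full
# greedy loop runs in seconds.

smallCfg <- function(...) optimizationConfig(seed = 1L, ...)

test_that("evaluateModel equals the manual score -> rank -> metric pipeline", {
  fx <- smallFixture()
  cfg <- smallCfg()
  manual <- bedroc(makeRanking(scoreLibrary(fx$model, fx$library, fx$labels,
                                            wShape = cfg$wShape),
                               cfg$seed), 20)
  expect_equal(evaluateModel(fx$model, fx$library, fx$labels, cfg), manual)
  # identical calls give identical values
  expect_identical(evaluateModel(fx$model, fx$library, fx$labels, cfg),
                   evaluateModel(fx$model, fx$library, fx$labels, cfg))
  # AUC and EFd targets run through the same machinery
  cfgA <- smallCfg(metric = "auc")
  expect_equal(evaluateModel(fx$model, fx$library, fx$labels, cfgA),
               rocAuc(makeRanking(scoreLibrary(fx$model, fx$library,
                                               fx$labels), 1))$auc)
})

test_that("greedy pruning recovers the planted signal on the small fixture", {
  fx <- smallFixture()
  res <- brnibOptimize(fx$model, fx$library, fx$labels, smallCfg())

  surv <- survivingAtoms(fx$model, finalModel(res))
  expect_gte(length(intersect(surv, fx$truth$signal)),
             ceiling(0.9 * length(fx$truth$signal)))
  expect_gte(length(setdiff(fx$truth$noise, surv)),
             ceiling(0.8 * length(fx$truth$noise)))

  # trajectory strictly increases over accepted generations
  expect_true(all(diff(trajectory(res)) > 0))
  expect_gt(max(trajectory(res)), res@initialMetric)

  # accepted removal present iff the best variant beat the parent
  for (g in generations(res)) {
    if (!is.na(g$accepted))
      expect_gt(max(g$variants$metric), g$bestMetric - 1e-15)
  }
})

test_that("a locally optimal model terminates after one full generation", {
  fx <- smallFixture()
  base <- brnibOptimize(fx$model, fx$library, fx$labels, smallCfg())
  fin <- finalModel(base)

  # restarting from the optimizer's own output: exactly one failed
  # generation of nAtoms evaluations, model returned unchanged
  res <- brnibOptimize(fin, fx$library, fx$labels, smallCfg())
  expect_identical(atoms(finalModel(res)), atoms(fin))
  expect_length(generations(res), 1L)
  expect_true(is.na(generations(res)[[1]]$accepted))
  expect_identical(evaluations(res), as.numeric(nAtoms(fin)))
  expect_length(trajectory(res), 1L)
})

test_that("evaluation bookkeeping matches the greedy-count formula", {
  fx <- smallFixture()
  res <- brnibOptimize(fx$model, fx$library, fx$labels, smallCfg())
  n <- nAtoms(fx$model)
  a1 <- nAtoms(finalModel(res))
  # the run ended with a failed generation (not the size floor), so the
  # total number of variant evaluations is exactly sum(a1:n)
  expect_gt(a1, smallCfg()$minModelSize)
  expect_identical(evaluations(res), greedyCount(n, a1))
})

test_that("optimization is deterministic across repeats and worker counts", {
  fx <- smallFixture()
  r1 <- brnibOptimize(fx$model, fx$library, fx$labels, smallCfg(workers = 1))
  r2 <- brnibOptimize(fx$model, fx$library, fx$labels, smallCfg(workers = 1))
  r4 <- brnibOptimize(fx$model, fx$library, fx$labels, smallCfg(workers = 4))
  for (other in list(r2, r4)) {
    expect_identical(atoms(finalModel(other)), atoms(finalModel(r1)))
    expect_identical(trajectory(other), trajectory(r1))
    expect_identical(lapply(generations(other), `[[`, "variants"),
                     lapply(generations(r1), `[[`, "variants"))
    expect_identical(evaluations(other), evaluations(r1))
  }
})

test_that("min model size floors the search and single-class labels error", {
  fx <- smallFixture()
  cfg <- smallCfg(minModelSize = nAtoms(fx$model) - 1L)
  res <- brnibOptimize(fx$model, fx$library, fx$labels, cfg)
  expect_gte(nAtoms(finalModel(res)), cfg$minModelSize)
  expect_lte(length(generations(res)), 1L + 1L)

  oneClass <- ActivitySet(actives(fx$labels), character())
  expect_error(brnibOptimize(fx$model, fx$library, oneClass, smallCfg()),
               "both actives and decoys")
  cfgCap <- smallCfg(maxGenerations = 2)
  resCap <- brnibOptimize(fx$model, fx$library, fx$labels, cfgCap)
  expect_lte(length(generations(resCap)), 2L)
})

test_that("cut-and-go prunes in one pass and never beats the greedy budget", {
  fx <- smallFixture()
  full <- brnibOptimize(fx$model, fx$library, fx$labels, smallCfg())
  cg <- cutAndGo(fx$model, fx$library, fx$labels, smallCfg())

  expect_lte(evaluations(cg), evaluations(full))
  expect_gte(max(trajectory(cg)), cg@initialMetric)   # final >= Gen 0
  expect_gte(nAtoms(finalModel(cg)), smallCfg()$minModelSize)
  expect_identical(generations(cg)[[1]]$generation, 0L)

  # with no improving single deletions the cut pass is a no-op and the
  # result equals plain greedy optimization of the same input
  fin <- finalModel(full)
  cg2 <- cutAndGo(fin, fx$library, fx$labels, smallCfg())
  expect_length(generations(cg2)[[1]]$removedIndices, 0L)
  expect_identical(atoms(finalModel(cg2)), atoms(fin))
})

test_that("persisted runs are re-readable and logged generation by generation", {
  fx <- smallFixture()
  outdir <- withr::local_tempdir()
  res <- brnibOptimize(fx$model, fx$library, fx$labels, smallCfg(),
                       outdir = outdir)
  files <- list.files(outdir, pattern = "^gen_\\d{4}\\.mol2$")
  expect_length(files, length(res@models))
  # every persisted generation model parses back to the in-memory one
  for (i in seq_along(res@models)) {
    back <- readNibModel(file.path(outdir, sprintf("gen_%04d.mol2", i - 1L)))
    expect_equal(atoms(back)$x, atoms(res@models[[i]])$x, tolerance = 1e-4)
    expect_identical(nAtoms(back), nAtoms(res@models[[i]]))
  }
  logLines <- readLines(file.path(outdir, "log.jsonl"))
  expect_length(logLines, length(generations(res)))
  rec <- jsonlite::fromJSON(logLines[[1]])
  expect_identical(rec$generation, 1L)
  summary <- jsonlite::read_json(file.path(outdir, "summary.json"))
  expect_equal(summary$evaluations, evaluations(res))
})

test_that("model merging concatenates and collapses duplicate atoms", {
  a <- NIBModel("a", atomTable(c("C", "N"), c(0, 2), c(0, 0), c(0, 0),
                               c(0, 0.4)))
  b <- NIBModel("b", atomTable(c("O", "C", "S"), c(10, 12, 14), c(0, 0, 0),
                               c(0, 0, 0), c(-0.4, 0, 0)))
  expect_identical(atoms(mergeModels(list(a, a))), atoms(a))
  mAB <- mergeModels(list(a, b))
  expect_identical(nAtoms(mAB), 5L)
  expect_identical(atoms(mAB)$element, c("C", "N", "O", "C", "S"))

  # near-duplicates within tolerance collapse to the first occurrence;
  # same position with a different element does not collapse
  shifted <- NIBModel("a2", atomTable(c("C", "O"), c(0.1, 2.01), c(0, 0),
                                      c(0, 0), c(0, -0.4)))
  m2 <- mergeModels(list(a, shifted), tolerance = 0.25)
  expect_identical(nAtoms(m2), 3L)   # C collapses, O at N's site survives
  m3 <- mergeModels(list(a, shifted), collapse = FALSE)
  expect_identical(nAtoms(m3), 4L)
  expect_error(mergeModels(list()), "non-empty")
})

test_that("merging subpocket models recovers scoring power neither has alone", {
  fx <- smallFixture()
  sig <- fx$truth$signal
  half1 <- NIBModel("h1", atoms(fx$model)[sig[1:3], ])
  half2 <- NIBModel("h2", atoms(fx$model)[sig[4:6], ])
  merged <- mergeModels(list(half1, half2))
  cfg <- smallCfg()
  vMerged <- evaluateModel(merged, fx$library, fx$labels, cfg)
  v1 <- evaluateModel(half1, fx$library, fx$labels, cfg)
  v2 <- evaluateModel(half2, fx$library, fx$labels, cfg)
  expect_gt(vMerged, max(v1, v2))
})

test_that("search-size formulas match enumeration and the generation trace", {
  expect_identical(exhaustiveCount(5, 3), 16)
  # brute-force oracle: enumerate all 2^5 subsets, count those of size >= 3
  grid <- expand.grid(rep(list(c(FALSE, TRUE)), 5))
  expect_identical(sum(rowSums(grid) >= 3), 16L)
  expect_identical(exhaustiveCount(4, 4), 1)
  expect_identical(greedyCount(5, 3), 12)   # 5 + 4 + 3
  expect_identical(greedyCount(6, 6), 6)    # single terminating generation
  expect_error(exhaustiveCount(5, 6), "a1 <= n")
  expect_error(greedyCount(5, 0), "a1")
})
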