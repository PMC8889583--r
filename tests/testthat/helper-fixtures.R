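# Shared fixtures for the test suite. The small benchmark keeps optimizer
# tests fast; the default benchmark is the standard planted-signal scenario.

smallFixtureSpec <- function(seed = 7L) {
  fixtureSpec(nSignal = 6L, nNoise = 4L, nActives = 10L, nDecoys = 40L,
              posesPerCompound = 2L, seed = seed)
}

# memoise the expensive fixtures across test files
.fixtureCache <- new.env(parent = emptyenv())

cachedFixture <- function(key, spec) {
  if (is.null(.fixtureCache[[key]]))
    .fixtureCache[[key]] <- makeFixture(spec)
  .fixtureCache[[key]]
}

smallFixture <- function() cachedFixture("small", smallFixtureSpec())
defaultFixture <- function() cachedFixture("default", fixtureSpec())

# map the atoms of a pruned model back to row indices of the original
survivingAtoms <- function(original, pruned) {
  keyO <- paste(round(original@atoms$x, 6), round(original@atoms$y, 6),
                round(original@atoms$z, 6), original@atoms$element)
  keyK <- paste(round(pruned@atoms$x, 6), round(pruned@atoms$y, 6),
                round(pruned@atoms$z, 6), pruned@atoms$element)
  which(keyO %in% keyK)
}

# a deterministic score table with no skipped compounds
toyScoreTable <- function(scores, labels, skipped = rep(FALSE, length(scores))) {
  data.frame(compound_id = sprintf("c%02d", seq_along(scores)),
             label = labels, skipped = skipped,
             shape = scores, esp = scores, combined = scores,
             best_pose_index = 1L, stringsAsFactors = FALSE)
}

# ranking with actives at the given positions among n entries, scores
# strictly decreasing
rankingWithActivesAt <- function(activePos, n) {
  lab <- rep("decoy", n)
  lab[activePos] <- "active"
  tab <- toyScoreTable(seq(n, 1), lab)
  makeRanking(tab, seed = 1)
}
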