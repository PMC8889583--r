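## Synthetic benchmark generator with planted, recoverable structure.
##
## The cavity model is the union of a compact "signal" cluster (which active
## poses overlap) and an equally compact "noise" cluster — a decoy subpocket
## — centred well outside the active-pose envelope. Actives are jittered
## subsets of the signal cluster; decoys come in two flavours exercising the
## two similarity channels: shape-mismatched decoys straddle the clusters,
## anchoring between one atom and all but one of their atoms in the signal
## site and the rest in the noise cluster (so noise atoms genuinely reward them, pruning the
## noise genuinely helps enrichment, and the classes stay interleaved until
## the noise is nearly gone rather than separating after a removal or two),
## while charge-mismatched decoys sit on the signal with negated charges.
## Per-compound random atom subsets add score spread within each class, so
## the planted structure is recoverable but not trivially separated. Ground truth (which cavity
## atoms are signal) is recorded so optimizer tests can measure recovery.

#' Fixture specification
#'
#' Parameters of the synthetic benchmark. The defaults describe the standard
#' desk-scale scenario: a 16-atom cavity model (8 signal + 8 noise atoms),
#' 30 actives and 300 decoys with 3 poses each, 0.3 Angstrom pose jitter, a
#' noise cluster / decoy docking site 6 Angstrom from the signal centre,
#' half of the cavity atoms charged at 0.4 e, and no skipped compounds.
#'
#' @param nSignal,nNoise cavity atoms in the signal / noise cluster.
#' @param nActives,nDecoys compound counts per class.
#' @param posesPerCompound rigid poses generated per compound.
#' @param jitterSd per-coordinate Gaussian jitter of ligand poses (Angstrom).
#' @param decoyDisplacement distance from the signal centre at which the
#'   noise cluster sits and shape-mismatched decoys dock (Angstrom).
#' @param chargeFraction fraction of cavity atoms carrying a charge.
#' @param chargeMagnitude absolute partial charge of charged atoms (e).
#' @param skipFraction fraction of all compounds marked skipped by docking.
#' @param seed integer seed driving all randomness.
#' @return A named list of class `"nibopt_fixture_spec"`.
#' @export
fixtureSpec <- function(nSignal = 8L, nNoise = 8L, nActives = 30L,
                        nDecoys = 300L, posesPerCompound = 3L,
                        jitterSd = 0.3, decoyDisplacement = 6,
                        chargeFraction = 0.5, chargeMagnitude = 0.4,
                        skipFraction = 0, seed = 42L) {
  spec <- list(nSignal = as.integer(nSignal), nNoise = as.integer(nNoise),
               nActives = as.integer(nActives), nDecoys = as.integer(nDecoys),
               posesPerCompound = as.integer(posesPerCompound),
               jitterSd = jitterSd, decoyDisplacement = decoyDisplacement,
               chargeFraction = chargeFraction,
               chargeMagnitude = chargeMagnitude,
               skipFraction = skipFraction, seed = as.integer(seed))
  with(spec, stopifnot(nSignal >= 1L, nNoise >= 0L, nActives >= 0L,
                       nDecoys >= 0L, posesPerCompound >= 1L, jitterSd >= 0,
                       decoyDisplacement >= 0, chargeFraction >= 0,
                       chargeFraction <= 1, skipFraction >= 0,
                       skipFraction <= 1))
  structure(spec, class = "nibopt_fixture_spec")
}

## compact lattice positions nearest the origin. The 2.2 A spacing keeps
## neighbouring Gaussians' cross-overlap small relative to their self
## overlap, so a pose's self-volume is close to proportional to its atom
## count whatever its geometry — single-atom edits then shift only the
## compounds that actually use the edited atom, not the whole ranking.
signalPositions <- function(n, spacing = 2.2) {
  s <- seq(-spacing, spacing, by = spacing)
  g <- as.matrix(expand.grid(x = s, y = s, z = s))
  g[order(rowSums(g^2), g[, 1], g[, 2], g[, 3])[seq_len(n)], , drop = FALSE]
}

## noise cluster: same compact lattice, displaced along +x
noisePositions <- function(n, displacement) {
  if (n == 0L) return(matrix(numeric(), 0L, 3L))
  p <- signalPositions(n)
  p[, 1] <- p[, 1] + displacement
  p
}

## element/charge assignment: first the positive (N) atoms, then negative
## (O), then neutral (C); charged count = round(fraction * n), balanced.
chargeScheme <- function(n, fraction, magnitude) {
  nc <- round(fraction * n)
  npos <- ceiling(nc / 2); nneg <- nc - npos
  element <- c(rep("N", npos), rep("O", nneg), rep("C", n - nc))
  charge <- c(rep(magnitude, npos), rep(-magnitude, nneg), rep(0, n - nc))
  list(element = element, charge = charge)
}

jitterAtoms <- function(at, sd) {
  if (sd > 0) {
    at$x <- at$x + stats::rnorm(nrow(at), 0, sd)
    at$y <- at$y + stats::rnorm(nrow(at), 0, sd)
    at$z <- at$z + stats::rnorm(nrow(at), 0, sd)
  }
  at
}

#' Generate a synthetic benchmark in memory
#'
#' Builds the cavity model, pose library, activity labels and ground truth
#' described by a [fixtureSpec()], all randomness drawn from the spec's seed
#' (identical spec and seed give identical objects).
#'
#' @param spec a [fixtureSpec()].
#' @return A list with elements `model` ([NIBModel-class]), `library`
#'   ([PoseLibrary-class]), `labels` ([ActivitySet-class]) and `truth` (list
#'   with `signal` and `noise` atom-index vectors partitioning the model).
#' @export
makeFixture <- function(spec = fixtureSpec()) {
  stopifnot(inherits(spec, "nibopt_fixture_spec"))
  withSeed(spec$seed, {
    ## cavity model: signal cluster + noise shell
    sigPos <- signalPositions(spec$nSignal)
    sigCh <- chargeScheme(spec$nSignal, spec$chargeFraction,
                          spec$chargeMagnitude)
    noiPos <- noisePositions(spec$nNoise, spec$decoyDisplacement)
    noiCh <- chargeScheme(spec$nNoise, spec$chargeFraction,
                          spec$chargeMagnitude)
    model <- NIBModel("synthetic_cavity", atomTable(
      c(sigCh$element, noiCh$element),
      c(sigPos[, 1], noiPos[, 1]), c(sigPos[, 2], noiPos[, 2]),
      c(sigPos[, 3], noiPos[, 3]),
      c(sigCh$charge, noiCh$charge)))
    truth <- list(signal = seq_len(spec$nSignal),
                  noise = spec$nSignal + seq_len(spec$nNoise))

    ## ligand templates; each compound is a random subset of its cluster's
    ## atoms (roughly three quarters), so per-compound coverage varies and
    ## the two classes' score distributions interleave
    activeTemplate <- atomTable(sigCh$element, sigPos[, 1], sigPos[, 2],
                                sigPos[, 3], sigCh$charge)
    shapeDecoyTemplate <- if (spec$nNoise > 0L) {
      atomTable(noiCh$element, noiPos[, 1], noiPos[, 2], noiPos[, 3],
                noiCh$charge)
    } else NULL
    subsetSize <- function(n) max(min(3L, n), ceiling(0.75 * n))

    actIds <- sprintf("act_%03d", seq_len(spec$nActives))
    decIds <- sprintf("dec_%03d", seq_len(spec$nDecoys))
    allIds <- c(actIds, decIds)
    nSkip <- round(spec$skipFraction * length(allIds))
    skippedIds <- if (nSkip > 0L) sort(sample(allIds, nSkip)) else character()

    makePoses <- function(template, subset = TRUE) {
      sub <- if (subset) {
        k <- subsetSize(nrow(template))
        template[sort(sample(nrow(template), k)), , drop = FALSE]
      } else template
      lapply(seq_len(spec$posesPerCompound),
             function(i) jitterAtoms(sub, spec$jitterSd))
    }
    ## shape-mismatched decoy: part of its atoms on the signal site, the
    ## rest anchored in the noise cluster. The noise-atom count cycles
    ## deterministically from 1 to all-but-one and the anchors walk the
    ## noise cluster round-robin, so every noise atom keeps supporting some
    ## hard (mostly-signal) decoys — its removal demonstrably improves the
    ## ranking at whatever stage of pruning it happens.
    hybridDecoyTemplate <- function(jj) {
      k <- subsetSize(spec$nSignal)
      ## composition cycle, weighted towards single-anchor ("hard") decoys:
      ## these stay interleaved with the actives and make the last noise
      ## atoms' removal still improve the ranking
      pattern <- if (k > 3L) c(1L, 1L, seq_len(k - 2L)) else seq_len(max(1L, k - 1L))
      kNoi <- min(pattern[(jj %% length(pattern)) + 1L], spec$nNoise)
      kSig <- k - kNoi
      noiIdx <- ((jj + seq_len(kNoi) - 1L) %% spec$nNoise) + 1L
      sig <- if (kSig > 0L)
        activeTemplate[sort(sample(spec$nSignal, kSig)), , drop = FALSE]
      else NULL
      rbind(sig, shapeDecoyTemplate[sort(noiIdx), , drop = FALSE])
    }
    poses <- list()
    for (id in actIds) {
      if (!(id %in% skippedIds)) poses[[id]] <- makePoses(activeTemplate)
    }
    nShapeSeen <- 0L
    for (j in seq_len(spec$nDecoys)) {
      id <- decIds[j]
      shapeFlavour <- j %% 2L == 1L
      if (shapeFlavour && !is.null(shapeDecoyTemplate)) {
        tm <- hybridDecoyTemplate(nShapeSeen)
        nShapeSeen <- nShapeSeen + 1L
        if (!(id %in% skippedIds))
          poses[[id]] <- makePoses(tm, subset = FALSE)
        next
      }
      template <- if (shapeFlavour) {
        u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
        tm <- activeTemplate
        tm$x <- tm$x + u[1] * spec$decoyDisplacement
        tm$y <- tm$y + u[2] * spec$decoyDisplacement
        tm$z <- tm$z + u[3] * spec$decoyDisplacement
        tm
      } else {
        tm <- activeTemplate
        tm$charge <- -tm$charge
        tm
      }
      if (!(id %in% skippedIds)) poses[[id]] <- makePoses(template)
    }
    labels <- ActivitySet(actIds, decIds, skippedIds)
    library <- if (length(poses)) PoseLibrary(poses) else NULL
    list(model = model, library = library, labels = labels, truth = truth,
         spec = unclass(spec))
  })
}

#' Generate a synthetic benchmark on disk
#'
#' Runs [makeFixture()] and writes `model.mol2`, `poses.mol2`,
#' `actives.txt`, `decoys.txt`, `skipped.txt` and a `truth.json` recording
#' the signal/noise atom indices and the generating spec. Byte-identical for
#' identical spec and seed.
#'
#' @param spec a [fixtureSpec()].
#' @param outdir output directory (created if absent).
#' @return The fixture list from [makeFixture()], invisibly, with a `files`
#'   element naming the written paths.
#' @export
generateFixture <- function(spec = fixtureSpec(), outdir) {
  fx <- makeFixture(spec)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- list(model = file.path(outdir, "model.mol2"),
                poses = file.path(outdir, "poses.mol2"),
                actives = file.path(outdir, "actives.txt"),
                decoys = file.path(outdir, "decoys.txt"),
                skipped = file.path(outdir, "skipped.txt"),
                truth = file.path(outdir, "truth.json"))
  writeNibModel(fx$model, files$model)
  if (!is.null(fx$library)) writePoseLibrary(fx$library, files$poses)
  writeIdList(fx$labels@actives, files$actives)
  writeIdList(fx$labels@decoys, files$decoys)
  writeIdList(fx$labels@skipped, files$skipped)
  jsonlite::write_json(
    list(signal = fx$truth$signal, noise = fx$truth$noise, spec = fx$spec),
    files$truth, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  fx$files <- files
  invisible(fx)
}
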