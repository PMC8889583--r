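## Rigid shape and electrostatic-potential similarity between docked poses
## and a cavity NIB model. Poses are never moved: no superposition, no
## optimization — the docking engine's placement is scored as-is.
##
## Shape: first-order Gaussian volume overlap (ROCS-style). Each atom is a
## spherical Gaussian rho_i(r) = p * exp(-alpha_i |r - r_i|^2) with amplitude
## p = 2.7 and width alpha_i fixed so the Gaussian integrates to the
## hard-sphere volume (4/3) pi R_i^3:
##   alpha_i = pi * (3 p / (4 pi R_i^3))^(2/3).
## The overlap of two atom sets is the sum of pairwise Gaussian product
## integrals; similarity is the Hodgkin index 2 O_AB / (O_AA + O_BB) in (0,1].
##
## ESP: Coulomb potentials of both charge sets evaluated at the union of both
## structures' atom centres (softened denominator, epsilon = 0.5 A, so the
## potential stays finite on its own sources), compared by the Hodgkin index
## h in [-1,1] and mapped to (1+h)/2 so shape and ESP blend on one scale.
## Self-terms are kept: excluding a structure's own coincident source while
## the partner's near-coincident source still contributes inverts the sign
## of the comparison for poses within the softening radius of the model, so
## the symmetric (all sources, softened) form is used.

GAUSS_P <- 2.7
ESP_EPSILON <- 0.5

gaussAlpha <- function(radius) {
  pi * (3 * GAUSS_P / (4 * pi * radius^3))^(2 / 3)
}

## coerce NIBModel / atom table to the compiled form used by the inner loops
compileAtoms <- function(x) {
  at <- if (is(x, "NIBModel")) x@atoms else x
  validateAtomTable(at)
  list(xyz = as.matrix(at[, c("x", "y", "z")]),
       alpha = gaussAlpha(at$radius),
       q = at$charge)
}

## squared distances between two coordinate matrices (m x 3, n x 3)
crossDist2 <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}

overlapCompiled <- function(A, B) {
  as_ <- outer(A$alpha, B$alpha, "+")
  ap <- outer(A$alpha, B$alpha)
  sum(GAUSS_P^2 * (pi / as_)^1.5 * exp(-ap * crossDist2(A$xyz, B$xyz) / as_))
}

#' Gaussian volume overlap of two atom sets
#'
#' First-order pairwise Gaussian overlap volume (Angstrom^3) between two
#' rigid atom sets, each atom represented as an amplitude-2.7 Gaussian whose
#' integral equals its hard-sphere van der Waals volume. Symmetric,
#' non-negative, and invariant under common rigid motions.
#'
#' @param a,b atom tables (see [atomTable()]) or [NIBModel-class] objects.
#' @return Overlap volume in cubic Angstrom.
#' @export
#' @examples
#' c1 <- atomTable("C", 0, 0, 0)
#' gaussianOverlap(c1, c1)   # self-overlap of a single carbon
gaussianOverlap <- function(a, b) {
  overlapCompiled(compileAtoms(a), compileAtoms(b))
}

shapeCompiled <- function(P, M, oMM, oPP) {
  2 * overlapCompiled(P, M) / (oMM + oPP)
}

#' Shape similarity of a pose against a cavity model
#'
#' Hodgkin index of the two Gaussian density fields,
#' `2 O_AB / (O_AA + O_BB)`: 1 for identical atom sets, approaching 0 as the
#' structures separate; always positive. The pose is compared where it lies
#' — no realignment of any kind.
#'
#' @param pose atom table of the rigid pose (hydrogens included as read).
#' @param model an [NIBModel-class] or atom table.
#' @return Shape similarity in (0, 1].
#' @export
shapeSimilarity <- function(pose, model) {
  P <- compileAtoms(pose); M <- compileAtoms(model)
  shapeCompiled(P, M, overlapCompiled(M, M), overlapCompiled(P, P))
}

## Coulomb potential of sources (xyz, q) at observer points obs, softened so
## an observer sitting on (or near) a source sees the finite value q / eps.
coulombPotential <- function(obs, src, q, eps = ESP_EPSILON) {
  d <- sqrt(crossDist2(obs, src))
  as.vector((1 / pmax(d, eps)) %*% q)
}

espCompiled <- function(P, M) {
  obs <- rbind(P$xyz, M$xyz)
  vP <- coulombPotential(obs, P$xyz, P$q)
  vM <- coulombPotential(obs, M$xyz, M$q)
  sP <- sum(vP^2); sM <- sum(vM^2)
  if (sP == 0 || sM == 0) return(0.5)   # one or both fields identically zero
  h <- 2 * sum(vP * vM) / (sP + sM)
  (1 + h) / 2
}

#' Electrostatic-potential similarity of a pose against a cavity model
#'
#' Both structures' Coulomb potentials (partial charges, denominator
#' softened below 0.5 Angstrom so the field stays finite on its sources) are
#' sampled at the union of the two structures' atom centres and compared by
#' the Hodgkin index `h in [-1, 1]`, returned mapped to `(1 + h) / 2` so it
#' shares the shape score's `[0, 1]` scale: 1 for an identical charge set in
#' place, 0 for the same geometry with all charges negated. If either charge
#' set is identically zero the neutral value 0.5 is returned.
#'
#' @inheritParams shapeSimilarity
#' @return ESP similarity in `[0, 1]`.
#' @export
espSimilarity <- function(pose, model) {
  espCompiled(compileAtoms(pose), compileAtoms(model))
}

#' Combined shape/ESP similarity score
#'
#' Linear blend `wShape * shape + (1 - wShape) * esp`. The default 0.5 gives
#' the 50/50 shape/ESP weighting; `wShape = 1` is shape-only scoring.
#'
#' @inheritParams shapeSimilarity
#' @param wShape shape weight in `[0, 1]`; the ESP weight is `1 - wShape`.
#' @return A list with components `shape`, `esp` and `combined`, all in
#'   `[0, 1]`.
#' @export
combinedScore <- function(pose, model, wShape = 0.5) {
  stopifnot(is.numeric(wShape), length(wShape) == 1L,
            wShape >= 0, wShape <= 1)
  s <- shapeSimilarity(pose, model)
  e <- if (wShape < 1) espSimilarity(pose, model) else 0.5
  list(shape = s, esp = e, combined = wShape * s + (1 - wShape) * e)
}

#' Rescore a pose library against a cavity model
#'
#' Scores every pose of every labelled compound against the model (rigidly,
#' where the poses lie) and keeps, per compound, the best-scoring pose — the
#' ranking substrate for the enrichment metrics. Compounds in the label set's
#' skipped list are flagged and left unscored. The result is identical for
#' any worker count and any evaluation order.
#'
#' @param model an [NIBModel-class].
#' @param library a [PoseLibrary-class] containing every labelled, non-skipped
#'   compound.
#' @param labels an [ActivitySet-class].
#' @param wShape shape weight in `[0, 1]` (0.5 = 50/50 shape/ESP blend).
#' @param workers number of parallel workers (forked; results are
#'   deterministic regardless).
#' @return A `data.frame` ("score table") with one row per labelled compound:
#'   `compound_id`, `label`, `skipped`, `shape`, `esp`, `combined`,
#'   `best_pose_index` (1-based pose index within the compound). Skipped rows
#'   carry `NA` scores.
#' @export
scoreLibrary <- function(model, library, labels, wShape = 0.5, workers = 1L) {
  stopifnot(is(model, "NIBModel"), is(library, "PoseLibrary"))
  scoreCompiled(model, precompileLibrary(library), labels, wShape, workers)
}

## Precompile every pose (coordinates, Gaussian widths, charges, self
## overlap — all independent of the model) so repeated rescoring against
## model variants skips the per-pose setup.
precompileLibrary <- function(library) {
  lapply(library@poses, function(ps) lapply(ps, function(at) {
    P <- compileAtoms(at)
    P$oPP <- overlapCompiled(P, P)
    P
  }))
}

scoreCompiled <- function(model, compiled, labels, wShape = 0.5,
                          workers = 1L) {
  stopifnot(is(model, "NIBModel"), is(labels, "ActivitySet"))
  stopifnot(is.numeric(wShape), length(wShape) == 1L,
            wShape >= 0, wShape <= 1)
  ids <- c(labels@actives, labels@decoys)
  lab <- rep(c("active", "decoy"),
             c(length(labels@actives), length(labels@decoys)))
  skp <- ids %in% labels@skipped
  missing <- setdiff(ids[!skp], names(compiled))
  if (length(missing))
    stop("labelled compounds missing from the pose library: ",
         paste(missing, collapse = ", "), call. = FALSE)

  M <- compileAtoms(model)
  oMM <- overlapCompiled(M, M)
  scoreOne <- function(id) {
    best <- c(shape = NA_real_, esp = NA_real_, combined = -Inf, pose = NA_real_)
    ps <- compiled[[id]]
    for (k in seq_along(ps)) {
      P <- ps[[k]]
      s <- shapeCompiled(P, M, oMM, P$oPP)
      e <- if (wShape < 1) espCompiled(P, M) else 0.5
      comb <- wShape * s + (1 - wShape) * e
      if (comb > best[["combined"]])
        best <- c(shape = s, esp = e, combined = comb, pose = k)
    }
    best
  }

  todo <- ids[!skp]
  res <- if (workers > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(todo, scoreOne, mc.cores = workers)
  } else {
    lapply(todo, scoreOne)
  }
  tab <- data.frame(
    compound_id = ids, label = lab, skipped = skp,
    shape = NA_real_, esp = NA_real_, combined = NA_real_,
    best_pose_index = NA_integer_,
    stringsAsFactors = FALSE
  )
  if (length(todo)) {
    m <- do.call(rbind, res)
    rows <- match(todo, ids)
    tab$shape[rows] <- m[, "shape"]
    tab$esp[rows] <- m[, "esp"]
    tab$combined[rows] <- m[, "combined"]
    tab$best_pose_index[rows] <- as.integer(m[, "pose"])
  }
  tab
}

#' Write / read a score table as CSV
#'
#' Plain CSV serialization of the [scoreLibrary()] result with columns
#' `compound_id, label, skipped, shape, esp, combined, best_pose_index`.
#'
#' @param table a score table data.frame.
#' @param path file path.
#' @return `writeScoreTable()` returns the path invisibly; `readScoreTable()`
#'   returns the data.frame.
#' @export
writeScoreTable <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeScoreTable
#' @export
readScoreTable <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  tab$skipped <- as.logical(tab$skipped)
  tab
}
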