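#' @import methods
NULL

## Atom tables --------------------------------------------------------------
##
## Cavity pseudo-atoms and ligand atoms share one tabular shape: a data.frame
## with columns element, x, y, z (Angstrom), charge (e) and radius (Angstrom,
## assigned from the Bondi table, never stored in MOL2).

ATOM_COLUMNS <- c("element", "x", "y", "z", "charge", "radius")

#' Build an atom table
#'
#' Assembles the internal atom representation shared by cavity models and
#' ligand poses: one row per (pseudo-)atom with element symbol, Cartesian
#' coordinates in Angstrom, partial charge in elementary-charge units, and a
#' van der Waals radius assigned from the element via [vdwRadius()].
#'
#' @param element character vector of element symbols.
#' @param x,y,z numeric coordinate vectors (Angstrom).
#' @param charge numeric partial charges (e). Defaults to 0.
#' @return A data.frame with columns `element, x, y, z, charge, radius`.
#' @export
#' @examples
#' atomTable("C", 0, 0, 0)
atomTable <- function(element, x, y, z, charge = 0) {
  n <- length(element)
  stopifnot(length(x) == n, length(y) == n, length(z) == n)
  charge <- rep_len(as.numeric(charge), n)
  df <- data.frame(
    element = as.character(element),
    x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
    charge = charge,
    radius = vdwRadius(as.character(element)),
    stringsAsFactors = FALSE
  )
  validateAtomTable(df)
  df
}

validateAtomTable <- function(df, what = "atom table") {
  if (!is.data.frame(df) || !all(ATOM_COLUMNS %in% names(df)))
    stop(what, " must be a data.frame with columns ",
         paste(ATOM_COLUMNS, collapse = ", "), call. = FALSE)
  if (nrow(df) < 1L)
    stop(what, " must contain at least one atom", call. = FALSE)
  if (!all(is.finite(as.matrix(df[, c("x", "y", "z")]))))
    stop(what, ": coordinates must be finite", call. = FALSE)
  if (!all(is.finite(df$charge)))
    stop(what, ": charges must be finite", call. = FALSE)
  if (!all(df$radius > 0))
    stop(what, ": radii must be positive", call. = FALSE)
  invisible(df)
}

## NIBModel ------------------------------------------------------------------

#' NIBModel: a cavity negative-image model
#'
#' An ordered set of cavity pseudo-atoms describing the negative image of a
#' protein binding cavity. By convention neutral points are carbons, positive
#' points nitrogens and negative points oxygens, but any element is allowed;
#' charges are carried explicitly in the `charge` column.
#'
#' @slot name single character, the model name (MOL2 molecule name).
#' @slot atoms atom table (see [atomTable()]); row order is meaningful and is
#'   preserved by MOL2 round-trips.
#' @export
setClass("NIBModel",
  representation(name = "character", atoms = "data.frame"),
  validity = function(object) {
    if (length(object@name) != 1L) return("name must be a single string")
    ok <- tryCatch({ validateAtomTable(object@atoms, "NIBModel atoms"); TRUE },
                   error = function(e) conditionMessage(e))
    if (!isTRUE(ok)) return(ok)
    TRUE
  }
)

#' Construct an NIBModel
#'
#' @param name model name.
#' @param atoms atom table as produced by [atomTable()].
#' @return An [NIBModel-class] object.
#' @export
#' @examples
#' NIBModel("toy", atomTable(c("C", "O"), c(0, 1.4), c(0, 0), c(0, 0),
#'                           charge = c(0, -0.4)))
NIBModel <- function(name, atoms) {
  new("NIBModel", name = as.character(name), atoms = atoms)
}

## PoseLibrary ---------------------------------------------------------------

#' PoseLibrary: rigid docked poses grouped by compound
#'
#' Holds the docking output to be rescored: every compound maps to one or
#' more rigid 3D poses (atom tables), in file order. Repeated molecule names
#' in the source MOL2 are additional poses of the same compound.
#'
#' @slot poses named list; each element is a list of atom tables, one per
#'   pose, in order of appearance (pose index 1, 2, ...).
#' @slot sourceOrder compound identifiers in first-appearance order.
#' @export
setClass("PoseLibrary",
  representation(poses = "list", sourceOrder = "character"),
  validity = function(object) {
    if (length(object@poses) == 0L) return("library must contain >= 1 compound")
    if (anyDuplicated(object@sourceOrder))
      return("sourceOrder must not contain duplicates")
    if (!setequal(names(object@poses), object@sourceOrder))
      return("names(poses) must equal sourceOrder as a set")
    if (any(vapply(object@poses, length, 0L) < 1L))
      return("every compound must have >= 1 pose")
    TRUE
  }
)

#' Construct a PoseLibrary
#'
#' @param poses named list of per-compound pose lists (each pose an atom
#'   table). Names are compound identifiers.
#' @return A [PoseLibrary-class] object whose `sourceOrder` is `names(poses)`.
#' @export
PoseLibrary <- function(poses) {
  new("PoseLibrary", poses = poses, sourceOrder = names(poses))
}

## ActivitySet ---------------------------------------------------------------

#' ActivitySet: active / decoy / skipped compound partition
#'
#' The benchmark labels: known active compounds, presumed-inactive decoys,
#' and the subset of either class that was skipped by docking (no poses
#' available). Actives and decoys are disjoint; skipped is a subset of their
#' union.
#'
#' @slot actives,decoys,skipped character vectors of compound identifiers.
#' @export
setClass("ActivitySet",
  representation(actives = "character", decoys = "character",
                 skipped = "character"),
  validity = function(object) {
    if (length(intersect(object@actives, object@decoys)) > 0L)
      return("actives and decoys overlap")
    if (!all(object@skipped %in% c(object@actives, object@decoys)))
      return("skipped must be a subset of actives plus decoys")
    if (anyDuplicated(object@actives) || anyDuplicated(object@decoys) ||
        anyDuplicated(object@skipped))
      return("compound id sets must not contain duplicates")
    TRUE
  }
)

#' Construct an ActivitySet
#'
#' @param actives,decoys,skipped character vectors of compound ids; `skipped`
#'   must be a subset of the other two combined.
#' @return An [ActivitySet-class] object.
#' @export
#' @examples
#' ActivitySet(actives = c("a1", "a2"), decoys = c("d1", "d2"), skipped = "d2")
ActivitySet <- function(actives, decoys, skipped = character()) {
  new("ActivitySet", actives = unique(as.character(actives)),
      decoys = unique(as.character(decoys)),
      skipped = unique(as.character(skipped)))
}

## Ranking -------------------------------------------------------------------

#' Ranking: an ordered benchmark list
#'
#' The substrate of all enrichment metrics: compounds ordered by decreasing
#' best similarity score (stable in input order on ties), with compounds
#' skipped by docking appended at the bottom in a seeded uniform-random
#' permutation — the order corresponding to random picking — so that early
#' enrichment stays comparable across models.
#'
#' @slot ids compound identifiers in rank order (best first).
#' @slot label per-entry class, `"active"` or `"decoy"`.
#' @slot score per-entry best combined score; `NA` for skipped entries.
#' @slot scored logical; `FALSE` for the appended skipped block.
#' @slot seed integer seed used for the appended-block shuffle.
#' @export
setClass("Ranking",
  representation(ids = "character", label = "character", score = "numeric",
                 scored = "logical", seed = "integer"),
  validity = function(object) {
    n <- length(object@ids)
    if (length(object@label) != n || length(object@score) != n ||
        length(object@scored) != n)
      return("ids, label, score and scored must have equal length")
    if (!all(object@label %in% c("active", "decoy")))
      return("labels must be 'active' or 'decoy'")
    if (any(object@scored & is.na(object@score)))
      return("scored entries must carry a score")
    sc <- which(object@scored); sk <- which(!object@scored)
    if (length(sc) && length(sk) && max(sc) > min(sk))
      return("skipped entries must all rank after scored entries")
    s <- object@score[object@scored]
    if (is.unsorted(-s)) return("scored entries must be sorted descending")
    TRUE
  }
)

## OptimizationResult --------------------------------------------------------

#' OptimizationResult: the trace of a greedy model optimization
#'
#' Everything a run of [brnibOptimize()] or [cutAndGo()] produced: the final
#' pruned model, every intermediate (per-generation) model, the per-generation
#' records of which removals were tried and which was accepted, and the total
#' number of variant evaluations spent.
#'
#' @slot initialModel,finalModel [NIBModel-class] before and after pruning.
#' @slot models list of per-generation accepted models (`models[[1]]` is the
#'   input, one entry per accepted generation thereafter).
#' @slot generations list of generation records; each is a list with fields
#'   `generation`, `parentSize`, `variants` (data.frame `removedIndex`,
#'   `metric`), `accepted` (removed-atom index or `NA`), and `bestMetric`.
#' @slot evaluations total number of single-removal variants evaluated.
#' @slot initialMetric target-metric value of the input model.
#' @slot trajectory metric values of accepted models, strictly increasing,
#'   starting at `initialMetric`.
#' @slot config the [optimizationConfig()] list used.
#' @export
setClass("OptimizationResult",
  representation(initialModel = "NIBModel", finalModel = "NIBModel",
                 models = "list", generations = "list",
                 evaluations = "numeric", initialMetric = "numeric",
                 trajectory = "numeric", config = "list"),
  validity = function(object) {
    tr <- object@trajectory
    if (length(tr) >= 2L && any(diff(tr) <= 0))
      return("accepted-metric trajectory must be strictly increasing")
    TRUE
  }
)
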