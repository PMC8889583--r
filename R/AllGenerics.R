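#' Accessors for nibopt classes
#'
#' Small accessor layer over the S4 slots: `atoms()` returns the atom table of
#' a model, `nAtoms()` its size, `modelName()` its name; `compoundIds()` and
#' `poseCount()` query a [PoseLibrary-class]; `actives()`, `decoys()` and
#' `skipped()` query an [ActivitySet-class]; `finalModel()`, `generations()`,
#' `evaluations()` and `trajectory()` query an [OptimizationResult-class].
#'
#' @param x the object to query.
#' @param compound for `poseCount()`, an optional compound id; when omitted a
#'   named integer vector over all compounds is returned.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))
#' @rdname accessors
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))
#' @rdname accessors
#' @export
setGeneric("modelName", function(x) standardGeneric("modelName"))
#' @rdname accessors
#' @export
setGeneric("compoundIds", function(x) standardGeneric("compoundIds"))
#' @rdname accessors
#' @export
setGeneric("poseCount", function(x, compound) standardGeneric("poseCount"))
#' @rdname accessors
#' @export
setGeneric("actives", function(x) standardGeneric("actives"))
#' @rdname accessors
#' @export
setGeneric("decoys", function(x) standardGeneric("decoys"))
#' @rdname accessors
#' @export
setGeneric("skipped", function(x) standardGeneric("skipped"))
#' @rdname accessors
#' @export
setGeneric("finalModel", function(x) standardGeneric("finalModel"))
#' @rdname accessors
#' @export
setGeneric("generations", function(x) standardGeneric("generations"))
#' @rdname accessors
#' @export
setGeneric("evaluations", function(x) standardGeneric("evaluations"))
#' @rdname accessors
#' @export
setGeneric("trajectory", function(x) standardGeneric("trajectory"))

#' @rdname accessors
#' @export
setMethod("atoms", "NIBModel", function(x) x@atoms)
#' @rdname accessors
#' @export
setMethod("nAtoms", "NIBModel", function(x) nrow(x@atoms))
#' @rdname accessors
#' @export
setMethod("modelName", "NIBModel", function(x) x@name)

#' @rdname accessors
#' @export
setMethod("compoundIds", "PoseLibrary", function(x) x@sourceOrder)
#' @rdname accessors
#' @export
setMethod("poseCount", "PoseLibrary", function(x, compound) {
  counts <- vapply(x@poses, length, 0L)[x@sourceOrder]
  if (missing(compound)) counts else unname(counts[compound])
})

#' @rdname accessors
#' @export
setMethod("actives", "ActivitySet", function(x) x@actives)
#' @rdname accessors
#' @export
setMethod("decoys", "ActivitySet", function(x) x@decoys)
#' @rdname accessors
#' @export
setMethod("skipped", "ActivitySet", function(x) x@skipped)

#' @rdname accessors
#' @export
setMethod("finalModel", "OptimizationResult", function(x) x@finalModel)
#' @rdname accessors
#' @export
setMethod("generations", "OptimizationResult", function(x) x@generations)
#' @rdname accessors
#' @export
setMethod("evaluations", "OptimizationResult", function(x) x@evaluations)
#' @rdname accessors
#' @export
setMethod("trajectory", "OptimizationResult", function(x) x@trajectory)

## show methods -------------------------------------------------------------

setMethod("show", "NIBModel", function(object) {
  elems <- table(object@atoms$element)
  cat("NIBModel '", object@name, "': ", nrow(object@atoms), " cavity atoms (",
      paste0(names(elems), ":", elems, collapse = " "), ")\n", sep = "")
})

setMethod("show", "PoseLibrary", function(object) {
  counts <- vapply(object@poses, length, 0L)
  cat("PoseLibrary: ", length(object@poses), " compounds, ",
      sum(counts), " poses (", min(counts), "-", max(counts),
      " per compound)\n", sep = "")
})

setMethod("show", "ActivitySet", function(object) {
  cat("ActivitySet: ", length(object@actives), " actives, ",
      length(object@decoys), " decoys, ",
      length(object@skipped), " skipped\n", sep = "")
})

setMethod("show", "Ranking", function(object) {
  cat("Ranking: ", length(object@ids), " compounds (",
      sum(object@label == "active"), " active, ",
      sum(!object@scored), " skipped at bottom), shuffle seed ",
      object@seed, "\n", sep = "")
})

setMethod("show", "OptimizationResult", function(object) {
  cat("OptimizationResult: ", nAtoms(object@initialModel), " -> ",
      nAtoms(object@finalModel), " atoms in ",
      length(object@generations), " generations; metric ",
      format(object@initialMetric, digits = 4), " -> ",
      format(object@trajectory[length(object@trajectory)], digits = 4),
      " (", object@evaluations, " variant evaluations)\n", sep = "")
})
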