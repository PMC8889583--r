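## TRIPOS MOL2 input/output for cavity models and docked-pose libraries,
## plus plain-text compound-id lists and the Bondi radius table.
##
## Dialect: records start at @<TRIPOS>MOLECULE; the line after the tag is the
## molecule name; atoms live in @<TRIPOS>ATOM with the SYBYL column layout
## (id, name, x, y, z, atom_type, subst_id, subst_name, charge) — the ninth
## column is the partial charge and is required. All other sections are
## ignored. Coordinates are Angstrom throughout.

BONDI_RADII <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
  F = 1.47, Cl = 1.75, Br = 1.85, I = 1.98
)
DEFAULT_RADIUS <- 1.70

#' Van der Waals radius of an element
#'
#' Bondi radii for the common organic elements and halogens; unknown elements
#' fall back to a configurable default. Only relative Gaussian overlaps enter
#' the similarity scores, so the fallback is benign for exotic pseudo-atoms.
#'
#' @param element character vector of element symbols (case-sensitive, e.g.
#'   `"Cl"`).
#' @param default radius in Angstrom for unrecognized elements.
#' @return Numeric vector of radii in Angstrom.
#' @export
#' @examples
#' vdwRadius(c("C", "O", "Xx"))
vdwRadius <- function(element, default = DEFAULT_RADIUS) {
  r <- BONDI_RADII[element]
  r[is.na(r)] <- default
  unname(r)
}

## Split MOL2 text lines into records (one per @<TRIPOS>MOLECULE tag).
mol2Records <- function(lines) {
  tags <- which(trimws(lines) == "@<TRIPOS>MOLECULE")
  if (length(tags) == 0L)
    stop("not a TRIPOS MOL2 file: no @<TRIPOS>MOLECULE record", call. = FALSE)
  ends <- c(tags[-1L] - 1L, length(lines))
  lapply(seq_along(tags), function(i) lines[tags[i]:ends[i]])
}

## Parse one MOLECULE record into list(name, atoms).
parseMol2Record <- function(rec, index = 1L) {
  if (length(rec) < 2L)
    stop("malformed MOL2 record ", index, ": missing molecule name",
         call. = FALSE)
  name <- trimws(rec[2L])
  sect <- which(startsWith(trimws(rec), "@<TRIPOS>"))
  atomTag <- which(trimws(rec) == "@<TRIPOS>ATOM")
  if (length(atomTag) != 1L)
    stop("malformed MOL2 record ", index, " ('", name,
         "'): expected exactly one @<TRIPOS>ATOM section", call. = FALSE)
  nxt <- sect[sect > atomTag]
  to <- if (length(nxt)) min(nxt) - 1L else length(rec)
  body <- trimws(rec[seq.int(atomTag + 1L, length.out = max(0L, to - atomTag))])
  body <- body[nzchar(body) & !startsWith(body, "#")]
  if (length(body) == 0L)
    stop("MOL2 record ", index, " ('", name, "') contains zero atoms",
         call. = FALSE)
  fields <- strsplit(body, "[[:space:]]+")
  nf <- vapply(fields, length, 0L)
  if (any(nf < 9L))
    stop("malformed MOL2 record ", index, " ('", name,
         "'): atom line lacks the ninth (partial charge) column",
         call. = FALSE)
  m <- t(vapply(fields, function(f) f[1:9], character(9L)))
  xyz <- suppressWarnings(apply(m[, 3:5, drop = FALSE], 2L, as.numeric))
  charge <- suppressWarnings(as.numeric(m[, 9L]))
  if (any(is.na(xyz)) || any(is.na(charge)))
    stop("malformed MOL2 record ", index, " ('", name,
         "'): non-numeric coordinate or charge", call. = FALSE)
  xyz <- matrix(xyz, ncol = 3L)
  element <- sub("\\..*$", "", m[, 6L])
  list(name = name,
       atoms = atomTable(element, xyz[, 1L], xyz[, 2L], xyz[, 3L], charge))
}

#' Read a cavity NIB model from a TRIPOS MOL2 file
#'
#' The file must contain exactly one `@<TRIPOS>MOLECULE` record; atom order
#' is preserved, radii are assigned from the element via [vdwRadius()], and
#' partial charges are taken verbatim from the ninth atom-line column.
#'
#' @param path path to a single-record MOL2 file.
#' @return An [NIBModel-class].
#' @seealso [writeNibModel()], [readPoseLibrary()]
#' @export
readNibModel <- function(path) {
  lines <- readLines(path, warn = FALSE)
  recs <- mol2Records(lines)
  if (length(recs) != 1L)
    stop("NIB model files must contain exactly one MOLECULE record, found ",
         length(recs), call. = FALSE)
  p <- parseMol2Record(recs[[1L]])
  NIBModel(p$name, p$atoms)
}

mol2AtomTypes <- function(element) {
  ## minimal SYBYL typing: plain element symbol (readable back as-is)
  element
}

formatMol2Record <- function(name, at) {
  n <- nrow(at)
  c("@<TRIPOS>MOLECULE",
    name,
    sprintf("%5d %5d %5d %5d %5d", n, 0L, 0L, 0L, 0L),
    "SMALL",
    "USER_CHARGES",
    "@<TRIPOS>ATOM",
    sprintf("%7d %-8s %10.4f %10.4f %10.4f %-8s %3d %-8s %9.4f",
            seq_len(n), paste0(at$element, seq_len(n)),
            at$x, at$y, at$z, mol2AtomTypes(at$element),
            1L, "UNL1", at$charge))
}

#' Write a cavity NIB model as TRIPOS MOL2
#'
#' Emits a single-record MOL2 that [readNibModel()] parses back to an equal
#' model (element, coordinates to 1e-4 Angstrom, charge to 1e-4 e), preserving
#' atom order.
#'
#' @param model an [NIBModel-class].
#' @param path output file path.
#' @return The path, invisibly.
#' @export
writeNibModel <- function(model, path) {
  stopifnot(is(model, "NIBModel"))
  writeLines(formatMol2Record(model@name, model@atoms), path)
  invisible(path)
}

#' Read a docked-pose library from a multi-record TRIPOS MOL2 file
#'
#' Each `@<TRIPOS>MOLECULE` record is one rigid pose; the molecule name
#' identifies the compound and repeated names are additional poses of the
#' same compound, indexed by order of appearance. Hydrogens are kept as read.
#'
#' @param path path to a multi-record MOL2 file.
#' @return A [PoseLibrary-class].
#' @export
readPoseLibrary <- function(path) {
  lines <- readLines(path, warn = FALSE)
  recs <- mol2Records(lines)
  poses <- list()
  order <- character()
  for (i in seq_along(recs)) {
    p <- parseMol2Record(recs[[i]], index = i)
    if (is.null(poses[[p$name]])) {
      poses[[p$name]] <- list(p$atoms)
      order <- c(order, p$name)
    } else {
      poses[[p$name]] <- c(poses[[p$name]], list(p$atoms))
    }
  }
  new("PoseLibrary", poses = poses[order], sourceOrder = order)
}

#' Write a pose library as multi-record TRIPOS MOL2
#'
#' Inverse of [readPoseLibrary()]: one MOLECULE record per pose, compounds in
#' `sourceOrder`, poses in index order (so repeated names encode the pose
#' index implicitly).
#'
#' @param library a [PoseLibrary-class].
#' @param path output file path.
#' @return The path, invisibly.
#' @export
writePoseLibrary <- function(library, path) {
  stopifnot(is(library, "PoseLibrary"))
  out <- unlist(lapply(library@sourceOrder, function(id) {
    unlist(lapply(library@poses[[id]], function(at) formatMol2Record(id, at)))
  }))
  writeLines(out, path)
  invisible(path)
}

#' Read a plain-text compound-id list
#'
#' One id per line; blank lines and lines starting with `#` are ignored;
#' duplicates collapse. An empty file yields an empty set.
#'
#' @param path path to the id list.
#' @return Character vector of unique ids (file order of first appearance).
#' @export
readIdList <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  unique(x[nzchar(x) & !startsWith(x, "#")])
}

#' Write a compound-id list
#'
#' @param ids character vector of compound ids.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
writeIdList <- function(ids, path) {
  writeLines(as.character(ids), path)
  invisible(path)
}

#' Read activity labels from id-list files
#'
#' Convenience wrapper building an [ActivitySet-class] from the actives,
#' decoys and (optional) skipped-compound id lists that accompany a
#' benchmark. Overlapping actives/decoys raise a labelled error.
#'
#' @param activesPath,decoysPath,skippedPath paths to id lists
#'   (see [readIdList()]); `skippedPath` may be `NULL`.
#' @return An [ActivitySet-class].
#' @export
readActivitySet <- function(activesPath, decoysPath, skippedPath = NULL) {
  act <- readIdList(activesPath)
  dec <- readIdList(decoysPath)
  both <- intersect(act, dec)
  if (length(both))
    stop("compounds labelled both active and decoy: ",
         paste(both, collapse = ", "), call. = FALSE)
  skp <- if (is.null(skippedPath)) character() else readIdList(skippedPath)
  ActivitySet(act, dec, skp)
}
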