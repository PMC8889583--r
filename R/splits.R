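## Seeded random training/test division of labelled compound sets.

#' Randomly split labelled compounds into training and test sets
#'
#' Shuffles each class with a seeded Mersenne-Twister generator and assigns
#' the first `round(n_class * trainFraction)` compounds (at least one per
#' non-empty class) to training — the 70:30 and 10:90 protocols used when a
#' wealth of activity data or only a small set is available. Stratified by
#' class by default so both sides keep the active:decoy proportion; with
#' `stratified = FALSE` the pooled set is shuffled and cut once. Compounds in
#' the skipped list retain that status on whichever side they land.
#'
#' @param labels an [ActivitySet-class] with both classes non-empty.
#' @param trainFraction fraction in `(0, 1)` assigned to training.
#' @param seed integer seed; identical seeds give identical splits.
#' @param stratified split actives and decoys independently (default `TRUE`).
#' @return A list with elements `train` and `test`, both
#'   [ActivitySet-class] objects partitioning the input.
#' @export
#' @examples
#' labels <- ActivitySet(paste0("a", 1:10), paste0("d", 1:100))
#' sp <- randomSplit(labels, 0.7, seed = 1)
#' length(actives(sp$train))  # 7
randomSplit <- function(labels, trainFraction, seed = 1L, stratified = TRUE) {
  stopifnot(is(labels, "ActivitySet"))
  if (!is.numeric(trainFraction) || length(trainFraction) != 1L ||
      trainFraction <= 0 || trainFraction >= 1)
    stop("trainFraction must lie strictly between 0 and 1", call. = FALSE)
  if (length(labels@actives) == 0L || length(labels@decoys) == 0L)
    stop("both classes must be non-empty", call. = FALSE)

  takeTrain <- function(ids) {
    n <- length(ids)
    k <- max(1L, min(n, round(n * trainFraction)))
    sh <- sample(ids)
    list(train = sh[seq_len(k)], test = sh[-seq_len(k)])
  }
  parts <- withSeed(seed, {
    if (stratified) {
      a <- takeTrain(labels@actives)
      d <- takeTrain(labels@decoys)
      list(trainA = a$train, testA = a$test,
           trainD = d$train, testD = d$test)
    } else {
      all <- takeTrain(c(labels@actives, labels@decoys))
      list(trainA = intersect(all$train, labels@actives),
           testA = intersect(all$test, labels@actives),
           trainD = intersect(all$train, labels@decoys),
           testD = intersect(all$test, labels@decoys))
    }
  })
  list(
    train = ActivitySet(parts$trainA, parts$trainD,
                        intersect(labels@skipped,
                                  c(parts$trainA, parts$trainD))),
    test = ActivitySet(parts$testA, parts$testD,
                       intersect(labels@skipped,
                                 c(parts$testA, parts$testD)))
  )
}

#' Write a train/test split as id-list files plus a manifest
#'
#' Emits `train_actives.txt`, `train_decoys.txt`, `test_actives.txt`,
#' `test_decoys.txt` (plus the two skipped lists) and a `manifest.json`
#' recording the seed and fraction used.
#'
#' @param split a list from [randomSplit()].
#' @param outdir output directory (created if absent).
#' @param trainFraction,seed the parameters used, echoed into the manifest.
#' @return `outdir`, invisibly.
#' @export
writeSplit <- function(split, outdir, trainFraction = NA, seed = NA) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  writeIdList(split$train@actives, file.path(outdir, "train_actives.txt"))
  writeIdList(split$train@decoys, file.path(outdir, "train_decoys.txt"))
  writeIdList(split$train@skipped, file.path(outdir, "train_skipped.txt"))
  writeIdList(split$test@actives, file.path(outdir, "test_actives.txt"))
  writeIdList(split$test@decoys, file.path(outdir, "test_decoys.txt"))
  writeIdList(split$test@skipped, file.path(outdir, "test_skipped.txt"))
  jsonlite::write_json(
    list(train_fraction = trainFraction, seed = seed,
         train = list(actives = length(split$train@actives),
                      decoys = length(split$train@decoys)),
         test = list(actives = length(split$test@actives),
                     decoys = length(split$test@decoys))),
    file.path(outdir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(outdir)
}
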