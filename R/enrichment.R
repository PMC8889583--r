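## Ranking construction and virtual-screening enrichment metrics:
## ROC AUC with the Wilcoxon/Hanley-McNeil standard error, enrichment factor
## at fixed decoy fractions (EFd), BEDROC (Truchon-Bailey), and ROC-curve
## export.

#' Build a benchmark ranking from a score table
#'
#' Scored compounds are sorted by decreasing best combined score (stable:
#' ties keep their input order); compounds skipped by docking are appended at
#' the bottom in a seeded uniform-random permutation — the order that
#' corresponds to random picking — so early-enrichment values remain
#' comparable between models regardless of docking failures.
#'
#' @param table a score table from [scoreLibrary()].
#' @param seed integer seed for the appended-block shuffle (recorded in the
#'   ranking).
#' @return A [Ranking-class].
#' @export
makeRanking <- function(table, seed = 1L) {
  stopifnot(is.data.frame(table), nrow(table) >= 1L)
  seed <- as.integer(seed)
  sc <- which(!table$skipped)
  sk <- which(table$skipped)
  sc <- sc[orderDescStable(table$combined[sc])]
  if (length(sk) > 1L) sk <- withSeed(seed, sample(sk))
  idx <- c(sc, sk)
  new("Ranking",
      ids = table$compound_id[idx],
      label = table$label[idx],
      score = ifelse(table$skipped[idx], NA_real_, table$combined[idx]),
      scored = !table$skipped[idx],
      seed = seed)
}

checkTwoClasses <- function(ranking) {
  na <- sum(ranking@label == "active")
  nd <- sum(ranking@label == "decoy")
  if (na == 0L || nd == 0L)
    stop("metric undefined: ranking needs at least one active and one decoy",
         call. = FALSE)
  c(na = na, nd = nd)
}

## Effective scores: scored entries keep their combined score; skipped
## entries get strictly decreasing values below the minimum so that their
## realized (random-picking) order is what the threshold metrics see, while
## equal scores among scored entries still count as ties (0.5) in the AUC.
effectiveScores <- function(ranking) {
  s <- ranking@score
  nsk <- sum(!ranking@scored)
  if (nsk > 0L) {
    base <- if (any(ranking@scored)) min(s[ranking@scored]) else 0
    s[!ranking@scored] <- base - seq_len(nsk)
  }
  s
}

#' ROC AUC with Wilcoxon standard error
#'
#' The area under the ROC curve as the Wilcoxon-Mann-Whitney statistic: the
#' fraction of (active, decoy) pairs in which the active ranks higher, ties
#' counting one half. The standard error is the Hanley-McNeil estimate with
#' `Q1 = A / (2 - A)` and `Q2 = 2 A^2 / (1 + A)`.
#'
#' @param ranking a [Ranking-class] containing both classes.
#' @return A list with `auc` and `se`.
#' @export
rocAuc <- function(ranking) {
  n <- checkTwoClasses(ranking)
  s <- effectiveScores(ranking)
  r <- rank(s, ties.method = "average")
  A <- (sum(r[ranking@label == "active"]) - n["na"] * (n["na"] + 1) / 2) /
    (n["na"] * n["nd"])
  A <- unname(A)
  q1 <- A / (2 - A)
  q2 <- 2 * A^2 / (1 + A)
  se <- sqrt((A * (1 - A) + (n["na"] - 1) * (q1 - A^2) +
                (n["nd"] - 1) * (q2 - A^2)) / (n["na"] * n["nd"]))
  list(auc = A, se = unname(se))
}

#' Enrichment factor at a decoy fraction (EFd)
#'
#' Walks the ranking until `ceiling(fraction * n_decoys)` decoys have been
#' discovered and returns the percentage of actives found strictly before
#' that point — the EFd 0.1/0.5/1/5% family of early-enrichment measures.
#'
#' @param ranking a [Ranking-class] containing both classes.
#' @param fraction decoy fraction in `(0, 1]` (e.g. 0.01 for EFd 1%).
#' @return Percentage of actives retrieved, in `[0, 100]`.
#' @export
enrichmentFactorD <- function(ranking, fraction) {
  stopifnot(is.numeric(fraction), length(fraction) == 1L,
            fraction > 0, fraction <= 1)
  n <- checkTwoClasses(ranking)
  k <- ceiling(fraction * n["nd"])
  pos <- which(ranking@label == "decoy")[k]
  before <- if (pos > 1L) sum(ranking@label[seq_len(pos - 1L)] == "active")
            else 0L
  unname(100 * before / n["na"])
}

#' BEDROC early-recognition metric
#'
#' The Boltzmann-enhanced discrimination of the ROC (Truchon-Bailey): actives
#' at relative ranks `x_i = r_i / N` contribute `exp(-alpha x_i)`; the
#' resulting RIE is rescaled to `[0, 1]`. Larger `alpha` concentrates the
#' weight on the top of the ranking; `alpha = 20` (BR20) weights roughly the
#' first 8% of the list.
#'
#' @param ranking a [Ranking-class] with at least one active and two entries.
#' @param alpha positive exponential weight (default 20).
#' @return BEDROC value in `[0, 1]`.
#' @export
bedroc <- function(ranking, alpha = 20) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0)
    stop("alpha must be a positive number", call. = FALSE)
  N <- length(ranking@ids)
  ra <- which(ranking@label == "active")
  n <- length(ra)
  if (n < 1L || N < 2L)
    stop("BEDROC needs >= 1 active and >= 2 compounds", call. = FALSE)
  x <- ra / N
  rie <- sum(exp(-alpha * x)) /
    (n * (1 / N) * (1 - exp(-alpha)) / (exp(alpha / N) - 1))
  Ra <- n / N
  rie * Ra * sinh(alpha / 2) /
    (cosh(alpha / 2) - cosh(alpha / 2 - alpha * Ra)) +
    1 / (1 - exp(alpha * (1 - Ra)))
}

#' ROC curve of a ranking
#'
#' The standard staircase from (0,0) to (1,1): one point per distinct score
#' level (tied scores produce a single diagonal segment), so the trapezoid
#' area under the exported curve equals [rocAuc()] exactly.
#'
#' @param ranking a [Ranking-class] containing both classes.
#' @return A `data.frame` with columns `fpr` and `tpr`, both monotone
#'   non-decreasing from 0 to 1.
#' @export
rocCurve <- function(ranking) {
  n <- checkTwoClasses(ranking)
  s <- effectiveScores(ranking)
  o <- order(-s)                      # ranking order; ties grouped below
  tp <- cumsum(ranking@label[o] == "active")
  fp <- cumsum(ranking@label[o] == "decoy")
  keep <- c(diff(s[o]) != 0, TRUE)    # last index of each tied score group
  data.frame(fpr = c(0, fp[keep] / n["nd"]),
             tpr = c(0, tp[keep] / n["na"]))
}

trapezoidArea <- function(curve) {
  sum(diff(curve$fpr) * (utils::head(curve$tpr, -1) + utils::tail(curve$tpr, -1)) / 2)
}

#' Bundle the enrichment metrics for a score table
#'
#' Builds the ranking (see [makeRanking()]) and computes AUC with its
#' standard error, EFd at the requested decoy fractions and BEDROC at the
#' requested alphas. The result serializes cleanly to JSON.
#'
#' @param table a score table from [scoreLibrary()].
#' @param fractions decoy fractions for EFd (defaults to 0.1, 0.5, 1 and 5%).
#' @param alphas BEDROC alpha values (default 20).
#' @param seed shuffle seed for the skipped block.
#' @return A list with `auc`, `auc_se`, `efd` (named by fraction), `bedroc`
#'   (named by alpha) and `seed`.
#' @export
metricReport <- function(table, fractions = c(0.001, 0.005, 0.01, 0.05),
                         alphas = 20, seed = 1L) {
  rk <- makeRanking(table, seed)
  a <- rocAuc(rk)
  efd <- vapply(fractions, function(f) enrichmentFactorD(rk, f), 0)
  names(efd) <- as.character(fractions)
  br <- vapply(alphas, function(al) bedroc(rk, al), 0)
  names(br) <- as.character(alphas)
  list(auc = a$auc, auc_se = a$se,
       efd = as.list(efd), bedroc = as.list(br),
       seed = as.integer(seed))
}

#' Write a metric report as JSON / a ROC curve as TSV
#'
#' @param report a list from [metricReport()].
#' @param curve a data.frame from [rocCurve()].
#' @param path output file path.
#' @return The path, invisibly.
#' @export
writeMetricReport <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname writeMetricReport
#' @export
writeRocCurve <- function(curve, path) {
  utils::write.table(curve, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
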