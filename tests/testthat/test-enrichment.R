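test_that("rankings sort stably and append skipped entries reproducibly", {
  tab <- toyScoreTable(c(0.5, 0.9, 0.5, 0.1), c("active", "decoy", "active",
                                                "decoy"))
  rk <- makeRanking(tab, seed = 3)
  expect_identical(rk@ids, c("c02", "c01", "c03", "c04"))  # stable on the tie

  skp <- toyScoreTable(rep(NA_real_, 5), rep(c("active", "decoy"), c(2, 3)),
                       skipped = rep(TRUE, 5))
  r1 <- makeRanking(skp, seed = 9)
  r2 <- makeRanking(skp, seed = 9)
  expect_identical(r1@ids, r2@ids)
  expect_false(any(r1@scored))

  mix <- toyScoreTable(c(0.2, NA, 0.8, NA), rep("active", 4),
                       skipped = c(FALSE, TRUE, FALSE, TRUE))
  rm <- makeRanking(mix, seed = 1)
  expect_identical(rm@ids[1:2], c("c03", "c01"))
  expect_true(all(!rm@scored[3:4]))
})

test_that("AUC matches pair counting, symmetry and the printed toy case", {
  # actives at ranks 1 and 3 of 4: 3 of 4 pairs correct
  rk <- rankingWithActivesAt(c(1, 3), 4)
  expect_equal(rocAuc(rk)$auc, 0.75)

  perfect <- rankingWithActivesAt(1:5, 10)
  expect_equal(rocAuc(perfect)$auc, 1)
  expect_equal(rocAuc(perfect)$se, 0)

  set.seed(21)
  for (i in 1:5) {
    n <- 200
    lab <- sample(rep(c("active", "decoy"), c(40, 160)))
    scores <- round(runif(n), 2)            # deliberate ties
    skp <- runif(n) < 0.05
    scores[skp] <- NA
    tab <- toyScoreTable(scores, lab, skp)
    rk <- makeRanking(tab, seed = i)
    expect_equal(rocAuc(rk)$auc, aucPairOracle(rk), tolerance = 1e-12)
    # label inversion flips the AUC
    tab2 <- tab
    tab2$label <- ifelse(tab$label == "active", "decoy", "active")
    expect_equal(rocAuc(makeRanking(tab2, seed = i))$auc,
                 1 - rocAuc(rk)$auc, tolerance = 1e-12)
  }
  single <- toyScoreTable(c(0.4, 0.2), c("active", "active"))
  expect_error(rocAuc(makeRanking(single, 1)), "undefined")
})

test_that("AUC agrees with pROC on a tie-free ranking", {
  skip_if_not_installed("pROC")
  set.seed(22)
  n <- 150
  lab <- sample(rep(c("active", "decoy"), c(30, 120)))
  scores <- runif(n)
  tab <- toyScoreTable(scores, lab)
  a <- rocAuc(makeRanking(tab, 1))$auc
  p <- suppressMessages(pROC::auc(pROC::roc(
    response = lab, predictor = scores, levels = c("decoy", "active"),
    direction = "<")))
  expect_equal(a, as.numeric(p), tolerance = 1e-12)
})

test_that("Wilcoxon standard error follows the Hanley-McNeil formula", {
  rk <- rankingWithActivesAt(c(1, 3, 4), 10)
  res <- rocAuc(rk)
  A <- res$auc
  na <- 3; nd <- 7
  q1 <- A / (2 - A); q2 <- 2 * A^2 / (1 + A)
  se <- sqrt((A * (1 - A) + (na - 1) * (q1 - A^2) + (nd - 1) * (q2 - A^2)) /
               (na * nd))
  expect_equal(res$se, se, tolerance = 1e-12)
})

test_that("EFd counts actives before the threshold decoy", {
  perfect <- rankingWithActivesAt(1:10, 1010)
  for (f in c(0.001, 0.01, 0.05, 1)) {
    expect_equal(enrichmentFactorD(perfect, f), 100)
  }
  worst <- rankingWithActivesAt(1001:1010, 1010)
  expect_equal(enrichmentFactorD(worst, 0.01), 0)

  # 10 actives, 1000 decoys, 4 actives precede the 10th decoy
  pos <- c(1, 3, 5, 7, seq(990, 995))      # actives; 10th decoy at position 14
  stopifnot(sum(pos <= 13) == 4)
  rk <- rankingWithActivesAt(pos, 1010)
  expect_equal(enrichmentFactorD(rk, 0.01), 40)
  expect_equal(enrichmentFactorD(rk, 0.01), efdOracle(rk, 0.01))

  # monotone non-decreasing in the fraction
  set.seed(23)
  lab <- sample(rep(c("active", "decoy"), c(20, 200)))
  rk2 <- makeRanking(toyScoreTable(runif(220), lab), 1)
  fr <- c(0.001, 0.005, 0.01, 0.05, 0.2, 1)
  vals <- vapply(fr, function(f) enrichmentFactorD(rk2, f), 0)
  expect_true(all(diff(vals) >= 0))
  for (f in fr) expect_equal(enrichmentFactorD(rk2, f), efdOracle(rk2, f))
})

test_that("BEDROC matches the closed form, its limits and the min-max oracle", {
  # single active on top of 100: direct evaluation of the closed form
  rk <- rankingWithActivesAt(1, 100)
  alpha <- 20; N <- 100; n <- 1; Ra <- n / N
  rie <- exp(-alpha / N) / (n * (1 / N) * (1 - exp(-alpha)) /
                              (exp(alpha / N) - 1))
  expected <- rie * Ra * sinh(alpha / 2) /
    (cosh(alpha / 2) - cosh(alpha / 2 - alpha * Ra)) +
    1 / (1 - exp(alpha * (1 - Ra)))
  expect_equal(bedroc(rk, 20), expected, tolerance = 1e-12)
  expect_gt(bedroc(rk, 20), 0.9)

  # worst ranking with few actives in a large set
  worst <- rankingWithActivesAt(991:1000, 1000)
  expect_lt(bedroc(worst, 20), 0.01)

  # small-alpha limit approaches the AUC
  set.seed(24)
  for (i in 1:3) {
    lab <- sample(rep(c("active", "decoy"), c(100, 9900)))
    rk3 <- makeRanking(toyScoreTable(runif(10000), lab), 1)
    expect_lt(abs(bedroc(rk3, 0.1) - rocAuc(rk3)$auc), 0.05)
  }

  # min-max rescaled RIE oracle (independent route), large N
  lab <- sample(rep(c("active", "decoy"), c(50, 4950)))
  rk4 <- makeRanking(toyScoreTable(runif(5000), lab), 1)
  expect_equal(bedroc(rk4, 20), bedrocMinMaxOracle(rk4, 20),
               tolerance = 1e-3)

  # promoting an active by one adjacent swap increases BEDROC
  rk5 <- rankingWithActivesAt(c(5, 50), 200)
  rk6 <- rankingWithActivesAt(c(5, 49), 200)
  expect_gt(bedroc(rk6, 20), bedroc(rk5, 20))

  expect_error(bedroc(rk5, 0), "positive")
})

test_that("ROC curves are monotone staircases whose area equals the AUC", {
  perfect <- rankingWithActivesAt(1:5, 25)
  cv <- rocCurve(perfect)
  expect_equal(cv[1, ], data.frame(fpr = 0, tpr = 0))
  expect_equal(unlist(cv[nrow(cv), ]), c(fpr = 1, tpr = 1))
  expect_true(all(diff(cv$fpr) >= 0) && all(diff(cv$tpr) >= 0))
  expect_equal(cv$tpr[cv$fpr == 0][sum(cv$fpr == 0)], 1)  # vertical first

  trapezoid <- function(cv)
    sum(diff(cv$fpr) * (head(cv$tpr, -1) + tail(cv$tpr, -1)) / 2)

  set.seed(25)
  for (i in 1:5) {
    lab <- sample(rep(c("active", "decoy"), c(30, 120)))
    scores <- round(runif(150), 2)          # ties included
    rk <- makeRanking(toyScoreTable(scores, lab), i)
    expect_equal(trapezoid(rocCurve(rk)), rocAuc(rk)$auc, tolerance = 1e-12)
    # reversing the scores mirrors the curve: areas are exact complements
    rkRev <- makeRanking(toyScoreTable(-scores, lab), i)
    expect_equal(trapezoid(rocCurve(rkRev)), 1 - trapezoid(rocCurve(rk)),
                 tolerance = 1e-12)
  }
})

test_that("metrics are invariant to uniform positive rescaling of scores", {
  set.seed(26)
  lab <- sample(rep(c("active", "decoy"), c(20, 80)))
  sc <- runif(100)
  r1 <- makeRanking(toyScoreTable(sc, lab), 4)
  r2 <- makeRanking(toyScoreTable(sc * 7.3, lab), 4)
  expect_equal(rocAuc(r1)$auc, rocAuc(r2)$auc)
  expect_equal(bedroc(r1, 20), bedroc(r2, 20))
  expect_equal(enrichmentFactorD(r1, 0.05), enrichmentFactorD(r2, 0.05))
})

test_that("metric reports bundle the individual metrics and round-trip JSON", {
  perfect <- toyScoreTable(seq(1, 0.1, length.out = 10),
                           rep(c("active", "decoy"), c(3, 7)))
  rep1 <- metricReport(perfect, seed = 2)
  expect_equal(rep1$auc, 1)
  expect_true(all(unlist(rep1$efd) == 100))

  fx <- smallFixture()
  tab <- scoreLibrary(fx$model, fx$library, fx$labels)
  rep2 <- metricReport(tab, fractions = c(0.01, 0.05), alphas = c(20, 80.5),
                       seed = 3)
  rk <- makeRanking(tab, 3)
  expect_equal(rep2$auc, rocAuc(rk)$auc)
  expect_equal(rep2$efd[["0.05"]], enrichmentFactorD(rk, 0.05))
  expect_equal(rep2$bedroc[["80.5"]], bedroc(rk, 80.5))

  f <- withr::local_tempfile(fileext = ".json")
  writeMetricReport(rep2, f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(back$auc, rep2$auc, tolerance = 1e-12)
  expect_equal(back$bedroc$`20`, rep2$bedroc[["20"]], tolerance = 1e-12)
})
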