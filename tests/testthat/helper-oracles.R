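# Independent oracle implementations used to cross-check the package's
# analytic similarity engine and enrichment metrics. These deliberately take
# different computational routes than the implementation.

GAUSS_P_ORACLE <- 2.7

oracleAlpha <- function(radius) {
  pi * (3 * GAUSS_P_ORACLE / (4 * pi * radius^3))^(2 / 3)
}

# Gaussian density of an atom set evaluated on a separable 3D grid
gridDensity <- function(at, xs, ys, zs) {
  rho <- array(0, dim = c(length(xs), length(ys), length(zs)))
  a <- oracleAlpha(at$radius)
  for (i in seq_len(nrow(at))) {
    gx <- exp(-a[i] * (xs - at$x[i])^2)
    gy <- exp(-a[i] * (ys - at$y[i])^2)
    gz <- exp(-a[i] * (zs - at$z[i])^2)
    rho <- rho + GAUSS_P_ORACLE * outer(outer(gx, gy), gz)
  }
  rho
}

# Hodgkin shape index by trapezoid-style grid integration (0.05 A spacing,
# 8 A box centred on the atoms)
gridShapeSimilarity <- function(poseAtoms, modelAtoms, spacing = 0.05,
                                half = 4) {
  all <- rbind(poseAtoms[, c("x", "y", "z")], modelAtoms[, c("x", "y", "z")])
  ctr <- colMeans(all)
  xs <- seq(ctr[1] - half, ctr[1] + half, by = spacing)
  ys <- seq(ctr[2] - half, ctr[2] + half, by = spacing)
  zs <- seq(ctr[3] - half, ctr[3] + half, by = spacing)
  rhoA <- gridDensity(poseAtoms, xs, ys, zs)
  rhoB <- gridDensity(modelAtoms, xs, ys, zs)
  oAB <- sum(rhoA * rhoB)
  2 * oAB / (sum(rhoA^2) + sum(rhoB^2))
}

# grid integral of rho^2 for a single structure (overlap volume oracle)
gridSelfOverlap <- function(at, spacing = 0.05, half = 4) {
  ctr <- colMeans(at[, c("x", "y", "z")])
  xs <- seq(ctr[1] - half, ctr[1] + half, by = spacing)
  rho <- gridDensity(at, xs,
                     seq(ctr[2] - half, ctr[2] + half, by = spacing),
                     seq(ctr[3] - half, ctr[3] + half, by = spacing))
  sum(rho^2) * spacing^3
}

# ESP similarity by explicit loops over observer points (independent of the
# vectorized implementation)
espOracle <- function(poseAtoms, modelAtoms, eps = 0.5) {
  obs <- rbind(as.matrix(poseAtoms[, c("x", "y", "z")]),
               as.matrix(modelAtoms[, c("x", "y", "z")]))
  pot <- function(at) {
    v <- numeric(nrow(obs))
    for (k in seq_len(nrow(obs))) {
      for (j in seq_len(nrow(at))) {
        d <- sqrt(sum((obs[k, ] - c(at$x[j], at$y[j], at$z[j]))^2))
        v[k] <- v[k] + at$charge[j] / max(d, eps)
      }
    }
    v
  }
  vA <- pot(poseAtoms); vB <- pot(modelAtoms)
  if (sum(vA^2) == 0 || sum(vB^2) == 0) return(0.5)
  (1 + 2 * sum(vA * vB) / (sum(vA^2) + sum(vB^2))) / 2
}

# AUC by explicit pair counting over the realized ranking
aucPairOracle <- function(ranking) {
  s <- ranking@score
  nsk <- sum(!ranking@scored)
  if (nsk > 0) {
    base <- if (any(ranking@scored)) min(s[ranking@scored]) else 0
    s[!ranking@scored] <- base - seq_len(nsk)
  }
  sa <- s[ranking@label == "active"]
  sd <- s[ranking@label == "decoy"]
  cmp <- outer(sa, sd, function(a, d) (a > d) + 0.5 * (a == d))
  mean(cmp)
}

# EFd by an explicit walk down the ranking
efdOracle <- function(ranking, fraction) {
  nd <- sum(ranking@label == "decoy")
  na <- sum(ranking@label == "active")
  target <- ceiling(fraction * nd)
  seen <- 0; found <- 0
  for (lab in ranking@label) {
    if (lab == "decoy") {
      seen <- seen + 1
      if (seen == target) break
    } else found <- found + 1
  }
  100 * found / na
}

# BEDROC via min-max rescaling of the observed RIE against the explicitly
# constructed best and worst rankings (a different route than the closed
# form; agrees to O(1/N))
bedrocMinMaxOracle <- function(ranking, alpha) {
  N <- length(ranking@ids)
  n <- sum(ranking@label == "active")
  rie <- function(ranks) {
    sum(exp(-alpha * ranks / N)) /
      (n * mean(exp(-alpha * seq_len(N) / N)))
  }
  obs <- rie(which(ranking@label == "active"))
  best <- rie(seq_len(n))
  worst <- rie(N - n + seq_len(n))
  (obs - worst) / (best - worst)
}

# random rigid motion (rotation + translation) applied to an atom table
randomRigidMotion <- function() {
  m <- matrix(stats::rnorm(9), 3)
  q <- qr.Q(qr(m))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  list(R = q, t = stats::rnorm(3, sd = 10))
}

applyRigid <- function(at, motion) {
  xyz <- as.matrix(at[, c("x", "y", "z")]) %*% t(motion$R)
  xyz <- sweep(xyz, 2, motion$t, "+")
  at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
  at
}

randomAtoms <- function(n, spread = 1.5, charged = TRUE) {
  atomTable(sample(c("C", "N", "O", "S", "H"), n, replace = TRUE),
            stats::runif(n, -spread, spread),
            stats::runif(n, -spread, spread),
            stats::runif(n, -spread, spread),
            charge = if (charged) stats::runif(n, -0.5, 0.5) else 0)
}
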