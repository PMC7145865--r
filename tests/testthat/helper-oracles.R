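# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own computational routes.

# double-loop within-network statistic
oracleWithin <- function(A, idx, policy = "literal") {
  n <- length(idx)
  tot <- 0
  for (i in idx) for (j in idx) {
    if (policy == "exclude_diagonal" && i == j) next
    tot <- tot + A[i, j]
  }
  tot / if (policy == "literal") n^2 else n * (n - 1)
}

# double-loop between-network statistic
oracleBetween <- function(A, idxA, idxB) {
  tot <- 0
  for (i in idxA) for (j in idxB) tot <- tot + A[i, j]
  tot / (length(idxA) * length(idxB))
}

# partial correlation by explicit residual regression + textbook t transform
oraclePartialCor <- function(x, y, Z) {
  D <- cbind(1, Z)
  rx <- stats::residuals(stats::lm.fit(D, x))
  ry <- stats::residuals(stats::lm.fit(D, y))
  r <- sum(rx * ry) / sqrt(sum(rx^2) * sum(ry^2))
  df <- length(x) - 2 - ncol(as.matrix(Z))
  tval <- r * sqrt(df / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tval), df))
}

# hand-rolled Benjamini-Hochberg step-up adjustment
oracleBH <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  run <- Inf
  for (i in m:1) {
    run <- min(run, m * p[o[i]] / i, 1)
    adj[o[i]] <- run
  }
  adj
}

# a random symmetric "connectivity-like" matrix with unit diagonal
randomConnectivity <- function(n, ids = sprintf("n%02d", seq_len(n))) {
  A <- matrix(stats::runif(n * n, -1, 1), n, n)
  A <- (A + t(A)) / 2
  diag(A) <- 1
  dimnames(A) <- list(ids, ids)
  A
}

# wrap an arbitrary subject x measure matrix as a ConnectivityExperiment
# (each column treated as a "within" measure) with a behavioral colData
.toyExperiment <- function(X, behavior) {
  A <- t(X)
  colnames(A) <- behavior$subject_id
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(connectivity = A),
    rowData = S4Vectors::DataFrame(
      measure_type = rep("within", nrow(A)),
      network_a = rownames(A), network_b = NA_character_,
      row.names = rownames(A)),
    colData = S4Vectors::DataFrame(behavior, row.names = behavior$subject_id))
  new("ConnectivityExperiment", se)
}

# tiny cohort spec used by several files
tinySpec <- function(...) {
  args <- list(...)
  defaults <- list(nSubjects = 6L, tPoints = 40L,
                   partitionSizes = c(VAN = 4L, DAN = 3L, VN = 5L),
                   withinTargets = 0.4, betweenTargets = 0.1, seed = 11L)
  do.call(cohortSpec, utils::modifyList(defaults, args))
}
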