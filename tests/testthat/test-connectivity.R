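test_that("correlation matrix matches hand computation and handles exact cases", {
  x <- c(1, 2, 3, 4)
  y <- c(1, 2, 3, 5)
  ts <- cbind(a = x, b = y, c = -x)
  A <- correlationMatrix(ts)
  expect_equal(round(A["a", "b"], 4), 0.9827)
  expect_equal(A["a", "c"], -1)
  expect_equal(diag(A), c(a = 1, b = 1, c = 1))
  expect_equal(A, t(A))
  # identical columns correlate exactly 1
  A2 <- correlationMatrix(cbind(u = x, v = x, w = y))
  expect_equal(A2["u", "v"], 1)
})

test_that("degenerate time series are rejected with informative errors", {
  expect_error(correlationMatrix(matrix(1:4, 2, 2)), "3 time points")
  ts <- cbind(a = rnorm(10), b = rep(2, 10))
  expect_error(correlationMatrix(ts), "constant.*b")
  ts[3, 1] <- NA
  expect_error(correlationMatrix(ts), "missing")
})

test_that("within-network statistic matches its definition on small blocks", {
  # perfectly correlated network: every entry 1, both policies give 1
  ids <- c("p1", "p2", "q1")
  A <- matrix(1, 3, 3, dimnames = list(ids, ids))
  p <- NetworkPartition(ids, c("P", "P", "Q"))
  expect_equal(withinNetworkConnectivity(A, p, "literal")[["P"]], 1)
  expect_equal(withinNetworkConnectivity(A, p, "exclude_diagonal")[["P"]], 1)
  # 2-node network with r = 0.5: literal (1+.5+.5+1)/4, exclude 0.5
  B <- diag(3); B[1, 2] <- B[2, 1] <- 0.5
  dimnames(B) <- list(ids, ids)
  expect_equal(withinNetworkConnectivity(B, p, "literal")[["P"]], 0.75)
  expect_equal(withinNetworkConnectivity(B, p, "exclude_diagonal")[["P"]], 0.5)
  # singleton networks: literal is forced to 1, exclude has no links
  expect_equal(withinNetworkConnectivity(B, p, "literal")[["Q"]], 1)
  expect_true(is.na(withinNetworkConnectivity(B, p, "exclude_diagonal")[["Q"]]))
})

test_that("between-network statistic matches single-term and null cases", {
  ids <- c("a1", "b1")
  A <- matrix(c(1, 0.3, 0.3, 1), 2, 2, dimnames = list(ids, ids))
  p <- NetworkPartition(ids, c("A", "B"))
  expect_equal(betweenNetworkConnectivity(A, p)[["A-B"]], 0.3)
  # independent long series: |PB| below 3/sqrt(T)
  set.seed(42)
  T <- 4000
  ts <- matrix(rnorm(T * 6), T, 6,
               dimnames = list(NULL, sprintf("n%d", 1:6)))
  p2 <- NetworkPartition(sprintf("n%d", 1:6), rep(c("A", "B"), each = 3))
  pb <- betweenNetworkConnectivity(correlationMatrix(ts), p2)
  expect_lt(abs(pb[["A-B"]]), 3 / sqrt(T))
})

test_that("both statistics agree with the brute-force double-loop oracle", {
  set.seed(7)
  for (rep in 1:10) {
    n <- 20
    A <- randomConnectivity(n)
    nets <- sample(rep(c("W", "X", "Y", "Z"), length.out = n))
    p <- NetworkPartition(colnames(A), nets)
    idx <- split(seq_len(n), nets)
    wLit <- withinNetworkConnectivity(A, p, "literal")
    wExc <- withinNetworkConnectivity(A, p, "exclude_diagonal")
    for (a in names(idx)) {
      expect_equal(wLit[[a]], oracleWithin(A, idx[[a]], "literal"), tolerance = 1e-12)
      expect_equal(wExc[[a]], oracleWithin(A, idx[[a]], "exclude_diagonal"),
                   tolerance = 1e-12)
    }
    pb <- betweenNetworkConnectivity(A, p)
    for (pair in combn(sort(names(idx)), 2, simplify = FALSE)) {
      key <- paste(pair, collapse = "-")
      expect_equal(pb[[key]], oracleBetween(A, idx[[pair[1]]], idx[[pair[2]]]),
                   tolerance = 1e-12)
    }
  }
})

test_that("literal and exclude-diagonal policies satisfy the algebraic identity", {
  set.seed(8)
  A <- randomConnectivity(15)
  nets <- rep(c("A", "B", "C"), times = c(6, 5, 4))
  p <- NetworkPartition(colnames(A), nets)
  lit <- withinNetworkConnectivity(A, p, "literal")
  exc <- withinNetworkConnectivity(A, p, "exclude_diagonal")
  Na <- networkSizes(p)[names(lit)]
  expect_equal(lit, ((Na - 1) * exc + 1) / Na, tolerance = 1e-12)
})

test_that("connectivity statistics are invariant to consistent node permutation", {
  set.seed(9)
  A <- randomConnectivity(12)
  nets <- rep(c("A", "B", "C"), each = 4)
  p <- NetworkPartition(colnames(A), nets)
  perm <- sample(12)
  Ap <- A[perm, perm]
  pp <- NetworkPartition(colnames(A)[perm], nets[perm], networkOrder = c("A", "B", "C"))
  expect_equal(withinNetworkConnectivity(A, p), withinNetworkConnectivity(Ap, pp))
  expect_equal(betweenNetworkConnectivity(A, p), betweenNetworkConnectivity(Ap, pp))
})

test_that("cohort profiles equal the per-block statistics exactly", {
  spec <- tinySpec(nSubjects = 3L, tPoints = 60L)
  ts <- simulateCohort(spec)
  part <- defaultPartition(networkSizes(spec))
  for (policy in c("literal", "exclude_diagonal")) {
    ce <- profileCohort(ts, part, diagonalPolicy = policy)
    for (s in names(ts)) {
      A <- correlationMatrix(ts[[s]])
      w <- withinNetworkConnectivity(A, part, policy)
      b <- betweenNetworkConnectivity(A, part)
      got <- connectivityValues(ce)[, s]
      expect_equal(unname(got[paste0("within_", names(w))]), unname(w),
                   tolerance = 1e-12)
      expect_equal(unname(got[paste0("between_", sub("-", "_", names(b)))]),
                   unname(b), tolerance = 1e-12)
    }
  }
  # the Fisher-z option transforms off-diagonal entries before averaging
  ceZ <- profileCohort(ts[1], part, fisherZ = TRUE)
  A <- correlationMatrix(ts[[1]])
  wz <- withinNetworkConnectivity(A, part, fisherZ = TRUE)
  expect_equal(unname(connectivityValues(ceZ)[paste0("within_", names(wz)), 1]),
               unname(wz), tolerance = 1e-12)
  expect_gt(abs(wz[["VAN"]]), abs(withinNetworkConnectivity(A, part)[["VAN"]]) - 1)
})

test_that("cohort profiling preserves order, reports failures, orders effects", {
  spec <- tinySpec(nSubjects = 12L, tPoints = 400L,
                   withinTargets = c(VAN = 0.5, DAN = 0.1, VN = 0.3))
  ts <- simulateCohort(spec)
  part <- defaultPartition(networkSizes(spec))
  ce <- profileCohort(ts, part)
  expect_s4_class(ce, "ConnectivityExperiment")
  expect_identical(colnames(ce), names(ts))
  expect_identical(dim(ce), c(6L, 12L))
  # generator consistency: stronger within target -> larger mean W
  W <- connectivityValues(ce)
  expect_gt(mean(W["within_VAN", ]), mean(W["within_DAN", ]))
  # single subject
  ce1 <- profileCohort(ts[1], part)
  expect_identical(dim(ce1), c(6L, 1L))
  expect_false(anyNA(connectivityValues(ce1)))
  # empty input warns, yields empty experiment
  expect_warning(ce0 <- profileCohort(list(), part), "empty")
  expect_identical(ncol(ce0), 0L)
  # a constant node fails that subject only, with a warning naming it
  ts$S003[, 2] <- 5
  expect_warning(ceF <- profileCohort(ts, part), "S003")
  expect_false("S003" %in% colnames(ceF))
  expect_identical(ncol(ceF), 11L)
  # node-set mismatch is an error naming the subject
  ts2 <- simulateCohort(spec)
  colnames(ts2$S002)[1] <- "ROIxx"
  expect_error(profileCohort(ts2, part), "S002")
})
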