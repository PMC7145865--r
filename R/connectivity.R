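## Network-connectivity statistics: Pearson connectivity matrix, the
## within-network statistic W_a and the between-network statistic PB_{a-b}.

#' Pearson connectivity matrix of an ROI time-series matrix
#'
#' Entry (i, j) is the Pearson correlation of the time courses of nodes i
#' and j. The input must have at least 3 time points, no missing values, and
#' no constant column.
#'
#' @param ts numeric T x N matrix (time points x nodes); column names are the
#'   node identifiers.
#' @return N x N symmetric correlation matrix with unit diagonal, dimnames
#'   set to the node identifiers.
#' @examples
#' ts <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
#' A <- correlationMatrix(ts)
#' @export
correlationMatrix <- function(ts) {
  ts <- as.matrix(ts)
  if (!is.numeric(ts)) .stopf("time-series matrix must be numeric")
  if (nrow(ts) < 3L) .stopf("at least 3 time points are required, got %d", nrow(ts))
  if (anyNA(ts)) .stopf("time-series matrix contains missing values")
  vars <- colMeans(ts^2) - colMeans(ts)^2
  if (any(vars <= 0)) {
    bad <- colnames(ts)[vars <= 0]
    if (is.null(bad)) bad <- which(vars <= 0)
    .stopf("constant time course for node(s): %s", paste(bad, collapse = ", "))
  }
  A <- stats::cor(ts)
  A <- (A + t(A)) / 2    # enforce exact symmetry against rounding
  diag(A) <- 1
  A
}

# resolve per-network node index lists, checking A and partition agree
.blockIndices <- function(A, partition) {
  ids <- colnames(A)
  if (is.null(ids)) .stopf("connectivity matrix must carry node identifiers as dimnames")
  if (!setequal(ids, nodeIds(partition)))
    .stopf("connectivity matrix and partition cover different node sets")
  nets <- networkOf(partition, ids)
  split(seq_along(ids), factor(nets, levels = networkNames(partition)))
}

.applyFisherZ <- function(A) {
  # z-transform off-diagonal entries only; the unit diagonal is retained
  # untransformed so the literal W_a remains finite
  Z <- A
  off <- row(A) != col(A)
  Z[off] <- atanh(pmax(pmin(A[off], 1 - 1e-15), -1 + 1e-15))
  Z
}

#' Within-network connectivity W_a
#'
#' For each network a with node set of size \eqn{N_a}, the literal statistic
#' is \deqn{W_a = \sum_{i,j \in a} A_{i,j} / N_a^2,} the sum running over all
#' ordered node pairs of the network including the unit diagonal. The
#' `"exclude_diagonal"` policy instead averages the strictly off-diagonal
#' within-block entries (the conventional mean within-network correlation).
#' The two are related by \eqn{W_{literal} = ((N_a - 1) W_{excl} + 1)/N_a}.
#'
#' @param A connectivity matrix as returned by [correlationMatrix()].
#' @param partition a [NetworkPartition-class] over the same node set.
#' @param diagonalPolicy `"literal"` (default) or `"exclude_diagonal"`.
#' @param fisherZ if `TRUE`, off-diagonal correlations are Fisher
#'   z-transformed before averaging.
#' @return named numeric vector, one value per network.
#' @export
withinNetworkConnectivity <- function(A, partition,
                                      diagonalPolicy = c("literal", "exclude_diagonal"),
                                      fisherZ = FALSE) {
  diagonalPolicy <- match.arg(diagonalPolicy)
  idx <- .blockIndices(A, partition)
  if (fisherZ) A <- .applyFisherZ(A)
  vapply(idx, function(i) {
    n <- length(i)
    block <- A[i, i, drop = FALSE]
    if (diagonalPolicy == "literal") {
      sum(block) / n^2
    } else {
      if (n < 2L) return(NA_real_)
      (sum(block) - sum(diag(block))) / (n^2 - n)
    }
  }, numeric(1))
}

#' Between-network connectivity PB_{a-b}
#'
#' For two distinct networks a and b, \deqn{PB_{a-b} = \sum_{i \in a, j \in b}
#' A_{i,j} / (N_a N_b),} the mean connectivity across all links spanning the
#' two networks. Pairs are unordered and keyed by the alphabetically sorted
#' name pair `"a-b"`.
#'
#' @inheritParams withinNetworkConnectivity
#' @return named numeric vector with one value per unordered network pair.
#' @export
betweenNetworkConnectivity <- function(A, partition, fisherZ = FALSE) {
  idx <- .blockIndices(A, partition)
  if (fisherZ) A <- .applyFisherZ(A)
  nets <- names(idx)
  if (length(nets) < 2L) .stopf("at least two networks are required")
  pairs <- utils::combn(sort(nets), 2L)
  out <- apply(pairs, 2L, function(p) {
    i <- idx[[p[1]]]; j <- idx[[p[2]]]
    sum(A[i, j, drop = FALSE]) / (length(i) * length(j))
  })
  names(out) <- paste(pairs[1L, ], pairs[2L, ], sep = "-")
  out
}

# all 55 measures of one subject in a single aggregation: block sums of A
# are t(U) A U for the node-by-network indicator U, from which both W_a
# (literal or off-diagonal) and PB_{a-b} follow; algebraically identical to
# withinNetworkConnectivity()/betweenNetworkConnectivity(), which the test
# suite asserts against a brute-force double loop
.profileOne <- function(A, partition, mf, diagonalPolicy, fisherZ) {
  idx <- .blockIndices(A, partition)
  if (fisherZ) A <- .applyFisherZ(A)
  K <- length(idx)
  sizes <- lengths(idx)
  U <- matrix(0, ncol(A), K)
  for (a in seq_len(K)) U[idx[[a]], a] <- 1
  S <- crossprod(U, A %*% U)               # K x K block sums
  diagSums <- vapply(idx, function(i) sum(diag(A)[i]), numeric(1))
  w <- if (diagonalPolicy == "literal") diag(S) / sizes^2
       else ifelse(sizes > 1, (diag(S) - diagSums) / (sizes^2 - sizes), NA_real_)
  names(w) <- names(idx)
  isB <- mf$measure_type == "between"
  ia <- match(mf$network_a[isB], names(idx))
  ib <- match(mf$network_b[isB], names(idx))
  pb <- S[cbind(ia, ib)] / (sizes[ia] * sizes[ib])
  out <- c(w[mf$network_a[!isB]], pb)
  names(out) <- mf$measure
  out
}

# measure labelling shared by profileCohort and the IO round trip
.measureFrame <- function(partition) {
  nets <- networkNames(partition)
  pairs <- utils::combn(sort(nets), 2L)
  data.frame(
    measure = c(paste0("within_", nets),
                paste0("between_", pairs[1L, ], "_", pairs[2L, ])),
    measure_type = c(rep("within", length(nets)), rep("between", ncol(pairs))),
    network_a = c(nets, pairs[1L, ]),
    network_b = c(rep(NA_character_, length(nets)), pairs[2L, ]),
    stringsAsFactors = FALSE)
}

#' Connectivity profiles for a cohort
#'
#' Computes, for every subject, the full set of within-network and
#' between-network connectivity values (10 + 45 for a 10-network partition)
#' and assembles them into a [ConnectivityExperiment-class] (measures x
#' subjects), optionally attaching a behavioral table as `colData`.
#'
#' Subjects whose time series cannot be profiled (e.g. a constant node) are
#' reported by a warning naming the subject and excluded; a node set
#' differing from the partition is an error.
#'
#' @param ts a named list of T x N time-series matrices (columns = node ids),
#'   or a character vector of time-series TSV paths as written by
#'   [writeTimeSeries()].
#' @param partition a [NetworkPartition-class].
#' @inheritParams withinNetworkConnectivity
#' @param behavior optional behavioral `data.frame` with a `subject_id`
#'   column, matched against the subject names.
#' @return a [ConnectivityExperiment-class].
#' @export
profileCohort <- function(ts, partition,
                          diagonalPolicy = c("literal", "exclude_diagonal"),
                          fisherZ = FALSE, behavior = NULL) {
  diagonalPolicy <- match.arg(diagonalPolicy)
  if (is.character(ts)) {
    paths <- ts
    ts <- lapply(paths, readTimeSeries)
    names(ts) <- vapply(seq_along(ts), function(i) {
      sid <- attr(ts[[i]], "subject_id")
      if (is.null(sid)) sub("\\.tsv$", "", basename(paths[i])) else sid
    }, character(1))
  }
  if (length(ts) == 0L) {
    .warnf("empty cohort: no subjects to profile")
    ts <- list()
  }
  if (is.null(names(ts)) && length(ts))
    names(ts) <- sprintf("S%03d", seq_along(ts))
  mf <- .measureFrame(partition)
  prof <- matrix(NA_real_, nrow(mf), length(ts),
                 dimnames = list(mf$measure, names(ts)))
  failed <- character()
  for (s in seq_along(ts)) {
    m <- ts[[s]]
    if (!setequal(colnames(m), nodeIds(partition)))
      .stopf("subject %s: node set does not match the partition", names(ts)[s])
    res <- tryCatch({
      A <- correlationMatrix(m)
      .profileOne(A, partition, mf, diagonalPolicy, fisherZ)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failed <- c(failed, sprintf("%s (%s)", names(ts)[s], conditionMessage(res)))
    } else {
      prof[, s] <- res
    }
  }
  if (length(failed)) {
    .warnf("failed to profile %d subject(s): %s",
           length(failed), paste(failed, collapse = "; "))
    prof <- prof[, !colnames(prof) %in% sub(" \\(.*", "", failed), drop = FALSE]
  }
  cd <- NULL
  if (!is.null(behavior)) {
    if (!"subject_id" %in% colnames(behavior))
      .stopf("behavior table must contain a subject_id column")
    miss <- setdiff(colnames(prof), behavior$subject_id)
    if (length(miss))
      .stopf("behavior table is missing subject(s): %s", paste(miss, collapse = ", "))
    cd <- behavior[match(colnames(prof), behavior$subject_id), , drop = FALSE]
    rownames(cd) <- cd$subject_id
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(connectivity = prof),
    rowData = S4Vectors::DataFrame(mf[, -1L], row.names = mf$measure),
    colData = if (is.null(cd)) S4Vectors::DataFrame(row.names = colnames(prof))
              else S4Vectors::DataFrame(cd),
    metadata = list(diagonal_policy = diagonalPolicy, fisher_z = fisherZ,
                    networks = networkNames(partition)))
  new("ConnectivityExperiment", se)
}
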