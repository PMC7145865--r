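## Plain-text readers and writers for the pipeline's table dialects.
## Time series: TSV, one file per subject, header = node ids. Partition:
## two-column CSV (node_id, network_name). Behavior, trials, profiles,
## bias scores: CSV. The "NA" condition label of the dot-probe task is a
## real value, so trial CSVs are read with na.strings = "".

#' Write / read one subject's time-series matrix as TSV
#'
#' @param ts T x N matrix with node-id column names (and optionally a
#'   `subject_id` attribute, preserved as a `# subject:` comment line).
#' @param path file path.
#' @return `readTimeSeries` returns the matrix with the `subject_id`
#'   attribute restored when present.
#' @export
writeTimeSeries <- function(ts, path) {
  con <- file(path, "w")
  on.exit(close(con))
  sid <- attr(ts, "subject_id")
  if (!is.null(sid)) writeLines(sprintf("# subject: %s", sid), con)
  utils::write.table(ts, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTimeSeries
#' @export
readTimeSeries <- function(path) {
  first <- readLines(path, n = 1L)
  sid <- NULL
  skip <- 0L
  if (startsWith(first, "# subject:")) {
    sid <- trimws(sub("^# subject:", "", first))
    skip <- 1L
  }
  m <- as.matrix(utils::read.delim(path, skip = skip, check.names = FALSE))
  if (!is.null(sid)) attr(m, "subject_id") <- sid
  m
}

#' Write / read a node-to-network partition as two-column CSV
#'
#' @param partition a [NetworkPartition-class].
#' @param path file path.
#' @export
writePartition <- function(partition, path) {
  utils::write.csv(data.frame(node_id = nodeIds(partition),
                              network_name = as.character(partition@networks)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writePartition
#' @export
readPartition <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("node_id", "network_name") %in% colnames(d)))
    .stopf("partition file must have columns node_id, network_name")
  NetworkPartition(d$node_id, d$network_name)
}

#' Write / read the behavioral table as CSV
#'
#' @param behavior behavioral `data.frame`.
#' @param path file path.
#' @export
writeBehavior <- function(behavior, path) {
  utils::write.csv(behavior, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeBehavior
#' @param warnRanges warn when scores fall outside the instrument ranges
#'   (ELS 25-125, depression 0-63).
#' @export
readBehavior <- function(path, warnRanges = TRUE) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (warnRanges) {
    if ("els" %in% colnames(d) && any(d$els < 25 | d$els > 125, na.rm = TRUE))
      .warnf("ELS scores outside the 25-125 instrument range")
    if ("depression" %in% colnames(d) &&
        any(d$depression < 0 | d$depression > 63, na.rm = TRUE))
      .warnf("depression scores outside the 0-63 instrument range")
  }
  d
}

#' Write / read dot-probe trial logs as CSV
#'
#' @param trials trial `data.frame`.
#' @param path file path.
#' @export
writeTrials <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTrials
#' @export
readTrials <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  d$correct <- as.logical(d$correct)
  .validateTrials(d)
}

#' Write / read connectivity profiles as tidy CSV
#'
#' The tidy dialect has one row per subject x measure: `subject_id,
#' measure_type, network_or_pair, value`.
#'
#' @param object a [ConnectivityExperiment-class].
#' @param path file path.
#' @export
writeProfiles <- function(object, path) {
  stopifnot(is(object, "ConnectivityExperiment"))
  rd <- SummarizedExperiment::rowData(object)
  lab <- ifelse(rd$measure_type == "within", as.character(rd$network_a),
                paste(rd$network_a, rd$network_b, sep = "-"))
  A <- connectivityValues(object)
  d <- data.frame(
    subject_id = rep(colnames(A), each = nrow(A)),
    measure_type = rep(as.character(rd$measure_type), ncol(A)),
    network_or_pair = rep(lab, ncol(A)),
    value = as.vector(A))
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeProfiles
#' @param behavior optional behavioral table attached as `colData`.
#' @export
readProfiles <- function(path, behavior = NULL) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "measure_type", "network_or_pair", "value")
  if (!all(need %in% colnames(d)))
    .stopf("profile file must have columns %s", paste(need, collapse = ", "))
  measure <- ifelse(d$measure_type == "within",
                    paste0("within_", d$network_or_pair),
                    paste0("between_", sub("-", "_", d$network_or_pair)))
  subjects <- unique(d$subject_id)
  meas <- unique(measure)
  A <- matrix(NA_real_, length(meas), length(subjects),
              dimnames = list(meas, subjects))
  A[cbind(match(measure, meas), match(d$subject_id, subjects))] <- d$value
  first <- !duplicated(measure)
  rd <- data.frame(
    measure_type = d$measure_type[first],
    network_a = ifelse(d$measure_type[first] == "within", d$network_or_pair[first],
                       sub("-.*", "", d$network_or_pair[first])),
    network_b = ifelse(d$measure_type[first] == "within", NA_character_,
                       sub(".*-", "", d$network_or_pair[first])),
    stringsAsFactors = FALSE)
  cd <- NULL
  if (!is.null(behavior))
    cd <- behavior[match(subjects, behavior$subject_id), , drop = FALSE]
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(connectivity = A),
    rowData = S4Vectors::DataFrame(rd, row.names = meas),
    colData = if (is.null(cd)) S4Vectors::DataFrame(row.names = subjects)
              else S4Vectors::DataFrame(cd, row.names = subjects))
  new("ConnectivityExperiment", se)
}
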