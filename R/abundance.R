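#' Build a taxonomic profile from counts
#'
#' Container for per-sample taxon counts (genus or species level) together
#' with total and unclassified read counts, matching the semantics of a
#' read classifier's output: classified counts per taxon plus reads
#' without an assignment.
#'
#' @param counts non-negative integer matrix, samples x taxa (an
#'   `unclassified` column, if present, is split off automatically).
#' @param total_reads per-sample total reads; defaults to the row sums.
#' @param unclassified_reads per-sample unclassified counts (default 0).
#' @return object of class `taxonomic_profile`.
#' @export
taxonomic_profile <- function(counts, total_reads = NULL,
                              unclassified_reads = NULL) {
  counts <- as.matrix(counts)
  if ("unclassified" %in% colnames(counts)) {
    if (is.null(unclassified_reads)) {
      unclassified_reads <- counts[, "unclassified"]
    }
    counts <- counts[, colnames(counts) != "unclassified", drop = FALSE]
  }
  if (is.null(unclassified_reads)) unclassified_reads <- rep(0L, nrow(counts))
  if (is.null(total_reads)) {
    total_reads <- rowSums(counts) + unclassified_reads
  }
  bad <- which(counts < 0 | counts != round(counts), arr.ind = TRUE)
  if (nrow(bad)) {
    stop("negative or non-integer count at sample '",
         rownames(counts)[bad[1, 1]], "', taxon '",
         colnames(counts)[bad[1, 2]], "'")
  }
  if (any(total_reads < rowSums(counts))) {
    stop("total_reads smaller than the classified row sum for: ",
         paste(rownames(counts)[total_reads < rowSums(counts)],
               collapse = ", "))
  }
  structure(list(counts = counts,
                 total_reads = as.numeric(total_reads),
                 unclassified_reads = as.numeric(unclassified_reads)),
            class = "taxonomic_profile")
}

#' Read a count table from TSV
#'
#' Expects a header line and sample identifiers in the first column; an
#' `unclassified` column is treated as the unclassified read count.
#'
#' @param path TSV file.
#' @return a `taxonomic_profile`.
#' @export
load_count_table <- function(path) {
  x <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  counts <- as.matrix(x[, -1, drop = FALSE])
  rownames(counts) <- x[[1]]
  p <- taxonomic_profile(counts)
  message(sprintf("loaded %d samples x %d taxa from %s",
                  nrow(p$counts), ncol(p$counts), path))
  p
}

#' @export
print.taxonomic_profile <- function(x, ...) {
  cat("<taxonomic_profile> ", nrow(x$counts), " samples x ",
      ncol(x$counts), " taxa\n", sep = "")
  invisible(x)
}

#' Convert counts to relative abundances
#'
#' Each taxon count is divided by the sample's classified read total, so
#' rows sum to one. The relative abundance is read as an estimate of the
#' probability that a classified read is assigned to the taxon.
#'
#' @param profile a `taxonomic_profile`.
#' @return numeric matrix of fractions in \[0, 1\] with an all-`FALSE`
#'   missingness mask attribute `mask` (filled by [mask_outliers()]).
#' @export
to_relative <- function(profile) {
  stopifnot(inherits(profile, "taxonomic_profile"))
  cs <- rowSums(profile$counts)
  if (any(cs == 0)) {
    stop("samples without classified reads: ",
         paste(rownames(profile$counts)[cs == 0], collapse = ", "))
  }
  rel <- profile$counts / cs
  attr(rel, "mask") <- matrix(FALSE, nrow(rel), ncol(rel),
                              dimnames = dimnames(rel))
  rel
}

#' Filter taxa by prevalence
#'
#' Keeps taxa detected (nonzero) in strictly more than `min_prevalence` of
#' all samples; a taxon present in exactly half the samples is dropped at
#' the default 0.5.
#'
#' @param rel relative abundance matrix from [to_relative()].
#' @param min_prevalence fraction in (0, 1], default 0.5.
#' @return filtered matrix (mask attribute subset along).
#' @export
prevalence_filter <- function(rel, min_prevalence = 0.5) {
  stopifnot(min_prevalence > 0, min_prevalence <= 1)
  prev <- colMeans(rel > 0)
  keep <- prev > min_prevalence
  if (!any(keep)) warning("no taxa pass the prevalence filter")
  out <- rel[, keep, drop = FALSE]
  m <- attr(rel, "mask")
  attr(out, "mask") <- if (is.null(m)) {
    matrix(FALSE, nrow(out), ncol(out), dimnames = dimnames(out))
  } else m[, keep, drop = FALSE]
  out
}

#' Mask outlying abundance values
#'
#' Single-pass rule on the pooled sample: per taxon, values more than `k`
#' standard deviations from the taxon mean are marked missing. The rule is
#' applied once to the original column (no re-iteration after masking).
#'
#' @param rel relative abundance matrix.
#' @param k number of SDs (default 4).
#' @return the matrix with an updated logical `mask` attribute; masked
#'   entries are set to `NA`.
#' @export
mask_outliers <- function(rel, k = 4) {
  stopifnot(k > 0)
  m <- attr(rel, "mask")
  if (is.null(m)) m <- matrix(FALSE, nrow(rel), ncol(rel),
                              dimnames = dimnames(rel))
  mu <- colMeans(rel, na.rm = TRUE)
  sd <- apply(rel, 2, stats::sd, na.rm = TRUE)
  out <- rel
  for (j in seq_len(ncol(rel))) {
    if (is.na(sd[j]) || sd[j] == 0) next
    bad <- !is.na(rel[, j]) & abs(rel[, j] - mu[j]) > k * sd[j]
    m[bad, j] <- TRUE
    out[bad, j] <- NA
  }
  attr(out, "mask") <- m
  out
}
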