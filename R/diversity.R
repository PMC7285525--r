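#' Alpha diversity indices
#'
#' Per-sample richness (number of detected taxa), Shannon entropy
#' `H = -sum p log p` over nonzero fractions, and the Pielou evenness in
#' two variants: the Simpson-based evenness `(1 / sum p^2) / richness`
#' (the default) and the conventional Shannon-based `H / log(richness)`,
#' which is undefined for single-taxon samples and returned as `NA` there.
#'
#' @param rel relative abundance matrix (rows sum to 1).
#' @param pielou which evenness variant to report in the `pielou` column;
#'   both are always returned.
#' @return data.frame with `sample`, `richness`, `shannon`,
#'   `pielou_simpson`, `pielou_shannon` and `pielou`.
#' @export
alpha_diversity <- function(rel, pielou = c("simpson", "shannon")) {
  pielou <- match.arg(pielou)
  rich <- apply(rel, 1, function(p) sum(p > 0, na.rm = TRUE))
  shan <- apply(rel, 1, function(p) {
    p <- p[!is.na(p) & p > 0]
    -sum(p * log(p))
  })
  invsimp <- apply(rel, 1, function(p) {
    p <- p[!is.na(p) & p > 0]
    1 / sum(p^2)
  })
  ps <- invsimp / rich
  ph <- ifelse(rich > 1, shan / log(rich), NA_real_)
  ids <- rownames(rel)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(rel)))
  data.frame(sample = ids, richness = rich, shannon = shan,
             pielou_simpson = ps, pielou_shannon = ph,
             pielou = if (pielou == "simpson") ps else ph,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Bray-Curtis dissimilarity matrix
#'
#' `BC(i, j) = sum |x_i - x_j| / sum (x_i + x_j)`, computed with
#' `vegan::vegdist`; entries lie in \[0, 1\] with zero diagonal.
#'
#' @param rel relative abundance matrix (NAs not allowed; mask before
#'   diversity analysis is not part of this step).
#' @return symmetric `matrix` of dissimilarities.
#' @export
bray_curtis <- function(rel) {
  stopifnot(nrow(rel) >= 2L)
  as.matrix(vegan::vegdist(rel, method = "bray"))
}

#' ANOSIM permutation test
#'
#' Rank-based comparison of between- versus within-group dissimilarities:
#' `R = (mean between-rank - mean within-rank) / (M/2)` with
#' `M = n(n-1)/2`, mid-ranks for ties. The permutation p-value uses the
#' add-one estimator `(1 + #permuted R >= observed) / (1 + n_perm)`, so it
#' can never be exactly zero.
#'
#' @param d distance matrix (as from [bray_curtis()]) or `dist`.
#' @param labels group labels, at least two groups with two members each.
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed for the permutations.
#' @return list with `statistic` (R), `p.value` and `n_perm`.
#' @export
anosim <- function(d, labels, n_perm = 999, seed = 1L) {
  labels <- as.factor(labels)
  if (nlevels(labels) < 2L) stop("need at least two groups")
  if (any(table(labels) < 2L)) stop("every group needs >= 2 members")
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  fit <- vegan::anosim(stats::as.dist(d), labels, permutations = n_perm)
  list(statistic = unname(fit$statistic),
       p.value = fit$signif, n_perm = n_perm)
}

#' PERMANOVA (distance-based pseudo-F) permutation test
#'
#' Partitions the Gower-centred distance matrix into among- and
#' within-group sums of squares and compares the pseudo-F to its label
#' permutation distribution (add-one p estimator), via `vegan::adonis2`.
#'
#' @inheritParams anosim
#' @return list with `statistic` (pseudo-F), `p.value`, `r2` and `n_perm`.
#' @export
permanova <- function(d, labels, n_perm = 999, seed = 1L) {
  labels <- as.factor(labels)
  if (nlevels(labels) < 2L) stop("need at least two groups")
  if (any(table(labels) < 2L)) stop("every group needs >= 2 members")
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  df <- data.frame(g = labels)
  fit <- vegan::adonis2(stats::as.dist(d) ~ g, data = df,
                        permutations = n_perm)
  list(statistic = fit$F[1], p.value = fit$`Pr(>F)`[1],
       r2 = fit$R2[1], n_perm = n_perm)
}
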