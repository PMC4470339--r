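#' Median-of-ratios size factors
#'
#' Computes per-sample size factors as the median, over genes with strictly
#' positive counts in every sample, of the ratio of the gene's count in that
#' sample to its across-sample geometric mean. This is the standard
#' library-size correction for count matrices of total gene reads.
#'
#' @param counts a [meristem_counts()] object or numeric matrix.
#' @return named numeric vector of positive size factors, one per sample.
#' @export
compute_size_factors <- function(counts) {
  m <- if (inherits(counts, "meristem_set")) counts$counts else counts
  stopifnot(is.matrix(m), all(m >= 0))
  usable <- rowSums(m <= 0) == 0L
  if (!any(usable))
    stop("size factors undefined: no gene has strictly positive counts in every sample")
  mu <- m[usable, , drop = FALSE]
  geomean <- exp(rowMeans(log(mu)))
  s <- apply(mu / geomean, 2, stats::median)
  names(s) <- colnames(m)
  s
}

#' Normalize counts by size factors
#'
#' Elementwise division of each sample column by its size factor; metadata
#' is preserved.
#'
#' @param counts a [meristem_counts()] object.
#' @param size_factors named positive factors from [compute_size_factors()];
#'   computed on the fly when omitted.
#' @return a [meristem_norm()] object of normalized TGR counts.
#' @export
normalize_counts <- function(counts, size_factors = NULL) {
  stopifnot(inherits(counts, "meristem_counts"))
  if (is.null(size_factors)) size_factors <- compute_size_factors(counts)
  if (length(size_factors) != ncol(counts$counts))
    stop("size factor / sample mismatch")
  if (!is.null(names(size_factors)) &&
      !identical(names(size_factors), colnames(counts$counts)))
    stop("size factor names do not match sample IDs")
  if (any(size_factors <= 0)) stop("size factors must be positive")
  v <- sweep(counts$counts, 2, size_factors, "/")
  meristem_norm(v, counts$samples)
}

#' Filter for expressed genes
#'
#' Keeps exactly the genes expressed at `threshold` or more normalized
#' counts in both replicates of at least one stage.
#'
#' @param norm a [meristem_norm()] object.
#' @param threshold minimal normalized count (default 5, boundary inclusive).
#' @param min_replicates how many replicates of a stage must reach the
#'   threshold (default: all replicates present for that stage, i.e. "both"
#'   in a two-replicate design).
#' @return character vector of retained gene IDs.
#' @export
filter_expressed <- function(norm, threshold = 5, min_replicates = NULL) {
  stopifnot(inherits(norm, "meristem_norm"))
  stages <- unique(norm$samples$stage)
  nrep <- table(norm$samples$stage)
  if (all(nrep < 2L))
    stop("filter_expressed requires at least one stage with >= 2 replicates")
  keep <- rep(FALSE, nrow(norm$values))
  for (s in stages) {
    cols <- norm$samples$stage == s
    need <- if (is.null(min_replicates)) sum(cols) else min(min_replicates, sum(cols))
    ok <- rowSums(norm$values[, cols, drop = FALSE] >= threshold) >= need
    keep <- keep | ok
  }
  rownames(norm$values)[keep]
}

#' Replicate-averaged stage means
#'
#' Arithmetic mean of normalized counts over the replicates of each stage.
#'
#' @param norm a [meristem_norm()] object.
#' @return numeric gene x stage matrix; columns named `M<stage>` in
#'   increasing stage order.
#' @export
stage_average <- function(norm) {
  stopifnot(inherits(norm, "meristem_set"))
  m <- if (!is.null(norm$values)) norm$values else norm$counts
  stages <- sort(unique(norm$samples$stage))
  avg <- vapply(stages, function(s)
    rowMeans(m[, norm$samples$stage == s, drop = FALSE]),
    numeric(nrow(m)))
  colnames(avg) <- paste0("M", stages)
  rownames(avg) <- rownames(m)
  attr(avg, "stages") <- stages
  avg
}

#' Relative expression profiles
#'
#' Divides each gene's stage means by the gene's maximum over a scaling
#' stage set, yielding profiles on the \[0, 1\] scale. All-zero genes are
#' returned as all-zero and flagged rather than producing NaN.
#'
#' @param avg stage-mean matrix from [stage_average()].
#' @param scaling_stages stages over which the per-gene maximum is taken
#'   (default: all profiled stages).
#' @return a [profile_matrix()].
#' @export
relative_expression <- function(avg, scaling_stages = NULL) {
  stages <- attr(avg, "stages")
  if (is.null(stages)) stages <- as.integer(sub("^M", "", colnames(avg)))
  if (is.null(scaling_stages)) scaling_stages <- stages
  if (!length(scaling_stages)) stop("scaling stage set must be non-empty")
  if (!all(scaling_stages %in% stages))
    stop("scaling_stages must be a subset of the profiled stages")
  sel <- stages %in% scaling_stages
  mx <- apply(avg[, sel, drop = FALSE], 1, max)
  div <- ifelse(mx > 0, mx, 1)
  profile_matrix(avg / div, stages, mx, scaling_stages)
}

#' Joint cross-experiment scaling
#'
#' For a second experiment covering a stage subset, profiles from both
#' experiments are put on a common per-gene scale: the shared maximum is
#' taken over the second experiment's stages together with the first
#' experiment's stages not covered by the second, and both experiments'
#' stage means are divided by it.
#'
#' @param exp1_avg stage-mean matrix for experiment 1 (full stage set).
#' @param exp2_avg stage-mean matrix for experiment 2 (stage subset).
#' @return list of two [profile_matrix()] objects (`exp1`, `exp2`) for the
#'   genes common to both experiments.
#' @export
joint_scale <- function(exp1_avg, exp2_avg) {
  g <- intersect(rownames(exp1_avg), rownames(exp2_avg))
  if (!length(g)) stop("experiments share no genes")
  s1 <- attr(exp1_avg, "stages")
  if (is.null(s1)) s1 <- as.integer(sub("^M", "", colnames(exp1_avg)))
  s2 <- attr(exp2_avg, "stages")
  if (is.null(s2)) s2 <- as.integer(sub("^M", "", colnames(exp2_avg)))
  a1 <- exp1_avg[g, , drop = FALSE]
  a2 <- exp2_avg[g, , drop = FALSE]
  outside <- setdiff(s1, s2)
  pool <- cbind(a2, a1[, s1 %in% outside, drop = FALSE])
  mx <- apply(pool, 1, max)
  div <- ifelse(mx > 0, mx, 1)
  list(exp1 = profile_matrix(a1 / div, s1, mx, union(s2, outside)),
       exp2 = profile_matrix(a2 / div, s2, mx, union(s2, outside)))
}
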