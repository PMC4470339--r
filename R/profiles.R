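#' Cross-experiment profile similarity
#'
#' Similarity between two expression profiles over the same stage set,
#' defined as one minus the mean squared distance between the per-stage
#' expression values. On \[0, 1\]-scaled profiles (the output of
#' [joint_scale()]) the score is bounded in \[0, 1\] and equals 1 exactly for
#' identical profiles.
#'
#' @param p,q numeric profiles of equal length over the same stages.
#' @return list with `value` (the similarity) and `n_stages_compared`.
#' @export
profile_similarity <- function(p, q) {
  if (length(p) != length(q))
    stop("profiles differ in length (", length(p), " vs ", length(q), ")")
  if (!length(p)) stop("profiles must be non-empty")
  list(value = 1 - mean((p - q)^2), n_stages_compared = length(p))
}

#' Replication similarity report
#'
#' Per-item similarity between profiles from two experiments over their
#' shared stages, plus the summary median. Items are genes by default; with
#' `tier` given, super-cluster mean profiles are compared instead, matched
#' by gene identity through experiment 1's assignment (experiment 2's
#' super-cluster profile is re-averaged from experiment 2's data over the
#' same member genes, never re-clustered).
#'
#' @param exp1,exp2 [profile_matrix()] objects from [joint_scale()] (joint
#'   scaling must already be applied).
#' @param tier optional `supercluster_tier` from experiment 1.
#' @return list with `similarity` (data frame item/similarity) and `median`.
#' @export
replication_report <- function(exp1, exp2, tier = NULL) {
  v1 <- profile_values(exp1)
  v2 <- profile_values(exp2)
  s1 <- if (inherits(exp1, "profile_matrix")) exp1$stages
  else as.integer(sub("^M", "", colnames(v1)))
  s2 <- if (inherits(exp2, "profile_matrix")) exp2$stages
  else as.integer(sub("^M", "", colnames(v2)))
  shared <- intersect(s1, s2)
  if (!length(shared)) stop("experiments share no stages")
  a <- v1[, s1 %in% shared, drop = FALSE]
  b <- v2[, s2 %in% shared, drop = FALSE]
  if (is.null(tier)) {
    genes <- intersect(rownames(a), rownames(b))
    a <- a[genes, , drop = FALSE]
    b <- b[genes, , drop = FALSE]
    sim <- 1 - rowMeans((a - b)^2)
    df <- data.frame(item = genes, similarity = unname(sim),
                     stringsAsFactors = FALSE)
  } else {
    stopifnot(inherits(tier, "supercluster_tier"))
    ids <- names(tier$gene_members)
    sim <- vapply(ids, function(id) {
      g <- intersect(tier$gene_members[[id]], intersect(rownames(a), rownames(b)))
      if (!length(g)) return(NA_real_)
      profile_similarity(colMeans(a[g, , drop = FALSE]),
                         colMeans(b[g, , drop = FALSE]))$value
    }, 1.0)
    df <- data.frame(item = ids, similarity = unname(sim),
                     stringsAsFactors = FALSE)
  }
  list(similarity = df,
       median = stats::median(df$similarity, na.rm = TRUE),
       shared_stages = shared)
}

#' Classify a transition-point expression pattern
#'
#' Labels a stage profile by its behavior around a focus stage (M5 by
#' default, the floral-transition point): `TYPE_I` for a pronounced peak at
#' the focus stage (global maximum there, exceeding both neighbors by at
#' least the margin), `TYPE_II` for a dip at the focus stage flanked by
#' upregulation at both neighbors (each neighbor at least the margin above
#' the focus value), `OTHER` otherwise. `TYPE_I` takes precedence.
#'
#' @param p numeric profile over consecutive stages; names or the `stages`
#'   argument give the stage indices.
#' @param focus_stage the transition stage (default 5).
#' @param margin minimal difference `delta` on the relative scale
#'   (default 0.2).
#' @param stages stage indices of `p` (default `seq_along(p)`).
#' @return character label: `"TYPE_I"`, `"TYPE_II"` or `"OTHER"`.
#' @export
classify_pattern <- function(p, focus_stage = 5, margin = 0.2,
                             stages = NULL) {
  if (is.null(stages)) stages <- seq_along(p)
  f <- match(focus_stage, stages)
  if (is.na(f)) stop("focus stage absent from profile")
  if (f == 1L || f == length(p))
    stop("focus stage must not sit at the profile boundary")
  eps <- 1e-9  # guard against floating-point ties at the margin boundary
  neigh <- max(p[f - 1L], p[f + 1L])
  if (p[f] >= max(p) && p[f] - neigh >= margin - eps) return("TYPE_I")
  if (p[f - 1L] - p[f] >= margin - eps && p[f + 1L] - p[f] >= margin - eps)
    return("TYPE_II")
  "OTHER"
}

#' Classify every row of a profile matrix
#'
#' @param profiles a [profile_matrix()] or numeric matrix.
#' @param focus_stage,margin see [classify_pattern()].
#' @return named character vector of pattern labels, one per gene.
#' @export
classify_patterns <- function(profiles, focus_stage = 5, margin = 0.2) {
  x <- profile_values(profiles)
  stages <- if (inherits(profiles, "profile_matrix")) profiles$stages
  else if (!is.null(colnames(x)) && all(grepl("^M[0-9]+$", colnames(x))))
    as.integer(sub("^M", "", colnames(x)))
  else seq_len(ncol(x))
  out <- vapply(seq_len(nrow(x)), function(i)
    classify_pattern(x[i, ], focus_stage, margin, stages), "")
  names(out) <- rownames(x)
  out
}

#' Stage-pair fold change
#'
#' Ratio of the stage-B mean to the stage-A mean for one gene.
#'
#' @param avg stage-mean matrix from [stage_average()].
#' @param gene gene ID.
#' @param stage_a,stage_b stage indices.
#' @return the ratio; `Inf` (with a warning, not an error) when the
#'   denominator mean is zero and the numerator positive, `NaN` when both
#'   are zero.
#' @export
fold_change <- function(avg, gene, stage_a, stage_b) {
  if (!gene %in% rownames(avg)) stop("unknown gene: ", gene)
  stages <- attr(avg, "stages")
  if (is.null(stages)) stages <- as.integer(sub("^M", "", colnames(avg)))
  ia <- match(stage_a, stages)
  ib <- match(stage_b, stages)
  if (is.na(ia) || is.na(ib)) stop("stage absent from stage-mean matrix")
  a <- avg[gene, ia]
  b <- avg[gene, ib]
  if (a == 0) {
    warning("zero denominator mean for ", gene, " at stage ", stage_a)
    return(if (b > 0) Inf else NaN)
  }
  b / a
}

#' Relative qPCR quantification (ddCt)
#'
#' Computes relative expression with the ddCt method: the target gene's Ct
#' is referenced against the arithmetic mean Ct of the reference genes
#' within each sample (`dCt`), the calibrator sample's `dCt` is subtracted
#' (`ddCt`) and the result is `2^(-ddCt)`.
#'
#' @param ct long-format data frame with columns `gene`, `sample`, `ct`.
#' @param gene target gene.
#' @param sample sample of interest.
#' @param reference_genes character vector of reference gene IDs.
#' @param calibrator calibrator sample ID.
#' @return relative expression (1.0 when `sample` is the calibrator).
#' @export
ddct <- function(ct, gene, sample, reference_genes, calibrator) {
  stopifnot(all(c("gene", "sample", "ct") %in% names(ct)))
  pull <- function(g, s) {
    v <- ct$ct[ct$gene == g & ct$sample == s]
    if (!length(v))
      stop("missing Ct for gene ", g, " in sample ", s)
    mean(v)
  }
  dct <- function(s) pull(gene, s) - mean(vapply(reference_genes, pull, 1.0, s = s))
  2^(-(dct(sample) - dct(calibrator)))
}
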