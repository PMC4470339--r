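#' Ensemble of k-means runs
#'
#' Runs `repeats` independent k-means clusterings (Euclidean distance on the
#' profile vectors, random initial centers) and records the label table.
#' Only co-membership is meaningful downstream; labels are arbitrary per
#' repeat. Deterministic given `seed`: each repeat draws its initial centers
#' from its own derived RNG sub-stream.
#'
#' @param profiles a [profile_matrix()] or numeric item x feature matrix.
#' @param k requested number of clusters; must not exceed the number of
#'   items (scale k down for small inputs).
#' @param repeats number of ensemble repeats R (>= 1).
#' @param seed integer seed.
#' @return a `kmeans_ensemble`: list with `labels` (repeats x items integer
#'   matrix), `k`, `repeats`, `seed`.
#' @export
run_kmeans_ensemble <- function(profiles, k, repeats, seed = 1) {
  x <- profile_values(profiles)
  n <- nrow(x)
  if (k > n)
    stop("k = ", k, " exceeds the ", n,
         " items to cluster; scale k down for this input")
  if (repeats < 1L) stop("repeats must be >= 1")
  labels <- matrix(0L, nrow = repeats, ncol = n,
                   dimnames = list(NULL, rownames(x)))
  for (r in seq_len(repeats))
    labels[r, ] <- with_stream(seed, sprintf("kmeans/%d", r),
                               .safe_kmeans(x, k))
  structure(list(labels = labels, k = as.integer(k),
                 repeats = as.integer(repeats), seed = as.integer(seed)),
            class = "kmeans_ensemble")
}

# One k-means run robust to degenerate inputs: initial centers are sampled
# from distinct rows; empty-cluster failures are retried with fresh centers
# and finally resolved by nearest-center assignment. If fewer than k
# distinct rows exist, all distinct rows serve as centers.
.safe_kmeans <- function(x, k, iter_max = 300) {
  distinct <- which(!duplicated(x, MARGIN = 1))
  kk <- min(k, length(distinct))
  pick <- function() x[sample(distinct, kk), , drop = FALSE]
  centers <- NULL
  for (attempt in 1:5) {
    centers <- pick()
    fit <- tryCatch(
      suppressWarnings(stats::kmeans(x, centers = centers,
                                     iter.max = iter_max)),
      error = function(e) NULL)
    if (!is.null(fit)) return(as.integer(fit$cluster))
  }
  d2 <- outer(rowSums(x^2), rowSums(centers^2), "+") -
    2 * tcrossprod(x, centers)
  as.integer(max.col(-d2, ties.method = "first"))
}

#' Co-occurrence consensus model
#'
#' Counts, for every pair of items, the number of ensemble repeats in which
#' they fell in the same cluster (`N`), and derives the consensus distance
#' `D = R - N`.
#'
#' @param ensemble a `kmeans_ensemble` from [run_kmeans_ensemble()], or a
#'   plain repeats x items label matrix.
#' @return a `consensus_model`: list with integer matrices `N` and `D` and
#'   the repeat count `R`.
#' @export
cooccurrence <- function(ensemble) {
  labels <- if (inherits(ensemble, "kmeans_ensemble")) ensemble$labels
  else as.matrix(ensemble)
  if (any(is.na(labels))) stop("ensemble assignments must be complete")
  R <- nrow(labels)
  n <- ncol(labels)
  N <- matrix(0L, n, n, dimnames = list(colnames(labels), colnames(labels)))
  for (r in seq_len(R)) {
    for (members in split(seq_len(n), labels[r, ])) {
      N[members, members] <- N[members, members] + 1L
    }
  }
  structure(list(N = N, D = R - N, R = as.integer(R)),
            class = "consensus_model")
}

#' Hierarchical tree on a consensus distance
#'
#' Complete-linkage agglomerative clustering on the consensus distance
#' matrix.
#'
#' @param D a `consensus_model` or a symmetric distance matrix with zero
#'   diagonal.
#' @return an [stats::hclust] dendrogram.
#' @export
build_tree <- function(D) {
  if (inherits(D, "consensus_model")) D <- D$D
  stopifnot(is.matrix(D))
  if (!isSymmetric(unname(D))) stop("distance matrix must be symmetric")
  if (any(diag(D) != 0)) stop("distance matrix must have zero diagonal")
  stats::hclust(stats::as.dist(D), method = "complete")
}

#' Mean cluster profiles
#'
#' Arithmetic mean profile (per stage, over member genes) for every cluster
#' of a tier.
#'
#' @param tier a `cluster_tier` from [dynamic_cut()].
#' @param profiles the [profile_matrix()] (or matrix) the tier was built on.
#' @return numeric cluster x stage matrix, rownames = cluster IDs.
#' @export
mean_cluster_profiles <- function(tier, profiles) {
  x <- profile_values(profiles)
  missing <- setdiff(unlist(tier$clusters), rownames(x))
  if (length(missing))
    stop("cluster members absent from profiles: ", missing[1], " ...")
  out <- t(vapply(tier$clusters,
                  function(members) colMeans(x[members, , drop = FALSE]),
                  numeric(ncol(x))))
  rownames(out) <- names(tier$clusters)
  out
}

#' Tier-1 consensus clustering
#'
#' Convenience wrapper for the full first-tier stack: k-means ensemble ->
#' co-occurrence consensus distance -> complete-linkage tree -> dynamic cut
#' -> mean cluster profiles.
#'
#' @param profiles a [profile_matrix()] or numeric matrix.
#' @param k,repeats ensemble parameters.
#' @param min_size minimum cluster size for the dynamic cut.
#' @param min_gap split-depth control of [dynamic_cut()] (default 0, the
#'   deepest cut, appropriate for the fine-grained gene tier).
#' @param seed RNG seed.
#' @return a `cluster_tier` with a `mean_profiles` element attached.
#' @export
consensus_cluster <- function(profiles, k, repeats, min_size = 5, seed = 1,
                              min_gap = 0) {
  ens <- run_kmeans_ensemble(profiles, k, repeats, seed)
  model <- cooccurrence(ens)
  tree <- build_tree(model)
  tier <- dynamic_cut(tree, model$D, min_size = min_size, min_gap = min_gap)
  tier$mean_profiles <- mean_cluster_profiles(tier, profiles)
  tier
}

#' Second-tier super-clustering
#'
#' Applies the identical ensemble -> consensus -> tree -> dynamic-cut stack
#' to the tier-1 mean cluster profiles, then consolidates and expands the
#' result to gene level through the tier-1 assignment. Mean super-cluster
#' profiles are computed over all member genes (not over cluster means), so
#' large clusters weigh in proportionally.
#'
#' Super-clustering exists to combine clusters with similar expression
#' profiles, so after the consensus cut two profile-space passes run. (1)
#' A merge pass joins super-clusters that are not genuinely separated:
#' member-gene profiles of both groups are projected onto the axis joining
#' the two group centroids and the squared standardized separation
#' `t2 = (mean1 - mean2)^2 / (var1 + var2)` of the projections is compared
#' against `consolidate`. k-means with more centers than groups halves a
#' tight homogeneous cloud the same way in every repeat, so the consensus
#' distance cannot undo the split, but the projection statistic can: two
#' halves of one Gaussian cloud give a universal t2 of about 3.5 whatever
#' the cloud's scale, while genuinely distinct expression patterns sit far
#' above. (2) Tier-1 clusters the cut left unassigned re-attach to their
#' nearest super-cluster when the same statistic says they are not
#' separated from it.
#'
#' @param tier a `cluster_tier` from [consensus_cluster()]/[dynamic_cut()].
#' @param profiles the gene-level [profile_matrix()] used for tier 1.
#' @param k2 requested k for the cluster-profile k-means (must not exceed
#'   the number of tier-1 clusters).
#' @param repeats ensemble repeats.
#' @param min_size minimum super-cluster size (in clusters).
#' @param consolidate profile-space merge threshold on the squared
#'   standardized projected separation t2 (default 20: an order of
#'   magnitude above the value produced by halving one homogeneous cloud,
#'   far below the separation of distinct expression patterns). 0 disables
#'   consolidation and re-attachment.
#' @param seed RNG seed.
#' @return a `supercluster_tier`: list with `tier` (the cluster-level
#'   `cluster_tier` from the consensus cut), `super_members` (super-cluster
#'   -> tier-1 cluster IDs after consolidation), `gene_assignment` (named
#'   vector gene -> super-cluster ID, NA when the gene or its cluster is
#'   unassigned), `mean_profiles` (super-cluster x stage, over member
#'   genes) and `tier1`.
#' @export
supercluster <- function(tier, profiles, k2 = 100, repeats = 100,
                         min_size = 5, seed = 1, consolidate = 20) {
  cluster_profiles <- if (!is.null(tier$mean_profiles)) tier$mean_profiles
  else mean_cluster_profiles(tier, profiles)
  if (k2 > nrow(cluster_profiles))
    stop("k2 = ", k2, " exceeds the ", nrow(cluster_profiles),
         " tier-1 clusters; scale k2 down")
  tier2 <- consensus_cluster(cluster_profiles, k = k2, repeats = repeats,
                             min_size = min_size,
                             seed = derive_seed(seed, "tier2"))
  x <- profile_values(profiles)

  # super-clusters as lists of member clusters
  cluster_ids <- names(tier$clusters)
  super_members <- lapply(tier2$clusters, identity)
  genes_of <- function(clusters) unlist(tier$clusters[clusters], use.names = FALSE)
  centroid_of <- function(genes) colMeans(x[genes, , drop = FALSE])
  eps <- 1e-12
  # squared standardized separation of two gene sets along the axis
  # joining their centroids; 0 for identical centroids, Inf for separated
  # noiseless groups
  sep2_of <- function(g1, g2) {
    c1 <- centroid_of(g1)
    c2 <- centroid_of(g2)
    u <- c1 - c2
    nu <- sqrt(sum(u^2))
    if (nu <= eps) return(0)
    u <- u / nu
    p1 <- as.vector(x[g1, , drop = FALSE] %*% u)
    p2 <- as.vector(x[g2, , drop = FALSE] %*% u)
    v <- mean((p1 - mean(p1))^2) + mean((p2 - mean(p2))^2)
    if (v <= eps) return(Inf)
    (mean(p1) - mean(p2))^2 / v
  }

  # consolidation: merge super-clusters not genuinely separated in profile
  # space (projected separation below the threshold)
  if (consolidate > 0 && length(super_members) > 1L) {
    repeat {
      K <- length(super_members)
      if (K < 2L) break
      gl <- lapply(super_members, genes_of)
      best <- NULL
      best_r <- Inf
      for (i in seq_len(K - 1L)) for (j in seq.int(i + 1L, K)) {
        r <- sep2_of(gl[[i]], gl[[j]])
        if (r < best_r) { best_r <- r; best <- c(i, j) }
      }
      if (best_r >= consolidate) break
      super_members[[best[1]]] <- c(super_members[[best[1]]],
                                    super_members[[best[2]]])
      super_members[[best[2]]] <- NULL
    }
  }

  # re-attach tier-1 clusters the tier-2 cut left unassigned, by the same
  # criterion, against the pre-attachment super-cluster gene sets
  loose <- setdiff(cluster_ids, unlist(super_members))
  if (consolidate > 0 && length(loose) && length(super_members)) {
    gl <- lapply(super_members, genes_of)
    cen <- lapply(gl, centroid_of)
    attach_to <- lapply(loose, function(cl) {
      g <- tier$clusters[[cl]]
      p <- centroid_of(g)
      d <- vapply(cen, function(cc) mean((cc - p)^2), 1.0)
      best <- which.min(d)
      if (sep2_of(g, gl[[best]]) < consolidate) best else NA_integer_
    })
    for (i in seq_along(loose))
      if (!is.na(attach_to[[i]]))
        super_members[[attach_to[[i]]]] <- c(super_members[[attach_to[[i]]]],
                                             loose[i])
  }

  # renumber deterministically by the smallest member cluster ID
  ord <- order(vapply(super_members, function(m) min(as.integer(m)), 1L))
  super_members <- super_members[ord]
  names(super_members) <- as.character(seq_along(super_members))

  super_of_cluster <- rep(NA_integer_, length(cluster_ids))
  names(super_of_cluster) <- cluster_ids
  for (sid in seq_along(super_members))
    super_of_cluster[super_members[[sid]]] <- sid
  gene_assignment <- super_of_cluster[as.character(tier$assignment)]
  names(gene_assignment) <- names(tier$assignment)
  members_by_super <- split(names(gene_assignment)[!is.na(gene_assignment)],
                            gene_assignment[!is.na(gene_assignment)])
  mean_profiles <- t(vapply(members_by_super,
                            function(g) colMeans(x[g, , drop = FALSE]),
                            numeric(ncol(x))))
  structure(list(tier = tier2, super_members = super_members,
                 super_of_cluster = super_of_cluster,
                 gene_assignment = gene_assignment,
                 gene_members = members_by_super,
                 mean_profiles = mean_profiles, tier1 = tier),
            class = "supercluster_tier")
}

#' @export
print.supercluster_tier <- function(x, ...) {
  n <- length(x$gene_assignment)
  cov <- mean(!is.na(x$gene_assignment))
  cat(sprintf(paste0("supercluster_tier: %d super-clusters; %d/%d genes ",
                     "assigned (%.0f%% coverage)\n"),
              length(x$super_members), sum(!is.na(x$gene_assignment)), n,
              100 * cov))
  invisible(x)
}
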