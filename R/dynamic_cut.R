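#' Adaptive (dynamic) tree cut
#'
#' Decomposes a complete-linkage dendrogram into clusters of variable merge
#' height with a minimum size, in the spirit of the hybrid dynamic tree cut:
#' it uses both the tree and the distance matrix. The cut has two stages.
#'
#' Tree stage: the dendrogram is split recursively from the root. A branch
#' splits into its two sub-branches when both contain at least `min_size`
#' items and the sub-branches are separated: the mean between-branch
#' distance exceeds the larger of the two mean within-branch distances by
#' more than `min_gap` (branches whose halves are no farther from each
#' other than from themselves are kept together — merge heights alone are
#' uninformative here because complete-linkage heights saturate on
#' consensus distances). When only one sub-branch is large enough, the
#' small side's items drop into a provisional pool and the large side is
#' processed further; a branch none of whose sub-branches is large enough
#' becomes a terminal cluster.
#'
#' Distance stage: each pooled item is compared against the cluster cores
#' from the tree stage. It joins the cluster with the smallest average
#' distance to its members, provided that distance does not exceed the
#' cluster's radius (the largest average within-cluster distance of any
#' member); otherwise it stays unassigned. Attachment is computed against
#' the original cores for all pooled items, so the result does not depend
#' on processing order.
#'
#' @param tree an [stats::hclust] dendrogram (e.g. from [build_tree()]).
#' @param D the distance matrix the tree was built on.
#' @param min_size minimum cluster size (>= 1).
#' @param min_gap minimum excess of the mean between-branch distance over
#'   the larger mean within-branch distance required to split a branch
#'   whose two sub-branches are both large enough, as a fraction of the
#'   within-branch mean (a branch splits when `between > (1 + min_gap) *
#'   within`). 0, the default, is the deepest split: any strictly positive
#'   separation splits, which deliberately over-fragments — the regime this
#'   ensemble method operates in (the super-cluster tier later absorbs
#'   fragments with indistinguishable profiles, see [supercluster()]).
#' @return a `cluster_tier`: list with `assignment` (named integer vector,
#'   NA = unassigned), `clusters` (list cluster ID -> member names),
#'   `unassigned` (member names), `min_size`.
#' @export
dynamic_cut <- function(tree, D, min_size = 5, min_gap = 0) {
  if (inherits(D, "consensus_model")) D <- D$D
  if (min_size < 1) stop("min_size must be >= 1")
  stopifnot(inherits(tree, "hclust"))
  n <- length(tree$order)
  items <- tree$labels
  if (is.null(items)) items <- as.character(seq_len(n))
  if (!is.null(rownames(D)) && !identical(rownames(D), items))
    D <- D[items, items, drop = FALSE]

  if (n < min_size) {
    assignment <- rep(NA_integer_, n)
    names(assignment) <- items
    return(structure(list(assignment = assignment, clusters = list(),
                          unassigned = items, min_size = as.integer(min_size)),
                     class = "cluster_tier"))
  }

  merge <- tree$merge
  # leaves of each internal node (memoized bottom-up; children always
  # precede parents in hclust merge order)
  leaves <- vector("list", n - 1L)
  node_leaves <- function(id) if (id < 0) -id else leaves[[id]]
  for (i in seq_len(n - 1L))
    leaves[[i]] <- c(node_leaves(merge[i, 1]), node_leaves(merge[i, 2]))
  mean_within <- function(m) {
    if (length(m) < 2L) return(0)
    sub <- D[m, m]
    sum(sub) / (length(m) * (length(m) - 1L))
  }

  clusters <- list()
  pool <- integer(0)
  eps <- 1e-12
  recurse <- function(id) {
    if (length(node_leaves(id)) < min_size) {
      pool <<- c(pool, node_leaves(id))
      return(invisible())
    }
    if (id < 0) {  # single leaf, admissible only when min_size = 1
      clusters[[length(clusters) + 1L]] <<- -id
      return(invisible())
    }
    c1 <- merge[id, 1]; c2 <- merge[id, 2]
    m1 <- node_leaves(c1); m2 <- node_leaves(c2)
    big1 <- length(m1) >= min_size
    big2 <- length(m2) >= min_size
    b <- mean(D[m1, m2])
    w <- max(mean_within(m1), mean_within(m2))
    if (big1 && big2 && b > (1 + min_gap) * w + eps) {
      recurse(c1); recurse(c2)
    } else if (big1 && !big2) {
      pool <<- c(pool, m2); recurse(c1)
    } else if (big2 && !big1) {
      pool <<- c(pool, m1); recurse(c2)
    } else {
      clusters[[length(clusters) + 1L]] <<- node_leaves(id)
    }
  }
  recurse(n - 1L)

  # distance stage: try to attach pooled items to the cluster cores
  assignment <- rep(NA_integer_, n)
  if (length(clusters)) {
    # deterministic cluster IDs: order by smallest member index
    clusters <- clusters[order(vapply(clusters, min, 1L))]
    for (ci in seq_along(clusters)) assignment[clusters[[ci]]] <- ci
    radius <- vapply(clusters, function(members) {
      if (length(members) == 1L) return(0)
      sub <- D[members, members, drop = FALSE]
      max(rowSums(sub) / (length(members) - 1L))
    }, 1.0)
    for (i in pool) {
      avg <- vapply(clusters, function(members)
        mean(D[i, members]), 1.0)
      best <- which.min(avg)
      if (avg[best] <= radius[best] + eps) assignment[i] <- best
    }
    members_final <- split(items[!is.na(assignment)],
                           assignment[!is.na(assignment)])
    clusters <- members_final
    names(clusters) <- as.character(seq_along(clusters))
  }
  names(assignment) <- items
  structure(list(assignment = assignment, clusters = clusters,
                 unassigned = items[is.na(assignment)],
                 min_size = as.integer(min_size)),
            class = "cluster_tier")
}

#' @export
print.cluster_tier <- function(x, ...) {
  n <- length(x$assignment)
  cat(sprintf(paste0("cluster_tier: %d clusters over %d items; %d assigned ",
                     "(%.0f%% coverage), %d unassigned; min size %d\n"),
              length(x$clusters), n, n - length(x$unassigned),
              100 * (n - length(x$unassigned)) / max(n, 1),
              length(x$unassigned), x$min_size))
  invisible(x)
}
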