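test_that("k-means ensemble handles degenerate and separable inputs", {
  # identical items always share a cluster
  x <- matrix(rep(c(0.2, 0.8), each = 2), 2, 2,
              dimnames = list(c("a", "b"), NULL))
  ens <- run_kmeans_ensemble(x, k = 1, repeats = 1, seed = 1)
  expect_equal(unname(ens$labels[1, "a"]), unname(ens$labels[1, "b"]))

  # k = number of distinct items -> singletons in every repeat
  y <- matrix(c(0, 0, 5, 5, 10, 10), 3, 2, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), NULL))
  ens2 <- run_kmeans_ensemble(y, k = 3, repeats = 5, seed = 2)
  for (r in 1:5) expect_equal(length(unique(ens2$labels[r, ])), 3L)

  # two well-separated blobs, k = 2: every repeat identical up to label
  # permutation, agreeing with the planted split
  blob <- withr::with_seed(7, rbind(matrix(rnorm(50, 0, 0.05), 25, 2),
                                    matrix(rnorm(50, 10, 0.05), 25, 2)))
  rownames(blob) <- paste0("i", 1:50)
  ens3 <- run_kmeans_ensemble(blob, k = 2, repeats = 20, seed = 3)
  planted <- rep(1:2, each = 25)
  for (r in 1:20)
    expect_equal(adjusted_rand_index(ens3$labels[r, ], planted), 1)

  expect_error(run_kmeans_ensemble(y, k = 10, repeats = 1), "scale k")
  expect_error(run_kmeans_ensemble(y, k = 2, repeats = 0), "repeats")
})

test_that("co-occurrence counts equal the brute-force pair oracle", {
  # constant co-clustering and never co-clustering
  always <- matrix(1L, nrow = 4, ncol = 3)
  m_always <- cooccurrence(always)
  expect_true(all(m_always$D == 0))
  never <- matrix(c(1:3, 1:3, 1:3, 1:3), nrow = 4, byrow = TRUE)
  m_never <- cooccurrence(never)
  expect_true(all(m_never$D[upper.tri(m_never$D)] == 4))

  # random label tables vs the O(R n^2) oracle, plus model invariants
  for (seed in 1:4) {
    labels <- withr::with_seed(seed,
      matrix(sample(1:4, 10 * 20, replace = TRUE), nrow = 10))
    model <- cooccurrence(labels)
    expect_equal(unname(model$N), oracle_cooccurrence(labels))
    expect_true(isSymmetric(model$N))
    expect_equal(diag(model$N), rep(10L, 20), ignore_attr = TRUE)
    expect_true(all(model$N >= 0 & model$N <= 10))
    expect_identical(model$D, model$R - model$N)
    expect_true(all(diag(model$D) == 0))
  }
})

test_that("per-repeat label permutations leave the consensus unchanged", {
  labels <- withr::with_seed(9,
    matrix(sample(1:3, 8 * 15, replace = TRUE), nrow = 8))
  perm <- labels
  for (r in 1:8) {
    p <- withr::with_seed(100 + r, sample(1:3))
    perm[r, ] <- p[labels[r, ]]
  }
  expect_equal(cooccurrence(labels)$N, cooccurrence(perm)$N)
})

test_that("tree construction matches a hand-run complete-linkage oracle", {
  # two items: single merge at their distance
  d2 <- matrix(c(0, 7, 7, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  t2 <- build_tree(d2)
  expect_equal(t2$height, 7)

  # two zero-distance blocks at distance R: within merges at 0, root at R
  db <- matrix(10, 6, 6)
  db[1:3, 1:3] <- 0
  db[4:6, 4:6] <- 0
  diag(db) <- 0
  rownames(db) <- colnames(db) <- paste0("i", 1:6)
  tb <- build_tree(db)
  expect_equal(sort(tb$height), c(0, 0, 0, 0, 10))

  # 8-item toy vs stats::hclust is definitionally identical; check the
  # heights against a manual agglomeration instead
  dm <- withr::with_seed(11, {
    x <- matrix(runif(16), 8, 2)
    as.matrix(dist(x))
  })
  rownames(dm) <- colnames(dm) <- paste0("i", 1:8)
  tr <- build_tree(dm)
  # brute-force complete-linkage agglomeration
  groups <- as.list(1:8)
  heights <- numeric(0)
  while (length(groups) > 1) {
    best <- c(NA, NA); bestd <- Inf
    for (i in seq_along(groups)) for (j in seq_along(groups)) if (i < j) {
      d <- max(dm[groups[[i]], groups[[j]]])
      if (d < bestd) { bestd <- d; best <- c(i, j) }
    }
    heights <- c(heights, bestd)
    groups[[best[1]]] <- c(groups[[best[1]]], groups[[best[2]]])
    groups[[best[2]]] <- NULL
  }
  expect_equal(tr$height, heights, tolerance = 1e-12)

  asym <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(build_tree(asym), "symmetric")
  dd <- d2; diag(dd) <- c(0, 1)
  expect_error(build_tree(dd), "diagonal")
})

test_that("dynamic cut recovers planted blocks and respects the size rule", {
  # fewer items than min_size: everything unassigned
  d4 <- matrix(1, 4, 4); diag(d4) <- 0
  rownames(d4) <- colnames(d4) <- paste0("i", 1:4)
  tier4 <- dynamic_cut(build_tree(d4), d4, min_size = 5)
  expect_equal(length(tier4$clusters), 0L)
  expect_equal(tier4$unassigned, paste0("i", 1:4))

  # twenty identical profiles: one cluster of twenty
  d20 <- matrix(0, 20, 20, dimnames = list(paste0("i", 1:20), paste0("i", 1:20)))
  tier20 <- dynamic_cut(build_tree(d20), d20, min_size = 5)
  expect_equal(length(tier20$clusters), 1L)
  expect_equal(length(tier20$clusters[[1]]), 20L)
  expect_equal(length(tier20$unassigned), 0L)

  # three planted blobs of 10 at mutual distance R, within distance 0
  R <- 50
  db <- matrix(R, 30, 30)
  for (b in 0:2) db[b * 10 + 1:10, b * 10 + 1:10] <- 0
  diag(db) <- 0
  rownames(db) <- colnames(db) <- paste0("i", 1:30)
  tier <- dynamic_cut(build_tree(db), db, min_size = 5)
  expect_equal(length(tier$clusters), 3L)
  planted <- rep(1:3, each = 10)
  expect_equal(adjusted_rand_index(tier$assignment, planted), 1)

  expect_error(dynamic_cut(build_tree(db), db, min_size = 0), "min_size")
})

test_that("cluster tier invariants hold on noisy consensus output", {
  x <- withr::with_seed(13, rbind(
    matrix(rnorm(60, 0, 0.3), 20, 3),
    matrix(rnorm(60, 3, 0.3), 20, 3),
    matrix(rnorm(60, -3, 0.3), 20, 3)))
  rownames(x) <- paste0("g", 1:60)
  tier <- consensus_cluster(x, k = 6, repeats = 30, min_size = 5, seed = 5)
  sizes <- lengths(tier$clusters)
  expect_true(all(sizes >= 5))
  members <- unlist(tier$clusters)
  expect_equal(anyDuplicated(members), 0L)
  expect_setequal(c(members, tier$unassigned), rownames(x))
  # assignment vector consistent with the member lists
  for (id in names(tier$clusters))
    expect_true(all(tier$assignment[tier$clusters[[id]]] == as.integer(id)))

  # bit-identical rerun under the same seed
  tier_b <- consensus_cluster(x, k = 6, repeats = 30, min_size = 5, seed = 5)
  expect_identical(tier, tier_b)
})

test_that("mean cluster profiles average member genes per stage", {
  profiles <- rbind(a = c(0, 1), b = c(1, 0), c = c(1, 1), d = c(1, 1))
  colnames(profiles) <- c("M1", "M2")
  tier <- structure(list(
    assignment = c(a = 1L, b = 1L, c = 2L, d = 2L),
    clusters = list(`1` = c("a", "b"), `2` = c("c", "d")),
    unassigned = character(0), min_size = 1L), class = "cluster_tier")
  mp <- mean_cluster_profiles(tier, profiles)
  expect_equal(mp["1", ], c(M1 = 0.5, M2 = 0.5))
  expect_equal(mp["2", ], c(M1 = 1, M2 = 1))
  expect_error(mean_cluster_profiles(
    structure(list(clusters = list(`1` = "zz")), class = "cluster_tier"),
    profiles), "absent")
})

test_that("super-clustering consolidates tiers and averages over genes", {
  # 3-blob toy: tier-1 clusters == super-clusters, ARI 1 at gene level
  x <- rbind(matrix(0, 10, 3), matrix(5, 10, 3), matrix(-5, 10, 3)) +
    withr::with_seed(15, matrix(rnorm(90, 0, 0.01), 30, 3))
  rownames(x) <- paste0("g", 1:30)
  tier1 <- consensus_cluster(x, k = 3, repeats = 20, min_size = 5, seed = 2)
  # occasional k-means runs that split a blob leave graded co-occurrence,
  # so tier 1 may over-fragment; the consolidation tier must undo that
  expect_gte(length(tier1$clusters), 3L)
  sup <- supercluster(tier1, x, k2 = 3, repeats = 20, min_size = 1, seed = 2)
  expect_equal(length(sup$super_members), 3L)
  ok <- !is.na(sup$gene_assignment)
  expect_gte(mean(ok), 0.8)
  expect_equal(adjusted_rand_index(sup$gene_assignment[ok],
                                   rep(1:3, each = 10)[ok]), 1)

  # identical cluster profiles collapse into one super-cluster
  xx <- matrix(rep(c(1, 0), each = 20), 20, 2)
  rownames(xx) <- paste0("g", 1:20)
  tier_id <- structure(list(
    assignment = setNames(rep(1:4, each = 5), rownames(xx)),
    clusters = split(rownames(xx), rep(1:4, each = 5)),
    unassigned = character(0), min_size = 5L), class = "cluster_tier")
  sup_id <- supercluster(tier_id, xx, k2 = 2, repeats = 10, min_size = 1,
                         seed = 3)
  expect_equal(length(sup_id$super_members), 1L)

  # gene-weighted mean: clusters of size 5 and 15 -> (5p + 15q)/20
  p <- c(1, 0); q <- c(0, 1)
  y <- rbind(matrix(p, 5, 2, byrow = TRUE), matrix(q, 15, 2, byrow = TRUE))
  rownames(y) <- paste0("g", 1:20)
  tier_w <- structure(list(
    assignment = setNames(c(rep(1L, 5), rep(2L, 15)), rownames(y)),
    clusters = list(`1` = rownames(y)[1:5], `2` = rownames(y)[6:20]),
    unassigned = character(0), min_size = 5L), class = "cluster_tier")
  # force the two clusters into one super-cluster via a huge threshold
  sup_w <- supercluster(tier_w, y, k2 = 1, repeats = 5, min_size = 1,
                        seed = 4, consolidate = 1e9)
  expect_equal(length(sup_w$gene_members[["1"]]), 20L)
  expect_equal(unname(sup_w$mean_profiles["1", ]), (5 * p + 15 * q) / 20)

  expect_error(supercluster(tier_w, y, k2 = 10, repeats = 5), "scale k2")
})
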