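test_that("size factors match closed forms and the brute-force oracle", {
  # sample 2 is 4x sample 1 gene-for-gene
  m <- cbind(M1_R1 = c(10L, 20L, 40L), M1_R2 = c(40L, 80L, 160L))
  rownames(m) <- paste0("g", 1:3)
  expect_equal(unname(compute_size_factors(mk_counts(m))), c(0.5, 2.0))

  # identical samples
  m2 <- matrix(rep(c(7L, 30L, 120L, 9L), 3), ncol = 3,
               dimnames = list(paste0("g", 1:4),
                               c("M1_R1", "M1_R2", "M2_R1")))
  expect_equal(unname(compute_size_factors(mk_counts(m2))), rep(1, 3))

  # random integer toys vs the direct-definition oracle
  for (seed in 1:5) {
    m3 <- withr::with_seed(seed, matrix(rpois(12, 40) + 1L, 4, 3,
        dimnames = list(paste0("g", 1:4), c("M1_R1", "M1_R2", "M2_R1"))))
    expect_equal(compute_size_factors(mk_counts(m3)), oracle_size_factors(m3))
  }

  # even number of usable genes: median = mean of the two central ratios
  m4 <- cbind(M1_R1 = c(10L, 10L, 10L, 10L), M1_R2 = c(10L, 20L, 40L, 80L))
  rownames(m4) <- paste0("g", 1:4)
  expect_equal(compute_size_factors(mk_counts(m4)), oracle_size_factors(m4))

  # every gene contains a zero -> explicit error
  m5 <- cbind(M1_R1 = c(0L, 5L), M1_R2 = c(5L, 0L))
  rownames(m5) <- c("g1", "g2")
  expect_error(compute_size_factors(mk_counts(m5)), "no gene")
})

test_that("single-sample scaling follows the exact median-of-ratios law", {
  # the per-gene geometric mean absorbs c^(1/m), so the scaled sample's
  # factor grows by c^(1 - 1/m), the others shrink by c^(-1/m), factor
  # ratios scale by exactly c, and normalized values shift by the common
  # c^(1/m)
  m <- withr::with_seed(8, matrix(rpois(40, 80) + 1L, 10, 4,
      dimnames = list(paste0("g", 1:10),
                      c("M1_R1", "M1_R2", "M2_R1", "M2_R2"))))
  cc <- 3
  m2 <- m
  m2[, 2] <- m2[, 2] * cc
  s <- compute_size_factors(mk_counts(m))
  s2 <- compute_size_factors(mk_counts(m2))
  expect_equal(s2[2], s[2] * cc^(1 - 1 / 4), tolerance = 1e-9)
  expect_equal(s2[-2], s[-2] * cc^(-1 / 4), tolerance = 1e-9)
  expect_equal(unname(s2[2] / s2[1]), unname(cc * s[2] / s[1]),
               tolerance = 1e-9)
  n1 <- normalize_counts(mk_counts(m), s)
  n2 <- normalize_counts(mk_counts(m2), s2)
  expect_equal(n2$values, n1$values * cc^(1 / 4), tolerance = 1e-9)
})

test_that("normalization divides elementwise and recomputed factors are constant", {
  x <- toy_counts()
  s <- compute_size_factors(x)
  norm <- normalize_counts(x, s)
  expect_equal(norm$values, sweep(x$counts, 2, s, "/"))
  expect_equal(norm$samples, x$samples)

  # unit factors: identity
  ones <- setNames(rep(1, 4), colnames(x$counts))
  expect_equal(normalize_counts(x, ones)$values, x$counts + 0)

  # factors recomputed on a normalized zero-free matrix are all equal
  # (to the geometric mean of the original factors)
  s2 <- compute_size_factors(norm$values)
  expect_equal(unname(s2), rep(exp(mean(log(s))), 4), tolerance = 1e-9)

  expect_error(normalize_counts(x, s[-1]), "mismatch")
  bad <- setNames(s, rev(names(s)))
  expect_error(normalize_counts(x, bad), "names")
})

test_that("the expression filter keeps genes passing in all replicates of a stage", {
  v <- rbind(
    boundary = c(5, 5, 0, 0),      # exactly 5 in both reps of stage 1 -> kept
    one_rep  = c(100, 4.9, 100, 4.9), # never both reps -> dropped
    late     = c(0, 0, 6, 7),      # passes at stage 2 -> kept
    low      = c(4, 4, 4, 4))      # never reaches 5 -> dropped
  colnames(v) <- c("M1_R1", "M1_R2", "M2_R1", "M2_R2")
  norm <- meristem_norm(v, parse_sample_ids(colnames(v)))
  expect_setequal(filter_expressed(norm, 5), c("boundary", "late"))

  # exhaustive oracle on random matrices + threshold monotonicity
  for (seed in 1:3) {
    m <- withr::with_seed(seed, matrix(rexp(60, 1 / 8), 10, 6,
        dimnames = list(paste0("g", 1:10),
                        c("M1_R1", "M1_R2", "M2_R1", "M2_R2",
                          "M3_R1", "M3_R2"))))
    nm <- meristem_norm(m, parse_sample_ids(colnames(m)))
    oracle <- rownames(m)[vapply(seq_len(nrow(m)), function(g) {
      any(vapply(1:3, function(s) {
        cols <- parse_sample_ids(colnames(m))$stage == s
        all(m[g, cols] >= 5)
      }, TRUE))
    }, TRUE)]
    expect_setequal(filter_expressed(nm, 5), oracle)
    expect_true(all(filter_expressed(nm, 8) %in% filter_expressed(nm, 5)))
  }

  solo <- meristem_norm(matrix(10, 1, 2, dimnames = list("g1", c("M1_R1", "M2_R1"))),
                        parse_sample_ids(c("M1_R1", "M2_R1")))
  expect_error(filter_expressed(solo), "replicates")
})

test_that("stage averaging and relative expression behave on toys", {
  v <- rbind(a = c(10, 20, 2, 4), b = c(3, 3, 3, 3))
  colnames(v) <- c("M1_R1", "M1_R2", "M2_R1", "M2_R2")
  norm <- meristem_norm(v, parse_sample_ids(colnames(v)))
  avg <- stage_average(norm)
  expect_equal(avg["a", ], c(M1 = 15, M2 = 3))
  expect_equal(avg["b", ], c(M1 = 3, M2 = 3))

  m <- rbind(ramp = c(2, 4, 8), zero = c(0, 0, 0), const = c(5, 5, 5))
  colnames(m) <- paste0("M", 1:3)
  prof <- relative_expression(m)
  expect_equal(unname(prof$values["ramp", ]), c(0.25, 0.5, 1))
  expect_equal(unname(prof$values["zero", ]), c(0, 0, 0))
  expect_true(prof$all_zero["zero"])
  expect_false(prof$all_zero["ramp"])
  expect_equal(unname(prof$values["const", ]), c(1, 1, 1))
  expect_true(all(prof$values >= 0 & prof$values <= 1))
  expect_error(relative_expression(m, integer(0)), "non-empty")
  expect_error(relative_expression(m, 9), "subset")
})

test_that("joint scaling uses the shared maximum across experiments", {
  avg1 <- rbind(g1 = c(1, 2, 3, 4, 10), g2 = c(2, 8, 2, 2, 2))
  colnames(avg1) <- paste0("M", 1:5)
  attr(avg1, "stages") <- 1:5

  # second experiment identical to the restriction -> identical profiles
  avg2 <- avg1[, 2:4]
  attr(avg2, "stages") <- 2:4
  js <- joint_scale(avg1, avg2)
  expect_equal(js$exp2$values, js$exp1$values[, 2:4])
  expect_equal(unname(js$exp1$values["g1", ]), c(0.1, 0.2, 0.3, 0.4, 1))

  # gene whose global max lies outside the shared stages: exp2 max < 1
  expect_lt(max(js$exp2$values["g1", ]), 1)
  # gene maximal inside the shared stages reaches 1 there
  expect_equal(max(js$exp2$values["g2", ]), 1)

  # brute-force shared-max oracle on a toy pair with differing values
  avg2b <- avg1[, 2:4] * 1.5
  attr(avg2b, "stages") <- 2:4
  js2 <- joint_scale(avg1, avg2b)
  for (g in rownames(avg1)) {
    mx <- max(c(avg2b[g, ], avg1[g, c(1, 5)]))
    expect_equal(js2$exp1$values[g, ], avg1[g, ] / mx)
    expect_equal(js2$exp2$values[g, ], avg2b[g, ] / mx)
  }

  rownames(avg2) <- c("h1", "h2")
  expect_error(joint_scale(avg1, avg2), "share no genes")
})
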