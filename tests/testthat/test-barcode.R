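test_that("dissimilarity conversion implements 1 - |corr| with zero diagonal", {
  f <- cm(rbind(c(1, 1, -0.5), c(1, 1, 0.2), c(-0.5, 0.2, 1)))
  d <- dissimilarity_from_connectivity(f)
  expect_equal(d[1, 2], 0)
  expect_equal(d[1, 3], 0.5)
  expect_equal(diag(d), rep(0, 3), ignore_attr = TRUE)
  # sign-flip invariance
  expect_equal(dissimilarity_from_connectivity(-unclass(f)), d,
               ignore_attr = TRUE)

  # random correlation-type input stays in [0, 1]
  fc <- generate_correlation_matrix(25, 3, 0.5, seed = 4)
  dr <- dissimilarity_from_connectivity(fc)
  expect_true(all(dr >= 0 & dr <= 1))

  # out-of-range entries trigger max-abs rescaling with a warning
  big <- cm(rbind(c(0, 2), c(2, 0)))
  expect_warning(d2 <- dissimilarity_from_connectivity(big), "rescaling")
  expect_equal(d2[1, 2], 0) # 2/2 = 1 -> distance 0
})

test_that("barcode of the three-node hand example has the stated structure", {
  d <- rbind(c(0, 0.2, 0.9), c(0.2, 0, 0.5), c(0.9, 0.5, 0))
  b <- betti0_barcode(d)
  expect_equal(b$breakpoints, c(0.2, 0.5))
  expect_equal(b$counts, c(3L, 2L, 1L))
  # left continuity: at lambda equal to a merge height, not yet merged
  expect_equal(evaluate_barcode(b, 0), 3L)
  expect_equal(evaluate_barcode(b, 0.2), 3L)
  expect_equal(evaluate_barcode(b, 0.21), 2L)
  expect_equal(evaluate_barcode(b, 0.5), 2L)
  expect_equal(evaluate_barcode(b, 2), 1L)
})

test_that("barcode equals the BFS component-count oracle everywhere", {
  set.seed(77)
  for (rep in 1:50) {
    n <- sample(3:20, 1)
    d <- rand_dissimilarity(n)
    b <- betti0_barcode(d)
    expect_equal(b$counts[1], n)
    lams <- seq(0, 1, length.out = 100)
    got <- evaluate_barcode(b, lams)
    want <- vapply(lams, function(l) bfs_beta0(d, l), integer(1))
    expect_identical(got, as.integer(want))
  }
})

test_that("breakpoints coincide with single-linkage merge heights", {
  # cross-check against hclust single linkage, an independent route
  set.seed(12)
  for (rep in 1:10) {
    n <- sample(5:25, 1)
    d <- rand_dissimilarity(n)
    b <- betti0_barcode(d)
    hc_heights <- sort(unique(stats::hclust(stats::as.dist(d),
                                            method = "single")$height))
    expect_equal(b$breakpoints, hc_heights, tolerance = 1e-12)
    # continuous weights: one merge per breakpoint
    expect_equal(length(b$breakpoints), b$counts[1] - tail(b$counts, 1))
    expect_true(all(diff(b$counts) < 0))
  }
})

test_that("barcode rejects invalid dissimilarities", {
  expect_error(betti0_barcode(rbind(c(0, -0.1), c(-0.1, 0))),
               class = "polyconn_validation_error")
  expect_error(betti0_barcode(rbind(c(0, 1, 0), c(1, 0, 0))),
               class = "polyconn_validation_error")
  expect_error(evaluate_barcode(betti0_barcode(matrix(0, 2, 2)), -0.5),
               class = "polyconn_parameter_error")
})

test_that("sse_beta reproduces the N = 2 hand integral exactly", {
  merges <- betti0_barcode(rbind(c(0, 0.5), c(0.5, 0)))
  never <- betti0_barcode(rbind(c(0, 2), c(2, 0))) # merge outside [0, 1]
  # difference is 1 on (0.5, 1]: integral 0.5, normalized by N^2 = 4
  expect_identical(sse_beta(merges, never), 0.125)
  expect_identical(sse_beta(never, merges), 0.125)
  expect_identical(sse_beta(merges, merges), 0)
})

test_that("exact sse_beta integral matches a dense Riemann-grid oracle", {
  set.seed(31)
  for (rep in 1:25) {
    n <- sample(3:15, 1)
    a <- betti0_barcode(rand_dissimilarity(n))
    b <- betti0_barcode(rand_dissimilarity(n))
    exact <- sse_beta(a, b)
    grid <- seq(0.5e-5, 1 - 0.5e-5, length.out = 1e5)
    riemann <- mean((evaluate_barcode(a, grid) -
                       evaluate_barcode(b, grid))^2) / n^2
    expect_equal(exact, riemann, tolerance = 1e-3)
    # symmetry and bounds
    expect_identical(sse_beta(b, a), exact)
    expect_gte(exact, 0)
    expect_lte(exact, (n - 1)^2 / n^2)
  }
  # mismatched node counts are not comparable
  expect_error(
    sse_beta(betti0_barcode(rand_dissimilarity(4)),
             betti0_barcode(rand_dissimilarity(5))),
    class = "polyconn_validation_error"
  )
})

test_that("sse_beta is invariant under simultaneous node relabeling", {
  set.seed(55)
  for (rep in 1:10) {
    n <- 12
    d1 <- rand_dissimilarity(n)
    d2 <- rand_dissimilarity(n)
    perm <- sample(n)
    expect_equal(
      sse_beta(betti0_barcode(d1[perm, perm]),
               betti0_barcode(d2[perm, perm])),
      sse_beta(betti0_barcode(d1), betti0_barcode(d2)),
      tolerance = 1e-12
    )
  }
})

test_that("barcode export writes the documented two-column text form", {
  b <- betti0_barcode(rbind(c(0, 0.2, 0.9), c(0.2, 0, 0.5), c(0.9, 0.5, 0)))
  path <- withr::local_tempfile()
  write_barcode(b, path)
  lines <- readLines(path)
  expect_match(lines[1], "n_nodes\t3")
  expect_equal(length(lines), 4) # header + column names + 2 breakpoints
})
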