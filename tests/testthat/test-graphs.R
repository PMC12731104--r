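# Gaussian-median-distance adjacency, graph filter, cosine adjacency and
# symmetric normalization.

collinear3 <- function() {
  co <- cbind(c(0, 1, 3), 0, 0)
  rownames(co) <- c("a", "b", "c")
  co
}

test_that("gmd_delta is the median pairwise distance", {
  expect_equal(gmd_delta(collinear3())$delta, 2)    # pairs {1, 2, 3}
  two <- cbind(c(0, 1), 0, 0)
  expect_equal(gmd_delta(two)$delta, 1)
  expect_error(gmd_delta(matrix(0, 3, 3)), class = "lpggnet_numeric_error")
})

test_that("gmd_adjacency applies the three-branch rule", {
  a <- gmd_adjacency(collinear3())$values
  expect_equal(a["a", "b"], exp(-1 / 4), tolerance = 1e-12)
  expect_equal(a["b", "c"], exp(-1), tolerance = 1e-12)
  expect_identical(a["a", "c"], 0)                   # hard cutoff: d=3 > 2
  expect_equal(diag(a), c(a = 1, b = 1, c = 1))
  expect_equal(a, t(a))
  # cutoff can be disabled
  a2 <- gmd_adjacency(collinear3(), cutoff = FALSE)$values
  expect_equal(a2["a", "c"], exp(-9 / 4), tolerance = 1e-12)
})

test_that("gmd adjacency is invariant to global coordinate rescaling", {
  set.seed(20)
  for (i in 1:10) {
    co <- matrix(rnorm(8 * 3), 8, 3)
    rownames(co) <- paste0("e", 1:8)
    s <- runif(1, 0.01, 100)
    expect_equal(gmd_adjacency(co)$values, gmd_adjacency(co * s)$values,
                 tolerance = 1e-10)
  }
})

test_that("gmd is at least as sparse as the inverse-square comparator", {
  m <- montage_dataset_a()
  for (p in scheme_dataset_a()$partitions) {
    co <- m$coords[p, , drop = FALSE]
    zeros_gmd <- sum(gmd_adjacency(co)$values == 0)
    zeros_ised <- sum(ised_adjacency(co)$values == 0)
    expect_gte(zeros_gmd, zeros_ised)
  }
  # on the whole montage the cutoff removes many long-range links
  expect_gt(sum(gmd_adjacency(m)$values == 0), 0)
  expect_identical(sum(ised_adjacency(m)$values == 0), 0L)
})

test_that("gaussian_filter is the printed random-walk Laplacian", {
  adj <- adjacency_matrix(rbind(c(1, 0.5), c(0.5, 1)), self_loops = TRUE)
  f <- gaussian_filter(adj)
  expect_equal(unname(f$operator),
               rbind(c(1 / 3, -1 / 3), c(-1 / 3, 1 / 3)), tolerance = 1e-12)
  expect_equal(apply_filter(f, c(1, 0)), c(1 / 3, -1 / 3), tolerance = 1e-12)
  # identity adjacency (isolated self-looped nodes) -> zero operator
  f0 <- gaussian_filter(adjacency_matrix(diag(3), self_loops = TRUE))
  expect_equal(unname(f0$operator), matrix(0, 3, 3), tolerance = 1e-15)
})

test_that("the filter annihilates constants and common-mode offsets", {
  set.seed(21)
  co <- montage_dataset_a()$coords[scheme_dataset_a()$partitions$P1, ]
  f <- gaussian_filter(gmd_adjacency(co))
  expect_lt(max(abs(rowSums(f$operator))), 1e-9)
  expect_equal(apply_filter(f, rep(1, 7)), rep(0, 7), tolerance = 1e-12)
  x <- matrix(rnorm(7 * 50), 7, 50)
  rownames(x) <- rownames(f$operator)
  expect_equal(apply_filter(f, x + 5), apply_filter(f, x), tolerance = 1e-9)
  expect_equal(apply_filter(f, x * 0), x * 0, tolerance = 1e-15)
  bad <- x[c(2:7, 1), ]
  expect_error(apply_filter(f, bad), class = "lpggnet_validation_error")
})

test_that("cosine adjacency matches hand values and respects bounds", {
  expect_equal(unname(cosine_adjacency(rbind(c(1, 0), c(1, 1)))$values),
               rbind(c(1, 1 / sqrt(2)), c(1 / sqrt(2), 1)),
               tolerance = 1e-12)
  expect_equal(unname(cosine_adjacency(rbind(c(1, 2), c(2, 4)))$values),
               matrix(1, 2, 2), tolerance = 1e-12)
  expect_equal(unname(cosine_adjacency(diag(3))$values), diag(3),
               tolerance = 1e-12)
  set.seed(22)
  x <- matrix(rnorm(12 * 5), 12, 5)
  raw <- cosine_adjacency(x, negatives = "none")$values
  expect_true(all(raw >= -1 - 1e-12 & raw <= 1 + 1e-12))
  cl <- cosine_adjacency(x)$values
  expect_true(all(cl >= 0 & cl <= 1))
  ab <- cosine_adjacency(x, negatives = "abs")$values
  expect_equal(unname(ab), unname(pmin(abs(raw), 1)), tolerance = 1e-12)
  x0 <- x
  x0[3, ] <- 0
  rownames(x0) <- paste0("n", 1:12)
  err <- expect_error(cosine_adjacency(x0), class = "lpggnet_numeric_error")
  expect_match(conditionMessage(err), "n3")
})

test_that("sym_normalize matches the closed form and bounds its spectrum", {
  a <- sym_normalize(matrix(c(0, 0.5, 0.5, 0), 2, 2))$values
  expect_equal(unname(a), rbind(c(2 / 3, 1 / 3), c(1 / 3, 2 / 3)),
               tolerance = 1e-12)
  expect_equal(unname(sym_normalize(matrix(0, 4, 4))$values), diag(4))
  set.seed(23)
  for (i in 1:20) {
    n <- sample(2:8, 1L)
    m <- matrix(runif(n * n), n, n)
    m <- (m + t(m)) / 2
    diag(m) <- 0
    v <- sym_normalize(m)$values
    expect_lt(max(abs(eigen(v, only.values = TRUE)$values)), 1 + 1e-9)
  }
  expect_error(sym_normalize(matrix(c(0, -1, -1, 0), 2, 2)),
               class = "lpggnet_validation_error")
})
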