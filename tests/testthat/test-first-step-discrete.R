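test_that("count screening enforces the minimum state counts", {
  withr::with_seed(1, {
    n <- 300
    v <- cbind(f14 = rep(c(1, 0), c(14, n - 14)),
               f15 = rep(c(1, 0), c(15, n - 15)),
               const = rep(0, n),
               common = rbinom(n, 1, 0.5))
    rownames(v) <- sprintf("C%03d", 1:n)
    kept <- screenFeatures(v, "binary", 15)
    expect_identical(kept, c("f15", "common"))

    # exactly 15 of each state passes the boundary
    v2 <- cbind(edge = rep(c(1, 0), c(15, 15)))
    expect_identical(screenFeatures(v2, "binary", 15), "edge")

    # ternary screening splits aberrant vs neutral
    v3 <- cbind(cn = rep(c(-1, 1, 0), c(8, 8, 15)))
    expect_identical(screenFeatures(v3, "ternary", 15), "cn")
    expect_identical(screenFeatures(v3, "ternary", 16), character())

    # tissue only needs the membership count
    t1 <- cbind(small = rep(c(1, 0), c(9, 291)),
                big = rep(c(0, 1), c(9, 291)))
    expect_identical(screenFeatures(t1, "onehot", 10), "big")
  })
})

test_that("association t-test matches the pooled-t oracle and conventions", {
  p <- testFeatureAssociation(c(1, 2, 3, 4, 5), c(2, 3, 4, 5, 6))
  oracle <- t.test(c(1, 2, 3, 4, 5), c(2, 3, 4, 5, 6), var.equal = TRUE)
  expect_equal(p, oracle$p.value, tolerance = 1e-10)

  # identical groups: t = 0, p = 1
  expect_equal(testFeatureAssociation(c(1, 2, 3), c(3, 2, 1)), 1)

  # well-separated groups with tiny jitter
  withr::with_seed(2, {
    a <- 0.1 + rnorm(4, sd = 1e-4)
    b <- 0.9 + rnorm(4, sd = 1e-4)
    expect_lt(testFeatureAssociation(a, b), 1e-6)
  })

  # zero-variance conventions
  expect_equal(testFeatureAssociation(c(2, 2, 2), c(2, 2, 2)), 1)
  expect_equal(testFeatureAssociation(c(1, 1, 1), c(2, 2, 2)), 0)
  expect_equal(testFeatureAssociation(rep(0.1, 5), rep(0.1, 7)), 1)

  # Welch flavour against its oracle
  withr::with_seed(8, {
    x <- rnorm(12)
    y <- rnorm(20, sd = 3)
    expect_equal(testFeatureAssociation(x, y, varEqual = FALSE),
                 t.test(x, y)$p.value, tolerance = 1e-10)
  })
})

test_that("Bonferroni selection thresholds at alpha / m, ordered by p", {
  p <- c(a = 4e-4, b = 6e-4, c = 1)
  expect_identical(bonferroniSelect(p, alpha = 0.05, m = 100), "a")
  expect_identical(bonferroniSelect(c(a = 1, b = 1), 0.05, 2), character())
  p2 <- c(x = 3e-4, y = 1e-5, z = 4.9e-4)
  expect_identical(bonferroniSelect(p2, 0.05, 100), c("y", "x", "z"))
  expect_error(bonferroniSelect(p, m = 0), class = "twoStepValidationError")
})

test_that("redundancy pruning keeps one representative per pattern", {
  base <- c(1, 1, 0, 0, 1)
  m <- cbind(f1 = base, f2 = 1 - base, f3 = base, f4 = base,
             f5 = c(1, 0, 0, 0, 1))
  rr <- removeRedundant(m)
  expect_identical(rr$kept, c("f1", "f2", "f5"))
  expect_identical(rr$redundancyMap, c(f3 = "f1", f4 = "f1"))

  distinct <- cbind(a = c(1, 0, 0), b = c(0, 1, 0))
  expect_identical(removeRedundant(distinct)$kept, c("a", "b"))

  # pairwise pattern-equality oracle on random matrices
  withr::with_seed(13, {
    for (i in 1:25) {
      mm <- matrix(rbinom(60, 1, 0.5), 10, 6,
                   dimnames = list(NULL, letters[1:6]))
      rr <- removeRedundant(mm)
      keptPatterns <- apply(mm[, rr$kept, drop = FALSE], 2, paste,
                            collapse = "")
      expect_false(any(duplicated(keptPatterns)))
      for (drop in names(rr$redundancyMap))
        expect_identical(unname(mm[, drop]),
                         unname(mm[, rr$redundancyMap[[drop]]]))
      expect_equal(length(rr$kept) + length(rr$redundancyMap), 6L)
    }
  })
})

test_that("cluster models partition training cells and average labels", {
  v <- cbind(f1 = c(1, 1, 0, 0, 1, 0), f2 = c(1, 0, 1, 0, 0, 0))
  rownames(v) <- sprintf("C%d", 1:6)
  y <- c(1, 1, 0, 0, 1, 1)
  model <- buildClusterModel(v, c("f1", "f2"), y, dataType = "mutation")
  expect_lte(nrow(model@clusters), 4)
  expect_equal(sum(model@clusters$n), 6)

  # single feature: present {1,1,0}, absent {0,0,1} -> 2/3 and 1/3
  v1 <- cbind(f = c(1, 1, 1, 0, 0, 0))
  rownames(v1) <- sprintf("C%d", 1:6)
  m1 <- buildClusterModel(v1, "f", c(1, 1, 0, 0, 0, 1), dataType = "mutation")
  lut <- stats::setNames(m1@clusters$prediction, m1@clusters$pattern)
  expect_equal(unname(lut["1"]), 2 / 3)
  expect_equal(unname(lut["0"]), 1 / 3)

  # trivial model: constant prediction equals responder fraction
  m0 <- buildClusterModel(v, character(), y, dataType = "mutation")
  expect_true(m0@constant)
  expect_equal(unique(unname(predict(m0, v))), mean(y))
})

test_that("member-weighted cluster means reconstruct the responder fraction", {
  withr::with_seed(21, {
    for (i in 1:20) {
      n <- sample(30:80, 1)
      k <- sample(1:4, 1)
      v <- matrix(rbinom(n * k, 1, 0.5), n, k,
                  dimnames = list(sprintf("C%03d", 1:n),
                                  sprintf("f%d", 1:k)))
      y <- rbinom(n, 1, 0.4)
      m <- buildClusterModel(v, colnames(v), y, dataType = "mutation")
      expect_equal(sum(m@clusters$n * m@clusters$prediction) /
                     sum(m@clusters$n), mean(y), tolerance = 1e-12)
    }
  })
})

test_that("prediction looks up clusters and falls back for unseen patterns", {
  v <- cbind(f1 = c(1, 1, 0, 0), f2 = c(0, 0, 0, 0))
  rownames(v) <- sprintf("C%d", 1:4)
  y <- c(1, 1, 0, 1)
  m <- buildClusterModel(v, c("f1", "f2"), y, dataType = "mutation")
  test <- cbind(f1 = c(1, 1), f2 = c(0, 1))
  rownames(test) <- c("T1", "T2")
  pred <- predict(m, test)
  expect_equal(unname(pred["T1"]), 1)       # matches cluster "10"
  expect_equal(unname(pred["T2"]), mean(y)) # pattern "11" unseen -> fallback
})

test_that("redundancy pruning never changes the training partition", {
  withr::with_seed(31, {
    for (i in 1:10) {
      n <- 40
      base <- matrix(rbinom(n * 3, 1, 0.5), n, 3)
      v <- cbind(base, base[, 1], base[, 2])
      colnames(v) <- sprintf("f%d", 1:5)
      rownames(v) <- sprintf("C%02d", 1:n)
      y <- rbinom(n, 1, 0.5)
      rr <- removeRedundant(v)
      full <- apply(v != 0, 1, paste, collapse = "")
      pruned <- apply(v[, rr$kept, drop = FALSE] != 0, 1, paste,
                      collapse = "")
      # identical pattern grouping before and after pruning
      expect_identical(as.integer(factor(full, unique(full))),
                       as.integer(factor(pruned, unique(pruned))))
    }
  })
})

test_that("ternary clusters report the modal aberrant state", {
  v <- cbind(cn = c(-1, -1, -1, 1, 0, 0))
  rownames(v) <- sprintf("C%d", 1:6)
  m <- buildClusterModel(v, "cn", c(1, 1, 0, 1, 0, 0), dataType = "cnv")
  expect_equal(unname(m@states["1", "cn"]), -1)
  expect_equal(unname(m@states["0", "cn"]), 0)
})

test_that("tissue models pool non-significant tissues into the first cluster", {
  n <- 30
  withr::with_seed(4, {
    idx <- sample(1:5, n, TRUE)
    v <- matrix(0, n, 5, dimnames = list(sprintf("C%02d", 1:n),
                                         sprintf("tissue%d", 1:5)))
    v[cbind(1:n, idx)] <- 1
    y <- rbinom(n, 1, 0.5)
    m <- buildTissueModel(v, c("tissue2", "tissue4"), y)
    expect_equal(nrow(m@clusters), 3)            # n + 1 with n = 2
    expect_identical(m@clusters$pattern[1], "<other>")
    pooled <- idx %in% c(1, 3, 5)
    expect_equal(m@clusters$prediction[1], mean(y[pooled]))
    expect_equal(m@clusters$prediction[m@clusters$pattern == "tissue2"],
                 mean(y[idx == 2]))

    m0 <- buildTissueModel(v, character(), y)
    expect_true(m0@constant)
    expect_equal(nrow(m0@clusters), 1)

    pred <- predict(m, v)
    expect_equal(unname(pred[idx == 4][1]),
                 m@clusters$prediction[m@clusters$pattern == "tissue4"])
    expect_equal(unname(pred[pooled][1]), m@clusters$prediction[1])
  })
})

test_that("feature cap keeps the smallest p-value features", {
  withr::with_seed(6, {
    n <- 60
    v <- matrix(rbinom(n * 5, 1, 0.5), n, 5,
                dimnames = list(sprintf("C%02d", 1:n), sprintf("f%d", 1:5)))
    y <- rbinom(n, 1, 0.5)
    m <- buildClusterModel(v, colnames(v), y, dataType = "mutation",
                           featureCap = 2L)
    expect_identical(m@nonredundant, c("f1", "f2"))
    expect_lte(nrow(m@clusters), 4)
  })
})
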