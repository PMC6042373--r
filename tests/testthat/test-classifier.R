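planted_matrix <- function(n = 400L, ninf = 5L, nnoise = 40L, eff = 0.8,
                           seed = 31) {
  withr::local_seed(seed)
  y <- rep(c(1, -1), each = n / 2)
  Xinf <- vapply(seq_len(ninf), function(j)
    rbinom(n, 1L, ifelse(y > 0, 0.5 + eff / 2, 0.5 - eff / 2)), numeric(n))
  Xnoise <- vapply(seq_len(nnoise), function(j)
    rbinom(n, 1L, 0.15), numeric(n))
  X <- methods::as(methods::as(Matrix::Matrix(cbind(Xinf, Xnoise), sparse = TRUE),
                               "CsparseMatrix"), "generalMatrix")
  colnames(X) <- c(paste0("inf", seq_len(ninf)), paste0("noise", seq_len(nnoise)))
  list(X = X, y = y, ninf = ninf, nnoise = nnoise)
}

test_that("a separable 1-D problem learns a positive weight and AUC 1", {
  X <- Matrix::sparseMatrix(i = 1:20, j = rep(1, 20),
                            x = rep(c(1, -1), each = 10), dims = c(20, 1))
  colnames(X) <- "f1"
  y <- rep(c(1, -1), each = 10)
  m <- trainL1Logistic(X, y, C = 1)
  expect_gt(modelWeights(m)[["f1"]], 0)
  expect_equal(aucRank(scoreVariants(m, X), y), 1)
})

test_that("an all-zero feature column gets weight exactly 0", {
  pm <- planted_matrix()
  X <- cbind(pm$X, Matrix::sparseMatrix(i = integer(), j = integer(),
                                        x = numeric(), dims = c(nrow(pm$X), 1)))
  colnames(X) <- c(colnames(pm$X), "zero")
  for (C in c(0.01, 1, 100)) {
    m <- trainL1Logistic(methods::as(X, "generalMatrix"), pm$y, C = C)
    expect_identical(unname(modelWeights(m)[["zero"]]), 0)
  }
})

test_that("training rejects degenerate inputs", {
  pm <- planted_matrix(n = 20L)
  expect_error(trainL1Logistic(pm$X, rep(1, 20)), "both classes")
  expect_error(trainL1Logistic(pm$X, pm$y, C = -1), "C must be")
  expect_error(trainL1Logistic(pm$X, rep(c(1, 0), 10)), "\\+1 / -1")
  bad <- pm$X; bad[1, 1] <- NA
  expect_error(trainL1Logistic(bad, pm$y), "non-finite")
})

test_that("scores equal a dense dot-product + sigmoid oracle", {
  pm <- planted_matrix(n = 100L)
  m <- trainL1Logistic(pm$X, pm$y, C = 1)
  got <- scoreVariants(m, pm$X)
  dense <- as.matrix(pm$X)
  want <- 1 / (1 + exp(-(dense %*% modelWeights(m) + modelIntercept(m))))
  expect_equal(got, as.numeric(want), tolerance = 1e-12)
  expect_true(all(got > 0 & got < 1))
})

test_that("zero model scores 0.5 everywhere; empty rows score sigmoid(intercept)", {
  X <- Matrix::sparseMatrix(i = 1, j = 1, x = 1, dims = c(3, 2))
  colnames(X) <- c("a", "b")
  zero <- new("SparseLogisticModel", weights = c(a = 0, b = 0), intercept = 0,
              featureNames = c("a", "b"), cost = 1, tol = 1e-9)
  expect_equal(scoreVariants(zero, X), rep(0.5, 3))
  m <- new("SparseLogisticModel", weights = c(a = 2, b = -1), intercept = 0.3,
           featureNames = c("a", "b"), cost = 1, tol = 1e-9)
  expect_equal(scoreVariants(m, X)[2], plogis(0.3))  # all-missing row
})

test_that("scoring rejects a mismatched feature registry", {
  pm <- planted_matrix(n = 40L)
  m <- trainL1Logistic(pm$X, pm$y)
  X2 <- pm$X; colnames(X2) <- rev(colnames(pm$X))
  expect_error(scoreVariants(m, X2), "registry mismatch")
})

test_that("rank AUC equals exhaustive pair counting on all small arrangements", {
  withr::local_seed(23)
  for (np in 1:5) for (nn in 1:5) for (rep in 1:20) {
    scores <- sample(1:4, np + nn, replace = TRUE)  # heavy ties on purpose
    labels <- c(rep(1, np), rep(-1, nn))[sample(np + nn)]
    expect_identical(aucRank(scores, labels), oracle_auc(scores, labels))
  }
  expect_error(aucRank(1:3, rep(1, 3)), "both classes")
})

test_that("random labels give AUC near 0.5 and perfect separation gives 1", {
  withr::local_seed(29)
  labels <- rep(c(1, -1), 2000)
  expect_equal(aucRank(runif(4000), labels), 0.5, tolerance = 0.05)
  expect_equal(aucRank(c(2, 3, 0, 1), c(1, 1, -1, -1)), 1)
})

test_that("rank-sum p-values track the exact enumeration for small samples", {
  withr::local_seed(37)
  for (rep in 1:20) {
    na <- sample(4:8, 1); nb <- sample(4:8, 1)
    a <- round(rnorm(na), 1); b <- round(rnorm(nb, 0.5), 1)
    for (alt in c("two.sided", "greater", "less")) {
      approx <- ranksumPvalue(a, b, alt)
      exact <- oracle_ranksum_exact(a, b, alt)
      expect_lt(abs(approx - exact), 0.1)  # normal-approximation bound
    }
  }
  expect_gte(ranksumPvalue(1:10, 1:10), 0.99)
  expect_lt(ranksumPvalue(rnorm(20, 10), rnorm(20), "greater"), 1e-6)
})

test_that("cross-validation partitions rows exactly once, stratified, seeded", {
  pm <- planted_matrix()
  cv <- crossValidate(pm$X, pm$y, folds = 10, C = 0.1, seed = 5)
  expect_equal(sort(unique(cv$fold)), 1:10)
  expect_equal(length(cv$fold), nrow(pm$X))
  per_fold_pos <- tapply(pm$y > 0, cv$fold, sum)
  expect_true(max(per_fold_pos) - min(per_fold_pos) <= 1)
  cv2 <- crossValidate(pm$X, pm$y, folds = 10, C = 0.1, seed = 5)
  expect_identical(cv$fold, cv2$fold)
  expect_identical(cv$foldAuc, cv2$foldAuc)
  expect_gte(cv$meanAuc, 0.95)
})

test_that("refitting on identical input is bit-reproducible", {
  pm <- planted_matrix()
  m1 <- trainL1Logistic(pm$X, pm$y, C = 0.5)
  m2 <- trainL1Logistic(pm$X, pm$y, C = 0.5)
  expect_identical(modelWeights(m1), modelWeights(m2))
  expect_identical(modelIntercept(m1), modelIntercept(m2))
})

test_that("AUC from probabilities equals AUC from decision values", {
  pm <- planted_matrix(n = 200L)
  m <- trainL1Logistic(pm$X, pm$y, C = 1)
  expect_equal(aucRank(scoreVariants(m, pm$X), pm$y),
               aucRank(decisionValues(m, pm$X), pm$y))
})

test_that("sparsity is non-increasing as C shrinks", {
  pm <- planted_matrix()
  nnz <- vapply(c(10, 1, 0.1, 0.01), function(C)
    sum(modelWeights(trainL1Logistic(pm$X, pm$y, C = C)) != 0), 1)
  expect_true(all(diff(nnz) <= 0))
})

test_that("model serialization round-trips weights and metadata", {
  pm <- planted_matrix(n = 100L)
  m <- trainL1Logistic(pm$X, pm$y, C = 0.3)
  p <- tempfile(fileext = ".tsv")
  writeModel(m, p)
  m2 <- readModel(p)
  expect_equal(modelWeights(m2), modelWeights(m), tolerance = 1e-15)
  expect_equal(modelIntercept(m2), modelIntercept(m))
  expect_identical(m2@featureNames, m@featureNames)
  expect_equal(scoreVariants(m2, pm$X), scoreVariants(m, pm$X),
               tolerance = 1e-12)
})
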