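# Sparse L1-regularized logistic regression and the evaluation statistics
# used throughout: rank-based AUC and the Wilcoxon rank-sum test.
#
# The solver is glmnet's coordinate descent. The regularization strength is
# expressed as C (larger C = weaker penalty, the convention of the LIBLINEAR
# solver family): the penalized objective C * sum(logloss) + ||w||_1 is
# equivalent to glmnet's (1/n) sum(logloss) + lambda ||w||_1 at
# lambda = 1 / (n * C). Features are not standardized before fitting.

.as_dgc <- function(X) {
  if (methods::is(X, "FeatureMatrix")) X@matrix
  else methods::as(methods::as(X, "CsparseMatrix"), "generalMatrix")
}

.feature_names_of <- function(X) {
  if (methods::is(X, "FeatureMatrix")) X@featureNames
  else colnames(X) %||% paste0("f", seq_len(ncol(X)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Train an L1-regularized logistic regression
#'
#' Fits a sparse logistic model on a variant-by-feature matrix whose absent
#' entries count as 0 in the dot product (the sparse-format semantics the
#' missing-value contract relies on). With small `C` many weights are exactly
#' zero; an all-zero feature column always gets weight exactly 0. The fit is
#' deterministic for identical inputs.
#'
#' @param X a [FeatureMatrix-class] or sparse matrix, rows = variants.
#' @param y labels in `{+1, -1}` (numeric), both classes present.
#' @param C regularization strength (> 0); default 1.
#' @param tol coordinate-descent convergence threshold; default `1e-9`.
#' @return a [SparseLogisticModel-class].
#' @export
trainL1Logistic <- function(X, y, C = 1, tol = 1e-9) {
  m <- .as_dgc(X)
  if (nrow(m) < 2L) stop("need at least two training rows")
  if (!all(y %in% c(-1, 1))) stop("labels must be +1 / -1")
  if (length(unique(y)) < 2L) stop("both classes must be present in y")
  if (any(!is.finite(m@x))) stop("non-finite values in the feature matrix")
  if (C <= 0) stop("C must be > 0")
  n <- nrow(m)
  lam <- 1 / (n * C)
  yf <- factor(y, levels = c(-1, 1))
  # the solver needs >= 2 columns; pad with an all-zero dummy, whose weight
  # is exactly 0 under L1, and drop it again below
  padded <- ncol(m) < 2L
  if (padded)
    m <- methods::as(cbind(m, Matrix::sparseMatrix(
      i = integer(), j = integer(), x = numeric(),
      dims = c(n, 2L - ncol(m)))), "generalMatrix")
  # warm-started path from lambda_max down to the target lambda
  ybar <- mean(y == 1)
  lmax <- max(abs(Matrix::crossprod(m, (y + 1) / 2 - ybar))) / n
  lseq <- if (lam >= lmax) lam else
    exp(seq(log(lmax * 1.0001), log(lam), length.out = 50L))
  fit <- withCallingHandlers(
    glmnet::glmnet(m, yf, family = "binomial", alpha = 1,
                   standardize = FALSE, lambda = lseq, thresh = tol),
    # small positive classes are routine for the preliminary ranking model
    warning = function(w) {
      if (grepl("fewer than 8", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  b <- as.numeric(glmnet::coef.glmnet(fit, s = lam))
  if (padded) b <- b[seq_len(length(.feature_names_of(X)) + 1L)]
  new("SparseLogisticModel",
      weights = stats::setNames(b[-1L], .feature_names_of(X)),
      intercept = b[1L], featureNames = .feature_names_of(X),
      cost = C, tol = tol)
}

.check_registry <- function(model, X) {
  if (!identical(model@featureNames, .feature_names_of(X)))
    stop("feature registry mismatch between model and matrix")
}

#' Decision values of a sparse logistic model
#'
#' `intercept + sum_i w_i x_i` over stored entries; an all-missing row scores
#' exactly the intercept.
#'
#' @param model a [SparseLogisticModel-class].
#' @param X matrix with the same feature registry as at fit time.
#' @return numeric decision values, one per row.
#' @export
decisionValues <- function(model, X) {
  .check_registry(model, X)
  as.numeric(.as_dgc(X) %*% model@weights) + model@intercept
}

#' Probability scores of variants
#'
#' Logistic sigmoid of the decision values, in (0, 1); monotone in the
#' decision value, so rankings (and AUC) computed from probabilities and from
#' decision values coincide.
#'
#' @inheritParams decisionValues
#' @return numeric probabilities in (0, 1), one per row.
#' @export
scoreVariants <- function(model, X) {
  stats::plogis(decisionValues(model, X))
}

#' Rank-based (Mann-Whitney) AUC
#'
#' Probability that a uniformly chosen positive outranks a uniformly chosen
#' negative, with ties contributing 1/2.
#'
#' @param scores numeric scores.
#' @param labels labels in `{+1, -1}`, both classes present.
#' @return AUC in `[0, 1]`.
#' @export
aucRank <- function(scores, labels) {
  pos <- labels > 0
  np <- sum(pos); nn <- sum(!pos)
  if (np == 0L || nn == 0L) stop("AUC needs both classes")
  r <- rank(scores)
  (sum(r[pos]) - np * (np + 1) / 2) / (np * nn)
}

#' Wilcoxon rank-sum p-value (normal approximation)
#'
#' Mann-Whitney test with tie and continuity corrections, as used to compare
#' score distributions between variant groups.
#'
#' @param groupA,groupB numeric score vectors (non-empty).
#' @param alternative `"two.sided"`, `"greater"` (A shifted above B) or
#'   `"less"`.
#' @return p-value in (0, 1].
#' @export
ranksumPvalue <- function(groupA, groupB,
                          alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (!length(groupA) || !length(groupB)) stop("both groups must be non-empty")
  p <- suppressWarnings(stats::wilcox.test(
    groupA, groupB, alternative = alternative,
    exact = FALSE, correct = TRUE)$p.value)
  min(p, 1)
}

.stratified_folds <- function(y, folds, seed) {
  fold <- integer(length(y))
  .with_seed(seed, {
    for (cls in c(1, -1)) {
      idx <- which(y == cls)
      if (length(idx) < folds)
        stop("class ", cls, " has fewer rows than folds")
      idx <- sample(idx)
      fold[idx] <- rep_len(seq_len(folds), length(idx))  # remainder round-robin
    }
  })
  fold
}

#' Stratified k-fold cross-validated AUC
#'
#' Seeded stratified fold assignment (class ratio preserved per fold,
#' remainder distributed round-robin); the model is fit on k-1 folds and AUC
#' measured on the held-out fold.
#'
#' @inheritParams trainL1Logistic
#' @param folds number of folds (>= 2); default 10.
#' @param seed integer seed for the fold assignment.
#' @return list with `foldAuc` (length `folds`), `meanAuc`, and `fold`
#'   (the per-row fold assignment).
#' @export
crossValidate <- function(X, y, folds = 10, C = 1, seed = 1, tol = 1e-9) {
  if (folds < 2L) stop("folds must be >= 2")
  m <- .as_dgc(X)
  fold <- .stratified_folds(y, folds, seed)
  aucs <- vapply(seq_len(folds), function(k) {
    tr <- fold != k
    fit <- trainL1Logistic(m[tr, , drop = FALSE], y[tr], C = C, tol = tol)
    aucRank(as.numeric(m[!tr, , drop = FALSE] %*% fit@weights) + fit@intercept,
            y[!tr])
  }, 1)
  list(foldAuc = aucs, meanAuc = mean(aucs), fold = fold)
}

#' Select C by cross-validation on a grid
#'
#' Runs [crossValidate()] for each grid value and picks, among values whose
#' mean AUC is within `tie` of the best, the smallest C (the sparsest model
#' that performs indistinguishably — a one-standard-error-style parsimony
#' rule).
#'
#' @inheritParams crossValidate
#' @param grid candidate C values; default `c(0.01, 0.1, 1, 10)`.
#' @param tie AUC slack within which a smaller C is preferred; default 0.005.
#' @return list with `C` (the selection) and `table` (data.frame of grid
#'   values and mean AUCs).
#' @export
selectC <- function(X, y, grid = c(0.01, 0.1, 1, 10), folds = 10, seed = 1,
                    tie = 0.005, tol = 1e-9) {
  grid <- sort(grid)
  auc <- vapply(grid, function(C)
    crossValidate(X, y, folds = folds, C = C, seed = seed, tol = tol)$meanAuc, 1)
  ok <- auc >= max(auc) - tie
  list(C = grid[which(ok)[1L]], table = data.frame(C = grid, meanAuc = auc))
}

#' Serialize a model (TSV weights + JSON header)
#'
#' Writes `<path>` as a TSV of nonzero weights (`index`, `name`, `weight`)
#' and `<path>.json` with the intercept, C, tolerance and the full feature
#' name list used as the registry fingerprint.
#'
#' @param model a [SparseLogisticModel-class].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeModel <- function(model, path) {
  nz <- which(model@weights != 0)
  utils::write.table(
    data.frame(index = nz, name = model@featureNames[nz],
               weight = format(model@weights[nz], digits = 17, trim = TRUE)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(intercept = model@intercept, C = model@cost, tol = model@tol,
         featureNames = model@featureNames),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a model written by [writeModel()]
#'
#' @param path TSV path (with its `.json` sidecar).
#' @return a [SparseLogisticModel-class].
#' @export
readModel <- function(path) {
  hdr <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  w <- stats::setNames(numeric(length(hdr$featureNames)), hdr$featureNames)
  tab <- utils::read.delim(path)
  if (nrow(tab)) w[tab$index] <- as.numeric(tab$weight)
  new("SparseLogisticModel", weights = w, intercept = hdr$intercept,
      featureNames = hdr$featureNames, cost = hdr$C, tol = hdr$tol)
}
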