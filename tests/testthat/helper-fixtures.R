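# shared fixtures, all generated in code

fmFromValues <- function(values, dtype, ids = NULL, features = NULL) {
  if (is.null(ids)) ids <- sprintf("CL%02d", seq_len(nrow(values)))
  if (is.null(features)) features <- sprintf("f%02d", seq_len(ncol(values)))
  dimnames(values) <- list(ids, features)
  FeatureMatrix(values, dtype)
}

# a small aligned dataset with every layer, optionally with a mutation
# driver of the given effect (in noise-SD units)
tinyDataset <- function(n = 60, seed = 42, mutEffect = 0) {
  withr::with_seed(seed, {
    ids <- sprintf("CL%02d", seq_len(n))
    mut <- matrix(rbinom(n * 8, 1, 0.4), n, 8,
                  dimnames = list(ids, sprintf("MUT%02d", 1:8)))
    cnv <- matrix(sample(c(-1, 0, 1), n * 6, TRUE, c(0.2, 0.6, 0.2)), n, 6,
                  dimnames = list(ids, sprintf("CNV%02d", 1:6)))
    meth <- matrix(rbinom(n * 6, 1, 0.4), n, 6,
                   dimnames = list(ids, sprintf("METH%02d", 1:6)))
    tisIdx <- sample(1:3, n, TRUE)
    tis <- matrix(0, n, 3, dimnames = list(ids, sprintf("tissue%02d", 1:3)))
    tis[cbind(1:n, tisIdx)] <- 1
    pw <- matrix(rnorm(n * 11), n, 11,
                 dimnames = list(ids, sprintf("pathway%02d", 1:11)))
    expr <- matrix(rnorm(n * 20, 7), n, 20,
                   dimnames = list(ids, sprintf("EXPR%02d", 1:20)))
    auc <- 0.7 + 0.1 * (rnorm(n) - mutEffect * mut[, 1])
    names(auc) <- ids
    alignDataset(list(mutation = FeatureMatrix(mut, "binary"),
                      cnv = FeatureMatrix(cnv, "ternary"),
                      methylation = FeatureMatrix(meth, "binary"),
                      tissue = FeatureMatrix(tis, "onehot"),
                      pathway = FeatureMatrix(pw, "continuous"),
                      expression = FeatureMatrix(expr, "continuous")),
                 auc, drug = "tiny", verbose = FALSE)
  })
}

# brute-force all-pairs ROC-AUC oracle (ties count one half)
pairwiseAuc <- function(scores, truth) {
  pos <- scores[truth == 1]
  neg <- scores[truth == 0]
  if (!length(pos) || !length(neg)) return(NA_real_)
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# independent linear-interpolation quantile oracle
interpQuantile <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p
  lo <- floor(h)
  x[lo + 1] + (h - lo) * (x[min(lo + 2, length(x))] - x[lo + 1])
}
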