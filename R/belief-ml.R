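#' @title Feature-based reliability classifiers
#' @description Deterministic feature encoding of assembled statements
#'   (per-source direct and refinement-extended mention counts, unique
#'   publication counts, one-hot statement type, mean mention token length,
#'   "promoter" keyword frequency) and stratified cross-validated
#'   evaluation of standard classifiers by AUPRC.
#' @name belief_ml
NULL

#' Encode statement features for reliability prediction
#'
#' Column order is fixed: per-source direct counts, then (if enabled)
#' per-source extended counts in separate columns, unique-publication
#' counts (direct, then extended if enabled), one-hot statement type, mean
#' evidence token length (whitespace split), and the fraction of mention
#' texts containing the term "promoter".
#'
#' @param corpus an [assemble_corpus()] result
#' @param extended include refinement-extended count columns
#' @return numeric matrix, one row per unique statement
#' @export
encode_features <- function(corpus, extended = FALSE) {
  keys <- names(corpus$statements)
  types <- sort(unique(vapply(corpus$statements, `[[`, character(1), "type")))
  onehot <- sapply(types, function(tp)
    as.numeric(vapply(corpus$statements, function(s)
      identical(s$type, tp), logical(1))))
  if (is.null(dim(onehot))) onehot <- matrix(onehot, nrow = length(keys))
  colnames(onehot) <- paste0("type_", types)
  txtstats <- t(vapply(corpus$statements, function(s) {
    texts <- vapply(s$evidence, `[[`, character(1), "text")
    texts <- texts[!is.na(texts)]
    if (!length(texts)) return(c(0, 0))
    toks <- vapply(strsplit(texts, "\\s+"), length, integer(1))
    c(mean(toks), mean(grepl("promoter", texts, fixed = TRUE)))
  }, numeric(2)))
  colnames(txtstats) <- c("mean_evidence_length", "promoter_freq")
  direct <- corpus$counts
  colnames(direct) <- paste0("src_", colnames(direct))
  blocks <- list(direct)
  if (extended) {
    ext <- corpus$counts_ext
    colnames(ext) <- paste0("ext_", colnames(ext))
    blocks <- c(blocks, list(ext))
  }
  blocks <- c(blocks, list(n_pmids = matrix(corpus$pmids, ncol = 1,
                                            dimnames = list(keys, "n_pmids"))))
  if (extended)
    blocks <- c(blocks, list(matrix(corpus$pmids_ext, ncol = 1,
                                    dimnames = list(keys, "n_pmids_ext"))))
  blocks <- c(blocks, list(onehot, txtstats))
  m <- do.call(cbind, blocks)
  rownames(m) <- keys
  m
}

#' Area under the precision-recall curve (average precision)
#'
#' Step-wise average precision over the ranking induced by `scores`.
#'
#' @param scores numeric prediction scores (higher = more likely positive)
#' @param labels logical (or 0/1) true labels
#' @return scalar AUPRC
#' @export
auprc <- function(scores, labels) {
  labels <- as.logical(labels)
  o <- order(scores, decreasing = TRUE)
  y <- labels[o]
  tp <- cumsum(y)
  prec <- tp / seq_along(y)
  npos <- sum(y)
  if (npos == 0) return(NA_real_)
  sum(prec[y]) / npos
}

.stratified_folds <- function(labels, folds) {
  idx <- seq_along(labels)
  fold <- integer(length(labels))
  for (cls in unique(labels)) {
    i <- sample(idx[labels == cls])
    fold[i] <- rep(seq_len(folds), length.out = length(i))
  }
  fold
}

.fit_predict <- function(spec, xtr, ytr, xte) {
  switch(spec,
    logistic = {
      # log-transform only non-negative (count-like) columns
      logc <- apply(xtr, 2, min) >= 0
      tf <- function(x) { x[, logc] <- log1p(x[, logc, drop = FALSE]); x }
      df <- as.data.frame(tf(xtr)); df$.y <- as.numeric(ytr)
      fit <- suppressWarnings(stats::glm(.y ~ ., data = df,
                                         family = stats::binomial()))
      as.numeric(suppressWarnings(
        stats::predict(fit, as.data.frame(tf(xte)), type = "response")))
    },
    knn = {
      pr <- class::knn(xtr, xte, factor(ytr, levels = c(FALSE, TRUE)),
                       k = 5, prob = TRUE)
      p <- attr(pr, "prob")
      ifelse(pr == "TRUE", p, 1 - p)
    },
    svc = {
      fit <- e1071::svm(xtr, factor(ytr, levels = c(FALSE, TRUE)),
                        probability = TRUE)
      pr <- stats::predict(fit, xte, probability = TRUE)
      attr(pr, "probabilities")[, "TRUE"]
    },
    rf = {
      # regression forest on 0/1 labels: predictions are averaged leaf
      # class frequencies (calibrated probabilities), not vote shares
      fit <- suppressWarnings(
        randomForest::randomForest(xtr, as.numeric(ytr), ntree = 500))
      pmin(pmax(stats::predict(fit, xte), 0), 1)
    },
    stop("unknown model_spec: ", spec))
}

#' Cross-validated AUPRC of a reliability classifier
#'
#' Stratified k-fold cross-validation; folds whose training or test part
#' contains a single class are skipped with a warning.
#'
#' @param features numeric feature matrix (see [encode_features()])
#' @param labels logical statement-correctness labels
#' @param model_spec one of `"logistic"` (log-transformed counts), `"knn"`,
#'   `"svc"`, `"rf"`
#' @param folds number of folds (default 10)
#' @param seed RNG seed for fold assignment (and any stochastic learner)
#' @return `list(mean_auprc, fold_auprc, prevalence)`
#' @export
train_and_evaluate <- function(features, labels,
                               model_spec = c("rf", "logistic", "knn",
                                              "svc"),
                               folds = 10L, seed = 1L) {
  model_spec <- match.arg(model_spec)
  labels <- as.logical(labels)
  set.seed(seed)
  fold <- .stratified_folds(labels, folds)
  vals <- rep(NA_real_, folds)
  for (f in seq_len(folds)) {
    tr <- fold != f; te <- fold == f
    if (length(unique(labels[tr])) < 2 || length(unique(labels[te])) < 2) {
      warning("fold ", f, " has a single class; skipped")
      next
    }
    scores <- .fit_predict(model_spec, features[tr, , drop = FALSE],
                           labels[tr], features[te, , drop = FALSE])
    vals[f] <- auprc(scores, labels[te])
  }
  list(mean_auprc = mean(vals, na.rm = TRUE), fold_auprc = vals,
       prevalence = mean(labels))
}
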