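#' @title Descriptive corpus statistics
#' @description Mention-count distributions and discrete power-law fitting
#'   (maximum likelihood and log-CCDF regression, with likelihood-ratio
#'   comparisons against exponential and positive lognormal alternatives),
#'   multi-source overlap tables, inter-source count correlations, and
#'   empirical precision stratified by mention count.
#' @name corpus_stats
NULL

.mention_counts <- function(x) {
  if (inherits(x, "assembled_corpus")) rowSums(x$counts) else as.numeric(x)
}

#' Mention-count histogram and complement cumulative distribution
#'
#' @param x an `assembled_corpus` or a numeric vector of per-statement
#'   mention counts
#' @return `list(hist = data.frame(mentions, n_statements), ccdf =
#'   data.frame(mentions, ccdf))` where `ccdf` is `P(X >= k)`
#' @export
mention_distribution <- function(x) {
  counts <- .mention_counts(x)
  tab <- table(counts)
  k <- as.numeric(names(tab))
  hist <- data.frame(mentions = k, n_statements = as.integer(tab))
  ccdf <- data.frame(mentions = k,
                     ccdf = rev(cumsum(rev(hist$n_statements))) /
                       length(counts))
  list(hist = hist, ccdf = ccdf)
}

# log of the generalized zeta function sum_{x >= xmin} x^(-alpha),
# direct sum plus an Euler-Maclaurin tail correction
.lzeta <- function(alpha, xmin) {
  N <- 1e4
  x <- xmin:N
  log(sum(x^(-alpha)) + (N + 0.5)^(1 - alpha) / (alpha - 1))
}

# exact discrete power-law pointwise log-pmf
.ll_powerlaw <- function(x, alpha, xmin)
  -alpha * log(x) - .lzeta(alpha, xmin)

# discrete (geometric-tail) exponential on x >= xmin, MLE in closed form
.fit_exponential <- function(x, xmin) {
  m <- mean(x)
  q <- (m - xmin) / (m - xmin + 1)
  list(q = q, ll = log(1 - q) + (x - xmin) * log(q))
}

# discrete lognormal with non-negative location, normalized over x >= xmin
.fit_lognormal_pos <- function(x, xmin) {
  lognorm <- function(mu, sig) {
    N <- 1e5
    xx <- xmin:N
    log(sum(stats::dlnorm(xx, mu, sig)) +
          (1 - stats::plnorm(N + 0.5, mu, sig)))
  }
  nll <- function(p) {
    mu <- p[1]; sig <- exp(p[2])
    -sum(stats::dlnorm(x, mu, sig, log = TRUE)) +
      length(x) * lognorm(mu, sig)
  }
  opt <- stats::optim(c(max(mean(log(x)), 0.01),
                        log(max(stats::sd(log(x)), 0.1))),
                      nll, method = "L-BFGS-B",
                      lower = c(0, -5), upper = c(20, 5))
  mu <- opt$par[1]; sig <- exp(opt$par[2])
  list(mu = mu, sigma = sig,
       ll = stats::dlnorm(x, mu, sig, log = TRUE) - lognorm(mu, sig))
}

.vuong <- function(ll1, ll2) {
  d <- ll1 - ll2
  n <- length(d)
  s <- stats::sd(d)
  if (s == 0) return(list(ratio = sum(d), p = 1))
  stat <- sum(d) / (s * sqrt(n))
  list(ratio = sum(d), p = 2 * stats::pnorm(-abs(stat)))
}

#' Fit a discrete power law to mention counts
#'
#' Maximum-likelihood fit of the discrete power law
#' `p(x) = x^(-alpha) / zeta(alpha, xmin)` on the tail `x >= xmin` by
#' numerical likelihood maximization (the closed-form continuous
#' approximation `1 + n [sum ln(x_i/(xmin - 1/2))]^(-1)` is also reported
#' as `alpha_approx`; it is visibly biased for small `xmin`). The standard
#' error is `(alpha - 1)/sqrt(n)`. A second exponent estimate comes from
#' linear regression of the log complement cumulative distribution
#' (`P(X > x)` against `x + 1/2` with a continuity correction, weighted by
#' observation counts; exponent = 1 - slope). Normalized likelihood-ratio
#' (Vuong) tests compare the power law against a discrete exponential and
#' a positive (non-negative location) discrete lognormal; a positive ratio
#' favors the power law.
#'
#' @param counts numeric vector of mention counts (or an
#'   `assembled_corpus`)
#' @param xmin smallest count in the modeled tail (default 1)
#' @param xmin_scan if TRUE, scan candidate `xmin` values and keep the one
#'   minimizing the Kolmogorov-Smirnov distance to the fitted tail
#' @return object of class `power_law_fit`
#' @export
fit_power_law <- function(counts, xmin = 1, xmin_scan = FALSE) {
  x_all <- .mention_counts(counts)
  mle <- function(x, xm) {
    S <- sum(log(x)); n <- length(x)
    stats::optimize(function(a) a * S + n * .lzeta(a, xm),
                    c(1.01, 8))$minimum
  }
  if (xmin_scan) {
    cands <- sort(unique(x_all))
    cands <- cands[cands <= stats::quantile(x_all, 0.9)]
    ks <- vapply(cands, function(xm) {
      x <- x_all[x_all >= xm]
      if (length(unique(x)) < 2) return(Inf)
      a <- mle(x, xm)
      v <- sort(unique(x))
      emp <- vapply(v, function(k) mean(x >= k), numeric(1))
      mod <- vapply(v, function(k)
        exp(.lzeta(a, k) - .lzeta(a, xm)), numeric(1))
      max(abs(emp - mod))
    }, numeric(1))
    xmin <- cands[which.min(ks)]
  }
  x <- x_all[x_all >= xmin]
  n <- length(x)
  if (length(unique(x)) < 2)
    stop("power-law exponent undefined: all counts equal")
  alpha <- mle(x, xmin)
  alpha_approx <- 1 + n / sum(log(x / (xmin - 0.5)))
  sigma <- (alpha - 1) / sqrt(n)
  # weighted log-CCDF regression with continuity correction
  v <- sort(unique(x))
  wts <- as.numeric(table(x))
  ccdf_gt <- vapply(v, function(k) mean(x > k), numeric(1))
  ok <- ccdf_gt > 0
  reg <- stats::lm(log(ccdf_gt[ok]) ~ log(v[ok] + 0.5),
                   weights = wts[ok])
  slope <- unname(stats::coef(reg)[2])
  r2 <- summary(reg)$r.squared
  ll_pl <- .ll_powerlaw(x, alpha, xmin)
  fe <- .fit_exponential(x, xmin)
  fl <- .fit_lognormal_pos(x, xmin)
  structure(list(alpha = alpha, sigma = sigma, alpha_approx = alpha_approx,
                 xmin = xmin, n_tail = n,
                 slope = slope, alpha_regression = 1 - slope,
                 r_squared = r2,
                 lr_exponential = .vuong(ll_pl, fe$ll),
                 lr_lognormal = .vuong(ll_pl, fl$ll)),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("Discrete power-law fit (xmin = %g, n_tail = %d)\n",
              x$xmin, x$n_tail))
  cat(sprintf("  MLE exponent alpha = %.3f (SE %.4f)\n", x$alpha, x$sigma))
  cat(sprintf("  log-CCDF regression: exponent %.3f, r^2 = %.4f\n",
              x$alpha_regression, x$r_squared))
  cat(sprintf("  LR vs exponential: %.1f (p = %.2g); vs lognormal: %.1f (p = %.2g)\n",
              x$lr_exponential$ratio, x$lr_exponential$p,
              x$lr_lognormal$ratio, x$lr_lognormal$p))
  invisible(x)
}

#' Multi-source support overlap (upset table)
#'
#' For every exact subset of sources, the number of statements supported by
#' precisely that subset, plus the fraction of statements with support from
#' two or more sources. Subset counts partition the corpus.
#'
#' @param corpus an `assembled_corpus` (direct counts)
#' @return `list(table = data.frame(subset, n), multi_source_fraction)`
#' @export
reader_overlap <- function(corpus) {
  m <- corpus$counts > 0
  subset <- apply(m, 1, function(r)
    paste(colnames(m)[r], collapse = "+"))
  tab <- table(subset)
  list(table = data.frame(subset = names(tab), n = as.integer(tab)),
       multi_source_fraction = mean(rowSums(m) >= 2))
}

#' Pairwise correlation of per-statement source mention counts
#'
#' Pearson correlation between each pair of sources' count vectors; a
#' source with constant counts yields `NA` against every other source.
#'
#' @param corpus an `assembled_corpus`
#' @return symmetric correlation matrix
#' @export
reader_count_correlations <- function(corpus) {
  m <- corpus$counts
  k <- ncol(m)
  out <- matrix(NA_real_, k, k, dimnames = list(colnames(m), colnames(m)))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (stats::sd(m[, i]) == 0 || stats::sd(m[, j]) == 0) next
    out[i, j] <- stats::cor(m[, i], m[, j])
  }
  out
}

#' Empirical precision by mention count
#'
#' Fraction of curated statements that are correct among those with exactly
#' `k` mentions from the given source, optionally restricted to statements
#' supported by no other source.
#'
#' @param data curation dataset: `list(counts = <statement x source
#'   matrix>, correct = <logical>)`
#' @param source source name (a column of `data$counts`)
#' @param scope `"all"` or `"source_only"` (statements supported only by
#'   `source`)
#' @return data.frame with columns `mentions, n_correct, n_total,
#'   precision`
#' @export
empirical_precision <- function(data, source,
                                scope = c("all", "source_only")) {
  scope <- match.arg(scope)
  cnt <- data$counts[, source]
  keep <- cnt > 0
  if (scope == "source_only") {
    others <- setdiff(colnames(data$counts), source)
    keep <- keep & rowSums(data$counts[, others, drop = FALSE]) == 0
  }
  ks <- sort(unique(cnt[keep]))
  rows <- lapply(ks, function(k) {
    sel <- keep & cnt == k
    data.frame(mentions = k, n_correct = sum(data$correct[sel]),
               n_total = sum(sel),
               precision = mean(data$correct[sel]))
  })
  do.call(rbind, rows)
}

#' Assemble a curation dataset from curations and a corpus
#'
#' Resolves multi-curator labels, derives statement-level correctness (at
#' least one correct mention), and pairs it with the corpus's per-source
#' counts for the curated statements.
#'
#' @param cur a [curation_table()]
#' @param corpus an `assembled_corpus` containing the curated statements
#' @param extended use extended counts instead of direct
#' @return `list(counts, correct, keys)` suitable for the fitting and
#'   precision functions
#' @export
curations_to_dataset <- function(cur, corpus, extended = FALSE) {
  res <- resolve_curations(cur)
  keys <- unique(res$statement_key)
  missing <- setdiff(keys, names(corpus$statements))
  if (length(missing))
    stop("curated statements absent from corpus: ", length(missing))
  correct <- vapply(keys, function(k)
    statement_correct(res$label[res$statement_key == k]), logical(1))
  m <- if (extended) corpus$counts_ext else corpus$counts
  list(counts = m[keys, , drop = FALSE], correct = unname(correct),
       keys = keys)
}
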