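#' @title Statement reliability (belief) models
#' @description Parametric models of the probability that a statement is
#'   correctly extracted given its per-source mention counts: a binomial
#'   model (independent per-mention errors), a beta-binomial model
#'   (per-statement error probability drawn from a beta distribution), and a
#'   two-parameter model separating systematic from random source errors.
#' @name belief
NULL

BELIEF_MODELS <- c("indra", "binomial", "beta_binomial")

#' Single-source two-parameter belief
#'
#' For a statement with `n` mentions from one source with systematic error
#' rate `e_syst` (the source extracts this statement wrongly in a way
#' repeated across all mentions) and per-mention random error rate
#' `e_rand`:
#' \deqn{B = 1 - (e_{syst} + e_{rand}^n (1 - e_{syst}))}
#' The value lies in `[0, 1 - e_syst)` and increases strictly in `n` while
#' `e_rand < 1`.
#'
#' @param n mention count (>= 1)
#' @param e_syst,e_rand error parameters in `[0, 1]`
#' @return probability (vectorized over `n`)
#' @export
belief_simple <- function(n, e_syst, e_rand) {
  if (any(n < 1)) stop("n must be >= 1 (use belief_multisource for n = 0)")
  1 - (e_syst + e_rand^n * (1 - e_syst))
}

.joint_error_factor <- function(model, N, p) {
  # probability that the source is jointly wrong on all N mentions;
  # N = 0 contributes a factor of 1 (the source says nothing)
  if (N == 0) return(1)
  switch(model,
    indra = p$e_syst + p$e_rand^N * (1 - p$e_syst),
    binomial = p$e_rand^N,
    beta_binomial = exp(lbeta(p$alpha, N + p$beta) - lbeta(p$alpha, p$beta)))
}

#' Multi-source belief
#'
#' Belief of a statement given its per-source mention counts: one minus the
#' product over sources of the per-source joint-error probability. Sources
#' with zero count contribute nothing; with one source the two-parameter
#' model reduces exactly to [belief_simple()].
#'
#' @param counts named numeric vector of per-source mention counts
#' @param params named list of per-source parameter lists: `list(e_syst,
#'   e_rand)` for `"indra"`, `list(e_rand)` for `"binomial"`, `list(alpha,
#'   beta)` for `"beta_binomial"`. A `"__default__"` entry, if present,
#'   covers sources without their own parameters.
#' @param model one of `"indra"`, `"binomial"`, `"beta_binomial"`
#' @return probability in `[0, 1)`
#' @export
belief_multisource <- function(counts, params,
                               model = c("indra", "binomial",
                                         "beta_binomial")) {
  model <- match.arg(model)
  prod_err <- 1
  for (src in names(counts)) {
    N <- counts[[src]]
    if (N == 0) next
    p <- params[[src]]
    if (is.null(p)) p <- params[["__default__"]]
    if (is.null(p))
      stop("no belief parameters for source '", src, "' and no default")
    prod_err <- prod_err * .joint_error_factor(model, N, p)
  }
  1 - prod_err
}

#' Beliefs over an assembled corpus using extended evidence
#'
#' Computes each statement's belief from its refinement-extended source
#' counts, so that evidence for more specific statements also supports the
#' generic statements they refine.
#'
#' @param corpus an [assemble_corpus()] result
#' @param params per-source parameters (see [belief_multisource()])
#' @param model belief model name
#' @param extended use extended counts (default) or direct counts
#' @return named numeric vector of beliefs, one per unique statement
#' @export
belief_with_refinements <- function(corpus, params, model = "indra",
                                    extended = TRUE) {
  m <- if (extended) corpus$counts_ext else corpus$counts
  out <- vapply(rownames(m), function(k)
    belief_multisource(m[k, ], params, model), numeric(1))
  stats::setNames(out, rownames(m))
}

#' Attach beliefs to an assembled corpus
#'
#' @param corpus an `assembled_corpus`
#' @param beliefs named vector from [belief_with_refinements()]
#' @return the corpus with per-statement `belief` fields set
#' @export
set_beliefs <- function(corpus, beliefs) {
  for (k in names(beliefs)) corpus$statements[[k]]$belief <-
      unname(beliefs[[k]])
  corpus
}

#' Negative log-likelihood of a belief model on curated statements
#'
#' Statement-level Bernoulli likelihood in the model belief `B(T)`:
#' \deqn{-\sum_i y_i \log B_i + (1 - y_i) \log(1 - B_i)}
#' Beliefs of exactly 0 or 1 with a contradicting label are clamped to
#' `[eps, 1 - eps]`.
#'
#' @param params per-source parameters (see [belief_multisource()])
#' @param data curation dataset: `list(counts = <statement x source
#'   matrix>, correct = <logical>)`
#' @param model belief model name
#' @param eps clamp width
#' @return scalar negative log-likelihood
#' @export
neg_log_likelihood <- function(params, data, model = "indra", eps = 1e-12) {
  B <- apply(data$counts, 1, belief_multisource, params = params,
             model = model)
  B <- pmin(pmax(B, eps), 1 - eps)
  y <- as.numeric(data$correct)
  -sum(y * log(B) + (1 - y) * log(1 - B))
}

# ---- parameter vector packing ----------------------------------------------

.par_layout <- function(model, sources) {
  per <- switch(model, indra = c("e_syst", "e_rand"),
                binomial = "e_rand", beta_binomial = c("log10_alpha",
                                                       "log10_beta"))
  nm <- as.vector(t(outer(sources, per, paste, sep = ".")))
  lo <- rep(switch(model, beta_binomial = -2, 0), length(nm))
  hi <- rep(switch(model, beta_binomial = 2, 1), length(nm))
  list(names = nm, lower = lo, upper = hi, per = per)
}

.vec_to_params <- function(theta, model, sources) {
  per <- switch(model, indra = 2L, binomial = 1L, beta_binomial = 2L)
  params <- list()
  for (i in seq_along(sources)) {
    v <- unname(theta[(i - 1L) * per + seq_len(per)])
    params[[sources[i]]] <- switch(model,
      indra = list(e_syst = v[1], e_rand = v[2]),
      binomial = list(e_rand = v[1]),
      beta_binomial = list(alpha = 10^v[1], beta = 10^v[2]))
  }
  params
}

# Grouped likelihood: identical count rows share one belief evaluation.
.grouped_nll_fun <- function(data, model, eps = 1e-9) {
  key <- apply(data$counts, 1, paste, collapse = ",")
  tab <- table(key, factor(data$correct, levels = c(FALSE, TRUE)))
  ukey <- rownames(tab)
  urows <- data$counts[match(ukey, key), , drop = FALSE]
  n0 <- tab[, 1]; n1 <- tab[, 2]
  function(theta, sources) {
    params <- .vec_to_params(theta, model, sources)
    B <- vapply(seq_len(nrow(urows)), function(i)
      belief_multisource(urows[i, ], params, model), numeric(1))
    B <- pmin(pmax(B, eps), 1 - eps)
    -sum(n1 * log(B) + n0 * log(1 - B))
  }
}
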