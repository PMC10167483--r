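#' @title Belief-model fitting
#' @description Fits per-source belief-model parameters to curated
#'   statements by affine-invariant ensemble MCMC (Goodman-Weare stretch
#'   moves) under uniform priors, or by deterministic L-BFGS-B maximum
#'   likelihood. Returns a classed model object with the usual accessor
#'   methods.
#' @name belief_fit
NULL

# Affine-invariant ensemble sampler (stretch move), split into two
# half-ensembles updated alternately. log_post returns -Inf outside support.
.ensemble_mcmc <- function(log_post, init, burn, steps, a = 2) {
  W <- nrow(init); d <- ncol(init)
  x <- init
  lp <- apply(x, 1, log_post)
  halves <- list(seq_len(W %/% 2), (W %/% 2 + 1L):W)
  samples <- array(NA_real_, dim = c(steps, W, d))
  lps <- matrix(NA_real_, steps, W)
  for (it in seq_len(burn + steps)) {
    for (h in 1:2) {
      mov <- halves[[h]]; oth <- halves[[3 - h]]
      z <- ((a - 1) * stats::runif(length(mov)) + 1)^2 / a
      j <- sample(oth, length(mov), replace = TRUE)
      prop <- x[j, , drop = FALSE] +
        z * (x[mov, , drop = FALSE] - x[j, , drop = FALSE])
      lp_prop <- apply(prop, 1, log_post)
      log_acc <- (d - 1) * log(z) + lp_prop - lp[mov]
      acc <- log(stats::runif(length(mov))) < log_acc
      x[mov[acc], ] <- prop[acc, , drop = FALSE]
      lp[mov[acc]] <- lp_prop[acc]
    }
    if (it > burn) {
      samples[it - burn, , ] <- x
      lps[it - burn, ] <- lp
    }
  }
  list(samples = samples, log_post = lps)
}

#' Fit belief-model parameters to curated statements
#'
#' Fits per-source error parameters by ensemble MCMC (default: 100 walkers,
#' 100 burn-in steps, 100 sampling steps) with uniform priors on error
#' rates in `[0, 1]` and log-uniform priors on the beta-binomial `alpha`,
#' `beta` in `[1e-2, 1e2]`; the point estimate is the maximum-posterior
#' sample. `method = "ml"` instead runs deterministic L-BFGS-B maximum
#' likelihood from a small multistart.
#'
#' @param data curation dataset: `list(counts = <statement x source
#'   matrix>, correct = <logical>)`
#' @param model `"indra"`, `"binomial"` or `"beta_binomial"`
#' @param method `"mcmc"` or `"ml"`
#' @param seed RNG seed for the sampler
#' @param walkers,burn,steps ensemble size and chain lengths
#' @return object of class `belief_model`
#' @export
fit_belief <- function(data, model = c("indra", "binomial", "beta_binomial"),
                       method = c("mcmc", "ml"), seed = 1L,
                       walkers = 100L, burn = 100L, steps = 100L) {
  model <- match.arg(model)
  method <- match.arg(method)
  sources <- colnames(data$counts)
  if (is.null(sources)) stop("data$counts must have source column names")
  sources <- sources[colSums(data$counts) > 0]
  if (!length(sources)) stop("no source has any mentions in the data")
  data$counts <- data$counts[, sources, drop = FALSE]
  if (all(data$correct) || !any(data$correct))
    warning("degenerate curation data (all one label); ",
            "estimates will sit at a parameter boundary")
  lay <- .par_layout(model, sources)
  d <- length(lay$names)
  nllf <- .grouped_nll_fun(data, model)
  log_post <- function(theta) {
    if (any(theta < lay$lower) || any(theta > lay$upper)) return(-Inf)
    -nllf(theta, sources)
  }
  if (method == "mcmc") {
    set.seed(seed)
    init <- matrix(stats::runif(walkers * d, rep(lay$lower, each = walkers),
                                rep(lay$upper, each = walkers)),
                   nrow = walkers)
    run <- .ensemble_mcmc(log_post, init, burn, steps)
    flat <- matrix(aperm(run$samples, c(2, 1, 3)), ncol = d)
    colnames(flat) <- lay$names
    lp <- as.vector(t(run$log_post))
    best <- which.max(lp)
    theta <- flat[best, ]
    samples <- flat
  } else {
    starts <- switch(model,
      indra = list(c(0.1, 0.3), c(0.3, 0.6), c(0.05, 0.8)),
      binomial = list(0.3, 0.6, 0.9),
      beta_binomial = list(c(0, 0), c(-1, 1), c(1, -1)))
    best_val <- Inf; theta <- NULL
    for (s0 in starts) {
      st <- rep(unlist(s0), length(sources))
      opt <- stats::optim(st, function(th) nllf(th, sources),
                          method = "L-BFGS-B",
                          lower = lay$lower + 1e-9,
                          upper = lay$upper - 1e-9)
      if (opt$value < best_val) { best_val <- opt$value; theta <- opt$par }
    }
    names(theta) <- lay$names
    samples <- NULL
  }
  nll <- nllf(theta, sources)
  structure(list(model = model, method = method, sources = sources,
                 estimate = stats::setNames(theta, lay$names),
                 params = .vec_to_params(theta, model, sources),
                 samples = samples, nll = nll,
                 n = nrow(data$counts), call = match.call()),
            class = "belief_model")
}

#' @export
print.belief_model <- function(x, ...) {
  cat(sprintf("Belief model: %s (fit by %s, n = %d statements)\n",
              x$model, toupper(x$method), x$n))
  cat("Parameters:\n")
  for (src in x$sources) {
    p <- x$params[[src]]
    cat(sprintf("  %s: %s\n", src,
                paste(sprintf("%s = %.4f", names(p), unlist(p)),
                      collapse = ", ")))
  }
  cat(sprintf("Negative log-likelihood: %.2f\n", x$nll))
  invisible(x)
}

#' @export
coef.belief_model <- function(object, ...) object$estimate

#' @export
logLik.belief_model <- function(object, ...) {
  structure(-object$nll, df = length(object$estimate), nobs = object$n,
            class = "logLik")
}

#' @export
summary.belief_model <- function(object, ...) {
  out <- list(model = object$model, method = object$method,
              estimate = object$estimate, nll = object$nll, n = object$n)
  if (!is.null(object$samples)) {
    out$posterior <- t(apply(object$samples, 2, stats::quantile,
                             probs = c(0.025, 0.25, 0.5, 0.75, 0.975)))
  }
  class(out) <- "summary.belief_model"
  out
}

#' @export
print.summary.belief_model <- function(x, ...) {
  cat(sprintf("Belief model: %s (%s), n = %d, NLL = %.2f\n",
              x$model, x$method, x$n, x$nll))
  cat("Point estimate (maximum posterior):\n")
  print(round(x$estimate, 4))
  if (!is.null(x$posterior)) {
    cat("Posterior quantiles:\n")
    print(round(x$posterior, 4))
  }
  invisible(x)
}

#' Predict beliefs for new evidence-count profiles
#'
#' @param object a fitted `belief_model`
#' @param newdata a statement x source count matrix, or a plain numeric
#'   vector of single-source counts (interpreted against the model's first
#'   source)
#' @param ... unused
#' @return numeric vector of beliefs
#' @export
predict.belief_model <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) {
    newdata <- matrix(newdata, ncol = 1,
                      dimnames = list(NULL, object$sources[1]))
  }
  apply(newdata, 1, belief_multisource, params = object$params,
        model = object$model)
}

#' Simulate statement correctness under a fitted belief model
#'
#' @param object a fitted `belief_model`
#' @param nsim number of replicate label sets
#' @param seed RNG seed
#' @param newdata count matrix (see [predict.belief_model()])
#' @param ... unused
#' @return logical matrix, `nrow(newdata)` x `nsim`
#' @export
simulate.belief_model <- function(object, nsim = 1, seed = NULL,
                                  newdata, ...) {
  if (!is.null(seed)) set.seed(seed)
  B <- predict(object, newdata)
  matrix(stats::runif(length(B) * nsim) < rep(B, nsim), ncol = nsim)
}

#' Residuals of a fitted belief model on curated data
#'
#' @param object a fitted `belief_model`
#' @param data the curation dataset the model was (or could be) fit on
#' @param ... unused
#' @return response residuals `y - B`
#' @export
residuals.belief_model <- function(object, data, ...) {
  as.numeric(data$correct) - predict(object, data$counts)
}

#' One-mention reliability heuristic for a source
#'
#' The probability that a single-mention statement is correct,
#' `1 - (e_syst + (1 - e_syst) e_rand)`; identical to `belief_simple(1, .)`
#' and convenient as a per-source reliability summary.
#'
#' @param fit a `belief_model` of model `"indra"`
#' @return named numeric vector, one entry per source
#' @export
single_mention_precision <- function(fit) {
  stopifnot(fit$model == "indra")
  vapply(fit$params, function(p)
    belief_simple(1, p$e_syst, p$e_rand), numeric(1))
}
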