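#' Truncated exponential distribution on [0, 1]
#'
#' Density, distribution function and random generation for the exponential
#' distribution truncated to the unit interval,
#' `f(x; lambda) = lambda exp(-lambda x) / (1 - exp(-lambda))` for
#' `0 <= x <= 1`. It models the axonal component of the normalized
#' delay-SD scores, which pile up near zero.
#'
#' @param x,q Quantiles in `[0, 1]`.
#' @param n Number of draws.
#' @param lambda Rate parameter (> 0).
#' @return `dtruncexp` the density, `ptruncexp` the CDF, `rtruncexp` draws.
#' @export
dtruncexp <- function(x, lambda) {
  stopifnot(lambda > 0)
  out <- lambda * exp(-lambda * x) / (1 - exp(-lambda))
  out[x < 0 | x > 1] <- 0
  out
}

#' @rdname dtruncexp
#' @export
ptruncexp <- function(q, lambda) {
  stopifnot(lambda > 0)
  p <- (1 - exp(-lambda * pmin(pmax(q, 0), 1))) / (1 - exp(-lambda))
  p[q < 0] <- 0
  p[q > 1] <- 1
  p
}

#' @rdname dtruncexp
#' @export
rtruncexp <- function(n, lambda) {
  stopifnot(lambda > 0)
  u <- stats::runif(n)
  -log(1 - u * (1 - exp(-lambda))) / lambda
}

#' Fit a two-component score mixture
#'
#' Maximum-likelihood (EM) fit of the mixture models used to derive ROC
#' curves for the two segmentation methods:
#'
#' * `type = "normal"`: `p_N N(mu_N, sd_N) + p_P N(mu_P, sd_P)` for the
#'   amplitude scores `x = log(v_n / s_n)` of method I; the component with
#'   the smaller mean is labelled N (background).
#' * `type = "beta-truncexp"`: `p_N Beta(alpha_N, beta_N) +
#'   p_P TruncExp(lambda_P)` on `[0, 1]` for the normalized delay-SD
#'   scores `x = s_tau / (T/2)` of method II; the truncated-exponential
#'   component (axonal scores near zero) is labelled P, the beta component
#'   models the background mode near `1/sqrt(12)` of T/2-normalized scores.
#'
#' EM is initialized by a method-of-moments split at a quantile, with
#' seeded jittered restarts; the best log-likelihood is kept. The fit is
#' deterministic given `seed`.
#'
#' @param scores Numeric scores (>= 50); for `"beta-truncexp"` they must
#'   lie in `[0, 1]`.
#' @param type Mixture kind.
#' @param n_restarts Number of EM restarts.
#' @param max_iter,tol EM stopping rule (absolute log-likelihood change).
#' @param seed Integer seed for restart jitter.
#' @return Object of class `score_mixture`: list with `kind`, `weights`
#'   (named `N`, `P`), `params` (named vector: `mu_N, sd_N, mu_P, sd_P` or
#'   `alpha_N, beta_N, lambda_P`), `loglik`, `loglik_trace`, `n`,
#'   `converged`.
#' @export
fit_score_mixture <- function(scores, type = c("normal", "beta-truncexp"),
                              n_restarts = 10, max_iter = 500, tol = 1e-8,
                              seed = 1L) {
  type <- match.arg(type)
  scores <- scores[is.finite(scores)]
  if (length(scores) < 50) stop("need at least 50 scores")
  if (type == "beta-truncexp") {
    if (any(scores < 0 | scores > 1))
      stop("beta-truncexp scores must lie in [0, 1]")
    scores <- pmin(pmax(scores, 1e-9), 1 - 1e-9)
  }
  set.seed(seed)
  qs <- c(0.5, stats::runif(n_restarts - 1, 0.1, 0.9))
  best <- NULL
  for (q in qs) {
    fit <- tryCatch(
      em_mixture(scores, type, q, max_iter, tol),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$loglik > best$loglik))
      best <- fit
  }
  if (is.null(best)) stop("mixture fit failed for all restarts")
  best$n <- length(scores)
  class(best) <- "score_mixture"
  best
}

em_mixture <- function(x, type, q_init, max_iter, tol) {
  n <- length(x)
  lab <- x > stats::quantile(x, q_init)  # TRUE = upper component
  if (sum(lab) < 2 || sum(!lab) < 2) stop("degenerate initial split")
  if (type == "normal") {
    th <- list(w = mean(!lab),
               mu1 = mean(x[!lab]), sd1 = max(stats::sd(x[!lab]), 1e-6),
               mu2 = mean(x[lab]), sd2 = max(stats::sd(x[lab]), 1e-6))
    dens1 <- function(th) stats::dnorm(x, th$mu1, th$sd1)
    dens2 <- function(th) stats::dnorm(x, th$mu2, th$sd2)
    mstep <- function(r1, old) {
      w1 <- sum(r1); w2 <- n - w1
      mu1 <- sum(r1 * x) / w1
      mu2 <- sum((1 - r1) * x) / w2
      list(w = w1 / n,
           mu1 = mu1, sd1 = max(sqrt(sum(r1 * (x - mu1)^2) / w1), 1e-6),
           mu2 = mu2, sd2 = max(sqrt(sum((1 - r1) * (x - mu2)^2) / w2), 1e-6))
    }
  } else {
    # component 1 = truncated exponential (low scores, axon);
    # component 2 = beta (background)
    th <- list(w = mean(!lab),
               lambda = texp_mle(x[!lab], rep(1, sum(!lab))),
               ab = beta_mle(x[lab], rep(1, sum(lab))))
    dens1 <- function(th) dtruncexp(x, th$lambda)
    dens2 <- function(th) stats::dbeta(x, th$ab[1], th$ab[2])
    mstep <- function(r1, old) {
      ab_new <- beta_mle(x, 1 - r1)
      # guarantee a generalized-EM step: keep the old beta parameters if the
      # numeric M-step did not improve the weighted likelihood
      s1 <- sum((1 - r1) * log(x)); s2 <- sum((1 - r1) * log1p(-x))
      sw <- sum(1 - r1)
      wll <- function(ab)
        (ab[1] - 1) * s1 + (ab[2] - 1) * s2 - sw * lbeta(ab[1], ab[2])
      if (wll(ab_new) < wll(old$ab)) ab_new <- old$ab
      list(w = mean(r1),
           lambda = texp_mle(x, r1),
           ab = ab_new)
    }
  }
  ll_old <- -Inf
  trace <- numeric()
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    f1 <- th$w * dens1(th)
    f2 <- (1 - th$w) * dens2(th)
    tot <- pmax(f1 + f2, .Machine$double.xmin)
    ll <- sum(log(tot))
    trace <- c(trace, ll)
    if (is.finite(ll) && abs(ll - ll_old) < tol) { converged <- TRUE; break }
    ll_old <- ll
    th <- mstep(f1 / tot, th)
  }
  if (type == "normal") {
    # label the component with the smaller mean N
    if (th$mu1 <= th$mu2) {
      weights <- c(N = th$w, P = 1 - th$w)
      params <- c(mu_N = th$mu1, sd_N = th$sd1, mu_P = th$mu2, sd_P = th$sd2)
    } else {
      weights <- c(N = 1 - th$w, P = th$w)
      params <- c(mu_N = th$mu2, sd_N = th$sd2, mu_P = th$mu1, sd_P = th$sd1)
    }
  } else {
    weights <- c(N = 1 - th$w, P = th$w)
    params <- c(alpha_N = unname(th$ab[1]), beta_N = unname(th$ab[2]),
                lambda_P = th$lambda)
  }
  list(kind = type, weights = weights, params = params, loglik = ll,
       loglik_trace = trace, converged = converged)
}

# weighted MLE of the truncated-exponential rate on [0, 1]; the weighted
# log-likelihood depends on the data only through sum(w) and sum(w x)
texp_mle <- function(x, w) {
  sw <- sum(w)
  if (sw <= 0) return(1)
  swx <- sum(w * x)
  obj <- function(u) {
    lam <- exp(u)
    -(sw * log(lam) - lam * swx - sw * log1p(-exp(-lam)))
  }
  exp(stats::optimize(obj, c(log(1e-3), log(1e4)))$minimum)
}

# weighted MLE of beta parameters; the weighted log-likelihood reduces to
# (a-1) sum(w log x) + (b-1) sum(w log(1-x)) - sum(w) lbeta(a, b), so the
# optimization is over scalars after one pass over the data
beta_mle <- function(x, w) {
  sw <- sum(w)
  if (sw <= 0) return(c(1, 1))
  s1 <- sum(w * log(x))
  s2 <- sum(w * log1p(-x))
  m <- sum(w * x) / sw
  v <- max(sum(w * (x - m)^2) / sw, 1e-10)
  k <- max(m * (1 - m) / v - 1, 0.1)
  start <- log(pmax(c(m * k, (1 - m) * k), 1e-3))
  obj <- function(p) {
    a <- exp(p[1]); b <- exp(p[2])
    -((a - 1) * s1 + (b - 1) * s2 - sw * lbeta(a, b))
  }
  grad <- function(p) {
    a <- exp(p[1]); b <- exp(p[2])
    dab <- digamma(a + b)
    -c(a * (s1 - sw * (digamma(a) - dab)),
       b * (s2 - sw * (digamma(b) - dab)))
  }
  fit <- tryCatch(stats::optim(start, obj, grad, method = "BFGS"),
                  error = function(e) list(par = start))
  exp(fit$par)
}

#' @export
print.score_mixture <- function(x, ...) {
  cat(sprintf("Score mixture (%s), n = %d, logLik = %.2f%s\n", x$kind, x$n,
              x$loglik, if (x$converged) "" else " [not converged]"))
  cat(sprintf("  weights: N %.3f, P %.3f\n", x$weights["N"], x$weights["P"]))
  cat("  params: ",
      paste(names(x$params), format(x$params, digits = 4), sep = " = ",
            collapse = ", "), "\n")
  invisible(x)
}

#' @export
logLik.score_mixture <- function(object, ...) {
  k <- if (object$kind == "normal") 5 else 3
  structure(object$loglik, df = k, nobs = object$n, class = "logLik")
}

#' Mixture component densities
#'
#' Evaluates the weighted background (`N`) and axonal (`P`) component
#' densities of a fitted [fit_score_mixture()] at `x`.
#'
#' @param fit A `score_mixture`.
#' @param x Evaluation points.
#' @return List with elements `N` and `P`.
#' @export
mixture_components <- function(fit, x) {
  stopifnot(inherits(fit, "score_mixture"))
  p <- fit$params
  if (fit$kind == "normal") {
    list(N = fit$weights["N"] * stats::dnorm(x, p["mu_N"], p["sd_N"]),
         P = fit$weights["P"] * stats::dnorm(x, p["mu_P"], p["sd_P"]))
  } else {
    list(N = fit$weights["N"] * stats::dbeta(x, p["alpha_N"], p["beta_N"]),
         P = fit$weights["P"] * dtruncexp(x, p["lambda_P"]))
  }
}

#' ROC curve from a fitted score mixture
#'
#' Sweeps a threshold over the score axis and computes, from the fitted
#' component distributions, the true-positive rate (axonal mass on the
#' axon side of the threshold) and false-positive rate (background mass on
#' that side). For the normal mixture (method I amplitude scores) the axon
#' side is high scores; for the beta + truncated-exponential mixture
#' (method II delay-SD scores) it is low scores. The area under the curve
#' is obtained by trapezoidal integration.
#'
#' @param fit A [fit_score_mixture()] result.
#' @param n_thresholds Number of thresholds in the sweep.
#' @return Object of class `roc_curve`: list with `thresholds`, `fpr`,
#'   `tpr`, `auc`, `kind`, `axon_side`.
#' @export
roc_from_mixture <- function(fit, n_thresholds = 2000) {
  stopifnot(inherits(fit, "score_mixture"))
  p <- fit$params
  if (fit$kind == "normal") {
    lo <- min(p["mu_N"], p["mu_P"]) - 6 * max(p["sd_N"], p["sd_P"])
    hi <- max(p["mu_N"], p["mu_P"]) + 6 * max(p["sd_N"], p["sd_P"])
    thr <- seq(lo, hi, length.out = n_thresholds)
    tpr <- 1 - stats::pnorm(thr, p["mu_P"], p["sd_P"])
    fpr <- 1 - stats::pnorm(thr, p["mu_N"], p["sd_N"])
    side <- "high"
  } else {
    thr <- c(0, 10^seq(-6, 0, length.out = n_thresholds - 1))
    tpr <- ptruncexp(thr, p["lambda_P"])
    fpr <- stats::pbeta(thr, p["alpha_N"], p["beta_N"])
    side <- "low"
  }
  o <- order(fpr, tpr)
  fpr_s <- c(0, fpr[o], 1)
  tpr_s <- c(0, tpr[o], 1)
  auc <- sum(diff(fpr_s) * (tpr_s[-1] + tpr_s[-length(tpr_s)]) / 2)
  structure(list(thresholds = thr, fpr = as.numeric(fpr),
                 tpr = as.numeric(tpr), auc = as.numeric(auc),
                 kind = fit$kind, axon_side = side),
            class = "roc_curve")
}

#' Operating point of a threshold on a fitted mixture
#'
#' @param fit A `score_mixture`.
#' @param threshold Score threshold (on the same scale as the scores).
#' @return List with `tpr` and `fpr` at that threshold.
#' @export
operating_point <- function(fit, threshold) {
  stopifnot(inherits(fit, "score_mixture"))
  p <- fit$params
  if (fit$kind == "normal") {
    list(tpr = as.numeric(1 - stats::pnorm(threshold, p["mu_P"], p["sd_P"])),
         fpr = as.numeric(1 - stats::pnorm(threshold, p["mu_N"], p["sd_N"])))
  } else {
    list(tpr = as.numeric(ptruncexp(threshold, p["lambda_P"])),
         fpr = as.numeric(stats::pbeta(threshold, p["alpha_N"], p["beta_N"])))
  }
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC curve (%s mixture, axon side = %s scores): AUC = %.4f\n",
              x$kind, x$axon_side, x$auc))
  invisible(x)
}

#' @export
plot.roc_curve <- function(x, ...) {
  graphics::plot(c(0, x$fpr, 1), c(0, x$tpr, 1), type = "l",
                 xlab = "False positive rate", ylab = "True positive rate",
                 ...)
  graphics::abline(0, 1, lty = 3, col = "grey")
  invisible(x)
}
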