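LENGTH_MODELS <- c("lognormal", "power_law", "truncated_power_law",
                   "stretched_exponential", "exponential")

# ---- densities on [xmin, Inf), truncated-and-renormalized -----------------
# All five candidate models are conditioned on x >= xmin so that their
# likelihoods (and hence AICs) are comparable on identical support.

dlnormTrunc <- function(x, mu, sigma, xmin, log = FALSE) {
  ld <- stats::dlnorm(x, mu, sigma, log = TRUE) -
    stats::plnorm(xmin, mu, sigma, lower.tail = FALSE, log.p = TRUE)
  ld[x < xmin] <- -Inf
  if (log) ld else exp(ld)
}

dExpShift <- function(x, lambda, xmin, log = FALSE) {
  ld <- log(lambda) - lambda * (x - xmin)
  ld[x < xmin] <- -Inf
  if (log) ld else exp(ld)
}

dPowerLaw <- function(x, gamma, xmin, log = FALSE) {
  ld <- log(gamma - 1) - log(xmin) - gamma * (log(x) - log(xmin))
  ld[x < xmin] <- -Inf
  if (log) ld else exp(ld)
}

# Normalizing constant of x^-gamma * exp(-lambda x) on [xmin, Inf).
# Computed by quadrature; valid for lambda > 0 and any real gamma.
tplNorm <- function(gamma, lambda, xmin) {
  # integrate in u = x / xmin for conditioning
  f <- function(u) (u * xmin)^(-gamma) * exp(-lambda * xmin * u) * xmin
  val <- tryCatch(
    stats::integrate(f, 1, Inf, rel.tol = 1e-10)$value,
    error = function(e) NA_real_)
  val
}

dTruncPowerLaw <- function(x, gamma, lambda, xmin, log = FALSE) {
  Z <- tplNorm(gamma, lambda, xmin)
  ld <- -gamma * log(x) - lambda * x - log(Z)
  ld[x < xmin] <- -Inf
  if (log) ld else exp(ld)
}

# survival exp(-lambda x^beta), conditioned on x >= xmin
dStretchedExp <- function(x, lambda, beta, xmin, log = FALSE) {
  ld <- log(lambda) + log(beta) + (beta - 1) * log(x) -
    lambda * (x^beta - xmin^beta)
  ld[x < xmin] <- -Inf
  if (log) ld else exp(ld)
}

# ---- samplers -------------------------------------------------------------

#' Samplers for the candidate length distributions
#'
#' Inverse-CDF (or rejection) samplers for the five run/flight length
#' models, each restricted to `[xmin, Inf)`. Parameterizations: lognormal
#' with log-mean `mu` and log-sd `sigma`; power law with density
#' proportional to `x^-gamma`; truncated power law `x^-gamma *
#' exp(-lambda x)`; stretched exponential with survival
#' `exp(-lambda x^beta)`; exponential with rate `lambda` shifted to `xmin`.
#'
#' @param n number of draws.
#' @param mu,sigma,gamma,lambda,beta model parameters (see above).
#' @param xmin support lower bound; 0 where the unrestricted model is
#'   proper.
#' @return Numeric vector of `n` draws.
#' @name length-samplers
NULL

#' @rdname length-samplers
#' @export
rLognormal <- function(n, mu, sigma, xmin = 0) {
  p0 <- stats::plnorm(xmin, mu, sigma)
  stats::qlnorm(p0 + stats::runif(n) * (1 - p0), mu, sigma)
}

#' @rdname length-samplers
#' @export
rPowerLaw <- function(n, gamma, xmin) {
  if (gamma <= 1) stop("pure power law needs gamma > 1")
  xmin * stats::runif(n)^(-1 / (gamma - 1))
}

#' @rdname length-samplers
#' @export
rTruncPowerLaw <- function(n, gamma, lambda, xmin, max_tries = 10000L) {
  # rejection from the pure power law (gamma > 1) with acceptance
  # exp(-lambda (x - xmin)); falls back to exponential proposal for
  # gamma <= 1
  out <- numeric(0)
  tries <- 0L
  while (length(out) < n && tries < max_tries) {
    m <- max(n - length(out), 100L)
    if (gamma > 1) {
      x <- rPowerLaw(m, gamma, xmin)
      acc <- stats::runif(m) < exp(-lambda * (x - xmin))
    } else {
      x <- xmin + stats::rexp(m, lambda)
      acc <- stats::runif(m) < (x / xmin)^(-gamma)
    }
    out <- c(out, x[acc])
    tries <- tries + 1L
  }
  if (length(out) < n) stop("rTruncPowerLaw: rejection sampling stalled")
  out[seq_len(n)]
}

#' @rdname length-samplers
#' @export
rStretchedExp <- function(n, lambda, beta, xmin = 0) {
  (xmin^beta - log(stats::runif(n)) / lambda)^(1 / beta)
}

#' @rdname length-samplers
#' @export
rExponential <- function(n, lambda, xmin = 0) {
  xmin + stats::rexp(n, lambda)
}

# ---- empirical CCDF -------------------------------------------------------

#' Empirical complementary cumulative distribution function
#'
#' Survival probabilities `P(X >= x)` at the sorted unique sample values:
#' starts at 1 (or below for tied minima with other mass) and ends at
#' (number tied at the maximum)/n.
#'
#' @param x positive length sample.
#' @return Data.frame with `value` (sorted unique values) and `surv`.
#' @export
lengthCCDF <- function(x) {
  if (!length(x)) stop("empty sample")
  n <- length(x)
  v <- sort(unique(x))
  surv <- vapply(v, function(vi) sum(x >= vi) / n, numeric(1))
  data.frame(value = v, surv = surv)
}

# ---- MLE fits -------------------------------------------------------------

newModelFit <- function(model, params, xmin, loglik, n,
                        convergence = 0L, method = "analytic") {
  k <- length(params)
  structure(list(model = model, params = params, xmin = xmin,
                 loglik = loglik, k = k, AIC = 2 * k - 2 * loglik,
                 n = n, convergence = convergence, method = method),
            class = "ModelFit")
}

#' @export
print.ModelFit <- function(x, ...) {
  cat(sprintf("ModelFit [%s] n = %d, xmin = %.4g: %s; loglik = %.2f, AIC = %.2f\n",
              x$model, x$n, x$xmin,
              paste(sprintf("%s = %.4g", names(x$params), x$params),
                    collapse = ", "),
              x$loglik, x$AIC))
  invisible(x)
}

#' Analytic MLE of the shifted exponential model
#'
#' Density `lambda * exp(-lambda (x - xmin))` on `[xmin, Inf)`;
#' `lambda_hat = 1 / mean(x - xmin)`.
#'
#' @param x positive sample with all values `>= xmin`.
#' @param xmin support lower bound; default `min(x)`.
#' @return A `ModelFit`.
#' @export
fitExponential <- function(x, xmin = min(x)) {
  checkSample(x, xmin)
  m <- mean(x - xmin)
  if (m == 0) stop("degenerate sample: all values equal xmin")
  lambda <- 1 / m
  ll <- sum(dExpShift(x, lambda, xmin, log = TRUE))
  newModelFit("exponential", c(lambda = lambda), xmin, ll, length(x))
}

#' Analytic MLE of the pure power-law model
#'
#' Density `(gamma - 1)/xmin * (x/xmin)^-gamma` on `[xmin, Inf)`;
#' `gamma_hat = 1 + n / sum(log(x / xmin))`.
#'
#' @inheritParams fitExponential
#' @return A `ModelFit`.
#' @export
fitPowerLaw <- function(x, xmin = min(x)) {
  checkSample(x, xmin)
  if (xmin <= 0) stop("power law requires xmin > 0")
  s <- sum(log(x / xmin))
  if (s == 0) stop("degenerate sample: all values equal xmin")
  gamma <- 1 + length(x) / s
  ll <- sum(dPowerLaw(x, gamma, xmin, log = TRUE))
  newModelFit("power_law", c(gamma = gamma), xmin, ll, length(x))
}

checkSample <- function(x, xmin) {
  if (!length(x)) stop("empty sample")
  if (any(x <= 0)) stop("lengths must be positive")
  if (any(x < xmin)) stop("all values must be >= xmin")
  invisible(TRUE)
}

# negative log-likelihood factories on transformed (unconstrained) scales
nllFactory <- function(x, model, xmin) {
  switch(model,
    lognormal = function(p)
      -sum(dlnormTrunc(x, p[1L], exp(p[2L]), xmin, log = TRUE)),
    stretched_exponential = function(p)
      -sum(dStretchedExp(x, exp(p[1L]), exp(p[2L]), xmin, log = TRUE)),
    truncated_power_law = function(p) {
      v <- -sum(dTruncPowerLaw(x, p[1L], exp(p[2L]), xmin, log = TRUE))
      if (!is.finite(v)) 1e10 else v
    },
    stop("unknown numeric model: ", model))
}

numericStarts <- function(x, model, xmin) {
  lx <- log(x)
  switch(model,
    lognormal = list(c(mean(lx), log(stats::sd(lx))),
                     c(mean(lx) - 0.3, log(stats::sd(lx) * 1.5)),
                     c(stats::median(lx), log(max(stats::sd(lx) * 0.5, 1e-3)))),
    stretched_exponential = list(c(log(1 / mean(x)), 0),
                                 c(log(1 / mean(x)), log(0.7)),
                                 c(log(1 / stats::median(x)), log(1.3))),
    truncated_power_law = list(c(1.5, log(1 / mean(x))),
                               c(1.01, log(1 / mean(x))),
                               c(2.5, log(0.1 / mean(x)))))
}

backTransform <- function(p, model) {
  switch(model,
    lognormal = c(mu = p[1L], sigma = exp(p[2L])),
    stretched_exponential = c(lambda = exp(p[1L]), beta = exp(p[2L])),
    truncated_power_law = c(gamma = p[1L], lambda = exp(p[2L])))
}

#' Numerical MLE of the lognormal, stretched-exponential or truncated
#' power-law model
#'
#' Maximizes the model log-likelihood on `[xmin, Inf)` (densities
#' renormalized by the model survival at `xmin`) by Nelder-Mead with
#' moment-based multi-starts; the best converged optimum is returned.
#'
#' @param x positive sample with all values `>= xmin`.
#' @param model `"lognormal"`, `"stretched_exponential"` or
#'   `"truncated_power_law"`.
#' @param xmin support lower bound; default `min(x)`.
#' @param min_n smallest sample size accepted; default 10.
#' @return A `ModelFit` with convergence diagnostics.
#' @export
fitNumeric <- function(x, model = c("lognormal", "stretched_exponential",
                                    "truncated_power_law"),
                       xmin = min(x), min_n = 10L) {
  model <- match.arg(model)
  checkSample(x, xmin)
  if (length(x) < min_n)
    stop("need at least ", min_n, " values for a numerical fit")
  nll <- nllFactory(x, model, xmin)
  best <- NULL
  for (p0 in numericStarts(x, model, xmin)) {
    opt <- tryCatch(
      stats::optim(p0, nll, method = "Nelder-Mead",
                   control = list(maxit = 5000, reltol = 1e-10)),
      error = function(e) NULL)
    if (is.null(opt)) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best) || !is.finite(best$value))
    stop("numerical MLE failed to converge for model ", model)
  if (best$convergence != 0L)
    warning("optimizer reported non-convergence (code ", best$convergence,
            ") for model ", model)
  newModelFit(model, backTransform(best$par, model), xmin, -best$value,
              length(x), convergence = best$convergence, method = "numeric")
}

#' Fit one candidate length model
#'
#' Dispatches to the analytic MLE (exponential, power law) or the numeric
#' MLE (lognormal, stretched exponential, truncated power law). For the
#' analytic models `method = "numeric"` forces a numerical optimum, which
#' the analytic estimate should reproduce to optimizer tolerance.
#'
#' @param x positive sample.
#' @param model one of `"lognormal"`, `"power_law"`,
#'   `"truncated_power_law"`, `"stretched_exponential"`, `"exponential"`.
#' @param xmin support lower bound; default `min(x)`.
#' @param method `"auto"` (default), `"analytic"` or `"numeric"`.
#' @return A `ModelFit`.
#' @export
fitLengthModel <- function(x, model = LENGTH_MODELS, xmin = min(x),
                           method = c("auto", "analytic", "numeric")) {
  model <- match.arg(model)
  method <- match.arg(method)
  analytic <- model %in% c("exponential", "power_law")
  if (analytic && method != "numeric") {
    return(switch(model, exponential = fitExponential(x, xmin),
                  power_law = fitPowerLaw(x, xmin)))
  }
  if (!analytic && method == "analytic")
    stop("no analytic MLE for model ", model)
  if (analytic) {
    # numerical optimum for cross-checking the closed forms
    nll <- switch(model,
      exponential = function(p) -sum(dExpShift(x, exp(p), xmin, log = TRUE)),
      power_law = function(p)
        -sum(dPowerLaw(x, 1 + exp(p), xmin, log = TRUE)))
    p0 <- switch(model, exponential = log(1 / mean(x - xmin + 1e-12)),
                 power_law = log(length(x) / sum(log(x / xmin))))
    opt <- stats::optim(p0, nll, method = "Brent", lower = p0 - 10,
                        upper = p0 + 10)
    par <- switch(model, exponential = c(lambda = exp(opt$par)),
                  power_law = c(gamma = 1 + exp(opt$par)))
    return(newModelFit(model, par, xmin, -opt$value, length(x),
                       convergence = opt$convergence, method = "numeric"))
  }
  fitNumeric(x, model, xmin)
}

# ---- model comparison -----------------------------------------------------

#' Akaike weights over a set of fits
#'
#' `Delta_i = AIC_i - min(AIC)`; `w_i = exp(-Delta_i/2) / sum_j
#' exp(-Delta_j/2)`. All fits must be of the same sample (same n) at the
#' same `xmin`.
#'
#' @param fits list of `ModelFit`s.
#' @return A `ModelComparison`: list with `fits`, named `weights` summing
#'   to 1, and `winner` (model name with the largest weight).
#' @export
akaikeWeights <- function(fits) {
  if (length(fits) < 2L) stop("need at least two fits to compare")
  ns <- vapply(fits, function(f) f$n, numeric(1))
  xs <- vapply(fits, function(f) f$xmin, numeric(1))
  if (length(unique(ns)) != 1L || max(xs) - min(xs) > 1e-12)
    stop("fits must share the sample and xmin")
  aic <- vapply(fits, function(f) f$AIC, numeric(1))
  delta <- aic - min(aic)
  w <- exp(-delta / 2)
  w <- w / sum(w)
  names(w) <- vapply(fits, function(f) f$model, character(1))
  structure(list(fits = fits, weights = w,
                 winner = names(w)[which.max(w)]),
            class = "ModelComparison")
}

#' @export
print.ModelComparison <- function(x, ...) {
  cat("Model comparison (Akaike weights):\n")
  for (m in names(sort(x$weights, decreasing = TRUE)))
    cat(sprintf("  %-22s %.4f%s\n", m, x$weights[[m]],
                if (m == x$winner) "  <- winner" else ""))
  invisible(x)
}

#' Fit and compare all five candidate length models
#'
#' @param x positive sample.
#' @param xmin support lower bound shared by all models; default `min(x)`.
#' @param models subset of the five candidates to include.
#' @return A `ModelComparison`.
#' @export
compareLengthModels <- function(x, xmin = min(x), models = LENGTH_MODELS) {
  fits <- lapply(models, function(m) fitLengthModel(x, m, xmin))
  akaikeWeights(fits)
}

# ---- two-sample tests -----------------------------------------------------

# CDF of the limiting distribution of the Cramer-von Mises statistic
# (Anderson-Darling 1952 series, Bessel-K form). Terms only start to decay
# once (4k+1)^2 > 16x, so the truncation point must grow like sqrt(x).
pcvmAsymptotic <- function(x) {
  if (x <= 0) return(0)
  k_max <- max(20L, ceiling(2 * sqrt(x)) + 10L)
  k <- 0:k_max
  z <- (4 * k + 1)^2 / (16 * x)
  term <- exp(lgamma(k + 0.5) - lgamma(0.5) - lfactorial(k)) *
    sqrt(4 * k + 1) * exp(-z) * besselK(z, 0.25)
  min(1, max(0, sum(term) / (pi * sqrt(x))))
}

cvmStatistic <- function(a, b) {
  n <- length(a); m <- length(b); N <- n + m
  r <- rank(c(a, b), ties.method = "average")
  ra <- sort(r[seq_len(n)]); rb <- sort(r[n + seq_len(m)])
  u <- n * sum((ra - seq_len(n))^2) + m * sum((rb - seq_len(m))^2)
  u / (n * m * N) - (4 * m * n - 1) / (6 * N)
}

#' Two-sample Cramer-von Mises test
#'
#' Rank-based two-sample Cramer-von Mises statistic with an asymptotic
#' p-value (statistic standardized to the limiting distribution of the
#' one-sample statistic) or a permutation p-value for small samples. The
#' test is symmetric in its arguments and invariant under a common monotone
#' rescaling.
#'
#' @param a,b numeric samples (each of size at least 2).
#' @param p_method `"asymptotic"` (default) or `"permutation"`.
#' @param n_perm number of permutations when `p_method = "permutation"`.
#' @return A `TestResult`: list with `test`, `statistic`, `p_value`.
#' @export
cvmTest2 <- function(a, b, p_method = c("asymptotic", "permutation"),
                     n_perm = 2000L) {
  p_method <- match.arg(p_method)
  if (length(a) < 2L || length(b) < 2L) stop("both samples need n >= 2")
  Tobs <- cvmStatistic(a, b)
  n <- length(a); m <- length(b); N <- n + m
  if (p_method == "asymptotic") {
    # standardize to the limiting distribution (mean 1/6, matching variance)
    et <- (1 + 1 / N) / 6
    vt <- (N + 1) * (4 * m * n * N - 3 * (m^2 + n^2) - 2 * m * n) /
      (45 * N^2 * 4 * m * n)
    tn <- 1 / 6 + (Tobs - et) / sqrt(45 * vt)
    p <- 1 - pcvmAsymptotic(tn)
  } else {
    pool <- c(a, b)
    cnt <- 0L
    for (i in seq_len(n_perm)) {
      idx <- sample.int(N, n)
      if (cvmStatistic(pool[idx], pool[-idx]) >= Tobs) cnt <- cnt + 1L
    }
    p <- (cnt + 1) / (n_perm + 1)
  }
  structure(list(test = "cramer_von_mises_2s", statistic = Tobs,
                 p_value = min(1, max(0, p))),
            class = "TestResult")
}

#' @export
print.TestResult <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g\n", x$test, x$statistic,
              x$p_value))
  invisible(x)
}

#' Group comparison of per-cell summaries
#'
#' Unpaired comparisons use the Wilcoxon-Mann-Whitney test; paired
#' comparisons (e.g. cargo-bearing vs remaining organelles of the same
#' cells) use the two-tailed paired Student's t-test matched by cell id.
#'
#' @param a,b numeric per-cell summary vectors.
#' @param paired use the paired t-test instead of Mann-Whitney.
#' @param ids_a,ids_b cell ids for pairing; must match one-to-one when
#'   `paired = TRUE`.
#' @return A `TestResult`.
#' @export
groupTest <- function(a, b, paired = FALSE, ids_a = NULL, ids_b = NULL) {
  if (paired) {
    if (length(a) != length(b))
      stop("paired test requires equal-length, matched vectors")
    if (!is.null(ids_a) || !is.null(ids_b)) {
      if (is.null(ids_a) || is.null(ids_b) || !identical(ids_a, ids_b))
        stop("paired test requires matched cell ids")
    }
    d <- a - b
    if (all(d == 0)) {
      res <- list(statistic = 0, p.value = 1)
    } else {
      ht <- stats::t.test(a, b, paired = TRUE)
      res <- list(statistic = unname(ht$statistic), p.value = ht$p.value)
    }
    return(structure(list(test = "paired_t_two_tailed",
                          statistic = res$statistic,
                          p_value = res$p.value),
                     class = "TestResult"))
  }
  ht <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                            correct = FALSE))
  p <- ht$p.value
  if (is.na(p)) p <- 1  # degenerate full-tie case: no evidence either way
  structure(list(test = "wilcoxon_mann_whitney",
                 statistic = unname(ht$statistic), p_value = p),
            class = "TestResult")
}
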