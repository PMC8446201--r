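#' Variance components of the correlated service-sire/dam model
#'
#' Container for the seven (co)variance parameters of one trait's model:
#' additive variances of service sire (`sigma2_ss`) and dam (`sigma2_d`),
#' their covariance (`sigma_ssd`), permanent-environment variances of
#' service sire (`sigma2_pess`) and dam (`sigma2_ped`), herd-year-month
#' variance (`sigma2_hym`) and residual variance (`sigma2_e`), optionally
#' with the sampling covariance matrix of the estimates, the restricted
#' log-likelihood and a convergence flag.
#'
#' @param sigma2_ss,sigma_ssd,sigma2_d,sigma2_pess,sigma2_ped,sigma2_hym,sigma2_e
#'   The seven parameters (trait units squared).
#' @param vcov Optional 7x7 sampling covariance matrix of the estimates
#'   (typically the inverse average-information matrix).
#' @param logLik Optional restricted log-likelihood at the estimates.
#' @param converged Logical convergence flag.
#' @return An object of class `gess_varcomp`.
#' @export
varcomp <- function(sigma2_ss, sigma_ssd, sigma2_d, sigma2_pess, sigma2_ped,
                    sigma2_hym, sigma2_e, vcov = NULL, logLik = NA_real_,
                    converged = NA) {
  comp <- c(sigma2_ss = sigma2_ss, sigma_ssd = sigma_ssd, sigma2_d = sigma2_d,
            sigma2_pess = sigma2_pess, sigma2_ped = sigma2_ped,
            sigma2_hym = sigma2_hym, sigma2_e = sigma2_e)
  vars <- comp[-2L]
  if (any(vars < 0)) stop("variances must be non-negative")
  if (sigma_ssd^2 > sigma2_ss * sigma2_d * (1 + 1e-10) + 1e-300)
    stop("genetic (co)variance matrix of service sire and dam is not PSD")
  if (!is.null(vcov)) {
    vcov <- as.matrix(vcov)
    stopifnot(nrow(vcov) == 7L, ncol(vcov) == 7L)
    dimnames(vcov) <- list(names(comp), names(comp))
  }
  structure(list(components = comp, vcov = vcov, logLik = logLik,
                 converged = converged),
            class = "gess_varcomp")
}

#' @export
print.gess_varcomp <- function(x, ...) {
  cat("Variance components (service-sire/dam model)\n")
  print(signif(x$components, 5))
  if (!is.na(x$logLik)) cat("restricted logLik:", format(x$logLik), "\n")
  if (!is.na(x$converged)) cat("converged:", x$converged, "\n")
  invisible(x)
}

phenotypic_variance <- function(comp, include_cov = FALSE) {
  d <- comp[["sigma2_ss"]] + comp[["sigma2_d"]] + comp[["sigma2_pess"]] +
    comp[["sigma2_ped"]] + comp[["sigma2_hym"]] + comp[["sigma2_e"]]
  if (include_cov) d <- d + 2 * comp[["sigma_ssd"]]
  d
}

#' Heritability of the service-sire and dam genetic effects
#'
#' `h2_ss = sigma2_ss / V_P` and `h2_d = sigma2_d / V_P`, where `V_P` is the
#' sum of all variance components. With `include_cov = TRUE` the denominator
#' additionally carries `2 * sigma_ssd`; the default omits it, which is the
#' convention the bundled reference estimates follow.
#'
#' @param vc A `gess_varcomp` (or named 7-vector).
#' @param include_cov Include `2 * sigma_ssd` in the denominator?
#' @return Named numeric vector `c(h2_ss, h2_d)`.
#' @export
heritability <- function(vc, include_cov = FALSE) {
  comp <- if (inherits(vc, "gess_varcomp")) vc$components else vc
  den <- phenotypic_variance(comp, include_cov)
  if (den <= 0) stop("phenotypic variance is zero")
  c(h2_ss = comp[["sigma2_ss"]] / den, h2_d = comp[["sigma2_d"]] / den)
}

#' Repeatability of the service-sire and dam effects
#'
#' `re_ss = (sigma2_ss + sigma2_pess) / V_P`; the dam analogue replaces the
#' numerator by `sigma2_d + sigma2_ped`. Denominator as in
#' [heritability()].
#'
#' @inheritParams heritability
#' @return Named numeric vector `c(re_ss, re_d)`.
#' @export
repeatability <- function(vc, include_cov = FALSE) {
  comp <- if (inherits(vc, "gess_varcomp")) vc$components else vc
  den <- phenotypic_variance(comp, include_cov)
  if (den <= 0) stop("phenotypic variance is zero")
  c(re_ss = (comp[["sigma2_ss"]] + comp[["sigma2_pess"]]) / den,
    re_d = (comp[["sigma2_d"]] + comp[["sigma2_ped"]]) / den)
}

#' Genetic correlation between the service-sire and dam effects
#'
#' `r = sigma_ssd / sqrt(sigma2_ss * sigma2_d)`, clamped to `[-1, 1]`.
#'
#' @inheritParams heritability
#' @return Scalar correlation.
#' @export
genetic_correlation <- function(vc) {
  comp <- if (inherits(vc, "gess_varcomp")) vc$components else vc
  if (comp[["sigma2_ss"]] <= 0 || comp[["sigma2_d"]] <= 0)
    stop("genetic correlation undefined with a zero additive variance")
  r <- comp[["sigma_ssd"]] / sqrt(comp[["sigma2_ss"]] * comp[["sigma2_d"]])
  unname(min(1, max(-1, r)))
}

## analytic gradients of the derived parameters w.r.t. the 7 components
derived_gradient <- function(comp, target = c("h2_ss", "h2_d", "re_ss",
                                              "re_d", "r"),
                             include_cov = FALSE) {
  target <- match.arg(target)
  g <- stats::setNames(numeric(7), names(comp))
  if (target == "r") {
    r <- comp[["sigma_ssd"]] / sqrt(comp[["sigma2_ss"]] * comp[["sigma2_d"]])
    g["sigma_ssd"] <- 1 / sqrt(comp[["sigma2_ss"]] * comp[["sigma2_d"]])
    g["sigma2_ss"] <- -r / (2 * comp[["sigma2_ss"]])
    g["sigma2_d"] <- -r / (2 * comp[["sigma2_d"]])
    return(g)
  }
  den <- phenotypic_variance(comp, include_cov)
  num <- switch(target,
    h2_ss = comp[["sigma2_ss"]],
    h2_d = comp[["sigma2_d"]],
    re_ss = comp[["sigma2_ss"]] + comp[["sigma2_pess"]],
    re_d = comp[["sigma2_d"]] + comp[["sigma2_ped"]])
  in_num <- switch(target,
    h2_ss = "sigma2_ss",
    h2_d = "sigma2_d",
    re_ss = c("sigma2_ss", "sigma2_pess"),
    re_d = c("sigma2_d", "sigma2_ped"))
  g[] <- -num / den^2                       # denominator-only terms
  g[in_num] <- (den - num) / den^2          # in both
  g["sigma_ssd"] <- if (include_cov) -2 * num / den^2 else 0
  g
}

#' Delta-method standard error of a derived genetic parameter
#'
#' Propagates the sampling covariance of the seven variance-component
#' estimates through the (analytic) gradient of a derived parameter:
#' `SE = sqrt(g' C g)`.
#'
#' @param vc A `gess_varcomp` carrying a sampling covariance matrix, or a
#'   named 7-vector together with `vcov`.
#' @param target One of `"h2_ss"`, `"h2_d"`, `"re_ss"`, `"re_d"`, `"r"`.
#' @param include_cov Denominator convention, as in [heritability()].
#' @param vcov Sampling covariance matrix if `vc` is a plain vector.
#' @return Scalar standard error.
#' @export
delta_method_se <- function(vc, target, include_cov = FALSE, vcov = NULL) {
  comp <- if (inherits(vc, "gess_varcomp")) vc$components else vc
  C <- if (inherits(vc, "gess_varcomp")) vc$vcov else vcov
  if (is.null(C)) stop("no sampling covariance matrix available")
  C <- as.matrix(C)
  ev <- eigen(0.5 * (C + t(C)), symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1))
    stop("sampling covariance matrix is not positive semi-definite")
  g <- derived_gradient(comp, target, include_cov)
  sqrt(max(0, drop(t(g) %*% C %*% g)))
}

#' Wald test of an estimate against zero
#'
#' Two-sided normal test: `p = 2 * (1 - Phi(|estimate| / SE))`.
#'
#' @param estimate Point estimate.
#' @param se Standard error (> 0).
#' @return Two-sided p-value.
#' @export
wald_test <- function(estimate, se) {
  if (any(se <= 0)) stop("SE must be positive")
  2 * stats::pnorm(-abs(estimate / se))
}

#' All derived genetic parameters of one fitted trait
#'
#' Computes heritabilities, repeatabilities and the sire-dam genetic
#' correlation with delta-method standard errors and Wald p-values.
#'
#' @inheritParams delta_method_se
#' @return Data frame with columns `parameter`, `estimate`, `se`, `p_wald`
#'   (`se`/`p_wald` `NA` when no sampling covariance is available).
#' @export
derived_parameters <- function(vc, include_cov = FALSE) {
  comp <- if (inherits(vc, "gess_varcomp")) vc$components else vc
  est <- c(heritability(vc, include_cov), repeatability(vc, include_cov),
           r = genetic_correlation(vc))
  targets <- c("h2_ss", "h2_d", "re_ss", "re_d", "r")
  has_C <- inherits(vc, "gess_varcomp") && !is.null(vc$vcov)
  se <- rep(NA_real_, 5)
  if (has_C)
    se <- vapply(targets, function(t) delta_method_se(vc, t, include_cov),
                 numeric(1))
  p <- ifelse(is.na(se) | se <= 0, NA_real_, wald_test(est, pmax(se, 1e-300)))
  data.frame(parameter = targets, estimate = unname(est), se = unname(se),
             p_wald = unname(p), stringsAsFactors = FALSE)
}
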