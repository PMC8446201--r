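#' Restricted log-likelihood of the sire/dam model
#'
#' Evaluates the REML log-likelihood (constant `-(n-p)/2 log(2*pi)`
#' omitted) at a given set of variance components, through the sparse
#' mixed-model equations:
#' `-2 l_R = n log sigma2_e + log|G| + log|C| + y' P y`,
#' with `log|G| = q log|G0| + 2 log|A| + sum_k q_k log sigma2_k`.
#'
#' @param design A `gess_design` (or records, with `spec`/`ped` given).
#' @param vc A `gess_varcomp`.
#' @param Ainv Sparse A-inverse (built from `ped` if missing).
#' @param spec,ped As in [build_mme()].
#' @return Scalar restricted log-likelihood.
#' @export
restricted_loglik <- function(design, vc, Ainv = NULL, spec = NULL,
                              ped = NULL) {
  if (!inherits(design, "gess_design")) {
    stopifnot(!is.null(spec), !is.null(ped))
    if (is.null(Ainv)) Ainv <- a_inverse(ped)
    design <- build_design(design, spec, ped)
  }
  if (is.null(Ainv)) Ainv <- a_inverse(design$ped)
  st <- reml_state(design, Ainv)
  reml_loglik_at(st, vc$components)
}

## persistent per-fit state: cross-products, symbolic factorizations
reml_state <- function(d, Ainv) {
  M <- cbind(d$X, d$Z1, d$Z2, d$W1, d$W2, d$Zh)
  MtM <- Matrix::forceSymmetric(Matrix::crossprod(M))
  st <- new.env(parent = emptyenv())
  st$d <- d
  st$M <- M
  st$MtM <- MtM
  st$Mty <- as.numeric(Matrix::crossprod(M, d$y))
  st$yty <- sum(d$y^2)
  st$Ainv <- Ainv
  st$chA <- Matrix::Cholesky(Ainv, LDL = FALSE)
  st$ldetAinv <- as.numeric(Matrix::determinant(Ainv, logarithm = TRUE)$modulus)
  st$chC <- NULL
  st
}

## factorize C(theta); returns log|C| and keeps the factor in state
reml_factor <- function(st, comp) {
  C <- mme_coef(st$MtM, st$d, comp, st$Ainv)
  C <- methods::as(C, "CsparseMatrix")
  ## the sparsity pattern gains/loses the sire-dam cross blocks when the
  ## genetic covariance moves off/onto zero: re-analyze when that happens
  has_cov <- comp[["sigma_ssd"]] != 0
  fresh <- function() Matrix::Cholesky(C, LDL = FALSE, super = TRUE)
  if (is.null(st$chC) || !identical(st$cov_pattern, has_cov)) {
    st$chC <- fresh()
    st$cov_pattern <- has_cov
  } else {
    st$chC <- tryCatch(Matrix::update(st$chC, C), error = function(e) fresh())
  }
  as.numeric(Matrix::determinant(st$chC, sqrt = FALSE)$modulus)
}

reml_loglik_at <- function(st, comp, keep_sol = FALSE) {
  d <- st$d
  if (any(!is.finite(comp))) return(-Inf)
  ldetC <- tryCatch(suppressWarnings(reml_factor(st, comp)),
                    error = function(e) NA_real_)
  if (is.na(ldetC)) return(-Inf)
  se2 <- comp[["sigma2_e"]]
  rhs <- st$Mty / se2
  sol <- as.numeric(Matrix::solve(st$chC, rhs, system = "A"))
  yPy <- st$yty / se2 - sum(sol * st$Mty) / se2
  st$yPy <- yPy
  G0 <- matrix(c(comp[["sigma2_ss"]], comp[["sigma_ssd"]],
                 comp[["sigma_ssd"]], comp[["sigma2_d"]]), 2, 2)
  ldetG0 <- log(max(G0[1, 1] * G0[2, 2] - G0[1, 2]^2, 1e-300))
  ldetG <- d$q * ldetG0 - 2 * st$ldetAinv +
    d$n_pe_ss * log(comp[["sigma2_pess"]]) +
    d$n_pe_d * log(comp[["sigma2_ped"]]) +
    d$n_hym * log(comp[["sigma2_hym"]])
  ll <- -0.5 * (d$n * log(se2) + ldetG + ldetC + yPy)
  if (keep_sol) st$sol <- sol
  ll
}

## average-information matrix at comp; requires a current factor/solution
reml_ai <- function(st, comp) {
  d <- st$d
  se2 <- comp[["sigma2_e"]]
  e <- d$y - as.numeric(st$M %*% st$sol)
  Py <- e / se2
  Av <- function(v) as.numeric(Matrix::solve(st$chA, v, system = "A"))
  t1 <- as.numeric(Matrix::crossprod(d$Z1, Py))
  t2 <- as.numeric(Matrix::crossprod(d$Z2, Py))
  At1 <- Av(t1); At2 <- Av(t2)
  F <- cbind(
    sigma2_ss = as.numeric(d$Z1 %*% At1),
    sigma_ssd = as.numeric(d$Z1 %*% At2) + as.numeric(d$Z2 %*% At1),
    sigma2_d = as.numeric(d$Z2 %*% At2),
    sigma2_pess = as.numeric(d$W1 %*% Matrix::crossprod(d$W1, Py)),
    sigma2_ped = as.numeric(d$W2 %*% Matrix::crossprod(d$W2, Py)),
    sigma2_hym = as.numeric(d$Zh %*% Matrix::crossprod(d$Zh, Py)),
    sigma2_e = Py)
  S <- Matrix::crossprod(st$M, F) / se2
  T <- Matrix::solve(st$chC, S, system = "A")
  PF <- (F - as.matrix(st$M %*% T)) / se2
  AI <- 0.5 * crossprod(F, PF)
  0.5 * (AI + t(AI))
}

## finite-difference gradient of the restricted log-likelihood; forward
## differences while far from the optimum, central near it
reml_gradient <- function(st, comp, scales, ll0 = NULL, central = TRUE) {
  g <- numeric(7)
  if (!central && is.null(ll0)) ll0 <- reml_loglik_at(st, comp)
  for (i in seq_len(7)) {
    h <- 1e-3 * abs(comp[i]) + 1e-4 * scales[i]
    up <- comp; up[i] <- comp[i] + h
    up <- project_feasible(up, scales)
    lu <- reml_loglik_at(st, up)
    if (central) {
      dn <- comp; dn[i] <- comp[i] - h
      dn <- project_feasible(dn, scales)
      hh <- up[i] - dn[i]
      ld <- reml_loglik_at(st, dn)
      g[i] <- if (is.finite(lu) && is.finite(ld) && hh > 0)
        (lu - ld) / hh else 0
    } else {
      hh <- up[i] - comp[i]
      g[i] <- if (is.finite(lu) && is.finite(ll0) && hh > 0)
        (lu - ll0) / hh else 0
    }
  }
  names(g) <- names(comp)
  g
}

## residual-scale profiling: multiplying every component by
## c = y'Py / (n - p) cannot decrease the restricted likelihood
rescale_components <- function(st, comp, scales) {
  ll <- reml_loglik_at(st, comp)
  if (!is.finite(ll) || is.null(st$yPy)) return(list(comp = comp, ll = ll))
  c_opt <- st$yPy / (st$d$n - st$d$p)
  cand <- project_feasible(comp * c_opt, scales)
  ll2 <- reml_loglik_at(st, cand)
  if (is.finite(ll2) && ll2 > ll) list(comp = cand, ll = ll2)
  else list(comp = comp, ll = ll)
}

## keep variances above their floors and G0 inside the PSD cone
project_feasible <- function(comp, scales) {
  floors <- 1e-8 * scales
  vi <- c(1, 3, 4, 5, 6, 7)
  comp[vi] <- pmax(comp[vi], floors[vi])
  bound <- 0.999 * sqrt(comp[[1]] * comp[[3]])
  comp[2] <- min(max(comp[[2]], -bound), bound)
  comp
}

## damped AI-Newton ascent of the restricted likelihood from one start
reml_newton <- function(st, comp, scales, opt, maxit) {
  rs <- rescale_components(st, comp, scales)
  comp <- rs$comp; ll <- rs$ll
  converged <- FALSE
  it <- 0L
  floors <- 1e-8 * scales
  ridge <- 1e-6
  near <- FALSE   # near convergence: switch to central differences
  repeat {
    it <- it + 1L
    ll <- reml_loglik_at(st, comp, keep_sol = TRUE)
    AI <- reml_ai(st, comp)
    central <- if (opt$gradient == "forward") FALSE
               else if (opt$gradient == "central") TRUE else near
    g <- reml_gradient(st, comp, scales, ll0 = ll, central = central)
    ## freeze variances stuck at their floor with outward-pointing gradient
    free <- rep(TRUE, 7)
    vi <- c(1, 3, 4, 5, 6, 7)
    free[vi] <- !(comp[vi] <= floors[vi] * 1.0001 & g[vi] < 0)
    dAI <- pmax(diag(AI), 1e-12 * max(diag(AI), 1))
    accepted <- FALSE
    for (try in 1:8) {
      ## Levenberg-Marquardt damped average-information step
      Af <- AI[free, free, drop = FALSE] +
        ridge * diag(dAI[free], sum(free))
      step <- numeric(7)
      step[free] <- tryCatch(solve(Af, g[free]),
                             error = function(e) g[free] / dAI[free])
      lam <- 1
      for (half in 1:12) {
        cand <- project_feasible(comp + lam * step, scales)
        ll_new <- reml_loglik_at(st, cand)
        if (is.finite(ll_new) && ll_new >= ll - 1e-10) { accepted <- TRUE; break }
        lam <- lam / 2
      }
      if (accepted) { ridge <- max(ridge / 10, 1e-8); break }
      ridge <- ridge * 100
    }
    if (!accepted) {
      converged <- near
      if (!near) { near <- TRUE; next }  # retry once with central gradient
      break
    }
    ## profile the overall scale (free uphill move)
    rs <- rescale_components(st, cand, scales)
    cand <- rs$comp; ll_new <- rs$ll
    rel <- max(abs(cand - comp) / (abs(comp) + 1e-6 * scales))
    dll <- ll_new - ll
    comp <- cand
    ll <- ll_new
    if (opt$verbose)
      message(sprintf("it %d logLik %.6f max-rel-change %.2e dll %.2e",
                      it, ll, rel, dll))
    if (rel == 0 && near) { converged <- TRUE; break }  # pinned, cannot move
    if (!near && (rel < 1e-3 || dll < 1e-4)) near <- TRUE
    else if (near && ridge <= 1e-5 &&
             (rel < opt$tol_par || dll < opt$tol_ll)) {
      converged <- TRUE
      break
    }
    if (it >= maxit) break
  }
  list(comp = comp, ll = ll, converged = converged, iterations = it)
}

#' AI-REML estimation of the seven (co)variance components
#'
#' Fits the correlated service-sire/dam linear mixed model by restricted
#' maximum likelihood. Newton steps use the exact average-information
#' matrix (computed through mixed-model-equation solves) as curvature and
#' a central finite-difference gradient of the exact restricted
#' log-likelihood; any step leaving the parameter space is projected back
#' onto it (variance floors, PSD sire/dam block) and step-halved until the
#' restricted log-likelihood does not decrease, so accepted iterates are
#' monotone. The inverse average-information matrix at convergence is the
#' sampling covariance of the estimates.
#'
#' @param records Edited trait records.
#' @param spec A [trait_model_spec()].
#' @param ped A `ped_pedigree`.
#' @param init Optional `gess_varcomp` or named 7-vector of starting
#'   values; a variance-partition heuristic is used otherwise.
#' @param options List: `maxit` (200), `tol_par` (1e-8 relative parameter
#'   change), `tol_ll` (1e-9 log-likelihood change), `gradient` (`"auto"`:
#'   forward differences far from the optimum, central near it;
#'   `"forward"`/`"central"` force one scheme), `polish` (run a short
#'   derivative-free refinement; default on problems up to 2000 records),
#'   `verbose` (FALSE).
#' @return A list of class `gess_reml`: `vc` (a `gess_varcomp` with the
#'   AI-based sampling covariance), `loglik`, `iterations`, `converged`,
#'   `ai`, plus the solution and factorization needed by [solve_blup()]
#'   and [reliability()].
#' @export
reml_estimate <- function(records, spec, ped, init = NULL, options = list()) {
  opt <- utils::modifyList(list(maxit = 200L, tol_par = 1e-8, tol_ll = 1e-9,
                                gradient = "auto", verbose = FALSE), options)
  design <- build_design(records, spec, ped)
  Fcoef <- inbreeding(ped)
  Ainv <- a_inverse(ped, Fcoef)
  st <- reml_state(design, Ainv)
  vy <- stats::var(design$y)
  scales <- stats::setNames(rep(vy, 7), c(
    "sigma2_ss", "sigma_ssd", "sigma2_d", "sigma2_pess", "sigma2_ped",
    "sigma2_hym", "sigma2_e"))
  comp <- if (!is.null(init)) {
    if (inherits(init, "gess_varcomp")) init$components else init
  } else {
    c(sigma2_ss = 0.05 * vy, sigma_ssd = 0, sigma2_d = 0.05 * vy,
      sigma2_pess = 0.05 * vy, sigma2_ped = 0.05 * vy,
      sigma2_hym = 0.1 * vy, sigma2_e = 0.7 * vy)
  }
  comp <- project_feasible(comp, scales)
  run <- reml_newton(st, comp, scales, opt, opt$maxit)
  comp <- run$comp; ll <- run$ll
  converged <- run$converged
  it <- run$iterations

  ## The sire (dam) genetic variance and the matching permanent-environment
  ## variance are exchangeable local optima when family information is
  ## weak. If a genetic variance collapsed onto its floor, retry from the
  ## swapped split and keep the higher restricted likelihood.
  floors <- 1e-8 * scales
  swaps <- list()
  if (comp[[1]] <= 10 * floors[[1]] && comp[[4]] > 10 * floors[[4]])
    swaps <- c(swaps, list(c(1L, 4L)))
  if (comp[[3]] <= 10 * floors[[3]] && comp[[5]] > 10 * floors[[5]])
    swaps <- c(swaps, list(c(3L, 5L)))
  for (sw in swaps) {
    cand0 <- comp
    cand0[sw] <- comp[rev(sw)]
    ## re-seed the sire-dam covariance: it collapses with the variance and
    ## otherwise cannot pull the restart out of the degenerate basin
    cand0[2] <- sign(comp[[2]] + 1e-300) * 0.5 *
      sqrt(cand0[[1]] * cand0[[3]])
    cand0 <- project_feasible(cand0, scales)
    alt <- reml_newton(st, cand0, scales, opt, min(opt$maxit, 30L))
    if (alt$ll > ll + 1e-6) {
      comp <- alt$comp; ll <- alt$ll
      converged <- alt$converged
      it <- it + alt$iterations
    }
  }
  ## derivative-free polish on small problems: guards against stalls of
  ## the finite-difference gradient on flat likelihood surfaces
  do_polish <- if (is.null(opt$polish)) design$n <= 2000 else opt$polish
  if (do_polish) {
    tr <- function(comp) c(log(comp[1]),
                           atanh(max(-0.999, min(0.999,
                             comp[2] / sqrt(comp[1] * comp[3])))),
                           log(comp[3:7]))
    untr <- function(par) {
      v <- exp(par[c(1, 3:7)])
      cc <- c(v[1], tanh(par[2]) * sqrt(v[1] * v[2]), v[2:6])
      names(cc) <- names(comp)
      project_feasible(cc, scales)
    }
    nm <- stats::optim(tr(comp), function(par) {
      v <- reml_loglik_at(st, untr(par))
      if (is.finite(v)) -v else 1e12
    }, method = "Nelder-Mead",
    control = list(maxit = 500L, reltol = 1e-12))
    cand <- untr(nm$par)
    if (-nm$value > reml_loglik_at(st, comp)) {
      comp <- cand
      converged <- TRUE
    }
  }
  ## final factorization/solution and sampling covariance
  ll <- reml_loglik_at(st, comp, keep_sol = TRUE)
  AI <- reml_ai(st, comp)
  ## PSD-safe inverse: sampling covariance from the information matrix
  eg <- eigen(AI, symmetric = TRUE)
  evals <- pmax(eg$values, 1e-10 * max(abs(eg$values), 1e-300))
  vcov <- eg$vectors %*% diag(1 / evals, 7) %*% t(eg$vectors)
  vc <- varcomp(comp[["sigma2_ss"]], comp[["sigma_ssd"]], comp[["sigma2_d"]],
                comp[["sigma2_pess"]], comp[["sigma2_ped"]],
                comp[["sigma2_hym"]], comp[["sigma2_e"]],
                vcov = vcov, logLik = ll, converged = converged)
  if (!converged)
    warning("REML did not converge in ", opt$maxit, " iterations")
  structure(list(vc = vc, loglik = ll, iterations = it,
                 converged = converged, ai = AI, design = design,
                 state = st, blocks = design_blocks(design),
                 ped = ped, F = Fcoef, spec = spec),
            class = "gess_reml")
}

#' @export
print.gess_reml <- function(x, ...) {
  cat("AI-REML fit:", x$spec$trait, "|", x$design$n, "records |",
      x$iterations, "iterations | converged:", x$converged, "\n")
  print(x$vc)
  invisible(x)
}
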