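# frozen reference derived parameters (printed estimates the formula layer
# must reproduce; see test-acceptance.R for the full table)
ref_gl <- as_varcomp(reference_components("GL"))

test_that("derived-parameter formulas behave on edge cases", {
  only_ss <- varcomp(1, 0, 0, 0, 0, 0, 0)
  expect_equal(unname(heritability(only_ss)["h2_ss"]), 1)
  expect_error(genetic_correlation(only_ss), "zero additive variance")

  ## zero permanent environment: repeatability equals heritability
  vc <- varcomp(0.4, 0.1, 0.3, 0, 0, 0.2, 1.1)
  expect_equal(unname(repeatability(vc)), unname(heritability(vc)))

  ## zero covariance: r = 0
  expect_equal(genetic_correlation(varcomp(1, 0, 2, 0, 0, 0, 1)), 0)

  ## covariance-in-denominator flag shifts the estimate
  h_no <- heritability(ref_gl, include_cov = FALSE)
  h_yes <- heritability(ref_gl, include_cov = TRUE)
  expect_gt(h_no[["h2_ss"]], h_yes[["h2_ss"]])
})

test_that("reference gestation-length parameters reproduce printed values", {
  expect_equal(round(unname(heritability(ref_gl)["h2_ss"]), 4), 0.1024)
  expect_equal(round(unname(repeatability(ref_gl)["re_d"]), 4), 0.1160)
  expect_equal(round(genetic_correlation(ref_gl), 4), 0.7871)
})

test_that("delta-method SEs are exact for linear targets and match Monte
          Carlo for ratios", {
  comp <- c(sigma2_ss = 0.5, sigma_ssd = 0.1, sigma2_d = 0.6,
            sigma2_pess = 0.05, sigma2_ped = 0.07, sigma2_hym = 0.3,
            sigma2_e = 2)
  ## linear target with diagonal covariance: SE = |c| * SE(sigma2_ss)
  Cd <- diag(c(0.02, 0.005, 0.02, 0.001, 0.001, 0.01, 0.05)^2)
  g <- gesskit:::derived_gradient(comp, "h2_ss")
  expect_equal(delta_method_se(comp, "h2_ss", vcov = matrix(0, 7, 7)), 0)

  ## analytic gradient agrees with finite differences
  for (target in c("h2_ss", "h2_d", "re_ss", "re_d", "r")) {
    ga <- gesskit:::derived_gradient(comp, target)
    fn <- function(x) {
      names(x) <- names(comp)
      switch(target,
             h2_ss = heritability(x)[["h2_ss"]],
             h2_d = heritability(x)[["h2_d"]],
             re_ss = repeatability(x)[["re_ss"]],
             re_d = repeatability(x)[["re_d"]],
             r = x[["sigma_ssd"]] / sqrt(x[["sigma2_ss"]] * x[["sigma2_d"]]))
    }
    gn <- vapply(1:7, function(i) {
      h <- 1e-6 * max(abs(comp[i]), 1e-3)
      up <- comp; up[i] <- comp[i] + h
      dn <- comp; dn[i] <- comp[i] - h
      (fn(up) - fn(dn)) / (2 * h)
    }, numeric(1))
    expect_equal(unname(ga), gn, tolerance = 1e-5)
  }

  ## Monte-Carlo propagation oracle
  set.seed(99)
  L <- matrix(rnorm(49, sd = 0.03), 7, 7)
  C <- crossprod(L) * outer(abs(comp), abs(comp))
  se_delta <- delta_method_se(comp, "h2_ss", vcov = C)
  draws <- matrix(rnorm(7 * 1e5), 1e5, 7) %*% chol(C)
  draws <- sweep(draws, 2, comp, "+")
  h2_draws <- draws[, 1] / rowSums(draws[, -2, drop = FALSE])
  expect_lt(abs(se_delta - sd(h2_draws)) / sd(h2_draws), 0.02)
})

test_that("the Wald test matches the normal-CDF oracle", {
  expect_equal(wald_test(1.959964 * 2, 2), 0.05, tolerance = 1e-6)
  expect_equal(wald_test(0, 1), 1)
  expect_error(wald_test(1, 0), "positive")
  z <- seq(-4, 4, by = 0.25)
  expect_equal(wald_test(z, 1), 2 * (1 - pnorm(abs(z))), tolerance = 1e-12)
})

test_that("MME dimensions follow the block contract", {
  herd <- toy_herd(seed = 3)
  spec <- trait_model_spec("GL")
  d <- build_design(herd$records, spec, herd$pedigree)
  mme <- build_mme(d, as_varcomp(reference_components("GL")),
                   Ainv = a_inverse(herd$pedigree))
  expect_equal(nrow(mme$C),
               d$p + 2 * nrow(herd$pedigree) + d$n_pe_ss + d$n_pe_d +
                 d$n_hym)
})

test_that("MME solutions equal the dense GLS/BLUP oracle", {
  herd <- toy_herd(seed = 11, n_founders = 10, cows_per_generation = 10,
                   n_service_sires = 3, n_parities = 2)
  spec <- trait_model_spec("GL")
  d <- build_design(herd$records, spec, herd$pedigree)
  A <- a_submatrix(herd$pedigree)
  vc <- as_varcomp(reference_components("GL"))
  mme <- build_mme(d, vc, Ainv = a_inverse(herd$pedigree))
  sols <- solve_mme(mme)
  oracle <- oracle_gls_blup(d, vc$components, A)
  expect_equal(unname(sols$fixed), unname(oracle$beta), tolerance = 1e-6)
  expect_equal(unname(c(sols$u_ss, sols$u_d)), unname(oracle$u),
               tolerance = 1e-6)
})

test_that("the sparse restricted likelihood equals the dense oracle", {
  herd <- toy_herd(seed = 5, n_founders = 12, cows_per_generation = 12,
                   n_service_sires = 4, n_parities = 2)
  spec <- trait_model_spec("GL")
  d <- build_design(herd$records, spec, herd$pedigree)
  A <- a_submatrix(herd$pedigree)
  for (s in 1:3) {
    set.seed(s)
    comp <- reference_components("GL") * exp(runif(7, -0.3, 0.3))
    comp["sigma_ssd"] <- 0.5 * sqrt(comp["sigma2_ss"] * comp["sigma2_d"])
    vc <- as_varcomp(comp)
    ll <- restricted_loglik(d, vc)
    expect_equal(ll, oracle_reml_loglik(d, vc$components, A),
                 tolerance = 1e-6)
  }
})

test_that("MME solutions are invariant to record order and id relabeling", {
  herd <- toy_herd(seed = 9)
  spec <- trait_model_spec("GL")
  vc <- as_varcomp(reference_components("GL"))
  Ainv <- a_inverse(herd$pedigree)
  d1 <- build_design(herd$records, spec, herd$pedigree)
  s1 <- solve_mme(build_mme(d1, vc, Ainv = Ainv))
  perm <- sample(nrow(herd$records))
  d2 <- build_design(herd$records[perm, ], spec, herd$pedigree)
  s2 <- solve_mme(build_mme(d2, vc, Ainv = Ainv))
  expect_equal(s1$u_ss, s2$u_ss, tolerance = 1e-8)
  expect_equal(s1$fixed, s2$fixed, tolerance = 1e-8)

  ## relabel ids consistently
  relab <- function(x) paste0("id_", x)
  ped2 <- as.data.frame(herd$pedigree)
  ped2 <- data.frame(animal = relab(ped2$id),
                     sire = ifelse(is.na(ped2$sire), NA, relab(ped2$sire)),
                     dam = ifelse(is.na(ped2$dam), NA, relab(ped2$dam)),
                     sex = ped2$sex)
  rec2 <- herd$records
  rec2$cow <- relab(rec2$cow); rec2$sire <- relab(rec2$sire)
  sp2 <- sort_pedigree(ped2)
  d3 <- build_design(rec2, spec, sp2)
  s3 <- solve_mme(build_mme(d3, vc, Ainv = a_inverse(sp2)))
  expect_equal(unname(s3$u_ss[relab(names(s1$u_ss))]), unname(s1$u_ss),
               tolerance = 1e-8)
})

test_that("AI-REML reaches a stationary point of the restricted likelihood", {
  herd <- toy_herd(seed = 17, n_founders = 20, cows_per_generation = 25,
                   n_service_sires = 5, n_parities = 2)
  spec <- trait_model_spec("GL")
  fit <- reml_estimate(herd$records, spec, herd$pedigree,
                       options = list(maxit = 100))
  d <- fit$design
  Ainv <- a_inverse(herd$pedigree)
  scales <- stats::setNames(rep(stats::var(d$y), 7),
                            names(fit$vc$components))
  obj <- function(par) {
    comp <- exp(par[c(1, 3:7)])
    comp <- c(comp[1], tanh(par[2]) * sqrt(comp[1] * comp[2]), comp[2:6])
    names(comp) <- names(fit$vc$components)
    ## search over the same feasible region the fitter uses
    comp <- gesskit:::project_feasible(comp, scales)
    vc <- tryCatch(as_varcomp(comp), error = function(e) NULL)
    if (is.null(vc)) return(1e10)
    -restricted_loglik(d, vc, Ainv = Ainv)
  }
  cc <- fit$vc$components
  start <- c(log(cc[1]), atanh(max(-0.999, min(0.999,
              cc[2] / sqrt(cc[1] * cc[3])))), log(cc[3:7]))
  nm <- optim(start, obj, method = "Nelder-Mead",
              control = list(maxit = 400, reltol = 1e-12))
  ## a derivative-free maximizer started at the AI solution cannot improve
  ## the restricted likelihood materially
  expect_lt(-nm$value - fit$loglik, 1e-3)
})

test_that("a null sire variance is recovered at the boundary", {
  cfg <- sim_config(trait = "GL", n_founders = 60, n_generations = 2,
                    cows_per_generation = c(120, 400), male_frac = c(0.25, 0),
                    n_service_sires = 25, n_parities = 4,
                    components = c(sigma2_ss = 0, sigma_ssd = 0,
                                   sigma2_d = 4, sigma2_pess = 0,
                                   sigma2_ped = 0.5, sigma2_hym = 3.3,
                                   sigma2_e = 27), seed = 41)
  herd <- simulate_herd(cfg)
  fit <- reml_estimate(herd$records, trait_model_spec("GL"), herd$pedigree)
  est <- fit$vc$components
  se <- sqrt(pmax(diag(fit$vc$vcov), 0))
  expect_lt(est[["sigma2_ss"]], 3 * max(se[1], 0.2))
  ## Wald test of h2_ss should not reject at conventional levels
  h2 <- heritability(fit$vc)[["h2_ss"]]
  se_h2 <- delta_method_se(fit$vc, "h2_ss")
  expect_gt(wald_test(h2, max(se_h2, 1e-12)), 0.01)
})
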