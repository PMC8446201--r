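test_that("BLUP gives parent-average values to unrecorded progeny", {
  herd <- toy_herd(seed = 13, n_founders = 10, cows_per_generation = 15,
                   n_service_sires = 3, n_parities = 2)
  ## append a progeny with no records to the pedigree
  ped_df <- as.data.frame(herd$pedigree)[, c("id", "sire", "dam", "sex")]
  names(ped_df)[1] <- "animal"
  cow1 <- herd$records$cow[1]
  sire1 <- herd$records$sire[1]
  ped_df <- rbind(ped_df, data.frame(animal = "youngster", sire = sire1,
                                     dam = cow1, sex = "F"))
  ped2 <- sort_pedigree(ped_df)
  spec <- trait_model_spec("GL")
  vc <- as_varcomp(reference_components("GL"))
  mme <- build_mme(herd$records, vc, spec = spec, ped = ped2)
  sols <- solve_blup(mme)
  expect_equal(sols$u_ss[["youngster"]],
               0.5 * (sols$u_ss[[sire1]] + sols$u_ss[[cow1]]),
               tolerance = 1e-8)
  expect_equal(sols$u_d[["youngster"]],
               0.5 * (sols$u_d[[sire1]] + sols$u_d[[cow1]]),
               tolerance = 1e-8)
  expect_setequal(unique(sols$ebv$effect), c("GESS", "GED"))
})

test_that("reliabilities are exact against the dense inverse and bounded", {
  herd <- toy_herd(seed = 19, n_founders = 12, cows_per_generation = 12,
                   n_service_sires = 4, n_parities = 2)
  spec <- trait_model_spec("GL")
  fit <- reml_estimate(herd$records, spec, herd$pedigree,
                       options = list(maxit = 30))
  ids <- herd$pedigree$id
  rel <- reliability(fit, ids, "GESS")
  expect_true(all(rel >= 0 & rel < 1))
  ## dense-inverse PEV oracle
  C <- gesskit:::mme_coef(fit$state$MtM, fit$design, fit$vc$components,
                          fit$state$Ainv)
  Cinv <- solve(as.matrix(C))
  off <- fit$blocks$u_ss[1] - 1L
  pev <- diag(Cinv)[off + seq_along(ids)]
  rel_oracle <- 1 - pev / ((1 + fit$F) * fit$vc$components[["sigma2_ss"]])
  expect_equal(unname(rel), unname(pmin(pmax(rel_oracle, 0), 1 - 1e-12)),
               tolerance = 1e-10)
})

test_that("an unconnected animal without records has zero reliability", {
  herd <- toy_herd(seed = 13, n_founders = 10, cows_per_generation = 15,
                   n_service_sires = 3, n_parities = 2)
  ped_df <- as.data.frame(herd$pedigree)[, c("id", "sire", "dam", "sex")]
  names(ped_df)[1] <- "animal"
  ped_df <- rbind(ped_df, data.frame(animal = "stranger", sire = NA,
                                     dam = NA, sex = "M"))
  ped2 <- sort_pedigree(ped_df)
  fit <- reml_estimate(herd$records, trait_model_spec("GL"), ped2,
                       options = list(maxit = 25))
  expect_lt(reliability(fit, "stranger", "GESS")[[1]], 1e-8)
})

test_that("deregression removes shrinkage and respects the accuracy filter", {
  ped <- sort_pedigree(data.frame(animal = c("s", "d", "o", "p"),
                                  sire = c(NA, NA, "s", "s"),
                                  dam = c(NA, NA, "d", "d")))
  ebv <- c(s = 0, d = 0, o = 2, p = 1)
  rel <- c(s = 1e-9, d = 1e-9, o = 0.999999, p = 0.008)
  out <- deregress(ebv, rel, ped, h2 = 0.1)
  ## rel -> 1 with no parent information: DRP -> EBV
  expect_equal(out$drp[out$id == "o"], 2, tolerance = 1e-4)
  ## accuracy sqrt(0.008) = 0.089 <= 0.10: excluded
  expect_false(out$included[out$id == "p"])
  expect_true(out$included[out$id == "o"])
  expect_true(all(out$weight[out$included] > 0))
})

test_that("re-regressing DRP reproduces the original EBV", {
  herd <- toy_herd(seed = 29, n_founders = 14, cows_per_generation = 20,
                   n_service_sires = 4, n_parities = 3)
  spec <- trait_model_spec("GL")
  fit <- reml_estimate(herd$records, spec, herd$pedigree,
                       options = list(maxit = 30))
  sires <- colnames(fit$design$W1)
  sols <- solve_blup(fit)
  rel <- reliability(fit, herd$pedigree$id, "GESS")
  h2 <- max(heritability(fit$vc)[["h2_ss"]], 0.01)
  out <- deregress(sols$u_ss[herd$pedigree$id], rel, herd$pedigree, h2 = h2)
  ok <- out$included
  ## one-step shrinkage regression back onto the parent average
  rows <- match(out$id, herd$pedigree$id)
  pa <- vapply(seq_along(rows), function(k) {
    sr <- herd$pedigree$sire_row[rows[k]]
    dr <- herd$pedigree$dam_row[rows[k]]
    g <- function(r) if (r > 0) sols$u_ss[[herd$pedigree$id[r]]] else 0
    0.5 * (g(sr) + g(dr))
  }, numeric(1))
  r2pa <- vapply(seq_along(rows), function(k) {
    sr <- herd$pedigree$sire_row[rows[k]]
    dr <- herd$pedigree$dam_row[rows[k]]
    g <- function(r) if (r > 0) rel[[herd$pedigree$id[r]]] else 0
    (g(sr) + g(dr)) / 4
  }, numeric(1))
  r2d <- (out$rel - r2pa) / (1 - r2pa)
  back <- pa + r2d * (out$drp - pa)
  expect_equal(back[ok], out$ebv[ok], tolerance = 1e-6)
})

test_that("Calo-type correlation scales the raw correlation correctly", {
  ## identical EBVs with full reliability: factor 1, r 1
  e <- c(a = 1, b = 2, c = 3, d = 2.5)
  r1 <- c(a = 1, b = 1, c = 1, d = 1)
  out <- approx_genetic_correlation(e, r1, e, r1)
  expect_equal(out$factor, 1)
  expect_equal(out$r, 1)

  ## weighting factor >= 1 so |r_approx| >= |raw Pearson|
  set.seed(8)
  x <- rnorm(60); y <- 0.5 * x + rnorm(60, sd = 0.8)
  ra <- runif(60, 0.2, 0.9); rb <- runif(60, 0.2, 0.9)
  names(x) <- names(y) <- names(ra) <- names(rb) <- sprintf("i%02d", 1:60)
  out2 <- approx_genetic_correlation(x, ra, y, rb)
  expect_gte(out2$factor, 1)
  expect_gte(abs(out2$r), abs(out2$r_raw) - 1e-12)
  ## independent scalar evaluation of the formula
  fac <- sqrt(sum(ra) * sum(rb)) / sum(sqrt(ra * rb))
  expect_equal(out2$r, min(1, cor(x, y) * fac))
  ## symmetry
  out3 <- approx_genetic_correlation(y, rb, x, ra)
  expect_equal(out3$r, out2$r)
  expect_error(approx_genetic_correlation(x[1:2], ra[1:2], y[1:2], rb[1:2]),
               "at least 3")
})

test_that("the closed-form Calo SE agrees with a bootstrap", {
  set.seed(15)
  n <- 300
  x <- rnorm(n); y <- 0.6 * x + rnorm(n, sd = 0.8)
  ra <- runif(n, 0.4, 0.9); rb <- runif(n, 0.4, 0.9)
  names(x) <- names(y) <- names(ra) <- names(rb) <- sprintf("i%03d", 1:n)
  out <- approx_genetic_correlation(x, ra, y, rb)
  boot <- replicate(1000, {
    ix <- sample(n, replace = TRUE)
    approx_genetic_correlation(unname(x[ix]), unname(ra[ix]),
                               unname(y[ix]), unname(rb[ix]))$r
  })
  expect_lt(abs(out$se - sd(boot)) / sd(boot), 0.15)
})
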