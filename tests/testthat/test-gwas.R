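test_that("HWE chi-squared test matches the scalar oracle", {
  expect_equal(hwe_test(c(25, 50, 25)), 1)
  ## independent evaluation of the 1-df chi-squared formula
  counts <- c(60, 20, 20)
  n <- sum(counts)
  p <- (2 * counts[3] + counts[2]) / (2 * n)
  e <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  x2 <- sum((counts - e)^2 / e)
  expect_equal(hwe_test(counts), pchisq(x2, 1, lower.tail = FALSE))
  expect_error(hwe_test(c(0, 0, 0)), "no genotypes")
  ## exact test is close to chi-squared at moderate counts
  expect_lt(abs(hwe_test(c(40, 45, 15), exact = TRUE) -
                  hwe_test(c(40, 45, 15))), 0.05)
})

test_that("QC removes exactly the planted violations", {
  set.seed(55)
  n <- 400
  m <- 1000
  maf <- runif(m, 0.2, 0.5)
  G <- sapply(maf, function(f) rbinom(n, 2, f))
  rownames(G) <- sprintf("an%03d", 1:n)
  colnames(G) <- sprintf("s%04d", 1:m)
  map <- data.frame(snp = colnames(G), chr = rep(1:10, each = 100),
                    pos = rep(seq(1e6, 1e8, length.out = 100), 10))
  conc <- rep(1, m)
  ## plant 50 distinct violations
  G[, 1:20] <- 0L                                   # monomorphic: MAF 0
  for (j in 21:35) G[, j] <- rbinom(n, 1, 0.5) * 2L # no hets: HWE failure
  map$pos[36:45] <- NA                              # missing position
  conc[46:50] <- 0.80                               # poor imputation
  out <- qc_filter(list(genotypes = G, map = map), concordance = conc)
  expect_equal(unname(out$report["kept"]), 950)
  expect_equal(unname(out$report["maf"]), 20)
  expect_equal(unname(out$report["position"]), 10)
  expect_equal(unname(out$report["concordance"]), 5)
  expect_gte(unname(out$report["hwe"]), 15)
  expect_error(qc_filter(list(genotypes = G[, 1:20, drop = FALSE],
                              map = map[1:20, ])), "all SNPs removed")
})

test_that("BH step-up matches brute-force enumeration", {
  p <- c(0.0001, 0.004, 0.019, 0.095, 0.201, 0.278, 0.298, 0.344, 0.459,
         0.9)
  out <- bh_fdr(p, alpha = 0.05)
  ## brute force: largest k with p_(k) <= k alpha / m
  ps <- sort(p)
  k <- max(c(0, which(ps <= seq_along(ps) * 0.05 / length(ps))))
  expect_equal(out$n_reject, k)
  expect_equal(out$n_reject, 2)
  expect_true(all(out$reject[order(p)][seq_len(k)]))

  expect_equal(bh_fdr(rep(1, 20))$n_reject, 0)
  m <- 40
  expect_equal(bh_fdr(rep(0.05 / m, m))$n_reject, m)
  ## monotone in alpha
  set.seed(2)
  pr <- runif(200)^2
  expect_true(all(bh_fdr(pr, 0.01)$reject <= bh_fdr(pr, 0.05)$reject))
})

test_that("the inflation factor is calibrated and monotone", {
  expect_equal(inflation_factor(rep(0.5, 11)), 1)
  set.seed(3)
  u <- runif(1e5)
  lam <- inflation_factor(u)
  expect_gt(lam, 0.98); expect_lt(lam, 1.02)
  expect_gt(inflation_factor(u / 2), lam)
})

test_that("degenerate scan equals the textbook WLS oracle", {
  set.seed(21)
  cfg <- sim_config(trait = "GL", n_founders = 150, n_generations = 0,
                    n_snps = 40, seed = 21)
  ped <- simulate_pedigree(cfg)
  geno <- simulate_genotypes(ped, cfg)
  y <- stats::setNames(rnorm(150), ped$id)
  w <- stats::setNames(runif(150, 0.5, 2), ped$id)
  scan <- farmcpu_scan(geno, y, weights = w, options = list(max_qtn = 0))
  for (j in c(1, 7, 40)) {
    fit <- lm(y ~ geno$genotypes[, j], weights = w)
    expect_equal(scan$result$p[j], summary(fit)$coefficients[2, 4],
                 tolerance = 1e-10)
    expect_equal(scan$result$effect[j], unname(coef(fit)[2]),
                 tolerance = 1e-10)
  }
})

test_that("QC + scan output is invariant to SNP column order", {
  set.seed(33)
  cfg <- sim_config(trait = "GL", n_founders = 120, n_generations = 0,
                    n_snps = 60, seed = 33)
  ped <- simulate_pedigree(cfg)
  geno <- simulate_genotypes(ped, cfg)
  y <- stats::setNames(rnorm(120), ped$id)
  perm <- sample(60)
  geno2 <- list(genotypes = geno$genotypes[, perm],
                map = geno$map[perm, ])
  s1 <- farmcpu_scan(qc_filter(geno), y, options = list(max_qtn = 0))
  s2 <- farmcpu_scan(qc_filter(geno2), y, options = list(max_qtn = 0))
  r1 <- s1$result[order(s1$result$snp), ]
  r2 <- s2$result[order(s2$result$snp), ]
  expect_equal(r1$p, r2$p, tolerance = 1e-12)
})

test_that("a strong planted signal drives pseudo-QTN iteration", {
  set.seed(44)
  cfg <- sim_config(trait = "GL", n_founders = 500, n_generations = 0,
                    n_snps = 400, seed = 44)
  ped <- simulate_pedigree(cfg)
  geno <- simulate_genotypes(ped, cfg)
  g <- geno$genotypes[, 200]
  y <- stats::setNames(sqrt(0.10 / var(g)) * g + rnorm(500, 0, sqrt(0.9)),
                       ped$id)
  scan <- farmcpu_scan(geno, y)
  expect_gt(scan$iterations, 1)
  expect_equal(which.min(scan$result$p), 200)
  expect_true(scan$result$significant[200])
})

test_that("plot-ready tables are consistent with the scan", {
  set.seed(5)
  cfg <- sim_config(trait = "GL", n_founders = 100, n_generations = 0,
                    n_snps = 80, seed = 5)
  ped <- simulate_pedigree(cfg)
  geno <- simulate_genotypes(ped, cfg)
  y <- stats::setNames(rnorm(100), ped$id)
  scan <- farmcpu_scan(geno, y, options = list(max_qtn = 0))
  qm <- qq_manhattan_data(scan)
  expect_equal(nrow(qm$qq), 80)
  expect_true(all(diff(qm$qq$expected) <= 0) ||
                all(diff(qm$qq$expected) >= 0))
  ## genome coordinates monotone within chromosome
  by_chr <- split(qm$manhattan$genome_pos, qm$manhattan$chr)
  expect_true(all(vapply(by_chr, function(v) all(diff(v) > 0), logical(1))))
  ## threshold equals the BH threshold of the same p-values
  fdr <- bh_fdr(scan$result$p, scan$alpha)
  expect_equal(qm$threshold_logp,
               if (is.na(fdr$threshold)) NA_real_ else -log10(fdr$threshold))
})
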