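test_that("simulate_pedigree honours the configured layout", {
  cfg0 <- sim_config(trait = "GL", n_founders = 7, n_generations = 0, seed = 1)
  ped0 <- simulate_pedigree(cfg0)
  expect_equal(nrow(ped0), 7)
  expect_true(all(ped0$sire_row == 0L & ped0$dam_row == 0L))

  cfg <- sim_config(trait = "GL", n_founders = 5, n_generations = 2,
                    cows_per_generation = 10, seed = 1)
  ped <- simulate_pedigree(cfg)
  expect_equal(nrow(ped), 25)
  expect_equal(as.vector(table(ped$generation)), c(5, 10, 10))
  for (i in seq_len(nrow(ped))) {
    expect_lt(ped$sire_row[i], i)
    expect_lt(ped$dam_row[i], i)
  }
  ## non-founders have a male sire and a female dam
  nf <- ped$sire_row > 0L
  expect_true(all(ped$sex[ped$sire_row[nf]] == "M"))
  expect_true(all(ped$sex[ped$dam_row[nf]] == "F"))
})

test_that("a fixed seed reproduces the simulation bit for bit", {
  cfg <- sim_config(trait = "CR", n_founders = 30, n_generations = 1,
                    cows_per_generation = 40, male_frac = 0,
                    n_service_sires = 5, n_snps = 50, seed = 77)
  h1 <- simulate_herd(cfg, genotypes = TRUE)
  h2 <- simulate_herd(cfg, genotypes = TRUE)
  expect_identical(h1$pedigree, h2$pedigree)
  expect_identical(h1$bv, h2$bv)
  expect_identical(h1$records, h2$records)
  expect_identical(h1$geno, h2$geno)
})

test_that("gene-dropped breeding values realize the configured G0", {
  ped <- simulate_pedigree(sim_config(trait = "GL", n_founders = 20000,
                                      n_generations = 0, seed = 7))
  r_target <- 0.7871
  G0 <- matrix(c(1, r_target, r_target, 1), 2, 2)
  u <- simulate_breeding_values(ped, G0, seed = 7)
  expect_lt(abs(cor(u[, 1], u[, 2]) - r_target), 0.02)

  ## zero genetic variance: all values identically zero
  u0 <- simulate_breeding_values(ped[1:50, ], matrix(0, 2, 2), seed = 1)
  expect_true(all(u0 == 0))
})

test_that("trio covariance converges to A kron G0 (many replicate trios)", {
  n_rep <- 15000
  ids <- c(outer(c("s", "d", "o"), seq_len(n_rep), paste0))
  df <- data.frame(
    animal = ids,
    sire = ifelse(startsWith(ids, "o"), sub("^o", "s", ids), NA),
    dam = ifelse(startsWith(ids, "o"), sub("^o", "d", ids), NA),
    stringsAsFactors = FALSE)
  ped <- sort_pedigree(df)
  G0 <- matrix(c(1, 0.5, 0.5, 2), 2, 2)
  u <- simulate_breeding_values(ped, G0, seed = 42)
  ## stack (u_ss, u_d) for the trio positions across replicates
  pick <- function(prefix, col) u[paste0(prefix, seq_len(n_rep)), col]
  Umat <- cbind(pick("s", 1), pick("d", 1), pick("o", 1),
                pick("s", 2), pick("d", 2), pick("o", 2))
  emp <- cov(Umat)
  A_trio <- matrix(c(1, 0, 0.5, 0, 1, 0.5, 0.5, 0.5, 1), 3, 3)
  expected <- kronecker(G0, A_trio)
  mc_se <- sqrt((outer(diag(expected), diag(expected)) + expected^2) / n_rep)
  expect_true(all(abs(emp - expected) < 3.5 * mc_se))
})

test_that("degenerate record simulation returns the fixed-effect constant", {
  comp <- c(sigma2_ss = 0, sigma_ssd = 0, sigma2_d = 0, sigma2_pess = 0,
            sigma2_ped = 0, sigma2_hym = 0, sigma2_e = 0)
  cfg <- sim_config(trait = "GL", n_founders = 10, n_generations = 1,
                    cows_per_generation = 10, male_frac = 0,
                    n_service_sires = 2, n_parities = 1,
                    components = comp, mu = 278.36,
                    fixed_effects = list(calf_sex = c(0, 0), parity = 0,
                                         calf_size = c(0, 0, 0)),
                    seed = 3)
  herd <- simulate_herd(cfg)
  expect_true(all(herd$records$y == 278.36))
})

test_that("service-sire usage is skewed with the configured mean load", {
  ## ~489 services per bull on average: 20 bulls, ~1500 cows, 3 parities,
  ## repeated services until conception at the CR incidence
  cfg <- sim_config(trait = "CR", n_founders = 40, n_generations = 1,
                    cows_per_generation = 1500, male_frac = 0,
                    n_service_sires = 20, n_parities = 3, seed = 13)
  herd <- simulate_herd(cfg)
  load <- table(herd$records$sire)
  expect_lt(abs(mean(load) - 489) / 489, 0.10)
  ## heavy tail: most-used bull carries several times the median load
  expect_gt(max(load) / stats::median(load), 2)
})

test_that("thresholded phenotypes match the configured incidences", {
  cfg <- sim_config(trait = "SB", n_founders = 100, n_generations = 1,
                    cows_per_generation = 4000, male_frac = 0,
                    n_service_sires = 30, n_parities = 2, seed = 5,
                    fixed_effects = list(calf_sex = c(0, 0), parity = 0,
                                         calf_size = c(0, 0, 0)))
  herd <- simulate_herd(cfg)
  expect_lt(abs(mean(herd$records$y) - 0.0667), 0.01)

  cfg_ce <- sim_config(trait = "CE", n_founders = 100, n_generations = 1,
                       cows_per_generation = 4000, male_frac = 0,
                       n_service_sires = 30, n_parities = 2, seed = 6,
                       fixed_effects = list(calf_sex = c(0, 0), parity = 0,
                                            calf_size = c(0, 0, 0)))
  herd_ce <- simulate_herd(cfg_ce)
  expect_lt(abs(mean(herd_ce$records$y > 1) - 0.0521), 0.01)
})

test_that("simulated genotypes follow Mendelian transmission and HWE", {
  cfg <- sim_config(trait = "GL", n_founders = 10000, n_generations = 0,
                    n_snps = 200, maf_range = c(0.5, 0.5), seed = 8)
  ped <- simulate_pedigree(cfg)
  geno <- simulate_genotypes(ped, cfg)
  freq <- colMeans(geno$genotypes) / 2
  expect_true(all(abs(freq - 0.5) < 0.015))

  ## offspring share at least one allele with each parent at every locus
  cfg2 <- sim_config(trait = "GL", n_founders = 20, n_generations = 2,
                     cows_per_generation = 30, n_snps = 100, seed = 9)
  ped2 <- simulate_pedigree(cfg2)
  g2 <- simulate_genotypes(ped2, cfg2)$genotypes
  for (i in which(ped2$sire_row > 0L)) {
    for (p in c(ped2$sire_row[i], ped2$dam_row[i])) {
      incompatible <- (g2[p, ] == 0L & g2[i, ] == 2L) |
        (g2[p, ] == 2L & g2[i, ] == 0L)
      expect_false(any(incompatible))
    }
  }

  ## founder panel simulated under the null passes the HWE filter
  cfg3 <- sim_config(trait = "GL", n_founders = 2000, n_generations = 0,
                     n_snps = 1000, seed = 10)
  ped3 <- simulate_pedigree(cfg3)
  g3 <- simulate_genotypes(ped3, cfg3)
  hwe_p <- apply(g3$genotypes, 2, function(g)
    hwe_test(tabulate(g + 1L, nbins = 3L)))
  expect_gte(mean(hwe_p >= 1e-6), 0.99)
})

test_that("marker effects planted via qtl_spec shift breeding values", {
  cfg <- sim_config(trait = "GL", n_founders = 500, n_generations = 0,
                    n_snps = 50, seed = 14,
                    qtl_spec = data.frame(snp = 10, beta_ss = 1, beta_d = 0))
  ped <- simulate_pedigree(cfg)
  geno <- simulate_genotypes(ped, cfg)
  bv <- simulate_breeding_values(ped, cfg$G0, seed = 14)
  bv2 <- apply_qtl_effects(bv, geno, cfg$qtl_spec)
  g <- geno$genotypes[, 10]
  expect_equal(unname(bv2[, "u_ss"] - bv[, "u_ss"]), unname(g - mean(g)))
  expect_equal(bv2[, "u_d"], bv[, "u_d"])
})
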