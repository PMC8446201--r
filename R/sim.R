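#' Simulation configuration for a synthetic dairy herd
#'
#' Assembles the parameter set the synthetic-data generator works from.
#' Defaults emulate the structure of a commercial Holstein recording
#' scheme: multi-parity cows with repeated inseminations, a small pool of
#' heavily and unevenly used service sires, herd-year-month contemporary
#' groups, and sire/dam breeding values drawn from a correlated 2x2
#' genetic covariance. Trait parameter defaults come from
#' [reference_components()]; observed-scale incidences default to
#' CR 0.43, NRR56 0.50, calving-ease scores >1 5.21% (4.42% score 2,
#' 0.79% score 3), stillbirth 6.67%, gestation-length mean 278.36 d.
#'
#' @param trait One of `"CR"`, `"NRR56"`, `"CE"`, `"SB"`, `"GL"`.
#' @param n_founders,n_generations,cows_per_generation Pedigree layout;
#'   `cows_per_generation` (and `male_frac`) may be vectors, one entry
#'   per generation (recycled).
#' @param n_service_sires Number of bulls in service.
#' @param n_parities Parities recorded per cow.
#' @param male_frac Fraction of males in each non-founder cohort (founders
#'   are half male). Deterministic counts, so herd sizes are exact.
#' @param sire_skew Exponent of the Zipf-like weights used to assign
#'   service sires (larger = more skewed usage).
#' @param n_herds,n_years,n_months Contemporary-group layout.
#' @param components Named 7-vector of simulation-truth (co)variances
#'   (defaults to the bundled reference estimates for `trait`).
#' @param trait_kind `"binary"`, `"ordinal3"` or `"continuous"`
#'   (defaulted from `trait`).
#' @param mu Latent-scale intercept (278.36 for GL, 0 otherwise).
#' @param incidence Observed-scale incidence(s) used to place threshold
#'   cut points (ignored for continuous traits).
#' @param fixed_effects Named list of numeric level-effect vectors.
#' @param max_services Cap on inseminations per parity (success traits).
#' @param n_snps,maf_range,n_chr Genotype panel layout.
#' @param qtl_spec Optional data frame (`snp`, `beta_ss`, `beta_d`) of
#'   marker effects added to the sire/dam breeding values.
#' @param seed Integer master seed; every stage derives its own stream
#'   from it via [stage_seed()].
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(trait = "GL",
                       n_founders = 200L,
                       n_generations = 2L,
                       cows_per_generation = 500L,
                       n_service_sires = 40L,
                       n_parities = 3L,
                       male_frac = 0.15,
                       sire_skew = 1.1,
                       n_herds = 5L, n_years = 4L, n_months = 12L,
                       components = NULL,
                       trait_kind = NULL,
                       mu = NULL,
                       incidence = NULL,
                       fixed_effects = NULL,
                       max_services = 6L,
                       n_snps = 1000L,
                       maf_range = c(0.05, 0.5),
                       n_chr = 29L,
                       qtl_spec = NULL,
                       seed = 1L) {
  trait <- match.arg(trait, c("CR", "NRR56", "CE", "SB", "GL"))
  if (is.null(components)) components <- reference_components(trait)
  if (is.null(trait_kind))
    trait_kind <- switch(trait, CR = "binary", NRR56 = "binary",
                         CE = "ordinal3", SB = "binary", GL = "continuous")
  trait_kind <- match.arg(trait_kind, c("binary", "ordinal3", "continuous"))
  if (is.null(mu)) mu <- if (trait == "GL") 278.36 else 0
  if (is.null(incidence))
    incidence <- switch(trait,
                        CR = 0.43, NRR56 = 0.50, SB = 0.0667,
                        CE = c(0.0442, 0.0079), GL = NA_real_)
  if (is.null(fixed_effects)) {
    success <- trait %in% c("CR", "NRR56")
    sdl <- sqrt(sum(components) + components[["sigma_ssd"]])
    eff <- function(k, frac) seq(-1, 1, length.out = k) * frac * sdl
    fixed_effects <- if (success)
      list(technician = eff(5, 0.05), parity = eff(3, 0.05),
           semen_type = eff(2, 0.03), insem_number = eff(3, 0.04))
    else
      list(calf_sex = eff(2, 0.08), parity = eff(3, 0.06),
           calf_size = eff(3, 0.10))
  }
  g0 <- matrix(c(components[["sigma2_ss"]], components[["sigma_ssd"]],
                 components[["sigma_ssd"]], components[["sigma2_d"]]), 2, 2)
  check_psd2(g0)
  if (any(components[-2L] < 0)) stop("variances must be non-negative")
  if (maf_range[1] <= 0 || maf_range[2] > 0.5)
    stop("minor allele frequencies must lie in (0, 0.5]")
  ng <- max(1L, as.integer(n_generations))
  structure(list(trait = trait, n_founders = as.integer(n_founders),
                 n_generations = as.integer(n_generations),
                 cows_per_generation = rep_len(as.integer(cows_per_generation), ng),
                 male_frac = rep_len(male_frac, ng),
                 n_service_sires = as.integer(n_service_sires),
                 n_parities = as.integer(n_parities),
                 sire_skew = sire_skew,
                 n_herds = as.integer(n_herds), n_years = as.integer(n_years),
                 n_months = as.integer(n_months),
                 components = components, G0 = g0, trait_kind = trait_kind,
                 mu = mu, incidence = incidence, fixed_effects = fixed_effects,
                 max_services = as.integer(max_services),
                 n_snps = as.integer(n_snps), maf_range = maf_range,
                 n_chr = as.integer(n_chr), qtl_spec = qtl_spec,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Study conditions for the parameter-recovery harness
#'
#' The simulation configuration used to verify that AI-REML recovers the
#' reference gestation-length components: 40,000 records from 5,000 cows
#' (8 parities each) across three cohorts bred from 200 founders, with 80
#' contemporary service sires and 10 herds x 4 years x 12 months
#' contemporary groups.
#'
#' @param trait Trait whose reference components act as truth.
#' @param seed Master seed.
#' @return A [sim_config()].
#' @export
recovery_config <- function(trait = "GL", seed = 1L) {
  sim_config(trait = trait, n_founders = 200L, n_generations = 3L,
             cows_per_generation = c(500L, 2300L, 2300L),
             male_frac = c(0.2, 0, 0), n_service_sires = 80L,
             n_parities = 8L, n_herds = 10L, n_years = 4L, seed = seed)
}

check_psd2 <- function(G) {
  if (!isTRUE(all.equal(G[1, 2], G[2, 1])) ||
      G[1, 1] < 0 || G[2, 2] < 0 ||
      G[1, 2]^2 > G[1, 1] * G[2, 2] * (1 + 1e-10) + 1e-300)
    stop("G0 must be symmetric positive semi-definite")
  invisible(TRUE)
}

#' Per-stage seed derivation
#'
#' Expands one master seed into independent per-stage seeds by a fixed
#' counter scheme, so each simulation stage is reproducible on its own.
#' @param seed Integer master seed.
#' @param stage Stage name.
#' @return Integer seed (< 2^31).
#' @export
stage_seed <- function(seed, stage = c("pedigree", "breeding_values",
                                       "records", "genotypes", "gwas",
                                       "misc")) {
  stage <- match.arg(stage)
  k <- match(stage, c("pedigree", "breeding_values", "records", "genotypes",
                      "gwas", "misc"))
  as.integer((as.double(seed) + 999983 * k) %% 2147483629)
}

#' Simulate a topologically ordered pedigree
#'
#' Founders first, then `n_generations` cohorts of `cows_per_generation`
#' animals each; every non-founder receives a male sire and a female dam
#' drawn from earlier rows. Sex is assigned at random (roughly half male
#' in the founder cohort, mostly female afterwards, as in a dairy herd).
#'
#' @param config A [sim_config()].
#' @return A `ped_pedigree` with an extra `generation` column.
#' @export
simulate_pedigree <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_founders < 2L) stop("need at least 2 founders")
  set.seed(stage_seed(config$seed, "pedigree"))
  nf <- config$n_founders
  sex <- rep(c("M", "F"), length.out = nf)
  id <- sprintf("F%05d", seq_len(nf))
  sire <- rep(NA_character_, nf)
  dam <- rep(NA_character_, nf)
  gen <- rep(0L, nf)
  males <- id[sex == "M"]
  females <- id[sex == "F"]
  if (!length(males) || !length(females))
    stop("impossible mating pool: need both sexes among founders")
  cnt <- 0L
  for (g in seq_len(config$n_generations)) {
    ng <- config$cows_per_generation[g]
    nid <- sprintf("G%d_%05d", g, seq_len(ng))
    nm <- round(config$male_frac[g] * ng)
    nsex <- sample(c(rep("M", nm), rep("F", ng - nm)))
    nsire <- sample(males, ng, replace = TRUE)
    ndam <- sample(females, ng, replace = TRUE)
    id <- c(id, nid); sire <- c(sire, nsire); dam <- c(dam, ndam)
    sex <- c(sex, nsex); gen <- c(gen, rep(g, ng))
    males <- c(males, nid[nsex == "M"])
    females <- c(females, nid[nsex == "F"])
    cnt <- cnt + ng
  }
  ped <- sort_pedigree(data.frame(animal = id, sire = sire, dam = dam,
                                  sex = sex, stringsAsFactors = FALSE))
  ped$generation <- gen[match(ped$id, id)]
  ped
}

#' Gene-drop correlated sire/dam breeding values down a pedigree
#'
#' Founders are drawn from N(0, G0); each descendant is the parent average
#' plus a Mendelian-sampling deviation with covariance
#' `G0 * (0.5 - 0.25 * (F_s + F_d))` (one-known-parent and founder cases
#' use 0.75 - 0.25 F and 1 respectively). Over replicates the realized
#' covariance of the stacked values converges to `A (x) G0`.
#'
#' @param ped A `ped_pedigree`.
#' @param G0 2x2 genetic covariance of the service-sire and dam effects.
#' @param seed Integer seed.
#' @return Numeric matrix (animals x 2), columns `u_ss`, `u_d`, rownames
#'   pedigree ids.
#' @export
simulate_breeding_values <- function(ped, G0, seed = 1L) {
  stopifnot(inherits(ped, "ped_pedigree"))
  check_psd2(G0)
  set.seed(seed)
  n <- nrow(ped)
  F <- inbreeding(ped)
  ## matrix square root robust to singular G0
  ev <- eigen(G0, symmetric = TRUE)
  L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), 2) %*% t(ev$vectors)
  z <- matrix(stats::rnorm(2 * n), n, 2) %*% L   # N(0, G0) draws
  u <- matrix(0, n, 2, dimnames = list(ped$id, c("u_ss", "u_d")))
  si <- ped$sire_row; di <- ped$dam_row
  for (i in seq_len(n)) {
    if (si[i] > 0L && di[i] > 0L) {
      k <- 0.5 - 0.25 * (F[si[i]] + F[di[i]])
      u[i, ] <- 0.5 * (u[si[i], ] + u[di[i], ]) + sqrt(k) * z[i, ]
    } else if (si[i] > 0L || di[i] > 0L) {
      p <- max(si[i], di[i])
      u[i, ] <- 0.5 * u[p, ] + sqrt(0.75 - 0.25 * F[p]) * z[i, ]
    } else {
      u[i, ] <- z[i, ]
    }
  }
  u
}

## Zipf-like service-sire usage weights
sire_weights <- function(n, skew) {
  w <- seq_len(n)^(-skew)
  w / sum(w)
}

threshold_cuts <- function(config) {
  vl <- sum(config$components) + config$components[["sigma_ssd"]]
  sdl <- sqrt(vl)
  if (config$trait_kind == "binary") {
    config$mu + stats::qnorm(1 - config$incidence[1]) * sdl
  } else if (config$trait_kind == "ordinal3") {
    p23 <- sum(config$incidence)          # P(score > 1)
    p3 <- config$incidence[2]             # P(score 3)
    config$mu + stats::qnorm(c(1 - p23, 1 - p3)) * sdl
  } else NA_real_
}

code_phenotype <- function(latent, config) {
  cuts <- threshold_cuts(config)
  switch(config$trait_kind,
         continuous = latent,
         binary = as.integer(latent > cuts[1]),
         ordinal3 = 1L + (latent > cuts[1]) + (latent > cuts[2]))
}

#' Simulate reproduction records under the correlated sire/dam model
#'
#' Generates analysis-ready trait records whose phenotypes follow the
#' model exactly: `y = mu + sum(fixed) + u_ss(sire) + u_d(cow) + pe_ss +
#' pe_d + hym + e`, with binary/ordinal traits obtained by thresholding
#' the latent value at the configured cut points. Success traits (binary
#' CR-like) produce one row per insemination, repeating within a
#' cow-parity until conception or the service cap; calving traits produce
#' one row per cow-parity.
#'
#' @param ped A `ped_pedigree` (from [simulate_pedigree()]).
#' @param bv Breeding-value matrix from [simulate_breeding_values()].
#' @param config A [sim_config()].
#' @return List with `records` (data frame), and `truth` (list carrying
#'   the simulated components, breeding values, permanent-environment and
#'   herd-year-month effects, and the cut points).
#' @export
simulate_records <- function(ped, bv, config) {
  stopifnot(inherits(ped, "ped_pedigree"), inherits(config, "sim_config"))
  set.seed(stage_seed(config$seed, "records"))
  comp <- config$components
  males <- ped$id[ped$sex == "M"]
  if (length(males) < config$n_service_sires)
    stop("not enough males in pedigree for the requested service sires")
  non_founder_f <- ped$id[ped$sex == "F" & ped$sire_row > 0L]
  cows <- if (length(non_founder_f) >= 2L) non_founder_f
          else ped$id[ped$sex == "F"]
  ## service sires: prefer the youngest male cohort (contemporary bulls)
  mrow <- match(males, ped$id)
  mgen <- if ("generation" %in% names(ped)) ped$generation[mrow] else 0L
  sires <- males[order(-mgen, mrow)][seq_len(config$n_service_sires)]
  w <- sire_weights(length(sires), config$sire_skew)
  pe_ss <- stats::setNames(stats::rnorm(length(sires), 0,
                                        sqrt(comp[["sigma2_pess"]])), sires)
  pe_d <- stats::setNames(stats::rnorm(length(cows), 0,
                                       sqrt(comp[["sigma2_ped"]])), cows)
  herd_of <- stats::setNames(sample.int(config$n_herds, length(cows),
                                        replace = TRUE), cows)
  success <- config$trait %in% c("CR", "NRR56") &&
    config$trait_kind != "continuous"
  cuts <- threshold_cuts(config)
  fx <- config$fixed_effects

  ## cow-parity grid
  cp_cow <- rep(cows, each = config$n_parities)
  cp_par <- rep(seq_len(config$n_parities), times = length(cows))
  ncp <- length(cp_cow)
  cp_year <- sample.int(config$n_years, ncp, replace = TRUE)
  cp_month <- sample.int(config$n_months, ncp, replace = TRUE)
  cp_lbl <- paste0("h", herd_of[cp_cow], "_y", cp_year, "_m", cp_month)
  labs <- unique(cp_lbl)
  hym_eff <- stats::setNames(stats::rnorm(length(labs), 0,
                                          sqrt(comp[["sigma2_hym"]])), labs)

  if (!success) {
    sire <- sample(sires, ncp, replace = TRUE, prob = w)
    lev <- lapply(fx, function(e) sample.int(length(e), ncp, replace = TRUE))
    fixed_sum <- Reduce(`+`, Map(function(e, l) e[l], fx, lev))
    latent <- config$mu + fixed_sum + bv[sire, "u_ss"] + bv[cp_cow, "u_d"] +
      pe_ss[sire] + pe_d[cp_cow] + hym_eff[cp_lbl] +
      stats::rnorm(ncp, 0, sqrt(comp[["sigma2_e"]]))
    records <- data.frame(cow = cp_cow, sire = sire, parity = cp_par,
                          herd = herd_of[cp_cow], year = cp_year,
                          month = cp_month, hym = cp_lbl,
                          calf_sex = lev$calf_sex,
                          calf_size = lev$calf_size,
                          latent = unname(latent),
                          y = code_phenotype(unname(latent), config),
                          stringsAsFactors = FALSE)
  } else {
    ## candidate services 1..max_services per cow-parity; keep up to the
    ## first conception
    S <- config$max_services
    ns <- ncp * S
    sv_cp <- rep(seq_len(ncp), each = S)
    sv_no <- rep(seq_len(S), times = ncp)
    sire <- sample(sires, ns, replace = TRUE, prob = w)
    lev <- lapply(fx[setdiff(names(fx), "insem_number")],
                  function(e) sample.int(length(e), ns, replace = TRUE))
    ins_lev <- pmin(sv_no, length(fx$insem_number))
    fixed_sum <- Reduce(`+`, Map(function(e, l) e[l],
                                 fx[names(lev)], lev)) +
      fx$insem_number[ins_lev]
    latent <- config$mu + fixed_sum + bv[sire, "u_ss"] +
      bv[cp_cow[sv_cp], "u_d"] + pe_ss[sire] + pe_d[cp_cow[sv_cp]] +
      hym_eff[cp_lbl[sv_cp]] + stats::rnorm(ns, 0, sqrt(comp[["sigma2_e"]]))
    y <- code_phenotype(unname(latent), config)
    ## first success per cow-parity (or cap)
    succ <- matrix(y == 1L, nrow = S)
    first <- apply(succ, 2L, function(s) if (any(s)) which(s)[1] else S)
    keep <- sv_no <= first[sv_cp]
    ## enforce at most one success per parity: services after the first
    ## conception are dropped by construction
    records <- data.frame(cow = cp_cow[sv_cp][keep], sire = sire[keep],
                          parity = cp_par[sv_cp][keep],
                          herd = herd_of[cp_cow[sv_cp]][keep],
                          year = cp_year[sv_cp][keep],
                          month = cp_month[sv_cp][keep],
                          hym = cp_lbl[sv_cp][keep],
                          technician = lev$technician[keep],
                          semen_type = lev$semen_type[keep],
                          insem_number = ins_lev[keep],
                          latent = unname(latent)[keep], y = y[keep],
                          stringsAsFactors = FALSE)
  }
  rownames(records) <- NULL
  truth <- list(components = comp, G0 = config$G0, bv = bv, pe_ss = pe_ss,
                pe_d = pe_d, hym = hym_eff, cuts = cuts, mu = config$mu,
                fixed_effects = config$fixed_effects)
  list(records = records, truth = truth)
}

#' Simulate biallelic SNP genotypes by gene dropping
#'
#' Founder alleles are drawn per SNP from the configured minor-allele
#' frequency distribution (uniform over `maf_range`); descendants receive
#' one allele from each known parent by Mendelian transmission, so every
#' offspring shares at least one allele with each parent at every locus.
#' SNPs are unlinked.
#'
#' @param ped A `ped_pedigree`.
#' @param config A [sim_config()] (uses `n_snps`, `maf_range`, `n_chr`,
#'   `seed`).
#' @return List with `genotypes` (integer matrix animals x SNPs, additive
#'   codes 0/1/2) and `map` (data frame `snp`, `chr`, `pos`, `a1`, `a2`,
#'   `maf` = founder design frequency).
#' @export
simulate_genotypes <- function(ped, config) {
  stopifnot(inherits(ped, "ped_pedigree"), inherits(config, "sim_config"))
  if (config$n_snps < 1L) stop("need at least one SNP")
  set.seed(stage_seed(config$seed, "genotypes"))
  n <- nrow(ped); m <- config$n_snps
  maf <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  chr <- sort(sample.int(config$n_chr, m, replace = TRUE))
  pos <- unlist(lapply(split(seq_len(m), chr), function(ix)
    sort(sample.int(1.5e8, length(ix)))), use.names = FALSE)
  G <- matrix(0L, n, m, dimnames = list(ped$id, sprintf("snp%05d", seq_len(m))))
  si <- ped$sire_row; di <- ped$dam_row
  gamete <- function(g) {
    ## one allele from a parent with genotype vector g
    a <- integer(length(g))
    a[g == 2L] <- 1L
    het <- g == 1L
    a[het] <- stats::rbinom(sum(het), 1L, 0.5)
    a
  }
  for (i in seq_len(n)) {
    a1 <- if (si[i] > 0L) gamete(G[si[i], ]) else stats::rbinom(m, 1L, maf)
    a2 <- if (di[i] > 0L) gamete(G[di[i], ]) else stats::rbinom(m, 1L, maf)
    G[i, ] <- a1 + a2
  }
  map <- data.frame(snp = colnames(G), chr = chr, pos = pos,
                    a1 = "A", a2 = "B", maf = maf, stringsAsFactors = FALSE)
  list(genotypes = G, map = map)
}

#' Add marker (QTL) effects to simulated breeding values
#'
#' For each row of `qtl_spec` the centered additive genotype code of the
#' named SNP, times the specified effect, is added to the sire and/or dam
#' breeding value, so downstream association power is testable.
#'
#' @param bv Breeding-value matrix.
#' @param geno Output of [simulate_genotypes()].
#' @param qtl_spec Data frame with columns `snp` (index or name),
#'   `beta_ss`, `beta_d`.
#' @return Updated breeding-value matrix.
#' @export
apply_qtl_effects <- function(bv, geno, qtl_spec) {
  if (is.null(qtl_spec) || !nrow(qtl_spec)) return(bv)
  for (i in seq_len(nrow(qtl_spec))) {
    j <- qtl_spec$snp[i]
    g <- geno$genotypes[, j]
    gc <- g - mean(g)
    ids <- intersect(rownames(bv), names(gc))
    bv[ids, "u_ss"] <- bv[ids, "u_ss"] + qtl_spec$beta_ss[i] * gc[ids]
    bv[ids, "u_d"] <- bv[ids, "u_d"] + qtl_spec$beta_d[i] * gc[ids]
  }
  bv
}

#' Simulate a complete synthetic herd
#'
#' Convenience wrapper running pedigree, breeding-value, genotype and
#' record simulation from one configuration.
#'
#' @param config A [sim_config()].
#' @param genotypes Also simulate genotypes?
#' @return List with `pedigree`, `bv`, `records`, `truth`, and optionally
#'   `geno`.
#' @export
simulate_herd <- function(config, genotypes = FALSE) {
  ped <- simulate_pedigree(config)
  bv <- simulate_breeding_values(ped, config$G0,
                                 stage_seed(config$seed, "breeding_values"))
  geno <- NULL
  if (genotypes || !is.null(config$qtl_spec)) {
    geno <- simulate_genotypes(ped, config)
    bv <- apply_qtl_effects(bv, geno, config$qtl_spec)
  }
  rec <- simulate_records(ped, bv, config)
  out <- list(pedigree = ped, bv = bv, records = rec$records,
              truth = rec$truth)
  if (!is.null(geno)) out$geno <- geno
  out
}
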