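# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the relationship oracle is a memoised pairwise
# recursion (not the tabular sweep), and the likelihood/BLUP oracles work
# from the dense phenotypic covariance matrix V.

# pairwise numerator relationship by the classical recursion
# a(i, j) with parents looked up from integer vectors sire/dam (0 = unknown)
oracle_a_pair <- function(sire, dam) {
  memo <- new.env(parent = emptyenv())
  a <- function(i, j) {
    if (i == 0L || j == 0L) return(0)
    if (i > j) { tmp <- i; i <- j; j <- tmp }
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    val <- if (i == j) {
      1 + 0.5 * a(sire[i], dam[i])
    } else {
      # j is the younger animal by topological order
      0.5 * (a(i, sire[j]) + a(i, dam[j]))
    }
    memo[[key]] <- val
    val
  }
  a
}

oracle_a_matrix <- function(ped) {
  n <- nrow(ped)
  a <- oracle_a_pair(ped$sire_row, ped$dam_row)
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) for (j in i:n) A[i, j] <- A[j, i] <- a(i, j)
  A
}

# dense phenotypic covariance of a design at given components
oracle_dense_v <- function(d, comp, A) {
  G0 <- matrix(c(comp[["sigma2_ss"]], comp[["sigma_ssd"]],
                 comp[["sigma_ssd"]], comp[["sigma2_d"]]), 2, 2)
  Z <- cbind(as.matrix(d$Z1), as.matrix(d$Z2))
  Z %*% kronecker(G0, A) %*% t(Z) +
    as.matrix(Matrix::tcrossprod(d$W1)) * comp[["sigma2_pess"]] +
    as.matrix(Matrix::tcrossprod(d$W2)) * comp[["sigma2_ped"]] +
    as.matrix(Matrix::tcrossprod(d$Zh)) * comp[["sigma2_hym"]] +
    diag(d$n) * comp[["sigma2_e"]]
}

# dense restricted log-likelihood (same constant convention as the package)
oracle_reml_loglik <- function(d, comp, A) {
  V <- oracle_dense_v(d, comp, A)
  X <- as.matrix(d$X)
  y <- d$y
  Vi <- solve(V)
  XVX <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(XVX, t(X) %*% Vi)
  -0.5 * (as.numeric(determinant(V)$modulus) +
            as.numeric(determinant(XVX)$modulus) +
            drop(t(y) %*% P %*% y))
}

# dense GLS fixed effects and BLUP random effects
oracle_gls_blup <- function(d, comp, A) {
  V <- oracle_dense_v(d, comp, A)
  X <- as.matrix(d$X)
  y <- d$y
  Vi <- solve(V)
  XVX <- t(X) %*% Vi %*% X
  beta <- solve(XVX, t(X) %*% Vi %*% y)
  P <- Vi - Vi %*% X %*% solve(XVX, t(X) %*% Vi)
  G0 <- matrix(c(comp[["sigma2_ss"]], comp[["sigma_ssd"]],
                 comp[["sigma_ssd"]], comp[["sigma2_d"]]), 2, 2)
  Z <- cbind(as.matrix(d$Z1), as.matrix(d$Z2))
  u <- kronecker(G0, A) %*% t(Z) %*% P %*% y
  list(beta = drop(beta), u = drop(u), P = P, V = V)
}

# small random pedigree as a raw data frame (animal/sire/dam triples)
random_pedigree_df <- function(n, n_founders = max(3L, n %/% 4L),
                               seed = 1L) {
  set.seed(seed)
  id <- sprintf("A%03d", seq_len(n))
  sire <- dam <- rep(NA_character_, n)
  sex <- c(rep(c("M", "F"), length.out = n_founders),
           sample(c("M", "F"), n - n_founders, replace = TRUE))
  for (i in (n_founders + 1L):n) {
    males <- which(sex[1:(i - 1L)] == "M")
    females <- which(sex[1:(i - 1L)] == "F")
    sire[i] <- id[sample(males, 1L)]
    dam[i] <- id[sample(females, 1L)]
  }
  data.frame(animal = id, sire = sire, dam = dam, sex = sex,
             stringsAsFactors = FALSE)
}

# small herd for mixed-model toy problems
toy_herd <- function(seed = 7L, trait = "GL", n_founders = 16L,
                     cows_per_generation = 12L, n_service_sires = 4L,
                     n_parities = 2L) {
  cfg <- sim_config(trait = trait, n_founders = n_founders,
                    n_generations = 1L,
                    cows_per_generation = cows_per_generation,
                    male_frac = 0, n_service_sires = n_service_sires,
                    n_parities = n_parities, n_herds = 2L, n_years = 2L,
                    n_months = 3L, seed = seed)
  simulate_herd(cfg)
}
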