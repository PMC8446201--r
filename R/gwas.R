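#' Hardy-Weinberg equilibrium test from genotype counts
#'
#' One-degree-of-freedom chi-squared goodness-of-fit test of observed
#' genotype counts against Hardy-Weinberg proportions, with an optional
#' exact test (conditional enumeration of heterozygote counts) for small
#' samples.
#'
#' @param counts Integer vector `c(n0, n1, n2)` of genotype counts
#'   (copies of the alternate allele).
#' @param exact Use the exact conditional test instead of chi-squared.
#' @return p-value.
#' @export
hwe_test <- function(counts, exact = FALSE) {
  stopifnot(length(counts) == 3, all(counts >= 0))
  n <- sum(counts)
  if (n == 0) stop("no genotypes")
  n0 <- counts[1]; n1 <- counts[2]; n2 <- counts[3]
  na <- 2 * n2 + n1          # alternate allele count
  if (exact) {
    ## enumerate heterozygote counts compatible with the allele counts
    nb <- 2 * n - na
    rare <- min(na, nb)
    h_all <- seq(rare %% 2, rare, by = 2)
    logpr <- vapply(h_all, function(h) {
      hom_r <- (rare - h) / 2
      hom_c <- (n - h - hom_r)
      lgamma(n + 1) - lgamma(hom_r + 1) - lgamma(h + 1) - lgamma(hom_c + 1) +
        h * log(2)
    }, numeric(1))
    pr <- exp(logpr - max(logpr))
    pr <- pr / sum(pr)
    obs <- pr[match(n1, h_all)]
    return(min(1, sum(pr[pr <= obs + 1e-12])))
  }
  p <- na / (2 * n)
  e <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  if (any(e == 0)) return(1)
  x2 <- sum((counts - e)^2 / e)
  stats::pchisq(x2, df = 1, lower.tail = FALSE)
}

observed_maf <- function(g) {
  g <- g[!is.na(g)]
  if (!length(g)) return(NA_real_)
  f <- mean(g) / 2
  min(f, 1 - f)
}

#' Genotype quality control
#'
#' Removes SNPs with minor allele frequency below `maf_min`, extreme
#' Hardy-Weinberg deviation (p below `hwe_min`), unknown chromosome or
#' position, or imputation concordance at or below `concordance_min`.
#'
#' @param geno List with `genotypes` (animals x SNPs, codes 0/1/2/NA) and
#'   `map` (`snp`, `chr`, `pos`).
#' @param concordance Optional per-SNP imputation concordance vector.
#' @param maf_min,hwe_min,concordance_min Filter thresholds.
#' @return List with filtered `genotypes`/`map` and `report`: counts
#'   removed per rule (a SNP failing several rules is counted in each)
#'   and the survivor count.
#' @export
qc_filter <- function(geno, concordance = NULL, maf_min = 0.05,
                      hwe_min = 1e-6, concordance_min = 0.90) {
  G <- geno$genotypes
  map <- geno$map
  stopifnot(ncol(G) == nrow(map))
  bad_code <- !(G %in% c(0L, 1L, 2L) | is.na(G))
  if (any(bad_code)) stop("invalid genotype codes")
  maf <- apply(G, 2L, observed_maf)
  hwe <- apply(G, 2L, function(g) {
    tb <- tabulate(g[!is.na(g)] + 1L, nbins = 3L)
    if (sum(tb) == 0) return(NA_real_)
    hwe_test(tb)
  })
  fail_maf <- is.na(maf) | maf < maf_min
  fail_hwe <- !is.na(hwe) & hwe < hwe_min
  fail_pos <- is.na(map$chr) | is.na(map$pos) | map$chr == "" |
    map$pos < 0
  fail_conc <- if (!is.null(concordance)) concordance <= concordance_min
               else rep(FALSE, ncol(G))
  drop <- fail_maf | fail_hwe | fail_pos | fail_conc
  if (all(drop)) stop("all SNPs removed by QC")
  report <- c(maf = sum(fail_maf), hwe = sum(fail_hwe),
              position = sum(fail_pos), concordance = sum(fail_conc),
              removed = sum(drop), kept = sum(!drop))
  out_map <- map[!drop, , drop = FALSE]
  out_map$maf_observed <- maf[!drop]
  rownames(out_map) <- NULL
  list(genotypes = G[, !drop, drop = FALSE], map = out_map,
       report = report)
}

#' Benjamini-Hochberg false-discovery-rate control
#'
#' Step-up procedure at level `alpha`: reject the k smallest p-values
#' where k is the largest index with `p_(k) <= k * alpha / m`.
#'
#' @param p Vector of p-values in `(0, 1]`.
#' @param alpha FDR level (default 0.05).
#' @return List with `reject` (logical), `q` (BH-adjusted p-values),
#'   `threshold` (largest rejected p, `NA` if none) and `n_reject`.
#' @export
bh_fdr <- function(p, alpha = 0.05) {
  if (!length(p)) stop("empty p-value vector")
  stopifnot(all(p > 0), all(p <= 1))
  q <- stats::p.adjust(p, method = "BH")
  reject <- q <= alpha
  list(reject = reject, q = q,
       threshold = if (any(reject)) max(p[reject]) else NA_real_,
       n_reject = sum(reject))
}

#' Genomic inflation factor
#'
#' `lambda = median(qchisq(1 - p, 1)) / qchisq(0.5, 1)`; approximately 1
#' for a well-calibrated scan.
#'
#' @param p Vector of p-values in `(0, 1]`.
#' @return Scalar lambda.
#' @export
inflation_factor <- function(p) {
  if (!length(p)) stop("empty p-value vector")
  stopifnot(all(p > 0), all(p <= 1))
  stats::median(stats::qchisq(p, df = 1, lower.tail = FALSE)) /
    stats::qchisq(0.5, df = 1)
}

## weighted least-squares scan of every SNP given a covariate matrix;
## SNPs listed in `excl` (a list: per tested SNP, covariate columns to
## drop) are re-tested individually without the excluded covariates.
wls_scan <- function(G, y, w, cov, df_extra = 0L) {
  sw <- sqrt(w)
  ys <- y * sw
  covs <- cov * sw
  qrc <- qr(covs)
  ry <- qr.resid(qrc, ys)
  ## residualize all SNPs against the covariates
  Gs <- G * sw
  RG <- Gs - qr.fitted(qrc, Gs)
  gss <- colSums(RG^2)
  gy <- as.numeric(crossprod(RG, ry))
  b <- ifelse(gss > 1e-10, gy / gss, NA_real_)
  df <- length(y) - ncol(cov) - 1L - df_extra
  rss <- sum(ry^2) - ifelse(gss > 1e-10, gy^2 / gss, 0)
  se <- sqrt(pmax(rss / df, 0) / pmax(gss, 1e-300))
  tval <- b / se
  p <- 2 * stats::pt(-abs(tval), df = df)
  p[is.na(p)] <- 1
  list(effect = b, p = pmin(pmax(p, 1e-300), 1), df = df)
}

## maximum likelihood of y ~ N(mu, sg2 * SS' + se2 * I) with S the
## column-scaled candidate pseudo-QTN matrix; low-rank evaluation
lowrank_ml <- function(y, S) {
  n <- length(y)
  t <- ncol(S)
  B <- crossprod(S)
  eg <- eigen(B, symmetric = TRUE)
  keep <- eg$values > 1e-8 * max(eg$values, 1)
  lam <- eg$values[keep]
  U <- S %*% eg$vectors[, keep, drop = FALSE] %*%
    diag(1 / sqrt(lam), sum(keep))
  zy <- as.numeric(crossprod(U, y))
  z1 <- as.numeric(crossprod(U, rep(1, n)))
  yy <- sum(y^2); y1 <- sum(y); n1 <- n
  negll <- function(ldelta) {
    delta <- exp(ldelta)
    d <- delta * lam + 1
    ## GLS intercept
    a11 <- n1 - sum(z1^2 * (1 - 1 / d))
    a1y <- y1 - sum(z1 * zy * (1 - 1 / d))
    mu <- a1y / a11
    ## quadratic form (y - mu)' V^-1 (y - mu) with V = delta K + I
    q <- (yy - sum(zy^2 * (1 - 1 / d))) - 2 * mu * a1y + mu^2 * a11
    ldet <- sum(log(d))
    s2 <- q / n
    0.5 * (n * log(s2) + ldet + n)
  }
  op <- stats::optimize(negll, c(-12, 12))
  -op$objective
}

#' FarmCPU-style multi-locus association scan
#'
#' Iterative two-step procedure on de-regressed proofs: (i) a
#' fixed-effect step tests every SNP by weighted least squares with the
#' current pseudo-QTNs as covariates, excluding any pseudo-QTN within
#' `excl_window` of the tested SNP; (ii) a selection step bins SNPs by
#' position over a grid of bin sizes, takes the best SNP per bin, and
#' chooses the pseudo-QTN set (bin size x set size) maximizing the
#' likelihood of a random-effect model whose kinship is built from the
#' candidate QTNs. Iteration stops when the significant-SNP set is
#' stable, when no SNP passes the seeding threshold (first iteration), or
#' at `max_iter`. With `max_qtn = 0` the scan reduces exactly to
#' single-marker weighted regression.
#'
#' @param geno List with `genotypes` and `map` (post-QC).
#' @param drp Named response vector (de-regressed proofs), names matching
#'   genotype rownames.
#' @param weights Optional record weights (DRP weights); default 1.
#' @param covariates Optional numeric matrix of fixed covariates.
#' @param options List overriding: `max_qtn` (10), `bin_sizes`
#'   (1e4, 1e5, 1e6 bp), `qtn_counts` (5, 10, ..., max_qtn),
#'   `excl_window` (1e7 bp), `max_iter` (10), `alpha` (0.05),
#'   `p_threshold` (0.01/m seeding threshold).
#' @return List of class `gess_gwas`: `result` (per-SNP `snp`, `chr`,
#'   `pos`, `maf`, `effect`, `p`, `q`, `significant`), `lambda`,
#'   `qtns`, `iterations`, `fdr_threshold`, `alpha`.
#' @export
farmcpu_scan <- function(geno, drp, weights = NULL, covariates = NULL,
                         options = list()) {
  opt <- utils::modifyList(
    list(max_qtn = 10L, bin_sizes = c(1e4, 1e5, 1e6), qtn_counts = NULL,
         excl_window = 1e7, max_iter = 10L, alpha = 0.05,
         p_threshold = NULL), options)
  G <- geno$genotypes
  map <- geno$map
  ids <- intersect(rownames(G), names(drp))
  if (length(ids) < 30) stop("need at least 30 animals with DRP and genotypes")
  G <- G[ids, , drop = FALSE]
  y <- as.numeric(drp[ids])
  if (stats::sd(y) == 0) stop("constant DRP")
  w <- if (is.null(weights)) rep(1, length(y)) else as.numeric(weights[ids])
  m <- ncol(G)
  if (is.null(opt$qtn_counts))
    opt$qtn_counts <- if (opt$max_qtn > 0) unique(pmin(seq(5, 50, by = 5),
                                                       opt$max_qtn)) else 0L
  if (is.null(opt$p_threshold)) opt$p_threshold <- 0.01 / m
  ## mean-impute missing genotypes
  if (anyNA(G)) {
    mu_g <- colMeans(G, na.rm = TRUE)
    na_ix <- which(is.na(G), arr.ind = TRUE)
    G[na_ix] <- mu_g[na_ix[, 2]]
  }
  storage.mode(G) <- "double"
  base_cov <- cbind(intercept = rep(1, length(y)), covariates)
  maf <- apply(G, 2L, function(g) { f <- mean(g) / 2; min(f, 1 - f) })

  qtns <- integer(0)
  prev_sig <- NULL
  it <- 0L
  repeat {
    it <- it + 1L
    ## drop collinear pseudo-QTNs
    if (length(qtns) > 1L) {
      cc <- abs(stats::cor(G[, qtns, drop = FALSE]))
      diag(cc) <- 0
      while (any(cc > 0.99)) {
        drop1 <- which.max(apply(cc, 1L, max))
        qtns <- qtns[-drop1]
        if (length(qtns) < 2L) break
        cc <- abs(stats::cor(G[, qtns, drop = FALSE]))
        diag(cc) <- 0
      }
    }
    cov <- cbind(base_cov, G[, qtns, drop = FALSE])
    scan <- wls_scan(G, y, w, cov)
    ## re-test SNPs near a pseudo-QTN without the offending covariates
    if (length(qtns)) {
      for (j in seq_len(m)) {
        near <- qtns[map$chr[qtns] == map$chr[j] &
                       abs(map$pos[qtns] - map$pos[j]) <= opt$excl_window]
        if (!length(near)) next
        keep_q <- setdiff(qtns, near)
        cov_j <- cbind(base_cov, G[, keep_q, drop = FALSE])
        s1 <- wls_scan(G[, j, drop = FALSE], y, w, cov_j)
        scan$effect[j] <- s1$effect
        scan$p[j] <- s1$p
      }
    }
    p <- scan$p
    if (it == 1L && min(p) > opt$p_threshold) break  # nothing to seed on
    if (opt$max_qtn == 0L) break
    sig <- which(bh_fdr(p, opt$alpha)$reject)
    if (!is.null(prev_sig) && identical(sig, prev_sig)) break
    prev_sig <- sig
    if (it >= opt$max_iter) break
    ## pseudo-QTN selection over the bin grid
    ord <- order(p)
    best_ll <- -Inf; best_set <- qtns
    for (b in opt$bin_sizes) {
      bin <- paste0(map$chr, "_", floor(map$pos / b))
      first <- ord[!duplicated(bin[ord])]
      for (t in opt$qtn_counts) {
        cand <- utils::head(first, t)
        cand <- cand[p[cand] < 0.01]      # only promising markers
        if (!length(cand)) next
        S <- scale(G[, cand, drop = FALSE]) / sqrt(length(cand))
        S[is.nan(S)] <- 0
        ll <- lowrank_ml(y, S)
        if (ll > best_ll) { best_ll <- ll; best_set <- cand }
      }
    }
    new_qtns <- sort(unique(best_set))
    if (identical(new_qtns, sort(qtns)) && it > 1L) break
    qtns <- new_qtns
  }
  fdr <- bh_fdr(scan$p, opt$alpha)
  result <- data.frame(snp = map$snp, chr = map$chr, pos = map$pos,
                       maf = maf, effect = scan$effect, p = scan$p,
                       q = fdr$q, significant = fdr$reject,
                       stringsAsFactors = FALSE)
  structure(list(result = result, lambda = inflation_factor(scan$p),
                 qtns = map$snp[qtns], iterations = it,
                 fdr_threshold = fdr$threshold, alpha = opt$alpha),
            class = "gess_gwas")
}

#' Q-Q and Manhattan plot data
#'
#' Plot-ready tables from a completed scan: sorted expected/observed
#' `-log10(p)` pairs, cumulative genome coordinates per SNP, and the
#' FDR threshold line.
#'
#' @param scan A `gess_gwas`.
#' @return List with `qq` (data frame `expected`, `observed`),
#'   `manhattan` (`snp`, `chr`, `pos`, `genome_pos`, `logp`,
#'   `significant`) and `threshold_logp`.
#' @export
qq_manhattan_data <- function(scan) {
  stopifnot(inherits(scan, "gess_gwas"))
  r <- scan$result
  m <- nrow(r)
  qq <- data.frame(expected = -log10(stats::ppoints(m)),
                   observed = sort(-log10(r$p), decreasing = TRUE))
  ord <- order(suppressWarnings(as.numeric(r$chr)), r$chr, r$pos)
  rr <- r[ord, ]
  offs <- c(0, cumsum(as.numeric(
    tapply(rr$pos, factor(rr$chr, levels = unique(rr$chr)), max))))
  chri <- match(rr$chr, unique(rr$chr))
  man <- data.frame(snp = rr$snp, chr = rr$chr, pos = rr$pos,
                    genome_pos = rr$pos + offs[chri], logp = -log10(rr$p),
                    significant = rr$significant, stringsAsFactors = FALSE)
  list(qq = qq, manhattan = man,
       threshold_logp = if (is.na(scan$fdr_threshold)) NA_real_
                        else -log10(scan$fdr_threshold))
}
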