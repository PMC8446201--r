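#' Per-trait model specification
#'
#' Fixed-effect layout of the correlated service-sire/dam model: AI
#' technician, parity, semen type and insemination number for the
#' insemination success traits (CR, NRR56); calf sex, parity and calf-size
#' group for the calving traits (CE, SB, GL). Random terms are always the
#' correlated genetic effects of service sire (`u_ss`) and dam/cow
#' (`u_d`), the two permanent-environment effects, the herd-year-month
#' contemporary group and the residual.
#'
#' @param trait Trait name.
#' @param response Response column (default `"y"`).
#' @param fixed Character vector of fixed-effect factor columns
#'   (defaulted from the trait).
#' @return A list of class `trait_spec`.
#' @export
trait_model_spec <- function(trait = "GL", response = "y", fixed = NULL) {
  trait <- match.arg(trait, c("CR", "NRR56", "CE", "SB", "GL"))
  if (is.null(fixed))
    fixed <- if (trait %in% c("CR", "NRR56"))
      c("technician", "parity", "semen_type", "insem_number")
    else c("calf_sex", "parity", "calf_size")
  structure(list(trait = trait, response = response, fixed = fixed),
            class = "trait_spec")
}

## sparse indicator matrix: rows of `f` (a factor) x levels
indicator <- function(f) {
  f <- droplevels(as.factor(f))
  Matrix::sparseMatrix(i = seq_along(f), j = as.integer(f), x = 1,
                       dims = c(length(f), nlevels(f)),
                       dimnames = list(NULL, levels(f)))
}

#' Build the design matrices of the sire/dam mixed model
#'
#' Constructs the response and all incidence matrices: `X` (fixed effects
#' with reference-level constraints; rank-deficient columns dropped),
#' `Z1`/`Z2` (genetic effects, indexed by service sire and by cow over
#' *all* pedigree animals), `W1`/`W2` (permanent environment of sires and
#' cows with records) and `Zh` (herd-year-month).
#'
#' @param records Edited trait records; must contain the spec's response
#'   and fixed columns plus `cow`, `sire`, `hym`.
#' @param spec A [trait_model_spec()].
#' @param ped A `ped_pedigree` containing every cow and service sire.
#' @return A list of class `gess_design`.
#' @export
build_design <- function(records, spec, ped) {
  stopifnot(inherits(spec, "trait_spec"), inherits(ped, "ped_pedigree"))
  need <- c(spec$response, spec$fixed, "cow", "sire", "hym")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("records lack columns: ", paste(miss, collapse = ", "))
  out <- setdiff(unique(c(records$cow, records$sire)), ped$id)
  if (length(out)) stop("animals absent from pedigree: ",
                        paste(utils::head(out, 5), collapse = ", "))
  y <- as.numeric(records[[spec$response]])
  n <- length(y)
  ## fixed effects with intercept; drop rank-deficient columns
  fml <- stats::as.formula(paste("~", paste(
    sprintf("factor(%s)", spec$fixed), collapse = " + ")))
  X <- stats::model.matrix(fml, data = records)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
  X <- Matrix::Matrix(X, sparse = TRUE)
  q <- nrow(ped)
  z_idx <- function(ids) Matrix::sparseMatrix(
    i = seq_len(n), j = match(ids, ped$id), x = 1, dims = c(n, q),
    dimnames = list(NULL, ped$id))
  Z1 <- z_idx(records$sire)
  Z2 <- z_idx(records$cow)
  W1 <- indicator(records$sire)
  W2 <- indicator(records$cow)
  Zh <- indicator(records$hym)
  structure(list(y = y, X = X, Z1 = Z1, Z2 = Z2, W1 = W1, W2 = W2, Zh = Zh,
                 n = n, p = ncol(X), q = q,
                 n_pe_ss = ncol(W1), n_pe_d = ncol(W2), n_hym = ncol(Zh),
                 ped_ids = ped$id, ped = ped, spec = spec),
            class = "gess_design")
}

## block index bookkeeping: order [beta, u_ss(q), u_d(q), pe_ss, pe_d, hym]
design_blocks <- function(d) {
  sizes <- c(fixed = d$p, u_ss = d$q, u_d = d$q, pe_ss = d$n_pe_ss,
             pe_d = d$n_pe_d, hym = d$n_hym)
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1L
  Map(function(s, e) s:e, starts, ends)
}

## inverse of the 2x2 genetic covariance, ridge-stabilized if singular
g0_inverse <- function(G0) {
  det <- G0[1, 1] * G0[2, 2] - G0[1, 2]^2
  if (det <= 1e-12 * max(G0[1, 1] * G0[2, 2], 1e-300)) {
    warning("singular sire/dam genetic covariance; ridge-stabilized")
    G0 <- G0 + diag(2) * (1e-8 * max(mean(diag(G0)), 1e-12))
  }
  solve(G0)
}

#' Assemble Henderson's mixed-model equations
#'
#' Coefficient matrix in residual-precision units:
#' `C = M' M / sigma2_e + diag(0, G0^{-1} (x) A^{-1}, I/sigma2_pess,
#' I/sigma2_ped, I/sigma2_hym)` with `M = [X Z1 Z2 W1 W2 Zh]`, and right
#' hand side `M' y / sigma2_e`. The stacked genetic effect `[u_ss; u_d]`
#' (animal-major within effect) has prior covariance `G0 (x) A`.
#'
#' @param design A `gess_design` from [build_design()] (or raw records,
#'   in which case `spec` and `ped` must be supplied and the design is
#'   built on the fly).
#' @param vc A `gess_varcomp` of current components.
#' @param Ainv Sparse A-inverse over the design's pedigree (computed from
#'   `ped` if missing).
#' @param spec,ped Used only when `design` is a records data frame.
#' @return List of class `gess_mme` with elements `C`, `rhs`, `blocks`,
#'   `design`, `vc`.
#' @export
build_mme <- function(design, vc, Ainv = NULL, spec = NULL, ped = NULL) {
  if (!inherits(design, "gess_design")) {
    stopifnot(!is.null(spec), !is.null(ped))
    if (is.null(Ainv)) Ainv <- a_inverse(ped)
    design <- build_design(design, spec, ped)
  }
  stopifnot(inherits(vc, "gess_varcomp"), !is.null(Ainv))
  d <- design
  comp <- vc$components
  M <- cbind(d$X, d$Z1, d$Z2, d$W1, d$W2, d$Zh)
  MtM <- Matrix::crossprod(M)
  Mty <- Matrix::crossprod(M, d$y)
  C <- mme_coef(MtM, d, comp, Ainv)
  list(C = C, rhs = Mty / comp[["sigma2_e"]], blocks = design_blocks(d),
       design = d, vc = vc, M = M) |>
    structure(class = "gess_mme")
}

## coefficient matrix from a precomputed cross-product
mme_coef <- function(MtM, d, comp, Ainv) {
  G0 <- matrix(c(comp[["sigma2_ss"]], comp[["sigma_ssd"]],
                 comp[["sigma_ssd"]], comp[["sigma2_d"]]), 2, 2)
  Gprec <- Matrix::kronecker(g0_inverse(G0), Ainv)
  prior <- Matrix::bdiag(
    Matrix::Diagonal(d$p, 0), Gprec,
    Matrix::Diagonal(d$n_pe_ss, 1 / comp[["sigma2_pess"]]),
    Matrix::Diagonal(d$n_pe_d, 1 / comp[["sigma2_ped"]]),
    Matrix::Diagonal(d$n_hym, 1 / comp[["sigma2_hym"]]))
  Matrix::forceSymmetric(MtM / comp[["sigma2_e"]] + prior)
}

#' Solve mixed-model equations
#'
#' @param mme A `gess_mme`.
#' @return Named list of solution blocks: `fixed`, `u_ss`, `u_d`,
#'   `pe_ss`, `pe_d`, `hym`, plus the full vector `sol`.
#' @export
solve_mme <- function(mme) {
  sol <- as.numeric(Matrix::solve(mme$C, mme$rhs))
  b <- mme$blocks
  d <- mme$design
  out <- list(
    fixed = stats::setNames(sol[b$fixed], colnames(d$X)),
    u_ss = stats::setNames(sol[b$u_ss], d$ped_ids),
    u_d = stats::setNames(sol[b$u_d], d$ped_ids),
    pe_ss = stats::setNames(sol[b$pe_ss], colnames(d$W1)),
    pe_d = stats::setNames(sol[b$pe_d], colnames(d$W2)),
    hym = stats::setNames(sol[b$hym], colnames(d$Zh)),
    sol = sol)
  out
}
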