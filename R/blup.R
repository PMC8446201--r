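#' BLUP solutions from a converged REML fit
#'
#' Extracts the mixed-model-equation solutions at the converged variance
#' components: fixed effects and BLUPs of the service-sire (GESS) and dam
#' (GED) genetic effects, the permanent-environment effects and the
#' herd-year-month effects. Animals without records or descendants
#' receive parent-average breeding values through the relationship
#' structure.
#'
#' @param fit A `gess_reml` from [reml_estimate()] (or a `gess_mme`).
#' @return List with the solution blocks (as in [solve_mme()]) plus
#'   `ebv`: a data frame `id`, `effect` (GESS/GED), `ebv`.
#' @export
solve_blup <- function(fit) {
  if (inherits(fit, "gess_mme")) {
    sols <- solve_mme(fit)
    ids <- fit$design$ped_ids
  } else {
    stopifnot(inherits(fit, "gess_reml"))
    st <- fit$state
    sol <- st$sol
    b <- fit$blocks
    d <- fit$design
    ids <- d$ped_ids
    sols <- list(fixed = stats::setNames(sol[b$fixed], colnames(d$X)),
                 u_ss = stats::setNames(sol[b$u_ss], ids),
                 u_d = stats::setNames(sol[b$u_d], ids),
                 pe_ss = stats::setNames(sol[b$pe_ss], colnames(d$W1)),
                 pe_d = stats::setNames(sol[b$pe_d], colnames(d$W2)),
                 hym = stats::setNames(sol[b$hym], colnames(d$Zh)),
                 sol = sol)
  }
  sols$ebv <- data.frame(
    id = rep(ids, 2L),
    effect = rep(c("GESS", "GED"), each = length(ids)),
    ebv = c(unname(sols$u_ss), unname(sols$u_d)),
    stringsAsFactors = FALSE)
  sols
}

#' Reliability of breeding values
#'
#' `rel_i = 1 - PEV_i / ((1 + F_i) sigma2_u)`, with the prediction error
#' variance taken from the corresponding diagonal of the inverse
#' mixed-model coefficient matrix (exact; computed by sparse solves for
#' the requested animals only).
#'
#' @param fit A `gess_reml`.
#' @param ids Animal ids (default: all pedigree animals).
#' @param effect `"GESS"` (service sire) or `"GED"` (dam).
#' @return Named numeric vector of reliabilities in `[0, 1)`.
#' @export
reliability <- function(fit, ids = NULL, effect = c("GESS", "GED")) {
  stopifnot(inherits(fit, "gess_reml"))
  effect <- match.arg(effect)
  d <- fit$design
  if (is.null(ids)) ids <- d$ped_ids
  rows <- match(ids, d$ped_ids)
  if (anyNA(rows)) stop("unknown ids: ",
                        paste(ids[is.na(rows)], collapse = ", "))
  off <- if (effect == "GESS") fit$blocks$u_ss[1] else fit$blocks$u_d[1]
  idx <- off - 1L + rows
  dim_c <- length(fit$state$sol)
  pev <- numeric(length(idx))
  for (start in seq(1L, length(idx), by = 200L)) {
    cols <- start:min(start + 199L, length(idx))
    E <- Matrix::sparseMatrix(i = idx[cols], j = seq_along(cols), x = 1,
                              dims = c(dim_c, length(cols)))
    S <- as.matrix(Matrix::solve(fit$state$chC, E, system = "A"))
    pev[cols] <- S[cbind(idx[cols], seq_along(cols))]
  }
  su2 <- if (effect == "GESS") fit$vc$components[["sigma2_ss"]]
         else fit$vc$components[["sigma2_d"]]
  rel <- 1 - pev / ((1 + fit$F[rows]) * su2)
  rel <- pmin(pmax(rel, 0), 1 - 1e-12)
  stats::setNames(rel, ids)
}

#' De-regressed proofs and information weights
#'
#' Removes parent-average and shrinkage from EBVs so they can serve as
#' association-study response variables. Following the classical
#' deregression construction: with `r2_PA = (rel_sire + rel_dam)/4` and
#' the own-information (deregressed) reliability
#' `r2_dereg = (rel - r2_PA)/(1 - r2_PA)`,
#' `DRP = PA + (EBV - PA)/r2_dereg`, and the record weight is
#' `w = (1 - h2) / ((c + (1 - r2_dereg)/r2_dereg) * h2)`, where `c` is the
#' fraction of genetic variance not captured by markers. Animals with
#' accuracy `sqrt(rel) <= min_accuracy` (or no own information) are
#' flagged excluded.
#'
#' @param ebv Named EBV vector (names = animal ids).
#' @param rel Named reliability vector in `[0, 1)`.
#' @param ped A `ped_pedigree` (for parent averages); may be `NULL` in
#'   `simple` mode.
#' @param h2 Trait heritability used in the weights.
#' @param c Fraction of genetic variance not accounted for by markers
#'   (default 0.5).
#' @param min_accuracy Exclusion threshold on accuracy (default 0.10).
#' @param simple If `TRUE`, plain `EBV/rel` scaling without
#'   parent-average removal.
#' @return Data frame `id`, `ebv`, `rel`, `drp`, `weight`, `included`.
#' @export
deregress <- function(ebv, rel, ped = NULL, h2, c = 0.5,
                      min_accuracy = 0.10, simple = FALSE) {
  stopifnot(length(ebv) == length(rel), !is.null(names(ebv)))
  ids <- names(ebv)
  rel <- rel[ids]
  if (any(rel >= 1)) stop("reliabilities must be < 1")
  if (simple) {
    ok <- rel > 0
    drp <- ifelse(ok, ebv / pmax(rel, 1e-12), NA_real_)
    r2d <- rel
  } else {
    stopifnot(inherits(ped, "ped_pedigree"))
    rows <- match(ids, ped$id)
    if (anyNA(rows)) stop("ids missing from pedigree")
    par_ebv <- function(prow) ifelse(prow > 0 & ped$id[pmax(prow, 1)] %in% ids,
                                     ebv[ped$id[pmax(prow, 1)]], 0)
    par_rel <- function(prow) ifelse(prow > 0 & ped$id[pmax(prow, 1)] %in% ids,
                                     rel[ped$id[pmax(prow, 1)]], 0)
    sr <- ped$sire_row[rows]; dr <- ped$dam_row[rows]
    pa <- 0.5 * (par_ebv(sr) + par_ebv(dr))
    r2pa <- (par_rel(sr) + par_rel(dr)) / 4
    r2d <- (rel - r2pa) / (1 - r2pa)
    ok <- r2d > 1e-6 & rel > 0
    drp <- ifelse(ok, pa + (ebv - pa) / pmax(r2d, 1e-12), NA_real_)
  }
  w <- ifelse(ok, (1 - h2) / ((c + (1 - r2d) / pmax(r2d, 1e-12)) * h2),
              NA_real_)
  included <- ok & sqrt(rel) > min_accuracy
  data.frame(id = ids, ebv = unname(ebv), rel = unname(rel),
             drp = unname(drp), weight = unname(w),
             included = unname(included), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Approximate genetic correlation between two EBV sets (Calo's method)
#'
#' Scales the raw Pearson correlation of the two EBV vectors by the
#' reliability factor
#' `sqrt(sum(rel1) * sum(rel2)) / sum(sqrt(rel1 * rel2))` (>= 1 by
#' Cauchy-Schwarz) and clamps to `[-1, 1]`. The standard error treats the
#' factor as fixed: `SE = factor * (1 - r_raw^2) / sqrt(n - 2)`.
#'
#' @param ebv1,ebv2 EBV vectors; if named, matched on common ids.
#' @param rel1,rel2 Reliability vectors in `(0, 1]`, aligned with the
#'   EBVs.
#' @return List with `r` (approximate genetic correlation), `se`,
#'   `factor`, `r_raw`, `n`.
#' @export
approx_genetic_correlation <- function(ebv1, rel1, ebv2, rel2) {
  if (!is.null(names(ebv1)) && !is.null(names(ebv2))) {
    common <- intersect(names(ebv1), names(ebv2))
    ebv1 <- ebv1[common]; rel1 <- rel1[common]
    ebv2 <- ebv2[common]; rel2 <- rel2[common]
  }
  n <- length(ebv1)
  if (n < 3) stop("need at least 3 common animals")
  stopifnot(length(ebv2) == n, length(rel1) == n, length(rel2) == n,
            all(rel1 > 0), all(rel2 > 0), all(rel1 <= 1), all(rel2 <= 1))
  r_raw <- stats::cor(ebv1, ebv2)
  fac <- sqrt(sum(rel1) * sum(rel2)) / sum(sqrt(rel1 * rel2))
  r <- min(1, max(-1, r_raw * fac))
  se <- fac * (1 - r_raw^2) / sqrt(n - 2)
  list(r = r, se = se, factor = fac, r_raw = r_raw, n = n)
}
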