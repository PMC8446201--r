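#' Pedigree construction and topological ordering
#'
#' Builds a validated, topologically ordered pedigree from animal/sire/dam
#' triples. Parents always precede their offspring in the returned table;
#' unknown parents are allowed (coded `NA`, `""` or `"0"` on input).
#'
#' @param ped A data frame with at least the columns `animal`, `sire`, `dam`
#'   (ids, coerced to character). Optional columns `sex` (`"M"`/`"F"`) and
#'   `year` are carried through. `"0"`, `""` and `NA` denote an unknown
#'   parent.
#' @return An object of class `ped_pedigree`: a data frame with columns
#'   `id`, `sire`, `dam`, `sex`, and integer columns `sire_row`, `dam_row`
#'   (row index of each parent, `0L` if unknown), in topological order.
#' @details A parent id that never appears as an animal is added as a
#'   founder row (unknown parents themselves). Cycles in the ancestry graph
#'   are an error; the offending cycle is named in the message.
#' @examples
#' ped <- sort_pedigree(data.frame(animal = c("C", "A", "B"),
#'                                 sire = c("A", NA, NA),
#'                                 dam  = c("B", NA, NA)))
#' ped$id
#' @export
sort_pedigree <- function(ped) {
  stopifnot(is.data.frame(ped))
  nm <- tolower(names(ped))
  need <- c("animal", "sire", "dam")
  if (!all(need %in% nm)) stop("pedigree needs columns animal, sire, dam")
  names(ped) <- nm
  id <- as.character(ped$animal)
  if (anyDuplicated(id)) stop("duplicated animal ids in pedigree: ",
                              paste(unique(id[duplicated(id)]), collapse = ", "))
  clean <- function(x) {
    x <- as.character(x)
    x[is.na(x) | x == "" | x == "0"] <- NA_character_
    x
  }
  sire <- clean(ped$sire)
  dam <- clean(ped$dam)

  ## implicit founders: parents never listed as animals
  extra <- setdiff(stats::na.omit(unique(c(sire, dam))), id)
  if (length(extra)) {
    ex_sex <- ifelse(extra %in% sire, "M", "F")
    id <- c(extra, id)
    sire <- c(rep(NA_character_, length(extra)), sire)
    dam <- c(rep(NA_character_, length(extra)), dam)
    sex_in <- if ("sex" %in% nm) as.character(ped$sex) else rep(NA_character_, nrow(ped))
    sex <- c(ex_sex, sex_in)
    year <- if ("year" %in% nm) c(rep(NA, length(extra)), ped$year) else NULL
  } else {
    sex <- if ("sex" %in% nm) as.character(ped$sex) else rep(NA_character_, length(id))
    year <- if ("year" %in% nm) ped$year else NULL
  }
  ## infer sex from parental role where missing
  sex[is.na(sex) & id %in% sire] <- "M"
  sex[is.na(sex) & id %in% dam] <- "F"

  n <- length(id)
  idx <- match(id, id)
  si <- match(sire, id)
  di <- match(dam, id)
  si[is.na(si)] <- 0L
  di[is.na(di)] <- 0L

  ## Kahn topological sort on the parent -> offspring DAG
  indeg <- integer(n)
  has_s <- si > 0L
  has_d <- di > 0L
  indeg <- as.integer(has_s) + as.integer(has_d)
  children <- vector("list", n)
  for (i in seq_len(n)) {
    if (has_s[i]) children[[si[i]]] <- c(children[[si[i]]], i)
    if (has_d[i]) children[[di[i]]] <- c(children[[di[i]]], i)
  }
  order <- integer(0)
  queue <- which(indeg == 0L)
  indeg2 <- indeg
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    order <- c(order, v)
    for (w in children[[v]]) {
      indeg2[w] <- indeg2[w] - 1L
      if (indeg2[w] == 0L) queue <- c(queue, w)
    }
  }
  if (length(order) < n) {
    bad <- setdiff(seq_len(n), order)
    stop("ancestry cycle involving: ", paste(id[bad], collapse = " -> "))
  }

  pos <- integer(n); pos[order] <- seq_len(n)
  out <- data.frame(id = id[order],
                    sire = sire[order],
                    dam = dam[order],
                    sex = sex[order],
                    stringsAsFactors = FALSE)
  if (!is.null(year)) out$year <- year[order]
  so <- si[order]; do_ <- di[order]
  sr <- integer(n); dr <- integer(n)
  sr[so > 0L] <- pos[so[so > 0L]]
  dr[do_ > 0L] <- pos[do_[do_ > 0L]]
  out$sire_row <- sr
  out$dam_row <- dr
  rownames(out) <- NULL
  class(out) <- c("ped_pedigree", "data.frame")
  out
}

#' Inbreeding coefficients by the Meuwissen-Luo recursion
#'
#' Computes per-animal inbreeding coefficients F from a sorted pedigree,
#' exactly equal to the tabular-method diagonal minus one. Founders and
#' animals with an unknown parent have F = 0 (unknown parents are treated
#' as unrelated founders; no unknown-parent groups).
#'
#' @param ped A `ped_pedigree` from [sort_pedigree()].
#' @return Numeric vector of F, one per pedigree row, in pedigree order.
#' @export
inbreeding <- function(ped) {
  stopifnot(inherits(ped, "ped_pedigree"))
  n <- nrow(ped)
  si <- ped$sire_row
  di <- ped$dam_row
  F <- numeric(n)
  D <- numeric(n) # within-family (Mendelian) variance, filled on the fly
  v <- numeric(n) # scratch gene-flow coefficients
  for (i in seq_len(n)) {
    fs <- if (si[i] > 0L) F[si[i]] else -1
    fd <- if (di[i] > 0L) F[di[i]] else -1
    D[i] <- 0.5 - 0.25 * (fs + fd)
    if (si[i] == 0L || di[i] == 0L) { F[i] <- 0; next }
    ## a_ii = sum_j v_j^2 D_j over ancestors, walking indices downward
    touched <- i
    v[i] <- 1
    aii <- 0
    for (k in i:1L) {
      if (v[k] == 0) next
      aii <- aii + v[k]^2 * D[k]
      if (si[k] > 0L) { if (v[si[k]] == 0) touched <- c(touched, si[k]); v[si[k]] <- v[si[k]] + 0.5 * v[k] }
      if (di[k] > 0L) { if (v[di[k]] == 0) touched <- c(touched, di[k]); v[di[k]] <- v[di[k]] + 0.5 * v[k] }
    }
    v[touched] <- 0
    F[i] <- aii - 1
  }
  F
}

#' Dense numerator-relationship block by the tabular method
#'
#' Returns the additive genetic relationship coefficients `a_ij` among the
#' requested animals, computed by the tabular recursion over the ancestor
#' closure of `ids`. The diagonal equals `1 + F`.
#'
#' @param ped A `ped_pedigree`.
#' @param ids Character ids to extract; default all animals.
#' @return Dense symmetric matrix with dimnames = ids.
#' @export
a_submatrix <- function(ped, ids = ped$id) {
  stopifnot(inherits(ped, "ped_pedigree"))
  miss <- setdiff(ids, ped$id)
  if (length(miss)) stop("unknown ids: ", paste(miss, collapse = ", "))
  ## ancestor closure
  keep <- logical(nrow(ped))
  keep[match(ids, ped$id)] <- TRUE
  for (i in rev(seq_len(nrow(ped)))) {
    if (keep[i]) {
      if (ped$sire_row[i] > 0L) keep[ped$sire_row[i]] <- TRUE
      if (ped$dam_row[i] > 0L) keep[ped$dam_row[i]] <- TRUE
    }
  }
  rows <- which(keep)
  m <- length(rows)
  remap <- integer(nrow(ped)); remap[rows] <- seq_len(m)
  si <- ifelse(ped$sire_row[rows] > 0L, remap[pmax(ped$sire_row[rows], 1L)], 0L)
  di <- ifelse(ped$dam_row[rows] > 0L, remap[pmax(ped$dam_row[rows], 1L)], 0L)
  A <- matrix(0, m, m)
  for (i in seq_len(m)) {
    s <- si[i]; d <- di[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      as_ <- if (s > 0L) A[j, s] else 0
      ad_ <- if (d > 0L) A[j, d] else 0
      A[j, i] <- 0.5 * (as_ + ad_)
      A[i, j] <- A[j, i]
    }
    A[i, i] <- 1 + if (s > 0L && d > 0L) 0.5 * A[s, d] else 0
  }
  dimnames(A) <- list(ped$id[rows], ped$id[rows])
  A[ids, ids, drop = FALSE]
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Builds A-inverse directly from the pedigree by Henderson's rules,
#' accounting for parental inbreeding. Each animal contributes at most nine
#' nonzeros. The result satisfies `a_inverse(ped) %*% a_submatrix(ped) = I`.
#'
#' @param ped A `ped_pedigree`.
#' @param F Optional precomputed inbreeding vector (from [inbreeding()]);
#'   computed if missing.
#' @return A sparse symmetric [Matrix::dsCMatrix-class] with dimnames =
#'   pedigree ids.
#' @export
a_inverse <- function(ped, F = NULL) {
  stopifnot(inherits(ped, "ped_pedigree"))
  if (is.null(F)) F <- inbreeding(ped)
  n <- nrow(ped)
  si <- ped$sire_row
  di <- ped$dam_row
  ## accumulate triplets, vectorized by known-parent pattern
  D <- ifelse(si > 0L & di > 0L, 0.5 - 0.25 * (F[pmax(si, 1L)] + F[pmax(di, 1L)]),
       ifelse(si > 0L, 0.75 - 0.25 * F[pmax(si, 1L)],
       ifelse(di > 0L, 0.75 - 0.25 * F[pmax(di, 1L)], 1)))
  al <- 1 / D
  idx <- seq_len(n)
  ii <- idx; jj <- idx; xx <- al
  hs <- si > 0L; hd <- di > 0L
  ii <- c(ii, idx[hs], si[hs], si[hs])
  jj <- c(jj, si[hs], idx[hs], si[hs])
  xx <- c(xx, -al[hs] / 2, -al[hs] / 2, al[hs] / 4)
  ii <- c(ii, idx[hd], di[hd], di[hd])
  jj <- c(jj, di[hd], idx[hd], di[hd])
  xx <- c(xx, -al[hd] / 2, -al[hd] / 2, al[hd] / 4)
  b <- hs & hd
  ii <- c(ii, si[b], di[b])
  jj <- c(jj, di[b], si[b])
  xx <- c(xx, al[b] / 4, al[b] / 4)
  Ai <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                             dimnames = list(ped$id, ped$id))
  methods::as(Matrix::forceSymmetric(Ai), "CsparseMatrix")
}

#' Read / write pedigree CSV
#'
#' Plain CSV with columns animal,sire,dam and optionally sex,year;
#' `"0"` or empty = unknown parent.
#' @param path File path.
#' @return `read_pedigree` returns a sorted `ped_pedigree`.
#' @export
read_pedigree <- function(path) {
  sort_pedigree(utils::read.csv(path, colClasses = "character"))
}

#' @rdname read_pedigree
#' @param ped Pedigree to write.
#' @export
write_pedigree <- function(ped, path) {
  out <- as.data.frame(ped)[, intersect(c("id", "sire", "dam", "sex", "year"), names(ped))]
  names(out)[1] <- "animal"
  out$sire[is.na(out$sire)] <- "0"
  out$dam[is.na(out$dam)] <- "0"
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
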