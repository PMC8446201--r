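#' Write / read genotypes as PLINK text (.ped/.map)
#'
#' Biallelic diploid text format: one `.ped` row per animal (family id,
#' animal id, parents 0, sex 0, phenotype -9, then two allele columns per
#' SNP, `0 0` for missing) and a 4-column `.map` (chromosome, SNP id,
#' genetic distance 0, bp position).
#'
#' @param geno List with `genotypes` (codes 0/1/2/NA) and `map`.
#' @param prefix Output path prefix (writes `prefix.ped`, `prefix.map`).
#' @return `write_plink` returns the prefix; `read_plink` a `geno` list.
#' @export
write_plink <- function(geno, prefix) {
  G <- geno$genotypes
  map <- geno$map
  a1 <- if ("a1" %in% names(map)) map$a1 else rep("A", ncol(G))
  a2 <- if ("a2" %in% names(map)) map$a2 else rep("B", ncol(G))
  allele_txt <- function(g) {
    out <- character(length(g))
    out[is.na(g)] <- "0 0"
    out[!is.na(g) & g == 0L] <- paste(a1[!is.na(g) & g == 0L],
                                      a1[!is.na(g) & g == 0L])
    out[!is.na(g) & g == 1L] <- paste(a1[!is.na(g) & g == 1L],
                                      a2[!is.na(g) & g == 1L])
    out[!is.na(g) & g == 2L] <- paste(a2[!is.na(g) & g == 2L],
                                      a2[!is.na(g) & g == 2L])
    out
  }
  lines <- vapply(seq_len(nrow(G)), function(i)
    paste(c("FAM", rownames(G)[i], "0", "0", "0", "-9",
            allele_txt(as.integer(G[i, ]))), collapse = " "), character(1))
  writeLines(lines, paste0(prefix, ".ped"))
  utils::write.table(data.frame(map$chr, map$snp, 0, map$pos),
                     paste0(prefix, ".map"), row.names = FALSE,
                     col.names = FALSE, quote = FALSE, sep = "\t")
  invisible(prefix)
}

#' @rdname write_plink
#' @export
read_plink <- function(prefix) {
  map <- utils::read.table(paste0(prefix, ".map"),
                           col.names = c("chr", "snp", "cm", "pos"),
                           colClasses = c("character", "character",
                                          "numeric", "integer"))
  lines <- readLines(paste0(prefix, ".ped"))
  toks <- strsplit(trimws(lines), "[ \t]+")
  m <- nrow(map)
  n <- length(toks)
  ids <- vapply(toks, `[`, character(1), 2L)
  A1 <- matrix(NA_character_, n, m)
  A2 <- matrix(NA_character_, n, m)
  for (i in seq_len(n)) {
    al <- toks[[i]][-(1:6)]
    if (length(al) != 2 * m) stop("malformed .ped row ", i)
    A1[i, ] <- al[c(TRUE, FALSE)]
    A2[i, ] <- al[c(FALSE, TRUE)]
  }
  A1[A1 == "0"] <- NA; A2[A2 == "0"] <- NA
  ## counted allele per SNP: lexicographically last of the observed ones
  counted <- vapply(seq_len(m), function(j) {
    u <- stats::na.omit(unique(c(A1[, j], A2[, j])))
    if (!length(u)) NA_character_ else max(u)
  }, character(1))
  G <- (A1 == rep(counted, each = n)) + (A2 == rep(counted, each = n))
  storage.mode(G) <- "integer"
  dimnames(G) <- list(ids, map$snp)
  list(genotypes = G, map = data.frame(snp = map$snp, chr = map$chr,
                                       pos = map$pos,
                                       stringsAsFactors = FALSE))
}

#' Write / read genotypes as a minimal VCF
#'
#' Biallelic diploid VCFv4.2 with GT-only FORMAT.
#'
#' @param geno List with `genotypes` and `map`.
#' @param path Output file.
#' @return `write_vcf` returns `path`; `read_vcf` a `geno` list (codes
#'   count the ALT allele).
#' @export
write_vcf <- function(geno, path) {
  G <- geno$genotypes
  map <- geno$map
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(G)), collapse = "\t")), con)
  gt <- c("0/0", "0/1", "1/1")
  for (j in seq_len(ncol(G))) {
    g <- G[, j]
    cells <- ifelse(is.na(g), "./.", gt[g + 1L])
    writeLines(paste(c(map$chr[j], map$pos[j], map$snp[j], "A", "B", ".",
                       "PASS", ".", "GT", cells), collapse = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_vcf
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#CHROM")]
  if (!length(hdr)) stop("no #CHROM header in ", path)
  cols <- strsplit(hdr, "\t")[[1]]
  ids <- cols[-(1:9)]
  body <- lines[!startsWith(lines, "#")]
  toks <- strsplit(body, "\t")
  m <- length(toks)
  G <- matrix(NA_integer_, length(ids), m, dimnames = list(ids, NULL))
  map <- data.frame(snp = character(m), chr = character(m), pos = integer(m),
                    stringsAsFactors = FALSE)
  for (j in seq_len(m)) {
    tk <- toks[[j]]
    map$chr[j] <- tk[1]; map$pos[j] <- as.integer(tk[2]); map$snp[j] <- tk[3]
    gt <- substr(tk[-(1:9)], 1, 3)
    g <- rep(NA_integer_, length(gt))
    g[gt %in% c("0/0", "0|0")] <- 0L
    g[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
    g[gt %in% c("1/1", "1|1")] <- 2L
    G[, j] <- g
  }
  colnames(G) <- map$snp
  list(genotypes = G, map = map)
}

#' Write simulation truth as JSON
#'
#' Stores the simulated variance components, cut points and effect sizes
#' so downstream recovery tests can compare against them.
#' @param truth The `truth` element of [simulate_records()].
#' @param path Output file.
#' @export
write_truth_json <- function(truth, path) {
  out <- list(components = as.list(truth$components),
              cuts = truth$cuts, mu = truth$mu,
              fixed_effects = truth$fixed_effects)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
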