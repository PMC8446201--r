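#' Read gene/QTL feature intervals from BED or GFF3
#'
#' Thin wrapper over `rtracklayer::import()`: BED input (0-based
#' half-open) and GFF3 input (1-based inclusive) are both converted to the
#' 1-based inclusive coordinates used internally. Feature names are taken
#' from `name`, `Name`, `ID` or `gene_name`, whichever exists first.
#'
#' @param path File path (`.bed`, `.gff`, `.gff3`).
#' @param kind Feature kind label (`"gene"` or `"qtl"`).
#' @param source Free-text source label.
#' @return Data frame `feature`, `chr`, `start`, `end`, `kind`, `source`.
#' @export
read_features <- function(path, kind = c("gene", "qtl"),
                          source = basename(path)) {
  kind <- match.arg(kind)
  fmt <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "BED" else "GFF3"
  gr <- rtracklayer::import(path, format = fmt)
  mc <- S4Vectors::mcols(gr)
  nm <- NULL
  for (cand in c("name", "Name", "ID", "gene_name"))
    if (cand %in% names(mc)) { nm <- as.character(mc[[cand]]); break }
  if (is.null(nm)) nm <- paste0("feature", seq_along(gr))
  data.frame(feature = nm,
             chr = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             kind = kind, source = source, stringsAsFactors = FALSE)
}

#' Map SNPs to features within a genomic window
#'
#' Reports every feature whose interval `[start, end]` intersects
#' `[pos - window, pos + window]` around each SNP (boundary inclusive on
#' both sides), with the gene-body distance and the side of the feature
#' relative to the SNP.
#'
#' @param snps Data frame with `snp`, `chr`, `pos`.
#' @param features Data frame as from [read_features()] (`feature`,
#'   `chr`, `start`, `end`, optionally `kind`).
#' @param window Window half-width in bp (default 200000).
#' @return Data frame `snp`, `chr`, `pos`, `feature`, `kind`, `distance`
#'   (0 if the SNP lies inside the feature), `side` (`"upstream"` =
#'   feature before the SNP, `"downstream"`, `"overlapping"`). SNPs on a
#'   chromosome absent from the feature table are returned with
#'   `feature = NA` and flagged in the `unknown_chr` attribute.
#' @export
map_features <- function(snps, features, window = 2e5) {
  stopifnot(all(c("snp", "chr", "pos") %in% names(snps)))
  if (is.null(features) || !nrow(features)) {
    out <- snps[0, c("snp", "chr", "pos")]
    out$feature <- character(0); out$kind <- character(0)
    out$distance <- numeric(0); out$side <- character(0)
    return(out)
  }
  stopifnot(all(features$start <= features$end))
  gr_s <- GenomicRanges::GRanges(
    as.character(snps$chr),
    IRanges::IRanges(start = pmax(1, snps$pos - window),
                     end = snps$pos + window))
  gr_f <- GenomicRanges::GRanges(
    as.character(features$chr),
    IRanges::IRanges(start = features$start, end = features$end))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(gr_s, gr_f))
  si <- S4Vectors::queryHits(hits)
  fi <- S4Vectors::subjectHits(hits)
  pos <- snps$pos[si]
  st <- features$start[fi]
  en <- features$end[fi]
  dist <- ifelse(pos < st, st - pos, ifelse(pos > en, pos - en, 0))
  side <- ifelse(en < pos, "upstream", ifelse(st > pos, "downstream",
                                              "overlapping"))
  out <- data.frame(snp = snps$snp[si], chr = snps$chr[si], pos = pos,
                    feature = features$feature[fi],
                    kind = if ("kind" %in% names(features))
                      features$kind[fi] else "gene",
                    distance = dist, side = side, stringsAsFactors = FALSE)
  out <- out[order(match(out$snp, snps$snp), out$distance), ]
  rownames(out) <- NULL
  unknown <- setdiff(unique(as.character(snps$chr)),
                     unique(as.character(features$chr)))
  attr(out, "unknown_chr") <- unknown
  out
}

#' Shared and unique features between two mapped sets
#'
#' Set algebra over the feature names mapped to two significant-SNP sets
#' (e.g. service-sire vs dam scans).
#'
#' @param set1,set2 Character vectors (or `map_features()` outputs, in
#'   which case their `feature` columns are used).
#' @return List with `shared`, `only1`, `only2` and `counts`.
#' @export
overlap_report <- function(set1, set2) {
  f <- function(x) if (is.data.frame(x)) unique(stats::na.omit(x$feature))
                   else unique(stats::na.omit(x))
  a <- f(set1); b <- f(set2)
  shared <- intersect(a, b)
  list(shared = shared, only1 = setdiff(a, b), only2 = setdiff(b, a),
       counts = c(shared = length(shared), only1 = length(setdiff(a, b)),
                  only2 = length(setdiff(b, a))))
}
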