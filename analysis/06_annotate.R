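#!/usr/bin/env Rscript
# Stage 6 - positional annotation of significant markers.
#
# Maps the FDR-significant SNPs from stage 5 to gene and QTL intervals
# within a 200-kb window. The feature tables here are synthetic (random
# intervals written as GFF3/BED and read back through the format layer);
# with real data the same calls take Ensembl gene models and cattle QTL
# intervals.

source(file.path("analysis", "_common.R"))

scan <- utils::read.csv(file.path(RESULTS, "gwas_ged_gl.csv"))
hits <- scan[scan$significant, c("snp", "chr", "pos")]
if (!nrow(hits)) {
  cat("No significant SNPs to annotate; run analysis/05_gwas.R first.\n")
  quit(save = "no")
}

## synthetic gene/QTL intervals over the simulated genome
set.seed(MASTER_SEED)
genes_gff <- file.path(RESULTS, "synthetic_genes.gff3")
starts <- sort(sample.int(1.45e8, 2000))
chrs <- sample(unique(scan$chr), 2000, replace = TRUE)
writeLines(c("##gff-version 3", sprintf(
  "%s\tsim\tgene\t%d\t%d\t.\t+\t.\tID=gene%04d;Name=SYNGENE%04d",
  chrs, starts, starts + sample(2e4:2e5, 2000, replace = TRUE),
  seq_len(2000), seq_len(2000))), genes_gff)
qtl_bed <- file.path(RESULTS, "synthetic_qtl.bed")
qs <- sort(sample.int(1.4e8, 150))
writeLines(sprintf("%s\t%d\t%d\tSYNQTL%03d",
                   sample(unique(scan$chr), 150, replace = TRUE), qs,
                   qs + sample(5e5:5e6, 150, replace = TRUE), seq_len(150)),
           qtl_bed)

genes <- read_features(genes_gff, kind = "gene")
qtl <- read_features(qtl_bed, kind = "qtl")
ann_g <- map_features(hits, genes, window = 2e5)
ann_q <- map_features(hits, qtl, window = 2e5)
ann <- rbind(ann_g, ann_q)
utils::write.csv(ann, file.path(RESULTS, "annotation.csv"),
                 row.names = FALSE)

cat(sprintf(paste0(
  "Annotated %d significant SNPs against %d synthetic genes and %d",
  " synthetic QTL intervals (200-kb window):\n",
  "  %d SNP-gene pairs (median gene distance %.0f kb), %d SNP-QTL",
  " overlaps.\n"),
  nrow(hits), nrow(genes), nrow(qtl), nrow(ann_g),
  ifelse(nrow(ann_g), stats::median(ann_g$distance) / 1e3, NA), nrow(ann_q)))
ov <- overlap_report(ann_g, ann_q)
cat(sprintf("Features shared between the gene and QTL views: %d.\n",
            ov$counts[["shared"]]))
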