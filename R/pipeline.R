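#' Run the full analysis pipeline on a synthetic herd
#'
#' End-to-end driver: simulate -> edit -> REML -> BLUP/reliability/DRP ->
#' GWAS (optional) -> annotation (optional). Every stage's parameters and
#' output-file checksums are recorded in a provenance manifest; rerunning
#' with the same configuration reproduces the hashes of the deterministic
#' stages. One master seed is expanded into per-stage seeds via
#' [stage_seed()].
#'
#' @param config A [sim_config()] describing the herd and trait.
#' @param out_dir Output directory (created if needed).
#' @param gwas Run the association scan on the service-sire DRPs?
#' @param features Optional feature table (as from [read_features()]) for
#'   positional annotation of significant SNPs.
#' @param window Annotation window in bp.
#' @return Invisibly, a list with the stage artifacts (`herd`, `records`,
#'   `fit`, `ebv`, `drp`, `scan`, `annotation`, `manifest`).
#' @export
run_pipeline <- function(config, out_dir, gwas = FALSE, features = NULL,
                         window = 2e5) {
  stopifnot(inherits(config, "sim_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  manifest <- list(seed = config$seed, trait = config$trait, stages = list())
  t0 <- Sys.time()
  emit <- function(stage, files, params = list()) {
    hashes <- if (length(files)) as.list(tools::md5sum(files)) else list()
    manifest$stages[[stage]] <<- list(params = params, files = hashes)
  }

  ## 1. simulate
  herd <- simulate_herd(config, genotypes = gwas)
  ped_file <- file.path(out_dir, "pedigree.csv")
  write_pedigree(herd$pedigree, ped_file)
  rec_file <- file.path(out_dir, "records.csv")
  utils::write.csv(herd$records, rec_file, row.names = FALSE)
  truth_file <- file.path(out_dir, "truth.json")
  write_truth_json(herd$truth, truth_file)
  files <- c(ped_file, rec_file, truth_file)
  if (gwas) {
    write_plink(herd$geno, file.path(out_dir, "genotypes"))
    write_vcf(herd$geno, file.path(out_dir, "genotypes.vcf"))
    files <- c(files, file.path(out_dir, c("genotypes.ped", "genotypes.map",
                                           "genotypes.vcf")))
  }
  emit("simulate", files,
       list(n_records = nrow(herd$records), trait = config$trait))

  ## 2. edit
  if (config$trait %in% c("CR", "NRR56")) {
    log <- simulate_raw_log(herd$records)
    cr <- assign_conception(log$inseminations, log$diagnoses, log$calvings)
    nr <- compute_nrr56(cr$records, log$calvings)
    edited <- herd$records
    audit <- rbind(cr$audit, nr$audit)
  } else {
    rec <- herd$records
    if (config$trait == "GL") rec$gl <- rec$y
    ed <- edit_calving(rec)
    edited <- ed$records
    audit <- ed$audit
  }
  audit_file <- file.path(out_dir, "audit.csv")
  utils::write.csv(audit, audit_file, row.names = FALSE)
  emit("edit", audit_file, list(kept = nrow(edited), dropped = nrow(audit)))

  ## 3. variance components
  spec <- trait_model_spec(config$trait)
  fit <- reml_estimate(edited, spec, herd$pedigree)
  vc_file <- file.path(out_dir, "varcomp.json")
  dp <- derived_parameters(fit$vc)
  jsonlite::write_json(list(components = as.list(fit$vc$components),
                            loglik = fit$loglik, converged = fit$converged,
                            derived = dp),
                       vc_file, auto_unbox = TRUE, digits = NA)
  emit("reml", vc_file, list(iterations = fit$iterations))

  ## 4. breeding values + DRP
  sol <- solve_blup(fit)
  sires <- colnames(fit$design$W1)
  cows <- colnames(fit$design$W2)
  ids <- herd$pedigree$id
  rel_ss <- reliability(fit, ids, "GESS")
  rel_d <- reliability(fit, ids, "GED")
  h2 <- heritability(fit$vc)
  ## deregress over the whole pedigree (parent averages need parent EBVs),
  ## then keep the animals with records for each effect
  drp_ss <- deregress(sol$u_ss, rel_ss, herd$pedigree, h2 = h2[["h2_ss"]])
  drp_ss <- drp_ss[drp_ss$id %in% sires, ]
  drp_d <- deregress(sol$u_d, rel_d, herd$pedigree, h2 = h2[["h2_d"]])
  drp_d <- drp_d[drp_d$id %in% cows, ]
  ebv_file <- file.path(out_dir, "ebv_drp.csv")
  utils::write.csv(rbind(cbind(effect = "GESS", drp_ss),
                         cbind(effect = "GED", drp_d)),
                   ebv_file, row.names = FALSE)
  emit("ebv_drp", ebv_file,
       list(n_gess = nrow(drp_ss), n_ged = nrow(drp_d)))

  scan <- NULL
  ann <- NULL
  if (gwas) {
    ## 5. association scan on the service-sire DRPs
    qc <- qc_filter(herd$geno)
    use <- drp_ss[drp_ss$included, ]
    drp_vec <- stats::setNames(use$drp, use$id)
    wt <- stats::setNames(use$weight, use$id)
    scan <- farmcpu_scan(qc, drp_vec, weights = wt)
    gw_file <- file.path(out_dir, "gwas.csv")
    utils::write.csv(scan$result, gw_file, row.names = FALSE)
    emit("gwas", gw_file, list(lambda = scan$lambda,
                               n_significant = sum(scan$result$significant)))
    ## 6. annotation
    if (!is.null(features)) {
      hits <- scan$result[scan$result$significant, c("snp", "chr", "pos")]
      ann <- map_features(hits, features, window)
      ann_file <- file.path(out_dir, "annotation.csv")
      utils::write.csv(ann, ann_file, row.names = FALSE)
      emit("annotate", ann_file, list(window = window))
    }
  }
  manifest$elapsed_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  mf <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA)
  invisible(list(herd = herd, records = edited, fit = fit, ebv = sol$ebv,
                 drp = list(GESS = drp_ss, GED = drp_d), scan = scan,
                 annotation = ann, manifest = manifest))
}
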