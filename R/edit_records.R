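#' Assign conception (CR) codes to insemination events
#'
#' Applies the conception rule: within each cow-parity the last
#' insemination before a positive pregnancy diagnosis is coded CR = 1 and
#' all other inseminations 0. Cows with a calving but no positive
#' diagnosis are considered pregnant at the last insemination before the
#' calving. A calving that precedes every insemination of its parity is
#' structurally invalid: the cow-parity is dropped and logged.
#'
#' @param inseminations Data frame with columns `cow`, `parity`, `date`
#'   (numeric day or `Date`); other columns pass through.
#' @param diagnoses Data frame with `cow`, `parity`, `date`, `positive`
#'   (logical). May be empty or `NULL`.
#' @param calvings Data frame with `cow`, `parity`, `date`. May be empty
#'   or `NULL`.
#' @return List with `records` (inseminations plus a `cr` column) and
#'   `audit` (data frame `rule`, `cow`, `parity`, `detail` of drops).
#' @export
assign_conception <- function(inseminations, diagnoses = NULL,
                              calvings = NULL) {
  ins <- inseminations
  stopifnot(all(c("cow", "parity", "date") %in% names(ins)))
  ins <- ins[order(ins$cow, ins$parity, ins$date), , drop = FALSE]
  key <- paste(ins$cow, ins$parity, sep = "\r")
  ins$cr <- 0L
  audit <- empty_audit()
  pos_date <- function(tab) {
    if (is.null(tab) || !nrow(tab)) return(character(0))
    stats::setNames(as.numeric(tab$date), paste(tab$cow, tab$parity, sep = "\r"))
  }
  dg <- if (!is.null(diagnoses) && nrow(diagnoses))
    diagnoses[diagnoses$positive, , drop = FALSE] else NULL
  dpos <- pos_date(dg)
  cpos <- pos_date(calvings)
  drop <- logical(nrow(ins))
  for (k in unique(key)) {
    ix <- which(key == k)
    d <- as.numeric(ins$date[ix])
    target <- NA_real_
    if (k %in% names(dpos)) target <- dpos[[k]]
    else if (k %in% names(cpos)) target <- cpos[[k]]
    if (is.na(target)) next                      # no diagnosis, no calving
    before <- which(d < target)
    if (!length(before)) {
      drop[ix] <- TRUE
      audit <- rbind(audit, data.frame(
        rule = "calving_before_insemination", cow = ins$cow[ix[1]],
        parity = ins$parity[ix[1]],
        detail = "pregnancy event precedes all inseminations",
        stringsAsFactors = FALSE))
      next
    }
    ins$cr[ix[before[length(before)]]] <- 1L
  }
  records <- ins[!drop, , drop = FALSE]
  rownames(records) <- NULL
  list(records = records, audit = audit)
}

empty_audit <- function() {
  data.frame(rule = character(0), cow = character(0), parity = integer(0),
             detail = character(0), stringsAsFactors = FALSE)
}

#' 56-day non-return (NRR56) codes from insemination events
#'
#' Per cow, in time order: an insemination is coded 1 if no re-insemination
#' occurs within 56 days, 0 if the next insemination falls 18-56 days
#' later, and excluded (`NA`) if the next insemination falls within 1-17
#' days or if no later insemination nor calving exists after the 56-day
#' window. Duplicate same-day inseminations are collapsed to one and
#' logged.
#'
#' @param inseminations Data frame with `cow`, `date`; extra columns pass
#'   through.
#' @param calvings Optional data frame with `cow`, `date`.
#' @return List with `records` (deduplicated inseminations plus `nrr56`)
#'   and `audit`.
#' @export
compute_nrr56 <- function(inseminations, calvings = NULL) {
  ins <- inseminations
  stopifnot(all(c("cow", "date") %in% names(ins)))
  ins <- ins[order(ins$cow, ins$date), , drop = FALSE]
  audit <- empty_audit()
  dup <- duplicated(ins[, c("cow", "date")])
  if (any(dup)) {
    for (i in which(dup))
      audit <- rbind(audit, data.frame(
        rule = "duplicate_same_day_insemination",
        cow = as.character(ins$cow[i]),
        parity = if ("parity" %in% names(ins)) ins$parity[i] else NA_integer_,
        detail = paste("day", as.numeric(ins$date[i])),
        stringsAsFactors = FALSE))
    ins <- ins[!dup, , drop = FALSE]
  }
  ins$nrr56 <- NA_integer_
  calv_last <- if (!is.null(calvings) && nrow(calvings))
    tapply(as.numeric(calvings$date), as.character(calvings$cow), max)
  else numeric(0)
  for (cw in unique(as.character(ins$cow))) {
    ix <- which(as.character(ins$cow) == cw)
    d <- as.numeric(ins$date[ix])
    for (j in seq_along(ix)) {
      nxt <- if (j < length(ix)) d[j + 1] - d[j] else NA_real_
      if (!is.na(nxt)) {
        if (nxt >= 1 && nxt <= 17) next              # excluded
        ins$nrr56[ix[j]] <- if (nxt <= 56) 0L else 1L
      } else {
        later_calving <- cw %in% names(calv_last) &&
          calv_last[[cw]] > d[j] + 56
        if (later_calving) ins$nrr56[ix[j]] <- 1L    # else excluded
      }
    }
  }
  rownames(ins) <- NULL
  list(records = ins, audit = audit)
}

#' Edit calving records
#'
#' Deletes gestation lengths outside [260, 302] days and out-of-range
#' calving-ease (1-3) or stillbirth (1-2) codes, and assigns the calf-size
#' group from birth weight (30-40, 40-50, 50-60 kg); weights outside
#' [30, 60] kg are dropped. Every removal is logged with the rule that
#' caused it. Editing is idempotent.
#'
#' @param records Data frame with any of the columns `gl`, `ce`, `sb`,
#'   `birth_weight` (plus identifiers that pass through). Existing
#'   `calf_size` labels are kept.
#' @return List with `records` and `audit`.
#' @export
edit_calving <- function(records) {
  r <- records
  audit <- empty_audit()
  note <- function(rule, ix, detail) {
    if (!length(ix)) return(audit)
    rbind(audit, data.frame(
      rule = rule,
      cow = as.character(if ("cow" %in% names(r)) r$cow[ix] else ix),
      parity = if ("parity" %in% names(r)) r$parity[ix] else NA_integer_,
      detail = detail, stringsAsFactors = FALSE))
  }
  drop <- logical(nrow(r))
  if ("gl" %in% names(r)) {
    bad <- which(!is.na(r$gl) & (r$gl < 260 | r$gl > 302))
    audit <- note("gl_out_of_bounds", bad, "GL outside [260, 302] days")
    drop[bad] <- TRUE
  }
  if ("ce" %in% names(r)) {
    bad <- which(!is.na(r$ce) & !(r$ce %in% 1:3))
    audit <- note("ambiguous_ce_code", bad, "CE not in 1..3")
    drop[bad] <- TRUE
  }
  if ("sb" %in% names(r)) {
    bad <- which(!is.na(r$sb) & !(r$sb %in% 1:2))
    audit <- note("ambiguous_sb_code", bad, "SB not in 1..2")
    drop[bad] <- TRUE
  }
  if ("birth_weight" %in% names(r) && !"calf_size" %in% names(r)) {
    bw <- r$birth_weight
    bad <- which(!is.na(bw) & (bw < 30 | bw > 60))
    audit <- note("birth_weight_out_of_bounds", bad,
                  "birth weight outside [30, 60] kg")
    drop[bad] <- TRUE
    r$calf_size <- cut(bw, breaks = c(30, 40, 50, 60),
                       labels = c("30-40", "40-50", "50-60"),
                       include.lowest = TRUE, right = FALSE)
    r$calf_size[!is.na(bw) & bw == 60] <- "50-60"
  }
  out <- r[!drop, , drop = FALSE]
  rownames(out) <- NULL
  list(records = out, audit = audit)
}

#' Expand simulated conception records into a raw insemination/event log
#'
#' Inverse of the editing layer, for round-trip testing and pipeline
#' demonstrations: turns per-insemination conception records (as produced
#' by [simulate_records()] for a success trait) into dated insemination
#' events, pregnancy diagnoses and calvings, using a fixed 21-day return
#' cycle, diagnosis 40 days after the conceiving service and calving 280
#' days after it.
#'
#' @param records Success-trait records with `cow`, `parity`,
#'   `insem_number`-like service order (row order within cow-parity is
#'   used), and `y` (1 = conception).
#' @param cycle_days,diag_lag,gestation_days Timing constants.
#' @return List of data frames `inseminations`, `diagnoses`, `calvings`.
#' @export
simulate_raw_log <- function(records, cycle_days = 21, diag_lag = 40,
                             gestation_days = 280) {
  stopifnot(all(c("cow", "parity", "y") %in% names(records)))
  key <- paste(records$cow, records$parity, sep = "\r")
  ord <- stats::ave(seq_along(key), key, FUN = seq_along)
  base <- as.numeric(factor(key)) * 1000    # separate parities in time
  date <- base + (ord - 1) * cycle_days
  ins <- data.frame(cow = records$cow, parity = records$parity, date = date,
                    stringsAsFactors = FALSE)
  keepcols <- intersect(c("sire", "technician", "semen_type"), names(records))
  for (cc in keepcols) ins[[cc]] <- records[[cc]]
  conc <- records$y == 1L
  diagnoses <- data.frame(cow = records$cow[conc],
                          parity = records$parity[conc],
                          date = date[conc] + diag_lag, positive = TRUE,
                          stringsAsFactors = FALSE)
  calvings <- data.frame(cow = records$cow[conc],
                         parity = records$parity[conc],
                         date = date[conc] + gestation_days,
                         stringsAsFactors = FALSE)
  list(inseminations = ins, diagnoses = diagnoses, calvings = calvings)
}
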