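#' Per-protein normalization of a plate reading
#'
#' Whole-body analyte quantities are expressed per mg of protein
#' (mg glucose / mg protein, mg TGA / mg protein) so that fly size drops
#' out. Wells with no measurable protein have no defined ratio and are
#' returned as `NA` with a warning so they can be rejected with a logged
#' reason.
#'
#' @param analyte_mg,protein_mg well quantities in mg; vectorized.
#' @return numeric vector of ratios.
#' @export
normalize_per_protein <- function(analyte_mg, protein_mg) {
  bad <- !is.na(protein_mg) & protein_mg <= 0
  if (any(bad)) warning(sum(bad), " well(s) rejected: protein quantity <= 0")
  out <- analyte_mg / protein_mg
  out[bad] <- NA_real_
  out
}

#' CantonS-normalized plate values
#'
#' Divides each well's per-protein value by the mean per-protein value
#' of the CantonS control wells on the same plate (per analyte). Because
#' any multiplicative plate effect hits experimental and control wells
#' alike, the normalized values are exactly invariant to it. Plates
#' without a usable CantonS well for an analyte are flagged and their
#' wells returned as `NA`.
#'
#' @param plates data frame of plate readings: `plate_id`, `well`,
#'   `genotype` (`"CantonS"` and `"Akhr"` are controls), `analyte`
#'   (`"glucose"`/`"TGA"`), `analyte_mg`, `protein_mg`, plus factors.
#' @return `plates` with added columns `per_protein` and `cantons_norm`.
#' @export
normalize_to_cantons <- function(plates) {
  plates$per_protein <- normalize_per_protein(plates$analyte_mg,
                                              plates$protein_mg)
  plates$cantons_norm <- NA_real_
  key <- paste(plates$plate_id, plates$analyte, sep = "\r")
  for (k in unique(key)) {
    sel <- key == k
    ctl <- plates$per_protein[sel & plates$genotype == "CantonS"]
    ctl <- ctl[!is.na(ctl)]
    if (!length(ctl)) {
      warning("plate ", plates$plate_id[sel][1], " has no usable CantonS well for ",
              plates$analyte[sel][1], "; left unnormalized")
      next
    }
    plates$cantons_norm[sel] <- plates$per_protein[sel] / mean(ctl)
  }
  plates
}

#' Control-genotype plate quality control
#'
#' Akhr (adipokinetic hormone receptor) mutants store elevated
#' triglyceride but normal glucose relative to CantonS; a plate whose
#' control wells do not reproduce this pattern indicates an assay
#' problem. Per plate, a one-sided Welch t-test of Akhr TGA > CantonS
#' TGA must be significant and a two-sided Welch t-test of Akhr vs
#' CantonS glucose must not be, both at `alpha`; otherwise the plate
#' fails. Plates with fewer than 2 replicate control wells per genotype
#' for a required analyte are "indeterminate" (kept, flagged).
#'
#' @param plates plate readings (see [normalize_to_cantons()]).
#' @param alpha significance level for both control tests.
#' @return data frame, one row per plate: `plate_id`, `p_tga`
#'   (one-sided, Akhr greater), `p_glucose` (two-sided), `verdict`
#'   (`"PASS"`/`"FAIL"`/`"indeterminate"`).
#' @export
plate_qc <- function(plates, alpha = 0.05) {
  plates$per_protein <- normalize_per_protein(plates$analyte_mg,
                                              plates$protein_mg)
  rows <- lapply(split(plates, plates$plate_id), function(d) {
    pull <- function(geno, analyte) {
      v <- d$per_protein[d$genotype == geno & d$analyte == analyte]
      v[!is.na(v)]
    }
    akhr_tga <- pull("Akhr", "TGA"); cs_tga <- pull("CantonS", "TGA")
    akhr_glu <- pull("Akhr", "glucose"); cs_glu <- pull("CantonS", "glucose")
    out <- data.frame(plate_id = d$plate_id[1], p_tga = NA_real_,
                      p_glucose = NA_real_, verdict = "indeterminate")
    has_tga <- length(akhr_tga) >= 2 && length(cs_tga) >= 2
    has_glu <- length(akhr_glu) >= 2 && length(cs_glu) >= 2
    if (!has_tga && !has_glu) return(out)
    fail <- FALSE
    if (has_tga) {
      out$p_tga <- t.test(akhr_tga, cs_tga, alternative = "greater")$p.value
      if (out$p_tga >= alpha) fail <- TRUE
    }
    if (has_glu) {
      out$p_glucose <- t.test(akhr_glu, cs_glu)$p.value
      if (out$p_glucose < alpha) fail <- TRUE
    }
    if (!has_tga || !has_glu) {
      out$verdict <- "indeterminate"
    } else {
      out$verdict <- if (fail) "FAIL" else "PASS"
    }
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Line-level metabolite summary
#'
#' Drops wells on failed plates (indeterminate plates are kept), then
#' averages per-protein and CantonS-normalized values per line, sex and
#' temperature for each analyte.
#'
#' @param plates plate readings.
#' @param qc output of [plate_qc()]; computed if missing.
#' @param alpha QC significance level when `qc` is missing.
#' @return data frame: `line`, `sex`, `temperature`,
#'   `glucose_per_protein`, `tga_per_protein`, `glucose_cantons_norm`,
#'   `tga_cantons_norm`, `n_glucose`, `n_tga`.
#' @export
summarize_metabolites <- function(plates, qc = NULL, alpha = 0.05) {
  if (is.null(qc)) qc <- plate_qc(plates, alpha)
  failed <- qc$plate_id[qc$verdict == "FAIL"]
  if (length(failed)) {
    message(length(failed), " plate(s) failed control QC and were excluded: ",
            paste(failed, collapse = ", "))
  }
  d <- normalize_to_cantons(plates[!plates$plate_id %in% failed, , drop = FALSE])
  d <- d[!d$genotype %in% c("CantonS", "Akhr"), , drop = FALSE]
  if (!"line" %in% names(d)) d$line <- d$genotype
  by <- intersect(c("line", "population", "sex", "temperature"), names(d))
  key <- do.call(paste, c(d[by], sep = "\r"))
  rows <- lapply(split(d, key), function(g) {
    out <- g[1, by, drop = FALSE]
    for (a in c("glucose", "TGA")) {
      sel <- g$analyte == a
      nm <- if (a == "glucose") "glucose" else "tga"
      out[[paste0(nm, "_per_protein")]] <- mean(g$per_protein[sel], na.rm = TRUE)
      out[[paste0(nm, "_cantons_norm")]] <- mean(g$cantons_norm[sel], na.rm = TRUE)
      out[[paste0("n_", nm)]] <- sum(sel & !is.na(g$per_protein))
    }
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[do.call(order, out[by]), ]
}
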