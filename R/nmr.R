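#' Secondary Calpha chemical shifts
#'
#' Difference between observed Calpha shifts and a user-supplied
#' random-coil reference, per residue:
#' `delta_delta_Ca(i) = delta_obs(i) - delta_rc(i)`.  Positive values
#' indicate alpha-helical structure.  Residues missing a reference are
#' omitted from the result (reported absent, not zero).
#'
#' @param observed data.frame with `resno`, `resname`, `shift_ppm`.
#' @param random_coil data.frame with `resno`, `resname`, `shift_ppm`
#'   (literature random-coil values; no scale is hardcoded).
#' @return data.frame `resno`, `resname`, `delta_delta_ca_ppm`.
#' @export
secondary_ca_shift <- function(observed, random_coil) {
  need <- c("resno", "resname", "shift_ppm")
  stopifnot(all(need %in% names(observed)), all(need %in% names(random_coil)))
  m <- merge(observed, random_coil, by = "resno",
             suffixes = c("_obs", "_rc"))
  if (nrow(m) && any(m$resname_obs != m$resname_rc))
    stop("residue-type mismatch between observed and reference tables at ",
         paste(m$resno[m$resname_obs != m$resname_rc], collapse = ", "))
  out <- data.frame(resno = m$resno, resname = m$resname_obs,
                    delta_delta_ca_ppm = m$shift_ppm_obs - m$shift_ppm_rc)
  out[order(out$resno), , drop = FALSE]
}

#' Concentration-dependent chemical shift perturbation, normalized
#'
#' Magnitude of self-assembly monitored on a probe resonance: the 15N
#' chemical shift perturbation between a high-concentration condition
#' (where intermolecular interactions form) and a low-concentration
#' monomeric reference, `ddN = |dN(high) - dN(low)|`, normalized to the
#' wild-type value (`CSP_norm = ddN / ddN_wt`).  Variants whose probe is
#' broadened beyond detection are declared through `excluded`, which
#' returns an explicit exclusion marker rather than 0.
#'
#' @param table_high,table_low data.frames with `resno` and `shift_n_ppm`
#'   (15N shifts) at the high and low concentration.
#' @param probe_resno probe residue number (default 328, the A328 amide).
#' @param wt_reference wild-type perturbation, ppm; `NULL` returns the raw
#'   perturbation (use for the WT itself).
#' @param excluded set `TRUE` when the probe is broadened beyond detection.
#' @return list `delta_n_ppm`, `csp_norm` (NULL when no reference),
#'   `excluded`.
#' @export
csp_norm <- function(table_high, table_low, probe_resno = 328,
                     wt_reference = NULL, excluded = FALSE) {
  if (excluded)
    return(structure(list(delta_n_ppm = NA_real_, csp_norm = NA_real_,
                          excluded = TRUE, reason = "broadened_NMR"),
                     class = "csp"))
  hi <- table_high$shift_n_ppm[table_high$resno == probe_resno]
  lo <- table_low$shift_n_ppm[table_low$resno == probe_resno]
  if (length(hi) != 1)
    stop("probe residue ", probe_resno, " missing in the high-concentration table")
  if (length(lo) != 1)
    stop("probe residue ", probe_resno, " missing in the low-concentration table")
  dn <- abs(hi - lo)
  if (!is.null(wt_reference)) {
    if (!is.finite(wt_reference) || wt_reference <= 0)
      stop("wt_reference must be > 0")
    cn <- dn / wt_reference
  } else cn <- NULL
  structure(list(delta_n_ppm = dn, csp_norm = cn, excluded = FALSE),
            class = "csp")
}

#' Solvent-PRE attenuation profile
#'
#' Per-residue attenuation of peak intensities by a soluble paramagnet,
#' `ratio(i, c) = I_para(i, c) / I_ref(i)`, normalized to the sample
#' without paramagnet.  Residues attenuated below `exposure_threshold`
#' at the highest paramagnet concentration (a ratio of 0 is complete
#' signal loss) are flagged solvent-exposed.
#'
#' @param intensities_para matrix (residues x paramagnet concentrations) of
#'   peak intensities, rownames = residue labels.
#' @param intensities_ref vector of reference intensities (no paramagnet),
#'   all > 0.
#' @param concentrations paramagnet concentrations (mM), one per column.
#' @param exposure_threshold attenuation ratio below which a residue is
#'   called solvent-exposed.
#' @return data.frame with `residue`, one `ratio_<conc>` column per
#'   concentration, and `exposed`.
#' @export
spre_attenuation <- function(intensities_para, intensities_ref,
                             concentrations, exposure_threshold = 0.1) {
  intensities_para <- as.matrix(intensities_para)
  stopifnot(nrow(intensities_para) == length(intensities_ref),
            ncol(intensities_para) == length(concentrations))
  if (any(intensities_ref <= 0)) stop("reference intensities must be > 0")
  ratios <- sweep(intensities_para, 1, intensities_ref, "/")
  colnames(ratios) <- paste0("ratio_", concentrations)
  exposed <- ratios[, which.max(concentrations)] < exposure_threshold
  res <- rownames(intensities_para)
  if (is.null(res)) res <- as.character(seq_len(nrow(ratios)))
  data.frame(residue = res, ratios, exposed = exposed, row.names = NULL)
}
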