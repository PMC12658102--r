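#' Construct a mutant measurement table
#'
#' Per-variant measurements used in the cross-modality correlation
#' analyses: saturation concentrations, normalized chemical-shift
#' perturbations, per-residue contact totals, toxicity scores, and named
#' exclusion flags (e.g. `broadened_NMR`, `no_droplets`,
#' `irregular_morphology`).  Excluded rows are carried, never silently
#' dropped, and never enter correlations.
#'
#' @param data data.frame with at least a `variant` column; measurement
#'   columns are free-form (e.g. `csat_uM`, `csp_norm`, `n_contact`,
#'   `toxicity`); optional `exclude` (character reason, `NA` = included)
#'   and logical `is_wt`.
#' @return the validated data.frame, class `mutant_table`.
#' @export
mutant_table <- function(data) {
  stopifnot(is.data.frame(data), "variant" %in% names(data))
  if (anyDuplicated(data$variant)) stop("duplicate variant labels")
  if (is.null(data$exclude)) data$exclude <- NA_character_
  if (is.null(data$is_wt)) data$is_wt <- toupper(data$variant) == "WT"
  if (!is.character(data$exclude)) data$exclude <- as.character(data$exclude)
  structure(data, class = c("mutant_table", "data.frame"))
}

#' Mean and SD of saturation-concentration replicates
#'
#' Summarizes supernatant-assay replicates per condition and flags
#' behaviors that need attention: non-monotone c_sat across increasing salt
#' (c_sat is expected non-increasing), and "no phase separation" when the
#' supernatant stays at the loading concentration at every condition.
#'
#' @param replicates data.frame with `condition` (e.g. salt mM),
#'   `csat_uM` replicate values (>= 2 per condition for a SD).
#' @param loading_uM loading concentration; used for the
#'   no-phase-separation flag.
#' @param tol relative tolerance for "supernatant equals loading".
#' @return data.frame `condition`, `mean_uM`, `sd_uM`, `n`; attributes
#'   `non_monotone` and `no_phase_separation`.
#' @export
csat_estimate <- function(replicates, loading_uM = NULL, tol = 0.05) {
  stopifnot(all(c("condition", "csat_uM") %in% names(replicates)))
  sp <- split(replicates$csat_uM, replicates$condition)
  out <- data.frame(
    condition = as.numeric(names(sp)),
    mean_uM = vapply(sp, mean, 0),
    sd_uM = vapply(sp, function(x) if (length(x) >= 2) sd(x) else NA_real_, 0),
    n = vapply(sp, length, 0L), row.names = NULL)
  out <- out[order(out$condition), ]
  if (any(out$n < 2))
    warning("fewer than 2 replicates for some conditions; SD unavailable")
  non_mono <- any(diff(out$mean_uM) > 0 + pmax(out$sd_uM[-1], 0, na.rm = TRUE))
  no_ps <- if (!is.null(loading_uM))
    all(abs(out$mean_uM - loading_uM) <= tol * loading_uM) else NA
  structure(out, non_monotone = isTRUE(non_mono),
            no_phase_separation = no_ps)
}

#' Correlate two per-variant measures
#'
#' Pearson or Spearman correlation between two columns of a
#' [mutant_table], applying exclusion flags pairwise and optionally
#' normalizing both axes to the wild-type row (an affine rescaling, so the
#' coefficient itself is unchanged; normalization matters only for
#' reporting the values).
#'
#' @param table a [mutant_table].
#' @param x,y column names to correlate.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param normalize_to_wt divide both axes by the WT row values.
#' @param include_wt keep the WT row in the correlation sample.
#' @return list `r`, `n`, `method`, `excluded` (data.frame of variants and
#'   reasons), `data` (the values used).
#' @export
correlate_measures <- function(table, x, y,
                               method = c("pearson", "spearman"),
                               normalize_to_wt = FALSE, include_wt = TRUE) {
  method <- match.arg(method)
  stopifnot(inherits(table, "mutant_table"),
            x %in% names(table), y %in% names(table))
  d <- as.data.frame(table)
  drop <- !is.na(d$exclude) | !is.finite(d[[x]]) | !is.finite(d[[y]])
  excluded <- data.frame(variant = d$variant[drop],
                         reason = ifelse(is.na(d$exclude[drop]),
                                         "missing value", d$exclude[drop]))
  d <- d[!drop, ]
  if (normalize_to_wt) {
    wt <- d[d$is_wt, ]
    if (nrow(wt) != 1) stop("WT row required for normalization")
    d[[x]] <- d[[x]] / wt[[x]]
    d[[y]] <- d[[y]] / wt[[y]]
  }
  if (!include_wt) d <- d[!d$is_wt, ]
  if (nrow(d) < 3)
    stop("fewer than 3 variant pairs remain after exclusions")
  list(r = cor(d[[x]], d[[y]], method = method), n = nrow(d),
       method = method, excluded = excluded,
       data = d[, c("variant", x, y)])
}
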