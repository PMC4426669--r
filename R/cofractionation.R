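#' Normalized sedimentation profiles over an analysis window
#'
#' Sums intensities over replicates per (protein, fraction), restricts
#' to the analysis window (default fractions 6-9, the window the
#' complex peaks in under drug), and rescales each protein's windowed
#' profile to sum to 1. Proteins with zero total windowed intensity are
#' excluded and reported in the `excluded` field rather than dropped
#' silently.
#'
#' @param table a `fraction_intensity_table` (columns `protein_id`,
#'   `replicate`, `fraction`, `intensity`).
#' @param window inclusive, contiguous fraction indices (length >= 3
#'   for downstream correlation).
#' @return an object of class `profile_matrix`: list with `profiles`
#'   (matrix, rows = proteins, columns = window fractions, rows sum to
#'   1), `window`, and `excluded` (character vector).
#' @export
normalize_profiles <- function(table, window = 6:9) {
  req <- c("protein_id", "replicate", "fraction", "intensity")
  if (!all(req %in% names(table))) {
    stopf("table must have columns: %s", paste(req, collapse = ", "))
  }
  if (any(table$intensity < 0)) stopf("intensities must be non-negative")
  window <- as.integer(window)
  if (any(diff(window) != 1L)) stopf("window must be contiguous")
  if (!all(window %in% table$fraction)) {
    stopf("window outside the table's fraction range")
  }
  sub <- table[table$fraction %in% window, ]
  agg <- stats::aggregate(intensity ~ protein_id + fraction, data = sub,
                          FUN = sum)
  prot <- sort(unique(agg$protein_id))
  mat <- matrix(0, nrow = length(prot), ncol = length(window),
                dimnames = list(prot, as.character(window)))
  mat[cbind(match(agg$protein_id, prot),
            match(agg$fraction, window))] <- agg$intensity
  totals <- rowSums(mat)
  excluded <- prot[totals == 0]
  keep <- totals > 0
  mat <- mat[keep, , drop = FALSE] / totals[keep]
  structure(list(profiles = mat, window = window, excluded = excluded),
            class = "profile_matrix")
}

#' Pearson correlation of every profile against a reference protein
#'
#' The co-sedimentation statistic: each protein's normalized windowed
#' profile is correlated (product-moment) with the reference subunit's
#' profile; proteins of the same complex track the reference closely
#' (R near 1). Constant profiles have undefined R and are flagged with
#' `NA`; the output is ranked by R, descending.
#'
#' @param profiles a `profile_matrix` from [normalize_profiles()].
#' @param reference_id protein id of the reference subunit.
#' @return a data.frame of class `correlation_table` with columns
#'   `protein_id`, `R`, `rank` (NA rank for flagged proteins), sorted
#'   by R descending.
#' @export
correlate_to_reference <- function(profiles, reference_id) {
  stopifnot(inherits(profiles, "profile_matrix"))
  mat <- profiles$profiles
  if (ncol(mat) < 3) stopf("window length must be >= 3 for correlation")
  if (!reference_id %in% rownames(mat)) {
    stopf("reference '%s' not present", reference_id)
  }
  ref <- mat[reference_id, ]
  if (sd(ref) == 0) stopf("zero-variance reference profile")
  sds <- apply(mat, 1, sd)
  R <- rep(NA_real_, nrow(mat))
  R[sds > 0] <- apply(mat[sds > 0, , drop = FALSE], 1, cor, y = ref)
  out <- data.frame(protein_id = rownames(mat), R = R,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$R, out$protein_id, na.last = TRUE), ]
  out$rank <- ifelse(is.na(out$R), NA_integer_, seq_len(nrow(out)))
  rownames(out) <- NULL
  class(out) <- c("correlation_table", "data.frame")
  out
}

#' Calibrate a gradient in Svedberg units from sedimentation standards
#'
#' Ordinary least-squares line `S = slope * fraction + intercept`
#' through standards of known sedimentation coefficient and observed
#' peak fraction (e.g. ovalbumin 3.5 S, aldolase 7.3 S, thyroglobulin
#' 19 S). Heavier species sediment further, so the slope must be
#' positive.
#'
#' @param standards data.frame with columns `label`, `S`,
#'   `peak_fraction`; at least 2 standards at distinct fractions.
#' @return an object of class `svedberg_calibration` with `slope`,
#'   `intercept` and the standards table. Evaluate with
#'   [svedberg_at()] or `predict()`.
#' @export
calibrate_svedberg <- function(standards) {
  req <- c("label", "S", "peak_fraction")
  if (!is.data.frame(standards) || !all(req %in% names(standards))) {
    stopf("standards must be a data.frame with columns: %s",
          paste(req, collapse = ", "))
  }
  if (nrow(standards) < 2) stopf("need >= 2 standards")
  if (anyDuplicated(standards$peak_fraction)) {
    stopf("standards must peak at distinct fractions")
  }
  fit <- lm(S ~ peak_fraction, data = standards)
  slope <- unname(coef(fit)[2])
  if (slope <= 0) stopf("calibration slope must be positive")
  structure(list(slope = slope, intercept = unname(coef(fit)[1]),
                 standards = standards),
            class = "svedberg_calibration")
}

#' Evaluate a Svedberg calibration at a fraction index
#' @param calibration a [calibrate_svedberg()] object.
#' @param fraction fraction index (may be fractional).
#' @return sedimentation coefficient(s) in S.
#' @export
svedberg_at <- function(calibration, fraction) {
  stopifnot(inherits(calibration, "svedberg_calibration"))
  calibration$slope * fraction + calibration$intercept
}

#' @export
predict.svedberg_calibration <- function(object, fraction, ...) {
  svedberg_at(object, fraction)
}

#' Peak fraction of each normalized profile
#'
#' Argmax over the window; ties broken toward the lighter (lower-index)
#' fraction. Used to place calibration standards.
#'
#' @param profiles a `profile_matrix`.
#' @return named numeric vector of peak fraction indices.
#' @export
peak_fractions <- function(profiles) {
  stopifnot(inherits(profiles, "profile_matrix"))
  idx <- apply(profiles$profiles, 1, which.max)
  setNames(profiles$window[idx], rownames(profiles$profiles))
}

#' Condition shift of sedimentation profiles
#'
#' Per protein present in both conditions, the difference of
#' intensity-weighted mean fractions:
#' `delta = sum(f * p_drug(f)) - sum(f * p_ctrl(f))`. Positive values
#' mean a shift toward heavier fractions under drug.
#'
#' @param profiles_ctrl,profiles_drug `profile_matrix` objects computed
#'   over the same window.
#' @return data.frame with columns `protein_id`, `delta`.
#' @export
detect_shift <- function(profiles_ctrl, profiles_drug) {
  stopifnot(inherits(profiles_ctrl, "profile_matrix"),
            inherits(profiles_drug, "profile_matrix"))
  if (!identical(profiles_ctrl$window, profiles_drug$window)) {
    stopf("window mismatch between conditions")
  }
  shared <- intersect(rownames(profiles_ctrl$profiles),
                      rownames(profiles_drug$profiles))
  w <- as.numeric(profiles_ctrl$window)
  delta <- vapply(shared, function(p) {
    sum(w * profiles_drug$profiles[p, ]) -
      sum(w * profiles_ctrl$profiles[p, ])
  }, numeric(1))
  data.frame(protein_id = shared, delta = unname(delta),
             stringsAsFactors = FALSE)
}
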