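# Built-in analog potency presets (EC50, molar), as printed for the
# drug series: the parent trans-isomer A1 (5 nM), the phenyl-spacer A7
# (53 nM), the cyclobutyl diastereomers A4 (142 nM) and A5 (1 uM), and
# the doubly meta-substituted A17 (600 pM). A17 curves are dosed from
# 100 nM; the others from 1 uM.
.dose_presets <- function() {
  list(
    A1  = list(ec50 = 5e-9,    top_dose = 1e-6),
    A7  = list(ec50 = 5.3e-8,  top_dose = 1e-6),
    A4  = list(ec50 = 1.42e-7, top_dose = 1e-6),
    A5  = list(ec50 = 1e-6,    top_dose = 1e-5),
    A17 = list(ec50 = 6e-10,   top_dose = 1e-7)
  )
}

#' Preset parameters for luminescence dose-response curves
#'
#' Parameters of a four-parameter logistic (4PL) reporter readout for
#' one analog. Built-in presets carry the measured cell-culture
#' potencies of the analog series (see [dose_preset_names()]); doses
#' default to an 8-point threefold serial dilution from the preset's
#' top dose, in duplicate, with 3% multiplicative CV noise.
#'
#' @param name a built-in analog name, or `"custom"` with `ec50` given.
#' @param ec50 molar EC50 (overrides the preset).
#' @param hill Hill slope (default 1.5).
#' @param top,bottom response asymptotes (relative luminescence units).
#' @param doses molar dose vector, positive and distinct. Default: 8
#'   threefold dilutions from the preset top dose.
#' @param noise_cv relative SD of multiplicative response noise.
#' @param n_rep replicates per dose (default 2).
#' @return an object of class `dose_preset`.
#' @export
dose_preset <- function(name = "A1", ec50 = NULL, hill = 1.5,
                        top = 100, bottom = 10, doses = NULL,
                        noise_cv = 0.03, n_rep = 2) {
  presets <- .dose_presets()
  if (name != "custom") {
    if (!name %in% names(presets)) {
      stopf("unknown dose preset '%s' (built-ins: %s)", name,
            paste(names(presets), collapse = ", "))
    }
    ec50 <- ec50 %||% presets[[name]]$ec50
    doses <- doses %||% (presets[[name]]$top_dose / 3^(0:7))
  }
  if (is.null(ec50)) stopf("custom preset requires ec50")
  doses <- doses %||% (1e-6 / 3^(0:7))
  if (ec50 <= 0) stopf("ec50 must be positive")
  if (top <= bottom) stopf("top must exceed bottom")
  if (any(doses <= 0)) stopf("doses must be positive")
  if (anyDuplicated(doses)) stopf("doses must be distinct")
  if (noise_cv < 0) stopf("noise_cv must be non-negative")
  if (n_rep < 1) stopf("n_rep must be >= 1")
  structure(list(name = name, ec50 = ec50, hill = hill, top = top,
                 bottom = bottom, doses = sort(doses, decreasing = TRUE),
                 noise_cv = noise_cv, n_rep = as.integer(n_rep)),
            class = "dose_preset")
}

#' Names of the built-in analog potency presets
#' @return character vector of analog names.
#' @export
dose_preset_names <- function() names(.dose_presets())

# Four-parameter logistic response at the given doses.
four_pl <- function(dose, ec50, hill, top, bottom) {
  bottom + (top - bottom) / (1 + (ec50 / dose)^hill)
}

#' Simulate a reporter dose-response table
#'
#' Response = `4PL(dose) * (1 + Normal(0, noise_cv))`, i.e. a
#' multiplicative CV on the luminescence signal.
#'
#' @param preset a [dose_preset()].
#' @param seed integer seed.
#' @return a data.frame of class `dose_response_dataset` with columns
#'   `analog`, `replicate`, `dose_molar`, `response`.
#' @export
simulate_dose_response <- function(preset, seed = 0) {
  stopifnot(inherits(preset, "dose_preset"))
  mu <- four_pl(preset$doses, preset$ec50, preset$hill, preset$top,
                preset$bottom)
  with_seed(seed, {
    rows <- lapply(seq_len(preset$n_rep), function(r) {
      resp <- mu * (1 + rnorm(length(mu), sd = preset$noise_cv))
      data.frame(analog = preset$name, replicate = r,
                 dose_molar = preset$doses, response = resp,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    class(out) <- c("dose_response_dataset", "data.frame")
    out
  })
}
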