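# Built-in GDP-release presets. Rate constants are derived exactly from
# the published half-lives (k = ln 2 / t_half); the intrinsic rate comes
# from 20% release after 20 min of unassisted exchange
# (k = -ln(0.8) / 20). Replicate counts follow the reported N per panel.
.decay_presets <- function() {
  k_int <- -log(0.8) / 20
  list(
    intrinsic      = list(k = k_int,          n_rep = 3),
    gef_basal      = list(k = log(2) / 3.2,   n_rep = 3),
    gef_isrib      = list(k = log(2) / 1.1,   n_rep = 3),
    mix31_noisrib  = list(k = log(2) / 6.7,   n_rep = 2),
    mix31_isrib    = list(k = log(2) / 2.7,   n_rep = 2),
    mix11_noisrib  = list(k = log(2) / 6.4,   n_rep = 2),
    mix11_isrib    = list(k = log(2) / 5.3,   n_rep = 2),
    eif2P_gef      = list(k = k_int,          n_rep = 2)
  )
}

#' Preset parameters for GDP-dissociation time courses
#'
#' Returns a validated parameter set for [simulate_decay()]. Built-in
#' presets cover the measured exchange regimes: `intrinsic` (unassisted
#' GDP release from eIF2; 20% released after 20 min), `gef_basal` /
#' `gef_isrib` (GEF-catalyzed exchange, half-life 3.2 min, accelerated
#' to 1.1 min by drug), `mix31_*` and `mix11_*` (3:1 and 1:1
#' substrate : phospho-inhibitor mixes; half-lives 6.7/2.7 and
#' 6.4/5.3 min) and `eif2P_gef` (phosphorylated substrate; release
#' stays at the intrinsic rate even with GEF present).
#'
#' @param name one of the built-in preset names, or `"custom"` with `k`
#'   supplied.
#' @param k first-order rate constant, 1/min (overrides the preset).
#' @param plateau residual bound fraction in `[0, 1)` (default 0).
#' @param timepoints sampling times, minutes, strictly increasing.
#' @param noise_sd additive Gaussian SD on the bound fraction.
#' @param n_rep number of replicates (defaults to the preset's N).
#' @return an object of class `decay_preset`.
#' @export
decay_preset <- function(name = "gef_basal", k = NULL, plateau = 0,
                         timepoints = c(0, 1, 2, 4, 8, 12, 20),
                         noise_sd = 0.02, n_rep = NULL) {
  presets <- .decay_presets()
  if (name != "custom") {
    if (!name %in% names(presets)) {
      stopf("unknown decay preset '%s' (built-ins: %s)", name,
            paste(names(presets), collapse = ", "))
    }
    k <- k %||% presets[[name]]$k
    n_rep <- n_rep %||% presets[[name]]$n_rep
  }
  if (is.null(k)) stopf("custom preset requires k")
  n_rep <- n_rep %||% 3L
  if (k < 0) stopf("k must be non-negative")
  if (plateau < 0 || plateau >= 1) stopf("plateau must be in [0, 1)")
  if (any(timepoints < 0) || is.unsorted(timepoints, strictly = TRUE)) {
    stopf("timepoints must be non-negative and strictly increasing")
  }
  if (noise_sd < 0) stopf("noise_sd must be non-negative")
  if (n_rep < 1) stopf("n_rep must be >= 1")
  structure(list(name = name, k = k, plateau = plateau,
                 timepoints = timepoints, noise_sd = noise_sd,
                 n_rep = as.integer(n_rep)),
            class = "decay_preset")
}

#' Names of the built-in decay presets
#' @return character vector of preset names.
#' @export
decay_preset_names <- function() names(.decay_presets())

#' Simulate a radiolabeled-GDP release time course
#'
#' Bound fraction
#' `F(t) = plateau + (1 - plateau) * exp(-k t) + Normal(0, noise_sd)`,
#' clipped to `[0, 1.05]` (filter-binding readouts can slightly exceed
#' the nominal t = 0 signal).
#'
#' @param preset a [decay_preset()].
#' @param seed integer seed.
#' @return a data.frame of class `decay_dataset` with columns
#'   `condition`, `replicate`, `time_min`, `bound_fraction`.
#' @export
simulate_decay <- function(preset, seed = 0) {
  stopifnot(inherits(preset, "decay_preset"))
  tp <- preset$timepoints
  mu <- preset$plateau + (1 - preset$plateau) * exp(-preset$k * tp)
  with_seed(seed, {
    rows <- lapply(seq_len(preset$n_rep), function(r) {
      f <- mu + rnorm(length(tp), sd = preset$noise_sd)
      data.frame(condition = preset$name, replicate = r, time_min = tp,
                 bound_fraction = pmin(pmax(f, 0), 1.05),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    class(out) <- c("decay_dataset", "data.frame")
    out
  })
}
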