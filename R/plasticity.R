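#' Plasticity parameters of the PF-PC learning rule
#'
#' LTD and LTP learning rates per 10 ms control step and the spontaneous
#' climbing-fiber rate that encodes the non-preferred error direction.
#'
#' @param gamma_ltd LTD rate (default 4e-6 per step)
#' @param gamma_ltp LTP rate (default 0.3e-6 per step)
#' @param cf_spont spontaneous CF activity (default 0.05)
#' @return list(gamma_ltd, gamma_ltp, cf_spont)
#' @export
plasticity_params <- function(gamma_ltd = 4e-6, gamma_ltp = 0.3e-6,
                              cf_spont = 0.05) {
  stopifnot(gamma_ltd > 0, gamma_ltp > 0, cf_spont > 0,
            gamma_ltd > gamma_ltp)
  list(gamma_ltd = gamma_ltd, gamma_ltp = gamma_ltp, cf_spont = cf_spont)
}

#' Encode a signed task error into the two climbing fibers
#'
#' Each hemisphere's CF prefers one direction of motion: the left CF rises
#' above the spontaneous rate for forward (positive) error and dips slightly
#' below it for backward error; the right CF mirrors this. The mapping is a
#' clipped linear function, continuous in the error, with a strong
#' preferred-direction gain and a weak non-preferred gain:
#' `cf_left = clip(cf_spont + g_pref * max(e, 0) - g_np * max(-e, 0), 0, 1)`.
#'
#' @param error signed task error (preferred direction of the left CF is
#'   positive error)
#' @param params list from [plasticity_params()]
#' @param g_pref gain on the preferred error direction (maps the plant's
#'   typical peak error to a CF rate around 0.5)
#' @param g_np gain on the non-preferred direction (default `g_pref / 10`)
#' @return list(cf_left, cf_right), both in [0, 1]
#' @export
encode_cf <- function(error, params = plasticity_params(),
                      g_pref = 1, g_np = g_pref / 10) {
  stopifnot(is.finite(error), g_pref > 0, g_np > 0)
  up <- pmax(error, 0); dn <- pmax(-error, 0)
  cf_l <- pmin(1, pmax(0, params$cf_spont + g_pref * up - g_np * dn))
  cf_r <- pmin(1, pmax(0, params$cf_spont + g_pref * dn - g_np * up))
  list(cf_left = cf_l, cf_right = cf_r)
}

#' Apply one step of the LTD/LTP rule to PF-PC weights
#'
#' When the CF rate exceeds its spontaneous level, every parallel-fiber
#' synapse is depressed in proportion to both the CF rate and its own PF
#' rate (`dw = -gamma_ltd * cf * y_pf`); otherwise every synapse is
#' potentiated in proportion to its PF rate alone (`dw = gamma_ltp * y_pf`).
#' Equality `cf == cf_spont` routes to the LTP branch (the depression
#' condition is a strict inequality). Weights are floored at zero; synapses
#' of knocked-down GCs carry `y_pf = 0` and are therefore untouched.
#'
#' @param w PF-PC weight vector (aligned with the PF->PC connectivity)
#' @param y_pf PF (granule-cell) rates gathered for those synapses, in [0,1]
#' @param cf climbing-fiber rate in [0, 1]
#' @param params list from [plasticity_params()]
#' @return the updated weight vector
#' @export
update_pf_pc <- function(w, y_pf, cf, params = plasticity_params()) {
  stopifnot(cf >= 0, cf <= 1)
  dw <- if (cf > params$cf_spont) {
    -params$gamma_ltd * cf * y_pf
  } else {
    params$gamma_ltp * y_pf
  }
  pmax(w + dw, 0)
}
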