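#' Activation parameters
#'
#' Sigmoid slope and threshold shared by all populations (defaults sigma = 8,
#' mu = 1/2).
#'
#' @param sigma slope (> 0)
#' @param mu threshold
#' @return list(sigma, mu)
#' @export
activation_params <- function(sigma = 8, mu = 0.5) {
  stopifnot(sigma > 0)
  list(sigma = sigma, mu = mu)
}

# Unit sigmoid used by the non-PC populations: rates in [0, 1].
rate_sigmoid <- function(x, sigma = 8, mu = 0.5) {
  1 / (1 + exp(-sigma * (x - mu)))
}

#' Purkinje-cell activation
#'
#' `y = 1 / (1 + exp(-sigma (x - mu))) - 0.5`: a centred sigmoid whose range
#' is the open interval (-0.5, 0.5), zero at `x = mu`, strictly increasing.
#' The -0.5 offset is specific to the PC; granule, Golgi and basket/stellate
#' rates use the same sigmoid without the offset so they stay in `[0, 1]`.
#'
#' @param x pre-activation (finite)
#' @param params list(sigma, mu) as from [activation_params()]
#' @return firing rate in (-0.5, 0.5)
#' @export
pc_rate <- function(x, params = activation_params()) {
  rate_sigmoid(x, params$sigma, params$mu) - 0.5
}

#' Initial hemisphere state
#'
#' All rates start at zero (quiescent network before the first control step).
#'
#' @param net a `hemisphere_net`
#' @return an object of class `hemisphere_state`
#' @export
hemisphere_state <- function(net) {
  n <- net$counts
  structure(list(
    y_mf = numeric(n[["MF"]]),
    y_gc = numeric(n[["GC"]]),
    y_go = numeric(n[["GO"]]),
    y_bc = numeric(n[["BC"]]),
    y_pc = 0, x_pc = 0
  ), class = "hemisphere_state")
}

# Gather-and-sum of one synapse group: for each target, sum over its
# afferents of (weight x source rate). `w` already carries the normalizer d.
group_drive <- function(group, y_src, scale = 1) {
  cm <- group$conn
  if (nrow(cm) == 0L) return(numeric(0))
  m <- matrix(group$w * y_src[cm] * scale, nrow = nrow(cm))
  rowSums(m)
}

#' Advance one hemisphere by one control step
#'
#' Populations update in the order GO, GC, BC, PC. Feedforward projections
#' (MF->GO, MF->GC, PF->BC, PF->PC, BC->PC) use the current step's rates;
#' the recurrent loops (PF->GO, BC->GO, GO->GC, PC->BC) use the previous
#' step's rates, breaking the algebraic loops with a one-control-step delay.
#' Inhibitory groups enter the weighted sum with negative sign. Knocked-down
#' GCs emit exactly 0; surviving parallel-fiber drive carries the knockdown
#' compensation factor.
#'
#' @param net a `hemisphere_net`
#' @param state a `hemisphere_state`
#' @param mf_rates MF input rates, length `counts[["MF"]]`, entries in [0,1]
#' @return the updated `hemisphere_state`
#' @export
step_hemisphere <- function(net, state, mf_rates) {
  n_mf <- net$counts[["MF"]]
  if (length(mf_rates) != n_mf) {
    stop("input-contract error: mf_rates must have length ", n_mf)
  }
  if (any(mf_rates < 0 | mf_rates > 1)) {
    stop("input-contract error: mf_rates must lie in [0, 1]")
  }
  s <- net$sigma; m <- net$mu; cs <- net$comp_scale
  # GO <- MF (current) + PF (previous, compensated) - BC (previous)
  x_go <- group_drive(net$syn$mf_go, mf_rates) +
    group_drive(net$syn$pf_go, state$y_gc, scale = cs) -
    group_drive(net$syn$bc_go, state$y_bc)
  y_go <- rate_sigmoid(x_go, s, m)
  # GC <- MF (current) - GO (previous); knocked-down GCs silent
  x_gc <- group_drive(net$syn$mf_gc, mf_rates) -
    group_drive(net$syn$go_gc, state$y_go)
  y_gc <- rate_sigmoid(x_gc, s, m) * net$active
  # BC <- PF (current, compensated) - PC (previous). The PC rate seen by
  # the BC population is the nonnegative sigmoid part of the PC activation
  # (y_pc + 0.5 in [0, 1]): a negative "rate" entering an inhibitory
  # projection would excite the BCs and latch the BC-PC loop.
  x_bc <- group_drive(net$syn$pf_bc, y_gc, scale = cs) -
    group_drive(net$syn$pc_bc, rep(state$y_pc + 0.5, net$counts[["PC"]]))
  y_bc <- rate_sigmoid(x_bc, s, m)
  # PC <- PF (current, weights already compensated) - BC (current)
  x_pc <- group_drive(net$syn$pf_pc, y_gc, scale = cs) -
    group_drive(net$syn$bc_pc, y_bc)
  y_pc <- pc_rate(x_pc, list(sigma = s, mu = m))
  structure(list(y_mf = mf_rates, y_gc = y_gc, y_go = y_go, y_bc = y_bc,
                 y_pc = unname(y_pc[1]), x_pc = unname(x_pc[1])),
            class = "hemisphere_state")
}

#' Combine hemispheric Purkinje outputs
#'
#' The left-hemisphere PC rate is inverted and added to the right one, so
#' the combined cerebellar contribution lies in `[-1, 1]` and identical
#' modulation of the two hemispheres cancels to zero.
#'
#' @param y_pc_left,y_pc_right PC firing rates
#' @return combined output, clipped to `[-1, 1]`
#' @export
combine_hemispheres <- function(y_pc_left, y_pc_right) {
  pmin(1, pmax(-1, y_pc_right - y_pc_left))
}
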