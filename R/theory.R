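#' Theory parameters
#'
#' Holds the embedding dimension d, the trajectory fractal dimension
#' d_f in [1, d], the linear size L, the initial node volume v0 and the
#' integration constant c of the continuous-time total-volume solution.
#' The mean-field regime applies when d_f <= d/2, where trajectories avoid
#' each other and the intersection probability reduces to v_i v_j / L^d;
#' all predictions implement it by substituting the effective fractal
#' dimension d_f_eff = max(d_f, d/2), which makes every branch continuous
#' at d_f = d/2.
#'
#' @param d embedding dimension.
#' @param d_f fractal dimension in [1, d].
#' @param L linear substrate size.
#' @param v0 initial node volume; default round(L^d_f) ("span" policy).
#' @param c integration constant; default chosen so that the predicted
#'   total volume at t = 0 equals v0.
#' @return object of class `theory_params`.
#' @export
theory_params <- function(d, d_f, L, v0 = round(L^d_f), c = NULL) {
  if (d_f < 1 || d_f > d) stop("`d_f` must lie in [1, d]")
  if (L < 2) stop("`L` must be >= 2")
  if (v0 < 1) stop("`v0` must be >= 1")
  df_eff <- max(d_f, d / 2)
  mean_field <- d_f <= d / 2
  Ld <- as.numeric(L)^d
  if (is.null(c)) {
    if (df_eff >= d) {
      c <- 0
    } else {
      # solve L^d * [ (d/(d-df)) (0+c)/L^d ]^{(d-df)/d} = v0 for c
      c <- Ld * (d - df_eff) / d * (v0 / Ld)^(d / (d - df_eff))
    }
  }
  structure(list(d = d, d_f = d_f, d_f_eff = df_eff, L = L, Ld = Ld,
                 v0 = v0, c = c, mean_field = mean_field),
            class = "theory_params")
}

#' @export
print.theory_params <- function(x, ...) {
  cat(sprintf("<theory_params> d=%d d_f=%.4f L=%d v0=%g c=%.4g%s\n",
              x$d, x$d_f, x$L, x$v0, x$c,
              if (x$mean_field) " (mean-field)" else ""))
  invisible(x)
}

stop_if_space_filling <- function(p) {
  if (p$d_f_eff >= p$d)
    stop("d_f = d (space-filling nodes): prediction undefined (division by zero)")
}

#' Intersection probability of two randomly placed nodes
#'
#' Box-counting scaling estimate of the probability that two nodes of
#' volumes v_i >= v_j intersect: v_i v_j^{d/d_f - 1} / L^d for
#' d_f >= d/2, and the mean-field v_i v_j / L^d below. Arguments are
#' symmetrized by sorting; the result is a scaling value clipped to
#' [0, 1] (the box-counting prefactor is an unspecified fit constant).
#'
#' @param v_i,v_j node volumes (>= 1).
#' @param params a [theory_params()].
#' @export
intersection_probability <- function(v_i, v_j, params) {
  if (any(c(v_i, v_j) < 1)) stop("volumes must be >= 1")
  a <- pmax(v_i, v_j); b <- pmin(v_i, v_j)
  p <- a * b^(params$d / params$d_f_eff - 1) / params$Ld
  pmin(pmax(p, 0), 1)
}

#' Predicted volume of the next node
#'
#' The node added when the network already occupies total volume `V_prev`
#' grows until its cumulative intersection probability with the existing
#' network reaches one: v_t = (V_prev / L^d)^(-d_f/(d - d_f)) (with
#' d_f_eff in the mean-field regime, where this is L^d / V_prev).
#'
#' @param V_prev total network volume before the addition (0 < V_prev <= L^d).
#' @param params a [theory_params()].
#' @export
predicted_next_volume <- function(V_prev, params) {
  stop_if_space_filling(params)
  if (any(V_prev <= 0) || any(V_prev > params$Ld))
    stop("`V_prev` must lie in (0, L^d]")
  df <- params$d_f_eff
  (V_prev / params$Ld)^(-df / (params$d - df))
}

#' Predicted total volume after t node additions
#'
#' Continuous-time solution
#' V_t = L^d \[ (d/(d - d_f)) (t + c)/L^d \]^{(d - d_f)/d},
#' asymptotically V_t ~ t^{1 - d_f/d}; in the mean-field regime the
#' exponent is 1/2 (diffusive growth).
#'
#' @param t number of nodes added (>= 0), vectorized.
#' @param params a [theory_params()].
#' @export
predicted_total_volume <- function(t, params) {
  stop_if_space_filling(params)
  if (any(t < 0)) stop("`t` must be >= 0")
  df <- params$d_f_eff
  params$Ld * ((params$d / (params$d - df)) * (t + params$c) / params$Ld)^((params$d - df) / params$d)
}

#' Asymptotic growth exponent of the total volume
#'
#' @param params a [theory_params()].
#' @return 1 - d_f/d, or 1/2 in the mean-field regime.
#' @export
growth_exponent <- function(params) {
  1 - params$d_f_eff / params$d
}

#' Predicted expected degree of node t after N additions
#'
#' k_t(N) = 1 + (v_t / L^d) * sum_{s=t+1}^{N} v_s^{d/d_f - 1}, with node
#' volumes from the continuous-time solution v_s = (s/L^d)^{-d_f/d}.
#' Proportional to v_t (N/L^d)^{d/d_f} for t << N.
#'
#' @param t birth time(s) of the node(s), 1 <= t <= N.
#' @param N total number of nodes.
#' @param params a [theory_params()].
#' @export
predicted_degree <- function(t, N, params) {
  stop_if_space_filling(params)
  if (any(t < 1) || any(t > N)) stop("`t` must lie in [1, N]")
  df <- params$d_f_eff
  s <- seq_len(N)
  vs <- (s / params$Ld)^(-df / params$d)
  # suffix sums of v_s^{d/df - 1}
  pw <- vs^(params$d / df - 1)
  suff <- rev(cumsum(rev(pw)))
  vapply(t, function(tt) {
    tt <- as.integer(tt)
    tail_sum <- if (tt >= N) 0 else suff[tt + 1L]
    1 + vs[tt] / params$Ld * tail_sum
  }, numeric(1))
}

#' Predicted degree-distribution exponent
#'
#' P(k) ~ k^{-(gamma - 1)} with gamma = 1 + d/d_f for d_f > d/2 and the
#' mean-field value gamma = 3 for d_f <= d/2.
#'
#' @param params a [theory_params()].
#' @export
predicted_degree_exponent <- function(params) {
  1 + params$d / params$d_f_eff
}

#' Theory prediction table
#'
#' Evaluates the closed-form predictions on a grid of times, as printed by
#' the `theory` CLI subcommand.
#'
#' @param params a [theory_params()].
#' @param t integer vector of times.
#' @param N horizon for the degree prediction (default max(t)).
#' @return data.frame with columns t, V_t, v_t, k_t and the constant gamma.
#' @export
theory_table <- function(params, t, N = max(t)) {
  data.frame(t = t,
             V_t = predicted_total_volume(t, params),
             v_t = (pmax(t, 1) / params$Ld)^(-params$d_f_eff / params$d),
             k_t = predicted_degree(pmax(t, 1), N, params),
             gamma = predicted_degree_exponent(params))
}
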