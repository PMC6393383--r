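#' Corticostriatal weight state
#'
#' Holds the plastic synaptic weights from cortical cue units (rows, j)
#' onto direct-pathway D1 and indirect-pathway D2 medium spiny neurons
#' (columns, i), together with the learning and degradation rates of
#' the trial-to-trial update rule.
#'
#' @param w1,w2 Non-negative numeric matrices of identical shape:
#'   weights onto D1 (direct) and D2 (indirect) units.
#' @param lambda1,lambda2 Base learning rates of the two pathways. The
#'   effective per-update rate is the base rate times a published
#'   factor that depends on the sign of the dopamine deviation (see
#'   [effective_rate()]).
#' @param dw Degradation (forgetting) rate per trial.
#' @return An object of class `tan_weights`.
#' @examples
#' weight_state(matrix(0.5, 1, 4), matrix(0.5, 1, 4))
#' @export
weight_state <- function(w1, w2, lambda1 = 1, lambda2 = 1, dw = 0.01) {
  w1 <- as.matrix(w1); w2 <- as.matrix(w2)
  if (!identical(dim(w1), dim(w2))) {
    stop("w1 and w2 must have identical shapes", call. = FALSE)
  }
  if (any(w1 < 0) || any(w2 < 0)) {
    stop("weights must be non-negative", call. = FALSE)
  }
  stopifnot(lambda1 > 0, lambda2 > 0, dw >= 0)
  structure(list(w1 = w1, w2 = w2, lambda1 = lambda1,
                 lambda2 = lambda2, dw = dw),
            class = "tan_weights")
}

#' @export
print.tan_weights <- function(x, ...) {
  cat(sprintf(
    "<tan_weights> %d cue x %d action units; lambda = (%g, %g), dw = %g\n",
    nrow(x$w1), ncol(x$w1), x$lambda1, x$lambda2, x$dw))
  invisible(x)
}

#' Population firing rates entering the plasticity rule
#'
#' @param c Cortical cue-unit firing rates (length = rows of the weight
#'   matrices).
#' @param d1,d2 D1- and D2-MSN firing rates (length = columns of the
#'   weight matrices).
#' @return An object of class `tan_rates`.
#' @export
population_rates <- function(c, d1, d2) {
  stopifnot(is.numeric(c), is.numeric(d1), is.numeric(d2),
            length(d1) == length(d2))
  if (any(c < 0) || any(d1 < 0) || any(d2 < 0)) {
    stop("firing rates must be non-negative", call. = FALSE)
  }
  structure(list(c = c, d1 = d1, d2 = d2), class = "tan_rates")
}

#' Effective learning rate given the sign of the dopamine deviation
#'
#' The base learning rate is scaled by 0.00125 when dopamine sits at or
#' above its baseline during the pause and by 0.0025 when it falls
#' below baseline, making depression from negative deviations twice as
#' fast as potentiation from positive ones.
#'
#' @param base_lambda Base learning rate, `> 0`.
#' @param da_sign `"above_baseline"` or `"below_baseline"`.
#' @return The effective rate, a single number.
#' @examples
#' effective_rate(1, "above_baseline") # 0.00125
#' effective_rate(1, "below_baseline") # 0.0025
#' @export
effective_rate <- function(base_lambda,
                           da_sign = c("above_baseline",
                                       "below_baseline")) {
  stopifnot(is.numeric(base_lambda), base_lambda > 0)
  da_sign <- match.arg(da_sign)
  factor <- if (da_sign == "above_baseline") 0.00125 else 0.0025
  base_lambda * factor
}

#' Update corticostriatal weights from the phasic dopamine integral
#'
#' Trial-to-trial update driven by the time-integral of the dopamine
#' deviation from baseline accumulated over the TAN pause: the direct
#' pathway gains `lambda_eff * c_j * d1_i * integral` while the
#' indirect pathway changes by the same product with opposite sign;
#' both decay by `dw * w`. The sign of the integral selects the
#' effective learning rate (potentiation vs depression factor), and
#' weights are clamped at zero from below.
#'
#' @param weights A [weight_state()].
#' @param rates A [population_rates()] whose dimensions match the
#'   weight matrices.
#' @param da_integral Phasic dopamine integral, concentration x ms
#'   (typically from [phasic_da_integral()]).
#' @return A new `tan_weights` with updated `w1`, `w2`.
#' @examples
#' w <- weight_state(matrix(0.5, 1, 2), matrix(0.5, 1, 2), dw = 0)
#' r <- population_rates(1, c(1, 0), c(1, 0))
#' update_weights(w, r, da_integral = 100)$w1
#' @export
update_weights <- function(weights, rates, da_integral) {
  stopifnot(inherits(weights, "tan_weights"),
            inherits(rates, "tan_rates"),
            is.numeric(da_integral), length(da_integral) == 1L,
            is.finite(da_integral))
  if (length(rates$c) != nrow(weights$w1) ||
      length(rates$d1) != ncol(weights$w1)) {
    stop("rate vector lengths (", length(rates$c), " cue, ",
         length(rates$d1), " action) do not match the weight shape ",
         nrow(weights$w1), " x ", ncol(weights$w1), call. = FALSE)
  }
  sign_lab <- if (da_integral >= 0) "above_baseline" else "below_baseline"
  lam1 <- effective_rate(weights$lambda1, sign_lab)
  lam2 <- effective_rate(weights$lambda2, sign_lab)
  hebb <- outer(rates$c, rates$d1)
  hebb2 <- outer(rates$c, rates$d2)
  w1 <- pmax(weights$w1 + lam1 * hebb * da_integral -
               weights$dw * weights$w1, 0)
  w2 <- pmax(weights$w2 - lam2 * hebb2 * da_integral -
               weights$dw * weights$w2, 0)
  weight_state(w1, w2, weights$lambda1, weights$lambda2, weights$dw)
}
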