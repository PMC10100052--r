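#' Akaike information criterion with small-sample correction
#'
#' \deqn{AICc = -2\ell + 2k + \frac{2k(k+1)}{n - k - 1}.}
#'
#' @param log_likelihood maximised log-likelihood.
#' @param k number of estimated parameters.
#' @param n sample size; must exceed \code{k + 1}.
#' @return AICc value.
#' @export
aicc <- function(log_likelihood, k, n) {
  stopifnot(is.finite(log_likelihood), k >= 0)
  if (n <= k + 1)
    stop("AICc undefined: n must exceed k + 1")
  -2 * log_likelihood + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' AICc comparison table with Akaike weights
#'
#' Ranks candidate models by AICc: \eqn{\Delta_i = AICc_i - \min AICc} and
#' \eqn{w_i = e^{-\Delta_i/2} / \sum_j e^{-\Delta_j/2}}. Models with
#' \eqn{\Delta \le 2} relative to the best model are flagged as having
#' substantial support.
#'
#' @param aicc_values named numeric vector of AICc values, one per model.
#' @return Data frame of class \code{"comparison_table"}, sorted ascending
#'   by AICc, with columns \code{model}, \code{aicc}, \code{delta},
#'   \code{weight}, \code{substantial}.
#' @export
delta_and_weights <- function(aicc_values) {
  stopifnot(length(aicc_values) >= 1, all(is.finite(aicc_values)))
  if (is.null(names(aicc_values)))
    names(aicc_values) <- sprintf("model%d", seq_along(aicc_values))
  delta <- aicc_values - min(aicc_values)
  w <- exp(-delta / 2)
  w <- w / sum(w)
  out <- data.frame(model = names(aicc_values), aicc = unname(aicc_values),
                    delta = unname(delta), weight = unname(w),
                    substantial = unname(delta <= 2),
                    stringsAsFactors = FALSE)
  out <- out[order(out$aicc), ]
  rownames(out) <- NULL
  class(out) <- c("comparison_table", "data.frame")
  out
}

#' @export
print.comparison_table <- function(x, ...) {
  disp <- data.frame(Model = x$model,
                     AICc = sprintf("%.2f", x$aicc),
                     dAICc = sprintf("%.2f", x$delta),
                     w = ifelse(x$weight < 0.005, "<0.01",
                                sprintf("%.2f", x$weight)),
                     stringsAsFactors = FALSE)
  print(disp, row.names = FALSE, right = FALSE)
  invisible(x)
}

#' Model-averaged coefficient
#'
#' Averages one coefficient across candidate models using Akaike weights.
#' Three conventions:
#' \describe{
#'   \item{\code{conditional}}{weights renormalised over the models that
#'     contain the coefficient (use \code{NA} for models lacking it).}
#'   \item{\code{full}}{models lacking the coefficient contribute 0 at
#'     their original weight (shrinkage towards zero).}
#'   \item{\code{top_set}}{restrict to models with \eqn{\Delta \le}
#'     \code{delta_max}, renormalise, then average conditionally within
#'     that set.}
#' }
#' Exponent parameters are averaged on the exponent scale.
#'
#' @param estimates numeric vector of per-model coefficient values;
#'   \code{NA} where a model does not contain the coefficient.
#' @param weights Akaike weights aligned with \code{estimates} (from
#'   [delta_and_weights()]).
#' @param mode averaging convention.
#' @param delta numeric vector of per-model \eqn{\Delta}AICc values,
#'   required for \code{mode = "top_set"}.
#' @param delta_max support cutoff for \code{top_set}.
#' @return The averaged coefficient.
#' @export
model_average <- function(estimates, weights,
                          mode = c("conditional", "full", "top_set"),
                          delta = NULL, delta_max = 2) {
  mode <- match.arg(mode)
  stopifnot(length(estimates) == length(weights))
  has <- !is.na(estimates)
  if (mode == "conditional") {
    if (!any(has)) stop("coefficient absent from every model")
    sum(estimates[has] * weights[has]) / sum(weights[has])
  } else if (mode == "full") {
    sum(ifelse(has, estimates, 0) * weights) / sum(weights)
  } else {
    stopifnot(!is.null(delta), length(delta) == length(estimates))
    keep <- delta <= delta_max & has
    if (!any(keep)) stop("coefficient absent from every supported model")
    sum(estimates[keep] * weights[keep]) / sum(weights[keep])
  }
}

#' Percent change in choice odds per fractional covariate step
#'
#' Translates a power-function exponent into the percentage change in a
#' male's relative attractiveness per fractional increase of the underlying
#' variable: \code{100 * ((1 + step)^alpha - 1)}. With
#' \code{alpha = 0.625} and a 10\% step this gives +6.1\% (a male's chances
#' rise 6.1\% with each 10\% increase in habitat attractiveness).
#'
#' @param alpha fitted exponent.
#' @param step fractional increase of the covariate (default 0.10); must
#'   exceed -1.
#' @return Percent change (e.g. \code{6.1} for +6.1\%).
#' @export
percent_change <- function(alpha, step = 0.10) {
  stopifnot(step > -1)
  100 * ((1 + step)^alpha - 1)
}
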