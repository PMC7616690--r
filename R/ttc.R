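# The downstream time-to-conversion (TTC) head: saliency map, sigmoid CDF,
# interval-censored loss, risk score, stratification and baselines.
#
# Time is normalized so that the 18-month horizon equals 1. The CDF of the
# conversion time T* is modeled as p_t = 1 / (1 + exp(-(t - b)/(a + 0.05))):
# b estimates T* (p_b = 0.5 exactly) and a controls the slope, with the
# +0.05 stabilizer retained on the normalized scale.

TTC_HORIZON_MONTHS <- 18
TTC_EPS <- 1e-6

#' TTC classifier (three 1x1x1 convolutions)
#'
#' Maps the 128-channel encoder feature map to a single-channel
#' non-negative saliency map through pointwise convolutions with ELU
#' between and a softplus output, plus the two non-negative learnable
#' scalars used by [head_predict()].
#'
#' @param hidden Hidden widths of the two intermediate layers.
#' @param in_channels Input channels (128 for the standard encoder).
#' @return A `ttc_classifier` object.
#' @export
ttc_classifier <- function(hidden = c(64L, 16L), in_channels = 128L) {
  cl <- new_layer("ttc_classifier")
  cl$conv1 <- nn_conv3d(in_channels, hidden[1L], c(1L, 1L, 1L), bias = TRUE)
  cl$act1 <- nn_elu()
  cl$conv2 <- nn_conv3d(hidden[1L], hidden[2L], c(1L, 1L, 1L), bias = TRUE)
  cl$act2 <- nn_elu()
  cl$conv3 <- nn_conv3d(hidden[2L], 1L, c(1L, 1L, 1L), bias = TRUE)
  cl$alpha1 <- nn_pos_scalar(1)
  cl$alpha2 <- nn_pos_scalar(1)
  cl$layers <- list(cl$conv1, cl$act1, cl$conv2, cl$act2, cl$conv3,
                    cl$alpha1, cl$alpha2)
  cl$fwd <- function(f, train = FALSE) {
    x <- cl$conv1$fwd(f, train)
    x <- cl$act1$fwd(x, train)
    x <- cl$conv2$fwd(x, train)
    x <- cl$act2$fwd(x, train)
    z <- cl$conv3$fwd(x, train)
    if (train) cl$z <- z
    softplus(z)
  }
  cl$bwd <- function(gM) {
    gz <- gM * stats::plogis(cl$z)
    cl$z <- NULL
    g <- cl$conv3$bwd(gz)
    g <- cl$act2$bwd(g)
    g <- cl$conv2$bwd(g)
    g <- cl$act1$bwd(g)
    cl$conv1$bwd(g)
  }
  class(cl) <- c("ttc_classifier", class(cl))
  cl
}

softplus <- function(x) ifelse(x > 30, x, log1p(exp(pmin(x, 30))))

#' Saliency map from encoder features
#'
#' @param f A `feature_map` or a bare (C,h,w,d) array.
#' @param classifier A [ttc_classifier()].
#' @return Non-negative saliency array (1,h,w,d).
#' @export
classifier_forward <- function(f, classifier) {
  x <- if (inherits(f, "feature_map")) f$F else f
  classifier$fwd(x, train = FALSE)
}

#' Spatial entropy of a saliency map
#'
#' `H = -sum(M' log M')` with `M' = M / sum(M)`; `0 * log 0` counts as 0.
#' The value lies in `[0, log(N)]` with N spatial positions.
#'
#' @param M Non-negative saliency array.
#' @return Scalar entropy (nats).
#' @export
spatial_entropy <- function(M) {
  s <- sum(M)
  if (!is.finite(s) || s <= 0)
    stop("spatial entropy undefined: saliency map must have positive sum")
  p <- as.numeric(M) / s
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Sigmoid CDF parameters from a saliency map
#'
#' `b = 1/(alpha1 * mean(M) + eps)` (higher saliency means earlier
#' predicted conversion) and `a = sigmoid(alpha2 * H)` with H the spatial
#' entropy (low entropy - a few salient loci - yields a steeper CDF).
#'
#' @param M Saliency array.
#' @param classifier The [ttc_classifier()] holding `alpha1`, `alpha2`.
#' @return A [sigmoid_cdf()].
#' @export
head_predict <- function(M, classifier) {
  a1 <- classifier$alpha1$value()
  a2 <- classifier$alpha2$value()
  b <- 1 / (a1 * mean(M) + TTC_EPS)
  a <- stats::plogis(a2 * spatial_entropy(M))
  sigmoid_cdf(a, b)
}

#' Sigmoid conversion-time CDF
#'
#' @param a Slope parameter in (0,1).
#' @param b Conversion-time estimate on the normalized scale (18 months = 1),
#'   non-negative.
#' @export
sigmoid_cdf <- function(a, b) {
  if (b < 0) stop("b must be non-negative")
  if (a <= 0 || a >= 1) stop("a must lie strictly inside (0,1)")
  structure(list(a = a, b = b), class = "sigmoid_cdf")
}

#' Evaluate the conversion CDF
#'
#' @param cdf A [sigmoid_cdf()].
#' @param t Normalized time (any real; evaluation beyond [0,1] permitted).
#' @return `P(T* <= t)`, strictly increasing in `t`, with `p = 0.5` exactly
#'   at `t = b`.
#' @export
cdf_eval <- function(cdf, t) {
  stats::plogis((t - cdf$b) / (cdf$a + 0.05))
}

#' Interval-censored conversion label
#'
#' `t_minus` is the last visit before conversion, `t_plus` the first
#' converted visit (months). Use `Inf` for both when conversion does not
#' occur within follow-up (beyond the horizon). `t_plus = 0` marks the
#' first conversion visit itself.
#'
#' @param t_minus_months,t_plus_months Label times in months (or `Inf`).
#' @param horizon_months Normalization horizon (default 18).
#' @export
ttc_label <- function(t_minus_months, t_plus_months,
                      horizon_months = TTC_HORIZON_MONTHS) {
  tm <- t_minus_months / horizon_months
  tp <- t_plus_months / horizon_months
  lab <- structure(list(t_minus = tm, t_plus = tp), class = "ttc_label")
  ttc_label_case(lab)  # validates the partition
  lab
}

ttc_label_case <- function(label) {
  tm <- label$t_minus; tp <- label$t_plus
  if (is.finite(tp) && tp == 0) return(3L)
  if (is.finite(tm) && is.finite(tp) && tm >= 0 && tp <= 1 && tm < tp)
    return(1L)
  if (tm > 1 && tp > 1) return(2L)
  stop("label (T- = ", tm, ", T+ = ", tp, " normalized) fits none of the ",
       "three loss cases")
}

#' Interval-censored classification loss
#'
#' Average binary cross-entropy at two time points, by case:
#' observed interval (labels 0 at T-, 1 at T+); beyond horizon (labels 0 at
#' t = 0 and t = 1); first conversion visit (labels 1 at t = 0 and t = 1).
#'
#' @param cdf A [sigmoid_cdf()].
#' @param label A [ttc_label()].
#' @return Scalar loss.
#' @export
ttc_loss <- function(cdf, label) {
  case <- ttc_label_case(label)
  ce <- function(p, y) -0.5 * (y * log(p) + (1 - y) * log(1 - p))
  switch(case,
    ce(cdf_eval(cdf, label$t_plus), 1) + ce(cdf_eval(cdf, label$t_minus), 0),
    ce(cdf_eval(cdf, 0), 0) + ce(cdf_eval(cdf, 1), 0),
    ce(cdf_eval(cdf, 0), 1) + ce(cdf_eval(cdf, 1), 1))
}

# d ttc_loss / d(a, b) — analytic, used by the trainers and the direct fit.
ttc_loss_grad <- function(cdf, label) {
  case <- ttc_label_case(label)
  pts <- switch(case,
                list(t = c(label$t_plus, label$t_minus), y = c(1, 0)),
                list(t = c(0, 1), y = c(0, 0)),
                list(t = c(0, 1), y = c(1, 1)))
  s <- cdf$a + 0.05
  ga <- 0; gb <- 0
  for (i in 1:2) {
    t <- pts$t[i]; y <- pts$y[i]
    p <- stats::plogis((t - cdf$b) / s)
    dldp <- -0.5 * (y / p - (1 - y) / (1 - p))
    dpdz <- p * (1 - p)
    gb <- gb + dldp * dpdz * (-1 / s)
    ga <- ga + dldp * dpdz * (-(t - cdf$b) / s^2)
  }
  c(a = ga, b = gb)
}

#' Total TTC loss with regularizers
#'
#' `L = L_cls + gamma1 * a^2 + gamma2 * || M * (1 - R_hat) ||_1` where
#' `R_hat` is the ROI mask nearest-resized to the feature grid; the mask
#' penalty discourages saliency outside the retina.
#'
#' @param loss_cls Classification loss (from [ttc_loss()]).
#' @param a Slope parameter.
#' @param M Saliency array.
#' @param roi_small ROI mask resized to the saliency grid (values 0/1).
#' @param gamma1,gamma2 Regularizer weights (default 0.1 each).
#' @return List: `loss`, `breakdown`.
#' @export
ttc_total_loss <- function(loss_cls, a, M, roi_small,
                           gamma1 = 0.1, gamma2 = 0.1) {
  pen_a <- gamma1 * a^2
  pen_m <- gamma2 * sum(abs(as.numeric(M) * (1 - as.numeric(roi_small))))
  list(loss = loss_cls + pen_a + pen_m,
       breakdown = list(L_cls = loss_cls, pen_a = pen_a, pen_mask = pen_m))
}

#' Conversion risk score
#'
#' `r = 2 / (1 + exp(b / (a + 0.05)))`: a single time-independent scalar in
#' (0, 1], inversely related to the predicted conversion time (r = 1 iff
#' b = 0, r -> 0 as b -> Inf).
#'
#' @param cdf A [sigmoid_cdf()] (or `a`, `b` given separately).
#' @export
risk_score <- function(cdf, b = NULL) {
  if (!is.null(b)) cdf <- list(a = cdf, b = b)
  if (cdf$b < 0) stop("risk score undefined for negative b")
  2 / (1 + exp(cdf$b / (cdf$a + 0.05)))
}

#' Stratify a risk score into low / moderate / high
#'
#' Boundaries as printed: low `[0, 0.33]`, moderate `(0.33, 0.67]`,
#' high `(0.67, 1]`.
#'
#' @param r Numeric vector of risk scores.
#' @return Factor with levels `low`, `moderate`, `high`.
#' @export
stratify_risk <- function(r) {
  if (any(r < 0 | r > 1)) stop("risk scores must lie in [0, 1]")
  cut(r, breaks = c(-Inf, 0.33, 0.67, 1), labels = c("low", "moderate",
                                                     "high"))
}

# --- baselines ---------------------------------------------------------------

#' Regression baseline: binned time-to-conversion predictions
#'
#' Treats the global average pooling of the saliency map as a direct
#' time-to-conversion estimate in months (trained elsewhere against the
#' interval midpoint with squared error) and bins it into the four
#' conversion-within-horizon indicators.
#'
#' @param pred_months Predicted conversion times (months).
#' @param horizons Horizons in months (default 0, 6, 12, 18).
#' @return Tibble: one row per prediction, logical columns `within_<t>`.
#' @export
regression_baseline_bins <- function(pred_months,
                                     horizons = c(0, 6, 12, 18)) {
  out <- tibble::tibble(pred_months = pred_months)
  for (h in horizons)
    out[[paste0("within_", h)]] <- pred_months <= h
  out
}

#' @rdname regression_baseline_bins
#' @param M Saliency array (GAP of which is the predicted months).
#' @export
regression_baseline <- function(M, horizons = c(0, 6, 12, 18)) {
  regression_baseline_bins(mean(M), horizons)
}

#' Regression-baseline training loss (squared error to interval midpoint)
#' @param pred_months Prediction (months).
#' @param t_minus_months,t_plus_months Label interval (months).
#' @export
regression_baseline_loss <- function(pred_months, t_minus_months,
                                     t_plus_months) {
  (pred_months - (t_minus_months + t_plus_months) / 2)^2
}

#' Multi-label baseline head
#'
#' A variant of the classifier whose last layer emits 4 channels; global
#' average pooling followed by a sigmoid gives `P(convert within t)` for
#' t = 0, 6, 12, 18 months. The four outputs are NOT constrained to be
#' monotone, unlike the sigmoid-CDF head.
#'
#' @inheritParams ttc_classifier
#' @export
multilabel_classifier <- function(hidden = c(64L, 16L), in_channels = 128L) {
  cl <- new_layer("multilabel_classifier")
  cl$conv1 <- nn_conv3d(in_channels, hidden[1L], c(1L, 1L, 1L), bias = TRUE)
  cl$act1 <- nn_elu()
  cl$conv2 <- nn_conv3d(hidden[1L], hidden[2L], c(1L, 1L, 1L), bias = TRUE)
  cl$act2 <- nn_elu()
  cl$conv3 <- nn_conv3d(hidden[2L], 4L, c(1L, 1L, 1L), bias = TRUE)
  cl$layers <- list(cl$conv1, cl$act1, cl$conv2, cl$act2, cl$conv3)
  cl$fwd <- function(f, train = FALSE) {
    x <- cl$conv1$fwd(f, train)
    x <- cl$act1$fwd(x, train)
    x <- cl$conv2$fwd(x, train)
    x <- cl$act2$fwd(x, train)
    cl$conv3$fwd(x, train)
  }
  class(cl) <- c("multilabel_classifier", class(cl))
  cl
}

#' Multi-label baseline predictions
#'
#' @param f Feature map (or array).
#' @param classifier A [multilabel_classifier()].
#' @return Named numeric vector of four probabilities (t = 0, 6, 12, 18).
#' @export
multilabel_baseline <- function(f, classifier) {
  x <- if (inherits(f, "feature_map")) f$F else f
  logits <- classifier$fwd(x, train = FALSE)
  gap <- apply(logits, 1, mean)
  stats::setNames(stats::plogis(gap), paste0("p_within_", c(0, 6, 12, 18)))
}

#' Count monotonicity violations among horizon probabilities
#'
#' A violation is an adjacent horizon pair whose probability decreases
#' (e.g. p(within 12) < p(within 6)).
#'
#' @param probs Numeric vector ordered by increasing horizon.
#' @return Integer count.
#' @export
count_monotonicity_violations <- function(probs) {
  sum(diff(probs) < 0)
}

# --- direct CDF fitting (no network) ----------------------------------------

#' Fit the sigmoid CDF directly to interval-censored labels
#'
#' Minimizes the interval-censored loss over (a, b) by gradient descent on
#' unconstrained parameters (`a` through a logistic map, `b` through an
#' exponential map), with no network involved. Used to verify that the loss
#' identifies the conversion-time parameter from bracketing labels alone.
#'
#' @param labels List of [ttc_label()] objects.
#' @param init Optional `c(a, b)` start.
#' @param maxit Optimizer iterations.
#' @return A `ttc_fit` object with elements `a`, `b`, `value`, `n`.
#' @export
fit_ttc_direct <- function(labels, init = c(a = 0.3, b = 0.6),
                           maxit = 500) {
  obj <- function(par) {
    cdf <- list(a = stats::plogis(par[1]), b = exp(par[2]))
    class(cdf) <- "sigmoid_cdf"
    mean(vapply(labels, function(l) ttc_loss(cdf, l), numeric(1)))
  }
  gr <- function(par) {
    a <- stats::plogis(par[1]); b <- exp(par[2])
    cdf <- structure(list(a = a, b = b), class = "sigmoid_cdf")
    g <- rowMeans(vapply(labels, function(l) ttc_loss_grad(cdf, l),
                         numeric(2)))
    c(g[1] * a * (1 - a), g[2] * b)
  }
  start <- c(stats::qlogis(init[["a"]]), log(init[["b"]]))
  fit <- stats::optim(start, obj, gr, method = "BFGS",
                      control = list(maxit = maxit))
  structure(list(a = stats::plogis(fit$par[1]), b = exp(fit$par[2]),
                 value = fit$value, n = length(labels),
                 convergence = fit$convergence),
            class = "ttc_fit")
}

#' @export
print.ttc_fit <- function(x, ...) {
  cat("<ttc_fit> a =", signif(x$a, 4), " b =", signif(x$b, 4),
      " (normalized time; 18 months = 1), loss =", signif(x$value, 4),
      "on", x$n, "labels\n")
  invisible(x)
}

#' Tidy a direct CDF fit
#' @param x A `ttc_fit`.
#' @param ... Unused.
#' @export
tidy.ttc_fit <- function(x, ...) {
  tibble::tibble(term = c("a", "b"),
                 estimate = c(x$a, x$b),
                 description = c("sigmoid CDF slope parameter",
                                 "conversion-time estimate (18 months = 1)"))
}

#' Glance at a direct CDF fit
#' @param x A `ttc_fit`.
#' @param ... Unused.
#' @export
glance.ttc_fit <- function(x, ...) {
  tibble::tibble(loss = x$value, n = x$n,
                 converged = x$convergence == 0)
}

#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @export
glance <- function(x, ...) UseMethod("glance")
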