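# Threshold selection, eye-level bootstrap, eye-level concordance and
# Kaplan-Meier risk stratification.

#' AUC of prediction scores
#'
#' Rank-based (Mann-Whitney) area under the ROC curve with tie correction,
#' delegated to pROC.
#'
#' @param scores Numeric prediction scores (higher = more positive).
#' @param labels Binary labels (0/1).
#' @return AUC in [0, 1].
#' @export
auc_score <- function(scores, labels) {
  if (length(unique(labels)) < 2L)
    stop("AUC undefined: both classes must be present")
  as.numeric(pROC::auc(pROC::roc(response = labels, predictor = scores,
                                 levels = c(0, 1), direction = "<",
                                 quiet = TRUE)))
}

#' Operating threshold by Youden's J, and balanced accuracy
#'
#' Scans the finite set of observed scores as candidate thresholds
#' (prediction = positive when score >= threshold), picks the one
#' maximizing `J = sensitivity + specificity - 1` (ties broken toward the
#' lower threshold) and reports the balanced accuracy
#' `(sensitivity + specificity) / 2` at that operating point.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (0/1); both classes must be present.
#' @return List: `threshold`, `balanced_accuracy`, `sensitivity`,
#'   `specificity`.
#' @export
youden_balanced_accuracy <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L)
    stop("Youden threshold undefined: both classes must be present")
  cand <- sort(unique(scores))
  best <- NULL
  for (thr in cand) {
    pred <- as.integer(scores >= thr)
    sens <- sum(pred == 1 & labels == 1) / sum(labels == 1)
    spec <- sum(pred == 0 & labels == 0) / sum(labels == 0)
    j <- sens + spec - 1
    if (is.null(best) || j > best$j + 1e-12) {
      best <- list(j = j, threshold = thr, sensitivity = sens,
                   specificity = spec)
    }
  }
  list(threshold = best$threshold,
       balanced_accuracy = (best$sensitivity + best$specificity) / 2,
       sensitivity = best$sensitivity, specificity = best$specificity)
}

#' Eye-level bootstrap of an evaluation metric
#'
#' Each of the `n_resamples` resamples keeps exactly one randomly chosen
#' visit per eye, computes the metric on that reduced set, and the mean and
#' standard deviation over resamples are reported. Fully reproducible under
#' `seed`.
#'
#' @param records Tibble with columns `eye_id`, `score`, `label` (one row
#'   per scan; a `visit_time` column is allowed and ignored here).
#' @param metric Function `(scores, labels) -> numeric`; default
#'   [auc_score()].
#' @param n_resamples Number of eye-level resamples (default 1000).
#' @param seed RNG seed.
#' @return Tibble with `mean`, `sd`, `n_resamples`, `n_eyes`.
#' @export
eye_level_bootstrap <- function(records, metric = auc_score,
                                n_resamples = 1000, seed = 1) {
  stopifnot(all(c("eye_id", "score", "label") %in% names(records)))
  eyes <- split(seq_len(nrow(records)), records$eye_id)
  if (length(eyes) < 2L) stop("need at least two eyes")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  vals <- vapply(seq_len(n_resamples), function(i) {
    pick <- vapply(eyes, function(ix) ix[sample.int(length(ix), 1L)],
                   integer(1))
    # a resample can be degenerate (single class); it contributes NA
    tryCatch(metric(records$score[pick], records$label[pick]),
             error = function(e) NA_real_)
  }, numeric(1))
  tibble::tibble(mean = mean(vals, na.rm = TRUE),
                 sd = stats::sd(vals, na.rm = TRUE),
                 n_resamples = n_resamples, n_eyes = length(eyes),
                 n_degenerate = sum(is.na(vals)))
}

#' Eye-level concordance index (eCI)
#'
#' For each eye with at least two visits, the fraction of ordered visit
#' pairs whose risk scores are non-decreasing over time (ties count as
#' concordant); the eCI is the mean of the per-eye fractions.
#'
#' @param records Tibble with `eye_id`, `visit_time`, `score`.
#' @return Scalar eCI in [0, 1].
#' @export
eye_concordance_index <- function(records) {
  stopifnot(all(c("eye_id", "visit_time", "score") %in% names(records)))
  per_eye <- records |>
    dplyr::arrange(.data$eye_id, .data$visit_time) |>
    dplyr::group_by(.data$eye_id) |>
    dplyr::summarise(frac = {
      r <- .data$score
      if (length(r) < 2L) NA_real_ else {
        pairs <- utils::combn(seq_along(r), 2L)
        mean(r[pairs[2L, ]] >= r[pairs[1L, ]])
      }
    }, .groups = "drop")
  frac <- per_eye$frac[!is.na(per_eye$frac)]
  if (length(frac) == 0L)
    stop("eCI undefined: no eye has two or more visits")
  mean(frac)
}

#' Kaplan-Meier curves stratified by risk group
#'
#' Product-limit survival estimate per risk group on the ground-truth
#' conversion times, with pairwise log-rank tests. With `n_bootstrap > 0`
#' the pairwise p-values are additionally summarized as the median over
#' eye-level bootstrap resamples (one random visit per eye each).
#'
#' @param data Tibble with columns `group` (factor from [stratify_risk()]),
#'   `time` (ground-truth conversion or censoring time), `event` (1 =
#'   converted, 0 = censored), and `eye_id` (needed when bootstrapping).
#' @param n_bootstrap Number of eye-level resamples (0 = none).
#' @param seed RNG seed for the bootstrap.
#' @return A `morphssl_km` object: `fit` (a [survival::survfit] object),
#'   `pairwise` (tibble of pairwise log-rank results), `data`.
#' @export
km_stratified_curves <- function(data, n_bootstrap = 0, seed = 1) {
  stopifnot(all(c("group", "time", "event") %in% names(data)))
  data$group <- droplevels(as.factor(data$group))
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = data)
  pairwise <- pairwise_logrank(data)
  if (n_bootstrap > 0) {
    stopifnot("eye_id" %in% names(data))
    eyes <- split(seq_len(nrow(data)), data$eye_id)
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    boot_p <- replicate(n_bootstrap, {
      pick <- vapply(eyes, function(ix) ix[sample.int(length(ix), 1L)],
                     integer(1))
      pw <- pairwise_logrank(data[pick, , drop = FALSE])
      stats::setNames(pw$p_value, paste(pw$group1, pw$group2, sep = "|"))
    })
    if (is.null(dim(boot_p))) boot_p <- matrix(boot_p, nrow = 1,
      dimnames = list(paste(pairwise$group1, pairwise$group2, sep = "|")))
    med <- apply(boot_p, 1, stats::median, na.rm = TRUE)
    pairwise$median_bootstrap_p <-
      med[paste(pairwise$group1, pairwise$group2, sep = "|")]
  }
  structure(list(fit = fit, pairwise = pairwise, data = data),
            class = "morphssl_km")
}

pairwise_logrank <- function(data) {
  lv <- levels(droplevels(as.factor(data$group)))
  if (length(lv) < 2L)
    return(tibble::tibble(group1 = character(), group2 = character(),
                          chisq = numeric(), p_value = numeric()))
  combs <- utils::combn(lv, 2L)
  purrr::map_dfr(seq_len(ncol(combs)), function(i) {
    sub <- data[data$group %in% combs[, i], , drop = FALSE]
    if (length(unique(sub$group[sub$event == 1])) == 0L ||
        length(unique(droplevels(factor(sub$group)))) < 2L)
      return(tibble::tibble(group1 = combs[1, i], group2 = combs[2, i],
                            chisq = NA_real_, p_value = NA_real_))
    sd_ <- tryCatch(
      survival::survdiff(survival::Surv(time, event) ~ group, data = sub),
      error = function(e) NULL)
    if (is.null(sd_))
      return(tibble::tibble(group1 = combs[1, i], group2 = combs[2, i],
                            chisq = NA_real_, p_value = NA_real_))
    tibble::tibble(group1 = combs[1, i], group2 = combs[2, i],
                   chisq = sd_$chisq,
                   p_value = stats::pchisq(sd_$chisq, df = 1,
                                           lower.tail = FALSE))
  })
}

#' @export
print.morphssl_km <- function(x, ...) {
  print(x$fit)
  cat("\nPairwise log-rank:\n")
  print(x$pairwise)
  invisible(x)
}

#' Plot stratified Kaplan-Meier curves
#'
#' @param object A `morphssl_km` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.morphssl_km <- function(object, ...) {
  fit <- object$fit
  strata <- rep(names(fit$strata), fit$strata)
  df <- tibble::tibble(time = fit$time, surv = fit$surv,
                       group = sub("^group=", "", strata))
  # prepend time 0 at survival 1 for each group
  df0 <- tibble::tibble(time = 0, surv = 1, group = unique(df$group))
  df <- dplyr::bind_rows(df0, df)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$surv,
                                   colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "months since visit", y = "conversion-free fraction",
                  colour = "risk group") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
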