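# Synthetic longitudinal retina generator.
#
# Produces banded retina-like OCT volumes (dark vitreous, bright
# intra-retinal bands with a strong RPE band, darker choroid) with smooth
# random ILM/BM surfaces, Gaussian-bump drusen that elevate the RPE band,
# speckle-like additive noise, longitudinal pairs with known morphing
# ground truth, and interval-censored conversion cohorts in which drusen
# load accelerates as conversion approaches, so a learnable signal exists.
# Everything is deterministic given the config seed.

#' Synthetic-data configuration
#'
#' @param shape Volume shape (H, W, D); the 48x48x8 default keeps tests at
#'   desk scale, 192x192x32 exercises the full-scale path.
#' @param n_eyes Number of eyes for cohort generation.
#' @param interval_mean,interval_sd Inter-visit interval distribution in
#'   months (normal truncated to be positive; defaults 3.6 and 5.7,
#'   matching a real-world revisit pattern).
#' @param followup_months Follow-up horizon per eye.
#' @param p_convert Probability that an eye's latent conversion time is
#'   finite.
#' @param conversion_range Range (months) of the latent conversion time for
#'   converters.
#' @param drusen_n_range Range of drusen count per volume.
#' @param drusen_amp_um Baseline drusen elevation amplitude (micrometres).
#' @param lesion_sparsity Fraction of voxels receiving additive lesions in
#'   longitudinal pairs.
#' @param noise_sd Additive noise standard deviation (intensity units).
#' @param seed RNG seed; identical configs generate identical data.
#' @export
synth_config <- function(shape = c(48L, 48L, 8L), n_eyes = 30L,
                         interval_mean = 3.6, interval_sd = 5.7,
                         followup_months = 36, p_convert = 0.6,
                         conversion_range = c(2, 30),
                         drusen_n_range = c(1L, 4L),
                         drusen_amp_um = 60,
                         lesion_sparsity = 0.01,
                         noise_sd = 0.03, seed = 1L) {
  structure(list(shape = as.integer(shape), n_eyes = as.integer(n_eyes),
                 interval_mean = interval_mean, interval_sd = interval_sd,
                 followup_months = followup_months, p_convert = p_convert,
                 conversion_range = conversion_range,
                 drusen_n_range = as.integer(drusen_n_range),
                 drusen_amp_um = drusen_amp_um,
                 lesion_sparsity = lesion_sparsity,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synth_config")
}

# Spacing chosen so the en-face field of view is 3.2 x 3.2 mm (slightly
# larger than the 3 mm standardization crop) and the axial extent ~650 um.
synth_spacing <- function(shape) {
  c(650 / shape[1L], 3200 / shape[2L], 3200 / shape[3L])
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

# Smooth random field on the en-face grid: a few low-frequency cosines.
smooth_field <- function(W, D, amplitude, n_waves = 3L) {
  f <- matrix(0, W, D)
  gw <- matrix(seq_len(W) / W, W, D)
  gd <- matrix(rep(seq_len(D) / D, each = W), W, D)
  for (k in seq_len(n_waves)) {
    f <- f + stats::runif(1, -1, 1) *
      cos(2 * pi * (stats::runif(1, 0.3, 1.2) * gw +
                    stats::runif(1, 0.3, 1.2) * gd) + stats::runif(1, 0, 2 * pi))
  }
  f * amplitude / n_waves
}

#' Generate one synthetic retina volume with its layer surfaces
#'
#' @param config A [synth_config()].
#' @param seed Seed for this volume (defaults to `config$seed`).
#' @param drusen_scale Multiplier on the drusen elevation (used by the
#'   cohort generator to encode progression).
#' @param tilt_um Linear BM tilt amplitude across the volume (gives the
#'   flattening step real work).
#' @return List: `volume` ([oct_volume()]), `surfaces` ([layer_surfaces()]).
#' @export
make_retina_volume <- function(config, seed = config$seed,
                               drusen_scale = 1, tilt_um = 40) {
  shp <- config$shape
  with_seed(seed, {
    H <- shp[1L]; W <- shp[2L]; D <- shp[3L]
    sp <- synth_spacing(shp)
    depth_um <- H * sp[1L]
    # surfaces (um): ILM near 35% depth, BM = ILM + ~300 um, plus smooth
    # variation and a linear tilt of the whole retina
    gw <- matrix(seq_len(W) / W, W, D)
    tilt <- tilt_um * (gw - 0.5) * 2
    ilm <- 0.35 * depth_um + smooth_field(W, D, 15) + tilt
    bm <- ilm + 300 + smooth_field(W, D, 8)
    surf <- layer_surfaces(ilm, bm)
    # drusen: Gaussian elevations of the RPE band above BM
    nd <- sample(seq(config$drusen_n_range[1L], config$drusen_n_range[2L]), 1L)
    druse <- matrix(0, W, D)
    for (k in seq_len(nd)) {
      cw <- stats::runif(1, 0.2, 0.8) * W
      cd <- stats::runif(1, 0.2, 0.8) * D
      sw <- stats::runif(1, 0.06, 0.15) * W
      sd_ <- stats::runif(1, 0.12, 0.3) * D
      amp <- config$drusen_amp_um * drusen_scale * stats::runif(1, 0.5, 1.5)
      gw_ <- matrix(seq_len(W), W, D); gd_ <- matrix(rep(seq_len(D), each = W), W, D)
      druse <- druse + amp * exp(-((gw_ - cw)^2 / (2 * sw^2) +
                                   (gd_ - cd)^2 / (2 * sd_^2)))
    }
    # build the banded volume
    v <- array(-0.85, c(H, W, D))
    rows_um <- (seq_len(H) - 0.5) * sp[1L]
    for (d in seq_len(D)) for (w in seq_len(W)) {
      i_um <- ilm[w, d]; b_um <- bm[w, d]; dr <- druse[w, d]
      z <- rows_um
      inner <- z >= i_um & z < i_um + 60            # bright inner band
      mid <- z >= i_um + 60 & z < b_um - 40 - dr    # mid retina
      rpe <- z >= b_um - 40 - dr & z < b_um - dr * 0  # RPE band, lifted by drusen
      rpe <- z >= b_um - 40 - dr & z < b_um         # from lifted band to BM
      chor <- z >= b_um & z < b_um + 150            # choroid
      v[inner, w, d] <- 0.45
      v[mid, w, d] <- 0.05
      v[rpe, w, d] <- 0.8
      v[chor, w, d] <- -0.25
      v[z >= b_um + 150, w, d] <- -0.8
    }
    v <- v + array(stats::rnorm(length(v), 0, config$noise_sd), dim(v))
    v <- pmin(pmax(v, -1), 1)
    vol <- oct_volume(v, spacing = sp, provenance = list(synthetic = TRUE))
    list(volume = vol, surfaces = surf)
  })
}

#' Generate a longitudinal pair with known morph ground truth
#'
#' The later scan is exactly `apply_morph(I_t, field)` for a smooth
#' positive-Jacobian displacement (up to three Gaussian growth bumps,
#' axially dominated) plus a sparse additive lesion map, so morph-recovery
#' tests have an exact target. ROI masks for both time points are included.
#'
#' @param config A [synth_config()].
#' @param seed Seed.
#' @param magnitude Overall morph magnitude multiplier (0 gives the
#'   identity pair).
#' @return List: `I_t`, `I_tk` ([oct_volume()]s), `field` (true
#'   [morph_field()]), `R_t`, `R_tk` (`roi_mask`s), `surfaces`.
#' @export
make_longitudinal_pair <- function(config, seed = config$seed,
                                   magnitude = 1) {
  base <- make_retina_volume(config, seed = seed)
  shp <- config$shape
  with_seed(seed + 1L, {
    H <- shp[1L]; W <- shp[2L]; D <- shp[3L]
    Dfield <- array(0, c(3L, H, W, D))
    n_bump <- sample(1:3, 1L)
    if (magnitude > 0) {
      gh <- array(rep(seq_len(H), W * D), c(H, W, D))
      gw <- array(rep(rep(seq_len(W), each = H), D), c(H, W, D))
      gd <- array(rep(seq_len(D), each = H * W), c(H, W, D))
      for (k in seq_len(n_bump)) {
        ch <- stats::runif(1, 0.3, 0.7) * H
        cw <- stats::runif(1, 0.2, 0.8) * W
        cd <- stats::runif(1, 0.2, 0.8) * D
        sh <- stats::runif(1, 0.15, 0.3) * H
        sw <- stats::runif(1, 0.15, 0.3) * W
        sd_ <- max(stats::runif(1, 0.25, 0.5) * D, 1.5)
        bump <- exp(-((gh - ch)^2 / (2 * sh^2) + (gw - cw)^2 / (2 * sw^2) +
                      (gd - cd)^2 / (2 * sd_^2)))
        # axial displacement with amplitude well below sigma: |grad| << 1,
        # so the Jacobian determinant stays positive
        amp <- magnitude * stats::runif(1, 0.2, 0.4) * sh / 3
        Dfield[1L, , , ] <- Dfield[1L, , , ] - amp * bump
        amp_l <- magnitude * stats::runif(1, 0.1, 0.2) * sw / 3
        Dfield[2L, , , ] <- Dfield[2L, , , ] + amp_l * bump
      }
    }
    A <- array(0, c(H, W, D))
    if (magnitude > 0 && config$lesion_sparsity > 0) {
      n_lesion <- max(1L, round(config$lesion_sparsity * H * W * D / 20))
      for (k in seq_len(n_lesion)) {
        ch <- sample(seq(round(0.3 * H), round(0.7 * H)), 1L)
        cw <- sample(seq_len(W), 1L); cd <- sample(seq_len(D), 1L)
        hh <- max(1L, ch - 1L):min(H, ch + 1L)
        ww <- max(1L, cw - 1L):min(W, cw + 1L)
        A[hh, ww, cd] <- A[hh, ww, cd] +
          magnitude * stats::runif(1, 0.2, 0.4)
      }
    }
    field <- morph_field(Dfield, A)
    I_tk <- apply_morph(base$volume, field)
    I_tk$visit_time <- base$volume$visit_time +
      max(0.5, stats::rnorm(1, config$interval_mean, config$interval_sd))
    roi_t <- build_roi_mask(base$surfaces, base$volume)
    # the later visit's ROI follows the deformed anatomy
    m_tk <- round(array(warp_fw_cpp(roi_t$mask, dim(roi_t$mask),
                                    Dfield, 0), dim(roi_t$mask)))
    roi_tk <- structure(list(mask = m_tk), class = "roi_mask")
    list(I_t = base$volume, I_tk = I_tk, field = field,
         R_t = roi_t, R_tk = roi_tk, surfaces = base$surfaces)
  })
}

# Positive inter-visit interval (months), truncated normal.
draw_interval <- function(mean, sd) {
  repeat {
    x <- stats::rnorm(1, mean, sd)
    if (x > 0.5) return(x)
  }
}

#' Generate an interval-censored conversion cohort
#'
#' Each eye receives a latent conversion time `T*` (finite with probability
#' `p_convert`), irregular visit times, and per-scan labels `(T-, T+)` given
#' by the visits bracketing `T*`; scans after the first converted visit are
#' dropped, the scan at the first converted visit gets `T+ = 0`, and scans
#' whose conversion lies beyond the horizon (or never occurs in follow-up)
#' are censored. Drusen load grows as `1/(T* - t)` so conversion proximity
#' is visible in the images. All three label cases occur for
#' `n_eyes >= 30` under the default configuration.
#'
#' @param config A [synth_config()].
#' @param with_volumes Generate the image volumes (set `FALSE` for
#'   label-only studies).
#' @return List: `visits` (tibble with scan_id, eye_id, visit times, labels
#'   and the latent truth), `volumes`, `surfaces` (named lists keyed by
#'   scan_id; empty when `with_volumes = FALSE`).
#' @export
make_ttc_cohort <- function(config, with_volumes = TRUE) {
  horizon <- TTC_HORIZON_MONTHS
  rows <- list()
  volumes <- list()
  surfaces <- list()
  eye_meta <- with_seed(config$seed, {
    lapply(seq_len(config$n_eyes), function(e) {
      t_star <- if (stats::runif(1) < config$p_convert)
        stats::runif(1, config$conversion_range[1L],
                     config$conversion_range[2L]) else Inf
      visits <- 0
      while (utils::tail(visits, 1L) < config$followup_months) {
        visits <- c(visits,
                    utils::tail(visits, 1L) +
                      draw_interval(config$interval_mean, config$interval_sd))
      }
      visits <- visits[visits <= config$followup_months]
      list(t_star = t_star, visits = visits,
           vol_seed = config$seed + 7919L * e)
    })
  })
  for (e in seq_along(eye_meta)) {
    em <- eye_meta[[e]]
    eye_id <- sprintf("eye%03d", e)
    t_star <- em$t_star
    visits <- em$visits
    conv_idx <- if (is.finite(t_star)) which(visits >= t_star)[1L] else NA_integer_
    keep <- if (!is.na(conv_idx)) seq_len(conv_idx) else seq_along(visits)
    for (k in keep) {
      t <- visits[k]
      if (!is.na(conv_idx)) {
        t_plus <- visits[conv_idx] - t
        t_minus <- if (conv_idx > 1L) visits[conv_idx - 1L] - t else NA_real_
        if (k == conv_idx) { t_plus <- 0; t_minus <- -Inf }
      } else {
        t_plus <- Inf; t_minus <- Inf
      }
      # classify into the three loss cases; drop unusable brackets
      lab <- ttc_case_of(t_minus, t_plus, horizon)
      if (is.na(lab)) next
      if (lab == 2L) { t_minus <- Inf; t_plus <- Inf }
      scan_id <- sprintf("%s_v%02d", eye_id, k)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        scan_id = scan_id, eye_id = eye_id, visit_time_months = t,
        t_minus_months = t_minus, t_plus_months = t_plus,
        t_star_months = t_star, case = lab)
      if (with_volumes) {
        # drusen load accelerates as conversion approaches
        scale <- if (is.finite(t_star))
          1 + 4 / pmax(t_star - t, 1) else 1
        rv <- make_retina_volume(config, seed = em$vol_seed + k,
                                 drusen_scale = scale)
        rv$volume$eye_id <- eye_id
        rv$volume$visit_time <- t
        volumes[[scan_id]] <- rv$volume
        surfaces[[scan_id]] <- rv$surfaces
      }
    }
  }
  visits <- dplyr::bind_rows(rows)
  list(visits = visits, volumes = volumes, surfaces = surfaces)
}

# Case of a raw (t_minus, t_plus) month pair; NA when it fits no case.
ttc_case_of <- function(t_minus, t_plus, horizon = TTC_HORIZON_MONTHS) {
  if (is.finite(t_plus) && t_plus == 0) return(3L)
  if (!is.finite(t_plus)) return(2L)
  if (t_plus > horizon) {
    if (is.na(t_minus) || t_minus > horizon) return(2L)
    return(NA_integer_)  # bracket straddles the horizon: unusable
  }
  if (is.na(t_minus) || !is.finite(t_minus) || t_minus < 0) return(NA_integer_)
  if (t_minus < t_plus) return(1L)
  NA_integer_
}

#' Labels of a cohort as [ttc_label()] objects
#' @param visits The `visits` tibble from [make_ttc_cohort()].
#' @export
cohort_labels <- function(visits) {
  lapply(seq_len(nrow(visits)), function(i)
    ttc_label(visits$t_minus_months[i], visits$t_plus_months[i]))
}
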