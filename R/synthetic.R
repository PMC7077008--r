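#' Configuration of a synthetic glandular layout
#'
#' Describes one TMA-core-like field of perturbed-ellipse glands. Gland
#' long-axis orientations are axial (undirected), so they are drawn with the
#' doubled-angle trick: 2*theta ~ von Mises(2*mu, kappa), halved back into
#' `[0, 180)`. `kappa = 0` gives fully disordered fields (uniform axial
#' orientations); large kappa gives aligned, "ordered" fields. Boundary shape
#' is an ellipse with low-order sinusoidal radial perturbation of relative
#' amplitude `shape_noise`, which stays simple (non-self-intersecting) for
#' `shape_noise <= 0.3`.
#'
#' @param n_glands number of glands to place.
#' @param field_size square field side, pixels.
#' @param kappa von Mises concentration (>= 0) of orientations.
#' @param mu_deg mean orientation, degrees in `[0, 180)`.
#' @param shape_noise radial boundary perturbation, fraction of radius (>= 0).
#' @param axis_ratio mean major/minor axis ratio (>= 1).
#' @param min_gap minimum gap between gland envelopes, pixels.
#' @param seed RNG seed.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(n_glands = 30L, field_size = 384L, kappa = 2,
                         mu_deg = 90, shape_noise = 0.08, axis_ratio = 2,
                         min_gap = 4, seed = 1L) {
  if (n_glands < 0 || kappa < 0 || shape_noise < 0 || axis_ratio < 1)
    stop_domain("invalid synth_config")
  structure(list(n_glands = as.integer(n_glands),
                 field_size = as.integer(field_size), kappa = kappa,
                 mu_deg = mu_deg %% 180, shape_noise = shape_noise,
                 axis_ratio = axis_ratio, min_gap = min_gap,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# Best-Fisher (1979) rejection sampler for the von Mises distribution
rvonmises <- function(n, mu, kappa) {
  if (kappa < 1e-8) return(runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 0L
  while (i < n) {
    z <- cos(pi * runif(1))
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    u2 <- runif(1)
    if (cc * (2 - cc) - u2 > 0 || log(cc / u2) + 1 - cc >= 0) {
      i <- i + 1L
      out[i] <- (sign(runif(1) - 0.5) * acos(pmin(1, pmax(-1, f))) + mu) %% (2 * pi)
    }
  }
  out
}

#' Sample a synthetic gland layout
#'
#' Places non-overlapping perturbed ellipses by rejection (dart throwing
#' with a bounded retry budget), each with a von Mises axial orientation.
#' Deterministic for a given seed. The generating truth (center, axes,
#' orientation) is attached as attribute `"truth"`.
#'
#' @param cfg a [synth_config()].
#' @return A [gland_set()] with provenance "synthetic" and a `truth`
#'   attribute (data.frame of per-gland generating parameters).
#' @export
sample_layout <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  withr::with_seed(cfg$seed, {
    n <- cfg$n_glands
    fs <- cfg$field_size
    if (n == 0) {
      out <- gland_set("synth", list(), provenance = "synthetic")
      attr(out, "truth") <- data.frame()
      return(out)
    }
    # envelope radius ~0.24 fs/sqrt(n) keeps the packing fraction near 0.18
    # so dart-throwing placement terminates reliably
    r_base <- 0.24 * fs /
      (sqrt(max(n, 4)) * sqrt(cfg$axis_ratio) * (1 + 2 * cfg$shape_noise))
    r0 <- r_base * rlnorm(n, 0, 0.15)
    ar <- pmax(1, rnorm(n, cfg$axis_ratio, 0.15 * cfg$axis_ratio))
    major <- r0 * sqrt(ar); minor <- r0 / sqrt(ar)
    theta <- (rvonmises(n, 2 * cfg$mu_deg * pi / 180, cfg$kappa) / 2) %% pi
    rmax <- major * (1 + 2 * cfg$shape_noise)
    cx <- numeric(n); cy <- numeric(n)
    placed <- 0L
    tries <- 0L
    max_tries <- 400L * n
    while (placed < n) {
      tries <- tries + 1L
      if (tries > max_tries)
        stop_domain("packing error: cannot place %d glands in a %d px field",
                    n, fs)
      i <- placed + 1L
      m <- rmax[i] + 1
      x <- runif(1, m, fs - 1 - m); y <- runif(1, m, fs - 1 - m)
      ok <- TRUE
      if (placed > 0) {
        dd <- sqrt((cx[1:placed] - x)^2 + (cy[1:placed] - y)^2)
        ok <- all(dd >= rmax[1:placed] + rmax[i] + cfg$min_gap)
      }
      if (ok) { cx[i] <- x; cy[i] <- y; placed <- i }
    }
    glands <- vector("list", n)
    for (i in seq_len(n)) {
      phi <- seq(0, 2 * pi, length.out = 65)[-65]
      re <- major[i] * minor[i] /
        sqrt((minor[i] * cos(phi))^2 + (major[i] * sin(phi))^2)
      pert <- rep(0, length(phi))
      for (m in 2:4) {
        pert <- pert + rnorm(1, 0, 1 / sqrt(3)) * cos(m * phi) +
          rnorm(1, 0, 1 / sqrt(3)) * sin(m * phi)
      }
      fac <- pmin(1.45, pmax(0.55, 1 + cfg$shape_noise * pert))
      r <- re * fac
      xs <- r * cos(phi); ys <- r * sin(phi)
      ct <- cos(theta[i]); st <- sin(theta[i])
      poly <- cbind(cx[i] + ct * xs - st * ys, cy[i] + st * xs + ct * ys)
      glands[[i]] <- gland(i, poly)
    }
    out <- gland_set(sprintf("synth_seed%d", cfg$seed), glands,
                     provenance = "synthetic")
    attr(out, "truth") <- data.frame(
      id = seq_len(n), cx = cx, cy = cy,
      theta_deg = theta * 180 / pi, major = major, minor = minor)
    out
  })
}

#' Render a pseudo-H&E image of a gland layout
#'
#' Paints pink stroma, a purple epithelial ring per gland, and a bright
#' near-white lumen (the interior of the mask eroded by the ring width),
#' plus seeded Gaussian pixel noise. Lumens are constructed strictly
#' brighter than epithelium and stroma, which is what the lumen-seeded
#' segmenter exploits.
#'
#' @param glands a [gland_set()].
#' @param field_size square field side, pixels.
#' @param seed RNG seed for the pixel noise.
#' @param ring_width epithelial ring width, pixels.
#' @return A [gland_image()].
#' @export
render_image <- function(glands, field_size = 256L, seed = 1L, ring_width = 6L) {
  stopifnot(inherits(glands, "gland_set"))
  stroma <- c(234, 176, 191)
  epith <- c(150, 95, 170)
  lumen <- c(248, 244, 250)
  withr::with_seed(seed, {
    px <- array(0, dim = c(field_size, field_size, 3))
    for (c in 1:3) px[, , c] <- stroma[c]
    lab <- paint_labels(glands$glands, c(field_size, field_size))
    full <- lab > 0
    if (any(full)) {
      dm <- EBImage::distmap(EBImage::Image(t(full)))
      dmat <- t(EBImage::imageData(dm))
      lum <- full & dmat > ring_width
      if (!any(lum)) lum <- full & dmat >= max(dmat) / 2
      ring <- full & !lum
      for (c in 1:3) {
        ch <- px[, , c]
        ch[ring] <- epith[c]
        ch[lum] <- lumen[c]
        px[, , c] <- ch
      }
    }
    noise <- array(rnorm(length(px), 0, 3), dim = dim(px))
    px <- array(pmin(255, pmax(0, px + noise)), dim = dim(noise))
  })
  gland_image(px, id = glands$image_id)
}

#' Configuration of synthetic clinical outcomes
#'
#' @param n_patients number of patients (one layout each).
#' @param beta_disorder log-odds of recurrence per unit disorder score,
#'   where the disorder score of a layout with concentration kappa is
#'   `1/(1 + kappa)` (bounded in (0, 1], monotone in disorder).
#' @param baseline_hazard events per month for non-recurrent patients (> 0).
#' @param hr_recurrence hazard ratio of recurrent patients (> 0).
#' @param censor_time administrative censoring time, months.
#' @param seed RNG seed.
#' @return list of class `synth_outcome_config`.
#' @export
synth_outcome_config <- function(n_patients = 100L, beta_disorder = 2,
                                 baseline_hazard = 0.01, hr_recurrence = 4,
                                 censor_time = 60, seed = 1L) {
  if (baseline_hazard <= 0 || hr_recurrence <= 0)
    stop_domain("baseline_hazard and hr_recurrence must be > 0")
  structure(list(n_patients = as.integer(n_patients),
                 beta_disorder = beta_disorder,
                 baseline_hazard = baseline_hazard,
                 hr_recurrence = hr_recurrence,
                 censor_time = censor_time, seed = as.integer(seed)),
            class = "synth_outcome_config")
}

#' Simulate a cohort table linked to layout disorder
#'
#' Recurrence is Bernoulli with probability
#' `plogis(beta_disorder * 1/(1 + kappa))`; survival time is exponential
#' with rate `baseline_hazard * hr_recurrence^recurrence`, administratively
#' censored at `censor_time` (censored rows have `event = 0`).
#'
#' @param layout_cfgs list of [synth_config()], one per patient.
#' @param out_cfg a [synth_outcome_config()].
#' @return A `cohort_table` with columns patient_id, image_id, kappa,
#'   disorder, recurrence, survival_time, event.
#' @export
simulate_cohort <- function(layout_cfgs, out_cfg) {
  stopifnot(inherits(out_cfg, "synth_outcome_config"))
  n <- length(layout_cfgs)
  kappa <- vapply(layout_cfgs, function(cf) cf$kappa, numeric(1))
  disorder <- 1 / (1 + kappa)
  withr::with_seed(out_cfg$seed, {
    rec <- rbinom(n, 1, stats::plogis(out_cfg$beta_disorder * disorder))
    raw <- rexp(n, rate = out_cfg$baseline_hazard *
                  out_cfg$hr_recurrence^rec)
    event <- as.integer(raw < out_cfg$censor_time)
    tt <- pmin(raw, out_cfg$censor_time)
  })
  validate_cohort(data.frame(
    patient_id = sprintf("P%04d", seq_len(n)),
    image_id = sprintf("synth_seed%d", vapply(layout_cfgs,
                                              function(cf) cf$seed, integer(1))),
    kappa = kappa, disorder = disorder,
    recurrence = rec, survival_time = tt, event = event,
    stringsAsFactors = FALSE))
}

# circular dispersion of axial angles: 1 - mean resultant length on the
# doubled-angle circle (0 = perfectly aligned, 1 = uniform)
axial_dispersion <- function(theta_deg) {
  a <- 2 * theta_deg * pi / 180
  1 - sqrt(mean(cos(a))^2 + mean(sin(a))^2)
}
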