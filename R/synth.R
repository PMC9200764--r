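#' Parameters of the synthetic slide/cohort generator
#'
#' The generator emulates H&E-like slides: a pinkish stroma background with
#' dark-purple elliptical nuclei placed by an inhomogeneous Poisson process
#' whose smooth local intensity varies around a per-patient base density, a
#' near-white glass margin (so Otsu segmentation is exercised), and a
#' proportional-hazards survival process driven by the patient's nuclear
#' density with uniform right censoring.
#'
#' @param n_patients cohort size.
#' @param slide_size slide side in pixels.
#' @param h0 baseline hazard in events/month (constant, i.e. exponential
#'   event times; `weibull_shape != 1` switches to a Weibull baseline).
#' @param beta_true log-hazard per unit of the standardized patient feature.
#' @param censor_rate target expected censored fraction in `[0, 1)`.
#' @param nuclei_density_range `(low, high)` expected nuclei per 100 x 100
#'   pixels of tissue; patient densities are drawn uniformly from it.
#' @param weibull_shape Weibull shape of the baseline hazard (1 = exponential).
#' @param slides_per_patient number of slides generated per patient.
#' @param seed integer master seed.
#' @return list of class `synth_params`.
#' @export
synth_params <- function(n_patients = 40, slide_size = 192, h0 = 0.02,
                         beta_true = 1.5, censor_rate = 0.3,
                         nuclei_density_range = c(5, 40), weibull_shape = 1,
                         slides_per_patient = 1, seed = 1) {
  stopifnot(h0 > 0, censor_rate >= 0, censor_rate < 1,
            nuclei_density_range[1L] < nuclei_density_range[2L],
            nuclei_density_range[1L] >= 0, weibull_shape > 0)
  structure(list(n_patients = n_patients, slide_size = slide_size, h0 = h0,
                 beta_true = beta_true, censor_rate = censor_rate,
                 nuclei_density_range = nuclei_density_range,
                 weibull_shape = weibull_shape,
                 slides_per_patient = slides_per_patient, seed = seed),
            class = "synth_params")
}

# Smooth multiplicative random field around 1 (coarse uniform grid,
# bilinearly upsampled); `amp` sets the relative fluctuation.
smooth_field <- function(h, w, amp = 0.6, knots = 5L) {
  coarse <- matrix(stats::runif(knots * knots, -1, 1), knots, knots)
  1 + amp * resize_matrix(coarse, h, w)
}

#' Generate one synthetic H&E-like slide
#'
#' @param density expected nuclei per 100 x 100 px of tissue (the slide-level
#'   base rate; the local rate fluctuates smoothly around it).
#' @param slide_size slide side in pixels.
#' @param seed integer seed; generation is bit-reproducible.
#' @param margin glass margin width in pixels (default `slide_size / 12`).
#' @param density_ref fixed reference density mapping the ground-truth local
#'   density onto the `[0, 1]` informativeness scale (shared across slides so
#'   slide means stay comparable between patients).
#' @return object of class `synth_slide`: `image` (`H x W x 3`),
#'   `informativeness` (per-pixel `[0, 1]` local expected nuclear density,
#'   0 on glass), `tissue` (logical mask), `patient_feature` (mean
#'   informativeness over tissue), `tissue_fraction`, `density`.
#' @export
generate_slide <- function(density, slide_size = 192, seed = 1,
                           margin = max(8L, round(slide_size / 12)),
                           density_ref = 80) {
  stopifnot(density >= 0, slide_size > 4 * margin)
  with_local_seed(seed, {
    h <- w <- as.integer(slide_size)
    tissue <- matrix(FALSE, h, w)
    tissue[(margin + 1L):(h - margin), (margin + 1L):(w - margin)] <- TRUE

    # glass background
    img <- array(stats::rnorm(h * w * 3L, 0, 0.004), dim = c(h, w, 3L))
    img <- img + rep(c(0.96, 0.96, 0.97), each = h * w)

    # stroma: pink with low-frequency texture + fine noise; tones are chosen
    # so the tissue-vs-glass grayscale separation dominates the histogram
    # (as on real low-magnification thumbnails) and Otsu finds it
    tex <- smooth_field(h, w, amp = 0.03, knots = 7L)
    base <- c(0.86, 0.62, 0.74)
    for (c in 1:3) {
      layer <- img[, , c]
      layer[tissue] <- (base[c] * tex + stats::rnorm(h * w, 0, 0.015))[tissue]
      img[, , c] <- layer
    }

    # local nuclear intensity field (expected nuclei per 100x100 px)
    lambda <- density * pmax(smooth_field(h, w, amp = 0.6), 0)
    lambda[!tissue] <- 0

    # place nuclei by thinning a homogeneous candidate process
    n_expected <- sum(lambda) / 1e4
    n_nuclei <- stats::rpois(1L, n_expected)
    if (n_nuclei > 0 && max(lambda) > 0) {
      placed <- 0L
      lam_max <- max(lambda)
      guard <- 0L
      while (placed < n_nuclei && guard < 50L * n_nuclei + 1000L) {
        guard <- guard + 1L
        py <- sample.int(h, 1L); px <- sample.int(w, 1L)
        if (!tissue[py, px] || stats::runif(1L) > lambda[py, px] / lam_max) next
        placed <- placed + 1L
        img <- draw_nucleus(img, px, py)
      }
    }

    info <- clamp01(lambda / density_ref)
    info[!tissue] <- 0

    structure(list(image = clamp01(img),
                   informativeness = info,
                   tissue = tissue,
                   patient_feature = mean(info[tissue]),
                   tissue_fraction = mean(tissue),
                   density = density),
              class = "synth_slide")
  })
}

# paint one dark-purple ellipse (rotated, jittered colour) at (px, py)
draw_nucleus <- function(img, px, py) {
  h <- nrow(img); w <- ncol(img)
  rx <- stats::runif(1L, 2.5, 4.5)
  ry <- stats::runif(1L, 2.5, 4.5)
  th <- stats::runif(1L, 0, pi)
  col <- clamp01(c(0.47, 0.32, 0.58) + stats::rnorm(3L, 0, 0.04))
  r <- ceiling(max(rx, ry))
  ys <- max(1L, py - r):min(h, py + r)
  xs <- max(1L, px - r):min(w, px + r)
  dy <- outer(ys - py, rep(1, length(xs)))
  dx <- outer(rep(1, length(ys)), xs - px)
  u <- (dx * cos(th) + dy * sin(th)) / rx
  v <- (-dx * sin(th) + dy * cos(th)) / ry
  inside <- u^2 + v^2 <= 1
  for (c in 1:3) {
    sub <- img[ys, xs, c]
    sub[inside] <- col[c]
    img[ys, xs, c] <- sub
  }
  img
}

#' Generate a synthetic cohort with known image-driven hazard
#'
#' Each patient receives a base nuclear density drawn uniformly from
#' `params$nuclei_density_range`; the patient feature is the slide-mean
#' ground-truth informativeness (or the density itself when
#' `render_slides = FALSE`), standardized across the cohort to `z`. Event
#' times follow a proportional-hazards model with baseline hazard
#' `h0` (Weibull shape `weibull_shape`, exponential by default):
#' `T ~ h(t | z) = h0 * exp(beta_true * z)`. Censoring times are uniform on
#' `(0, q)` with `q` solved so the expected censored fraction matches
#' `censor_rate`; the recorded time is `min(T, C)` with `event = 1` when the
#' death was observed.
#'
#' @param params a [synth_params].
#' @param render_slides when `FALSE`, skips image rendering (slides list is
#'   empty and the feature equals the drawn density); useful for large
#'   cohorts where only the survival joint law matters.
#' @return list with `slides` (named list: patient id -> list of
#'   `synth_slide`), `cohort` (a [cohort]), and `truth` (data.frame with
#'   `patient_id`, `density`, `feature`, `z`, `event_time`, `time_months`,
#'   `event`).
#' @export
generate_cohort <- function(params = synth_params(), render_slides = TRUE) {
  stopifnot(inherits(params, "synth_params"))
  n <- params$n_patients
  ids <- sprintf("P%03d", seq_len(n))
  with_local_seed(params$seed, {
    dens <- stats::runif(n, params$nuclei_density_range[1L], params$nuclei_density_range[2L])
    slide_seeds <- matrix(sample.int(.Machine$integer.max %/% 2L,
                                     n * params$slides_per_patient),
                          nrow = n)
    slides <- stats::setNames(vector("list", n), ids)
    if (render_slides) {
      for (i in seq_len(n)) {
        slides[[i]] <- lapply(seq_len(params$slides_per_patient), function(s) {
          generate_slide(dens[i], params$slide_size, seed = slide_seeds[i, s],
                         density_ref = 2 * params$nuclei_density_range[2L])
        })
      }
      feature <- vapply(slides, function(sl) mean(vapply(sl, `[[`, 0, "patient_feature")), 0)
    } else {
      feature <- dens
    }
    z <- as.vector(scale(feature))

    rate <- params$h0 * exp(params$beta_true * z)
    event_time <- if (params$weibull_shape == 1) {
      stats::rexp(n, rate)
    } else {
      # PH Weibull: S(t) = exp(-(h0 t)^k * exp(beta z))
      (-log(stats::runif(n)) / exp(params$beta_true * z))^(1 / params$weibull_shape) / params$h0
    }

    if (params$censor_rate > 0) {
      q <- censor_horizon(rate, params$censor_rate, params$weibull_shape, params$h0,
                          exp(params$beta_true * z))
      cens_time <- stats::runif(n, 0, q)
    } else {
      cens_time <- rep(Inf, n)
    }
    time <- pmin(event_time, cens_time)
    event <- as.integer(event_time <= cens_time)

    truth <- data.frame(patient_id = ids, density = dens, feature = feature,
                        z = z, event_time = event_time, time_months = time,
                        event = event, stringsAsFactors = FALSE)
    patients <- data.frame(patient_id = ids, time_months = time, event = event,
                           stringsAsFactors = FALSE)
    patients$slide_ids <- lapply(seq_len(n), function(i) {
      sprintf("%s_s%d.png", ids[i], seq_len(params$slides_per_patient))
    })
    list(slides = slides, cohort = cohort(patients, name = "synthetic"), truth = truth)
  })
}

# Solve for the uniform-censoring horizon q giving the target expected
# censored fraction: P(C < T) averaged over patients.
censor_horizon <- function(rate, target, shape = 1, h0 = NULL, hr = NULL) {
  p_cens <- function(q) {
    if (shape == 1) {
      mean((1 - exp(-rate * q)) / (rate * q))
    } else {
      # numeric expectation of S(t) over C ~ U(0, q)
      mean(vapply(seq_along(hr), function(i) {
        stats::integrate(function(t) exp(-(h0 * t)^shape * hr[i]), 0, q)$value / q
      }, 0))
    }
  }
  f <- function(q) p_cens(q) - target
  lo <- 1e-6; hi <- 1
  while (f(hi) > 0 && hi < 1e9) hi <- hi * 2
  stats::uniroot(f, c(lo, hi), tol = 1e-8)$root
}

#' Write a synthetic cohort to disk
#'
#' Slides as PNG, cohort in the standard CSV schema (slide paths point at
#' the written PNGs), and the truth table as CSV.
#'
#' @param synth result of [generate_cohort()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_synth_cohort <- function(synth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  co <- synth$cohort
  for (i in seq_len(nrow(co$patients))) {
    pid <- co$patients$patient_id[i]
    files <- co$patients$slide_ids[[i]]
    for (s in seq_along(files)) {
      png::writePNG(synth$slides[[pid]][[s]]$image, file.path(dir, files[s]))
    }
    co$patients$slide_ids[[i]] <- file.path(dir, files)
  }
  write_cohort(co, file.path(dir, "cohort.csv"))
  utils::write.csv(synth$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(dir)
}
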