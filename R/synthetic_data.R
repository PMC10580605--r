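#' Default marginal moments of the trait table
#'
#' Per-trait mean and standard deviation (with the observed min/max carried
#' as metadata) used to calibrate the trait generator: plant height PH (cm),
#' penultimate diameter PeD (mm), internode lengths IL1 and IL2 (cm), and
#' the lodging score LS (unitless, \[0, 1\]).
#'
#' @return data.frame with columns `trait`, `mean`, `sd`, `min`, `max`.
#' @export
default_trait_moments <- function() {
  data.frame(
    trait = c("PH", "PeD", "IL1", "IL2", "LS"),
    mean  = c(102.225, 4.020, 7.632, 13.059, 0.288),
    sd    = c(12.952, 0.592, 1.836, 2.139, 0.263),
    min   = c(73.6, 2.24, 4.0, 8.4, 0.0),
    max   = c(127.4, 5.65, 11.6, 18.3, 0.842),
    stringsAsFactors = FALSE
  )
}

#' Default trait-to-lodging-score correlations
#'
#' The planted Pearson correlations between each predictor trait and the
#' lodging score: PH 0.78, IL1 0.70, IL2 0.63, PeD -0.48.
#'
#' @return named numeric vector.
#' @export
default_trait_correlations <- function() {
  c(PH = 0.78, PeD = -0.48, IL1 = 0.70, IL2 = 0.63)
}

#' Configuration for the trait-table generator
#'
#' The generator draws a multivariate-normal latent vector whose
#' correlation matrix is assembled from a single "lodging propensity"
#' factor: the lodging score loads on the factor with loading
#' `ls_loading` (default 0.9), and each predictor trait with loading
#' `r_i / ls_loading`, so every planted trait-score correlation is hit
#' exactly while predictor-predictor correlations
#' `r_i * r_j / ls_loading^2` arise as realistic multicollinearity.
#'
#' @param n number of accessions (rows); may be 0.
#' @param seed integer seed; every draw is deterministic given it.
#' @param moments data.frame as [default_trait_moments()].
#' @param correlations named vector of trait-LS correlations.
#' @param ls_loading loading of LS on the common factor, in (max |r|, 1\].
#' @param zero_inflation `"none"` (latent scores reported as drawn, the
#'   calibration mode) or `"censor"` (left-censor at 0, creating the
#'   point mass of lodging-resistant accessions; scores also capped at 1).
#' @param landrace_fraction fraction of accessions labeled landrace
#'   (default 156/228, the remainder cultivars).
#' @return a list of class `trait_gen_config`.
#' @export
trait_gen_config <- function(n = 456, seed = 1,
                             moments = default_trait_moments(),
                             correlations = default_trait_correlations(),
                             ls_loading = 0.9,
                             zero_inflation = c("none", "censor"),
                             landrace_fraction = 156 / 228) {
  zero_inflation <- match.arg(zero_inflation)
  if (n < 0) stop("`n` must be non-negative", call. = FALSE)
  if (any(moments$sd <= 0)) stop("all marginal sds must be positive",
                                 call. = FALSE)
  if (ls_loading <= max(abs(correlations)) || ls_loading > 1) {
    stop("`ls_loading` must exceed the largest |correlation| and be <= 1",
         call. = FALSE)
  }
  structure(list(n = n, seed = seed, moments = moments,
                 correlations = correlations, ls_loading = ls_loading,
                 zero_inflation = zero_inflation,
                 landrace_fraction = landrace_fraction),
            class = "trait_gen_config")
}

# Assemble the latent correlation matrix from the single-factor structure,
# repairing to the nearest positive-definite matrix if needed.
assemble_correlation <- function(correlations, ls_loading) {
  traits <- names(correlations)
  loadings <- c(correlations / ls_loading, LS = ls_loading)
  k <- length(loadings)
  R <- tcrossprod(loadings)
  diag(R) <- 1
  rownames(R) <- colnames(R) <- c(traits, "LS")
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-8) {
    R <- as.matrix(Matrix::nearPD(R, corr = TRUE)$mat)
    ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < 1e-10) {
      stop("correlation matrix could not be repaired to positive definite",
           call. = FALSE)
    }
  }
  R
}

#' Generate a synthetic accession-by-trait table
#'
#' Draws `n` accessions from a multivariate normal with the configured
#' correlation structure, then scales each column to the configured
#' marginal mean and sd. For `n` above the trait count the latent draw is
#' recolored to sample-exact moments (empirical mode), so the planted
#' means, sds and correlations are reproduced in the sample, not just in
#' expectation. In `"censor"` mode, latent lodging scores at or
#' below 0 become exactly 0 (the lodging-resistant point mass, with
#' closed-form expected fraction `pnorm(-mean/sd)`), and scores above 1
#' are capped at 1 (the score index is bounded by construction).
#'
#' @param config a [trait_gen_config()].
#' @return data.frame with columns `accession_id`, `origin`, the predictor
#'   traits, and `LS`.
#' @export
gen_trait_table <- function(config) {
  stopifnot(inherits(config, "trait_gen_config"))
  traits <- c(names(config$correlations), "LS")
  if (config$n == 0L) {
    out <- data.frame(accession_id = character(), origin = character(),
                      stringsAsFactors = FALSE)
    for (tr in traits) out[[tr]] <- numeric()
    return(out)
  }
  R <- assemble_correlation(config$correlations, config$ls_loading)
  mom <- config$moments
  rownames(mom) <- mom$trait
  with_seed(config$seed, {
    z <- if (config$n >= length(traits) + 1L) {
      # sample-exact calibration: recolor the draw so the sample mean and
      # covariance equal the planted values (the planted correlations are
      # then population AND sample parameters)
      MASS::mvrnorm(config$n, mu = rep(0, length(traits)), Sigma = R,
                    empirical = TRUE)
    } else {
      matrix(stats::rnorm(config$n * length(traits)),
             config$n) %*% chol(R)
    }
    colnames(z) <- traits
    x <- sapply(traits, function(tr) {
      mom[tr, "mean"] + mom[tr, "sd"] * z[, tr]
    })
    x <- matrix(x, nrow = config$n, dimnames = list(NULL, traits))
    if (config$zero_inflation == "censor") {
      x[, "LS"] <- pmin(pmax(x[, "LS"], 0), 1)
    }
    origin <- ifelse(
      stats::runif(config$n) < config$landrace_fraction,
      "landrace", "cultivar")
    data.frame(
      accession_id = sprintf("ACC%04d", seq_len(config$n)),
      origin = origin,
      as.data.frame(x),
      stringsAsFactors = FALSE
    )
  })
}

#' Simulate a plumb-bob height pair for a known inclination angle
#'
#' Inverts the angle formula: `hv = hsl * cos(angle)` plus optional
#' Gaussian measurement noise, clamped to \[0, hsl\]. With zero noise the
#' pair round-trips through [cai_from_plumb()] exactly.
#'
#' @param true_cai angle(s) in degrees, \[0, 90\].
#' @param hsl slant height(s), > 0.
#' @param noise_sd sd of additive Gaussian noise on `hv`, same unit.
#' @param seed integer seed (used only when `noise_sd > 0`).
#' @return data.frame with columns `hv`, `hsl`.
#' @export
gen_plumb <- function(true_cai, hsl = 1, noise_sd = 0, seed = 1) {
  if (any(!is.finite(true_cai)) || any(true_cai < 0) || any(true_cai > 90)) {
    stop("`true_cai` must lie in [0, 90] degrees", call. = FALSE)
  }
  if (any(hsl <= 0)) stop("`hsl` must be positive", call. = FALSE)
  n <- max(length(true_cai), length(hsl))
  true_cai <- rep_len(true_cai, n)
  hsl <- rep_len(hsl, n)
  hv <- hsl * cos(true_cai * pi / 180)
  if (noise_sd > 0) {
    hv <- with_seed(seed, hv + stats::rnorm(n, 0, noise_sd))
  }
  data.frame(hv = pmin(pmax(hv, 0), hsl), hsl = hsl)
}

#' Configuration for the synthetic canopy-image generator
#'
#' Healthy canopy and lodged patches are sampled from CIELAB boxes chosen
#' to be separable by the default warm predicate: healthy pixels are green
#' (a* < 0), lodged pixels straw-colored (a* > 0).
#'
#' @param width,height image size in pixels.
#' @param la_true target lodged-area percentage, \[0, 100\].
#' @param n_patches nominal number of elliptical lodged patches.
#' @param healthy_lab,lodged_lab 3x2 matrices of per-channel \[lo, hi\]
#'   CIELAB sampling bounds (rows L, a, b).
#' @param noise_sd sd of additive Gaussian RGB noise, in 8-bit levels.
#' @param seed integer seed.
#' @return list of class `canopy_gen_config`.
#' @export
canopy_gen_config <- function(width = 160, height = 120, la_true = 30,
                              n_patches = 5,
                              healthy_lab = rbind(L = c(35, 50),
                                                  a = c(-40, -18),
                                                  b = c(20, 38)),
                              lodged_lab = rbind(L = c(55, 72),
                                                 a = c(8, 25),
                                                 b = c(28, 45)),
                              noise_sd = 0, seed = 1) {
  if (la_true < 0 || la_true > 100) {
    stop("`la_true` must lie in [0, 100]", call. = FALSE)
  }
  if (healthy_lab["a", 2] >= 0 || lodged_lab["a", 1] <= 0) {
    stop("color boxes must be separable: healthy a* < 0 < lodged a*",
         call. = FALSE)
  }
  structure(list(width = width, height = height, la_true = la_true,
                 n_patches = n_patches, healthy_lab = healthy_lab,
                 lodged_lab = lodged_lab, noise_sd = noise_sd, seed = seed),
            class = "canopy_gen_config")
}

# rasterize one ellipse into a logical H x W matrix
ellipse_mask <- function(h, w, cx, cy, rx, ry, theta) {
  xs <- matrix(rep(seq_len(w), each = h), h) - cx
  ys <- matrix(rep(seq_len(h), w), h) - cy
  u <- xs * cos(theta) + ys * sin(theta)
  v <- -xs * sin(theta) + ys * cos(theta)
  (u / rx)^2 + (v / ry)^2 <= 1
}

sample_lab_box <- function(box, n) {
  cbind(stats::runif(n, box["L", 1], box["L", 2]),
        stats::runif(n, box["a", 1], box["a", 2]),
        stats::runif(n, box["b", 1], box["b", 2]))
}

#' Generate a synthetic canopy image with known lodged fraction
#'
#' A green-textured background with elliptical straw-colored lodged
#' patches placed until the truth mask covers `la_true` to within 0.5
#' percentage points. Per-pixel colors are drawn from the configured
#' CIELAB boxes, converted to sRGB, Gaussian noise added at `noise_sd`
#' 8-bit levels, and quantized to 8-bit.
#'
#' @param config a [canopy_gen_config()].
#' @return list with `pixels` (`H x W x 3`, values 0-255) and `truth_mask`
#'   (integer `H x W`, 1 = lodged).
#' @export
gen_canopy_image <- function(config) {
  stopifnot(inherits(config, "canopy_gen_config"))
  h <- config$height; w <- config$width
  total <- h * w
  target <- config$la_true / 100
  with_seed(config$seed, {
    mask <- matrix(FALSE, h, w)
    if (target >= 1) {
      mask[] <- TRUE
    } else if (target > 0) {
      max_area <- max(total * target / config$n_patches, 16)
      iter <- 0L
      while (sum(mask) / total < target - 0.004) {
        iter <- iter + 1L
        if (iter > 50L * config$n_patches + 400L) {
          stop("placement failure: could not reach la_true with the ",
               "configured patch count", call. = FALSE)
        }
        deficit_px <- (target - sum(mask) / total) * total
        area <- min(max_area, deficit_px)
        aspect <- stats::runif(1, 0.5, 2)
        rx <- sqrt(area / pi * aspect)
        ry <- area / pi / rx
        cx <- stats::runif(1, 1, w)
        cy <- stats::runif(1, 1, h)
        theta <- stats::runif(1, 0, pi)
        cand <- mask | ellipse_mask(h, w, cx, cy, rx, ry, theta)
        # skip a candidate that would overshoot the tolerance band
        if (sum(cand) / total <= target + 0.004) mask <- cand
      }
    }
    lab <- matrix(0, total, 3)
    lodged_idx <- which(as.vector(mask))
    healthy_idx <- which(!as.vector(mask))
    if (length(healthy_idx)) {
      lab[healthy_idx, ] <- sample_lab_box(config$healthy_lab,
                                           length(healthy_idx))
    }
    if (length(lodged_idx)) {
      lab[lodged_idx, ] <- sample_lab_box(config$lodged_lab,
                                          length(lodged_idx))
    }
    rgb01 <- grDevices::convertColor(lab, from = "Lab", to = "sRGB",
                                     scale.out = 1)
    rgb01 <- pmin(pmax(rgb01, 0), 1)
    px <- rgb01 * 255
    if (config$noise_sd > 0) {
      px <- px + stats::rnorm(length(px), 0, config$noise_sd)
    }
    px <- round(pmin(pmax(px, 0), 255))
    pixels <- array(0, c(h, w, 3))
    pixels[, , 1] <- matrix(px[, 1], h, w)
    pixels[, , 2] <- matrix(px[, 2], h, w)
    pixels[, , 3] <- matrix(px[, 3], h, w)
    list(pixels = pixels, truth_mask = matrix(as.integer(mask), h, w))
  })
}

# Decompose a lodging score into a consistent (LA, CAI) pair plus
# field-protocol quadrant values and subplot angles whose aggregation
# reproduces the score exactly.
decompose_score <- function(ls) {
  if (ls <= 0) {
    return(list(la = 0, cai = 0, quadrants = rep(0, 4),
                angles = numeric()))
  }
  s <- sqrt(ls)
  f <- stats::runif(1, 0.85, 1.2)
  cai_frac <- min(1, s * f)
  la_frac <- ls / cai_frac
  if (la_frac > 1) {
    la_frac <- 1
    cai_frac <- ls
  }
  la <- 100 * la_frac
  cai <- 90 * cai_frac
  # split LA across quadrants proportionally to random weights, capping
  # saturated quadrants at 25 and redistributing (water-filling; exact
  # in at most 4 passes since la <= 100)
  wts <- stats::runif(4, 0.2, 1)
  q <- rep(0, 4)
  capped <- rep(FALSE, 4)
  for (i in 1:4) {
    rem <- la - 25 * sum(capped)
    q[!capped] <- rem * wts[!capped] / sum(wts[!capped])
    newly <- !capped & q > 25
    if (!any(newly)) break
    capped <- capped | newly
    q[capped] <- 25
  }
  # subplot angles with mean exactly cai, inside [0, 90]
  k <- sample(4:8, 1)
  d <- stats::rnorm(k, 0, 5)
  d <- d - mean(d)
  lim <- 1
  if (max(d) > 0) lim <- min(lim, (90 - cai) / max(d))
  if (min(d) < 0) lim <- min(lim, cai / (-min(d)))
  angles <- cai + lim * d
  angles <- angles - mean(angles) + cai
  list(la = la, cai = cai, quadrants = q, angles = angles)
}

#' Generate a complete desk-scale study fixture
#'
#' Emits a mutually consistent set of study inputs: an accession-by-trait
#' table (censored lodging scores, the default study condition), a
#' plot-measurement table whose quadrant values and subplot angles
#' aggregate exactly to each plot's lodging score, and a small set of
#' canopy images whose true lodged fraction matches the first plots'
#' lodged areas.
#'
#' @param n_accessions accessions (default 228).
#' @param n_reps field replications; rows = accessions x reps (default 2).
#' @param n_images number of canopy images to generate (default 6).
#' @param image_size `c(height, width)` in pixels.
#' @param noise_sd RGB noise for the images.
#' @param seed master seed.
#' @param out_dir optional directory; when given, writes `traits.csv`,
#'   `plots.csv`, `images/img_###.png` + truth masks, and returns paths.
#' @return list with `traits` (data.frame), `plots` (data.frame incl.
#'   list-column `subplot_angles`), `images` (list of generator outputs),
#'   and `paths` when written.
#' @export
gen_study <- function(n_accessions = 228, n_reps = 2, n_images = 6,
                      image_size = c(120, 160), noise_sd = 0, seed = 1,
                      out_dir = NULL) {
  n <- n_accessions * n_reps
  cfg <- trait_gen_config(n = n, seed = seed, zero_inflation = "censor")
  traits <- gen_trait_table(cfg)
  traits$accession_id <- sprintf("ACC%04d",
                                 rep(seq_len(n_accessions), n_reps))
  traits$rep <- rep(seq_len(n_reps), each = n_accessions)
  plots <- with_seed(seed + 1L, {
    rows <- lapply(seq_len(n), function(i) {
      d <- decompose_score(traits$LS[i])
      data.frame(plot_id = sprintf("P%04d", i),
                 genotype = traits$accession_id[i],
                 q1 = d$quadrants[1], q2 = d$quadrants[2],
                 q3 = d$quadrants[3], q4 = d$quadrants[4],
                 la_true = d$la, cai_true = d$cai,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out$subplot_angles <- lapply(seq_len(n), function(i) NULL)
    out
  })
  # regenerate angles deterministically (list-columns inside with_seed
  # above would be fine too, but keep the two streams separate)
  plots$subplot_angles <- with_seed(seed + 2L, {
    lapply(seq_len(n), function(i) {
      if (plots$la_true[i] <= 0) return(numeric())
      cai <- plots$cai_true[i]
      k <- sample(4:8, 1)
      d <- stats::rnorm(k, 0, 5)
      d <- d - mean(d)
      lim <- 1
      if (max(d) > 0) lim <- min(lim, (90 - cai) / max(d))
      if (min(d) < 0) lim <- min(lim, cai / (-min(d)))
      angles <- cai + lim * d
      angles - mean(angles) + cai
    })
  })
  images <- lapply(seq_len(n_images), function(i) {
    gen_canopy_image(canopy_gen_config(
      width = image_size[2], height = image_size[1],
      la_true = plots$la_true[i], noise_sd = noise_sd,
      seed = seed + 100L + i))
  })
  res <- list(traits = traits, plots = plots, images = images)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(out_dir, "images"), showWarnings = FALSE)
    tpath <- file.path(out_dir, "traits.csv")
    utils::write.csv(traits, tpath, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
    pl <- plots
    pl$angles <- vapply(pl$subplot_angles, function(a) {
      paste(sprintf("%.12g", a), collapse = ";")
    }, character(1))
    pl$subplot_angles <- NULL
    ppath <- file.path(out_dir, "plots.csv")
    utils::write.csv(pl, ppath, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
    ipaths <- vapply(seq_along(images), function(i) {
      p <- file.path(out_dir, "images", sprintf("img_%03d.png", i))
      png::writePNG(aperm(array(images[[i]]$pixels / 255,
                                dim(images[[i]]$pixels)), c(1, 2, 3)), p)
      write_mask_png(images[[i]]$truth_mask,
                     file.path(out_dir, "images",
                               sprintf("mask_%03d.png", i)))
      p
    }, character(1))
    res$paths <- list(traits = tpath, plots = ppath, images = ipaths)
  }
  res
}
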