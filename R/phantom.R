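#' Phantom generator parameters
#'
#' Study conditions for the synthetic paired-visit eye phantoms. The
#' phantom emulates the spectral structure the segmentation relies on:
#' drusen bright on all three channels with distinct centre and edge
#' spectral zones, pigmentary abnormalities dark predominantly on the
#' green channel, vessels dark on all channels, radial vignetting,
#' Gaussian sensor noise, and a small affine misalignment of each raw
#' channel relative to the reference frame.
#'
#' @param seed integer seed (mandatory); all randomness flows from it
#'   through named streams, so adding one component never perturbs the
#'   others.
#' @param image_size `c(rows, cols)`, default 192 x 192.
#' @param n_drusen number of drusen (default 3; intermediate AMD
#'   phantoms model a few large, partly confluent macular drusen).
#' @param drusen_radius_range radius range in px (default 12-20).
#' @param drusen_center_brightness,drusen_edge_brightness additive
#'   contrast of the drusen centre zone / edge annulus per channel
#'   (faf, ir, green), in \[0,1\] units.
#' @param pigment_count number of pigmentary lesions (default 2).
#' @param pigment_darkness subtractive contrast per channel; green
#'   dominates.
#' @param n_vessels number of vessel tracks (default 4).
#' @param vessel_darkness subtractive vessel contrast (all channels).
#' @param vignetting relative radial illumination falloff (default 0.15).
#' @param noise_sigma Gaussian noise sd in \[0,1\] units (default 0.02).
#' @param target_percent_change planted drusen-area change from visit 1
#'   to visit 2, percent (default 0; must be > -100).
#' @param misalignment list: `rotation_deg`, `translation_px`,
#'   `scale_dev` — maximum magnitudes of the per-channel affine jitter.
#' @return list of class `phantom_params`.
#' @export
phantom_params <- function(seed,
                           image_size = c(192L, 192L),
                           n_drusen = 3L,
                           drusen_radius_range = c(12, 20),
                           drusen_center_brightness = c(faf = 0.42, ir = 0.36, green = 0.26),
                           drusen_edge_brightness   = c(faf = 0.26, ir = 0.34, green = 0.10),
                           pigment_count = 2L,
                           pigment_darkness = c(faf = 0.10, ir = 0.06, green = 0.35),
                           n_vessels = 4L,
                           vessel_darkness = 0.25,
                           vignetting = 0.15,
                           noise_sigma = 0.02,
                           target_percent_change = 0,
                           misalignment = list(rotation_deg = 2,
                                               translation_px = 3,
                                               scale_dev = 0.02)) {
  if (missing(seed)) .stop_validation("phantom seed is mandatory")
  if (target_percent_change <= -100)
    .stop_validation("target_percent_change must be > -100")
  amp <- c(drusen_center_brightness, drusen_edge_brightness,
           pigment_darkness, vessel_darkness, vignetting, noise_sigma)
  if (any(amp < 0) || any(amp > 1))
    .stop_validation("all amplitudes must lie within the [0,1] dynamic range")
  structure(list(seed = as.integer(seed), image_size = as.integer(image_size),
                 n_drusen = as.integer(n_drusen),
                 drusen_radius_range = drusen_radius_range,
                 drusen_center_brightness = drusen_center_brightness,
                 drusen_edge_brightness = drusen_edge_brightness,
                 pigment_count = as.integer(pigment_count),
                 pigment_darkness = pigment_darkness,
                 n_vessels = as.integer(n_vessels),
                 vessel_darkness = vessel_darkness,
                 vignetting = vignetting, noise_sigma = noise_sigma,
                 target_percent_change = target_percent_change,
                 misalignment = misalignment),
            class = "phantom_params")
}

# Rasterize a union of discs: centers m x 2 (row, col), radii length m.
.rasterize_discs <- function(centers, radii, shape, inner = 0) {
  m <- matrix(FALSE, shape[1], shape[2])
  if (is.null(centers) || nrow(centers) == 0L) return(m)
  for (i in seq_len(nrow(centers))) {
    r <- radii[i]
    if (r < 0.5) next
    cr <- centers[i, 1]; cc <- centers[i, 2]
    rows <- max(1L, floor(cr - r)):min(shape[1], ceiling(cr + r))
    cols <- max(1L, floor(cc - r)):min(shape[2], ceiling(cc + r))
    d2 <- outer((rows - cr)^2, (cols - cc)^2, `+`)
    sel <- d2 <= r^2 & d2 >= (inner * r)^2
    m[rows, cols] <- m[rows, cols] | sel
  }
  m
}

# Fixed per-eye geometry: drusen/pigment centers and radii, vessel tracks,
# landmark positions. Deterministic given params$seed.
.phantom_geometry <- function(params) {
  sz <- params$image_size
  ctr <- (sz + 1) / 2
  lim <- 0.30 * min(sz)                      # lesions stay well inside the macular mask
  set.seed(.stream_seed(params$seed, "vessels"))
  vessels <- lapply(seq_len(params$n_vessels), function(v) {
    ang <- runif(1, 0, pi)
    off <- runif(1, -0.25, 0.25) * min(sz)
    amp <- runif(1, 2, 6); freq <- runif(1, 1, 2.5)
    list(ang = ang, off = off, amp = amp, freq = freq, phase = runif(1, 0, 2 * pi))
  })
  vmask <- .vessel_mask(vessels, sz)
  vidx <- which(vmask, arr.ind = TRUE)
  # drusen avoid the vessel tree: graders annotate drusen in the clear
  # macula between vessels, and overlapping strips would create spurious
  # mixed spectral classes no real eye exhibits
  clear_of_vessels <- function(p, r) {
    if (nrow(vidx) == 0L) return(TRUE)
    min((vidx[, 1] - p[1])^2 + (vidx[, 2] - p[2])^2) > (r + 3)^2
  }
  set.seed(.stream_seed(params$seed, "drusen"))
  centers <- matrix(0, 0, 2); radii <- numeric(0)
  # packing margins are relaxed in deterministic stages before giving up
  for (relax in c(1, 0.7, 0.45, 0.2)) {
    tries <- 0L
    while (nrow(centers) < params$n_drusen && tries < 800L) {
      tries <- tries + 1L
      r <- runif(1, params$drusen_radius_range[1], params$drusen_radius_range[2])
      ang <- runif(1, 0, 2 * pi); rad <- sqrt(runif(1)) * lim
      p <- ctr + rad * c(cos(ang), sin(ang))
      if (clear_of_vessels(p, (1.2 * r + 1) * relax) &&
          (nrow(centers) == 0L ||
           all(sqrt(rowSums((centers - rep(p, each = nrow(centers)))^2)) >
               1.15 * (radii + r) + 2))) {
        centers <- rbind(centers, p); radii <- c(radii, r)
      }
    }
    if (nrow(centers) == params$n_drusen) break
  }
  if (nrow(centers) < params$n_drusen)
    .stop_validation("drusen packing infeasible for these parameters")
  set.seed(.stream_seed(params$seed, "pigment"))
  pcenters <- matrix(0, 0, 2); pradii <- numeric(0)
  tries <- 0L
  while (nrow(pcenters) < params$pigment_count) {
    tries <- tries + 1L
    if (tries > 2000L) break   # pigment is optional texture; fewer is fine
    r <- runif(1, 3, 6)
    ang <- runif(1, 0, 2 * pi); rad <- sqrt(runif(1)) * lim
    p <- ctr + rad * c(cos(ang), sin(ang))
    clear <- all(sqrt(rowSums((centers - rep(p, each = nrow(centers)))^2)) >
                 1.2 * radii + r + 3) && clear_of_vessels(p, r)
    if (clear && (nrow(pcenters) == 0L ||
        all(sqrt(rowSums((pcenters - rep(p, each = nrow(pcenters)))^2)) > 2 * r))) {
      pcenters <- rbind(pcenters, p); pradii <- c(pradii, r)
    }
  }
  set.seed(.stream_seed(params$seed, "landmarks"))
  th <- seq(0, 2 * pi, length.out = 9L)[-9L] + runif(8, -0.15, 0.15)
  lrad <- 0.38 * min(sz) * runif(8, 0.85, 1.0)
  landmarks <- cbind(ctr[1] + lrad * sin(th), ctr[2] + lrad * cos(th))
  list(drusen_centers = centers, drusen_radii = radii,
       pigment_centers = pcenters, pigment_radii = pradii,
       vessels = vessels, landmarks = landmarks)
}

.vessel_mask <- function(vessels, shape, width = 1.2, transform = NULL) {
  m <- matrix(FALSE, shape[1], shape[2])
  diag_len <- sqrt(sum(shape^2))
  ctr <- (shape + 1) / 2
  for (v in vessels) {
    t <- seq(-0.6, 0.6, length.out = 4L * ceiling(diag_len))
    u <- c(cos(v$ang), sin(v$ang))          # along-track unit vector
    nrm <- c(-u[2], u[1])                   # normal
    wob <- v$amp * sin(v$freq * pi * t * 2 + v$phase)
    pr <- ctr[1] + t * diag_len * u[1] + (v$off + wob) * nrm[1]
    pc <- ctr[2] + t * diag_len * u[2] + (v$off + wob) * nrm[2]
    for (dw in seq(-width, width, by = 0.5)) {
      ri <- pr + dw * nrm[1]; ci <- pc + dw * nrm[2]
      if (!is.null(transform)) {
        p <- .transform_points(transform, cbind(ri, ci))
        ri <- p[, 1]; ci <- p[, 2]
      }
      ri <- round(ri); ci <- round(ci)
      ok <- ri >= 1 & ri <= shape[1] & ci >= 1 & ci <= shape[2]
      m[cbind(ri[ok], ci[ok])] <- TRUE
    }
  }
  m
}

.random_misalignment <- function(params, stream) {
  set.seed(.stream_seed(params$seed, stream))
  ma <- params$misalignment
  th <- runif(1, -ma$rotation_deg, ma$rotation_deg) * pi / 180
  s <- 1 + runif(1, -ma$scale_dev, ma$scale_dev)
  tr <- runif(2, -ma$translation_px, ma$translation_px)
  ctr <- (params$image_size + 1) / 2
  A <- s * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  b <- ctr - A %*% ctr + tr
  structure(list(model = "affine", parameters = cbind(A, b), residual_rmse = 0),
            class = "spatial_transform")
}

# Render the scene for one channel, with the lesion geometry mapped
# through an optional misalignment (a similarity transform, so planted
# discs stay discs and no image-space resampling is needed: raw channels
# carry sharp lesion boundaries exactly as a sensor would record them).
.render_channel <- function(params, geo, ch, radii, transform = NULL) {
  sz <- params$image_size
  dcen <- geo$drusen_centers; drad <- radii
  pcen <- geo$pigment_centers; prad <- geo$pigment_radii
  vshift <- NULL
  if (!is.null(transform)) {
    s <- sqrt(abs(det(transform$parameters[, 1:2])))
    dcen <- .transform_points(transform, dcen); drad <- radii * s
    if (nrow(pcen)) pcen <- .transform_points(transform, pcen)
    prad <- prad * s
    vshift <- transform
  }
  dmask <- .rasterize_discs(dcen, drad, sz)
  core  <- .rasterize_discs(dcen, 0.55 * drad, sz)
  edge  <- dmask & !core
  pmask <- .rasterize_discs(pcen, prad, sz)
  vmask <- .vessel_mask(geo$vessels, sz, transform = vshift)
  ctr <- (sz + 1) / 2
  dmax2 <- sum(((sz - 1) / 2)^2)
  vig <- outer(seq_len(sz[1]), seq_len(sz[2]),
               function(i, j) 1 - params$vignetting *
                 ((i - ctr[1])^2 + (j - ctr[2])^2) / dmax2)
  img <- 0.55 * vig
  img[vmask] <- img[vmask] - params$vessel_darkness
  img[core] <- img[core] + params$drusen_center_brightness[[ch]]
  img[edge] <- img[edge] + params$drusen_edge_brightness[[ch]]
  img[pmask & !dmask] <- img[pmask & !dmask] - params$pigment_darkness[[ch]]
  .clip01(img)
}

#' Generate one phantom visit
#'
#' Renders the three en face channels for one visit of one eye, both on
#' the common reference grid (`ref_channels`, noise added, no
#' misalignment) and as raw acquisitions (`channels`, warped into each
#' channel's own jittered frame before noise), together with the paired
#' landmarks needed to register them back and the visit's ground truth.
#'
#' @param params a [phantom_params()].
#' @param visit visit index (1 or 2); selects the per-visit noise and
#'   misalignment streams.
#' @param radius_scale multiplier applied to the planted drusen radii
#'   (used by [phantom_pair()] to impose an area change).
#' @return list with `channels`, `ref_channels` (each faf/ir/green
#'   matrices), `cfp` (reference composite), `landmarks` (per-channel
#'   [landmark_set()]s), `annotation` (expert-style drusen mask:
#'   ground truth dilated by a 3-px disc), and `truth` (`drusen_mask`,
#'   `pigment_mask`, `vessel_mask`, `drusen_area`).
#' @export
phantom_visit <- function(params, visit = 1L, radius_scale = 1) {
  stopifnot(inherits(params, "phantom_params"))
  geo <- .phantom_geometry(params)
  sz <- params$image_size
  radii <- geo$drusen_radii * radius_scale
  dmask <- .rasterize_discs(geo$drusen_centers, radii, sz)
  pmask <- .rasterize_discs(geo$pigment_centers, geo$pigment_radii, sz)
  vmask <- .vessel_mask(geo$vessels, sz)
  chans <- c("faf", "ir", "green")
  noise <- function(stream) {
    set.seed(.stream_seed(params$seed, stream))
    matrix(rnorm(prod(sz), 0, params$noise_sigma), sz[1], sz[2])
  }
  ref_channels <- lapply(setNames(chans, chans), function(ch)
    .clip01(.render_channel(params, geo, ch, radii) +
              noise(paste0("noise-ref-", ch, "-v", visit))))
  raw <- list(); lms <- list()
  for (ch in chans) {
    Tch <- .random_misalignment(params, paste0("jitter-", ch, "-v", visit))
    img <- .render_channel(params, geo, ch, radii, transform = Tch)
    raw[[ch]] <- .clip01(img + noise(paste0("noise-raw-", ch, "-v", visit)))
    lms[[ch]] <- landmark_set(moving = .transform_points(Tch, geo$landmarks),
                              fixed = geo$landmarks)
  }
  ideal_ref <- lapply(setNames(chans, chans), function(ch)
    .render_channel(params, geo, ch, radii))
  annotation <- as.matrix(EBImage::dilate(dmask, EBImage::makeBrush(3, "disc"))) > 0
  list(channels = raw, ref_channels = ref_channels,
       cfp = .clip01((ideal_ref$faf + ideal_ref$ir + ideal_ref$green) / 3),
       landmarks = lms, annotation = annotation,
       truth = list(drusen_mask = dmask, pigment_mask = pmask,
                    vessel_mask = vmask, drusen_area = sum(dmask)),
       visit = visit, radius_scale = radius_scale)
}

# Bisection on the drusen radius scale so the rasterized visit-2 area hits
# the target ratio within 1%.
.solve_radius_scale <- function(params, target_ratio) {
  geo <- .phantom_geometry(params)
  sz <- params$image_size
  a1 <- sum(.rasterize_discs(geo$drusen_centers, geo$drusen_radii, sz))
  if (a1 == 0L) .stop_validation("no drusen planted; cannot impose area change")
  area_at <- function(s) sum(.rasterize_discs(geo$drusen_centers,
                                              s * geo$drusen_radii, sz))
  lo <- 0.05; hi <- 3
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (area_at(mid) / a1 < target_ratio) lo <- mid else hi <- mid
  }
  s <- (lo + hi) / 2
  if (abs(area_at(s) / a1 - target_ratio) > 0.01 * target_ratio)
    .stop_validation("target percent change unreachable for these lesions")
  s
}

#' Generate a paired-visit phantom with a planted area change
#'
#' Visit 2 re-renders the same lesions with all drusen radii scaled
#' uniformly so that the planted-mask area ratio matches
#' `params$target_percent_change` within 1% (a 0% target reuses the
#' visit-1 geometry exactly).
#'
#' @param params a [phantom_params()].
#' @return list with `visits` (two [phantom_visit()] results), and
#'   `truth`: `area1`, `area2`, `true_percent_change`, `target`.
#' @export
phantom_pair <- function(params) {
  stopifnot(inherits(params, "phantom_params"))
  target_ratio <- 1 + params$target_percent_change / 100
  s <- if (params$target_percent_change == 0) 1 else
    .solve_radius_scale(params, target_ratio)
  v1 <- phantom_visit(params, 1L, 1)
  v2 <- phantom_visit(params, 2L, s)
  a1 <- v1$truth$drusen_area; a2 <- v2$truth$drusen_area
  list(visits = list(v1, v2),
       truth = list(area1 = a1, area2 = a2,
                    true_percent_change = 100 * (a2 / a1 - 1),
                    target = params$target_percent_change))
}

#' Generate a phantom cohort with expert-style labels
#'
#' Draws one paired-visit phantom per eye with seeded per-eye parameters.
#' Progression eyes receive planted changes of +10 to +33%, regression
#' eyes -30 to -10%, stable eyes -3 to +3% (comfortably inside the +/-5%
#' grading band). The default 11/11/11 design mirrors a balanced
#' three-group longitudinal study.
#'
#' @param n_progression,n_stable,n_regression eyes per label (default 11
#'   each).
#' @param seed cohort seed.
#' @param base_params optional [phantom_params()] template whose
#'   non-seed, non-target fields are reused for every eye.
#' @return list of class `phantom_cohort`: `eyes` (each with `pair`,
#'   `label`, `params`) and `manifest` (data.frame `eye_id,label,
#'   true_pct_change,target_pct_change,area1_px,area2_px`).
#' @export
phantom_cohort <- function(n_progression = 11L, n_stable = 11L,
                           n_regression = 11L, seed = 1L,
                           base_params = NULL) {
  if (any(c(n_progression, n_stable, n_regression) < 0))
    .stop_validation("cohort counts must be >= 0")
  labels <- rep(c("progression", "stable", "regression"),
                c(n_progression, n_stable, n_regression))
  eyes <- vector("list", length(labels))
  rows <- vector("list", length(labels))
  for (i in seq_along(labels)) {
    eye_seed <- .stream_seed(seed, paste0("eye-", i))
    set.seed(.stream_seed(seed, paste0("target-", i)))
    target <- switch(labels[i],
                     progression = runif(1, 10, 33),
                     regression  = runif(1, -30, -10),
                     stable      = runif(1, -3, 3))
    set.seed(.stream_seed(seed, paste0("shape-", i)))
    nd <- sample(2:3, 1)
    p <- if (is.null(base_params))
      phantom_params(seed = eye_seed, n_drusen = nd,
                     target_percent_change = target)
    else {
      q <- base_params
      q$seed <- eye_seed; q$n_drusen <- nd; q$target_percent_change <- target
      q
    }
    pair <- phantom_pair(p)
    eyes[[i]] <- list(pair = pair, label = labels[i], params = p)
    rows[[i]] <- data.frame(eye_id = sprintf("eye%02d", i), label = labels[i],
                            true_pct_change = pair$truth$true_percent_change,
                            target_pct_change = target,
                            area1_px = pair$truth$area1,
                            area2_px = pair$truth$area2)
  }
  structure(list(eyes = eyes, manifest = do.call(rbind, rows), seed = seed),
            class = "phantom_cohort")
}

#' @export
print.phantom_cohort <- function(x, ...) {
  cat("Phantom cohort:", nrow(x$manifest), "eyes (",
      paste(table(x$manifest$label)[unique(x$manifest$label)], collapse = "/"),
      ")\n")
  invisible(x)
}
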