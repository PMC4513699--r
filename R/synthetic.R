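# Fraction of each segment (top end) held at the plateau intensity; the
# lower part ramps up smoothly from the previous plateau.
RAMP_FRAC <- 0.45

# Nominal fraction of epithelium covered by dark objects under default
# nucleus/glycogen settings; enters the noise-selection calibration only.
NOMINAL_DARK_COVER <- 0.20

#' Phantom specification
#'
#' Parameters of one synthetic epithelium image: an epithelial band between
#' a wavy basement-membrane curve and a surface curve, cytoplasmic intensity
#' rising basal to superficial in three segment plateaus, dark non-
#' fluorescent objects (nuclei and glycogen patches), multiplicative
#' intensity noise, and a global scale factor emulating staining/exposure
#' differences between institutions.
#'
#' The bright (cytoplasmic) intensity at fractional epithelial height `h` is
#' `scale_c * basal_B * (1 + slope_s * (seg(h) - 1))` at the segment
#' plateaus, with a smooth cosine ramp over the basal 45% of each segment,
#' so that each segment's top-decile filtered mean recovers the plateau.
#' `basal_B` is in gray-value units; `slope_s` is the dimensionless
#' normalized slope the phantom encodes (per segment step).
#'
#' @param nrow,ncol image size in pixels.
#' @param basal_B basal plateau intensity, gray-value units, `> 0`.
#' @param slope_s true normalized slope, `>= 0`.
#' @param scale_c global intensity scale factor, `> 0`.
#' @param thickness nominal epithelial thickness in pixels (`>= 30`).
#' @param wave_amp,wave_len amplitude and wavelength (px) of the basement
#'   and surface undulation.
#' @param nucleus_density nuclei per px^2 of epithelium.
#' @param nucleus_radius length-2 range of nucleus radii (px).
#' @param nucleus_intensity intensity factor of nuclei (~ 0: devoid of
#'   fluorescence).
#' @param glycogen_density glycogen patches per px^2 of epithelium.
#' @param glycogen_radius length-2 range of patch semi-major axes (px).
#' @param noise_sd multiplicative noise sd as a fraction of local intensity.
#' @param background_frac stromal background intensity as a fraction of the
#'   basal plateau.
#' @param seed integer seed; one seed fully determines the phantom.
#' @param image_id identifier used in annotations; default derived from the
#'   seed.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(nrow = 440L, ncol = 420L,
                         basal_B = 8405.4, slope_s = 0.37, scale_c = 1,
                         thickness = 300, wave_amp = 8, wave_len = 240,
                         nucleus_density = 0.0039,
                         nucleus_radius = c(2.5, 5),
                         nucleus_intensity = 0,
                         glycogen_density = 1e-4,
                         glycogen_radius = c(6, 14),
                         noise_sd = 0.05,
                         background_frac = 0.12,
                         seed = 1L,
                         image_id = sprintf("phantom_seed%d", seed)) {
  if (basal_B <= 0) stop("`basal_B` must be > 0")
  if (slope_s < 0) stop("`slope_s` must be >= 0")
  if (scale_c <= 0) stop("`scale_c` must be > 0")
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  if (thickness < 30) stop("epithelium thickness must be >= 30 px")
  if (1.05 * thickness + 2 * wave_amp + 45 > nrow)
    stop("image too small for the requested thickness and undulation")
  structure(as.list(environment()), class = "phantom_spec")
}

# generators own the RNG stream: one integer seed determines the output
local_seed <- function(seed) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single integer")
  set.seed(as.integer(seed))
}

# mean of the upper tail of a standard normal above its (1-f) quantile
gaussian_tail_mean <- function(f) {
  if (f >= 1) return(0)
  stats::dnorm(stats::qnorm(1 - f)) / f
}

# Selection-bias calibration: averaging the top decile of noisy plateau
# samples inflates the mean by noise_sd * gaussian_tail_mean(f), where f is
# the fraction of eligible (plateau, artifact-free) samples that the top
# decile selects. The generated field is divided by this factor so the
# measured filtered means recover the nominal plateaus.
noise_selection_kappa <- function(noise_sd,
                                  dwell = 1 - RAMP_FRAC,
                                  dark_cover = NOMINAL_DARK_COVER) {
  f <- min(1, 0.11 / (dwell * (1 - dark_cover)))
  1 + noise_sd * gaussian_tail_mean(f)
}

# Plateau-and-ramp height profile: g(h) for fractional height h in [0, 1].
# Segment k plateau is 1 + s*(k-1); the basal RAMP_FRAC of each segment
# rises smoothly (cosine) from the previous plateau (0.75 of the basal
# plateau below segment 1).
height_profile <- function(h, s) {
  seg <- pmin(floor(h * 3) + 1, 3)
  u <- h * 3 - (seg - 1)
  plat <- 1 + s * (seg - 1)
  # every ramp spans one segment step (the sub-basal level sits s below the
  # basal plateau), so the top-decile selection pool has the same shape in
  # all three segments and its noise bias cancels between segments
  prev <- 1 + s * (seg - 2)
  w <- ifelse(u >= RAMP_FRAC, 1, (1 - cos(pi * u / RAMP_FRAC)) / 2)
  prev + (plat - prev) * w
}

#' Generate one epithelium phantom
#'
#' Renders the image described by a [phantom_spec] and places straight
#' basal-to-surface annotation lines on it. Lines are vertical at integer
#' columns with endpoints snapped to integer rows (the profile sampler then
#' reads exact pixel values), chosen so that every segment of every line
#' keeps at least 13% of its samples artifact-free at the segment plateau —
#' the top-decile filter therefore always has plateau pixels to find.
#' Deterministic for a fixed seed.
#'
#' @param spec a [phantom_spec].
#' @param n_lines number of annotation lines to place (default 24, `>= 20`).
#' @return list with `image` (a [gray_image]), `annotations` (list of
#'   [line_annotation]), and `truth` (list: `image_id`, `true_s`, `true_B`,
#'   `scale_c`, `seed`, `plateaus`).
#' @export
generate_phantom <- function(spec, n_lines = 24L) {
  stopifnot(inherits(spec, "phantom_spec"))
  local_seed(spec$seed)
  nr <- spec$nrow; nc <- spec$ncol
  cols0 <- 0:(nc - 1)

  # geometry: basement below, surface above (lower row index)
  phase_b <- stats::runif(1, 0, 2 * pi)
  phase_t <- stats::runif(1, 0, 2 * pi)
  basement <- (nr - 1 - 30) + spec$wave_amp * sin(2 * pi * cols0 / spec$wave_len + phase_b)
  thick <- spec$thickness * (1 + 0.04 * sin(2 * pi * cols0 / (spec$wave_len * 1.7) + phase_t))
  surface <- basement - thick
  if (any(thick < 30)) stop("epithelium thickness fell below 30 px")
  if (any(surface < 1) || any(basement > nr - 2))
    stop("epithelial band does not fit inside the image")

  rows0 <- 0:(nr - 1)
  bas_m <- matrix(basement, nr, nc, byrow = TRUE)
  thk_m <- matrix(thick, nr, nc, byrow = TRUE)
  h <- (bas_m - rows0) / thk_m       # fractional height, recycles by column
  in_band <- h >= 0 & h <= 1

  base_int <- spec$scale_c * spec$basal_B /
    noise_selection_kappa(spec$noise_sd)
  g <- height_profile(pmin(pmax(h, 0), 1), spec$slope_s)
  field <- matrix(spec$background_frac * base_int, nr, nc)
  field[h > 1] <- 0.02 * base_int    # above the surface: near-empty
  field[in_band] <- base_int * g[in_band]

  # dark objects: nuclei (disks) and glycogen patches (ellipses), hard-dark
  band_area <- sum(in_band)
  mask <- matrix(FALSE, nr, nc)
  stamp <- function(cy, cx, ry, rx) {
    r0 <- max(0, floor(cy - ry)); r1 <- min(nr - 1, ceiling(cy + ry))
    c0 <- max(0, floor(cx - rx)); c1 <- min(nc - 1, ceiling(cx + rx))
    rr <- r0:r1; cc <- c0:c1
    sub <- outer((rr - cy) / ry, (cc - cx) / rx,
                 function(a, b) a^2 + b^2 <= 1)
    mask[rr + 1, cc + 1] <<- mask[rr + 1, cc + 1] | sub
  }
  n_nuc <- round(spec$nucleus_density * band_area)
  if (n_nuc > 0) {
    cx <- stats::runif(n_nuc, 0, nc - 1)
    hh <- stats::runif(n_nuc, 0.03, 0.97)
    rad <- stats::runif(n_nuc, spec$nucleus_radius[1], spec$nucleus_radius[2])
    cy <- basement[floor(cx) + 1] - hh * thick[floor(cx) + 1]
    for (i in seq_len(n_nuc)) stamp(cy[i], cx[i], rad[i], rad[i])
  }
  n_gly <- round(spec$glycogen_density * band_area)
  if (n_gly > 0) {
    cx <- stats::runif(n_gly, 0, nc - 1)
    hh <- stats::runif(n_gly, 0.05, 0.95)
    ra <- stats::runif(n_gly, spec$glycogen_radius[1], spec$glycogen_radius[2])
    rb <- ra * stats::runif(n_gly, 0.5, 1)
    cy <- basement[floor(cx) + 1] - hh * thick[floor(cx) + 1]
    for (i in seq_len(n_gly)) stamp(cy[i], cx[i], rb[i], ra[i])
  }
  mask <- mask & in_band
  field[mask] <- spec$nucleus_intensity * field[mask]

  if (spec$noise_sd > 0) {
    noisy <- pmax(0, field * (1 + stats::rnorm(length(field), 0, spec$noise_sd)))
    field <- matrix(noisy, nr, nc)
  }

  # annotation lines: vertical, integer-snapped, dark-cover constrained
  dwell <- in_band & (h * 3 - (pmin(floor(h * 3) + 1, 3) - 1)) >= RAMP_FRAC
  margin <- 12
  candidates <- seq(margin, nc - 1 - margin)
  ok <- vapply(candidates, function(c0) {
    rb <- floor(basement[c0 + 1]); rs <- ceiling(surface[c0 + 1])
    if (rb > nr - 2 || rs < 1) return(FALSE)
    rows <- rb:rs                      # basal -> surface
    artifact <- mask[rows + 1, c0 + 1]
    in_dwell <- dwell[rows + 1, c0 + 1]
    lens <- segment_lengths(length(rows))
    ends <- cumsum(lens); starts <- c(1, ends[-3] + 1)
    for (k in 1:3) {
      idx <- starts[k]:ends[k]
      if (mean(artifact[idx]) >= 0.45) return(FALSE)
      if (sum(in_dwell[idx] & !artifact[idx]) < 0.13 * lens[k] + 2)
        return(FALSE)
    }
    TRUE
  }, TRUE)
  good <- candidates[ok]
  if (length(good) < max(20L, n_lines))
    stop("only ", length(good), " columns satisfy the artifact-cover ",
         "constraints; lower the dark-object density")
  pick <- good[unique(round(seq(1, length(good), length.out = n_lines)))]
  anns <- lapply(pick, function(c0)
    line_annotation(spec$image_id,
                    start = c(floor(basement[c0 + 1]), c0),
                    end = c(ceiling(surface[c0 + 1]), c0)))

  img <- gray_image(field, bit_depth = 32L,
                    metadata = list(phantom = TRUE, seed = spec$seed))
  truth <- list(image_id = spec$image_id, true_s = spec$slope_s,
                true_B = spec$basal_B, scale_c = spec$scale_c,
                seed = spec$seed,
                plateaus = spec$scale_c * spec$basal_B *
                  (1 + spec$slope_s * (0:2)))
  list(image = img, annotations = anns, truth = truth)
}

#' Built-in phantom presets
#'
#' Six presets encode the derivation-set (SIUH) and validation-set (Cornell)
#' class signatures: normalized slopes 0.37 / 0.19 / 0.02 (SIUH Normal,
#' CIN I, CIN III) and 0.41 / 0.22 / 0.10 (Cornell). Basal plateaus for the
#' SIUH presets are calibrated from the printed raw-to-normalized slope
#' ratios (8405.4, 6021.1, 7250.0 gray values); the Cornell presets reuse
#' them with a different global scale factor, emulating a second
#' institution's staining and exposure.
#'
#' @param name one of `"normal_siuh"`, `"cin1_siuh"`, `"cin3_siuh"`,
#'   `"normal_cornell"`, `"cin1_cornell"`, `"cin3_cornell"`.
#' @return an object of class `phantom_preset`: list with `name`, `group`,
#'   `cohort`, `basal_B`, `slope_s`, `scale_c`, `n_default`.
#' @export
phantom_preset <- function(name) {
  tab <- list(
    normal_siuh    = list(group = "Normal",  cohort = "SIUH",
                          basal_B = 8405.4, slope_s = 0.37, scale_c = 1,
                          n_default = 13L),
    cin1_siuh      = list(group = "CIN_I",   cohort = "SIUH",
                          basal_B = 6021.1, slope_s = 0.19, scale_c = 1,
                          n_default = 18L),
    cin3_siuh      = list(group = "CIN_III", cohort = "SIUH",
                          basal_B = 7250.0, slope_s = 0.02, scale_c = 1,
                          n_default = 12L),
    normal_cornell = list(group = "Normal",  cohort = "Cornell",
                          basal_B = 8405.4, slope_s = 0.41, scale_c = 0.55,
                          n_default = 34L),
    cin1_cornell   = list(group = "CIN_I",   cohort = "Cornell",
                          basal_B = 6021.1, slope_s = 0.22, scale_c = 0.55,
                          n_default = 16L),
    cin3_cornell   = list(group = "CIN_III", cohort = "Cornell",
                          basal_B = 7250.0, slope_s = 0.10, scale_c = 0.55,
                          n_default = 18L))
  if (!name %in% names(tab))
    stop("unknown preset '", name, "'; available: ",
         paste(names(tab), collapse = ", "))
  structure(c(list(name = name), tab[[name]]), class = "phantom_preset")
}

#' Preset names
#' @return character vector of the built-in preset names.
#' @export
phantom_presets <- function() {
  c("normal_siuh", "cin1_siuh", "cin3_siuh",
    "normal_cornell", "cin1_cornell", "cin3_cornell")
}

#' Generate a cohort of phantoms
#'
#' Generates `n_samples` phantom images from a preset with per-sample
#' variation: basal plateau jittered by +/-10% (uniform), true normalized
#' slope jittered multiplicatively (sd 8% of its value, keeping it
#' non-negative), and per-sample geometry (thickness, undulation). Sample i
#' uses seed `base_seed + i`; the jitters are drawn under `base_seed`
#' itself, so one integer reproduces the whole cohort.
#'
#' When `out_dir` is given, writes `<image_id>.tif` (32-bit float TIFF) per
#' sample plus `annotations.json`, `manifest.csv`
#' (`image_id,sample_id,group,cohort`) and `truth.csv`
#' (`sample_id,true_s,true_B,scale_c,seed`).
#'
#' @param preset a preset name or [phantom_preset].
#' @param n_samples number of samples; default the preset's cohort size.
#' @param base_seed integer base seed.
#' @param out_dir output directory (created if missing), or `NULL` to keep
#'   everything in memory.
#' @param n_lines annotation lines per image (default 24).
#' @param spec_overrides named list of [phantom_spec] arguments overriding
#'   the preset defaults (e.g. smaller geometry for quick runs).
#' @return (invisibly when writing) list with `phantoms` (list of
#'   [generate_phantom] results), `manifest` and `truth` data frames, and
#'   `dir`.
#' @export
generate_cohort <- function(preset, n_samples = NULL, base_seed = 1L,
                            out_dir = NULL, n_lines = 24L,
                            spec_overrides = list()) {
  if (is.character(preset)) preset <- phantom_preset(preset)
  stopifnot(inherits(preset, "phantom_preset"))
  if (is.null(n_samples)) n_samples <- preset$n_default
  if (n_samples < 1) stop("`n_samples` must be >= 1")
  local_seed(base_seed)
  B_i <- preset$basal_B * stats::runif(n_samples, 0.9, 1.1)
  s_i <- pmax(0, preset$slope_s * (1 + stats::rnorm(n_samples, 0, 0.08)))
  thick_i <- stats::runif(n_samples, 270, 330)
  amp_i <- stats::runif(n_samples, 4, 10)
  wl_i <- stats::runif(n_samples, 180, 300)

  phantoms <- vector("list", n_samples)
  manifest <- truth <- NULL
  for (i in seq_len(n_samples)) {
    sid <- sprintf("%s_s%02d", preset$name, i)
    args <- list(basal_B = B_i[i], slope_s = s_i[i],
                 scale_c = preset$scale_c, thickness = thick_i[i],
                 wave_amp = amp_i[i], wave_len = wl_i[i],
                 seed = base_seed + i, image_id = sid)
    args[names(spec_overrides)] <- spec_overrides
    ph <- generate_phantom(do.call(phantom_spec, args), n_lines = n_lines)
    phantoms[[i]] <- ph
    manifest <- rbind(manifest, data.frame(
      image_id = sid, sample_id = sid, group = preset$group,
      cohort = preset$cohort, stringsAsFactors = FALSE))
    truth <- rbind(truth, data.frame(
      sample_id = sid, true_s = s_i[i], true_B = B_i[i],
      scale_c = preset$scale_c, seed = base_seed + i,
      stringsAsFactors = FALSE))
  }
  out <- list(phantoms = phantoms, manifest = manifest, truth = truth,
              dir = out_dir)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    for (i in seq_len(n_samples)) {
      p <- file.path(out_dir, paste0(manifest$image_id[i], ".tif"))
      if (file.exists(p)) stop("output path collision: ", p)
      write_gray_image(phantoms[[i]]$image, p)
    }
    write_annotations(unlist(lapply(phantoms, `[[`, "annotations"),
                             recursive = FALSE),
                      file.path(out_dir, "annotations.json"))
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
    utils::write.csv(truth, file.path(out_dir, "truth.csv"),
                     row.names = FALSE)
    return(invisible(out))
  }
  out
}
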