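# Synthetic lesion phantoms: large, mostly-empty volumes containing a few
# small, distinct, roughly spherical lesions -- the statistical regime the
# two-stage model targets (foreground fraction around 1e-3).

#' Configure the lesion-phantom generator
#'
#' Phantoms consist of a smooth textured background with a small number of
#' non-overlapping spherical lesions. Lesion counts are Poisson distributed
#' (optionally truncated), diameters lognormal in mm, and all geometry is
#' measured in millimetres so anisotropic voxel spacing is honoured.
#'
#' @param shape integer length-3 volume shape in voxels, each >= 16.
#' @param spacing numeric length-3 voxel spacing in mm.
#' @param lesion_count_mean expected number of lesions per volume (Poisson).
#' @param lesion_count_min,lesion_count_max truncation bounds for the lesion
#'   count (rejection sampling); defaults impose no truncation.
#' @param diameter_log_mean,diameter_log_sd lognormal parameters of lesion
#'   diameter in mm; the median diameter is `exp(diameter_log_mean)`.
#' @param contrast_range interval from which each lesion's additive intensity
#'   contrast is drawn uniformly.
#' @param noise_sd amplitude of the smoothed background texture (intensity
#'   units; background is centred at 0.35).
#' @param smooth_sigma Gaussian correlation length of the background in mm.
#' @param edge_sigma lesion intensity edge softness in mm (0 = hard sphere);
#'   the ground-truth mask is always hard.
#' @param seed integer seed used by [generate_dataset()].
#' @return An object of class `phantom_config`.
#' @seealso [phantom_preset()] for lung-like and brain-like parameterisations.
#' @export
phantom_config <- function(shape = c(96, 96, 96),
                           spacing = c(1, 1, 1),
                           lesion_count_mean = 2,
                           lesion_count_min = 0,
                           lesion_count_max = Inf,
                           diameter_log_mean = log(8),
                           diameter_log_sd = 0.25,
                           contrast_range = c(0.3, 0.6),
                           noise_sd = 0.05,
                           smooth_sigma = 4,
                           edge_sigma = 0.5,
                           seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 16L))
    stop("shape must be 3 integers, each >= 16")
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("spacing must be 3 positive numbers")
  if (lesion_count_mean < 0) stop("lesion_count_mean must be >= 0")
  if (diameter_log_sd < 0) stop("diameter_log_sd must be >= 0")
  if (length(contrast_range) != 2L || contrast_range[1] > contrast_range[2])
    stop("contrast_range must be an interval c(lo, hi)")
  if (lesion_count_min > lesion_count_max)
    stop("lesion_count_min must not exceed lesion_count_max")
  structure(list(shape = shape, spacing = as.numeric(spacing),
                 lesion_count_mean = lesion_count_mean,
                 lesion_count_min = lesion_count_min,
                 lesion_count_max = lesion_count_max,
                 diameter_log_mean = diameter_log_mean,
                 diameter_log_sd = diameter_log_sd,
                 contrast_range = as.numeric(contrast_range),
                 noise_sd = noise_sd, smooth_sigma = smooth_sigma,
                 edge_sigma = edge_sigma, seed = as.integer(seed)),
            class = "phantom_config")
}

#' Preset phantom configurations
#'
#' `"lung_like"` emulates thoracic CT nodule data: anisotropic spacing and a
#' 10 mm median diameter (the clinical small-nodule threshold);
#' `"brain_like"` emulates T1 MRI metastasis data: near-isotropic ~1 mm
#' spacing and a 5 mm median diameter.
#'
#' @param name `"lung_like"` or `"brain_like"`.
#' @param ... overrides passed on to [phantom_config()].
#' @return A `phantom_config`.
#' @export
phantom_preset <- function(name = c("lung_like", "brain_like"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    lung_like = list(spacing = c(0.7, 0.7, 1.25),
                     diameter_log_mean = log(10), diameter_log_sd = 0.4),
    brain_like = list(spacing = c(0.94, 0.94, 1),
                      diameter_log_mean = log(5), diameter_log_sd = 0.35))
  do.call(phantom_config, utils::modifyList(base, list(...)))
}

#' Sample lesion specifications for one phantom
#'
#' Draws a lesion count from the (truncated) Poisson distribution, lognormal
#' diameters, and uniform centres subject to full containment within the
#' volume and pairwise non-overlap (so every ground-truth object is a
#' distinct connected component). Placement uses rejection sampling with
#' bounded retries.
#'
#' @param config a [phantom_config()].
#' @param seed optional integer; if given, the RNG is seeded first.
#' @param max_retries centre draws allowed per lesion before failing.
#' @return A data.frame with columns `cx, cy, cz` (0-based voxel
#'   coordinates, real-valued), `diameter_mm` and `contrast`.
#' @export
sample_lesions <- function(config, seed = NULL, max_retries = 100L) {
  stopifnot(inherits(config, "phantom_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- rpois(1, config$lesion_count_mean)
  tries <- 0L
  while ((n < config$lesion_count_min || n > config$lesion_count_max) &&
         tries < 1000L) {
    n <- rpois(1, config$lesion_count_mean)
    tries <- tries + 1L
  }
  n <- min(max(n, config$lesion_count_min), config$lesion_count_max)
  out <- data.frame(cx = numeric(0), cy = numeric(0), cz = numeric(0),
                    diameter_mm = numeric(0), contrast = numeric(0))
  if (n == 0) return(out)
  sp <- config$spacing
  size_mm <- (config$shape - 1) * sp
  gap <- 2 * max(sp)  # keeps voxelised masks in separate components
  for (i in seq_len(n)) {
    placed <- FALSE
    for (att in seq_len(max_retries)) {
      d <- rlnorm(1, config$diameter_log_mean, config$diameter_log_sd)
      r <- d / 2
      lo <- (r + sp) / sp           # 0-based voxel coords, 1-voxel border
      hi <- (size_mm - r - sp) / sp
      if (any(hi <= lo)) next      # lesion cannot fit; redraw
      ctr <- runif(3, lo, hi)
      ok <- TRUE
      if (nrow(out) > 0) {
        for (j in seq_len(nrow(out))) {
          dmm <- sqrt(sum(((ctr - c(out$cx[j], out$cy[j], out$cz[j])) * sp)^2))
          if (dmm <= r + out$diameter_mm[j] / 2 + gap) { ok <- FALSE; break }
        }
      }
      if (ok) {
        out <- rbind(out, data.frame(
          cx = ctr[1], cy = ctr[2], cz = ctr[3], diameter_mm = d,
          contrast = runif(1, config$contrast_range[1], config$contrast_range[2])))
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("could not place lesion ", i, " without overlap after ",
           max_retries, " retries; reduce lesion_count_mean or diameters")
  }
  out
}

#' Render a phantom volume and its ground-truth mask
#'
#' The background is a Gaussian-smoothed noise field centred at intensity
#' 0.35 with amplitude `noise_sd`; each lesion adds its contrast inside a
#' sphere of radius `diameter_mm / 2` (distances measured in mm, honouring
#' anisotropic spacing), with an optional soft Gaussian intensity edge. The
#' final volume is clipped to \[0, 1\]. The mask marks a voxel 1 iff its
#' centre lies within some lesion radius; it is always hard binary.
#'
#' @param config a [phantom_config()].
#' @param lesions data.frame from [sample_lesions()].
#' @param seed optional integer seeding the background noise.
#' @return `list(volume = , mask = )` of [volume()] and [mask_volume()].
#' @export
render_phantom <- function(config, lesions, seed = NULL) {
  stopifnot(inherits(config, "phantom_config"))
  if (!is.null(seed)) set.seed(seed)
  shp <- config$shape
  sp <- config$spacing
  z <- array(rnorm(prod(shp)), shp)
  z <- cpp_gauss_smooth3(z, config$smooth_sigma / sp)
  z <- (z - mean(z)) / max(stats::sd(z), 1e-12)
  vol <- 0.35 + config$noise_sd * z
  mask <- array(0, shp)
  if (nrow(lesions) > 0) {
    for (i in seq_len(nrow(lesions))) {
      ctr <- c(lesions$cx[i], lesions$cy[i], lesions$cz[i])
      r <- lesions$diameter_mm[i] / 2
      reach <- r + 3 * config$edge_sigma
      i0 <- pmax(floor(ctr - reach / sp), 0)
      i1 <- pmin(ceiling(ctr + reach / sp), shp - 1)
      ix <- i0[1]:i1[1]; iy <- i0[2]:i1[2]; iz <- i0[3]:i1[3]
      dx2 <- ((ix - ctr[1]) * sp[1])^2
      dy2 <- ((iy - ctr[2]) * sp[2])^2
      dz2 <- ((iz - ctr[3]) * sp[3])^2
      dist <- sqrt(outer(outer(dx2, dy2, `+`), dz2, `+`))
      inside <- dist <= r
      add <- lesions$contrast[i] * ifelse(inside, 1,
        if (config$edge_sigma > 0)
          exp(-(dist - r)^2 / (2 * config$edge_sigma^2)) else 0)
      sl <- list(ix + 1, iy + 1, iz + 1)
      vol[sl[[1]], sl[[2]], sl[[3]]] <- vol[sl[[1]], sl[[2]], sl[[3]]] + add
      msl <- mask[sl[[1]], sl[[2]], sl[[3]]]
      msl[inside] <- 1
      mask[sl[[1]], sl[[2]], sl[[3]]] <- msl
    }
  }
  vol <- pmin(pmax(vol, 0), 1)
  list(volume = volume(vol, sp), mask = mask_volume(mask, sp, is_binary = TRUE))
}

#' Generate a phantom dataset on disk
#'
#' Writes `n` (volume, mask) NIfTI pairs plus a manifest CSV with columns
#' `case_id, volume_path, mask_path, n_lesions, diameters_mm` (paths relative
#' to the manifest, diameters semicolon-separated). Case `i` is seeded with
#' `seed + i`, so regeneration from the same configuration is deterministic.
#'
#' @param config a [phantom_config()].
#' @param n number of cases.
#' @param out_dir output directory (created if needed).
#' @param seed base seed; defaults to `config$seed`.
#' @return The manifest as a data.frame (invisibly also written to
#'   `out_dir/manifest.csv`).
#' @export
generate_dataset <- function(config, n, out_dir, seed = config$seed) {
  stopifnot(inherits(config, "phantom_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    case_id <- sprintf("case_%03d", i)
    set.seed(seed + i)
    lesions <- sample_lesions(config)
    ph <- render_phantom(config, lesions)
    vp <- paste0(case_id, "_vol.nii.gz")
    mp <- paste0(case_id, "_mask.nii.gz")
    tryCatch({
      write_volume(ph$volume, file.path(out_dir, vp))
      write_volume(ph$mask, file.path(out_dir, mp))
    }, error = function(e) stop("failed writing case ", i, ": ",
                                conditionMessage(e)))
    rows[[i]] <- data.frame(
      case_id = case_id, volume_path = vp, mask_path = mp,
      n_lesions = nrow(lesions),
      diameters_mm = paste(sprintf("%.4f", lesions$diameter_mm),
                           collapse = ";"),
      stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  manifest
}

#' Read a dataset manifest
#'
#' @param path path to a `manifest.csv` written by [generate_dataset()].
#' @return data.frame with absolute `volume_path` / `mask_path` columns.
#' @export
read_manifest <- function(path) {
  m <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("case_id", "volume_path", "mask_path")
  if (!all(need %in% names(m)))
    stop("manifest lacks required columns: ",
         paste(setdiff(need, names(m)), collapse = ", "))
  base <- dirname(normalizePath(path))
  rel <- !grepl("^(/|[A-Za-z]:)", m$volume_path)
  m$volume_path[rel] <- file.path(base, m$volume_path[rel])
  rel <- !grepl("^(/|[A-Za-z]:)", m$mask_path)
  m$mask_path[rel] <- file.path(base, m$mask_path[rel])
  m
}
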