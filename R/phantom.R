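# Synthetic polar OCT pullback generator with analytic ground truth.
#
# The phantom emulates the consensus appearance of plaque tissue in
# intravascular OCT: fibrous tissue as uniform high-signal regions,
# calcified tissue as uneven low-signal regions with sharp borders, lipid
# tissue as low-signal regions with diffuse borders; plus a dark lumen, a
# thin bright lumen-interface rim, and a persistent dark guidewire shadow.

#' Describe a plaque region for the phantom
#'
#' A plaque region is an annular sector attached to the lumen contour:
#' an angular interval of A-lines (wrap-around allowed) with a fixed radial
#' thickness starting just beyond the lumen interface rim.
#'
#' @param class Tissue class: 1 fibrous, 2 calcified, 3 lipid (or the name).
#' @param a_start First A-line of the sector, 0-based.
#' @param a_span Width of the sector in A-lines.
#' @param thickness Radial thickness in pixels.
#' @return A `plaque_region` list.
#' @export
plaque_region <- function(class, a_start, a_span, thickness) {
  if (is.character(class)) class <- OCT_CLASSES[[class]]
  class <- as.integer(class)
  if (!class %in% 1:3) stop("plaque class must be 1 (fibrous), 2 (calcified) or 3 (lipid)")
  if (a_span < 1 || thickness < 1) stop("plaque region must have positive extent")
  structure(list(class = class, a_start = as.integer(a_start),
                 a_span = as.integer(a_span), thickness = as.integer(thickness)),
            class = "plaque_region")
}

#' Per-class texture parameters
#'
#' Mean intensity, variance and border sharpness for the three tissue
#' classes plus the vessel-wall background. `border_sharpness` is the
#' reciprocal border width: 1 gives a one-pixel (sharp) transition, 0.25
#' ramps the intensity in over four pixels (diffuse border). Defaults keep
#' fibrous bright and calcified/lipid equally dark, so the two low-signal
#' classes are separated only by texture unevenness and border character —
#' the cue structure the tissue consensus describes.
#'
#' @return Named list of per-class parameter lists.
#' @export
default_texture_params <- function() {
  list(
    background = list(mean = 130, variance = 100, border_sharpness = 1),
    fibrous    = list(mean = 200, variance = 36,  border_sharpness = 1),
    calcified  = list(mean = 75,  variance = 784, border_sharpness = 1),
    lipid      = list(mean = 75,  variance = 36,  border_sharpness = 0.25)
  )
}

#' Specification of a synthetic OCT pullback
#'
#' Defines the geometry (frames, A-lines, depth samples), the lumen contour
#' (base radius plus a sinusoidal wobble drifting along the pullback), the
#' guidewire shadow band (angular position, width, per-frame jitter,
#' multiplicative attenuation), the plaque sectors and per-class textures,
#' additive sensor noise, and the seed. The default scale (256 depth x 128
#' A-lines, 12 frames) is a reduced desk-scale geometry; the full clinical
#' geometry (976 x 504, 271 frames) is available by argument.
#'
#' @param n_frames,n_alines,depth_samples Pullback geometry.
#' @param lumen_base_radius,lumen_wobble_amplitude Lumen contour, pixels.
#' @param guidewire_center_angle Central A-line of the shadow band, 0-based.
#' @param guidewire_width Width of the shadow band in A-lines.
#' @param guidewire_jitter Max per-frame angular jitter of the band, A-lines.
#' @param guidewire_attenuation Multiplicative intensity factor in the band.
#' @param plaque_regions List of [plaque_region()] objects.
#' @param texture_params Per-class texture parameters, see
#'   [default_texture_params()].
#' @param noise_sd Additive Gaussian sensor noise, intensity units.
#' @param roi_depth Depth of the tissue band beyond the lumen, pixels.
#' @param rim_intensity,rim_width Bright lumen-interface rim.
#' @param lumen_mean Mean intensity inside the lumen.
#' @param seed Integer seed; identical seeds give bit-identical pullbacks.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(n_frames = 12L, n_alines = 128L,
                         depth_samples = 256L,
                         lumen_base_radius = 60, lumen_wobble_amplitude = 8,
                         guidewire_center_angle = 40L, guidewire_width = 11L,
                         guidewire_jitter = 1L, guidewire_attenuation = 0.08,
                         plaque_regions = list(
                           plaque_region("fibrous", 55L, 40L, 80L),
                           plaque_region("calcified", 5L, 25L, 60L),
                           plaque_region("lipid", 100L, 26L, 70L)),
                         texture_params = default_texture_params(),
                         noise_sd = 8, roi_depth = 100L,
                         rim_intensity = 235, rim_width = 2L,
                         lumen_mean = 3, seed = 42L) {
  spec <- structure(as.list(environment()), class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  with(spec, {
    if (n_frames < 1) stop("n_frames must be at least 1")
    if (lumen_base_radius - lumen_wobble_amplitude < rim_width + 1)
      stop("lumen radius too small for its wobble")
    tp <- texture_params
    if (!(tp$fibrous$mean > tp$calcified$mean && tp$fibrous$mean > tp$lipid$mean))
      stop("per-class means must satisfy fibrous > calcified and fibrous > lipid")
    for (rg in plaque_regions) {
      if (!inherits(rg, "plaque_region")) stop("plaque_regions must be plaque_region objects")
      if (rg$a_start < 0 || rg$a_start >= n_alines)
        stop("plaque region start must lie in [0, n_alines)")
      if (rg$a_span > n_alines) stop("plaque region wider than the frame")
    }
    # overlapping sectors of different classes are rejected: all sectors
    # attach at the lumen, so angular overlap implies spatial overlap
    cover <- integer(n_alines)
    for (rg in plaque_regions) {
      cols <- wrap_index(rg$a_start + seq_len(rg$a_span), n_alines)
      clash <- cover[cols] != 0L & cover[cols] != rg$class
      if (any(clash))
        stop(sprintf("region conflict: classes %d and %d overlap at A-line %d",
                     cover[cols][clash][1], rg$class, cols[clash][1] - 1L))
      cover[cols] <- rg$class
    }
  })
  invisible(spec)
}

# Distance (in pixels, edge pixel = 1) from each cell of an nr x nc raster
# to the nearest raster border, the geometry both texture_fill and the
# sector compositor use for border softness.
border_distance <- function(nr, nc) {
  r <- pmin(seq_len(nr), rev(seq_len(nr)))
  c <- pmin(seq_len(nc), rev(seq_len(nc)))
  outer(r, c, pmin)
}

#' Fill a region with class-conditional texture
#'
#' Produces the intensity raster of one tissue region: the class mean scaled
#' by a border ramp (`alpha = min(1, dist * border_sharpness)`) plus texture
#' noise. Fibrous fills are uniform and bright; calcified fills add a coarse
#' low-frequency "unevenness" field on top of pixel noise and keep a sharp
#' one-pixel border; lipid fills are smooth with a several-pixel diffuse
#' border ramp.
#'
#' @param class_id Tissue class, 1-3.
#' @param shape `c(rows, cols)` of the region raster.
#' @param params Parameter list for this class: `mean`, `variance`,
#'   `border_sharpness` (as in [default_texture_params()]).
#' @param noise_sd Texture noise SD; defaults to `sqrt(params$variance)`.
#' @return Numeric rows x cols matrix. Uses the current RNG stream.
#' @export
texture_fill <- function(class_id, shape, params, noise_sd = NULL) {
  class_id <- as.integer(class_id)
  if (!class_id %in% 1:3) stop("class_id must be 1, 2 or 3")
  nr <- as.integer(shape[1]); nc <- as.integer(shape[2])
  if (is.na(nr) || is.na(nc) || nr < 1 || nc < 1)
    stop("region shape must be positive")
  if (is.null(noise_sd)) noise_sd <- sqrt(params$variance)
  alpha <- matrix(pmin(1, border_distance(nr, nc) * params$border_sharpness),
                  nr, nc)
  base <- params$mean * alpha
  if (noise_sd > 0) {
    if (class_id == 2L) {
      # uneven appearance: half pixel noise, half coarse blotches
      fine <- matrix(rnorm(nr * nc, 0, noise_sd * 0.6), nr, nc)
      gr <- max(2L, nr %/% 6L); gc <- max(2L, nc %/% 6L)
      coarse <- matrix(rnorm(gr * gc, 0, noise_sd), gr, gc)
      blotch <- coarse[pmin(gr, ceiling(seq_len(nr) / nr * gr)),
                       pmin(gc, ceiling(seq_len(nc) / nc * gc)), drop = FALSE]
      base <- base + fine + blotch
    } else {
      base <- base + matrix(rnorm(nr * nc, 0, noise_sd), nr, nc)
    }
  }
  base
}

#' Generate a synthetic polar OCT pullback
#'
#' Renders every frame of the phantom together with its per-pixel label map
#' and the exact geometric ground truth: per-frame lumen contour (0-based
#' depth per A-line) and guidewire band (per-frame center A-line and
#' half-width). Each frame shows a dark lumen, a bright interface rim at the
#' true contour (so the axial intensity step peaks exactly at the contour),
#' vessel-wall background with depth decay, the plaque sectors, and a
#' multiplicative guidewire shadow from the lumen outward. Label maps mark
#' plaque classes only inside the tissue (ROI) band beyond the lumen;
#' everything else is background.
#'
#' @param spec A [phantom_spec()].
#' @return An `oct_phantom` list: `frames` (list of depth x A-line
#'   matrices), `labels` (list of integer matrices), `lumen_truth`
#'   (n_frames x n_alines matrix of 0-based depths), `guidewire_truth`
#'   (list with per-frame `center` and scalar `half_width`), and `spec`.
#' @export
generate_pullback <- function(spec) {
  validate_phantom_spec(spec)
  with_seed(spec$seed, {
    H <- spec$depth_samples; W <- spec$n_alines
    tp <- spec$texture_params
    frames <- vector("list", spec$n_frames)
    labels <- vector("list", spec$n_frames)
    lumen_truth <- matrix(0L, spec$n_frames, W)
    gw_center <- integer(spec$n_frames)
    jitters <- if (spec$guidewire_jitter > 0)
      sample(seq(-spec$guidewire_jitter, spec$guidewire_jitter),
             spec$n_frames, replace = TRUE) else integer(spec$n_frames)
    gw_hw <- spec$guidewire_width %/% 2L

    for (f in seq_len(spec$n_frames)) {
      phase <- 0.4 * (f - 1)
      a <- seq_len(W) - 1L
      contour <- as.integer(round(spec$lumen_base_radius +
        spec$lumen_wobble_amplitude * sin(2 * pi * a / W + phase)))
      lumen_truth[f, ] <- contour

      img <- matrix(spec$lumen_mean, H, W)
      lab <- matrix(0L, H, W)

      # vessel wall background with penetration decay
      depth0 <- matrix(seq_len(H) - 1L, H, W)
      cm <- matrix(contour, H, W, byrow = TRUE)
      rel <- depth0 - cm
      wall <- rel >= 0
      knee <- spec$roi_depth + 20
      decay <- ifelse(rel <= knee, 1, exp(-(rel - knee) / 25))
      img[wall] <- tp$background$mean * decay[wall]

      # plaque sectors: rectangles in (depth-beyond-rim, A-line) space
      for (rg in spec$plaque_regions) {
        cols <- wrap_index(rg$a_start + seq_len(rg$a_span), W)
        th <- min(rg$thickness, spec$roi_depth - spec$rim_width)
        fill <- texture_fill(rg$class, c(th, rg$a_span),
                             tp[[names(OCT_CLASSES)[rg$class + 1L]]])
        for (s in seq_along(cols)) {
          top <- contour[cols[s]] + spec$rim_width  # 0-based first row
          rows <- top + seq_len(th)                 # 1-based matrix rows
          keep <- rows <= H
          img[rows[keep], cols[s]] <- fill[keep, s]
          lab[rows[keep], cols[s]] <- rg$class
        }
      }

      # bright lumen-interface rim (labeled background)
      for (s in seq_len(W)) {
        rows <- contour[s] + seq_len(spec$rim_width)
        img[rows[rows <= H], s] <- spec$rim_intensity
      }

      # guidewire shadow: multiplicative attenuation from the lumen outward
      ctr <- wrap_index(spec$guidewire_center_angle + jitters[f] + 1L, W) - 1L
      gw_center[f] <- ctr
      gcols <- wrap_index(ctr + seq(-gw_hw, gw_hw) + 1L, W)
      for (s in gcols) {
        rows <- (contour[s] + 1L):H
        img[rows, s] <- img[rows, s] * spec$guidewire_attenuation
      }

      if (spec$noise_sd > 0)
        img <- img + matrix(rnorm(H * W, 0, spec$noise_sd), H, W)
      frames[[f]] <- pmax(img, 0)
      labels[[f]] <- lab
    }

    structure(list(frames = frames, labels = labels,
                   lumen_truth = lumen_truth,
                   guidewire_truth = list(center = gw_center,
                                          half_width = gw_hw),
                   spec = spec),
              class = "oct_phantom")
  })
}

#' Write a phantom pullback to disk
#'
#' Frames as 16-bit TIFF, label maps as PNG, lumen ground truth as CSV and
#' the spec as YAML.
#' @param phantom An `oct_phantom` from [generate_pullback()].
#' @param dir Output directory (created if needed).
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (f in seq_along(phantom$frames)) {
    write_polar_frame(phantom$frames[[f]],
                      file.path(dir, sprintf("frame_%03d.tiff", f)))
    write_label_map(phantom$labels[[f]],
                    file.path(dir, sprintf("labels_%03d.png", f)))
  }
  write_contour_csv(phantom$lumen_truth, file.path(dir, "lumen_truth.csv"))
  sp <- phantom$spec
  sp$plaque_regions <- lapply(sp$plaque_regions, unclass)
  yaml::write_yaml(unclass(sp), file.path(dir, "phantom_spec.yaml"))
  invisible(dir)
}
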