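#' Tissue class codes
#'
#' Integer label codes used throughout the package: background 0, tumor 1,
#' adipose 2, benign 3 (matching the overlay palette tumor = red,
#' adipose = green, benign = blue).
#'
#' @return named integer vector.
#' @export
tissue_classes <- function() {
  c(background = 0L, tumor = 1L, adipose = 2L, benign = 3L)
}

class_name <- function(code) {
  names(tissue_classes())[match(code, tissue_classes())]
}

#' Default per-class scattering parameters
#'
#' Free parameters of the phantom renderer (no quantitative per-class optics
#' are available for these tissues): mean reflectivity (arbitrary units),
#' texture contrast (unitless), attenuation coefficient mu (1/mm) and texture
#' correlation length (um). Tumor is rendered as high-contrast
#' short-correlation scattering, adipose as a honeycomb cell lattice (bright
#' septa around dark lumens), benign stroma as smooth mildly anisotropic
#' texture.
#'
#' The adipose entry additionally carries the honeycomb geometry:
#' `septa_frac` (septa width as a fraction of the cell size), `septa_gain`
#' (septa brightness relative to the cell interior) and `lumen_drop`
#' (fractional darkening of the lipid-filled lumens, which are nearly
#' signal-free in OCT).
#'
#' @return named list of per-class parameter lists.
#' @export
default_class_params <- function() {
  list(
    tumor      = list(mean = 1.0,  contrast = 0.45, mu = 1.2, scale_um = 30),
    adipose    = list(mean = 0.7,  contrast = 1.0,  mu = 0.5, scale_um = 220,
                      septa_frac = 0.08, septa_gain = 8, lumen_drop = 0.95),
    benign     = list(mean = 0.9,  contrast = 0.10, mu = 0.9, scale_um = 60),
    background = list(mean = 0.01, contrast = 0,    mu = 0,   scale_um = 0)
  )
}

#' Specification of a synthetic specimen phantom
#'
#' Describes a seeded surgical-specimen phantom: grid geometry, one of five
#' scenario templates (mirroring the representative specimen types seen
#' intraoperatively), per-class scattering parameters, speckle and noise
#' levels. A fixed spec and seed yield a bit-identical phantom.
#'
#' @param grid_shape integer `c(nx, ny, nz)` voxels; the default depth
#'   (220 voxels at 5 um) covers the clinically relevant first millimetre
#'   below the specimen surface.
#' @param lateral_voxel,axial_voxel voxel sizes in um (defaults 10 and 5).
#' @param layout_pattern one of `"uniform_tumor"`, `"adipose_only"`,
#'   `"lobule_insert"`, `"infiltrating_boundary"`, `"deep_focus"`.
#' @param class_params see [default_class_params()].
#' @param speckle_shape gamma shape of the multiplicative speckle field
#'   (mean 1); 0 disables speckle. Default 4.
#' @param noise_sd SD of the additive relative noise term. Default 0.05.
#' @param seed integer RNG seed.
#' @param surface_amp_vox amplitude (voxels) of the smooth top-surface height
#'   variation against the flat imaging window.
#' @param surface_reflect intensity (arb. units, same scale as the class
#'   mean reflectivities) of the specular window-tissue reflection placed at
#'   the surface voxel of every A-line. Index-mismatch reflection is
#'   coherent and far brighter than scattering speckle, which is what makes
#'   the top surface segmentable by peak finding; it is not
#'   speckle-modulated. 0 disables. Default 8.
#' @param thickness_um specimen thickness; default 80% of the axial extent.
#' @param tumor_fraction target tumor area fraction of the
#'   `infiltrating_boundary` template (default 0.4).
#' @param focus_depth_um depth of the `deep_focus` tumor focus below the
#'   surface (default 500 um).
#' @param focus_radius_frac,lobule_radius_frac radii of the focus/lobule
#'   regions as a fraction of `nx`.
#' @param lobule_contrast multiplier on the benign texture contrast inside
#'   the `lobule_insert` region (default 2.5); normal lobules scatter much
#'   like tumor, which is the known false-positive mode this template
#'   exercises.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(64, 64, 220), lateral_voxel = 10,
                         axial_voxel = 5,
                         layout_pattern = "infiltrating_boundary",
                         class_params = default_class_params(),
                         speckle_shape = 4, noise_sd = 0.05, seed = 1,
                         surface_amp_vox = 2, surface_reflect = 8,
                         thickness_um = NULL,
                         tumor_fraction = 0.4, focus_depth_um = 500,
                         focus_radius_frac = 0.15, lobule_radius_frac = 0.12,
                         lobule_contrast = 2.5) {
  layout_pattern <- match.arg(layout_pattern, layout_patterns())
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 8),
            lateral_voxel > 0, axial_voxel > 0,
            speckle_shape >= 0, noise_sd >= 0,
            all(vapply(class_params, function(p) p$mu, numeric(1)) >= 0))
  thickness_um <- thickness_um %||% (0.8 * grid_shape[3] * axial_voxel)
  structure(list(grid_shape = as.integer(grid_shape),
                 lateral_voxel = lateral_voxel, axial_voxel = axial_voxel,
                 layout_pattern = layout_pattern, class_params = class_params,
                 speckle_shape = speckle_shape, noise_sd = noise_sd,
                 seed = as.integer(seed),
                 surface_amp_vox = surface_amp_vox,
                 surface_reflect = surface_reflect, thickness_um = thickness_um,
                 tumor_fraction = tumor_fraction,
                 focus_depth_um = focus_depth_um,
                 focus_radius_frac = focus_radius_frac,
                 lobule_radius_frac = lobule_radius_frac,
                 lobule_contrast = lobule_contrast),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("Phantom spec: %s, %d x %d x %d voxels (%g um lateral, %g um axial), seed %d\n",
              x$layout_pattern, x$grid_shape[1], x$grid_shape[2], x$grid_shape[3],
              x$lateral_voxel, x$axial_voxel, x$seed))
  invisible(x)
}

#' Names of the five scenario templates
#' @return character vector.
#' @export
layout_patterns <- function() {
  c("uniform_tumor", "adipose_only", "lobule_insert",
    "infiltrating_boundary", "deep_focus")
}

# Smooth seeded Gaussian random field, zero mean, unit SD (after smoothing).
gaussian_field <- function(nx, ny, sigma_px, aniso = c(1, 1)) {
  g <- matrix(stats::rnorm(nx * ny), nx, ny)
  sx <- max(0.5, sigma_px * aniso[1])
  sy <- max(0.5, sigma_px * aniso[2])
  kx <- gaussian_kernel(sx); ky <- gaussian_kernel(sy)
  g <- conv_rows_padded(pad_rows(g, (length(kx) - 1L) %/% 2L), kx, nx)
  g <- t(conv_rows_padded(pad_rows(t(g), (length(ky) - 1L) %/% 2L), ky, ny))
  s <- stats::sd(as.vector(g))
  if (s > 0) g / s else g
}

#' Build a lateral tissue layout from a scenario template
#'
#' Generates the 2-D class map of one of the five specimen scenarios:
#' `uniform_tumor` (positive margins all around), `adipose_only` (benign,
#' fat-covered surface), `lobule_insert` (benign specimen containing a
#' normal lobule whose scattering mimics tumor), `infiltrating_boundary`
#' (tumor infiltrating benign stroma across an irregular boundary covering a
#' configurable area fraction) and `deep_focus` (a small tumor focus buried
#' at a configurable depth, returned as a `depth_offset_um` attribute).
#'
#' @param pattern template name, see [layout_patterns()].
#' @param shape lateral grid `c(nx, ny)`.
#' @param seed integer RNG seed.
#' @param tumor_fraction area fraction for `infiltrating_boundary`.
#' @param focus_depth_um,focus_radius_frac `deep_focus` geometry.
#' @param lobule_radius_frac `lobule_insert` geometry.
#' @return integer matrix `nx x ny` of class codes (see [tissue_classes()]),
#'   with attributes `pattern`, and template extras (`depth_offset_um`,
#'   `focus_mask`, `lobule_mask`, `tumor_fraction_target`).
#' @export
build_layout <- function(pattern, shape = c(64, 64), seed = 1,
                         tumor_fraction = 0.4, focus_depth_um = 500,
                         focus_radius_frac = 0.15, lobule_radius_frac = 0.12) {
  if (!pattern %in% layout_patterns()) {
    stop(sprintf("unknown layout pattern '%s'", pattern))
  }
  nx <- as.integer(shape[1]); ny <- as.integer(shape[2])
  cls <- tissue_classes()
  lay <- with_seed(seed, {
    m <- matrix(cls[["benign"]], nx, ny)
    switch(pattern,
      uniform_tumor = matrix(cls[["tumor"]], nx, ny),
      adipose_only = matrix(cls[["adipose"]], nx, ny),
      infiltrating_boundary = {
        amp <- 0.08 * nx
        z <- stats::rnorm(ny)
        k <- gaussian_kernel(max(1, ny / 16))
        zb <- conv_rows_padded(pad_rows(matrix(z, ny, 1), (length(k) - 1L) %/% 2L),
                               k, ny)[, 1]
        zb <- (zb - mean(zb))
        s <- stats::sd(zb); if (s > 0) zb <- zb / s
        b <- tumor_fraction * nx + amp * zb
        for (y in seq_len(ny)) {
          xt <- min(nx, max(0L, as.integer(round(b[y]))))
          if (xt >= 1) m[1:xt, y] <- cls[["tumor"]]
        }
        attr(m, "tumor_fraction_target") <- tumor_fraction
        m
      },
      lobule_insert = {
        # left third adipose, rest benign stroma with an embedded lobule
        xsplit <- as.integer(round(0.35 * nx))
        if (xsplit >= 1) m[1:xsplit, ] <- cls[["adipose"]]
        r <- lobule_radius_frac * nx
        cx <- stats::runif(1, xsplit + r + 2, nx - r - 1)
        cy <- stats::runif(1, r + 2, ny - r - 1)
        d2 <- outer((seq_len(nx) - cx)^2, (seq_len(ny) - cy)^2, `+`)
        lob <- d2 <= r^2
        attr(m, "lobule_mask") <- lob
        m
      },
      deep_focus = {
        r <- focus_radius_frac * nx
        cx <- stats::runif(1, r + 2, nx - r - 1)
        cy <- stats::runif(1, r + 2, ny - r - 1)
        d2 <- outer((seq_len(nx) - cx)^2, (seq_len(ny) - cy)^2, `+`)
        focus <- d2 <= r^2
        m[focus] <- cls[["tumor"]]
        attr(m, "focus_mask") <- focus
        attr(m, "depth_offset_um") <- focus_depth_um
        m
      })
  })
  attr(lay, "pattern") <- pattern
  lay
}

# Lateral texture fields per class, mean 1; adipose gets a 3-D honeycomb
# (returned separately) because fat cells are closed 3-D compartments: an
# A-line through a lumen crosses bright septa caps above and below it.
render_textures <- function(layout, spec, nz = NULL) {
  nx <- nrow(layout); ny <- ncol(layout)
  cp <- spec$class_params
  px <- function(um) max(1, um / spec$lateral_voxel)
  tex <- list()
  # tumor: homogeneously grainy short-correlation scattering (clipped linear
  # field keeps ROI-to-ROI mean intensity stable, unlike a lognormal field)
  g_t <- gaussian_field(nx, ny, px(cp$tumor$scale_um) / 2)
  t_t <- pmax(0.15, 1 + cp$tumor$contrast * g_t)
  tex$tumor <- t_t / mean(t_t)
  g_b <- gaussian_field(nx, ny, px(cp$benign$scale_um) / 2, aniso = c(1, 2.2))
  tex$benign <- pmax(0.1, 1 + cp$benign$contrast * g_b)
  if (any(layout == tissue_classes()[["adipose"]])) {
    a <- cp$adipose
    if (is.null(nz)) {
      hc <- honeycomb_texture3d(nx, ny, 1L, spec$lateral_voxel, spec$lateral_voxel,
                                a$scale_um, a$contrast,
                                a$septa_frac %||% 0.1, a$septa_gain %||% 6,
                                a$lumen_drop %||% 0.95)
      tex$adipose <- matrix(hc$texture[1, , ], nx, ny)
    } else {
      hc <- honeycomb_texture3d(nx, ny, nz, spec$lateral_voxel, spec$axial_voxel,
                                a$scale_um, a$contrast,
                                a$septa_frac %||% 0.1, a$septa_gain %||% 6,
                                a$lumen_drop %||% 0.95)
      tex$adipose3d <- hc$texture
      tex$adipose <- matrix(hc$texture[max(1L, nz %/% 2L), , ], nx, ny)
    }
    tex$adipose_centers <- hc$centers
  }
  tex$background <- matrix(1, nx, ny)
  lob <- attr(layout, "lobule_mask")
  if (!is.null(lob)) {
    g_l <- gaussian_field(nx, ny, px(cp$tumor$scale_um) / 2)
    t_l <- exp(spec$lobule_contrast * cp$benign$contrast * g_l)
    tex$lobule <- t_l / mean(t_l)
  }
  tex
}

# 3-D jittered-lattice honeycomb: dark lumens, bright septa on the Voronoi
# boundaries between cell centers; distances in physical um so the cells are
# round despite anisotropic voxels. nz = 1 gives a 2-D (equatorial) cut.
honeycomb_texture3d <- function(nx, ny, nz, lat_um, ax_um, cell_um, contrast,
                                septa_frac = 0.1, septa_gain = 6,
                                lumen_drop = 0.95) {
  cell_um <- max(4 * lat_um, cell_um)
  cxs <- seq(cell_um / 2, nx * lat_um, by = cell_um)
  cys <- seq(cell_um / 2, ny * lat_um, by = cell_um)
  czs <- if (nz == 1L) 0 else seq(cell_um / 2, max(nz * ax_um, cell_um * 0.51),
                                  by = cell_um)
  centers <- expand.grid(x_um = cxs, y_um = cys, z_um = czs)
  # stagger alternate depth layers by half a cell (close packing): the
  # boundaries between vertical neighbours become inclined facets, so every
  # en-face cut shows a honeycomb rather than broad horizontal septa sheets
  if (length(czs) > 1) {
    layer <- match(centers$z_um, czs)
    odd <- layer %% 2L == 1L
    centers$x_um[odd] <- centers$x_um[odd] + cell_um / 2
    centers$y_um[odd] <- centers$y_um[odd] + cell_um / 2
  }
  # modest jitter keeps cells irregular without letting neighbouring centers
  # squeeze a Voronoi boundary into a lumen interior
  jit <- function(n) stats::runif(n, -0.15, 0.15) * cell_um
  centers$x_um <- centers$x_um + jit(nrow(centers))
  centers$y_um <- centers$y_um + jit(nrow(centers))
  if (nz > 1L) centers$z_um <- centers$z_um + jit(nrow(centers))
  xs <- array(rep(seq_len(nx) * lat_um, each = nz, times = ny), dim = c(nz, nx, ny))
  ys <- array(rep(seq_len(ny) * lat_um, each = nz * nx), dim = c(nz, nx, ny))
  zs <- array(rep(seq_len(nz) * ax_um, times = nx * ny), dim = c(nz, nx, ny))
  if (nz == 1L) zs[] <- 0
  d1 <- array(Inf, dim = c(nz, nx, ny)); d2 <- d1
  for (i in seq_len(nrow(centers))) {
    d <- sqrt((xs - centers$x_um[i])^2 + (ys - centers$y_um[i])^2 +
                (zs - centers$z_um[i])^2)
    closer <- d < d1
    d2[closer] <- d1[closer]
    d1[closer] <- d[closer]
    mid <- !closer & d < d2
    d2[mid] <- d[mid]
  }
  septa <- exp(-((d2 - d1) / (septa_frac * cell_um))^2)
  lumen_level <- 1 - lumen_drop * contrast
  septa_level <- 1 + septa_gain * contrast
  tx <- lumen_level + (septa_level - lumen_level) * septa
  centers$x <- centers$x_um / lat_um
  centers$y <- centers$y_um / lat_um
  centers$z <- if (nz == 1L) rep(1, nrow(centers)) else centers$z_um / ax_um
  list(texture = tx / mean(tx), centers = centers)
}

#' Render the OCT volume and ground-truth labels of a phantom
#'
#' Voxel intensity is the product of the class mean reflectivity, the class
#' lateral texture field, the round-trip attenuation `exp(-2 mu z)` (z
#' measured from the local top surface), a multiplicative gamma speckle
#' field (mean 1) and `(1 + additive noise)`. The specimen sits against the
#' imaging window at shallow depth with a smooth height variation; voxels
#' outside the tissue slab carry the background level.
#'
#' @param layout 2-D class map from [build_layout()]; its lateral shape must
#'   match the spec.
#' @param spec a [phantom_spec()].
#' @return object of class `specimen_phantom` with `oct` and `labels`
#'   (`(nz, nx, ny)` arrays), truth attributes (`truth_top`, `truth_bottom`
#'   maps) and the spec.
#' @export
render_oct <- function(layout, spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  nx <- spec$grid_shape[1]; ny <- spec$grid_shape[2]; nz <- spec$grid_shape[3]
  if (nrow(layout) != nx || ncol(layout) != ny) {
    stop("layout shape does not match spec lateral grid")
  }
  cls <- tissue_classes()
  cp <- spec$class_params
  out <- with_seed(spec$seed, {
    # top surface height (voxels, >= 1) and bottom
    h <- matrix(1L, nx, ny)
    if (spec$surface_amp_vox > 0) {
      f <- gaussian_field(nx, ny, max(2, nx / 8))
      h <- matrix(1L + pmax(0L, as.integer(round(
        spec$surface_amp_vox * (f - min(f)) / 2))), nx, ny)
    }
    thick_vox <- max(4L, as.integer(round(spec$thickness_um / spec$axial_voxel)))
    bottom <- pmin(nz, h + thick_vox - 1L)

    tex <- render_textures(layout, spec, nz = nz)
    lob <- attr(layout, "lobule_mask")
    focus <- attr(layout, "focus_mask")
    offset_um <- attr(layout, "depth_offset_um")

    mean_map <- matrix(0, nx, ny); mu_map <- matrix(0, nx, ny)
    tex_map <- matrix(1, nx, ny)
    for (cn in c("tumor", "adipose", "benign")) {
      sel <- layout == cls[[cn]]
      if (!any(sel)) next
      mean_map[sel] <- cp[[cn]]$mean
      mu_map[sel] <- cp[[cn]]$mu
      tex_map[sel] <- tex[[cn]][sel]
    }
    if (!is.null(lob)) tex_map[lob] <- tex$lobule[lob]
    sel_adi <- layout == cls[["adipose"]]

    # fat lobules are wrapped in bright collagenous septa: paint a membrane
    # along the lateral adipose/tissue interface (vertical sheet in depth)
    membrane <- matrix(FALSE, nx, ny)
    if (any(sel_adi) && !all(sel_adi)) {
      other <- !sel_adi & layout != cls[["background"]]
      shift <- function(m, dx, dy) {
        m[pmin(pmax(seq_len(nx) + dx, 1L), nx),
          pmin(pmax(seq_len(ny) + dy, 1L), ny)]
      }
      near_other <- shift(other, 1, 0) | shift(other, -1, 0) |
        shift(other, 0, 1) | shift(other, 0, -1)
      near_adi <- shift(sel_adi, 1, 0) | shift(sel_adi, -1, 0) |
        shift(sel_adi, 0, 1) | shift(sel_adi, 0, -1)
      membrane <- (sel_adi & near_other) | (other & near_adi)
    }
    membrane_level <- 1 + (cp$adipose$septa_gain %||% 8) * cp$adipose$contrast

    # deep_focus: benign cap above the focus depth
    cap_map <- NULL
    if (!is.null(focus) && !is.null(offset_um)) {
      cap_map <- list(mean = cp$benign$mean, mu = cp$benign$mu,
                      tex = tex$benign, offset_vox = offset_um / spec$axial_voxel)
    }

    oct <- array(cp$background$mean, dim = c(nz, nx, ny))
    labels <- array(cls[["background"]], dim = c(nz, nx, ny))
    lay3 <- layout
    for (z in seq_len(nz)) {
      inside <- (z >= h) & (z <= bottom)
      if (!any(inside)) next
      dz_mm <- (z - h) * spec$axial_voxel / 1000   # depth below local surface
      mmap <- mean_map; mumap <- mu_map; tmap <- tex_map; lmap <- lay3
      if (!is.null(tex$adipose3d) && any(sel_adi)) {
        a3 <- matrix(tex$adipose3d[z, , ], nrow(layout), ncol(layout))
        tmap[sel_adi] <- a3[sel_adi]
      }
      if (!is.null(cap_map)) {
        above <- focus & ((z - h) < cap_map$offset_vox)
        mmap[above] <- cap_map$mean
        mumap[above] <- cap_map$mu
        tmap[above] <- cap_map$tex[above]
        lmap[above] <- cls[["benign"]]
      }
      if (any(membrane)) tmap[membrane] <- membrane_level
      sl <- mmap * tmap * exp(-2 * mumap * dz_mm)
      plane <- oct[z, , ]
      plane[inside] <- sl[inside]
      oct[z, , ] <- plane
      lab <- labels[z, , ]
      lab[inside] <- lmap[inside]
      labels[z, , ] <- lab
    }
    if (spec$speckle_shape > 0) {
      sp <- array(stats::rgamma(length(oct), shape = spec$speckle_shape,
                                rate = spec$speckle_shape), dim = dim(oct))
      oct <- oct * sp
    }
    if (spec$surface_reflect > 0) {
      # coherent specular reflection at the window-tissue interface:
      # constant amplitude, not speckle-modulated
      for (zz in sort(unique(as.vector(h)))) {
        at <- h == zz
        pl <- oct[zz, , ]
        pl[at] <- spec$surface_reflect
        oct[zz, , ] <- pl
      }
    }
    if (spec$noise_sd > 0) {
      oct <- oct * (1 + array(stats::rnorm(length(oct), 0, spec$noise_sd),
                              dim = dim(oct)))
    }
    oct <- pmax(oct, 0)
    list(oct = oct, labels = labels, truth_top = h, truth_bottom = bottom,
         adipose_centers = tex$adipose_centers)
  })
  structure(list(oct = out$oct, labels = out$labels, rcm = NULL, fl = NULL,
                 photo = NULL, spec = spec, layout = layout,
                 truth_top = out$truth_top, truth_bottom = out$truth_bottom,
                 adipose_centers = out$adipose_centers),
            class = "specimen_phantom")
}

#' Render the activated-fluorescence channel of a phantom
#'
#' Each lateral position carries the probe activation level
#' ([fluorescence_trace()]) at its class-specific E:S ratio and the given
#' incubation time, blurred by a Gaussian point-spread and degraded by
#' additive noise. Tumor (E:S 1:25) therefore outshines benign tissue
#' (1:200) for any positive incubation; at zero incubation every class sits
#' at the common quenched baseline. Lobule-insert regions receive a mildly
#' elevated enzyme level (the non-specific activation that makes benign
#' lobules light up).
#'
#' @param layout class map from [build_layout()].
#' @param kinetics a [kinetics_params()] (its `es` field is ignored; class
#'   ratios come from `es_map`).
#' @param incubation_min incubation time in minutes (>= 0; default 2).
#' @param es_map named vector of substrate-per-enzyme ratios per class.
#' @param psf_sigma_px Gaussian blur sigma in pixels.
#' @param noise_sd additive noise SD.
#' @param seed RNG seed.
#' @return fluorescence image matrix `nx x ny`.
#' @export
render_fl <- function(layout, kinetics = kinetics_params(), incubation_min = 2,
                      es_map = c(tumor = 25, adipose = 300, benign = 200,
                                 lobule = 100, background = Inf),
                      psf_sigma_px = 2, noise_sd = 0.02, seed = 1) {
  if (incubation_min < 0) stop("`incubation_min` must be non-negative")
  cls <- tissue_classes()
  fmap <- matrix(1, nrow(layout), ncol(layout))
  for (cn in c("tumor", "adipose", "benign", "background")) {
    sel <- layout == cls[[cn]]
    if (!any(sel)) next
    es <- es_map[[cn]]
    f <- if (is.finite(es)) {
      .trace_at(kinetics_params(kinetics$quench_efficiency,
                                kinetics$substrate_um, es,
                                kinetics$rate, kinetics$t_max),
                incubation_min)
    } else 1
    fmap[sel] <- f
  }
  lob <- attr(layout, "lobule_mask")
  if (!is.null(lob) && is.finite(es_map[["lobule"]])) {
    fmap[lob] <- .trace_at(kinetics_params(kinetics$quench_efficiency,
                                           kinetics$substrate_um,
                                           es_map[["lobule"]],
                                           kinetics$rate, kinetics$t_max),
                           incubation_min)
  }
  if (psf_sigma_px > 0) fmap <- gaussian_smooth(fmap, psf_sigma_px)
  if (noise_sd > 0) {
    fmap <- with_seed(seed, fmap + matrix(stats::rnorm(length(fmap), 0, noise_sd),
                                          nrow(fmap), ncol(fmap)))
  }
  fmap
}

#' Flat-shaded class-colour photograph of a phantom
#'
#' Exists to exercise the margin overlay: each class is painted a flat
#' tissue-like colour on the lateral grid.
#'
#' @param layout class map.
#' @return array `nx x ny x 3` of RGB values in `[0, 1]`.
#' @export
render_photo <- function(layout) {
  cols <- list(background = c(0.15, 0.15, 0.18),
               tumor = c(0.78, 0.55, 0.52),
               adipose = c(0.93, 0.84, 0.62),
               benign = c(0.85, 0.76, 0.72))
  cls <- tissue_classes()
  out <- array(0, dim = c(nrow(layout), ncol(layout), 3))
  for (cn in names(cols)) {
    sel <- layout == cls[[cn]]
    for (ch in 1:3) {
      pl <- out[, , ch]; pl[sel] <- cols[[cn]][ch]; out[, , ch] <- pl
    }
  }
  out
}

#' High-resolution en-face confocal-style image of a phantom
#'
#' Renders the lateral class textures on a finer grid (default 1 um pixels
#' against the 10 um OCT grid), emulating the confocal en-face view used to
#' label training regions. Purely a guidance channel; no depth sectioning is
#' modelled beyond the stated depth.
#'
#' @param layout class map.
#' @param spec a [phantom_spec()].
#' @param rcm_voxel_um confocal pixel size in um (default 1).
#' @param depth_um nominal imaging depth recorded as an attribute.
#' @return image matrix at the upsampled lateral grid.
#' @export
render_rcm <- function(layout, spec, rcm_voxel_um = 1, depth_um = 100) {
  f <- max(1L, as.integer(round(spec$lateral_voxel / rcm_voxel_um)))
  up <- layout[rep(seq_len(nrow(layout)), each = f),
               rep(seq_len(ncol(layout)), each = f)]
  attr(up, "lobule_mask") <- NULL
  spec_hr <- spec
  spec_hr$lateral_voxel <- rcm_voxel_um
  img <- with_seed(spec$seed + 1L, {
    tex <- render_textures(up, spec_hr)
    cls <- tissue_classes()
    m <- matrix(0, nrow(up), ncol(up))
    for (cn in c("tumor", "adipose", "benign")) {
      sel <- up == cls[[cn]]
      m[sel] <- spec$class_params[[cn]]$mean * tex[[cn]][sel]
    }
    m
  })
  attr(img, "depth_um") <- depth_um
  attr(img, "pixel_um") <- rcm_voxel_um
  img
}

#' Locate adipose lumen probe points in a phantom
#'
#' Returns the centers of the darkest fat-cell lumens: candidate cell
#' centers (from the honeycomb lattice) well inside the volume are ranked by
#' their local mean OCT intensity, mimicking how an operator would place a
#' region of interest inside a dark lumen. Intensity, not texture, drives
#' the selection.
#'
#' @param phantom a [specimen_phantom()] with adipose content.
#' @param n number of probes to return (default 3).
#' @param margin_px minimum distance of a probe from the lateral borders.
#' @return data.frame with columns `x, y, z` (voxel indices) and
#'   `intensity`, darkest first.
#' @export
adipose_lumen_probes <- function(phantom, n = 3, margin_px = 10) {
  ctr <- phantom$adipose_centers
  if (is.null(ctr)) stop("phantom has no adipose cells")
  d <- dim(phantom$oct)
  cand <- ctr[ctr$x > margin_px & ctr$x < d[2] - margin_px &
                ctr$y > margin_px & ctr$y < d[3] - margin_px &
                ctr$z > 6 & ctr$z < d[1] - 6, , drop = FALSE]
  if (nrow(cand) == 0) stop("no adipose cell center lies safely inside the volume")
  cand$xi <- round(cand$x); cand$yi <- round(cand$y); cand$zi <- round(cand$z)
  cand$intensity <- vapply(seq_len(nrow(cand)), function(i) {
    mean(phantom$oct[(cand$zi[i] - 1):(cand$zi[i] + 1),
                     (cand$xi[i] - 2):(cand$xi[i] + 2),
                     (cand$yi[i] - 2):(cand$yi[i] + 2)])
  }, numeric(1))
  cand <- cand[order(cand$intensity), , drop = FALSE]
  out <- data.frame(x = cand$xi, y = cand$yi, z = cand$zi,
                    intensity = cand$intensity)
  utils::head(out, n)
}

#' Generate a complete co-registered specimen phantom
#'
#' Builds the lateral layout for the spec's template, renders the OCT volume
#' with ground-truth labels, the activated-fluorescence image, the
#' brightfield photo and the high-resolution en-face confocal image, all on
#' co-registered lateral grids.
#'
#' @param spec a [phantom_spec()].
#' @param with_rcm render the (larger) confocal channel; default TRUE.
#' @return object of class `specimen_phantom` with fields `oct`, `labels`,
#'   `rcm`, `fl`, `photo`, `spec`, `layout` and ground-truth attributes.
#' @export
specimen_phantom <- function(spec = phantom_spec(), with_rcm = TRUE) {
  layout <- build_layout(spec$layout_pattern,
                         shape = spec$grid_shape[1:2], seed = spec$seed,
                         tumor_fraction = spec$tumor_fraction,
                         focus_depth_um = spec$focus_depth_um,
                         focus_radius_frac = spec$focus_radius_frac,
                         lobule_radius_frac = spec$lobule_radius_frac)
  ph <- render_oct(layout, spec)
  ph$fl <- render_fl(layout, seed = spec$seed + 2L)
  ph$photo <- render_photo(layout)
  if (with_rcm) ph$rcm <- render_rcm(layout, spec)
  ph
}

#' @export
print.specimen_phantom <- function(x, ...) {
  d <- dim(x$oct)
  fg <- x$labels != tissue_classes()[["background"]]
  fr <- table(factor(class_name(x$labels[fg]),
                     levels = c("tumor", "adipose", "benign"))) / max(1, sum(fg))
  cat(sprintf("Specimen phantom '%s': %d x %d lateral x %d depth voxels\n",
              x$spec$layout_pattern, d[2], d[3], d[1]))
  cat(sprintf("  foreground %.1f%%; tumor %.1f%%, adipose %.1f%%, benign %.1f%% of tissue\n",
              100 * mean(fg), 100 * fr[["tumor"]], 100 * fr[["adipose"]],
              100 * fr[["benign"]]))
  invisible(x)
}
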