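#' Straight fiber-bundle specification
#'
#' A cylinder of coherent fibers: voxels within `radius_mm` of the centerline
#' carry a tissue compartment whose principal direction is the bundle axis.
#'
#' @param center world-mm centerline midpoint.
#' @param axis unit 3-vector bundle direction.
#' @param length_mm,radius_mm cylinder length and radius (mm).
#' @param lambda1,lambda2 tissue diffusivities (mm^2/s).
#' @return A bundle specification list (`geometry = "straight"`).
#' @export
bundle_straight <- function(center, axis = c(1, 0, 0), length_mm = 60,
                            radius_mm = 3, lambda1 = 1.4e-3,
                            lambda2 = 0.5e-3) {
  axis <- axis / sqrt(sum(axis^2))
  list(geometry = "straight", center = as.numeric(center), axis = axis,
       length_mm = length_mm, radius_mm = radius_mm,
       lambda1 = lambda1, lambda2 = lambda2)
}

#' Circular-arc fiber-bundle specification
#'
#' @param center world-mm center of the arc's circle.
#' @param plane_u,plane_v orthonormal 3-vectors spanning the arc plane.
#' @param arc_radius_mm circle radius (mm).
#' @param angles length-2 angular range (radians) of the arc in the
#'   `(plane_u, plane_v)` frame.
#' @param radius_mm bundle tube radius (mm).
#' @param lambda1,lambda2 tissue diffusivities (mm^2/s).
#' @return A bundle specification list (`geometry = "arc"`).
#' @export
bundle_arc <- function(center, plane_u = c(1, 0, 0), plane_v = c(0, 1, 0),
                       arc_radius_mm = 20, angles = c(0, pi / 2),
                       radius_mm = 3, lambda1 = 1.4e-3, lambda2 = 0.5e-3) {
  plane_u <- plane_u / sqrt(sum(plane_u^2))
  plane_v <- plane_v - sum(plane_v * plane_u) * plane_u
  plane_v <- plane_v / sqrt(sum(plane_v^2))
  list(geometry = "arc", center = as.numeric(center), plane_u = plane_u,
       plane_v = plane_v, arc_radius_mm = arc_radius_mm, angles = angles,
       radius_mm = radius_mm, lambda1 = lambda1, lambda2 = lambda2)
}

#' A crossing pair of straight bundles
#'
#' @param center shared world-mm crossing point.
#' @param angle_deg crossing angle between the two bundle axes (degrees).
#' @param ... forwarded to [bundle_straight()].
#' @return List of two straight bundle specifications.
#' @export
bundles_crossing <- function(center, angle_deg = 60, ...) {
  a <- angle_deg * pi / 180
  list(bundle_straight(center, axis = c(1, 0, 0), ...),
       bundle_straight(center, axis = c(cos(a), sin(a), 0), ...))
}

#' Ellipsoidal edema region specification
#'
#' A localized region of elevated free-water fraction emulating vasogenic
#' peritumoral edema. Optionally the tissue compartments inside the region
#' have their radial diffusivity raised in proportion to the local FW
#' fraction, emulating the expanded extracellular space.
#'
#' @param center world-mm region center.
#' @param radii length-3 semi-axes (mm).
#' @param peak_fw peak FW fraction in `[0, 1]`.
#' @param profile `"flat"` (peak everywhere inside) or `"linear"`
#'   (taper from peak at the center to `rim_fw` at the boundary).
#' @param rim_fw FW fraction at the region boundary for the linear profile;
#'   `NULL` tapers all the way down to the phantom background. Vasogenic
#'   edema stays well above baseline FW at its radiological boundary, so the
#'   default phantom uses an elevated rim.
#' @param radial_boost tissue radial-diffusivity multiplier per unit local FW
#'   fraction (`lambda2' = lambda2 * (1 + radial_boost * fw)`).
#' @return An edema specification list.
#' @export
edema_region <- function(center, radii = c(5, 5, 5), peak_fw = 0.8,
                         profile = c("flat", "linear"), rim_fw = NULL,
                         radial_boost = 0.5) {
  profile <- match.arg(profile)
  radii <- rep(as.numeric(radii), length.out = 3L)
  if (any(radii <= 0)) stop("edema radii must be positive")
  if (peak_fw < 0 || peak_fw > 1) stop("peak_fw must lie in [0, 1]")
  if (!is.null(rim_fw) && (rim_fw < 0 || rim_fw > peak_fw))
    stop("rim_fw must lie in [0, peak_fw]")
  list(center = as.numeric(center), radii = radii, peak_fw = peak_fw,
       profile = profile, rim_fw = rim_fw, radial_boost = radial_boost)
}

#' Synthetic diffusion phantom specification
#'
#' Defines the ground-truth geometry and acquisition emulation: a voxel grid
#' (default 30^3 at 2.3 mm isotropic, matching the emulated protocol), one or
#' more fiber bundles, an optional edema region, an isotropic background, and
#' the noise model.
#'
#' @param grid length-3 integer grid shape.
#' @param voxel_mm isotropic voxel size (mm).
#' @param bundles list of bundle specifications.
#' @param edema an [edema_region()] or `NULL`.
#' @param background list with `diffusivity` (isotropic tissue diffusivity of
#'   non-bundle voxels, mm^2/s) and `fw` (background FW fraction).
#' @param s0 baseline intensity.
#' @param snr baseline signal-to-noise ratio (`Inf` = noise-free).
#' @param noise_model `"rician"`, `"gaussian"` or `"none"`.
#' @param fw_diffusivity fixed free-water diffusivity (mm^2/s).
#' @param rng_seed integer seed controlling the noise draw.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid = c(30L, 30L, 30L), voxel_mm = 2.3,
                         bundles = list(), edema = NULL,
                         background = list(diffusivity = 0.8e-3, fw = 0.05),
                         s0 = 400, snr = 20,
                         noise_model = c("rician", "gaussian", "none"),
                         fw_diffusivity = 3.0e-3, rng_seed = 1L) {
  noise_model <- match.arg(noise_model)
  if (is.infinite(snr)) noise_model <- "none"
  grid <- as.integer(grid)
  stopifnot(length(grid) == 3L, all(grid > 0), voxel_mm > 0, s0 > 0, snr > 0)
  structure(list(grid = grid, voxel_mm = voxel_mm, bundles = bundles,
                 edema = edema, background = background, s0 = s0, snr = snr,
                 noise_model = noise_model, fw_diffusivity = fw_diffusivity,
                 rng_seed = as.integer(rng_seed)),
            class = "phantom_spec")
}

#' The default edema phantom
#'
#' A straight 60 mm bundle through the grid center with an ellipsoidal
#' peritumoral-edema region centered mid-bundle: the FW fraction tapers
#' linearly from 0.8 at the region center to 0.55 at its boundary, and the
#' region is offset laterally so that part of the bundle cross-section is
#' spared — yielding both edema-traversing and non-traversing fiber
#' populations.
#'
#' @param snr baseline SNR (default 20, Rician).
#' @param edema logical; `FALSE` builds the matched no-edema control phantom.
#' @param edema_radius_mm edema size scale (mm): the ellipsoid semi-axes are
#'   `c(1.25, 0.5, 0.875) * edema_radius_mm` (elongated along the bundle);
#'   0 also disables edema.
#' @param peak_fw peak edema FW fraction.
#' @param grid,voxel_mm grid geometry.
#' @param bundle_radius_mm bundle tube radius (mm).
#' @param rng_seed noise seed.
#' @return A [phantom_spec()].
#' @export
default_edema_phantom <- function(snr = 20, edema = TRUE, edema_radius_mm = 8,
                                  peak_fw = 0.8, grid = c(30L, 30L, 30L),
                                  voxel_mm = 2.3, bundle_radius_mm = 3,
                                  rng_seed = 1L) {
  ctr <- (grid - 1) / 2 * voxel_mm
  bun <- bundle_straight(ctr, axis = c(1, 0, 0), length_mm = 60,
                         radius_mm = bundle_radius_mm)
  ed <- if (edema && edema_radius_mm > 0)
    edema_region(ctr + c(0, 2, 0),
                 radii = c(1.25, 0.5, 0.875) * edema_radius_mm,
                 peak_fw = peak_fw, profile = "linear",
                 rim_fw = peak_fw - 0.25)
  phantom_spec(grid = grid, voxel_mm = voxel_mm, bundles = list(bun),
               edema = ed, snr = snr, rng_seed = rng_seed)
}

phantom_affine <- function(spec) {
  a <- diag(4)
  diag(a)[1:3] <- spec$voxel_mm
  a
}

#' Build the ground-truth field of a phantom
#'
#' Assigns to each voxel its true tissue compartments (0-2), bundle
#' membership labels, FW-fraction value, and the brain mask.
#'
#' @param spec a [phantom_spec()].
#' @return An object of class `ground_truth_field` with per-voxel compartment
#'   slot arrays, `fw` map, `labels` arrays, `brain_mask`, and the affine.
#' @export
build_field <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$grid
  affine <- phantom_affine(spec)
  ijk <- as.matrix(expand.grid(i = 0:(d[1] - 1), j = 0:(d[2] - 1),
                               k = 0:(d[3] - 1)))
  w <- ijk * spec$voxel_mm                      # world coords of voxel centers
  nvox <- nrow(w)

  slot <- function() list(dir = matrix(0, nvox, 3L), l1 = numeric(nvox),
                          l2 = numeric(nvox), label = integer(nvox))
  slots <- list(slot(), slot())
  n_comp <- integer(nvox)

  for (b in seq_along(spec$bundles)) {
    bs <- spec$bundles[[b]]
    hit <- bundle_hit(bs, w)
    inside <- which(hit$inside)
    if (!length(inside)) next
    if (any(n_comp[inside] >= 2L))
      stop("more than 2 bundles overlap in a voxel")
    for (v in inside) {
      s <- n_comp[v] + 1L
      slots[[s]]$dir[v, ] <- hit$tangent[v, ]
      slots[[s]]$l1[v] <- bs$lambda1
      slots[[s]]$l2[v] <- bs$lambda2
      slots[[s]]$label[v] <- b
    }
    n_comp[inside] <- n_comp[inside] + 1L
  }

  fw <- rep(spec$background$fw, nvox)
  if (!is.null(spec$edema)) {
    ed <- spec$edema
    rho <- sqrt(colSums((t(w) - ed$center)^2 / ed$radii^2))
    ins <- rho < 1
    rim <- ed$rim_fw %||% spec$background$fw
    fw_ed <- if (ed$profile == "flat") rep(ed$peak_fw, sum(ins)) else
      rim + (ed$peak_fw - rim) * (1 - rho[ins])
    fw[ins] <- pmax(fw[ins], fw_ed)
    # expanded extracellular space raises tissue radial diffusivity
    if (ed$radial_boost > 0) {
      for (s in 1:2) {
        sel <- ins & slots[[s]]$label > 0
        slots[[s]]$l2[sel] <- pmin(
          slots[[s]]$l2[sel] * (1 + ed$radial_boost * fw[sel]),
          slots[[s]]$l1[sel])
      }
    }
  }

  arr <- function(x) array(x, d)
  structure(list(
    dims = d, affine = affine, voxel_mm = spec$voxel_mm,
    n_comp = arr(n_comp), fw = arr(fw),
    slots = lapply(slots, function(s) list(
      dir = array(s$dir, c(d, 3L)), l1 = arr(s$l1), l2 = arr(s$l2),
      label = arr(s$label))),
    brain_mask = arr(rep(TRUE, nvox)),
    background = spec$background, fw_diffusivity = spec$fw_diffusivity,
    n_bundles = length(spec$bundles)), class = "ground_truth_field")
}

# inside-test + local tangent of a bundle for a matrix of world points
bundle_hit <- function(bs, w) {
  nvox <- nrow(w)
  if (bs$geometry == "straight") {
    rel <- sweep(w, 2L, bs$center)
    t <- as.numeric(rel %*% bs$axis)
    perp <- rel - outer(t, bs$axis)
    dist <- sqrt(rowSums(perp^2))
    inside <- abs(t) <= bs$length_mm / 2 & dist <= bs$radius_mm
    tangent <- matrix(bs$axis, nvox, 3L, byrow = TRUE)
  } else if (bs$geometry == "arc") {
    rel <- sweep(w, 2L, bs$center)
    qu <- as.numeric(rel %*% bs$plane_u)
    qv <- as.numeric(rel %*% bs$plane_v)
    theta <- pmin(pmax(atan2(qv, qu), bs$angles[1]), bs$angles[2])
    nearest <- bs$arc_radius_mm *
      (outer(cos(theta), bs$plane_u) + outer(sin(theta), bs$plane_v))
    dist <- sqrt(rowSums((rel - nearest)^2))
    inside <- dist <= bs$radius_mm
    tangent <- -outer(sin(theta), bs$plane_u) + outer(cos(theta), bs$plane_v)
  } else stop("unknown bundle geometry: ", bs$geometry)
  list(inside = inside, tangent = tangent)
}

#' Render a synthetic DWI volume from a ground-truth field
#'
#' Noise-free intensity is `s0` times the normalized signal of the voxel's
#' true model state; Rician noise is applied as
#' `sqrt((S + n1)^2 + n2^2)` with `n1, n2 ~ N(0, sigma^2)`,
#' `sigma = s0 / snr`. Reproducible from `spec$rng_seed`.
#'
#' @param field a [build_field()] result.
#' @param gtab a [gradient_table()].
#' @param spec the [phantom_spec()] (noise settings and `s0`).
#' @return A [dwi_volume()].
#' @export
synthesize_dwi <- function(field, gtab, spec) {
  stopifnot(inherits(field, "ground_truth_field"),
            inherits(gtab, "gradient_table"))
  d <- field$dims
  nvox <- prod(d)
  ng <- length(gtab$bvals)
  b <- gtab$bvals
  g <- gtab$bvecs
  fw <- as.numeric(field$fw)
  nc <- as.numeric(field$n_comp)

  tissue <- matrix(0, nvox, ng)
  for (s in 1:2) {
    sel <- nc >= s
    if (!any(sel)) next
    dirs <- matrix(field$slots[[s]]$dir, nvox, 3L)[sel, , drop = FALSE]
    l1 <- as.numeric(field$slots[[s]]$l1)[sel]
    l2 <- as.numeric(field$slots[[s]]$l2)[sel]
    mg2 <- (dirs %*% t(g))^2                    # nsel x ng
    att <- exp(-outer(l2, b) - (l1 - l2) * mg2 * rep(b, each = sum(sel)))
    tissue[sel, ] <- tissue[sel, ] + att
  }
  bg <- nc == 0L
  if (any(bg))
    tissue[bg, ] <- matrix(exp(-b * field$background$diffusivity),
                           sum(bg), ng, byrow = TRUE)
  tissue[nc > 0L, ] <- tissue[nc > 0L, , drop = FALSE] / nc[nc > 0L]
  iso <- matrix(exp(-b * field$fw_diffusivity), nvox, ng, byrow = TRUE)
  signal <- spec$s0 * ((1 - fw) * tissue + fw * iso)

  if (spec$noise_model != "none") {
    sigma <- spec$s0 / spec$snr
    signal <- with_seed(spec$rng_seed, {
      if (spec$noise_model == "rician") {
        n1 <- matrix(stats::rnorm(nvox * ng, 0, sigma), nvox, ng)
        n2 <- matrix(stats::rnorm(nvox * ng, 0, sigma), nvox, ng)
        sqrt((signal + n1)^2 + n2^2)
      } else {
        pmax(signal + matrix(stats::rnorm(nvox * ng, 0, sigma), nvox, ng), 0)
      }
    })
  }
  dwi_volume(array(signal, c(d, ng)), field$affine, gtab)
}

#' Ground-truth membership mask of one bundle
#'
#' @param field a [build_field()] result.
#' @param bundle_id integer bundle index as listed in the phantom spec.
#' @return Logical 3-D array.
#' @export
ground_truth_bundle_mask <- function(field, bundle_id) {
  if (!bundle_id %in% seq_len(field$n_bundles))
    stop("unknown bundle id: ", bundle_id)
  field$slots[[1]]$label == bundle_id | field$slots[[2]]$label == bundle_id
}

# Evaluate an expression under a temporary RNG seed, restoring global state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
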