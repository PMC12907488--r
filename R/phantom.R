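#' Specification of a synthetic head phantom
#'
#' Describes a synthetic CT head on an isotropic grid: a bone ellipsoid shell
#' (skull), parenchyma filling its interior, and 12 CSF-filled ventricular
#' subregions modeled as geometric primitives with closed-form volumes —
#' ellipsoids for bodies, horns without strong curvature, atria and the
#' midline ventricles, and curved tubes (torus arcs) for the posterior and
#' temporal horns. Left-side primitives are exact mirror images of the
#' right-side ones. A ventriculomegaly scale dilates the whole ventricular
#' constellation about its centroid (volumes scale by `scale^3`; disjointness
#' is preserved by construction) and a pose jitter rotates it by small random
#' angles.
#'
#' HU defaults put CSF (8 +- 2) and parenchyma (35 +- 3) inside the 0-80
#' CSF window so their contrast is exercised exactly where it matters.
#'
#' @param seed integer seed controlling the voxel noise and jitter draws
#' @param grid edge length of the cubic native grid (voxels)
#' @param spacing_mm isotropic native voxel size, mm
#' @param head_scale global scale of the whole head geometry (1 = adult
#'   head on a 256 mm field of view); desk-scale tests shrink it with the grid
#' @param ventriculomegaly_scale dilation factor for the ventricular system,
#'   `>= 0.5`
#' @param pose_jitter_deg maximum rotation, degrees, about each axis
#' @param parenchyma_hu,csf_hu mean/sd HU of parenchyma and CSF
#' @param bone_hu,air_hu constant HU of bone and background air
#' @param noise_sd global Gaussian HU noise
#' @param skull_semiaxes_mm,skull_thickness_mm outer skull ellipsoid geometry
#' @return object of class `phantom_spec`
#' @export
phantom_spec <- function(seed = 1L, grid = 256L, spacing_mm = 1,
                         head_scale = 1, ventriculomegaly_scale = 1,
                         pose_jitter_deg = 0,
                         parenchyma_hu = c(35, 3), csf_hu = c(8, 2),
                         bone_hu = 900, air_hu = -1000, noise_sd = 4,
                         skull_semiaxes_mm = c(78, 98, 72),
                         skull_thickness_mm = 6) {
  if (ventriculomegaly_scale < 0.5) stop("ventriculomegaly_scale must be >= 0.5")
  structure(
    list(
      seed = as.integer(seed), grid = as.integer(grid), spacing_mm = spacing_mm,
      head_scale = head_scale, ventriculomegaly_scale = ventriculomegaly_scale,
      pose_jitter_deg = pose_jitter_deg,
      parenchyma_hu = parenchyma_hu, csf_hu = csf_hu,
      bone_hu = bone_hu, air_hu = air_hu, noise_sd = noise_sd,
      skull_semiaxes_mm = skull_semiaxes_mm * head_scale,
      skull_thickness_mm = skull_thickness_mm * head_scale,
      subregions = subregion_primitives(head_scale)
    ),
    class = "phantom_spec"
  )
}

# Right-side and midline primitives in mm, RAS, origin at head center;
# left side is the x-mirror. Centers/sizes chosen so that voxel volumes sit
# in the magnitude range of hydrocephalic anatomy (bodies in the tens of ml,
# posterior horns under 1 ml) and all regions stay pairwise disjoint.
subregion_primitives <- function(head_scale = 1) {
  ell <- function(center, semi) {
    list(kind = "ellipsoid", center = center * head_scale, semi = semi * head_scale)
  }
  arc <- function(center, u, v, ring_radius, tube_radius, theta) {
    list(
      kind = "tube_arc", center = center * head_scale, u = u, v = v,
      ring_radius = ring_radius * head_scale,
      tube_radius = tube_radius * head_scale, theta = theta
    )
  }
  mirror_x <- function(p) {
    p$center[1] <- -p$center[1]
    if (p$kind == "tube_arc") {
      p$u[1] <- -p$u[1]
      p$v[1] <- -p$v[1]
    }
    p
  }
  right <- list(
    body_right_lateral = ell(c(18, 2, 31), c(14, 29, 17)),
    right_anterior_horn = ell(c(14, 45, 14), c(11, 13, 14)),
    right_atrium = ell(c(20, -34, 18), c(10.5, 11, 11)),
    right_posterior_horn = arc(
      c(16, -40, 14), c(0, -1, 0), c(0, 0, 1),
      ring_radius = 12, tube_radius = 4, theta = c(-0.6, 0.6)
    ),
    right_temporal_horn = arc(
      c(24, -16, 12), c(0, 1, 0), c(0, 0, -1),
      ring_radius = 20, tube_radius = 7, theta = c(0.35, 1.45)
    )
  )
  midline <- list(
    third_ventricle = ell(c(0, 8, 8), c(3.5, 16, 13)),
    fourth_ventricle = ell(c(0, -32, -14), c(5, 9, 10))
  )
  left <- lapply(right, mirror_x)
  names(left) <- sub("right", "left", names(right))
  prims <- c(right, midline, left)
  prims <- prims[subregion_classes()$name]
  if (anyNA(names(prims)) || length(prims) != 12L) stop("primitive set incomplete")
  prims
}

primitive_volume_mm3 <- function(p) {
  if (p$kind == "ellipsoid") {
    4 / 3 * pi * prod(p$semi)
  } else {
    diff(p$theta) * p$ring_radius * pi * p$tube_radius^2
  }
}

primitive_bounding_radius <- function(p) {
  if (p$kind == "ellipsoid") max(p$semi) else p$ring_radius + p$tube_radius
}

# is the (already inverse-transformed) point set inside the primitive?
primitive_inside <- function(p, X, Y, Z) {
  if (p$kind == "ellipsoid") {
    ((X - p$center[1]) / p$semi[1])^2 +
      ((Y - p$center[2]) / p$semi[2])^2 +
      ((Z - p$center[3]) / p$semi[3])^2 <= 1
  } else {
    dx <- X - p$center[1]
    dy <- Y - p$center[2]
    dz <- Z - p$center[3]
    pu <- dx * p$u[1] + dy * p$u[2] + dz * p$u[3]
    pv <- dx * p$v[1] + dy * p$v[2] + dz * p$v[3]
    nrm <- c(
      p$u[2] * p$v[3] - p$u[3] * p$v[2],
      p$u[3] * p$v[1] - p$u[1] * p$v[3],
      p$u[1] * p$v[2] - p$u[2] * p$v[1]
    )
    pw <- dx * nrm[1] + dy * nrm[2] + dz * nrm[3]
    th <- atan2(pv, pu)
    radial <- sqrt(pu^2 + pv^2)
    (th >= p$theta[1]) & (th <= p$theta[2]) &
      ((radial - p$ring_radius)^2 + pw^2 <= p$tube_radius^2)
  }
}

rotation_matrix <- function(deg) {
  r <- deg * pi / 180
  cx <- cos(r[1]); sx <- sin(r[1])
  cy <- cos(r[2]); sy <- sin(r[2])
  cz <- cos(r[3]); sz <- sin(r[3])
  rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  rz %*% ry %*% rx
}

#' Generate a synthetic head phantom
#'
#' Deterministic given the spec's seed. Returns the noisy HU volume, the
#' exclusive ground-truth label volume, and the closed-form analytic volume
#' of every subregion in ml (primitive volume times
#' `ventriculomegaly_scale^3`; rotation does not change volume).
#'
#' @param spec a [phantom_spec()]
#' @param jitter_deg optional explicit rotation angles (degrees, length 3);
#'   by default drawn uniformly within `+-pose_jitter_deg` from the seeded
#'   stream
#' @return list with elements `image` ([native_volume()]), `labels`
#'   ([label_volume()] on the native frame), `analytic_volumes_ml` (named),
#'   and `spec`
#' @export
generate_phantom <- function(spec, jitter_deg = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, {
    if (is.null(jitter_deg)) {
      jitter_deg <- stats::runif(3, -spec$pose_jitter_deg, spec$pose_jitter_deg)
    }
    g <- spec$grid
    sp <- spec$spacing_mm
    coords <- (0:(g - 1) - (g - 1) / 2) * sp
    cls <- subregion_classes()
    prims <- spec$subregions
    s <- spec$ventriculomegaly_scale
    rot <- rotation_matrix(jitter_deg)
    centroid <- rowMeans(vapply(prims, function(p) p$center, numeric(3)))

    # skull and parenchyma via separable ellipsoid evaluation
    outer_semi <- spec$skull_semiaxes_mm
    inner_semi <- outer_semi - spec$skull_thickness_mm
    qfun <- function(semi) {
      qx <- (coords / semi[1])^2
      qy <- (coords / semi[2])^2
      qz <- (coords / semi[3])^2
      array(outer(outer(qx, qy, "+"), qz, "+"), dim = c(g, g, g))
    }
    hu <- array(spec$air_hu, dim = c(g, g, g))
    hu[qfun(outer_semi) <= 1] <- spec$bone_hu
    inside_inner <- qfun(inner_semi) <= 1
    hu[inside_inner] <- spec$parenchyma_hu[1]
    if (spec$parenchyma_hu[2] > 0) {
      n_in <- sum(inside_inner)
      hu[inside_inner] <- hu[inside_inner] + stats::rnorm(n_in, 0, spec$parenchyma_hu[2])
    }

    labels <- array(0L, dim = c(g, g, g))
    analytic <- numeric(12)
    names(analytic) <- cls$name
    for (i in seq_len(nrow(cls))) {
      p <- prims[[cls$name[i]]]
      analytic[i] <- primitive_volume_mm3(p) * s^3 / 1000
      # forward image of the primitive center and a conservative bound
      c_eff <- centroid + s * as.vector(rot %*% (p$center - centroid))
      rad <- s * primitive_bounding_radius(p)
      lo <- pmax(1L, floor((c_eff - rad) / sp + (g - 1) / 2) + 1L)
      hi <- pmin(g, ceiling((c_eff + rad) / sp + (g - 1) / 2) + 1L)
      if (any(lo > hi)) next
      xs <- coords[lo[1]:hi[1]]
      ys <- coords[lo[2]:hi[2]]
      zs <- coords[lo[3]:hi[3]]
      nb <- c(length(xs), length(ys), length(zs))
      X <- array(rep(xs, times = nb[2] * nb[3]), dim = nb)
      Y <- array(rep(rep(ys, each = nb[1]), times = nb[3]), dim = nb)
      Z <- array(rep(zs, each = nb[1] * nb[2]), dim = nb)
      # invert jitter + ventriculomegaly about the constellation centroid
      dx <- X - centroid[1]; dy <- Y - centroid[2]; dz <- Z - centroid[3]
      qx <- centroid[1] + (rot[1, 1] * dx + rot[2, 1] * dy + rot[3, 1] * dz) / s
      qy <- centroid[2] + (rot[1, 2] * dx + rot[2, 2] * dy + rot[3, 2] * dz) / s
      qz <- centroid[3] + (rot[1, 3] * dx + rot[2, 3] * dy + rot[3, 3] * dz) / s
      inside <- primitive_inside(p, qx, qy, qz)
      if (!any(inside)) next
      sub <- labels[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
      if (any(sub[inside] != 0L)) stop("subregion collision")
      sub[inside] <- cls$id[i] + 1L
      labels[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- sub
    }
    if (any(labels != 0L & !inside_inner)) stop("subregion outside skull interior")

    csf_idx <- which(labels != 0L)
    hu[csf_idx] <- spec$csf_hu[1]
    if (spec$csf_hu[2] > 0) {
      hu[csf_idx] <- hu[csf_idx] + stats::rnorm(length(csf_idx), 0, spec$csf_hu[2])
    }
    if (spec$noise_sd > 0) {
      hu <- hu + array(stats::rnorm(length(hu), 0, spec$noise_sd), dim = dim(hu))
    }
    list(
      image = native_volume(hu, spacing = rep(sp, 3), orientation = "RAS"),
      labels = label_volume(labels, frame = "native", spacing = rep(sp, 3)),
      analytic_volumes_ml = analytic,
      jitter_deg = jitter_deg,
      spec = spec
    )
  })
}

#' Generate a seeded cohort of phantoms
#'
#' Per-subject ventriculomegaly scale (log-normal, median at the base spec's
#' scale), pose jitter and voxel noise are drawn from per-subject seeded
#' streams, so subject `i` is reproducible from `(seed, i)` alone.
#'
#' @param n number of subjects
#' @param base_spec a [phantom_spec()] used as template
#' @param seed cohort seed
#' @param scale_sdlog sd of the log-normal per-subject ventriculomegaly scale
#' @param rasterize generate the voxel volumes (`TRUE`) or only specs and
#'   analytic volumes (`FALSE`, fast)
#' @return list of per-subject lists as returned by [generate_phantom()]
#'   (without `image`/`labels` when `rasterize = FALSE`)
#' @export
phantom_cohort <- function(n, base_spec = phantom_spec(), seed = 1L,
                           scale_sdlog = 0.12, rasterize = TRUE) {
  stopifnot(n >= 1)
  lapply(seq_len(n), function(i) {
    subj_seed <- (as.integer(seed) * 1000L + i) %% .Machine$integer.max
    draws <- with_seed(subj_seed, {
      list(
        scale = min(max(
          base_spec$ventriculomegaly_scale * stats::rlnorm(1, 0, scale_sdlog),
          0.7
        ), 1.3),
        jitter = stats::runif(3, -base_spec$pose_jitter_deg, base_spec$pose_jitter_deg)
      )
    })
    spec_i <- base_spec
    spec_i$ventriculomegaly_scale <- draws$scale
    spec_i$seed <- subj_seed
    if (!rasterize) {
      cls <- subregion_classes()
      analytic <- vapply(
        spec_i$subregions[cls$name], primitive_volume_mm3, 0
      ) * draws$scale^3 / 1000
      names(analytic) <- cls$name
      return(list(
        analytic_volumes_ml = analytic, spec = spec_i,
        jitter_deg = draws$jitter, subject = i
      ))
    }
    ph <- generate_phantom(spec_i, jitter_deg = draws$jitter)
    ph$subject <- i
    ph
  })
}

#' Write a phantom to disk
#'
#' Writes the image and label NIfTI pair plus a JSON sidecar holding the
#' analytic volumes and the generating parameters.
#'
#' @param phantom result of [generate_phantom()]
#' @param dir output directory
#' @param stem file name stem
#' @return the sidecar path, invisibly
#' @export
write_phantom <- function(phantom, dir, stem = "phantom") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_nifti(phantom$image, file.path(dir, paste0(stem, "_image.nii.gz")))
  write_nifti(phantom$labels, file.path(dir, paste0(stem, "_labels.nii.gz")))
  sidecar <- file.path(dir, paste0(stem, ".json"))
  spec <- unclass(phantom$spec)
  spec$subregions <- NULL
  jsonlite::write_json(
    list(
      analytic_volumes_ml = as.list(phantom$analytic_volumes_ml),
      jitter_deg = phantom$jitter_deg,
      spec = spec
    ),
    sidecar,
    auto_unbox = TRUE, digits = NA
  )
  invisible(sidecar)
}

# run code under a temporary seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
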