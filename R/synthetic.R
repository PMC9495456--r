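# Synthetic CT phantoms and synthetic candidate-mask sets. The phantom
# emulates the intensity regime of an abdominal soft-tissue window:
# air around the body, a soft-tissue body ellipse, a bright bone (spine)
# ellipse, a single connected liver-like ellipsoid, darker lesion spheres
# inside it, and an optional extrahepatic distractor of liver-like
# intensity (a spleen-like blob). Geometry is ellipsoid-based on purpose:
# the pipeline logic under test depends on topology and intensity bands,
# not anatomical realism.

#' Specification of a synthetic CT phantom
#'
#' Defaults place tissue means at typical portal-venous values: liver
#' 60 HU, hypodense lesions 30 HU, other soft tissue 40 HU, bone 400 HU,
#' air -1000 HU, with 10 HU Gaussian noise and 2.5 x 1 x 1 mm voxels.
#'
#' @param extents (n_slices, side, side) voxel grid extents.
#' @param liver_hu,lesion_hu,soft_tissue_hu,air_hu,bone_hu tissue means
#'   in HU; lesions must be darker than liver.
#' @param n_lesions number of lesion spheres inside the liver.
#' @param distractor logical; add an extrahepatic liver-intensity blob.
#' @param noise_sd Gaussian noise standard deviation in HU.
#' @param spacing voxel spacing in mm (slice, row, col).
#' @return list of class `phantom_spec`.
#' @export
phantom_spec <- function(extents = c(64L, 256L, 256L), liver_hu = 60,
                         lesion_hu = 30, soft_tissue_hu = 40,
                         air_hu = -1000, bone_hu = 400, n_lesions = 2L,
                         distractor = TRUE, noise_sd = 10,
                         spacing = c(2.5, 1, 1)) {
  stopifnot(lesion_hu < liver_hu, length(extents) == 3L,
            extents[2L] == extents[3L])
  structure(list(extents = as.integer(extents), liver_hu = liver_hu,
                 lesion_hu = lesion_hu, soft_tissue_hu = soft_tissue_hu,
                 air_hu = air_hu, bone_hu = bone_hu,
                 n_lesions = as.integer(n_lesions),
                 distractor = isTRUE(distractor), noise_sd = noise_sd,
                 spacing = spacing), class = "phantom_spec")
}

# voxel-center coordinate grids for one slice plane
plane_grids <- function(side) {
  list(r = matrix(seq_len(side), side, side),
       c = matrix(seq_len(side), side, side, byrow = TRUE))
}

# in-plane ellipse membership at axial position z for an ellipsoid
ellipsoid_mask <- function(grids, center, radii, z) {
  dz2 <- ((z - center[1L]) / radii[1L])^2
  if (dz2 >= 1) return(NULL)
  s <- sqrt(1 - dz2)
  ((grids$r - center[2L]) / (radii[2L] * s))^2 +
    ((grids$c - center[3L]) / (radii[3L] * s))^2 <= 1
}

#' Generate a synthetic CT phantom examination
#'
#' Deterministic for a fixed seed. The liver is a single connected
#' ellipsoid labelled 1; lesions are spheres inside it labelled 2; the
#' distractor keeps label 0 (it is not liver) but carries liver-like HU.
#'
#' @param spec a [phantom_spec()].
#' @param seed integer seed.
#' @return list with `volume` (`hu_volume`) and `labels`
#'   (`label_volume`).
#' @export
generate_phantom <- function(spec = phantom_spec(), seed = 1L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed) %% 100000L * 11003L + 7L)
  ns <- spec$extents[1L]; side <- spec$extents[2L]
  sc <- side / 256  # geometry is specified at a 256-pixel reference plane
  g <- plane_grids(side)
  body_c <- c(ns / 2, 128 * sc, 128 * sc)
  body_r <- c(ns, 100 * sc, 112 * sc)
  liver_c <- c(ns * 0.5, 112 * sc, 92 * sc)
  liver_r <- c(ns * 0.33, 56 * sc, 62 * sc)
  bone_c <- c(ns / 2, 196 * sc, 128 * sc)
  bone_r <- c(ns, 16 * sc, 13 * sc)
  distr_c <- c(ns * 0.5, 128 * sc, 212 * sc)
  distr_r <- c(ns * 0.22, 17 * sc, 14 * sc)
  # lesion centers at fixed fractions of the liver radii, plus jittered
  # extras when more are requested
  lesion_fracs <- list(c(0.1, -0.35, 0.25), c(-0.2, 0.3, -0.3),
                       c(0.35, 0.1, 0.35), c(-0.4, -0.2, -0.25))
  lesions <- lapply(seq_len(spec$n_lesions), function(i) {
    f <- lesion_fracs[[(i - 1L) %% length(lesion_fracs) + 1L]]
    jit <- if (i > length(lesion_fracs)) stats::runif(3, -0.08, 0.08) else c(0, 0, 0)
    ctr <- liver_c + (f + jit) * liver_r
    list(center = ctr, radius = (6 + 3 * ((i - 1L) %% 3L)) * sc)
  })
  vox <- array(spec$air_hu, spec$extents)
  lab <- array(0L, spec$extents)
  for (z in seq_len(ns)) {
    hu <- matrix(spec$air_hu, side, side)
    lz <- matrix(0L, side, side)
    bm <- ellipsoid_mask(g, body_c, body_r, z)
    if (!is.null(bm)) hu[bm] <- spec$soft_tissue_hu
    sp <- ellipsoid_mask(g, bone_c, bone_r, z)
    if (!is.null(sp)) hu[sp] <- spec$bone_hu
    lv <- ellipsoid_mask(g, liver_c, liver_r, z)
    if (!is.null(lv)) { hu[lv] <- spec$liver_hu; lz[lv] <- 1L }
    for (le in lesions) {
      lm <- ellipsoid_mask(g, le$center, rep(le$radius, 3L) /
                             c(spec$spacing[1L] / spec$spacing[2L], 1, 1), z)
      if (!is.null(lm)) {
        lm <- lm & lz == 1L  # lesions live inside the liver only
        hu[lm] <- spec$lesion_hu
        lz[lm] <- 2L
      }
    }
    if (spec$distractor) {
      dm <- ellipsoid_mask(g, distr_c, distr_r, z)
      if (!is.null(dm)) hu[dm] <- spec$liver_hu
    }
    vox[z, , ] <- hu
    lab[z, , ] <- lz
  }
  vox <- vox + array(stats::rnorm(length(vox), sd = spec$noise_sd),
                     dim(vox))
  vol <- hu_volume(vox, spec$spacing, meta = list(phantom_seed = seed))
  list(volume = vol, labels = label_volume(lab, vol))
}

#' Per-network error model for synthetic candidate masks
#'
#' @param boundary_jitter_px maximum morphological jitter radius at the
#'   mask boundary.
#' @param false_blob_rate per-slice probability of adding a spurious
#'   blob.
#' @param miss_rate per-region probability of dropping a true region.
#' @return list of class `error_model_spec`.
#' @export
error_model_spec <- function(boundary_jitter_px = 2L,
                             false_blob_rate = 0.1, miss_rate = 0.05) {
  stopifnot(false_blob_rate >= 0, false_blob_rate <= 1, miss_rate >= 0,
            miss_rate <= 1)
  structure(list(boundary_jitter_px = as.integer(boundary_jitter_px),
                 false_blob_rate = false_blob_rate, miss_rate = miss_rate),
            class = "error_model_spec")
}

#' Default error models for the four networks
#'
#' Mildly different rates per network so fused output can out-vote
#' individual mistakes.
#' @return named list of four [error_model_spec()]s.
#' @export
default_error_models <- function() {
  list(densenet201 = error_model_spec(1L, 0.08, 0.04),
       inceptionv3 = error_model_spec(3L, 0.15, 0.10),
       resnet152 = error_model_spec(2L, 0.10, 0.05),
       resnext101 = error_model_spec(2L, 0.12, 0.06))
}

perturb_mask <- function(mask, em) {
  out <- mask != 0
  if (em$boundary_jitter_px > 0L && any(out)) {
    k <- sample.int(em$boundary_jitter_px, 1L)
    brush <- EBImage::makeBrush(2L * k + 1L, "disc")
    out <- if (stats::runif(1) < 0.5) {
      EBImage::dilate(out + 0, brush) > 0
    } else {
      EBImage::erode(out + 0, brush) > 0
    }
  }
  if (em$miss_rate > 0 && any(out)) {
    lab <- label_components(out + 0)
    n <- attr(lab, "n")
    drop <- stats::runif(n) < em$miss_rate
    if (any(drop)) out[drop[pmax(lab, 1L)] & lab > 0L] <- FALSE
  }
  if (em$false_blob_rate > 0 && stats::runif(1) < em$false_blob_rate) {
    d <- dim(mask)
    rad <- sample(3:8, 1L)
    ctr <- c(stats::runif(1, rad + 1, d[1L] - rad),
             stats::runif(1, rad + 1, d[2L] - rad))
    gr <- plane_grids(d[1L])
    out <- out | ((gr$r - ctr[1L])^2 + (gr$c - ctr[2L])^2 <= rad^2)
  }
  out + 0
}

#' Generate four synthetic candidate-mask sequences from ground truth
#'
#' Applies each network's error model (boundary jitter, region misses,
#' false blobs) independently per network and per slice; deterministic
#' for a fixed seed. With all rates zero the output equals the ground
#' truth.
#'
#' @param gt list of binary ground-truth masks.
#' @param error_models list of 4 [error_model_spec()]s named as
#'   [fusion_network_ids].
#' @param seed integer seed.
#' @return list of 4 mask sequences (lists of matrices), named by
#'   network.
#' @export
generate_candidate_masks <- function(gt, error_models = default_error_models(),
                                     seed = 1L) {
  stopifnot(length(error_models) == 4L)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  out <- vector("list", 4L)
  names(out) <- fusion_network_ids
  for (j in seq_len(4L)) {
    set.seed((as.integer(seed) %% 100000L) * 13007L + j)
    em <- error_models[[j]]
    zero <- em$boundary_jitter_px == 0L && em$false_blob_rate == 0 &&
      em$miss_rate == 0
    out[[j]] <- lapply(gt, function(m) {
      if (zero) m + 0 else perturb_mask(m, em)
    })
  }
  out
}
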