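#' Specification for synthetic pathology volumes
#'
#' Generates a matched triple of 3D volumes at desk scale: a binary plaque
#' mask (spherical plaques, the amyloid/PFTAA channel), a binary tau mask
#' (cubic AT8-positive clusters) and an integer region-label volume (axis
#' order z, y, x; label 0 = background). `affinity` is the probability
#' that a tau cluster is seeded inside the dilated neighborhood of a
#' randomly chosen plaque (within `plaque_radius + affinity_radius` voxels
#' of its center), emulating plaque-associated tau; the remainder are
#' placed uniformly.
#'
#' @param shape integer vector (z, y, x), default `c(32, 64, 64)`.
#' @param n_regions number of labeled slab regions (>= 2), split along x.
#' @param plaque_count,plaque_radius number and radius (voxels) of plaques.
#' @param tau_count,tau_size number and cube side (voxels) of tau clusters.
#' @param affinity probability in \[0, 1\] of plaque-associated placement.
#' @param affinity_radius dilation radius defining "associated", voxels.
#' @param seed integer seed.
#' @return A list of class `pathology_spec`.
#' @seealso [simulate_pathology()]
#' @export
pathology_spec <- function(shape = c(32, 64, 64), n_regions = 2,
                           plaque_count = 20, plaque_radius = 3,
                           tau_count = 30, tau_size = 3, affinity = 0.5,
                           affinity_radius = 5, seed = 1) {
  if (length(shape) != 3 || any(shape < 1)) {
    abort("`shape` must be three positive voxel counts (z, y, x)")
  }
  assert_scalar_num(affinity, "affinity", 0, 1)
  assert_scalar_num(n_regions, "n_regions", lower = 2)
  assert_scalar_num(plaque_count, "plaque_count", lower = 0)
  assert_scalar_num(tau_count, "tau_count", lower = 0)
  structure(list(shape = as.integer(shape), n_regions = as.integer(n_regions),
                 plaque_count = as.integer(plaque_count),
                 plaque_radius = plaque_radius,
                 tau_count = as.integer(tau_count),
                 tau_size = as.integer(tau_size), affinity = affinity,
                 affinity_radius = affinity_radius, seed = seed),
            class = "pathology_spec")
}

# stamp value 1 into `vol` over a clipped box; returns list(vol, clipped)
stamp_box <- function(vol, lo, hi) {
  dims <- dim(vol)
  clo <- pmax(lo, 1L)
  chi <- pmin(hi, dims)
  clipped <- any(lo < 1L) || any(hi > dims)
  if (all(clo <= chi)) {
    vol[clo[1]:chi[1], clo[2]:chi[2], clo[3]:chi[3]] <- 1L
  }
  list(vol = vol, clipped = clipped)
}

stamp_ball <- function(vol, center, radius) {
  dims <- dim(vol)
  off <- ball_offsets(radius)
  pos <- sweep(off, 2, center, "+")
  keep <- pos[, 1] >= 1 & pos[, 1] <= dims[1] &
    pos[, 2] >= 1 & pos[, 2] <= dims[2] &
    pos[, 3] >= 1 & pos[, 3] <= dims[3]
  vol[pos[keep, , drop = FALSE]] <- 1L
  list(vol = vol, clipped = any(!keep))
}

#' Simulate plaque/tau masks and a region-label volume
#'
#' @param spec a [pathology_spec()].
#' @return A list with `plaque_mask`, `tau_mask` (binary 3D arrays),
#'   `regions` (a [labeled_volume()]) and `truth`, which records the exact
#'   per-region positive-voxel counts, the realized colocalized tau
#'   fraction (tau inside the `affinity_radius` dilation of the plaques),
#'   and a `clipped` counter for geometry clipped at the volume bounds.
#' @examples
#' sim <- simulate_pathology(pathology_spec(shape = c(16, 24, 24),
#'                                          plaque_count = 4, tau_count = 6))
#' sim$truth$colocalized_fraction
#' @export
simulate_pathology <- function(spec) {
  stopifnot(inherits(spec, "pathology_spec"))
  dims <- spec$shape
  with_seed(spec$seed, {
    # region slabs along x with a 1-voxel background border
    labels <- array(0L, dims)
    xs <- dims[3]
    cuts <- floor(seq(1, xs + 1, length.out = spec$n_regions + 1))
    for (r in seq_len(spec$n_regions)) {
      x0 <- max(2L, cuts[r])
      x1 <- min(xs - 1L, cuts[r + 1] - 1L)
      if (x0 <= x1 && dims[1] > 2 && dims[2] > 2) {
        labels[2:(dims[1] - 1), 2:(dims[2] - 1), x0:x1] <- r
      }
    }
    region_names <- setNames(paste0("region", seq_len(spec$n_regions)),
                             seq_len(spec$n_regions))

    clipped <- 0L
    plaque <- array(0L, dims)
    centers <- NULL
    if (spec$plaque_count > 0) {
      centers <- cbind(sample.int(dims[1], spec$plaque_count, TRUE),
                       sample.int(dims[2], spec$plaque_count, TRUE),
                       sample.int(dims[3], spec$plaque_count, TRUE))
      for (i in seq_len(spec$plaque_count)) {
        st <- stamp_ball(plaque, centers[i, ], spec$plaque_radius)
        plaque <- st$vol
        clipped <- clipped + st$clipped
      }
    }

    tau <- array(0L, dims)
    half <- (spec$tau_size - 1L) %/% 2L
    for (i in seq_len(spec$tau_count)) {
      near_plaque <- spec$plaque_count > 0 && runif(1) < spec$affinity
      if (near_plaque) {
        pc <- centers[sample.int(nrow(centers), 1), ]
        rmax <- spec$plaque_radius + spec$affinity_radius
        repeat {
          d <- round(runif(3, -rmax, rmax))
          if (sqrt(sum(d^2)) <= rmax) break
        }
        ctr <- pc + d
      } else {
        ctr <- c(sample.int(dims[1], 1), sample.int(dims[2], 1),
                 sample.int(dims[3], 1))
      }
      st <- stamp_box(tau, ctr - half, ctr - half + spec$tau_size - 1L)
      tau <- st$vol
      clipped <- clipped + st$clipped
    }

    regions <- labeled_volume(labels, region_names)
    per_region <- lapply(seq_len(spec$n_regions), function(r) {
      inr <- labels == r
      list(region = region_names[[as.character(r)]],
           n_voxels = sum(inr),
           plaque_voxels = sum(plaque[inr]),
           tau_voxels = sum(tau[inr]))
    })
    tau_total <- sum(tau)
    coloc <- if (tau_total > 0) {
      sum(tau & dilate_mask(plaque, spec$affinity_radius)) / tau_total
    } else 0
    list(plaque_mask = plaque, tau_mask = tau, regions = regions,
         truth = list(per_region = dplyr::bind_rows(per_region),
                      colocalized_fraction = coloc,
                      clipped = as.integer(clipped)))
  })
}
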