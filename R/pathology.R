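#' Region-label volume
#'
#' An integer 3D array (axis order z, y, x) of atlas region labels, with
#' label 0 reserved for background, plus a label -> region-name map (for
#' example hippocampal region, entorhinal area, isocortex, thalamus).
#'
#' @param voxels integer 3D array of labels.
#' @param label_names named character vector mapping label value (as name)
#'   to region name; defaults to `"region<label>"`.
#' @return An object of class `labeled_volume`.
#' @export
labeled_volume <- function(voxels, label_names = NULL) {
  if (length(dim(voxels)) != 3) abort("`voxels` must be a 3D array")
  if (any(voxels != round(voxels))) abort("labels must be integers")
  labs <- sort(setdiff(unique(as.integer(voxels)), 0L))
  if (is.null(label_names)) {
    label_names <- setNames(paste0("region", labs), labs)
  }
  structure(list(voxels = array(as.integer(voxels), dim(voxels)),
                 label_names = label_names),
            class = "labeled_volume")
}

#' @export
print.labeled_volume <- function(x, ...) {
  cat(sprintf("<labeled_volume> %s voxels (z,y,x); regions: %s\n",
              paste(dim(x$voxels), collapse = " x "),
              paste(x$label_names, collapse = ", ")))
  invisible(x)
}

check_binary_mask <- function(mask, name = "mask") {
  if (length(dim(mask)) != 3) abort(sprintf("`%s` must be a 3D array", name))
  if (!all(mask %in% c(0, 1))) {
    abort(sprintf("`%s` must be strictly binary (0/1)", name))
  }
  invisible(mask)
}

# Integer offsets (z, y, x) within Euclidean distance `radius` of the
# origin; the structuring element of the ball dilation.
ball_offsets <- function(radius) {
  r <- floor(radius)
  g <- expand.grid(dz = -r:r, dy = -r:r, dx = -r:r)
  g <- g[g$dz^2 + g$dy^2 + g$dx^2 <= radius^2, , drop = FALSE]
  as.matrix(g)
}

#' Binary dilation by a Euclidean ball
#'
#' Morphological dilation of a 3D binary mask with an isotropic ball
#' structuring element: an output voxel is positive iff any input-positive
#' voxel lies within Euclidean distance `radius` (in voxel units). This is
#' the operation that defines plaque-associated tau: tau voxels falling
#' inside the `radius`-voxel dilation of the segmented plaques. `radius =
#' 0` is the identity; the output is always a superset of the input.
#'
#' Anisotropy of the physical voxel size is deliberately ignored: the
#' boundary is defined in pixels, not micrometres.
#'
#' @param mask binary 3D array (z, y, x).
#' @param radius dilation radius in voxels (>= 0), default 5.
#' @return A binary 3D array of the same shape.
#' @examples
#' m <- array(0L, c(11, 11, 11)); m[6, 6, 6] <- 1L
#' sum(dilate_mask(m, 2))
#' @export
dilate_mask <- function(mask, radius = 5) {
  check_binary_mask(mask)
  assert_scalar_num(radius, "radius", lower = 0)
  if (radius == 0 || !any(mask == 1)) {
    return(array(as.integer(mask), dim(mask)))
  }
  dims <- dim(mask)
  out <- array(FALSE, dims)
  src <- mask == 1
  for (i in seq_len(nrow(off <- ball_offsets(radius)))) {
    dz <- off[i, 1]; dy <- off[i, 2]; dx <- off[i, 3]
    zs <- max(1, 1 + dz):min(dims[1], dims[1] + dz)
    ys <- max(1, 1 + dy):min(dims[2], dims[2] + dy)
    xs <- max(1, 1 + dx):min(dims[3], dims[3] + dx)
    out[zs, ys, xs] <- out[zs, ys, xs] | src[zs - dz, ys - dy, xs - dx]
  }
  array(as.integer(out), dims)
}

#' Regional pathology load (label ratio)
#'
#' The fraction of voxels of an atlas region that are mask-positive:
#' positive-and-in-region voxel count divided by the region's total voxel
#' count.
#'
#' @param mask binary 3D array.
#' @param regions a [labeled_volume()] of the same shape.
#' @param region_label integer label of the region.
#' @return A fraction in \[0, 1\].
#' @export
label_ratio <- function(mask, regions, region_label) {
  check_binary_mask(mask)
  stopifnot(inherits(regions, "labeled_volume"))
  if (!identical(dim(mask), dim(regions$voxels))) {
    abort("mask and region volume shapes differ")
  }
  inr <- regions$voxels == region_label
  n <- sum(inr)
  if (n == 0) abort(sprintf("region label %s has zero voxels", region_label))
  sum(mask[inr]) / n
}

#' Split tau load into plaque-associated and non-associated fractions
#'
#' Dilates the plaque mask by `radius` voxels; tau voxels inside the
#' dilated boundary count as plaque-associated, the rest as
#' non-associated. Loads are label ratios per region, computed with
#' integer voxel arithmetic so that `colocalized_load + noncolocalized_load
#' == load` exactly.
#'
#' @param tau,plaques binary 3D arrays of identical shape.
#' @param regions a [labeled_volume()] of the same shape.
#' @param radius dilation radius in voxels, default 5.
#' @return A tibble with one row per region: `region`, `marker`,
#'   `n_voxels`, `load`, `colocalized_load`, `noncolocalized_load`.
#' @export
split_colocalized <- function(tau, plaques, regions, radius = 5) {
  check_binary_mask(tau, "tau")
  check_binary_mask(plaques, "plaques")
  stopifnot(inherits(regions, "labeled_volume"))
  if (!identical(dim(tau), dim(plaques)) ||
      !identical(dim(tau), dim(regions$voxels))) {
    abort("tau, plaque and region volume shapes differ")
  }
  boundary <- dilate_mask(plaques, radius)
  assoc <- tau * boundary
  labs <- sort(setdiff(unique(as.integer(regions$voxels)), 0L))
  rows <- lapply(labs, function(l) {
    inr <- regions$voxels == l
    n <- sum(inr)
    tibble::tibble(
      region = regions$label_names[[as.character(l)]],
      marker = "AT8",
      n_voxels = n,
      load = sum(tau[inr]) / n,
      colocalized_load = sum(assoc[inr]) / n,
      noncolocalized_load = (sum(tau[inr]) - sum(assoc[inr])) / n
    )
  })
  dplyr::bind_rows(rows)
}

#' Pearson correlation between pathology loads
#'
#' Correlates two pooled load vectors (for example amyloid vs tau load
#' across animals, regions and timepoints) and reports the Pearson
#' coefficient with the two-sided p-value from the t transform on n - 2
#' degrees of freedom.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return A tibble with columns `r`, `p`, `n`.
#' @export
correlate_loads <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    abort("`x` and `y` must have equal length >= 3")
  }
  if (var(x) == 0 || var(y) == 0) {
    abort("zero variance in a load vector; correlation undefined")
  }
  ct <- cor.test(x, y, method = "pearson")
  tibble::tibble(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}
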