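#' Local thickness map
#'
#' At each foreground pixel, the diameter of the largest disk that lies
#' fully inside the foreground and contains that pixel — the standard
#' local-thickness definition used for fibre width estimation. Computed by
#' painting, for every foreground pixel, a disk of radius equal to its
#' Euclidean distance-to-background and taking the pixelwise maximum
#' diameter.
#'
#' @param mask logical or 0/1 matrix; foreground is `TRUE`/1.
#' @param pixel_size_um micrometres per pixel.
#' @return Numeric matrix of thickness in micrometres; 0 on background.
#' @export
local_thickness_map <- function(mask, pixel_size_um = 1) {
  m <- mask_to_int(mask)
  if (!any(m == 1L)) return(matrix(0, nrow(m), ncol(m)))
  dt <- as.matrix(EBImage::distmap(m))
  .cpp_local_thickness(m, dt) * pixel_size_um
}

mask_to_int <- function(mask) {
  if (is.logical(mask)) mask <- mask * 1L
  storage.mode(mask) <- "integer"
  mask
}

#' Skeletonize a binary mask
#'
#' Zhang-Suen thinning to a one-pixel-wide, 8-connected medial skeleton.
#'
#' @param mask logical or 0/1 matrix.
#' @return Logical matrix of skeleton pixels.
#' @export
skeletonize <- function(mask) {
  .cpp_thin(mask_to_int(mask)) == 1L
}

resolve_threshold <- function(x, threshold) {
  if (is.numeric(threshold)) return(list(value = threshold, mode = "fixed"))
  rng <- range(x)
  if (rng[1] == rng[2])
    return(list(value = rng[2], mode = "degenerate"))
  scaled <- (x - rng[1]) / (rng[2] - rng[1])
  t01 <- EBImage::otsu(EBImage::Image(scaled), range = c(0, 1))
  list(value = rng[1] + t01 * (rng[2] - rng[1]), mode = "otsu")
}

#' Three-class collagen fibre segmentation
#'
#' Segments an SHG channel into background, thin and thick collagen
#' fibres. Foreground pixels are those above an intensity threshold (Otsu
#' by default). The foreground is skeletonized; skeleton junction pixels
#' (more than two skeleton neighbours) split the skeleton into individual
#' fibre segments; the width of a fibre is the mean of twice the Euclidean
#' distance transform sampled along its skeleton — the average width along
#' its length. Fibres with mean width <= 10 um are thin, > 10 um thick
#' (the threshold is inclusive on the thin side), and every foreground
#' pixel inherits the class of its nearest skeleton segment.
#'
#' @param shg numeric intensity matrix (SHG channel).
#' @param pixel_size_um micrometres per pixel.
#' @param threshold `"otsu"` (default) or a fixed numeric intensity.
#' @param thin_max_um class boundary: mean fibre width <= this is thin.
#' @return A `fibre_class_mask`: list with `labels` (integer matrix, 0 =
#'   background, 1 = thin, 2 = thick), `thickness_um` (local-thickness
#'   raster, um), `fibre_table` (data.frame: fibre id, mean width um,
#'   class, pixel area), `mask`, `pixel_size_um`, and threshold
#'   provenance.
#' @export
segment_fibres <- function(shg, pixel_size_um, threshold = "otsu",
                           thin_max_um = 10) {
  stopifnot(is.matrix(shg), pixel_size_um > 0)
  thr <- resolve_threshold(shg, threshold)
  mask <- mask_to_int(shg > thr$value)
  out <- list(pixel_size_um = pixel_size_um,
              threshold = thr$value, threshold_mode = thr$mode,
              thin_max_um = thin_max_um)
  if (!any(mask == 1L)) {
    out$labels <- matrix(0L, nrow(shg), ncol(shg))
    out$thickness_um <- matrix(0, nrow(shg), ncol(shg))
    out$mask <- mask == 1L
    out$fibre_table <- data.frame(id = integer(0), width_um = numeric(0),
                                  class = character(0),
                                  n_pixels = integer(0))
    class(out) <- "fibre_class_mask"
    return(out)
  }
  dt <- as.matrix(EBImage::distmap(mask))
  thick_map <- .cpp_local_thickness(mask, dt) * pixel_size_um
  skel <- .cpp_thin(mask)
  # prune short spur branches (thinning artifacts) so junction splitting
  # below reflects real fibre crossings, not skeletonization noise
  n_prune <- ceiling(5 / pixel_size_um)
  for (i in seq_len(n_prune)) {
    ends <- skel == 1L & neighbour_count(skel) == 1L
    if (!any(ends)) break
    skel[ends] <- 0L
  }
  if (!any(skel == 1L)) skel <- .cpp_thin(mask)
  # junction pixels: skeleton pixels with > 2 skeleton neighbours
  nb <- neighbour_count(skel)
  segs <- skel
  segs[skel == 1L & nb > 2L] <- 0L
  seg_lab <- .cpp_label8(segs)
  # fibres whose whole skeleton was junction pixels keep a label
  orphan <- skel == 1L & seg_lab == 0L
  if (any(orphan)) {
    ol <- .cpp_label8(mask_to_int(orphan))
    seg_lab[orphan] <- max(seg_lab) + ol[orphan]
  }
  fibre_lab <- .cpp_propagate_labels(mask, seg_lab)

  sk_idx <- which(skel == 1L)
  widths <- tapply(2 * dt[sk_idx] * pixel_size_um, seg_lab[sk_idx], mean)
  ids <- as.integer(names(widths))
  cls <- ifelse(widths <= thin_max_um, "thin", "thick")
  area <- tabulate(fibre_lab[fibre_lab > 0L], nbins = max(ids))
  labels <- matrix(0L, nrow(shg), ncol(shg))
  cls_code <- integer(max(ids))
  cls_code[ids] <- ifelse(cls == "thin", 1L, 2L)
  fg <- fibre_lab > 0L
  labels[fg] <- cls_code[fibre_lab[fg]]
  # foreground pixels unreachable from any skeleton pixel: classify by
  # their own local thickness
  stray <- mask == 1L & fibre_lab == 0L
  labels[stray] <- ifelse(thick_map[stray] <= thin_max_um, 1L, 2L)

  out$labels <- labels
  out$thickness_um <- thick_map
  out$mask <- mask == 1L
  out$fibre_labels <- fibre_lab
  out$fibre_table <- data.frame(
    id = ids,
    width_um = as.numeric(widths),
    class = cls,
    n_pixels = area[ids],
    row.names = NULL
  )
  class(out) <- "fibre_class_mask"
  out
}

#' @export
print.fibre_class_mask <- function(x, ...) {
  n <- table(factor(x$fibre_table$class, levels = c("thin", "thick")))
  cat(sprintf(
    "fibre_class_mask: %d fibres (%d thin, %d thick), %.1f%% foreground\n",
    nrow(x$fibre_table), n["thin"], n["thick"],
    100 * mean(x$labels > 0L)))
  invisible(x)
}

# count of 8-neighbours that are foreground, per pixel
neighbour_count <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  p <- matrix(0L, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- m
  out <- matrix(0L, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    out <- out + p[(2:(nr + 1L)) + dr, (2:(nc + 1L)) + dc]
  }
  out
}

#' Detect nuclei in a nuclear-counterstain channel
#'
#' Gaussian smoothing, intensity thresholding (Otsu by default) and
#' connected-component analysis with an equivalent-diameter gate. One
#' centre is returned per accepted component; on the non-overlapping disk
#' nuclei rendered by [generate_section_image()] the count is exact.
#'
#' @param dapi numeric intensity matrix.
#' @param pixel_size_um micrometres per pixel.
#' @param diameter_range_um plausible nucleus diameter range (um).
#' @param threshold `"otsu"` or fixed numeric intensity.
#' @param smooth_sigma_um Gaussian smoothing scale; 0 disables.
#' @return data.frame with nucleus centres `x`, `y` (um) and `area_um2`.
#' @export
detect_nuclei <- function(dapi, pixel_size_um,
                          diameter_range_um = c(4, 10),
                          threshold = "otsu",
                          smooth_sigma_um = diameter_range_um[1] / 6) {
  stopifnot(is.matrix(dapi), pixel_size_um > 0,
            diameter_range_um[1] > 2 * pixel_size_um)
  img <- dapi
  if (smooth_sigma_um > 0)
    img <- as.matrix(EBImage::gblur(dapi,
                                    sigma = smooth_sigma_um /
                                      pixel_size_um))
  if (max(img) == min(img))
    return(data.frame(x = numeric(0), y = numeric(0),
                      area_um2 = numeric(0)))
  thr <- resolve_threshold(img, threshold)
  mask <- mask_to_int(img > thr$value)
  lab <- .cpp_label8(mask)
  if (max(lab) == 0L)
    return(data.frame(x = numeric(0), y = numeric(0),
                      area_um2 = numeric(0)))
  idx <- which(lab > 0L)
  rc <- arrayInd(idx, dim(lab))
  l <- lab[idx]
  area_px <- tabulate(l)
  cx <- tapply(rc[, 2], l, mean)
  cy <- tapply(rc[, 1], l, mean)
  d_eq <- 2 * sqrt(area_px / pi) * pixel_size_um
  keep <- d_eq >= 0.5 * diameter_range_um[1] &
    d_eq <= 1.5 * diameter_range_um[2]
  data.frame(
    x = px_x(as.numeric(cx), pixel_size_um)[keep],
    y = px_y(as.numeric(cy), pixel_size_um)[keep],
    area_um2 = (area_px * pixel_size_um^2)[keep],
    row.names = NULL
  )
}

#' Vessel mask from a COLIV channel
#'
#' Thresholds the collagen-IV channel within a dermal region; the stained
#' (vessel wall) area fraction of that region is the
#' percentage vessel density, computed downstream by [vessel_density()].
#'
#' @param coliv numeric intensity matrix.
#' @param pixel_size_um micrometres per pixel.
#' @param region rectangle `c(x0, y0, x1, y1)` in um, or a logical matrix
#'   of the same shape as `coliv`; must lie inside the image.
#' @param threshold `"otsu"` (computed within the region) or fixed numeric.
#' @return A list with `mask` (logical matrix, `TRUE` = vessel, `FALSE`
#'   outside the region), `region`, and threshold provenance, class
#'   `vessel_mask`.
#' @export
vessel_mask <- function(coliv, pixel_size_um, region, threshold = "otsu") {
  stopifnot(is.matrix(coliv), pixel_size_um > 0)
  reg <- region_to_mask(region, dim(coliv), pixel_size_um)
  vals <- coliv[reg]
  if (length(vals) == 0) stop("region is empty")
  if (min(vals) == max(vals)) {
    # degenerate region: uniformly zero -> empty; saturated -> full
    mk <- matrix(FALSE, nrow(coliv), ncol(coliv))
    mk[reg] <- vals[1] > 0
    return(structure(list(mask = mk, region = region,
                          threshold = NA_real_,
                          threshold_mode = "degenerate"),
                     class = "vessel_mask"))
  }
  thr <- resolve_threshold(vals, threshold)
  mk <- matrix(FALSE, nrow(coliv), ncol(coliv))
  mk[reg] <- coliv[reg] > thr$value
  structure(list(mask = mk, region = region, threshold = thr$value,
                 threshold_mode = thr$mode),
            class = "vessel_mask")
}

# region spec (rect in um or logical matrix) -> logical matrix
region_to_mask <- function(region, dims, pixel_size_um) {
  if (is.matrix(region)) {
    if (!is.logical(region) || !identical(dim(region), dims))
      stop("matrix `region` must be logical and match the image shape")
    return(region)
  }
  stopifnot(length(region) == 4)
  w_um <- dims[2] * pixel_size_um; h_um <- dims[1] * pixel_size_um
  if (region[1] < 0 || region[2] < 0 || region[3] > w_um + 1e-9 ||
      region[4] > h_um + 1e-9 || region[3] <= region[1] ||
      region[4] <= region[2])
    stop("region [", paste(region, collapse = ", "),
         "] um falls outside the image (",
         w_um, " x ", h_um, " um)")
  c0 <- max(1L, ceiling(um_to_col(region[1], pixel_size_um)))
  c1 <- min(dims[2], floor(um_to_col(region[3], pixel_size_um)))
  r0 <- max(1L, ceiling(um_to_row(region[2], pixel_size_um)))
  r1 <- min(dims[1], floor(um_to_row(region[4], pixel_size_um)))
  mk <- matrix(FALSE, dims[1], dims[2])
  mk[r0:r1, c0:c1] <- TRUE
  mk
}
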