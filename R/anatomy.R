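#' Classify a primary-dendrite orientation angle
#'
#' Angles are absolute values in \[0, 180\] degrees with 0 defined as
#' pointing exactly toward the IPL (perpendicular to it) and 180 pointing
#' away, toward the outer neuroblast layer (ONBL). The range is partitioned
#' into three classes: toward the IPL (`angle < low_cut`), tangential
#' (`low_cut <= angle <= high_cut`) and toward the ONBL
#' (`angle > high_cut`).
#'
#' @param angle_deg angle(s) in \[0, 180\].
#' @param low_cut,high_cut quadrant boundaries in degrees.
#' @return Factor with levels `IPL`, `TANGENTIAL`, `ONBL`.
#' @export
classify_dendrite_angle <- function(angle_deg, low_cut = 45, high_cut = 135) {
  if (any(!is.finite(angle_deg)) || any(angle_deg < 0 | angle_deg > 180))
    stop("angles must lie in [0, 180] degrees")
  stopifnot(0 < low_cut, low_cut < high_cut, high_cut < 180)
  out <- ifelse(angle_deg < low_cut, "IPL",
                ifelse(angle_deg <= high_cut, "TANGENTIAL", "ONBL"))
  factor(out, levels = c("IPL", "TANGENTIAL", "ONBL"))
}

#' Summarize dendrite orientations
#'
#' Category fractions plus a polar histogram of raw counts over \[0, 180\].
#'
#' @param angles_deg angles in \[0, 180\].
#' @param bin_width_deg histogram bin width.
#' @param ... passed to [classify_dendrite_angle()].
#' @return List with `fractions` (named, sums to 1), `n`, `histogram`
#'   (data frame `bin_lo`, `bin_hi`, `count`).
#' @export
orientation_summary <- function(angles_deg, bin_width_deg = 15, ...) {
  stopifnot(length(angles_deg) >= 1)
  cls <- classify_dendrite_angle(angles_deg, ...)
  frac <- as.numeric(table(cls)) / length(cls)
  names(frac) <- levels(cls)
  edges <- seq(0, 180, by = bin_width_deg)
  if (tail(edges, 1) < 180) edges <- c(edges, 180)
  counts <- tabulate(findInterval(angles_deg, edges,
                                  rightmost.closed = TRUE),
                     nbins = length(edges) - 1)
  list(fractions = frac, n = length(angles_deg),
       histogram = data.frame(bin_lo = head(edges, -1),
                              bin_hi = tail(edges, -1), count = counts))
}

#' Fluorescence intensity profile across the IPL
#'
#' Emulates the ROI measurement on a retinal cross-section: a vertical ROI
#' (default 12.5 um wide) perpendicular to the IPL strata, spanning the INL
#' border (0% depth) to the GCL border (100% depth). Intensity is averaged
#' across the ROI width at each depth, the background (minimum) subtracted,
#' and the result normalized to its maximum.
#'
#' @param image numeric matrix; rows are depth (row 1 = INL border, last row
#'   = GCL border), columns span the section laterally.
#' @param roi_cols columns of the ROI; default all columns.
#' @param roi_width_um physical ROI width, micrometers (metadata).
#' @return An `intensity_profile`: list with `depth_pct` (0 to 100),
#'   `intensity` (min 0, max 1), `roi_width_um`.
#' @export
ipl_profile <- function(image, roi_cols = NULL, roi_width_um = 12.5) {
  stopifnot(is.matrix(image), nrow(image) >= 2)
  if (is.null(roi_cols)) roi_cols <- seq_len(ncol(image))
  prof <- rowMeans(image[, roi_cols, drop = FALSE])
  prof <- prof - min(prof)
  if (max(prof) == 0) stop("flat ROI: profile has no contrast")
  intensity_profile(seq(0, 100, length.out = length(prof)),
                    prof / max(prof), roi_width_um)
}

#' @rdname ipl_profile
#' @param depth_pct depths in percent IPL (0 = INL border, 100 = GCL).
#' @param intensity intensities; re-normalized to min 0, max 1.
#' @export
intensity_profile <- function(depth_pct, intensity, roi_width_um = 12.5) {
  stopifnot(length(depth_pct) == length(intensity),
            !is.unsorted(depth_pct))
  intensity <- intensity - min(intensity)
  if (max(intensity) == 0) stop("flat profile")
  structure(list(depth_pct = as.numeric(depth_pct),
                 intensity = intensity / max(intensity),
                 roi_width_um = roi_width_um),
            class = "intensity_profile")
}

#' Locate fluorescence peaks in a depth profile
#'
#' Local maxima of the normalized profile above a prominence floor. A
#' plateau of equal maximal values counts as one peak located at the
#' plateau's center. Prominence of a local maximum is its height above the
#' higher of the two flanking minima separating it from higher ground (or
#' from the profile ends).
#'
#' @param p an `intensity_profile`.
#' @param min_prominence minimum prominence (profile is normalized to 1).
#' @return Numeric vector of peak depths in percent IPL (possibly empty),
#'   sorted by depth.
#' @export
find_peaks <- function(p, min_prominence = 0.1) {
  stopifnot(inherits(p, "intensity_profile"))
  lm <- local_maxima(p$intensity)
  if (nrow(lm) == 0) return(numeric(0))
  keep <- lm$prominence >= min_prominence
  if (!any(keep)) return(numeric(0))
  idx <- lm$index[keep]
  # fractional plateau-center index -> interpolated depth
  d <- p$depth_pct
  sort(vapply(idx, function(i) {
    lo <- floor(i); hi <- ceiling(i)
    if (lo == hi) d[i] else (d[lo] + d[hi]) / 2
  }, numeric(1)))
}

#' Distance between two stratification bands
#'
#' Absolute difference, in percent IPL depth, between the dominant peaks of
#' two profiles (e.g. two bipolar-cell bands).
#'
#' @param p_a,p_b `intensity_profile` objects.
#' @param ... passed to [find_peaks()].
#' @return Percent IPL depth.
#' @export
band_distance <- function(p_a, p_b, ...) {
  peak_of <- function(p) {
    pk <- find_peaks(p, ...)
    if (!length(pk)) stop("profile has no peak above the prominence floor")
    # dominant = highest; ties go to the first
    pk[which.max(vapply(pk, function(z) {
      p$intensity[which.min(abs(p$depth_pct - z))]
    }, numeric(1)))]
  }
  abs(peak_of(p_a) - peak_of(p_b))
}

#' Dendritic-field territory area from arbor tips
#'
#' The area of the simple polygon through a cell's dendritic tips: tips are
#' ordered by polar angle about their centroid (approximating tracing
#' nearest neighbor to nearest neighbor around the field) and the area is
#' computed by the shoelace formula.
#'
#' @param tips two-column matrix or data frame of tip coordinates,
#'   micrometers.
#' @return Area in um^2.
#' @export
arbor_territory_area <- function(tips) {
  tips <- as.matrix(tips)
  stopifnot(ncol(tips) == 2)
  if (nrow(tips) < 3) stop("need at least 3 tips to form a polygon")
  ctr <- colMeans(tips)
  o <- order(atan2(tips[, 2] - ctr[2], tips[, 1] - ctr[1]))
  a <- polygon_area(tips[o, , drop = FALSE])
  if (a == 0) stop("collinear tips: polygon has no area")
  a
}

#' Fraction of the field covered by a labeled plexus
#'
#' Thresholds a single-channel en-face image (Otsu's method by default, or a
#' fixed threshold), converts to binary and reports the percentage of pixels
#' in the foreground.
#'
#' @param image numeric matrix of intensities.
#' @param threshold `"otsu"` or a fixed numeric cut; pixels strictly above
#'   the cut are foreground.
#' @return Percent of field covered, in \[0, 100\].
#' @export
plexus_coverage <- function(image, threshold = "otsu") {
  stopifnot(is.matrix(image))
  rng <- range(image)
  if (diff(rng) == 0) stop("constant image: coverage undefined")
  if (identical(threshold, "otsu")) {
    scaled <- (image - rng[1]) / diff(rng)
    thr <- EBImage::otsu(scaled, range = c(0, 1))
    fg <- scaled > thr
  } else {
    stopifnot(is.numeric(threshold))
    fg <- image > threshold
  }
  mean(fg) * 100
}

#' Homotypic contact volume
#'
#' Scored dendritic-tip positions of labeled cells together with a binary
#' mask of the target population's somata/arbors, in a common voxel grid.
#'
#' @param tips integer matrix with columns x, y, z (1-based voxel indices).
#' @param target_mask 3-D logical array.
#' @param voxel_size_um physical voxel size (metadata).
#' @return An object of class `contact_volume`.
#' @export
contact_volume <- function(tips, target_mask, voxel_size_um = 0.5) {
  tips <- as.matrix(tips)
  stopifnot(ncol(tips) == 3, is.logical(target_mask),
            length(dim(target_mask)) == 3)
  d <- dim(target_mask)
  if (any(tips < 1) || any(tips[, 1] > d[1]) || any(tips[, 2] > d[2]) ||
      any(tips[, 3] > d[3]))
    stop("tips outside volume bounds")
  structure(list(tips = tips, target_mask = target_mask,
                 voxel_size_um = voxel_size_um),
            class = "contact_volume")
}

#' Homotypic contact rate and flipped-channel chance control
#'
#' `contact_rate()` reports the fraction of scored dendritic tips whose
#' voxel lies on the target population's soma/arbor mask (optionally within
#' a 1-voxel dilation, emulating confocal resolution).
#' `flipped_control()` recomputes the rate after flipping the target channel
#' about both in-plane axes — a negative control measuring how often the two
#' labels would interact by chance given their density and geometry.
#'
#' @param cv a [contact_volume()].
#' @param dilate 0 (direct voxel hit) or 1 (also count hits within the
#'   26-neighborhood).
#' @return `contact_rate()`: list with `rate_pct`, `n_contact`, `n_tips`.
#'   `flipped_control()`: the same for the flipped mask.
#' @export
contact_rate <- function(cv, dilate = 0) {
  stopifnot(inherits(cv, "contact_volume"), dilate %in% c(0, 1))
  mask <- cv$target_mask
  d <- dim(mask)
  hit_one <- function(t) {
    if (dilate == 0) return(mask[t[1], t[2], t[3]])
    xs <- max(1, t[1] - 1):min(d[1], t[1] + 1)
    ys <- max(1, t[2] - 1):min(d[2], t[2] + 1)
    zs <- max(1, t[3] - 1):min(d[3], t[3] + 1)
    any(mask[xs, ys, zs])
  }
  hits <- apply(cv$tips, 1, hit_one)
  list(rate_pct = mean(hits) * 100, n_contact = sum(hits),
       n_tips = nrow(cv$tips))
}

#' @rdname contact_rate
#' @export
flipped_control <- function(cv, dilate = 0) {
  stopifnot(inherits(cv, "contact_volume"))
  flipped <- cv$target_mask[dim(cv$target_mask)[1]:1,
                            dim(cv$target_mask)[2]:1, , drop = FALSE]
  contact_rate(contact_volume(cv$tips, flipped, cv$voxel_size_um),
               dilate = dilate)
}

#' Call laminar stratification of a single cell's depth profile
#'
#' Formalizes "ramified in a laminar pattern" for a single cell's arbor
#' intensity profile: the profile's dominant peak must fall within
#' `band_halfwidth_pct` of the reference band center, and at least
#' `min_band_fraction` of the total profile signal must lie inside that
#' band. Both knobs are reconstructions of a qualitative criterion and
#' should be reported alongside results.
#'
#' @param p an `intensity_profile` for the cell's arbor.
#' @param band_center_pct reference band depth, percent IPL.
#' @param band_halfwidth_pct half-width of the band, percent IPL.
#' @param min_band_fraction minimum fraction of total signal inside the
#'   band.
#' @param ... passed to [find_peaks()].
#' @return List with `stratified` (logical), `peak_pct`, `band_fraction`.
#' @export
stratification_call <- function(p, band_center_pct,
                                band_halfwidth_pct = 10,
                                min_band_fraction = 0.6, ...) {
  stopifnot(inherits(p, "intensity_profile"))
  pk <- find_peaks(p, ...)
  if (!length(pk))
    return(list(stratified = FALSE, peak_pct = NA_real_,
                band_fraction = NA_real_))
  dom <- pk[which.max(vapply(pk, function(z)
    p$intensity[which.min(abs(p$depth_pct - z))], numeric(1)))]
  in_band <- abs(p$depth_pct - band_center_pct) <= band_halfwidth_pct
  frac <- sum(p$intensity[in_band]) / sum(p$intensity)
  list(stratified = abs(dom - band_center_pct) <= band_halfwidth_pct &&
         frac >= min_band_fraction,
       peak_pct = dom, band_fraction = frac)
}

#' Projection-phenotype frequency table
#'
#' Per-group fractions of boolean projection phenotypes (IPL innervation,
#' laminar stratification, soma-layer projection, ...) with binomial
#' standard errors and group sizes.
#'
#' @param records data frame with one row per scored cell; boolean phenotype
#'   columns plus grouping columns.
#' @param group_by names of grouping columns (e.g. genotype, age).
#' @param fields names of the boolean columns to summarize; defaults to all
#'   logical columns.
#' @return Data frame with the grouping columns plus, per field, `n`,
#'   `<field>_frac` and `<field>_se`.
#' @export
projection_frequency_table <- function(records, group_by,
                                       fields = NULL) {
  stopifnot(is.data.frame(records), nrow(records) >= 1,
            all(group_by %in% names(records)))
  if (is.null(fields))
    fields <- names(records)[vapply(records, is.logical, logical(1))]
  stopifnot(length(fields) >= 1, all(fields %in% names(records)))
  if ("stratified" %in% fields && "innervates_ipl" %in% names(records) &&
      any(records$stratified & !records$innervates_ipl, na.rm = TRUE))
    stop("inconsistent records: stratified cells must innervate the IPL")
  key <- interaction(records[group_by], drop = TRUE, sep = " / ")
  rows <- lapply(levels(key), function(g) {
    sub <- records[key == g, , drop = FALSE]
    out <- sub[1, group_by, drop = FALSE]
    out$n <- nrow(sub)
    for (f in fields) {
      p <- mean(sub[[f]])
      out[[paste0(f, "_frac")]] <- p
      out[[paste0(f, "_se")]] <- sqrt(p * (1 - p) / nrow(sub))
    }
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Percent decrease relative to a reference
#'
#' `100 * (reference - value) / reference`; used e.g. to express mutant
#' plexus coverage relative to littermate controls.
#'
#' @param reference,value numeric.
#' @return Percent decrease (positive when `value < reference`).
#' @export
percent_decrease <- function(reference, value) {
  stopifnot(all(reference != 0))
  100 * (reference - value) / reference
}
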