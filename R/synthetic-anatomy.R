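#' Synthetic IPL depth profile
#'
#' Sum of Gaussian stratification bands on a uniform percent-depth grid,
#' plus optional Gaussian noise, normalized like a measured profile
#' (minimum subtracted, maximum scaled to 1).
#'
#' @param bands list of `c(center, width, amplitude)` triplets: band center
#'   in percent IPL depth (0-100), Gaussian SD in percent depth, amplitude.
#' @param noise_sd additive Gaussian noise SD (on the pre-normalized scale).
#' @param n_samples number of grid samples over 0-100%.
#' @param seed integer seed.
#' @return An `intensity_profile`.
#' @export
generate_ipl_profile <- function(bands, noise_sd = 0, n_samples = 201,
                                 seed = 1L) {
  stopifnot(length(bands) >= 1, n_samples >= 10)
  depth <- seq(0, 100, length.out = n_samples)
  y <- numeric(n_samples)
  for (b in bands) {
    stopifnot(length(b) == 3, b[1] >= 0, b[1] <= 100, b[2] > 0, b[3] > 0)
    y <- y + b[3] * exp(-(depth - b[1])^2 / (2 * b[2]^2))
  }
  if (noise_sd > 0)
    y <- y + with_seed(seed, rnorm(n_samples, 0, noise_sd))
  intensity_profile(depth, y)
}

## Separable Gaussian blur of a matrix (reflecting edges via zero padding of
## the kernel tails is acceptable here: the field is statistically uniform).
blur_matrix <- function(x, sd_px) {
  half <- ceiling(3 * sd_px)
  k <- dnorm(seq(-half, half), sd = sd_px)
  k <- k / sum(k)
  conv1 <- function(v) {
    padded <- c(rev(v[seq_len(half)]), v, rev(v[(length(v) - half + 1):length(v)]))
    as.numeric(stats::filter(padded, k, sides = 2))[(half + 1):(half + length(v))]
  }
  x <- apply(x, 2, conv1)
  t(apply(t(x), 2, conv1))
}

#' Synthetic plexus image with controlled coverage
#'
#' A binary en-face "dendritic plexus" image: smoothed Gaussian noise is
#' thresholded at the quantile that makes the foreground fraction equal
#' `coverage_target` (up to pixel rounding), then circular holes
#' (innervation gaps) are punched out. The coverage target applies before
#' holes; holes reduce the realized coverage by the hole area they remove.
#'
#' @param coverage_target foreground fraction in (0, 1) before holes.
#' @param hole_density expected holes per 10,000 px^2 (Poisson).
#' @param hole_radius_px hole radius in pixels.
#' @param size_px image side lengths `c(rows, cols)`.
#' @param smooth_sd_px correlation length of the plexus texture, pixels.
#' @param seed integer seed.
#' @return Binary (0/1) numeric matrix.
#' @export
generate_plexus_image <- function(coverage_target, hole_density = 0,
                                  hole_radius_px = 8, size_px = c(256, 256),
                                  smooth_sd_px = 3, seed = 1L) {
  stopifnot(coverage_target > 0, coverage_target < 1, hole_density >= 0)
  with_seed(seed, {
    field <- matrix(rnorm(prod(size_px)), size_px[1], size_px[2])
    field <- blur_matrix(field, smooth_sd_px)
    thr <- quantile(field, 1 - coverage_target)
    img <- (field > thr) * 1
    if (hole_density > 0) {
      n_holes <- rpois(1, hole_density * prod(size_px) / 1e4)
      if (n_holes > 0) {
        cx <- runif(n_holes, 1, size_px[1])
        cy <- runif(n_holes, 1, size_px[2])
        rows <- matrix(seq_len(size_px[1]), size_px[1], size_px[2])
        cols <- matrix(seq_len(size_px[2]), size_px[1], size_px[2],
                       byrow = TRUE)
        for (h in seq_len(n_holes)) {
          img[(rows - cx[h])^2 + (cols - cy[h])^2 <= hole_radius_px^2] <- 0
        }
      }
    }
    img
  })
}

#' Synthetic contact volume with known hit fraction
#'
#' Builds a 3-D target mask (a box or a ball) and places exactly
#' `round(hit_fraction * n_tips)` dendritic tips on target voxels, the rest
#' on background voxels, so the true contact rate is known by construction.
#'
#' @param n_tips number of scored tips.
#' @param hit_fraction fraction of tips on the target, in \[0, 1\].
#' @param dims volume dimensions `c(nx, ny, nz)`.
#' @param target_geometry list: `type` (`"box"` or `"ball"`) plus `lo`/`hi`
#'   corners (box) or `center`/`radius` (ball), in voxel units.
#' @param seed integer seed.
#' @return A [contact_volume()] with attribute `n_hit` (the placed count).
#' @export
generate_contact_volume <- function(n_tips, hit_fraction,
                                    dims = c(64, 64, 16),
                                    target_geometry = list(
                                      type = "box",
                                      lo = round(dims * 0.25),
                                      hi = round(dims * 0.6)),
                                    seed = 1L) {
  stopifnot(n_tips >= 1, hit_fraction >= 0, hit_fraction <= 1)
  gx <- seq_len(dims[1]); gy <- seq_len(dims[2]); gz <- seq_len(dims[3])
  mask <- array(FALSE, dims)
  if (target_geometry$type == "box") {
    lo <- pmax(target_geometry$lo, 1); hi <- pmin(target_geometry$hi, dims)
    mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
  } else if (target_geometry$type == "ball") {
    ctr <- target_geometry$center; r <- target_geometry$radius
    dist2 <- outer(outer((gx - ctr[1])^2, (gy - ctr[2])^2, `+`),
                   (gz - ctr[3])^2, `+`)
    mask[dist2 <= r^2] <- TRUE
  } else stop("unknown target geometry: ", target_geometry$type)
  on_idx <- which(mask); off_idx <- which(!mask)
  if (!length(on_idx) || !length(off_idx))
    stop("target geometry must leave both target and background voxels")
  n_hit <- round(hit_fraction * n_tips)
  tips_idx <- with_seed(seed, c(
    sample(on_idx, n_hit, replace = n_hit > length(on_idx)),
    sample(off_idx, n_tips - n_hit,
           replace = (n_tips - n_hit) > length(off_idx))))
  tips <- arrayInd(tips_idx, dims)
  cv <- contact_volume(tips, mask)
  attr(cv, "n_hit") <- n_hit
  cv
}
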