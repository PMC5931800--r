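#' Construct a mosaic point pattern
#'
#' @param x,y coordinates in micrometers.
#' @param bounds field rectangle `c(xmin, ymin, xmax, ymax)` in micrometers.
#' @param soma_radius_um nominal soma radius, micrometers (metadata).
#' @return An object of class `mosaic_pattern`.
#' @export
mosaic_pattern <- function(x, y, bounds, soma_radius_um = 4) {
  stopifnot(length(x) == length(y), length(bounds) == 4,
            bounds[3] > bounds[1], bounds[4] > bounds[2])
  if (any(x < bounds[1] | x > bounds[3] | y < bounds[2] | y > bounds[4]))
    stop("points outside bounds")
  if (anyDuplicated(cbind(x, y))) stop("duplicate points in pattern")
  structure(list(x = as.numeric(x), y = as.numeric(y),
                 bounds = as.numeric(bounds),
                 soma_radius_um = soma_radius_um),
            class = "mosaic_pattern")
}

#' @export
print.mosaic_pattern <- function(x, ...) {
  a <- (x$bounds[3] - x$bounds[1]) * (x$bounds[4] - x$bounds[2])
  cat("mosaic_pattern:", length(x$x), "cells in",
      paste(round(x$bounds), collapse = "x"), "um field (",
      signif(length(x$x) / a * 1e6, 4), "cells/mm^2 )\n")
  invisible(x)
}

#' Generate a synthetic cell-body mosaic
#'
#' Three point processes of decreasing regularity:
#' * `lattice_jitter` — hexagonal lattice at the target density with
#'   isotropic Gaussian positional jitter (`jitter_sd`);
#' * `hardcore` — sequential random placement rejecting candidates closer
#'   than `d_min` to an accepted point (the density-matched random null used
#'   for real mosaics; `d_min` defaults to a soma diameter of 8 um);
#' * `poisson` — uniform placement with no exclusion (`d_min` forced to 0).
#'
#' @param process `"lattice_jitter"`, `"hardcore"` or `"poisson"`.
#' @param density cells per mm^2.
#' @param bounds field rectangle `c(xmin, ymin, xmax, ymax)`, micrometers.
#' @param d_min hard-core exclusion distance, micrometers.
#' @param jitter_sd lattice jitter SD, micrometers.
#' @param seed integer seed; identical arguments and seed reproduce the
#'   pattern exactly.
#' @param max_tries_per_point rejection budget for the hard-core process; an
#'   error is raised when the packing is too dense to place the requested
#'   count.
#' @return A [mosaic_pattern()].
#' @export
generate_mosaic <- function(process = c("lattice_jitter", "hardcore",
                                        "poisson"),
                            density, bounds = c(0, 0, 500, 500),
                            d_min = 8, jitter_sd = 2, seed = 1L,
                            max_tries_per_point = 500) {
  process <- match.arg(process)
  stopifnot(density > 0, d_min >= 0, jitter_sd >= 0)
  w <- bounds[3] - bounds[1]; h <- bounds[4] - bounds[2]
  area_um2 <- w * h
  n_target <- round(density * 1e-6 * area_um2)
  if (n_target < 10) stop("density x area must give at least 10 cells")
  with_seed(seed, {
    if (process == "poisson") {
      x <- runif(n_target, bounds[1], bounds[3])
      y <- runif(n_target, bounds[2], bounds[4])
    } else if (process == "hardcore") {
      x <- numeric(n_target); y <- numeric(n_target)
      placed <- 0L
      tries <- 0L
      budget <- max_tries_per_point * n_target
      while (placed < n_target) {
        tries <- tries + 1L
        if (tries > budget)
          stop("hard-core packing too dense: placed ", placed, " of ",
               n_target, " points within the retry budget")
        cx <- runif(1, bounds[1], bounds[3])
        cy <- runif(1, bounds[2], bounds[4])
        if (placed == 0L ||
            min((x[seq_len(placed)] - cx)^2 +
                (y[seq_len(placed)] - cy)^2) >= d_min^2) {
          placed <- placed + 1L
          x[placed] <- cx; y[placed] <- cy
        }
      }
    } else { # lattice_jitter: hexagonal lattice at target density
      a <- sqrt(2 / (sqrt(3) * density * 1e-6)) # lattice constant, um
      dy <- a * sqrt(3) / 2
      ys <- seq(bounds[2] + dy / 2, bounds[4], by = dy)
      pts <- do.call(rbind, lapply(seq_along(ys), function(i) {
        off <- if (i %% 2 == 0) a / 2 else 0
        xs <- seq(bounds[1] + a / 2 + off, bounds[3], by = a)
        cbind(xs, ys[i])
      }))
      x <- pts[, 1] + rnorm(nrow(pts), 0, jitter_sd)
      y <- pts[, 2] + rnorm(nrow(pts), 0, jitter_sd)
      keep <- x >= bounds[1] & x <= bounds[3] &
        y >= bounds[2] & y <= bounds[4]
      x <- x[keep]; y <- y[keep]
    }
  })
  mosaic_pattern(x, y, bounds)
}

## Clip a convex polygon (matrix of vertices, counter-clockwise) by the
## half-plane {p : a . p <= b} (Sutherland-Hodgman step).
clip_halfplane <- function(poly, a, b) {
  n <- nrow(poly)
  if (n == 0) return(poly)
  val <- poly %*% a - b
  inside <- val <= 1e-12
  if (all(inside)) return(poly)
  if (!any(inside)) return(poly[0, , drop = FALSE])
  out <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    if (inside[i]) out <- rbind(out, poly[i, ])
    if (xor(inside[i], inside[j])) {
      t <- val[i] / (val[i] - val[j])
      out <- rbind(out, poly[i, ] + t * (poly[j, ] - poly[i, ]))
    }
  }
  out
}

polygon_area <- function(poly) {
  n <- nrow(poly)
  if (n < 3) return(0)
  x <- poly[, 1]; y <- poly[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

## Voronoi cell of point i, clipped to the bounding rectangle: start from
## the rectangle and cut with the perpendicular bisector towards each other
## point. Neighbors are visited nearest-first; once a point is farther than
## twice the cell's maximal vertex distance its bisector cannot cut.
voronoi_cell <- function(i, x, y, bounds) {
  poly <- cbind(c(bounds[1], bounds[3], bounds[3], bounds[1]),
                c(bounds[2], bounds[2], bounds[4], bounds[4]))
  px <- x[i]; py <- y[i]
  d2 <- (x - px)^2 + (y - py)^2
  ord <- order(d2)
  ord <- ord[ord != i]
  for (j in ord) {
    max_r2 <- max((poly[, 1] - px)^2 + (poly[, 2] - py)^2)
    if (d2[j] > 4 * max_r2) break
    a <- c(x[j] - px, y[j] - py)
    b <- sum(a * c((px + x[j]) / 2, (py + y[j]) / 2))
    poly <- clip_halfplane(poly, a, b)
    if (nrow(poly) < 3) break
  }
  poly
}

#' Voronoi domains and regularity index of a mosaic
#'
#' Assigns a Voronoi domain to every cell, excludes cells whose domain
#' touches the field boundary (their true domain extends beyond the imaged
#' field), and computes the Voronoi domain regularity index
#' VDRI = mean(domain area) / sd(domain area) over the interior cells.
#' Less regular arrays have more variable domains, hence a lower VDRI.
#'
#' @param m a [mosaic_pattern()].
#' @param vdri_cap sentinel returned (with `degenerate = TRUE`) when the
#'   interior areas have zero spread, e.g. a perfect lattice.
#' @param edge_tol distance (micrometers) within which a domain vertex is
#'   considered to touch the boundary.
#' @return A `voronoi_result`: list with `areas_um2` (interior domain
#'   areas), `is_edge` (logical per cell), `vdri`, `degenerate`,
#'   `density_mm2` (all cells over field area), `n_interior`, `polygons`
#'   (list of vertex matrices, all cells).
#' @export
voronoi_domains <- function(m, vdri_cap = 1e6, edge_tol = 1e-7) {
  stopifnot(inherits(m, "mosaic_pattern"))
  n <- length(m$x)
  if (n < 4) stop("too few points for a tessellation")
  b <- m$bounds
  polys <- lapply(seq_len(n), function(i) voronoi_cell(i, m$x, m$y, b))
  is_edge <- vapply(polys, function(p) {
    nrow(p) < 3 ||
      any(p[, 1] <= b[1] + edge_tol | p[, 1] >= b[3] - edge_tol |
          p[, 2] <= b[2] + edge_tol | p[, 2] >= b[4] - edge_tol)
  }, logical(1))
  areas_all <- vapply(polys, polygon_area, numeric(1))
  areas <- areas_all[!is_edge]
  if (length(areas) < 2)
    stop("fewer than 2 interior cells: VDRI undefined")
  s <- sd(areas)
  degenerate <- s < .Machine$double.eps^0.5 * mean(areas)
  vdri <- if (degenerate) vdri_cap else mean(areas) / s
  area_mm2 <- (b[3] - b[1]) * (b[4] - b[2]) * 1e-6
  structure(list(areas_um2 = areas, areas_all_um2 = areas_all,
                 is_edge = is_edge, vdri = vdri, degenerate = degenerate,
                 density_mm2 = n / area_mm2, n_interior = length(areas),
                 polygons = polys),
            class = "voronoi_result")
}

#' @export
print.voronoi_result <- function(x, ...) {
  cat("voronoi_result:", x$n_interior, "interior cells (",
      sum(x$is_edge), "edge-excluded ), VDRI",
      signif(x$vdri, 4), if (x$degenerate) "(degenerate: capped)" else "",
      "\n")
  invisible(x)
}

#' Density-matched random null for the regularity index
#'
#' Simulates hard-core random arrays matched in density (and exclusion
#' radius) to an observed mosaic and scores each with the VDRI, defining the
#' regularity expected of a randomly arranged array of the same cells.
#'
#' @param density cells per mm^2.
#' @param bounds field rectangle, micrometers.
#' @param d_min hard-core exclusion distance, micrometers (0 for a pure
#'   Poisson null).
#' @param n_sims number of simulated arrays.
#' @param seed integer seed.
#' @param probs quantiles reported for the envelope.
#' @return List with `vdri` (one per simulation), `mean`, `quantiles`.
#' @export
random_null <- function(density, bounds = c(0, 0, 500, 500), d_min = 8,
                        n_sims = 99, seed = 1L,
                        probs = c(0.025, 0.5, 0.975, 0.99)) {
  stopifnot(n_sims >= 1)
  v <- vapply(seq_len(n_sims), function(k) {
    m <- generate_mosaic("hardcore", density = density, bounds = bounds,
                         d_min = d_min, seed = derive_seed(seed, k))
    voronoi_domains(m)$vdri
  }, numeric(1))
  list(vdri = v, mean = mean(v), quantiles = quantile(v, probs))
}

#' Per-animal mosaic summary
#'
#' Averages the VDRI and cell density over the fields imaged from one
#' animal (unweighted), the unit entering group comparisons.
#'
#' @param fields list of `voronoi_result` objects (one per image).
#' @return List with `mean_vdri`, `mean_density_mm2`, `n_fields`.
#' @export
per_animal_summary <- function(fields) {
  stopifnot(length(fields) >= 1,
            all(vapply(fields, inherits, logical(1), "voronoi_result")))
  list(mean_vdri = mean(vapply(fields, `[[`, numeric(1), "vdri")),
       mean_density_mm2 = mean(vapply(fields, `[[`, numeric(1),
                                      "density_mm2")),
       n_fields = length(fields))
}

#' Outcome rate by Voronoi territory size
#'
#' Bins interior cells by Voronoi domain ("territory") area and reports the
#' fraction of a per-cell binary outcome (e.g. an ectopic projection error)
#' in each bin, with exact binomial confidence intervals. Default bins are
#' 100 um^2 wide with open-ended first (`< first_closed`) and last
#' (`> last_closed`) bins.
#'
#' @param vres a `voronoi_result`.
#' @param outcome logical vector aligned with the *interior* cells (i.e.
#'   `length(vres$areas_um2)`).
#' @param bin_width_um2 interior bin width.
#' @param first_closed,last_closed edges of the open-ended extreme bins.
#' @param conf_level confidence level of the per-bin intervals.
#' @return Data frame per nonempty bin: `bin_lo`, `bin_hi`, `label`, `n`,
#'   `n_true`, `rate`, `ci_lo`, `ci_hi`. Empty bins are omitted (missing,
#'   not zero).
#' @export
territory_bin_analysis <- function(vres, outcome, bin_width_um2 = 100,
                                   first_closed = 200, last_closed = 1100,
                                   conf_level = 0.95) {
  stopifnot(inherits(vres, "voronoi_result"),
            length(outcome) == length(vres$areas_um2),
            is.logical(outcome))
  breaks <- c(-Inf, seq(first_closed, last_closed, by = bin_width_um2), Inf)
  bin <- findInterval(vres$areas_um2, breaks)
  rows <- lapply(sort(unique(bin)), function(k) {
    in_bin <- bin == k
    nt <- sum(outcome[in_bin]); nn <- sum(in_bin)
    ci <- binom.test(nt, nn, conf.level = conf_level)$conf.int
    lo <- breaks[k]; hi <- breaks[k + 1]
    lab <- if (!is.finite(lo)) paste0("<", hi)
           else if (!is.finite(hi)) paste0(">", lo)
           else paste0(lo, "-", hi)
    data.frame(bin_lo = lo, bin_hi = hi, label = lab, n = nn, n_true = nt,
               rate = nt / nn, ci_lo = ci[1], ci_hi = ci[2])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
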