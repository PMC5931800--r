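#' Read and write spike-response tables
#'
#' A `spike_response_set` is serialized as a long-form CSV (columns
#' `cell_id`, `direction_deg`, `contrast_pct`, `speed_um_s`, `trial`,
#' `spike_time_s`) plus a JSON sidecar (`<path>.json`) holding the protocol
#' and the cell roster, so that cells and conditions with no spikes
#' round-trip losslessly.
#'
#' @param rs a `spike_response_set`.
#' @param path CSV path; the sidecar is written next to it.
#' @return `write_spike_table()` returns `path` invisibly;
#'   `read_spike_table()` returns a `spike_response_set` (without truth).
#' @export
write_spike_table <- function(rs, path) {
  stopifnot(inherits(rs, "spike_response_set"))
  write.csv(rs$spikes, path, row.names = FALSE)
  side <- list(protocol = unclass(rs$protocol), cells = rs$cells)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_spike_table
#' @export
read_spike_table <- function(path) {
  spikes <- read.csv(path, stringsAsFactors = FALSE)
  spikes$cell_id <- as.character(spikes$cell_id)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pr <- do.call(stimulus_protocol, side$protocol[
    c("directions", "contrasts", "n_trials", "bar_speed_um_s",
      "bar_width_um", "trial_duration_s")])
  spike_response_set(spikes, pr, cells = as.character(side$cells))
}

#' Read and write mosaic point tables
#'
#' Points as a two-column CSV (`x_um`, `y_um`) with a JSON sidecar for the
#' field bounds and soma radius.
#'
#' @param m a [mosaic_pattern()].
#' @param path CSV path.
#' @return `write_mosaic()` returns `path` invisibly; `read_mosaic()` a
#'   [mosaic_pattern()].
#' @export
write_mosaic <- function(m, path) {
  stopifnot(inherits(m, "mosaic_pattern"))
  write.csv(data.frame(x_um = m$x, y_um = m$y), path, row.names = FALSE)
  jsonlite::write_json(list(bounds = m$bounds,
                            soma_radius_um = m$soma_radius_um),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_mosaic
#' @export
read_mosaic <- function(path) {
  pts <- read.csv(path)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  mosaic_pattern(pts$x_um, pts$y_um, side$bounds, side$soma_radius_um)
}
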