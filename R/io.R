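#' Write / read a resistor mesh as CSV
#'
#' Plain-text grid exchange format: one row per resistor with columns
#' `resistor_id`, `orientation` ("h"/"v"), `k`, `j`, `ohms`, plus the grid
#' side and extent recoverable from the rows themselves.
#'
#' @param grid An `eit_grid`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_grid_csv <- function(grid, path) {
  stopifnot(inherits(grid, "eit_grid"))
  tab <- resistor_table(grid)
  out <- tab[, c("resistor_id", "orientation", "k", "j", "ohms")]
  out$extent_mm <- grid$extent_mm
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_grid_csv
#' @export
read_grid_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("resistor_id", "orientation", "k", "j", "ohms")
  if (!all(need %in% names(tab))) {
    stop("grid CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  s <- max(tab$k[tab$orientation == "h"])
  if (nrow(tab) != num_resistors(s)) {
    stop("grid CSV row count does not match a complete ", s, "-node mesh",
         call. = FALSE)
  }
  extent <- if ("extent_mm" %in% names(tab)) tab$extent_mm[1] else 130
  tab <- tab[order(tab$resistor_id), ]
  grid_from_vector(tab$ohms, s, extent)
}

#' Write / read a measurement frame as CSV
#'
#' Columns: `pattern_id`, `source_electrode`, `sink_electrode`,
#' `meas_electrode_a`, `meas_electrode_b`, `voltage_volts`, `frequency_khz`.
#'
#' @param frame An `eit_frame`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_frame_csv <- function(frame, path) {
  stopifnot(inherits(frame, "eit_frame"))
  out <- data.frame(pattern_id = frame$pattern,
                    source_electrode = frame$source,
                    sink_electrode = frame$sink,
                    meas_electrode_a = frame$meas_a,
                    meas_electrode_b = frame$meas_b,
                    voltage_volts = sprintf("%.17g", frame$voltage),
                    frequency_khz = attr(frame, "frequency_khz"))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_frame_csv
#' @param s,ground,amplitude_A Mesh metadata to re-attach on read (the CSV
#'   stores only the measurements themselves).
#' @export
read_frame_csv <- function(path, s = 26L, ground = default_ground(s),
                           amplitude_A = 0.015) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("pattern_id", "source_electrode", "sink_electrode",
            "meas_electrode_a", "meas_electrode_b", "voltage_volts")
  if (!all(need %in% names(tab))) {
    stop("measurement CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  freq <- if ("frequency_khz" %in% names(tab)) tab$frequency_khz[1] else 1
  new_frame(data.frame(pattern = tab$pattern_id,
                       source = tab$source_electrode,
                       sink = tab$sink_electrode,
                       meas_a = tab$meas_electrode_a,
                       meas_b = tab$meas_electrode_b,
                       voltage = as.numeric(tab$voltage_volts)),
            frequency_khz = freq, amplitude_A = amplitude_A,
            s = check_grid_side(s), ground = as.integer(ground))
}

#' Write a tomogram as CSV (and optionally PNG)
#'
#' The CSV holds the normalized pixel matrix (no header), row 1 the top
#' template row, so downstream checks stay image-library independent. When
#' `png_path` is given the image is also rendered to PNG via the standard
#' graphics device.
#'
#' @param tomo An `eit_tomogram`.
#' @param path CSV output path.
#' @param png_path Optional PNG output path.
#' @return `path`, invisibly.
#' @export
write_tomogram <- function(tomo, path, png_path = NULL) {
  stopifnot(inherits(tomo, "eit_tomogram"))
  utils::write.table(tomo$pixels, path, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  if (!is.null(png_path)) {
    grDevices::png(png_path, width = 600, height = 600)
    on.exit(grDevices::dev.off())
    plot(tomo)
  }
  invisible(path)
}
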