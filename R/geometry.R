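#' Build a linear tetrode-array electrode layout
#'
#' Constructs the recording-site map of a flexible gut-wall implant: a linear
#' array of tetrodes (groups of 4 closely spaced microelectrodes) laid out
#' along one axis, optionally flanked by large marker electrodes that carry no
#' recording role. Each tetrode is a square of side `within_spacing`, so the
#' four nearest-neighbour distances inside a tetrode equal `within_spacing`
#' and the two diagonals equal `within_spacing * sqrt(2)`. Consecutive tetrode
#' centers sit `between_spacing` apart along the array (x) axis, with the
#' origin at the first tetrode center.
#'
#' @param n_tetrodes Number of tetrodes (>= 1). The standard device uses 7,
#'   giving 28 recording sites.
#' @param within_spacing Side of the tetrode square, in micrometers
#'   (default 50).
#' @param between_spacing Distance between consecutive tetrode centers along
#'   the array axis, in micrometers (default 250).
#' @param site_diameter Diameter of each recording site, in micrometers
#'   (default 20).
#' @param n_markers Number of large marker electrodes to append (default 4,
#'   two flanking each end of the array). Markers have `role = "marker"` and
#'   are excluded from recording-site operations.
#' @param marker_diameter Diameter of marker electrodes, micrometers
#'   (default 200).
#'
#' @return An object of class `electrode_layout`: a data.frame with one row
#'   per site and columns `site_id`, `tetrode_id` (NA for markers), `x`, `y`
#'   (micrometers), `diameter`, `role` (`"recording"` or `"marker"`), plus
#'   attributes `within_spacing`, `between_spacing` and `n_tetrodes`.
#' @export
#' @examples
#' lay <- build_tetrode_layout(7)
#' sum(lay$role == "recording")  # 28
build_tetrode_layout <- function(n_tetrodes = 7, within_spacing = 50,
                                 between_spacing = 250, site_diameter = 20,
                                 n_markers = 4, marker_diameter = 200) {
  if (!is.numeric(n_tetrodes) || length(n_tetrodes) != 1 || n_tetrodes < 1 ||
      n_tetrodes != round(n_tetrodes)) {
    stop("`n_tetrodes` must be a positive integer")
  }
  if (within_spacing <= 0 || between_spacing <= 0 || site_diameter <= 0) {
    stop("geometry spacings and diameters must be positive")
  }
  if (n_markers < 0 || n_markers != round(n_markers)) {
    stop("`n_markers` must be a non-negative integer")
  }

  h <- within_spacing / 2
  # square corners, counter-clockwise from lower-left
  corner_x <- c(-h, h, h, -h)
  corner_y <- c(-h, -h, h, h)

  tet <- rep(seq_len(n_tetrodes), each = 4L)
  cx <- (tet - 1L) * between_spacing
  rec <- data.frame(
    site_id = seq_len(4L * n_tetrodes),
    tetrode_id = tet,
    x = cx + rep(corner_x, n_tetrodes),
    y = rep(corner_y, n_tetrodes),
    diameter = site_diameter,
    role = "recording",
    stringsAsFactors = FALSE
  )

  layout <- rec
  if (n_markers > 0) {
    span <- (n_tetrodes - 1L) * between_spacing
    # markers alternate left/right of the array, stepping outwards
    k <- seq_len(n_markers)
    side <- ifelse(k %% 2 == 1, -1, 1)
    step <- between_spacing * ceiling(k / 2)
    mx <- ifelse(side < 0, -step, span + step)
    markers <- data.frame(
      site_id = 4L * n_tetrodes + k,
      tetrode_id = NA_integer_,
      x = mx,
      y = 0,
      diameter = marker_diameter,
      role = "marker",
      stringsAsFactors = FALSE
    )
    layout <- rbind(rec, markers)
  }

  structure(layout,
    within_spacing = within_spacing,
    between_spacing = between_spacing,
    n_tetrodes = as.integer(n_tetrodes),
    class = c("electrode_layout", "data.frame")
  )
}

#' @export
print.electrode_layout <- function(x, ...) {
  cat(sprintf(
    "<electrode_layout> %d tetrodes (%d recording sites, %d markers), %g um within / %g um between\n",
    attr(x, "n_tetrodes"), sum(x$role == "recording"),
    sum(x$role == "marker"), attr(x, "within_spacing"),
    attr(x, "between_spacing")
  ))
  print.data.frame(utils::head(as.data.frame(x), 8), ...)
  if (nrow(x) > 8) cat(sprintf("... %d more sites\n", nrow(x) - 8))
  invisible(x)
}

#' Pairwise distance between two sites of a layout
#' @noRd
site_distance <- function(layout, a, b) {
  ia <- match(a, layout$site_id)
  ib <- match(b, layout$site_id)
  sqrt((layout$x[ia] - layout$x[ib])^2 + (layout$y[ia] - layout$y[ib])^2)
}

#' Recording sites within a radius of a center site
#'
#' Returns the recording sites whose center-to-center distance from
#' `center_site` is strictly less than `radius`, excluding the center site
#' itself and any marker electrodes. The strict inequality mirrors the
#' "within < r" neighbourhood convention used for spike detectability around
#' a microelectrode.
#'
#' @param layout An `electrode_layout`.
#' @param center_site A `site_id` present in `layout`.
#' @param radius Neighbourhood radius in micrometers (> 0).
#' @return Integer vector of neighbouring `site_id`s (possibly empty).
#' @export
recording_neighborhood <- function(layout, center_site, radius) {
  stopifnot(inherits(layout, "electrode_layout"))
  if (!is.numeric(radius) || length(radius) != 1 || radius <= 0) {
    stop("`radius` must be a positive number")
  }
  ic <- match(center_site, layout$site_id)
  if (is.na(ic)) stop(sprintf("unknown site_id: %s", center_site))
  d <- sqrt((layout$x - layout$x[ic])^2 + (layout$y - layout$y[ic])^2)
  keep <- layout$role == "recording" & d < radius &
    layout$site_id != center_site
  layout$site_id[keep]
}

#' Write / read a layout as a plain-text site table
#'
#' One row per site with columns id, tetrode, x, y, diameter, role --
#' the common probe-map table shape.
#'
#' @param layout An `electrode_layout`.
#' @param path File path for the tab-separated site table.
#' @return `write_layout` returns `path` invisibly; `read_layout` returns an
#'   `electrode_layout`.
#' @export
write_layout <- function(layout, path) {
  stopifnot(inherits(layout, "electrode_layout"))
  hdr <- sprintf("# within_spacing=%g between_spacing=%g n_tetrodes=%d",
                 attr(layout, "within_spacing"),
                 attr(layout, "between_spacing"),
                 attr(layout, "n_tetrodes"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(as.data.frame(layout), con, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_layout
#' @export
read_layout <- function(path) {
  hdr <- readLines(path, n = 1)
  kv <- regmatches(hdr, gregexpr("[a-z_]+=[0-9.]+", hdr))[[1]]
  vals <- as.numeric(sub(".*=", "", kv))
  names(vals) <- sub("=.*", "", kv)
  df <- utils::read.table(path, header = TRUE, sep = "\t", skip = 1,
                          stringsAsFactors = FALSE)
  structure(df,
    within_spacing = unname(vals["within_spacing"]),
    between_spacing = unname(vals["between_spacing"]),
    n_tetrodes = as.integer(vals["n_tetrodes"]),
    class = c("electrode_layout", "data.frame")
  )
}
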