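# Plain-text readers/writers.  Tabular data travels as CSV with units in
# the header names; structured results and metadata as JSON.  Numeric
# columns are serialized with 17 significant digits so every file
# round-trips through its reader bit-exactly.

fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) NA_character_ else sprintf("%.17g", v)
  }, character(1))
  out
}

write_csv_exact <- function(df, path) {
  out <- df
  for (nm in names(out)) {
    if (is.double(out[[nm]])) out[[nm]] <- fmt_num(out[[nm]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
}

#' Write / read a tissue pO2 grid as CSV
#'
#' Columns `x_um,y_um,z_um,po2_mmHg` (plus any distance/region columns
#' present).  Numeric values keep full double precision.
#'
#' @param grid a `tissue_grid` or its points data frame.
#' @param path output CSV path.
#' @return `read_tissue_grid` returns the points data frame.
#' @export
write_tissue_grid <- function(grid, path) {
  write_csv_exact(grid_points(grid), path)
  invisible(path)
}

#' @rdname write_tissue_grid
#' @export
read_tissue_grid <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (nm in names(df)) if (is.integer(df[[nm]])) df[[nm]] <- as.numeric(df[[nm]])
  df
}

#' Write / read a vessel graph as JSON
#'
#' @param graph a [vessel_graph()].
#' @param path output JSON path.
#' @return `read_vessel_graph` returns a `vessel_graph`.
#' @export
write_vessel_graph <- function(graph, path) {
  segs <- lapply(graph$segments, function(s)
    list(type = s$type, radius_um = s$radius_um,
         points = unname(as.matrix(s$points))))
  jsonlite::write_json(segs, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_vessel_graph
#' @export
read_vessel_graph <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  segs <- lapply(seq_len(nrow(raw)), function(i) {
    p <- raw$points[[i]]
    if (!is.matrix(p)) p <- matrix(unlist(p), ncol = 3, byrow = TRUE)
    list(type = raw$type[i], radius_um = raw$radius_um[i], points = p)
  })
  vessel_graph(segs)
}

#' Write / read a decay trace as CSV
#'
#' Columns `t_us,counts`; `n_cycles` goes in a comment-free companion
#' column so the file stays plain CSV.
#'
#' @param trace a `decay_trace`.
#' @param path output CSV path.
#' @return `read_decay_trace` returns a `decay_trace` (without truth).
#' @export
write_decay_trace <- function(trace, path) {
  df <- data.frame(t_us = trace$t_us, counts = trace$counts,
                   n_cycles = rep(trace$n_cycles, length(trace$t_us)))
  write_csv_exact(df, path)
  invisible(path)
}

#' @rdname write_decay_trace
#' @export
read_decay_trace <- function(path) {
  df <- utils::read.csv(path)
  structure(list(t_us = df$t_us, counts = df$counts,
                 n_cycles = df$n_cycles[1], truth = NULL),
            class = "decay_trace")
}

#' Write / read a space-time image (CSV matrix + JSON sidecar)
#'
#' The pixel matrix goes to `<path>` as a headerless CSV (rows = space);
#' pixel size, line period and orientation go to `<path>.json`.
#'
#' @param st a `spacetime_image`.
#' @param path output CSV path.
#' @return `read_spacetime_image` returns a `spacetime_image`
#'   (without truth).
#' @export
write_spacetime_image <- function(st, path) {
  utils::write.table(matrix(fmt_num(st$img), nrow(st$img)), path,
                     sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  jsonlite::write_json(list(dx_um = st$dx_um, line_period_s = st$line_period_s,
                            orientation = st$orientation),
                       paste0(path, ".json"), digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_spacetime_image
#' @export
read_spacetime_image <- function(path) {
  img <- as.matrix(utils::read.csv(path, header = FALSE))
  dimnames(img) <- NULL
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(list(img = img, dx_um = meta$dx_um,
                 line_period_s = meta$line_period_s,
                 orientation = meta$orientation, truth = NULL),
            class = "spacetime_image")
}

#' Write / read a velocity volume (long CSV + JSON sidecar)
#'
#' Voxels are written in long form (`ix,iy,iz,v_mm_s`, 1-based indices),
#' zeros omitted; geometry goes to `<path>.json`.
#'
#' @param vv a `velocity_volume`.
#' @param path output CSV path.
#' @return `read_velocity_volume` returns a `velocity_volume`
#'   (without truth).
#' @export
write_velocity_volume <- function(vv, path) {
  nz <- which(vv$v != 0)
  dm <- dim(vv$v)
  ix <- ((nz - 1L) %% dm[1]) + 1L
  iy <- (((nz - 1L) %/% dm[1]) %% dm[2]) + 1L
  iz <- ((nz - 1L) %/% (dm[1] * dm[2])) + 1L
  write_csv_exact(data.frame(ix = ix, iy = iy, iz = iz, v_mm_s = vv$v[nz]), path)
  jsonlite::write_json(list(dim = dm, voxel_xy_um = vv$voxel_xy_um,
                            voxel_z_um = vv$voxel_z_um, field_um = vv$field_um),
                       paste0(path, ".json"), digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_velocity_volume
#' @export
read_velocity_volume <- function(path) {
  df <- utils::read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  v <- array(0, dim = meta$dim)
  v[cbind(df$ix, df$iy, df$iz)] <- df$v_mm_s
  structure(list(v = v, voxel_xy_um = meta$voxel_xy_um[1],
                 voxel_z_um = meta$voxel_z_um[1],
                 field_um = meta$field_um[1], truth = NULL),
            class = "velocity_volume")
}
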