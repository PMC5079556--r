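#' Read an ESRI ASCII grid
#'
#' Parses the plain-text `.asc` raster format: a six-line header
#' (`ncols`, `nrows`, `xllcorner`/`xllcenter`, `yllcorner`/`yllcenter`,
#' `cellsize`, optional `NODATA_value`) followed by `nrows` rows of
#' values, north row first.  No projection handling is attempted; grids
#' intended to be combined must already be co-registered.
#'
#' @param path Path to the `.asc` file.
#' @return A list with `data` (numeric matrix, row 1 = north),
#'   `xllcorner`, `yllcorner`, `cellsize` and `nodata_value`
#'   (`NA` if the header declares none); nodata cells are `NA` in
#'   `data`.
#' @seealso [write_esri_ascii()]
#' @export
read_esri_ascii <- function(path) {
  if (!file.exists(path))
    stop("raster file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- list()
  i <- 1L
  repeat {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    key <- tolower(parts[1])
    if (!(key %in% c("ncols", "nrows", "xllcorner", "yllcorner",
                     "xllcenter", "yllcenter", "cellsize",
                     "nodata_value"))) break
    hdr[[key]] <- as.numeric(parts[2])
    i <- i + 1L
  }
  for (req in c("ncols", "nrows", "cellsize"))
    if (is.null(hdr[[req]]))
      stop("malformed ESRI ASCII header: missing ", req, call. = FALSE)
  ncols <- as.integer(hdr$ncols); nrows <- as.integer(hdr$nrows)
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != nrows * ncols)
    stop(sprintf("expected %d values, found %d", nrows * ncols,
                 length(vals)), call. = FALSE)
  data <- matrix(vals, nrows, ncols, byrow = TRUE)
  nodata <- if (is.null(hdr$nodata_value)) NA_real_ else hdr$nodata_value
  if (!is.na(nodata)) data[data == nodata] <- NA_real_
  list(data = data,
       xllcorner = if (!is.null(hdr$xllcorner)) hdr$xllcorner else
                   if (!is.null(hdr$xllcenter)) hdr$xllcenter else 0,
       yllcorner = if (!is.null(hdr$yllcorner)) hdr$yllcorner else
                   if (!is.null(hdr$yllcenter)) hdr$yllcenter else 0,
       cellsize = hdr$cellsize,
       nodata_value = nodata)
}

#' Write an ESRI ASCII grid
#'
#' @param data Numeric matrix, row 1 = north; `NA` entries are written
#'   as the nodata value.
#' @param path Output path.
#' @param xllcorner,yllcorner Coordinates of the lower-left corner.
#' @param cellsize Cell side in map units.
#' @param nodata_value Value standing in for `NA`.
#' @param digits Significant digits retained (values round-trip to this
#'   precision; the default is full double precision).
#' @export
write_esri_ascii <- function(data, path, xllcorner = 0, yllcorner = 0,
                             cellsize = 1, nodata_value = -9999,
                             digits = 17) {
  stopifnot(is.matrix(data))
  out <- data
  out[is.na(out)] <- nodata_value
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(data)),
    sprintf("nrows %d", nrow(data)),
    sprintf("xllcorner %.10g", xllcorner),
    sprintf("yllcorner %.10g", yllcorner),
    sprintf("cellsize %.10g", cellsize),
    sprintf("NODATA_value %.10g", nodata_value)), con)
  chr <- matrix(sprintf("%.*g", digits, out), nrow(out))
  writeLines(apply(chr, 1, paste, collapse = " "), con)
  invisible(path)
}

#' Write a landscape layer as an ESRI ASCII grid
#'
#' @param grid A [landscape_grid].
#' @param path Output path.
#' @param layer Which per-cell layer to export (e.g. `"emptiness"`,
#'   `"elevation"`, `"burn_state"`).
#' @export
write_grid <- function(grid, path, layer = "emptiness") {
  if (is.null(grid[[layer]]) || !is.matrix(grid[[layer]]))
    stop("grid has no numeric layer `", layer, "`", call. = FALSE)
  cellsize <- if (is.na(grid$cell_side)) 1 else grid$cell_side
  write_esri_ascii(grid[[layer]] + 0, path, cellsize = cellsize)
}

#' Assemble a full-model landscape from three co-registered rasters
#'
#' Reads elevation (meters), vegetation-type category codes and
#' vegetation-density category codes from three ESRI ASCII grids of
#' identical shape and cell size, maps the category codes onto the
#' effect values of `params`, and returns a full-model grid with
#' absorbing boundaries.  Cells that are nodata in any raster (or carry
#' the dedicated non-fuel code) are flagged non-flammable and take no
#' part in fire spread.
#'
#' @param elevation_path,type_path,density_path Paths to the three
#'   rasters.
#' @param params [ca_params()] providing the effect tables and cell side
#'   (the raster `cellsize` overrides `params$cell_side` when they
#'   disagree, with a warning).
#' @param type_codes,density_codes Named character vectors mapping raster
#'   integer codes (as names) to category labels of the corresponding
#'   effect table, e.g. `c("1" = "agricultural", "2" = "other",
#'   "3" = "pine")`.
#' @param nonfuel_code Optional numeric code marking bare/non-fuel cells
#'   in the type raster.
#' @return A full-model [landscape_grid].
#' @export
read_landscape_rasters <- function(elevation_path, type_path, density_path,
                                   params = ca_params(),
                                   type_codes = c("1" = "agricultural",
                                                  "2" = "other",
                                                  "3" = "pine"),
                                   density_codes = c("1" = "sparse",
                                                     "2" = "moderate",
                                                     "3" = "dense"),
                                   nonfuel_code = 0) {
  stopifnot_params(params)
  elev <- read_esri_ascii(elevation_path)
  type <- read_esri_ascii(type_path)
  dens <- read_esri_ascii(density_path)
  dims <- vapply(list(elev, type, dens), function(r) dim(r$data), integer(2))
  if (any(dims != dims[, 1]))
    stop("co-registration error: raster dimensions differ (",
         paste(apply(dims, 2, paste, collapse = "x"), collapse = " vs "),
         ")", call. = FALSE)
  sizes <- c(elev$cellsize, type$cellsize, dens$cellsize)
  if (max(sizes) - min(sizes) > 1e-9 * max(sizes))
    stop("co-registration error: raster cell sizes differ", call. = FALSE)
  origins <- rbind(c(elev$xllcorner, elev$yllcorner),
                   c(type$xllcorner, type$yllcorner),
                   c(dens$xllcorner, dens$yllcorner))
  if (any(abs(sweep(origins, 2, origins[1, ])) > 1e-6 * sizes[1]))
    stop("co-registration error: raster origins differ", call. = FALSE)

  cell_side <- sizes[1]
  if (!is.na(params$cell_side) &&
      abs(cell_side - params$cell_side) > 1e-9 * cell_side)
    warning("raster cellsize (", cell_side, " m) overrides params$cell_side (",
            params$cell_side, " m)")

  nr <- nrow(elev$data); nc <- ncol(elev$data)
  flammable <- !is.na(elev$data) & !is.na(type$data) & !is.na(dens$data)
  if (!is.null(nonfuel_code))
    flammable <- flammable & !(!is.na(type$data) & type$data == nonfuel_code)

  map_codes <- function(codes, mapping, table, what) {
    lab <- matrix(NA_character_, nr, nc)
    eff <- matrix(NA_real_, nr, nc)
    sel <- flammable
    seen <- unique(codes[sel])
    unknown <- setdiff(as.character(seen), names(mapping))
    if (length(unknown))
      stop("mapping error: unknown ", what, " code(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    lab[sel] <- mapping[as.character(codes[sel])]
    bad <- setdiff(unique(lab[sel]), names(table))
    if (length(bad))
      stop("mapping error: ", what, " categor(ies) missing from effect ",
           "table: ", paste(bad, collapse = ", "), call. = FALSE)
    eff[sel] <- table[lab[sel]]
    list(lab = lab, eff = eff)
  }
  ty <- map_codes(type$data, type_codes, params$type_effects, "type")
  de <- map_codes(dens$data, density_codes, params$density_effects,
                  "density")

  elev_filled <- elev$data
  elev_filled[is.na(elev_filled)] <- mean(elev$data, na.rm = TRUE)

  new_landscape(
    "full", nr, nc, boundary = "absorbing", cell_side = cell_side,
    layers = list(type_effect = ty$eff, density_effect = de$eff,
                  elevation = elev_filled, flammable = flammable,
                  type_cat = ty$lab, density_cat = de$lab))
}

#' Write an 8-bit grayscale image as plain PGM
#'
#' Plain (P2, ASCII) portable graymap: a text format readable by most
#' image tools.  Values outside `[0, 255]` are clamped.
#'
#' @param values Numeric matrix of gray levels (row 1 = top).
#' @param path Output path (conventionally `.pgm`).
#' @export
write_pgm <- function(values, path) {
  stopifnot(is.matrix(values))
  v <- round(values)
  v[v < 0] <- 0; v[v > 255] <- 255
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", sprintf("%d %d", ncol(v), nrow(v)), "255"), con)
  writeLines(apply(v, 1, paste, collapse = " "), con)
  invisible(path)
}

#' Read a plain (P2) PGM image
#'
#' @param path Path to the image.
#' @return Integer matrix of gray levels.
#' @export
read_pgm <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^#", lines)]
  toks <- scan(text = paste(lines[-1], collapse = "\n"), quiet = TRUE)
  if (!identical(trimws(lines[1]), "P2"))
    stop("not a plain (P2) PGM file: ", path, call. = FALSE)
  nc <- toks[1]; nr <- toks[2]
  matrix(as.integer(toks[-(1:3)]), nr, nc, byrow = TRUE)
}
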