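#' Hexagonal spot grid
#'
#' Container for a Visium-style hexagonal spot array. Spots live on an
#' offset-row hex lattice: `trans_y` is the array row, `trans_x` the array
#' column, and within one row all columns share parity (odd rows use odd
#' columns, even rows even columns), so horizontally adjacent spots differ
#' by 2 in `trans_x`. `transresolution` is the physical size of one grid
#' unit in micrometres; with the standard 100 um spot pitch it is 100.
#'
#' @param barcode character vector of unique spot identifiers.
#' @param trans_x integer array-column indices (>= 0).
#' @param trans_y integer array-row indices (>= 0).
#' @param in_tissue logical, whether the spot overlaps tissue.
#' @param transresolution micrometres per grid unit (> 0); the spot pitch.
#' @param spot_diameter spot diameter in micrometres, carried as metadata
#'   (it parameterizes the default pixel-matching radius downstream, not
#'   the coordinate conversion).
#' @return An object of class `spot_grid`: a data frame with columns
#'   `barcode`, `trans_x`, `trans_y`, `in_tissue` and attributes
#'   `transresolution`, `spot_diameter`.
#' @export
spot_grid <- function(barcode, trans_x, trans_y,
                      in_tissue = rep(TRUE, length(barcode)),
                      transresolution = 100, spot_diameter = 55) {
  barcode <- as.character(barcode)
  if (anyDuplicated(barcode)) {
    stop("duplicate spot barcodes: ",
         paste(unique(barcode[duplicated(barcode)]), collapse = ", "))
  }
  .check_indices(trans_x, barcode, "trans_x")
  .check_indices(trans_y, barcode, "trans_y")
  if (!is.numeric(transresolution) || length(transresolution) != 1L ||
      !is.finite(transresolution) || transresolution <= 0) {
    stop("transresolution must be a single positive number (micrometres)")
  }
  # hex offset encoding: within a row, columns share parity
  for (row in unique(trans_y)) {
    par <- unique(trans_x[trans_y == row] %% 2)
    if (length(par) > 1L) {
      stop("mixed trans_x parity within array row ", row,
           ": not a valid hex offset grid")
    }
  }
  out <- data.frame(barcode = barcode,
                    trans_x = as.integer(trans_x),
                    trans_y = as.integer(trans_y),
                    in_tissue = as.logical(in_tissue),
                    stringsAsFactors = FALSE)
  structure(out,
            transresolution = transresolution,
            spot_diameter = spot_diameter,
            class = c("spot_grid", "data.frame"))
}

.check_indices <- function(idx, barcode, what) {
  bad <- !is.finite(idx) | idx < 0 | idx != round(idx)
  if (any(bad)) {
    stop(what, " must be non-negative integers; offending barcode(s): ",
         paste(utils::head(barcode[bad], 5L), collapse = ", "))
  }
  invisible(TRUE)
}

#' @export
print.spot_grid <- function(x, ...) {
  cat(sprintf("spot_grid: %d spots (%d in tissue), pitch %g um, spot %g um\n",
              nrow(x), sum(x$in_tissue),
              attr(x, "transresolution"), attr(x, "spot_diameter")))
  invisible(x)
}

#' MSI pixel raster
#'
#' Container for mass-spectrometry-imaging ion images: a rectangular pixel
#' raster with an intensity matrix over an ordered m/z axis. `metaresolution`
#' is the raster step in micrometres (100 for the standard DESI acquisition).
#'
#' @param meta_x,meta_y integer pixel column/row indices; pairs must be
#'   unique.
#' @param mz_values strictly increasing m/z values (Da).
#' @param intensity numeric pixel-by-m/z matrix of non-negative intensities.
#' @param metaresolution micrometres per pixel step (> 0).
#' @param pixel_id optional pixel identifiers; default `px<k>`.
#' @param mz_range instrument mass range metadata (Da); m/z values outside
#'   it are rejected.
#' @return An object of class `msi_raster`: a list with elements `pixels`
#'   (data frame `pixel_id`, `meta_x`, `meta_y`), `mz_values`, `intensity`,
#'   and attributes `metaresolution`, `mz_range`.
#' @export
msi_raster <- function(meta_x, meta_y, mz_values, intensity,
                       metaresolution = 100, pixel_id = NULL,
                       mz_range = c(70, 1200)) {
  n <- length(meta_x)
  if (length(meta_y) != n) stop("meta_x and meta_y lengths differ")
  if (is.null(pixel_id)) pixel_id <- sprintf("px%d", seq_len(n))
  pixel_id <- as.character(pixel_id)
  key <- paste(meta_x, meta_y, sep = ",")
  if (anyDuplicated(key)) {
    stop("duplicate (meta_x, meta_y) pixel coordinates: ",
         paste(utils::head(unique(key[duplicated(key)]), 5L), collapse = "; "))
  }
  .check_indices(meta_x, pixel_id, "meta_x")
  .check_indices(meta_y, pixel_id, "meta_y")
  if (!is.numeric(metaresolution) || length(metaresolution) != 1L ||
      !is.finite(metaresolution) || metaresolution <= 0) {
    stop("metaresolution must be a single positive number (micrometres)")
  }
  mz_values <- as.numeric(mz_values)
  if (is.unsorted(mz_values, strictly = TRUE)) {
    stop("mz_values must be strictly increasing")
  }
  if (any(mz_values < mz_range[1] | mz_values > mz_range[2])) {
    stop(sprintf("m/z values outside the instrument range [%g, %g] Da",
                 mz_range[1], mz_range[2]))
  }
  intensity <- as.matrix(intensity)
  if (nrow(intensity) != n || ncol(intensity) != length(mz_values)) {
    stop("intensity must be a pixels x m/z matrix (",
         n, " x ", length(mz_values), ")")
  }
  if (any(!is.finite(intensity)) || any(intensity < 0)) {
    stop("intensities must be finite and non-negative")
  }
  dimnames(intensity) <- list(pixel_id, format(mz_values, trim = TRUE))
  structure(list(pixels = data.frame(pixel_id = pixel_id,
                                     meta_x = as.integer(meta_x),
                                     meta_y = as.integer(meta_y),
                                     stringsAsFactors = FALSE),
                 mz_values = mz_values,
                 intensity = intensity),
            metaresolution = metaresolution,
            mz_range = mz_range,
            class = "msi_raster")
}

#' @export
print.msi_raster <- function(x, ...) {
  cat(sprintf("msi_raster: %d pixels x %d m/z, step %g um, m/z %.4f-%.4f\n",
              nrow(x$pixels), length(x$mz_values),
              attr(x, "metaresolution"),
              min(x$mz_values), max(x$mz_values)))
  invisible(x)
}

#' Convert hex array indices to unified physical coordinates
#'
#' Maps each spot of the hexagonal array into the unified micrometre frame:
#' `x = (trans_x / 2 + 0.5) * transresolution`,
#' `y = trans_y * sqrt(0.75) * transresolution`.
#' The division by 2 undoes the parity-offset column encoding and the
#' `sqrt(0.75)` row spacing is the height of an equilateral triangle of
#' unit side, so all six hex neighbours of an interior spot lie at exactly
#' one pitch. The constant +0.5 shifts every spot uniformly and cancels in
#' registration.
#'
#' @param grid a [spot_grid].
#' @return A data frame of class `physical_points` with columns `id`
#'   (barcode), `x`, `y` (micrometres) and attribute `frame = "ST_unified"`,
#'   one row per spot in input order.
#' @export
hex_to_physical <- function(grid) {
  stopifnot(inherits(grid, "spot_grid"))
  res <- attr(grid, "transresolution")
  physical_points(id = grid$barcode,
                  x = (grid$trans_x / 2 + 0.5) * res,
                  y = grid$trans_y * sqrt(0.75) * res,
                  frame = "ST_unified")
}

#' Convert MSI raster indices to unified physical coordinates
#'
#' `x = meta_x * metaresolution`, `y = meta_y * metaresolution`: the raster
#' is square with the pixel step as the unit.
#'
#' @param raster an [msi_raster].
#' @return A `physical_points` data frame (`id`, `x`, `y`) in the
#'   `MSI_unified` frame, one row per pixel in input order.
#' @export
msi_to_physical <- function(raster) {
  stopifnot(inherits(raster, "msi_raster"))
  res <- attr(raster, "metaresolution")
  physical_points(id = raster$pixels$pixel_id,
                  x = raster$pixels$meta_x * res,
                  y = raster$pixels$meta_y * res,
                  frame = "MSI_unified")
}

#' Construct a set of physical points
#'
#' @param id point identifiers.
#' @param x,y coordinates in micrometres; must be finite.
#' @param frame `"ST_unified"` or `"MSI_unified"`.
#' @return data frame with class `physical_points` and a `frame` attribute.
#' @export
physical_points <- function(id, x, y, frame = c("ST_unified", "MSI_unified")) {
  frame <- match.arg(frame)
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("physical coordinates must be finite")
  }
  structure(data.frame(id = as.character(id), x = as.numeric(x),
                       y = as.numeric(y), stringsAsFactors = FALSE),
            frame = frame,
            class = c("physical_points", "data.frame"))
}

# ---------------------------------------------------------------------------
# readers

#' Read a Visium-style tissue_positions table
#'
#' Accepts both Space Ranger dialects: the headered `tissue_positions.csv`
#' (`barcode,in_tissue,array_row,array_col,pxl_row_in_fullres,
#' pxl_col_in_fullres`) and the older header-less `tissue_positions_list.csv`
#' with the same column order. The full-resolution pixel columns are
#' optional: tables with only `barcode,in_tissue,array_row,array_col` are
#' accepted. The header is auto-detected from the first field. `array_col`
#' is taken as the raw parity-offset hex column (`trans_x`), `array_row`
#' as `trans_y`; with the default 100 um `transresolution` this reproduces
#' the 100 um spot pitch.
#'
#' @param path CSV file path.
#' @param transresolution micrometres per grid unit (default 100).
#' @param spot_diameter spot diameter metadata in micrometres (default 55).
#' @param in_tissue_only keep only spots flagged in tissue (default TRUE).
#' @return a [spot_grid].
#' @export
read_tissue_positions <- function(path, transresolution = 100,
                                  spot_diameter = 55, in_tissue_only = TRUE) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("^\"?barcode", first, ignore.case = TRUE)
  df <- utils::read.csv(path, header = has_header,
                        stringsAsFactors = FALSE)
  if (!has_header) {
    nm <- c("barcode", "in_tissue", "array_row", "array_col",
            "pxl_row_in_fullres", "pxl_col_in_fullres")
    names(df) <- nm[seq_len(ncol(df))]
  }
  names(df) <- tolower(names(df))
  need <- c("barcode", "in_tissue", "array_row", "array_col")
  if (!all(need %in% names(df))) {
    stop("tissue positions file must provide columns: ",
         paste(need, collapse = ", "))
  }
  if (in_tissue_only) df <- df[df$in_tissue == 1 | df$in_tissue == TRUE, ]
  spot_grid(barcode = df$barcode,
            trans_x = df$array_col,
            trans_y = df$array_row,
            in_tissue = df$in_tissue == 1 | df$in_tissue == TRUE,
            transresolution = transresolution,
            spot_diameter = spot_diameter)
}

#' Read MSI ion images from long-format CSV
#'
#' Expects columns `x,y,mz,intensity` (pixel column index, pixel row index,
#' m/z in Da, intensity). Every pixel must report the same m/z list; missing
#' combinations are treated as zero intensity.
#'
#' @param path CSV file path.
#' @param metaresolution micrometres per pixel step (default 100).
#' @param mz_range instrument mass range (Da).
#' @return an [msi_raster].
#' @export
read_msi_csv <- function(path, metaresolution = 100, mz_range = c(70, 1200)) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  need <- c("x", "y", "mz", "intensity")
  if (!all(need %in% names(df))) {
    stop("long-format MSI CSV must have columns x, y, mz, intensity")
  }
  mz <- sort(unique(df$mz))
  key <- paste(df$x, df$y, sep = ",")
  ukey <- unique(key)
  px <- do.call(rbind, strsplit(ukey, ",", fixed = TRUE))
  i <- match(key, ukey)
  j <- match(df$mz, mz)
  mat <- matrix(0, nrow = length(ukey), ncol = length(mz))
  if (anyDuplicated(cbind(i, j))) {
    stop("duplicate (x, y, mz) entries in MSI CSV")
  }
  mat[cbind(i, j)] <- df$intensity
  msi_raster(meta_x = as.integer(px[, 1]), meta_y = as.integer(px[, 2]),
             mz_values = mz, intensity = mat,
             metaresolution = metaresolution, mz_range = mz_range)
}
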