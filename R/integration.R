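#' TIC-normalize an MSI raster
#'
#' Divides every pixel's spectrum by that pixel's total ion count, so each
#' retained pixel's intensities sum to one. Pixels with zero TIC carry no
#' signal and are excluded (their count is recorded), or raised as an
#' error when `on_zero = "error"`.
#'
#' @param raster an [msi_raster].
#' @param on_zero `"warn"` (default: drop zero-TIC pixels with a warning)
#'   or `"error"`.
#' @return an [msi_raster] of the retained pixels with attribute
#'   `n_zero_tic` (number of excluded pixels) and `tic_normalized = TRUE`.
#' @export
tic_normalize <- function(raster, on_zero = c("warn", "error")) {
  stopifnot(inherits(raster, "msi_raster"))
  on_zero <- match.arg(on_zero)
  tic <- rowSums(raster$intensity)
  zero <- tic == 0
  if (any(zero)) {
    msg <- sprintf("%d pixel(s) with zero total ion count", sum(zero))
    if (on_zero == "error") stop(msg)
    warning(msg, " excluded from TIC normalization")
  }
  keep <- !zero
  out <- msi_raster(meta_x = raster$pixels$meta_x[keep],
                    meta_y = raster$pixels$meta_y[keep],
                    mz_values = raster$mz_values,
                    intensity = raster$intensity[keep, , drop = FALSE] /
                      tic[keep],
                    metaresolution = attr(raster, "metaresolution"),
                    pixel_id = raster$pixels$pixel_id[keep],
                    mz_range = attr(raster, "mz_range"))
  attr(out, "n_zero_tic") <- sum(zero)
  attr(out, "tic_normalized") <- TRUE
  out
}

#' Assign transformed MSI pixels to their nearest ST spots
#'
#' Point-to-point matching in the unified ST frame: each pixel is assigned
#' to its nearest spot centre provided the distance does not exceed
#' `radius`; farther pixels stay unassigned. Exact distance ties are broken
#' by the lexicographically smallest spot barcode. The default radius of
#' half the 100 um spot pitch tiles the plane so that every in-tissue
#' pixel of a 100 um raster maps to exactly one nearest spot cell.
#'
#' @param spot_points `physical_points` of spot centres (ST frame).
#' @param pixel_points `physical_points` of transformed pixels (ST frame).
#' @param radius matching radius in micrometres (default 50).
#' @return data frame `pixel_id`, `barcode` (NA when unassigned),
#'   `distance` (micrometres), one row per pixel in input order.
#' @export
match_pixels_to_spots <- function(spot_points, pixel_points, radius = 50) {
  sp <- .as_xy(spot_points, "ST_unified")
  px <- .as_xy(pixel_points, "ST_unified")
  if (nrow(sp) == 0L) stop("empty spot set")
  barcodes <- if (inherits(spot_points, "physical_points"))
    spot_points$id else rownames(sp)
  # tie rule needs barcode order: sort spots lexicographically so the
  # first index attaining the minimum is the smallest barcode
  ord <- order(barcodes, method = "radix")
  sp <- sp[ord, , drop = FALSE]
  barcodes <- barcodes[ord]

  n <- nrow(px)
  assigned <- character(n)
  dmin <- numeric(n)
  sp_sq <- rowSums(sp^2)
  chunk <- max(1L, floor(2e6 / nrow(sp)))
  tol <- 1e-9
  for (s in seq(1L, n, by = chunk)) {
    idx <- s:min(n, s + chunk - 1L)
    # squared distances pixels x spots
    d2 <- outer(rowSums(px[idx, , drop = FALSE]^2), sp_sq, `+`) -
      2 * px[idx, , drop = FALSE] %*% t(sp)
    d2[d2 < 0] <- 0
    best <- max.col(-d2, ties.method = "first")
    dmin[idx] <- sqrt(d2[cbind(seq_along(idx), best)])
    assigned[idx] <- barcodes[best]
  }
  unas <- dmin > radius + tol
  assigned[unas] <- NA_character_
  pid <- if (inherits(pixel_points, "physical_points")) pixel_points$id
         else as.character(seq_len(n))
  structure(data.frame(pixel_id = pid, barcode = assigned,
                       distance = dmin, stringsAsFactors = FALSE),
            radius = radius, class = c("pixel_match", "data.frame"))
}

#' Aggregate matched pixel intensities to a spot-by-metabolite matrix
#'
#' Averages (or takes the median of) the TIC-normalized intensities of the
#' pixels assigned to each spot. Spots with no matched pixel are absent
#' from the result; unassigned pixels are counted.
#'
#' @param mapping result of [match_pixels_to_spots()].
#' @param raster the (TIC-normalized) [msi_raster] whose pixels were
#'   matched.
#' @param statistic `"mean"` (default) or `"median"`.
#' @return object of class `spot_metabolite_matrix`: list with
#'   `intensity` (spots x m/z), `mz_values`, `n_pixels_per_spot`,
#'   `unassigned_pixels`.
#' @export
aggregate_spot_metabolites <- function(mapping, raster,
                                       statistic = c("mean", "median")) {
  statistic <- match.arg(statistic)
  stopifnot(inherits(raster, "msi_raster"))
  idx <- match(mapping$pixel_id, raster$pixels$pixel_id)
  if (anyNA(idx)) stop("mapping refers to pixels absent from the raster")
  ok <- !is.na(mapping$barcode)
  if (!any(ok)) stop("no pixels were assigned to any spot")
  f <- factor(mapping$barcode[ok])
  rows <- idx[ok]
  agg <- apply(raster$intensity[rows, , drop = FALSE], 2, function(col) {
    tapply(col, f, if (statistic == "mean") mean else stats::median)
  })
  agg <- matrix(agg, nrow = nlevels(f),
                dimnames = list(levels(f),
                                colnames(raster$intensity)))
  spot_metabolite_matrix(
    intensity = agg, mz_values = raster$mz_values,
    n_pixels_per_spot = as.integer(table(f)),
    unassigned_pixels = sum(!ok))
}

#' Spot-by-metabolite intensity matrix
#'
#' @param intensity spots x m/z numeric matrix with barcode rownames.
#' @param mz_values m/z axis (Da), strictly increasing.
#' @param n_pixels_per_spot integer pixel counts per retained spot (>= 1).
#' @param unassigned_pixels count of pixels matched to no spot.
#' @return object of class `spot_metabolite_matrix`.
#' @export
spot_metabolite_matrix <- function(intensity, mz_values,
                                   n_pixels_per_spot =
                                     rep(1L, nrow(intensity)),
                                   unassigned_pixels = 0L) {
  intensity <- as.matrix(intensity)
  if (is.null(rownames(intensity))) stop("intensity needs barcode rownames")
  if (any(intensity < 0)) stop("intensities must be non-negative")
  if (length(mz_values) != ncol(intensity)) {
    stop("mz_values length must match intensity columns")
  }
  if (any(n_pixels_per_spot < 1L)) {
    stop("retained spots must have >= 1 matched pixel")
  }
  structure(list(intensity = intensity,
                 mz_values = as.numeric(mz_values),
                 n_pixels_per_spot = as.integer(n_pixels_per_spot),
                 unassigned_pixels = as.integer(unassigned_pixels)),
            class = "spot_metabolite_matrix")
}

#' @export
print.spot_metabolite_matrix <- function(x, ...) {
  cat(sprintf(
    "spot_metabolite_matrix: %d spots x %d m/z (%d unassigned pixels)\n",
    nrow(x$intensity), length(x$mz_values), x$unassigned_pixels))
  invisible(x)
}

#' Write a spot-by-metabolite matrix as TSV and MatrixMarket
#'
#' @param mat a [spot_metabolite_matrix].
#' @param prefix output path prefix; writes `<prefix>.tsv`,
#'   `<prefix>.mtx`, `<prefix>.barcodes.txt`, `<prefix>.mz.txt`.
#' @return the TSV path, invisibly.
#' @export
write_spot_matrix <- function(mat, prefix) {
  stopifnot(inherits(mat, "spot_metabolite_matrix"))
  tsv <- paste0(prefix, ".tsv")
  df <- data.frame(barcode = rownames(mat$intensity),
                   n_pixels = mat$n_pixels_per_spot,
                   mat$intensity, check.names = FALSE)
  utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  Matrix::writeMM(Matrix::Matrix(mat$intensity, sparse = TRUE),
                  paste0(prefix, ".mtx"))
  writeLines(rownames(mat$intensity), paste0(prefix, ".barcodes.txt"))
  writeLines(format(mat$mz_values, trim = TRUE), paste0(prefix, ".mz.txt"))
  invisible(tsv)
}

#' Read a spot-by-metabolite TSV written by [write_spot_matrix()]
#'
#' @param path the `.tsv` path.
#' @return a [spot_metabolite_matrix].
#' @export
read_spot_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  intensity <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(intensity) <- df$barcode
  spot_metabolite_matrix(intensity = intensity,
                         mz_values = as.numeric(colnames(intensity)),
                         n_pixels_per_spot = df$n_pixels)
}

# ---------------------------------------------------------------------------
# cell-type designation

#' Designate one cell type per spot from deconvolution proportions
#'
#' Literal threshold rule: when the highest cell-type proportion at a spot
#' strictly exceeds `threshold` (default 0.70), that cell type is
#' designated; otherwise the second most prevalent cell type is selected.
#' A proportion exactly at the threshold does not exceed it, so the
#' else-branch applies. The conventional alternative `rule = "dominant"`
#' (always the top cell type) is provided for users who expect a plain
#' argmax annotation.
#'
#' @param props data frame with a `barcode` column and one numeric column
#'   per cell type; each row must sum to 1 within 1e-6.
#' @param threshold dominance threshold as a fraction (default 0.70).
#' @param rule `"threshold_second"` (default, the literal rule) or
#'   `"dominant"`.
#' @return data frame `barcode`, `cell_type`, `rule_used` where
#'   `rule_used` is `"dominant_over_70"` or `"second_most_prevalent"`
#'   (always `"dominant"` under the alternative rule). Proportion ties are
#'   broken by alphabetical cell-type label, so the result is invariant to
#'   column order.
#' @export
assign_spot_celltype <- function(props, threshold = 0.70,
                                 rule = c("threshold_second", "dominant")) {
  rule <- match.arg(rule)
  if (!"barcode" %in% names(props)) stop("props needs a barcode column")
  labels <- setdiff(names(props), "barcode")
  if (length(labels) < 1L) stop("no cell-type columns in props")
  p <- as.matrix(props[, labels, drop = FALSE])
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("proportions must lie in [0, 1]")
  }
  bad <- abs(rowSums(p) - 1) > 1e-6
  if (any(bad)) {
    stop("proportions do not sum to 1 for barcode(s): ",
         paste(utils::head(props$barcode[bad], 5L), collapse = ", "))
  }
  # sort labels alphabetically so order(-p) tie-breaks deterministically
  alpha <- order(labels, method = "radix")
  labels <- labels[alpha]
  p <- p[, alpha, drop = FALSE]

  n <- nrow(p)
  cell_type <- character(n)
  rule_used <- character(n)
  for (i in seq_len(n)) {
    o <- order(-p[i, ], method = "radix")   # stable: alphabetical on ties
    if (rule == "dominant") {
      cell_type[i] <- labels[o[1]]
      rule_used[i] <- "dominant"
    } else if (p[i, o[1]] > threshold) {
      cell_type[i] <- labels[o[1]]
      rule_used[i] <- "dominant_over_70"
    } else {
      if (length(labels) < 2L) {
        stop("second-most-prevalent rule needs >= 2 cell types (barcode ",
             props$barcode[i], ")")
      }
      cell_type[i] <- labels[o[2]]
      rule_used[i] <- "second_most_prevalent"
    }
  }
  data.frame(barcode = as.character(props$barcode),
             cell_type = cell_type, rule_used = rule_used,
             stringsAsFactors = FALSE)
}

#' Read a per-spot cell-type proportion table
#'
#' CSV with a `barcode` column and one column per cell type.
#'
#' @param path CSV path.
#' @return data frame suitable for [assign_spot_celltype()].
#' @export
read_celltype_proportions <- function(path) {
  utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}
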