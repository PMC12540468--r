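#' Landmark set pairing ST spots with MSI positions
#'
#' A registration landmark is one tissue feature marked in both frames:
#' the spot barcode locates it on the ST hex array, the (possibly
#' fractional, sub-pixel) MSI pixel position locates it on the raster.
#' At least six evenly distributed landmarks are required; their spread
#' must be two-dimensional (non-collinear) for the rotation to be
#' estimable.
#'
#' @param st_points `physical_points` in the `ST_unified` frame (or a
#'   2-column matrix of micrometre coordinates).
#' @param msi_points `physical_points` in the `MSI_unified` frame (or a
#'   2-column matrix).
#' @param barcodes,pixel_ids optional identifiers; duplicates are rejected.
#' @param min_landmarks minimum accepted pair count (default 6).
#' @return object of class `landmark_set`: list with matrices `st`, `msi`
#'   (n x 2) and the identifier vectors.
#' @export
landmark_set <- function(st_points, msi_points, barcodes = NULL,
                         pixel_ids = NULL, min_landmarks = 6L) {
  st <- .as_xy(st_points, "ST_unified")
  msi <- .as_xy(msi_points, "MSI_unified")
  if (nrow(st) != nrow(msi)) stop("landmark point counts differ")
  n <- nrow(st)
  if (n < min_landmarks) {
    stop("at least ", min_landmarks, " landmark pairs are required (got ",
         n, "); select at least six evenly distributed spots")
  }
  if (is.null(barcodes)) barcodes <- rownames(st) %||% sprintf("spot%d", 1:n)
  if (is.null(pixel_ids)) pixel_ids <- sprintf("px%d", 1:n)
  if (anyDuplicated(barcodes)) stop("duplicate landmark spot barcodes")
  if (anyDuplicated(pixel_ids)) stop("duplicate landmark pixel ids")
  for (m in list(st = st, msi = msi)) {
    sv <- svd(scale(m, center = TRUE, scale = FALSE))$d
    if (sv[2] <= 1e-9 * max(sv[1], 1)) {
      stop("landmarks are collinear (rank-deficient spread); ",
           "rotation cannot be estimated")
    }
  }
  structure(list(st = st, msi = msi,
                 barcodes = as.character(barcodes),
                 pixel_ids = as.character(pixel_ids)),
            class = "landmark_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.as_xy <- function(p, frame) {
  if (inherits(p, "physical_points")) {
    if (!identical(attr(p, "frame"), frame)) {
      stop("expected points in frame ", frame, ", got ", attr(p, "frame"))
    }
    m <- cbind(x = p$x, y = p$y)
    rownames(m) <- p$id
    return(m)
  }
  m <- as.matrix(p)
  stopifnot(ncol(m) == 2, all(is.finite(m)))
  colnames(m) <- c("x", "y")
  m
}

#' Read a landmark file and resolve it against a spot grid
#'
#' CSV columns `spot_barcode,pixel_x,pixel_y`. Pixel positions may be
#' fractional (sub-pixel marks); they are converted to micrometres with
#' the raster step.
#'
#' @param path landmark CSV.
#' @param grid the [spot_grid] supplying barcode coordinates.
#' @param metaresolution micrometres per MSI pixel step.
#' @param min_landmarks minimum accepted pair count (default 6).
#' @return a [landmark_set].
#' @export
read_landmarks <- function(path, grid, metaresolution = 100,
                           min_landmarks = 6L) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  need <- c("spot_barcode", "pixel_x", "pixel_y")
  if (!all(need %in% names(df))) {
    stop("landmark CSV must have columns spot_barcode, pixel_x, pixel_y")
  }
  stp <- hex_to_physical(grid)
  idx <- match(df$spot_barcode, stp$id)
  if (anyNA(idx)) {
    stop("landmark barcodes absent from spot grid: ",
         paste(df$spot_barcode[is.na(idx)], collapse = ", "))
  }
  landmark_set(
    st_points = cbind(stp$x[idx], stp$y[idx]),
    msi_points = cbind(df$pixel_x, df$pixel_y) * metaresolution,
    barcodes = df$spot_barcode,
    min_landmarks = min_landmarks)
}

# ---------------------------------------------------------------------------
# scale

#' Pairwise landmark distance ratios
#'
#' For every unordered landmark pair (a, b), the ratio of the ST-frame
#' distance to the MSI-frame distance:
#' `sqrt((UTXa-UTXb)^2 + (UTYa-UTYb)^2) / sqrt((UMXa-UMXb)^2 + (UMYa-UMYb)^2)`.
#' Under a similarity transform every ratio equals the scale factor, so
#' their filtered mean estimates it.
#'
#' @param landmarks a [landmark_set].
#' @return numeric vector of length choose(n, 2), with attribute `pairs`
#'   (2-column index matrix).
#' @export
pairwise_scale_ratios <- function(landmarks) {
  stopifnot(inherits(landmarks, "landmark_set"))
  d_st <- stats::dist(landmarks$st)
  d_msi <- stats::dist(landmarks$msi)
  if (any(d_msi == 0)) {
    k <- which(as.vector(d_msi) == 0)[1]
    pr <- .pair_index(attr(d_msi, "Size"))[k, ]
    stop("coincident MSI landmark points for pair (",
         landmarks$pixel_ids[pr[1]], ", ", landmarks$pixel_ids[pr[2]],
         "): degenerate pair")
  }
  r <- as.vector(d_st) / as.vector(d_msi)
  attr(r, "pairs") <- .pair_index(nrow(landmarks$st))
  r
}

.pair_index <- function(n) {
  # row order of stats::dist: (2,1),(3,1),...,(n,1),(3,2),...
  j <- rep(seq_len(n - 1L), times = (n - 1L):1L)
  i <- unlist(lapply(seq_len(n - 1L), function(k) (k + 1L):n))
  cbind(i = i, j = j)
}

#' Estimate the scale factor from pairwise ratios
#'
#' Ratios are filtered for outliers, then averaged. The default rule keeps
#' ratios within `k * MAD` of the median (MAD with the usual 1.4826
#' consistency constant); when the MAD is zero the band degenerates to the
#' median itself, so any discrepant ratio is rejected. The alternative
#' `"iqr"` rule keeps ratios inside the 1.5 x IQR Tukey fences.
#'
#' @param ratios numeric vector from [pairwise_scale_ratios()] (>= 3).
#' @param rule `"mad"` (default) or `"iqr"`.
#' @param k MAD multiplier (default 3).
#' @return list with `scale` (mean of kept ratios), `kept` (logical mask),
#'   `rule`.
#' @export
estimate_scale <- function(ratios, rule = c("mad", "iqr"), k = 3) {
  rule <- match.arg(rule)
  if (length(ratios) < 3L) stop("need at least 3 ratios to estimate scale")
  if (any(!is.finite(ratios) | ratios <= 0)) {
    stop("ratios must be finite and positive")
  }
  if (rule == "mad") {
    med <- stats::median(ratios)
    band <- k * stats::mad(ratios) + 1e-12 * med
    kept <- abs(ratios - med) <= band
  } else {
    q <- stats::quantile(ratios, c(0.25, 0.75), names = FALSE)
    iqr <- q[2] - q[1]
    kept <- ratios >= q[1] - 1.5 * iqr & ratios <= q[2] + 1.5 * iqr
  }
  if (!any(kept)) {
    stop("all ratios rejected as outliers; add more (or better spread) ",
         "landmarks")
  }
  list(scale = mean(ratios[kept]), kept = kept, rule = rule)
}

# ---------------------------------------------------------------------------
# rotation

.wrap_deg <- function(a) {
  # wrap to (-180, 180]
  a <- (a + 180) %% 360 - 180
  a[a == -180] <- 180
  a
}

#' Pairwise landmark rotation angles
#'
#' For every unordered landmark pair, the signed angle (degrees) between
#' the MSI-frame and ST-frame directions of the pair's chord, computed
#' with the two-argument quadrant-aware arctangent and wrapped to
#' (-180, 180]. The sign convention is the correction to apply: the angle
#' that rotates the MSI frame onto the ST frame (counter-clockwise
#' positive). Under a similarity transform every pair reports the same
#' angle.
#'
#' @param landmarks a [landmark_set].
#' @return numeric vector of angles in degrees, one per unordered pair.
#' @export
pairwise_rotation_angles <- function(landmarks) {
  stopifnot(inherits(landmarks, "landmark_set"))
  pr <- .pair_index(nrow(landmarks$st))
  dst <- landmarks$st[pr[, 1], , drop = FALSE] -
    landmarks$st[pr[, 2], , drop = FALSE]
  dms <- landmarks$msi[pr[, 1], , drop = FALSE] -
    landmarks$msi[pr[, 2], , drop = FALSE]
  zero_st <- rowSums(dst^2) == 0
  zero_ms <- rowSums(dms^2) == 0
  if (any(zero_st | zero_ms)) {
    b <- which(zero_st | zero_ms)[1]
    stop("degenerate landmark pair (",
         landmarks$barcodes[pr[b, 1]], ", ", landmarks$barcodes[pr[b, 2]],
         "): coincident points")
  }
  ang <- atan2(dst[, 2], dst[, 1]) - atan2(dms[, 2], dms[, 1])
  .wrap_deg(ang * 180 / pi)
}

#' Estimate the rotation angle from pairwise angles
#'
#' Aggregates by the circular mean of the unit vectors (arithmetic
#' averaging is wrong near the +/-180 wrap) and reports the circular
#' standard deviation as the spread. The rotation-deviation flag follows
#' the 5-degree rule: `exceeds_5deg` is TRUE only when the magnitude of
#' the mean rotation strictly exceeds 5 degrees.
#'
#' @param angles numeric vector of pairwise angles in degrees (>= 3).
#' @param spread_ceiling maximum tolerated circular SD in degrees
#'   (default 15); beyond it the landmarks are inconsistent with a rigid
#'   rotation and an error is raised.
#' @param deviation_threshold the flag threshold in degrees (default 5).
#' @return list with `rotation` (degrees in (-180, 180]), `angle_spread`
#'   (circular SD, degrees), `exceeds_5deg`.
#' @export
estimate_rotation <- function(angles, spread_ceiling = 15,
                              deviation_threshold = 5) {
  if (length(angles) < 3L) stop("need at least 3 angles to estimate rotation")
  rad <- angles * pi / 180
  s <- mean(sin(rad)); c <- mean(cos(rad))
  rotation <- .wrap_deg(atan2(s, c) * 180 / pi)
  rbar <- min(1, sqrt(s^2 + c^2))
  spread <- sqrt(-2 * log(max(rbar, .Machine$double.eps))) * 180 / pi
  if (spread > spread_ceiling) {
    stop(sprintf(paste0("pairwise rotation angles are inconsistent with a ",
                        "rigid rotation (circular SD %.1f deg > ceiling ",
                        "%.1f deg); check landmark correspondence"),
                 spread, spread_ceiling))
  }
  list(rotation = rotation, angle_spread = spread,
       exceeds_5deg = abs(rotation) > deviation_threshold)
}

# ---------------------------------------------------------------------------
# transform

#' Similarity transform between the MSI and ST unified frames
#'
#' Maps an MSI-frame point p to the ST frame as
#' `p' = s * R(theta) * (p - centroid_msi) + centroid_st`: the "central
#' coordinates" (landmark centroids in the two frames) anchor the
#' translation, the scale and rotation come from the landmark estimators.
#'
#' @param scale positive scale factor.
#' @param rotation_deg rotation in degrees, (-180, 180], counter-clockwise
#'   positive, applied to MSI coordinates.
#' @param centroid_msi,centroid_st length-2 centroids (micrometres).
#' @param reflection logical; TRUE means the x-axis is flipped before
#'   rotating (mirrored section).
#' @return object of class `similarity_transform`.
#' @export
similarity_transform <- function(scale, rotation_deg, centroid_msi,
                                 centroid_st, reflection = FALSE) {
  stopifnot(is.finite(scale), scale > 0,
            is.finite(rotation_deg),
            length(centroid_msi) == 2, length(centroid_st) == 2)
  structure(list(scale = scale,
                 rotation_deg = .wrap_deg(rotation_deg),
                 centroid_msi = as.numeric(centroid_msi),
                 centroid_st = as.numeric(centroid_st),
                 reflection = isTRUE(reflection)),
            class = "similarity_transform")
}

#' @export
print.similarity_transform <- function(x, ...) {
  cat(sprintf(
    "similarity_transform: scale %.6g, rotation %.4g deg%s\n  MSI centroid (%.4g, %.4g) -> ST centroid (%.4g, %.4g)\n",
    x$scale, x$rotation_deg, if (x$reflection) ", reflected" else "",
    x$centroid_msi[1], x$centroid_msi[2],
    x$centroid_st[1], x$centroid_st[2]))
  invisible(x)
}

.rot_mat <- function(deg, reflection = FALSE) {
  th <- deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  if (reflection) R <- R %*% diag(c(-1, 1))
  R
}

#' Fit the similarity transform from landmarks
#'
#' The full landmark procedure: pairwise distance ratios are filtered and
#' averaged into the scale factor; pairwise chord angles are circularly
#' averaged into the rotation; the translation anchors the scaled and
#' rotated MSI landmark centroid on the ST landmark centroid. When the
#' estimated rotation deviates by more than 5 degrees the transform is
#' flagged (`exceeds_5deg`) and the rotation is always included; below the
#' threshold the default is still to apply the estimated rotation
#' (`rotation_mode = "always"`), because dropping small rotations biases
#' pixel-to-spot matching, but `rotation_mode = "threshold"` reproduces
#' the stricter reading in which sub-threshold rotations are ignored.
#'
#' @param landmarks a [landmark_set].
#' @param outlier_rule ratio filter passed to [estimate_scale()].
#' @param rotation_mode `"always"` (default) or `"threshold"`.
#' @param mad_k MAD multiplier for the ratio filter.
#' @param spread_ceiling angle-consistency ceiling in degrees.
#' @param reflection `"error"` (default) to fail when the landmark
#'   orientation is mirrored between frames, `"detect"` to fit a reflected
#'   transform, `"ignore"` to skip the check.
#' @return list with `transform` ([similarity_transform]) and
#'   `diagnostics` (pairwise ratios and kept mask, pairwise angles,
#'   circular spread, `exceeds_5deg`, `rotation_applied`, `landmark_rmse`
#'   in micrometres).
#' @export
fit_transform <- function(landmarks, outlier_rule = c("mad", "iqr"),
                          rotation_mode = c("always", "threshold"),
                          mad_k = 3, spread_ceiling = 15,
                          reflection = c("error", "detect", "ignore")) {
  stopifnot(inherits(landmarks, "landmark_set"))
  outlier_rule <- match.arg(outlier_rule)
  rotation_mode <- match.arg(rotation_mode)
  reflection <- match.arg(reflection)

  refl <- FALSE
  if (reflection != "ignore") {
    mirrored <- .orientation_mirrored(landmarks)
    if (mirrored && reflection == "error") {
      stop("landmark orientation is mirrored between frames (flipped ",
           "section?); refit with reflection = \"detect\" to allow it")
    }
    refl <- mirrored
  }
  msi <- landmarks$msi
  if (refl) msi <- cbind(-msi[, 1], msi[, 2])
  lm_use <- landmarks
  lm_use$msi <- msi

  ratios <- pairwise_scale_ratios(lm_use)
  sc <- estimate_scale(ratios, rule = outlier_rule, k = mad_k)
  angles <- pairwise_rotation_angles(lm_use)
  rot <- estimate_rotation(angles, spread_ceiling = spread_ceiling)
  applied <- if (rotation_mode == "always" || rot$exceeds_5deg)
    rot$rotation else 0

  tr <- similarity_transform(scale = sc$scale, rotation_deg = applied,
                             centroid_msi = colMeans(landmarks$msi),
                             centroid_st = colMeans(landmarks$st),
                             reflection = refl)
  fitted <- apply_transform(physical_points(landmarks$pixel_ids,
                                            landmarks$msi[, 1],
                                            landmarks$msi[, 2],
                                            frame = "MSI_unified"), tr)
  resid <- cbind(fitted$x, fitted$y) - landmarks$st
  rmse <- sqrt(mean(rowSums(resid^2)))
  diagnostics <- list(pairwise_ratios = as.numeric(ratios),
                      kept_ratio_mask = sc$kept,
                      pairwise_angles = angles,
                      rotation_estimate = rot$rotation,
                      angle_spread = rot$angle_spread,
                      exceeds_5deg = rot$exceeds_5deg,
                      rotation_applied = applied,
                      reflection = refl,
                      landmark_rmse = rmse)
  list(transform = tr, diagnostics = diagnostics)
}

.orientation_mirrored <- function(landmarks) {
  # a proper similarity preserves orientation, so the least-squares
  # rotation aligning the centred point sets has positive determinant;
  # det of the 2x2 cross-covariance carries that sign robustly over all
  # landmark triples at once
  Xc <- scale(landmarks$msi, center = TRUE, scale = FALSE)
  Yc <- scale(landmarks$st, center = TRUE, scale = FALSE)
  det(crossprod(Xc, Yc)) < 0
}

#' Apply a similarity transform to MSI-frame points
#'
#' @param points `physical_points` in the `MSI_unified` frame (or 2-column
#'   matrix of micrometre coordinates).
#' @param transform a [similarity_transform].
#' @return `physical_points` in the `ST_unified` frame.
#' @export
apply_transform <- function(points, transform) {
  stopifnot(inherits(transform, "similarity_transform"))
  m <- .as_xy(points, "MSI_unified")
  R <- .rot_mat(transform$rotation_deg, transform$reflection)
  centred <- sweep(m, 2, transform$centroid_msi)
  out <- transform$scale * centred %*% t(R)
  out <- sweep(out, 2, transform$centroid_st, `+`)
  ids <- if (inherits(points, "physical_points")) points$id
         else rownames(m) %||% as.character(seq_len(nrow(m)))
  physical_points(ids, out[, 1], out[, 2], frame = "ST_unified")
}

#' Invert a similarity transform
#'
#' @param transform a [similarity_transform] mapping MSI to ST.
#' @return a `similarity_transform` mapping ST back to MSI (reflections
#'   are self-inverse and unsupported here).
#' @export
invert_transform <- function(transform) {
  stopifnot(inherits(transform, "similarity_transform"))
  if (transform$reflection) {
    stop("inversion of reflected transforms is not supported")
  }
  similarity_transform(scale = 1 / transform$scale,
                       rotation_deg = -transform$rotation_deg,
                       centroid_msi = transform$centroid_st,
                       centroid_st = transform$centroid_msi)
}

#' Closed-form least-squares similarity fit (validation oracle)
#'
#' Independent of the pairwise-ratio/angle estimators: solves the
#' orthogonal Procrustes problem with isotropic scaling in closed form
#' (SVD of the cross-covariance, determinant-corrected to exclude
#' reflections), minimizing the sum of squared landmark residuals. Used
#' to validate [fit_transform()]; by construction its residual RMSE is
#' never larger.
#'
#' @param landmarks a [landmark_set].
#' @return list with `transform` and `landmark_rmse`.
#' @export
procrustes_oracle <- function(landmarks) {
  stopifnot(inherits(landmarks, "landmark_set"))
  X <- landmarks$msi; Y <- landmarks$st
  cx <- colMeans(X); cy <- colMeans(Y)
  Xc <- sweep(X, 2, cx); Yc <- sweep(Y, 2, cy)
  H <- crossprod(Xc, Yc)
  sv <- svd(H)
  if (sv$d[2] <= 1e-12 * max(sv$d[1], 1)) {
    stop("rank-deficient landmark spread; oracle fit impossible")
  }
  S <- diag(c(1, sign(det(sv$v %*% t(sv$u)))))
  R <- sv$v %*% S %*% t(sv$u)
  s <- sum(diag(S) * sv$d) / sum(Xc^2)
  theta <- atan2(R[2, 1], R[1, 1]) * 180 / pi
  tr <- similarity_transform(scale = s, rotation_deg = theta,
                             centroid_msi = cx, centroid_st = cy)
  fitted <- apply_transform(X, tr)
  rmse <- sqrt(mean(rowSums((cbind(fitted$x, fitted$y) - Y)^2)))
  list(transform = tr, landmark_rmse = rmse)
}

#' Serialize a fitted transform (with diagnostics) to JSON
#'
#' @param fit result of [fit_transform()] (or a bare
#'   [similarity_transform]).
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_transform <- function(fit, path) {
  if (inherits(fit, "similarity_transform")) {
    fit <- list(transform = fit, diagnostics = NULL)
  }
  tr <- fit$transform
  obj <- list(scale = tr$scale, rotation_deg = tr$rotation_deg,
              centroid_msi = tr$centroid_msi,
              centroid_st = tr$centroid_st,
              reflection = tr$reflection,
              diagnostics = fit$diagnostics)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a transform JSON written by [write_transform()]
#'
#' @param path JSON path.
#' @return a [similarity_transform].
#' @export
read_transform <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  similarity_transform(scale = obj$scale, rotation_deg = obj$rotation_deg,
                       centroid_msi = obj$centroid_msi,
                       centroid_st = obj$centroid_st,
                       reflection = isTRUE(obj$reflection))
}
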