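# Fixtures built in code: landmark sets with known similarity transforms,
# small rasters and grids.

# ST-frame landmark layout: 8 well-spread non-collinear points (micrometres)
st_layout <- function(n = 8) {
  ang <- 2 * pi * (seq_len(n) - 1) / n
  cbind(x = 700 + 520 * cos(ang) + 40 * cos(3 * ang),
        y = 650 + 480 * sin(ang) + 30 * sin(2 * ang))
}

# Build a landmark_set whose true MSI->ST transform has the given
# parameters; MSI points are the ST layout pushed through the inverse,
# plus optional iid Gaussian jitter on the MSI side.
make_landmarks <- function(scale = 1, rotation = 0,
                           translation = c(0, 0), n = 8,
                           jitter = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  st <- st_layout(n)
  th <- -rotation * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  msi <- sweep(st, 2, translation) %*% t(R) / scale
  if (jitter > 0) msi <- msi + matrix(rnorm(2 * n, 0, jitter), ncol = 2)
  landmark_set(st, msi, barcodes = sprintf("BC-%02d", seq_len(n)))
}

# true forward map for held-out points under the same parameterization
true_map <- function(points, scale, rotation, translation) {
  th <- rotation * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  sweep(scale * as.matrix(points) %*% t(R), 2, translation, `+`)
}

# compare a fitted transform to truth by action on held-out points
transform_max_rel_err <- function(transform, scale, rotation, translation) {
  pts <- rbind(c(0, 0), c(1000, 0), c(0, 1000), c(1234.5, -678.9),
               c(-400, 2200))
  got <- apply_transform(pts, transform)
  want <- true_map(pts, scale, rotation, translation)
  denom <- pmax(abs(want), 1)
  max(abs(cbind(got$x, got$y) - want) / denom)
}

tiny_raster <- function(intensity = NULL, nx = 3, ny = 2,
                        mz = c(100, 200, 300), metaresolution = 100) {
  px <- expand.grid(meta_x = seq_len(nx) - 1, meta_y = seq_len(ny) - 1)
  if (is.null(intensity)) {
    intensity <- matrix(seq_len(nrow(px) * length(mz)),
                        nrow(px), length(mz))
  }
  msi_raster(px$meta_x, px$meta_y, mz, intensity,
             metaresolution = metaresolution)
}
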