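# Synthetic paired-section generator with known ground truth.
#
# Emulates the acquisition geometry of the real study conditions: a
# Visium-style hex spot array at 100 um pitch and a DESI-style raster at a
# 100 um step over the same virtual tissue, related by a known similarity
# transform. Intensities are log-normal (MSI intensities are positive and
# right-skewed) with region structure, planted two-group effects on the
# log scale, and planted monotone per-branch pseudotime trends.

#' Define a synthetic paired-section scenario
#'
#' Defaults describe the emulated acquisition: a full hex capture area of
#' 78 array rows by 64 spots per row (about 5,000 spots over
#' 6.5 x 6.7 mm), both modalities at 100 um resolution (so the true scale
#' is 1), a small section-transfer rotation of 3 degrees and a
#' translation of a few hundred micrometres between adjacent sections,
#' 8 evenly distributed landmarks with 10 um marking jitter, 50
#' metabolites of which 5 differ between groups by 2 SD on the log scale
#' with 30 spots per group, and branch studies with 60 spots in the
#' progenitor pool and per branch.
#'
#' @param rows,cols hex grid extent (array rows, spots per row).
#' @param transresolution,metaresolution micrometres per grid unit / pixel
#'   step.
#' @param scale,rotation_deg,translation the true similarity transform
#'   mapping MSI coordinates into the ST frame.
#' @param n_landmarks number of landmarks (>= 6).
#' @param landmark_jitter landmark marking noise SD, micrometres.
#' @param outlier_fraction fraction of landmarks grossly displaced
#'   (< 0.5).
#' @param n_metabolites,n_informative metabolite count and number with a
#'   planted group effect.
#' @param effect_size planted group effect in SD units (log scale).
#' @param sdlog log-scale intensity SD.
#' @param group_n spots per group in the two-group study.
#' @param branch_n spots in each of prebranch, branch1, branch2.
#' @param trend_effect planted within-branch signal range in SD units.
#' @param seed mandatory RNG seed.
#' @return object of class `synthetic_scenario` (a validated list).
#' @export
synthetic_scenario <- function(rows = 78, cols = 64,
                               transresolution = 100, metaresolution = 100,
                               scale = 1.0, rotation_deg = 3,
                               translation = c(250, -150),
                               n_landmarks = 8, landmark_jitter = 10,
                               outlier_fraction = 0,
                               n_metabolites = 50, n_informative = 5,
                               effect_size = 2, sdlog = 0.3,
                               group_n = 30,
                               branch_n = c(prebranch = 60, branch1 = 60,
                                            branch2 = 60),
                               trend_effect = 3, seed) {
  if (missing(seed)) stop("seed is mandatory for a synthetic scenario")
  stopifnot(rows >= 2, cols >= 2, transresolution > 0, metaresolution > 0,
            scale > 0, n_landmarks >= 6, landmark_jitter >= 0,
            outlier_fraction >= 0, outlier_fraction < 0.5,
            n_metabolites >= 1, n_informative <= n_metabolites,
            effect_size >= 0, sdlog > 0, group_n >= 3,
            all(branch_n >= 10), trend_effect >= 0)
  structure(as.list(environment()), class = "synthetic_scenario")
}

.true_transform <- function(scenario) {
  similarity_transform(scale = scenario$scale,
                       rotation_deg = scenario$rotation_deg,
                       centroid_msi = c(0, 0),
                       centroid_st = scenario$translation)
}

.hex_grid <- function(rows, cols, transresolution) {
  trans_y <- rep(seq_len(rows) - 1L, each = cols)
  trans_x <- unlist(lapply(seq_len(rows) - 1L, function(r) {
    seq(r %% 2L, by = 2L, length.out = cols)
  }))
  spot_grid(barcode = sprintf("SP-%03d-%03d", trans_y, trans_x),
            trans_x = trans_x, trans_y = trans_y,
            transresolution = transresolution)
}

.random_mz <- function(n, lo = 70, hi = 1200) {
  mz <- sort(round(stats::runif(n, lo + 1, hi - 1), 4))
  while (anyDuplicated(mz)) mz <- mz + cumsum(duplicated(mz)) * 1e-4
  mz
}

#' Generate a paired ST/MSI section with known registration truth
#'
#' Builds the hex spot grid, pushes its physical extent through the
#' inverse of the true transform to size an MSI raster that covers the
#' tissue, samples region-structured log-normal pixel intensities (two
#' territories, villous-like and basal-plate-like, split across the
#' section), and marks landmarks evenly on an ellipse with the configured
#' jitter and outliers.
#'
#' @param scenario a [synthetic_scenario].
#' @return list with `grid` ([spot_grid]), `raster` ([msi_raster]),
#'   `landmarks` ([landmark_set]), and `truth` (list: the true
#'   [similarity_transform], per-spot and per-pixel region labels, the
#'   m/z axis, per-region log-mean offsets, outlier landmark indices).
#' @export
generate_section_pair <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  .with_seed(scenario$seed, .generate_section_pair(scenario))
}

.generate_section_pair <- function(sc) {
  grid <- .hex_grid(sc$rows, sc$cols, sc$transresolution)
  stp <- hex_to_physical(grid)
  truth_tr <- .true_transform(sc)
  inv <- invert_transform(truth_tr)

  # raster index range covering the tissue in the MSI frame
  pad <- sc$transresolution
  corners <- expand.grid(x = range(stp$x) + c(-pad, pad),
                         y = range(stp$y) + c(-pad, pad))
  mc <- apply_transform_st_to_msi(as.matrix(corners), truth_tr)
  xr <- floor(min(mc[, 1]) / sc$metaresolution):
        ceiling(max(mc[, 1]) / sc$metaresolution)
  yr <- floor(min(mc[, 2]) / sc$metaresolution):
        ceiling(max(mc[, 2]) / sc$metaresolution)
  xr <- xr - min(xr); shift_x <- floor(min(mc[, 1]) / sc$metaresolution)
  yr <- yr - min(yr); shift_y <- floor(min(mc[, 2]) / sc$metaresolution)
  if (length(xr) * length(yr) > 2e5) {
    stop("scenario raster would exceed 200k pixels; shrink the grid")
  }
  px <- expand.grid(meta_x = xr, meta_y = yr)
  # physical MSI coords include the shift so the raster truly covers the
  # tissue: fold the shift into the transform's MSI centroid
  truth_tr$centroid_msi <- truth_tr$centroid_msi -
    c(shift_x, shift_y) * sc$metaresolution

  mz <- .random_mz(sc$n_metabolites)
  base_logmean <- stats::runif(sc$n_metabolites, 1, 3)
  region_offset <- stats::rnorm(sc$n_metabolites, 0, 0.5)

  # region by ST-frame x position: left half villous-like, right half
  # basal-plate-like
  px_phys <- cbind(px$meta_x, px$meta_y) * sc$metaresolution
  px_st <- apply_transform(physical_points(sprintf("px%d", seq_len(nrow(px))),
                                           px_phys[, 1], px_phys[, 2],
                                           frame = "MSI_unified"), truth_tr)
  mid <- mean(range(stp$x))
  px_region <- ifelse(px_st$x < mid, "villous", "basal_plate")
  spot_region <- ifelse(stp$x < mid, "villous", "basal_plate")

  logmean <- outer(as.numeric(px_region == "basal_plate"), region_offset) +
    matrix(base_logmean, nrow(px), sc$n_metabolites, byrow = TRUE)
  intensity <- matrix(stats::rlnorm(length(logmean), logmean, sc$sdlog),
                      nrow(px), sc$n_metabolites)
  raster <- msi_raster(meta_x = px$meta_x, meta_y = px$meta_y,
                       mz_values = mz, intensity = intensity,
                       metaresolution = sc$metaresolution)

  # landmarks: nearest spots to evenly spaced points on an ellipse
  cx <- mean(range(stp$x)); cy <- mean(range(stp$y))
  rx <- diff(range(stp$x)) * 0.35; ry <- diff(range(stp$y)) * 0.35
  ang <- 2 * pi * (seq_len(sc$n_landmarks) - 1) / sc$n_landmarks
  chosen <- integer(sc$n_landmarks)
  for (k in seq_len(sc$n_landmarks)) {
    d2 <- (stp$x - (cx + rx * cos(ang[k])))^2 +
          (stp$y - (cy + ry * sin(ang[k])))^2
    d2[chosen] <- Inf
    chosen[k] <- which.min(d2)
  }
  lm_st <- cbind(stp$x[chosen], stp$y[chosen])
  lm_msi <- apply_transform_st_to_msi(lm_st, truth_tr)
  if (sc$landmark_jitter > 0) {
    lm_msi <- lm_msi + matrix(stats::rnorm(length(lm_msi), 0,
                                           sc$landmark_jitter), ncol = 2)
  }
  n_out <- floor(sc$outlier_fraction * sc$n_landmarks)
  outlier_idx <- integer(0)
  if (n_out > 0) {
    outlier_idx <- sample(sc$n_landmarks, n_out)
    disp <- max(10 * sc$landmark_jitter, 5 * sc$metaresolution)
    th <- stats::runif(n_out, 0, 2 * pi)
    lm_msi[outlier_idx, ] <- lm_msi[outlier_idx, ] +
      disp * cbind(cos(th), sin(th))
  }
  landmarks <- landmark_set(st_points = lm_st, msi_points = lm_msi,
                            barcodes = grid$barcode[chosen])

  list(grid = grid, raster = raster, landmarks = landmarks,
       truth = list(transform = truth_tr,
                    spot_region = stats::setNames(spot_region,
                                                  grid$barcode),
                    pixel_region = px_region,
                    mz_values = mz,
                    base_logmean = base_logmean,
                    region_offset = region_offset,
                    outlier_landmarks = outlier_idx))
}

# inverse mapping helper (ST -> MSI physical coordinates)
apply_transform_st_to_msi <- function(points_st, transform) {
  m <- as.matrix(points_st)
  R <- .rot_mat(-transform$rotation_deg)
  centred <- sweep(m, 2, transform$centroid_st)
  out <- (centred %*% t(R)) / transform$scale
  sweep(out, 2, transform$centroid_msi, `+`)
}

#' Generate a two-group metabolite study with planted effects
#'
#' Log-normal spot-level intensities for `group_n` case and `group_n`
#' control spots over `n_metabolites` m/z values; the first
#' `n_informative` metabolites receive an additive case shift of
#' `effect_size` SD on the log scale.
#'
#' @param scenario a [synthetic_scenario].
#' @return list with `matrix` ([spot_metabolite_matrix] over both
#'   groups), `design` ([group_design], case level `"case"`), `truth`
#'   (informative m/z values and their indices).
#' @export
generate_group_study <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  .with_seed(scenario$seed, {
    sc <- scenario
    mz <- .random_mz(sc$n_metabolites)
    n <- 2 * sc$group_n
    barcodes <- c(sprintf("case-%03d", seq_len(sc$group_n)),
                  sprintf("ctrl-%03d", seq_len(sc$group_n)))
    group <- rep(c("case", "control"), each = sc$group_n)
    base <- stats::runif(sc$n_metabolites, 1, 3)
    shift <- c(rep(sc$effect_size * sc$sdlog, sc$n_informative),
               rep(0, sc$n_metabolites - sc$n_informative))
    logmean <- matrix(base, n, sc$n_metabolites, byrow = TRUE) +
      outer(as.numeric(group == "case"), shift)
    X <- matrix(stats::rlnorm(length(logmean), logmean, sc$sdlog),
                n, sc$n_metabolites,
                dimnames = list(barcodes, format(mz, trim = TRUE)))
    list(matrix = spot_metabolite_matrix(X, mz),
         design = group_design(barcodes, group, case_level = "case"),
         truth = list(informative_mz = mz[seq_len(sc$n_informative)],
                      informative_idx = seq_len(sc$n_informative)))
  })
}

#' Generate a branched pseudotime study with planted metabolite trends
#'
#' Spots are split into a progenitor pool (prebranch, pseudotime in
#' [0, 0.35]) and two fates (branch1, branch2; pseudotime in [0.35, 1]).
#' Each metabolite is planted with a direction pair (d1, d2), d in
#' {-1, 0, +1}, cycling through the observed pattern classes: falling
#' along both fates, flat/rising, falling-then-rising across fates
#' (fall on branch 1, rise on branch 2), the mirrored rising/falling
#' class, and flat/flat. Log-intensity changes linearly within a branch
#' by `trend_effect` SD over the branch; the progenitor pool carries the
#' mean of the two branch slopes so trajectories diverge from a common
#' origin.
#'
#' @param scenario a [synthetic_scenario].
#' @return list with `matrix` ([spot_metabolite_matrix]), `assignment`
#'   ([branch_assignment]), `truth` (data frame `mz`, `d_branch1`,
#'   `d_branch2` of planted directions).
#' @export
generate_branch_study <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  .with_seed(scenario$seed, {
    sc <- scenario
    classes <- rbind(c(-1, -1), c(0, 1), c(-1, 1), c(1, -1), c(0, 0))
    nb <- sc$branch_n
    mz <- .random_mz(sc$n_metabolites)
    dirs <- classes[(seq_len(sc$n_metabolites) - 1) %% nrow(classes) + 1, ,
                    drop = FALSE]
    branch <- rep(c("prebranch", "branch1", "branch2"), times = nb)
    pt <- c(stats::runif(nb[1], 0, 0.35),
            stats::runif(nb[2], 0.35, 1),
            stats::runif(nb[3], 0.35, 1))
    barcodes <- sprintf("TB-%04d", seq_along(branch))
    base <- stats::runif(sc$n_metabolites, 1, 3)
    beta <- sc$trend_effect * sc$sdlog / 0.65   # per unit pseudotime
    slope <- matrix(0, length(branch), sc$n_metabolites)
    for (j in seq_len(sc$n_metabolites)) {
      slope[branch == "prebranch", j] <- mean(dirs[j, ]) * beta
      slope[branch == "branch1", j] <- dirs[j, 1] * beta
      slope[branch == "branch2", j] <- dirs[j, 2] * beta
    }
    logmean <- matrix(base, length(branch), sc$n_metabolites,
                      byrow = TRUE) + slope * pt
    X <- matrix(stats::rlnorm(length(logmean), logmean, sc$sdlog),
                length(branch), sc$n_metabolites,
                dimnames = list(barcodes, format(mz, trim = TRUE)))
    list(matrix = spot_metabolite_matrix(X, mz),
         assignment = branch_assignment(barcodes, branch, pt),
         truth = data.frame(mz = mz, d_branch1 = dirs[, 1],
                            d_branch2 = dirs[, 2]))
  })
}

#' Write a generated section pair in the external file dialects
#'
#' Emits the files the package readers consume: headered
#' `tissue_positions.csv`, long-format MSI CSV, landmark CSV (fractional
#' pixel positions), so generator output round-trips through
#' [read_tissue_positions()], [read_msi_csv()] and [read_landmarks()].
#'
#' @param section result of [generate_section_pair()].
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths.
#' @export
write_section_files <- function(section, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tp <- file.path(dir, "tissue_positions.csv")
  grid <- section$grid
  utils::write.csv(
    data.frame(barcode = grid$barcode,
               in_tissue = as.integer(grid$in_tissue),
               array_row = grid$trans_y, array_col = grid$trans_x,
               pxl_row_in_fullres = 0L, pxl_col_in_fullres = 0L),
    tp, row.names = FALSE, quote = FALSE)

  msi <- file.path(dir, "msi.csv")
  r <- section$raster
  long <- data.frame(
    x = rep(r$pixels$meta_x, times = length(r$mz_values)),
    y = rep(r$pixels$meta_y, times = length(r$mz_values)),
    mz = rep(r$mz_values, each = nrow(r$pixels)),
    intensity = as.vector(r$intensity))
  utils::write.csv(long, msi, row.names = FALSE, quote = FALSE)

  lmf <- file.path(dir, "landmarks.csv")
  metares <- attr(r, "metaresolution")
  utils::write.csv(
    data.frame(spot_barcode = section$landmarks$barcodes,
               pixel_x = section$landmarks$msi[, 1] / metares,
               pixel_y = section$landmarks$msi[, 2] / metares),
    lmf, row.names = FALSE, quote = FALSE)
  c(tissue_positions = tp, msi = msi, landmarks = lmf)
}

#' Write a two-group study design CSV
#'
#' @param design a [group_design].
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_design <- function(design, path) {
  utils::write.csv(data.frame(barcode = design$barcode,
                              group = as.character(design$group)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a branch assignment CSV
#'
#' @param assignment a [branch_assignment].
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_branches <- function(assignment, path) {
  utils::write.csv(as.data.frame(assignment)[, c("barcode", "branch",
                                                 "pseudotime")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
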