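# Metabolite dynamics along externally inferred pseudotime branches.
# The trajectory topology is a progenitor pool ("prebranch", VCT-like)
# diverging into two fates (branch1, SCT-like; branch2, EVT-like); each
# branch path therefore starts with all prebranch spots.

#' Branch assignment of spots along a differentiation trajectory
#'
#' @param barcode spot identifiers.
#' @param branch one of `"prebranch"`, `"branch1"`, `"branch2"` per spot.
#' @param pseudotime non-negative progression scores; rescaled to [0, 1]
#'   over the whole assignment.
#' @return object of class `branch_assignment` (data frame `barcode`,
#'   `branch`, `pseudotime`).
#' @export
branch_assignment <- function(barcode, branch, pseudotime) {
  branch <- as.character(branch)
  ok <- c("prebranch", "branch1", "branch2")
  if (!all(branch %in% ok)) {
    stop("branch labels must be one of: ", paste(ok, collapse = ", "))
  }
  if (any(!is.finite(pseudotime)) || any(pseudotime < 0)) {
    stop("pseudotime must be finite and non-negative")
  }
  missing <- setdiff(ok, unique(branch))
  if (length(missing)) {
    stop("every branch must be non-empty; missing: ",
         paste(missing, collapse = ", "))
  }
  rng <- range(pseudotime)
  pt <- if (rng[2] > rng[1]) (pseudotime - rng[1]) / (rng[2] - rng[1])
        else rep(0, length(pseudotime))
  structure(data.frame(barcode = as.character(barcode), branch = branch,
                       pseudotime = pt, stringsAsFactors = FALSE),
            class = c("branch_assignment", "data.frame"))
}

#' Read a branch assignment CSV (`barcode,branch,pseudotime`)
#'
#' @param path CSV path.
#' @return a [branch_assignment].
#' @export
read_branches <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  need <- c("barcode", "branch", "pseudotime")
  if (!all(need %in% names(df))) {
    stop("branch CSV must have columns barcode, branch, pseudotime")
  }
  branch_assignment(df$barcode, df$branch, df$pseudotime)
}

#' Project spot metabolite intensities onto the two branch paths
#'
#' Builds the two differentiation paths (prebranch -> branch1 and
#' prebranch -> branch2): for each path the prebranch spots are prepended
#' to the branch spots and the union is ordered by pseudotime, with the
#' spot-level metabolite intensities attached. Assigned spots absent from
#' the matrix are dropped and counted.
#'
#' @param matrix a [spot_metabolite_matrix] (or matrix with barcode
#'   rownames).
#' @param assignment a [branch_assignment].
#' @return list of class `branch_projection` with elements `branch1` and
#'   `branch2`, each a list of `barcode`, `pseudotime` (sorted ascending)
#'   and `intensity` (spots x m/z in that order); attribute
#'   `dropped_spots` counts assigned spots missing from the matrix.
#' @export
project_branches <- function(matrix, assignment) {
  stopifnot(inherits(assignment, "branch_assignment"))
  X <- if (inherits(matrix, "spot_metabolite_matrix"))
    matrix$intensity else as.matrix(matrix)
  idx <- match(assignment$barcode, rownames(X))
  dropped <- sum(is.na(idx))
  keep <- !is.na(idx)
  if (!any(keep)) stop("no assigned spot is present in the matrix")
  asg <- assignment[keep, ]
  idx <- idx[keep]

  path <- function(b) {
    sel <- asg$branch %in% c("prebranch", b)
    o <- order(asg$pseudotime[sel])
    rows <- idx[sel][o]
    list(barcode = asg$barcode[sel][o],
         pseudotime = asg$pseudotime[sel][o],
         intensity = X[rows, , drop = FALSE])
  }
  structure(list(branch1 = path("branch1"), branch2 = path("branch2")),
            dropped_spots = dropped,
            class = "branch_projection")
}

#' Classify the trend of one metabolite series along pseudotime
#'
#' Rank-based trend call: the Spearman correlation rho between intensity
#' and pseudotime is tested; the metabolite is `increasing` when
#' rho >= `rho_threshold` with p < `alpha`, `decreasing` when
#' rho <= -`rho_threshold` with p < `alpha`, and `unchanged` otherwise.
#' A constant series has no defined rank correlation and is reported as
#' `unchanged` with a note. The smoothed profile is the mean intensity in
#' `bins` equal-count pseudotime bins (fewer when the series is short).
#'
#' @param intensity numeric metabolite intensities.
#' @param pseudotime matching pseudotime values.
#' @param rho_threshold minimum |rho| to call a direction (default 0.3).
#' @param alpha significance level for the correlation test (default
#'   0.05).
#' @param bins number of equal-count bins for the profile (default 20).
#' @return list with `direction`, `rho`, `p_value`, `profile` (bin
#'   means), `note`.
#' @export
classify_trend <- function(intensity, pseudotime, rho_threshold = 0.3,
                           alpha = 0.05, bins = 20) {
  stopifnot(length(intensity) == length(pseudotime))
  n <- length(intensity)
  if (n < 10L) stop("need >= 10 observations along a path")
  nb <- min(bins, n)
  grp <- ceiling(seq_len(n) / (n / nb))
  profile <- as.numeric(tapply(intensity[order(pseudotime)], grp, mean))
  if (stats::sd(intensity) == 0) {
    return(list(direction = "unchanged", rho = NA_real_,
                p_value = NA_real_, profile = profile,
                note = "constant series"))
  }
  ct <- suppressWarnings(
    stats::cor.test(intensity, pseudotime, method = "spearman",
                    exact = FALSE))
  rho <- unname(ct$estimate)
  p <- ct$p.value
  direction <- if (is.finite(rho) && rho >= rho_threshold && p < alpha) {
    "increasing"
  } else if (is.finite(rho) && rho <= -rho_threshold && p < alpha) {
    "decreasing"
  } else "unchanged"
  list(direction = direction, rho = rho, p_value = p, profile = profile,
       note = NA_character_)
}

#' Classify all metabolite trends along both branch paths
#'
#' @param matrix a [spot_metabolite_matrix] (or matrix).
#' @param assignment a [branch_assignment].
#' @param rho_threshold,alpha,bins see [classify_trend()].
#' @return data frame of class `trend_table`: `mz`, `path`
#'   (`"prebranch->branch1"` or `"prebranch->branch2"`), `direction`,
#'   `rho`, `p_value`; attribute `profiles` holds the per-metabolite
#'   binned profiles (list of matrices, metabolites x bins).
#' @export
classify_trends <- function(matrix, assignment, rho_threshold = 0.3,
                            alpha = 0.05, bins = 20) {
  proj <- project_branches(matrix, assignment)
  mz <- colnames(proj$branch1$intensity)
  paths <- c(branch1 = "prebranch->branch1", branch2 = "prebranch->branch2")
  rows <- list(); profiles <- list()
  for (b in names(paths)) {
    pth <- proj[[b]]
    res <- lapply(seq_along(mz), function(j) {
      classify_trend(pth$intensity[, j], pth$pseudotime,
                     rho_threshold = rho_threshold, alpha = alpha,
                     bins = bins)
    })
    rows[[b]] <- data.frame(
      mz = mz, path = paths[[b]],
      direction = vapply(res, `[[`, "", "direction"),
      rho = vapply(res, `[[`, 0, "rho"),
      p_value = vapply(res, `[[`, 0, "p_value"),
      stringsAsFactors = FALSE)
    profiles[[b]] <- do.call(rbind, lapply(res, `[[`, "profile"))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, profiles = profiles,
            class = c("trend_table", "data.frame"))
}
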