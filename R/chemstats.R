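# Two-group differential metabolite analysis: OPLS-DA (orthogonal-signal-
# corrected NIPALS, single response), VIP scores, cross-validated Q2,
# permutation testing, and the VIP > 1 & p < 0.05 calling rule.

.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

#' Two-group design
#'
#' @param barcode observation identifiers (spots or samples).
#' @param group factor or character with exactly two levels; the first
#'   level (or `case_level`) is treated as the case group.
#' @param case_level optional level to treat as case.
#' @return object of class `group_design`: data frame `barcode`, `group`
#'   (factor, case level first).
#' @export
group_design <- function(barcode, group, case_level = NULL) {
  group <- as.factor(as.character(group))
  if (nlevels(group) != 2L) {
    stop("design must have exactly two groups, got: ",
         paste(levels(group), collapse = ", "))
  }
  if (!is.null(case_level)) group <- stats::relevel(group, case_level)
  if (any(table(group) < 3L)) stop("each group needs >= 3 members")
  structure(data.frame(barcode = as.character(barcode), group = group,
                       stringsAsFactors = FALSE),
            class = c("group_design", "data.frame"))
}

#' Read a two-group design CSV (`barcode,group`)
#'
#' @param path CSV path.
#' @param case_level optional group level to treat as case.
#' @return a [group_design].
#' @export
read_design <- function(path, case_level = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  if (!all(c("barcode", "group") %in% names(df))) {
    stop("design CSV must have columns barcode, group")
  }
  group_design(df$barcode, df$group, case_level = case_level)
}

.design_matrix <- function(matrix, design) {
  X <- if (inherits(matrix, "spot_metabolite_matrix"))
    matrix$intensity else as.matrix(matrix)
  idx <- match(design$barcode, rownames(X))
  if (anyNA(idx)) {
    stop("design barcodes absent from the matrix: ",
         paste(utils::head(design$barcode[is.na(idx)], 5L), collapse = ", "))
  }
  X[idx, , drop = FALSE]
}

.autoscale <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  sd[sd == 0] <- 1
  list(X = sweep(sweep(X, 2, mu), 2, sd, `/`), center = mu, scale = sd)
}

# core OPLS fit on an already-scaled matrix and centered response
.opls_core <- function(X, y, n_orth) {
  w_orth <- NULL; p_orth <- NULL; t_orth <- NULL
  for (o in seq_len(n_orth)) {
    w <- crossprod(X, y); w <- w / sqrt(sum(w^2))
    tt <- X %*% w
    p <- crossprod(X, tt) / sum(tt^2)
    wo <- p - as.numeric(crossprod(w, p)) * w
    nwo <- sqrt(sum(wo^2))
    if (nwo < 1e-12) break  # no orthogonal variation left
    wo <- wo / nwo
    to <- X %*% wo
    po <- crossprod(X, to) / sum(to^2)
    X <- X - to %*% t(po)
    w_orth <- cbind(w_orth, wo)
    p_orth <- cbind(p_orth, po)
    t_orth <- cbind(t_orth, to)
  }
  w <- crossprod(X, y); w <- w / sqrt(sum(w^2))
  tt <- X %*% w
  p <- crossprod(X, tt) / sum(tt^2)
  cc <- as.numeric(crossprod(tt, y) / crossprod(tt))
  list(w = as.numeric(w), t = as.numeric(tt), p = as.numeric(p), c = cc,
       w_orth = w_orth, p_orth = p_orth, t_orth = t_orth)
}

.opls_predict <- function(core, Xnew) {
  if (!is.null(core$w_orth)) {
    for (k in seq_len(ncol(core$w_orth))) {
      to <- Xnew %*% core$w_orth[, k]
      Xnew <- Xnew - to %*% t(core$p_orth[, k])
    }
  }
  as.numeric((Xnew %*% core$w) * core$c)
}

.strat_folds <- function(group, k, seed) {
  .with_seed(seed, {
    fold <- integer(length(group))
    for (g in levels(group)) {
      idx <- sample(which(group == g))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
}

#' Fit an OPLS-DA model
#'
#' One predictive plus `n_orth` orthogonal components via the
#' orthogonal-signal-corrected NIPALS scheme on column-centred,
#' unit-variance-scaled data, with a +/-1 response coding the two groups.
#' `R2X_cum` and `R2Y_cum` are the cumulative explained fractions of the
#' scaled data and response; `Q2_cum` is computed from stratified k-fold
#' cross-validated prediction residuals (scaling refit inside each
#' training fold).
#'
#' @param matrix a [spot_metabolite_matrix] or numeric observations x
#'   metabolites matrix with barcode rownames.
#' @param design a [group_design].
#' @param n_orth number of orthogonal components (default 1).
#' @param cv_folds cross-validation folds (default 7, stratified).
#' @param seed RNG seed controlling fold assignment (default 1).
#' @return object of class `oplsda_model` with elements `weights`
#'   (predictive w), `scores` (predictive t), `loadings`, `c`
#'   (inner relation), `w_orth`, `p_orth`, `t_orth`, `center`, `scale`,
#'   `R2X_cum`, `R2Y_cum`, `Q2_cum`, `mz_values`, `dropped`
#'   (constant metabolites removed), `design`.
#' @export
fit_oplsda <- function(matrix, design, n_orth = 1, cv_folds = 7, seed = 1) {
  stopifnot(inherits(design, "group_design"))
  X0 <- .design_matrix(matrix, design)
  if (ncol(X0) < 2L && n_orth > 0) {
    # a single metabolite has no orthogonal subspace; handled below
  }
  const <- apply(X0, 2, stats::sd) == 0
  if (any(const)) {
    warning(sum(const), " constant metabolite column(s) dropped")
    X0 <- X0[, !const, drop = FALSE]
  }
  if (ncol(X0) < 1L) stop("no variable metabolites left")
  n <- nrow(X0)
  if (n < cv_folds) stop("fewer observations than cross-validation folds")
  y_raw <- ifelse(design$group == levels(design$group)[1], 1, -1)
  y <- y_raw - mean(y_raw)

  sc <- .autoscale(X0)
  core <- .opls_core(sc$X, y, n_orth)

  ssx <- sum(sc$X^2)
  ssx_model <- sum((core$t %*% t(core$p))^2)
  if (!is.null(core$t_orth)) {
    for (k in seq_len(ncol(core$t_orth))) {
      ssx_model <- ssx_model +
        sum((core$t_orth[, k] %*% t(core$p_orth[, k]))^2)
    }
  }
  R2X <- ssx_model / ssx
  R2Y <- 1 - sum((y - core$t * core$c)^2) / sum(y^2)

  fold <- .strat_folds(design$group, cv_folds, seed)
  press <- 0
  for (k in seq_len(cv_folds)) {
    tr <- fold != k; te <- !tr
    sct <- .autoscale(X0[tr, , drop = FALSE])
    ytr <- y_raw[tr] - mean(y_raw[tr])
    coret <- .opls_core(sct$X, ytr, n_orth)
    Xte <- sweep(sweep(X0[te, , drop = FALSE], 2, sct$center),
                 2, sct$scale, `/`)
    yhat <- .opls_predict(coret, Xte)
    press <- press + sum((y_raw[te] - mean(y_raw[tr]) - yhat)^2)
  }
  Q2 <- 1 - press / sum(y^2)

  structure(list(weights = stats::setNames(core$w, colnames(X0)),
                 scores = core$t, loadings = core$p, c = core$c,
                 w_orth = core$w_orth, p_orth = core$p_orth,
                 t_orth = core$t_orth,
                 center = sc$center, scale = sc$scale,
                 R2X_cum = R2X, R2Y_cum = R2Y, Q2_cum = Q2,
                 mz_values = suppressWarnings(as.numeric(colnames(X0))),
                 dropped = names(const)[const],
                 n_orth = n_orth, cv_folds = cv_folds, seed = seed,
                 design = design),
            class = "oplsda_model")
}

#' @export
print.oplsda_model <- function(x, ...) {
  cat(sprintf(
    "oplsda_model: 1 predictive + %d orthogonal component(s), %d metabolites\n  R2X(cum) %.3f, R2Y(cum) %.3f, Q2(cum) %.3f\n",
    if (is.null(x$w_orth)) 0L else ncol(x$w_orth),
    length(x$weights), x$R2X_cum, x$R2Y_cum, x$Q2_cum))
  invisible(x)
}

#' Variable importance in projection (VIP)
#'
#' `VIP_j = sqrt(p * sum_a w_ja^2 SSY_a / sum_a SSY_a)` over the
#' predictive component(s); with the normalized weight vector this makes
#' the mean squared VIP exactly 1, so VIP > 1 marks above-average
#' contribution to the group separation.
#'
#' @param model a fitted [fit_oplsda()] model.
#' @return named numeric vector of VIP scores (one per metabolite).
#' @export
vip_scores <- function(model) {
  if (!inherits(model, "oplsda_model")) stop("vip_scores needs a fitted model")
  p <- length(model$weights)
  sqrt(p * model$weights^2 / sum(model$weights^2))
}

#' Permutation test of the OPLS-DA Q2
#'
#' Refits the whole cross-validated pipeline under `n_perm` random
#' permutations of the group labels. A sound model has an observed Q2 far
#' above the permuted distribution, whose centre is at or below zero.
#' The empirical p-value uses the add-one convention
#' `p = (1 + #permuted Q2 >= observed) / (n_perm + 1)`.
#'
#' @param matrix observations x metabolites matrix or
#'   [spot_metabolite_matrix].
#' @param design a [group_design].
#' @param n_perm number of permutations (default 200; < 20 warns).
#' @param n_orth,cv_folds passed to [fit_oplsda()].
#' @param seed RNG seed (default 1).
#' @return list with `observed_q2`, `permuted_q2` (length `n_perm`),
#'   `p_value`.
#' @export
permutation_test <- function(matrix, design, n_perm = 200, n_orth = 1,
                             cv_folds = 7, seed = 1) {
  if (n_perm < 1L) stop("n_perm must be >= 1")
  if (n_perm < 20L) warning("n_perm < 20 gives a very coarse p-value")
  obs <- fit_oplsda(matrix, design, n_orth = n_orth, cv_folds = cv_folds,
                    seed = seed)$Q2_cum
  perms <- .with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      d <- design
      d$group <- sample(d$group)
      suppressWarnings(
        fit_oplsda(matrix, d, n_orth = n_orth, cv_folds = cv_folds,
                   seed = seed)$Q2_cum)
    }, numeric(1))
  })
  list(observed_q2 = obs, permuted_q2 = perms,
       p_value = (1 + sum(perms >= obs)) / (n_perm + 1))
}

#' Call differential metabolites (VIP > 1 and p < 0.05)
#'
#' Fits the OPLS-DA model for VIP scores and tests each metabolite
#' univariately between the groups (default: two-sided Welch t-test on
#' log-transformed intensities with offset epsilon = half the smallest
#' positive intensity; Wilcoxon rank-sum optional). A metabolite is
#' significant when its VIP strictly exceeds `vip_threshold` AND its
#' p-value is strictly below `alpha`; both inequalities are strict, so a
#' VIP of exactly 1 does not qualify. Metabolites with zero variance are
#' excluded (their p-value is undefined) and listed in the `excluded`
#' attribute.
#'
#' @param matrix observations x metabolites matrix or
#'   [spot_metabolite_matrix].
#' @param design a [group_design].
#' @param test `"welch"` (default) or `"wilcoxon"`.
#' @param vip_threshold VIP cutoff (default 1.0, strict).
#' @param alpha p-value cutoff (default 0.05, strict).
#' @param p_adjust multiple-testing correction passed to
#'   [stats::p.adjust()] (default `"none"`, matching the raw-p rule;
#'   `"BH"` available).
#' @param n_orth,cv_folds,seed passed to [fit_oplsda()].
#' @return object of class `differential_result`: data frame `mz`, `VIP`,
#'   `p_value`, `log2FC` (case over control group means), `significant`,
#'   sorted by VIP descending; attributes `model` (the fitted
#'   [fit_oplsda()] model) and `excluded` (zero-variance metabolites).
#' @export
differential_metabolites <- function(matrix, design, test = c("welch",
                                     "wilcoxon"), vip_threshold = 1,
                                     alpha = 0.05, p_adjust = "none",
                                     n_orth = 1, cv_folds = 7, seed = 1) {
  test <- match.arg(test)
  X <- .design_matrix(matrix, design)
  const <- apply(X, 2, stats::sd) == 0
  excluded <- colnames(X)[const]
  X <- X[, !const, drop = FALSE]
  if (ncol(X) == 0L) stop("all metabolites have zero variance")

  model <- suppressWarnings(
    fit_oplsda(X, design, n_orth = n_orth, cv_folds = cv_folds,
               seed = seed))
  vip <- vip_scores(model)

  case <- design$group == levels(design$group)[1]
  pos <- X[X > 0]
  eps <- if (length(pos)) min(pos) / 2 else 1e-12
  pvals <- vapply(seq_len(ncol(X)), function(j) {
    a <- X[case, j]; b <- X[!case, j]
    if (test == "welch") {
      stats::t.test(log(a + eps), log(b + eps))$p.value
    } else {
      suppressWarnings(stats::wilcox.test(a, b)$p.value)
    }
  }, numeric(1))
  pvals <- stats::p.adjust(pvals, method = p_adjust)
  l2fc <- log2((colMeans(X[case, , drop = FALSE]) + eps) /
               (colMeans(X[!case, , drop = FALSE]) + eps))

  out <- data.frame(
    mz = suppressWarnings(as.numeric(colnames(X))),
    VIP = as.numeric(vip),
    p_value = pvals,
    log2FC = as.numeric(l2fc),
    significant = as.numeric(vip) > vip_threshold & pvals < alpha,
    stringsAsFactors = FALSE)
  if (all(is.na(out$mz))) out$mz <- colnames(X)
  out <- out[order(-out$VIP), ]
  rownames(out) <- NULL
  structure(out, model = model, excluded = excluded,
            class = c("differential_result", "data.frame"))
}
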