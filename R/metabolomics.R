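# Metabolomics screening: PLS-DA / OPLS-DA, VIP, cross-validated Q2,
# permutation validation, univariate stats and hypergeometric ORA.
#
# All multivariate fits work on the samples-by-variables orientation
# internally; user-facing functions take the field's usual
# metabolites-by-samples intensity matrix plus a group label vector.

# Transpose to samples x variables, apply centering/scaling and encode a
# centered +/-1 group response. `on_constant` controls what happens to a
# variable with zero variance under unit-variance scaling.
prepare_xy <- function(intensities, groups, case, scaling,
                       on_constant = c("error", "keep")) {
  on_constant <- match.arg(on_constant)
  if (!is.matrix(intensities) || !is.numeric(intensities)) {
    stop("`intensities` must be a numeric matrix (metabolites x samples)",
         call. = FALSE)
  }
  if (length(groups) != ncol(intensities)) {
    stop("`groups` must have one label per sample column", call. = FALSE)
  }
  labs <- unique(groups)
  if (length(labs) != 2) stop("exactly two groups required", call. = FALSE)
  if (is.null(case)) {
    case <- if ("treated" %in% labs) "treated" else labs[1]
  }
  if (!case %in% labs) {
    stop(sprintf("case label '%s' absent from `groups`", case), call. = FALSE)
  }
  x <- t(intensities)
  center <- colMeans(x)
  scale_ <- rep(1, ncol(x))
  if (scaling == "uv") {
    scale_ <- apply(x, 2, stats::sd)
    bad <- which(scale_ == 0)
    if (length(bad) > 0) {
      if (on_constant == "error") {
        stop(sprintf("constant variable under unit-variance scaling: %s",
                     paste(colnames(x)[bad], collapse = ", ")),
             call. = FALSE)
      }
      scale_[bad] <- 1
    }
  }
  if (scaling == "none") center <- rep(0, ncol(x))
  xs <- sweep(sweep(x, 2, center, "-"), 2, scale_, "/")
  y_raw <- ifelse(groups == case, 1, -1)
  y_center <- mean(y_raw)
  list(x = xs, y = y_raw - y_center, center = center, scale = scale_,
       y_center = y_center, case = case, groups = groups,
       sample_ids = colnames(intensities),
       variable_ids = rownames(intensities))
}

# Core NIPALS PLS1 on prepared (scaled) x and centered y.
nipals_pls1 <- function(x, y, n_components) {
  n <- nrow(x)
  p <- ncol(x)
  w <- matrix(0, p, n_components)
  tt <- matrix(0, n, n_components)
  pp <- matrix(0, p, n_components)
  qq <- numeric(n_components)
  ssx_a <- ssy_a <- numeric(n_components)
  xr <- x
  yr <- y
  for (a in seq_len(n_components)) {
    wa <- drop(crossprod(xr, yr))
    nw <- sqrt(sum(wa^2))
    if (nw < 1e-12) {
      stop("no remaining covariance between X and the group response",
           call. = FALSE)
    }
    wa <- wa / nw
    ta <- drop(xr %*% wa)
    tt_a <- sum(ta^2)
    if (tt_a < 1e-12) stop("degenerate score vector", call. = FALSE)
    qa <- sum(yr * ta) / tt_a
    pa <- drop(crossprod(xr, ta)) / tt_a
    xr <- xr - tcrossprod(ta, pa)
    yr <- yr - ta * qa
    w[, a] <- wa
    tt[, a] <- ta
    pp[, a] <- pa
    qq[a] <- qa
    ssx_a[a] <- tt_a * sum(pa^2)
    ssy_a[a] <- qa^2 * tt_a
  }
  list(weights = w, scores = tt, x_loadings = pp, y_loadings = qq,
       ssx_comp = ssx_a, ssy_comp = ssy_a,
       ssx_total = sum(x^2), ssy_total = sum(y^2))
}

#' Fit a PLS-DA model by NIPALS
#'
#' Partial least squares discriminant analysis of a two-group intensity
#' matrix: the group membership is dummy-coded as a centered +/-1
#' response and a PLS1 model is extracted component by component with the
#' NIPALS algorithm (deterministic, no random initialisation). Default
#' preprocessing is mean-centering plus unit-variance scaling of every
#' metabolite, the convention of SIMCA-style metabolomics software.
#'
#' @param intensities Numeric matrix, metabolites x samples, with
#'   dimnames.
#' @param groups Character vector of group labels per sample (two
#'   groups).
#' @param n_components Number of latent components; must be smaller than
#'   both the sample and variable count.
#' @param scaling `"uv"` (center + unit variance, default), `"center"`,
#'   or `"none"`.
#' @param case Label coded +1 (fold-change numerator); defaults to
#'   `"treated"` when present, else the first label.
#' @return A `pls_model`: scores `t`, unit-norm weights `w`, loadings
#'   `p`/`q`, cumulative `r2x`, `r2y` and per-component variance
#'   breakdowns, plus the preprocessing vectors needed for prediction.
#' @export
fit_plsda <- function(intensities, groups, n_components = 2,
                      scaling = c("uv", "center", "none"), case = NULL) {
  scaling <- match.arg(scaling)
  prep <- prepare_xy(intensities, groups, case, scaling)
  n_components <- check_positive_int(n_components, "n_components")
  if (n_components >= min(nrow(prep$x), ncol(prep$x))) {
    stop("`n_components` must be < min(n_samples, n_variables)",
         call. = FALSE)
  }
  fit <- nipals_pls1(prep$x, prep$y, n_components)
  r2x_cum <- cumsum(fit$ssx_comp) / fit$ssx_total
  r2y_cum <- cumsum(fit$ssy_comp) / fit$ssy_total
  dimnames(fit$scores) <- list(prep$sample_ids,
                               paste0("t", seq_len(n_components)))
  dimnames(fit$weights) <- list(prep$variable_ids,
                                paste0("w", seq_len(n_components)))
  dimnames(fit$x_loadings) <- list(prep$variable_ids,
                                   paste0("p", seq_len(n_components)))
  structure(
    list(n_components = n_components, scores = fit$scores,
         weights = fit$weights, x_loadings = fit$x_loadings,
         y_loadings = fit$y_loadings, r2x = r2x_cum[n_components],
         r2y = r2y_cum[n_components], r2x_cum = r2x_cum,
         r2y_cum = r2y_cum, ssx_comp = fit$ssx_comp,
         ssy_comp = fit$ssy_comp, ssy_total = fit$ssy_total,
         center = prep$center, scale = prep$scale,
         y_center = prep$y_center, scaling = scaling, case = prep$case,
         groups = prep$groups),
    class = "pls_model"
  )
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("PLS-DA model: %d component(s), R2X = %.3f, R2Y = %.3f\n",
              x$n_components, x$r2x, x$r2y))
  invisible(x)
}

# Predict the centered group response of new samples (columns) from a
# fitted pls_model via the regression vector B = W (P'W)^-1 q.
predict_pls <- function(model, intensities_new) {
  xs <- sweep(sweep(t(intensities_new), 2, model$center, "-"),
              2, model$scale, "/")
  b <- model$weights %*%
    solve(crossprod(model$x_loadings, model$weights), model$y_loadings)
  drop(xs %*% b)
}

#' Variable importance in projection (VIP)
#'
#' Wold's VIP score for every variable of a fitted PLS-DA model:
#' \deqn{VIP_j = \sqrt{p \sum_a SSY_a w_{aj}^2 / \sum_a SSY_a}}
#' with \eqn{p} the variable count and \eqn{SSY_a} the Y-variance
#' explained by component a. Because weight vectors are unit-norm, the
#' mean squared VIP is exactly 1, so VIP > 1 flags variables of
#' above-average importance.
#'
#' @param model A [fit_plsda()] model.
#' @return Named numeric vector of VIP scores (>= 0).
#' @export
vip_scores <- function(model) {
  stopifnot(inherits(model, "pls_model"))
  ssy <- model$ssy_comp
  if (sum(ssy) <= 0) {
    stop("VIP undefined: model explains no Y-variance", call. = FALSE)
  }
  p <- nrow(model$weights)
  vip2 <- p * drop(model$weights^2 %*% ssy) / sum(ssy)
  stats::setNames(sqrt(vip2), rownames(model$weights))
}

# Deterministic venetian-blind fold assignment: samples ordered by group
# label then sample id, folds dealt round-robin.
venetian_folds <- function(sample_ids, groups, n_folds) {
  ord <- order(groups, sample_ids)
  folds <- integer(length(ord))
  folds[ord] <- ((seq_along(ord) - 1L) %% n_folds) + 1L
  folds
}

#' Cross-validated Q2 of a PLS-DA model
#'
#' Predictive ability estimated by k-fold cross-validation with
#' deterministic venetian-blind folds (samples ordered by group then
#' sample id, dealt round-robin; never random):
#' \eqn{Q^2 = 1 - PRESS / SSY}, where PRESS accumulates squared
#' prediction errors of the centered group response over held-out folds.
#' Q2 near or below zero indicates a model with no predictive power.
#'
#' @inheritParams fit_plsda
#' @param n_folds Number of folds (default 7, the SIMCA convention).
#' @return Q2 (real, at most 1).
#' @export
q2_cross_validation <- function(intensities, groups, n_components = 2,
                                n_folds = 7,
                                scaling = c("uv", "center", "none"),
                                case = NULL) {
  scaling <- match.arg(scaling)
  n <- ncol(intensities)
  if (n_folds > n) stop("`n_folds` cannot exceed sample count", call. = FALSE)
  sample_ids <- colnames(intensities) %||% as.character(seq_len(n))
  folds <- venetian_folds(sample_ids, groups, n_folds)
  labs <- unique(groups)
  press <- 0
  y_all <- rep(NA_real_, n)
  for (k in sort(unique(folds))) {
    test <- folds == k
    if (any(vapply(labs, function(g) sum(groups[!test] == g), 0L) < 1L)) {
      stop(sprintf("fold %d removes every sample of one group", k),
           call. = FALSE)
    }
    prep <- prepare_xy(intensities[, !test, drop = FALSE], groups[!test],
                       case, scaling, on_constant = "keep")
    fit <- nipals_pls1(prep$x, prep$y, n_components)
    model <- list(weights = fit$weights, x_loadings = fit$x_loadings,
                  y_loadings = fit$y_loadings, center = prep$center,
                  scale = prep$scale)
    yhat <- predict_pls(model, intensities[, test, drop = FALSE])
    y_test <- ifelse(groups[test] == prep$case, 1, -1) - prep$y_center
    press <- press + sum((y_test - yhat)^2)
    y_all[test] <- ifelse(groups[test] == prep$case, 1, -1)
  }
  ssy <- sum((y_all - mean(y_all))^2)
  1 - press / ssy
}

#' Permutation validation of a PLS-DA model
#'
#' Refits the model under random permutations of the group labels and
#' compares the original cross-validated Q2 with the permuted Q2
#' distribution. Under the default `"quantile"` criterion the model is
#' declared valid when the original Q2 exceeds the 95th percentile of
#' the permuted Q2 values, so on signal-free data the call returns
#' valid about 5 percent of the time by construction. The `"intercept"`
#' criterion instead regresses permuted Q2 on the absolute correlation
#' between permuted and original labels and requires the extrapolated
#' intercept at zero correlation to fall below 0.05 (the SIMCA
#' convention).
#'
#' @inheritParams q2_cross_validation
#' @param n_permutations At least 20 (default 100).
#' @param seed Integer seed driving the label permutations.
#' @param criterion `"quantile"` (default) or `"intercept"`.
#' @return A `permutation_record`: permuted R2Y and Q2 vectors, the
#'   original values, and the validity verdict.
#' @export
permutation_validate <- function(intensities, groups, n_components = 2,
                                 n_permutations = 100, seed,
                                 n_folds = 7,
                                 scaling = c("uv", "center", "none"),
                                 case = NULL,
                                 criterion = c("quantile", "intercept")) {
  scaling <- match.arg(scaling)
  criterion <- match.arg(criterion)
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  n_permutations <- check_positive_int(n_permutations, "n_permutations")
  if (n_permutations < 20) {
    stop("`n_permutations` must be at least 20", call. = FALSE)
  }
  orig_fit <- fit_plsda(intensities, groups, n_components, scaling, case)
  orig_q2 <- q2_cross_validation(intensities, groups, n_components,
                                 n_folds, scaling, case)
  perm <- with_seed(seed, {
    lapply(seq_len(n_permutations), function(k) sample(groups))
  })
  perm_r2y <- perm_q2 <- perm_cor <- numeric(n_permutations)
  y0 <- ifelse(groups == orig_fit$case, 1, -1)
  for (k in seq_len(n_permutations)) {
    g <- perm[[k]]
    fit_k <- fit_plsda(intensities, g, n_components, scaling,
                       case = orig_fit$case)
    perm_r2y[k] <- fit_k$r2y
    perm_q2[k] <- q2_cross_validation(intensities, g, n_components,
                                      n_folds, scaling,
                                      case = orig_fit$case)
    perm_cor[k] <- abs(stats::cor(ifelse(g == orig_fit$case, 1, -1), y0))
  }
  valid <- if (criterion == "quantile") {
    orig_q2 > stats::quantile(perm_q2, 0.95, names = FALSE)
  } else {
    fit <- stats::lm(q2 ~ r, data.frame(q2 = c(perm_q2, orig_q2),
                                        r = c(perm_cor, 1)))
    unname(stats::coef(fit)[1]) < 0.05
  }
  structure(
    list(n_permutations = n_permutations, permuted_r2y = perm_r2y,
         permuted_q2 = perm_q2, permuted_cor = perm_cor,
         original_r2y = orig_fit$r2y, original_q2 = orig_q2,
         valid = valid, criterion = criterion, seed = as.integer(seed)),
    class = "permutation_record"
  )
}

#' @export
print.permutation_record <- function(x, ...) {
  cat(sprintf(
    "permutation validation (%d permutations, %s criterion)\n",
    x$n_permutations, x$criterion))
  cat(sprintf("  original R2Y = %.3f, Q2 = %.3f; permuted Q2 95th pct = %.3f\n",
              x$original_r2y, x$original_q2,
              stats::quantile(x$permuted_q2, 0.95, names = FALSE)))
  cat(sprintf("  model %s\n", if (x$valid) "VALID" else "NOT valid"))
  invisible(x)
}

#' Fit an OPLS-DA model and S-plot coordinates
#'
#' Orthogonal PLS-DA with one predictive and one Y-orthogonal component
#' (Trygg-Wold orthogonal signal correction): the first orthogonal
#' component is removed from X, a one-component PLS-DA is fitted on the
#' filtered matrix, and S-plot coordinates are returned for every
#' metabolite as (covariance with the predictive score, correlation with
#' the predictive score). Variables in the upper-right / lower-left
#' corners of the S-plot are both influential and reliable markers.
#' When the data carry no appreciable Y-orthogonal structure the
#' function falls back to a plain one-component PLS-DA with a warning.
#'
#' @inheritParams fit_plsda
#' @return An `oplsda_model`: `scores_pred`, `scores_ortho` (NULL after
#'   fallback), `s_plot` data frame (`variable`, `covariance`,
#'   `correlation`), `r2x_pred`, `r2x_ortho`, and the underlying weights.
#' @export
fit_oplsda <- function(intensities, groups,
                       scaling = c("uv", "center", "none"), case = NULL) {
  scaling <- match.arg(scaling)
  prep <- prepare_xy(intensities, groups, case, scaling)
  x <- prep$x
  y <- prep$y
  w <- drop(crossprod(x, y))
  w <- w / sqrt(sum(w^2))
  t1 <- drop(x %*% w)
  p1 <- drop(crossprod(x, t1)) / sum(t1^2)
  w_o <- p1 - sum(w * p1) * w
  nw_o <- sqrt(sum(w_o^2))
  fallback <- nw_o < 1e-8 * sqrt(sum(p1^2))
  if (fallback) {
    warning("no Y-orthogonal structure detected; returning plain PLS-DA",
            call. = FALSE)
    t_ortho <- NULL
    xd <- x
  } else {
    w_o <- w_o / nw_o
    t_ortho <- drop(x %*% w_o)
    p_o <- drop(crossprod(x, t_ortho)) / sum(t_ortho^2)
    xd <- x - tcrossprod(t_ortho, p_o)
  }
  wp <- drop(crossprod(xd, y))
  wp <- wp / sqrt(sum(wp^2))
  t_pred <- drop(xd %*% wp)
  covariance <- drop(crossprod(x, t_pred)) / (length(t_pred) - 1)
  sd_x <- apply(x, 2, stats::sd)
  correlation <- covariance / (sd_x * stats::sd(t_pred))
  correlation[sd_x == 0] <- 0
  s_plot <- data.frame(variable = prep$variable_ids,
                       covariance = unname(covariance),
                       correlation = unname(correlation),
                       stringsAsFactors = FALSE)
  structure(
    list(scores_pred = stats::setNames(t_pred, prep$sample_ids),
         scores_ortho = if (is.null(t_ortho)) NULL else
           stats::setNames(t_ortho, prep$sample_ids),
         s_plot = s_plot, weights_pred = wp,
         fallback = fallback, case = prep$case, groups = prep$groups),
    class = "oplsda_model"
  )
}

#' Per-metabolite univariate statistics
#'
#' Welch (unequal-variance) two-sided t-test and raw fold change
#' `mean(case) / mean(control)` for every metabolite, with the up/down
#' trend implied by the fold change.
#'
#' @inheritParams fit_plsda
#' @param control Denominator group; defaults to the label that is not
#'   `case`.
#' @return Data frame: `metabolite_id`, `p_value`, `fc`, `trend`.
#' @export
univariate_stats <- function(intensities, groups, case = NULL,
                             control = NULL) {
  if (!is.matrix(intensities) || !is.numeric(intensities)) {
    stop("`intensities` must be a numeric matrix", call. = FALSE)
  }
  labs <- unique(groups)
  if (length(labs) != 2) stop("exactly two groups required", call. = FALSE)
  if (is.null(case)) case <- if ("treated" %in% labs) "treated" else labs[1]
  if (is.null(control)) control <- setdiff(labs, case)
  if (sum(groups == case) < 2 || sum(groups == control) < 2) {
    stop("need at least two samples per group", call. = FALSE)
  }
  idx_case <- groups == case
  idx_ctrl <- groups == control
  res <- apply(intensities, 1, function(v) {
    m_ctrl <- mean(v[idx_ctrl])
    if (m_ctrl == 0) {
      stop("fold change undefined: zero control mean", call. = FALSE)
    }
    p <- tryCatch(stats::t.test(v[idx_case], v[idx_ctrl])$p.value,
                  error = function(e) NA_real_)
    c(p = p, fc = mean(v[idx_case]) / m_ctrl)
  })
  fc <- res["fc", ]
  data.frame(
    metabolite_id = rownames(intensities) %||%
      as.character(seq_len(nrow(intensities))),
    p_value = unname(res["p", ]), fc = unname(fc),
    trend = ifelse(fc > 1, "up", "down"),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Screen differential metabolites by VIP, p-value and fold change
#'
#' Joint screen: a metabolite passes when `vip > vip_threshold`,
#' `p_value < p_threshold` and its fold change clears the fold-change
#' criterion. The default criterion is two-sided
#' (`fc > fc_threshold` or `fc < 1/fc_threshold`), which with the
#' default `fc_threshold = 1` keeps any metabolite whose group means
#' differ in either direction — the behaviour implied by published
#' screens that report both increased and decreased metabolites. Set
#' `fc_mode = "greater"` for the literal one-sided `FC > threshold`
#' rule.
#'
#' @param stats Data frame with columns `metabolite_id` (or
#'   `metabolite`), `p_value` (or `p`), `fc`, and — if `vip` is not
#'   given separately — `vip`.
#' @param vip Optional named numeric vector of VIP scores aligned to the
#'   metabolite ids of `stats` (e.g. from [vip_scores()]).
#' @param vip_threshold,p_threshold,fc_threshold Strict cutoffs
#'   (defaults 1, 0.05, 1).
#' @param fc_mode `"two_sided"` (default) or `"greater"`.
#' @return Data frame: `metabolite_id`, `vip`, `p_value`, `fc`, `trend`,
#'   `passes`; the counts of passing, up- and down-regulated metabolites
#'   are attached as the `"summary"` attribute.
#' @export
screen_metabolites <- function(stats, vip = NULL, vip_threshold = 1,
                               p_threshold = 0.05, fc_threshold = 1,
                               fc_mode = c("two_sided", "greater")) {
  fc_mode <- match.arg(fc_mode)
  if (!is.data.frame(stats)) stop("`stats` must be a data frame", call. = FALSE)
  tab <- stats
  if (!"metabolite_id" %in% names(tab) && "metabolite" %in% names(tab)) {
    tab$metabolite_id <- tab$metabolite
  }
  if (!"p_value" %in% names(tab) && "p" %in% names(tab)) {
    tab$p_value <- tab$p
  }
  if (!all(c("metabolite_id", "p_value", "fc") %in% names(tab))) {
    stop("`stats` needs metabolite id, p-value and fc columns",
         call. = FALSE)
  }
  if (is.null(vip)) {
    if (!"vip" %in% names(tab)) {
      stop("supply `vip` or include a `vip` column in `stats`",
           call. = FALSE)
    }
    vip_vec <- tab$vip
  } else {
    if (is.null(names(vip)) ||
        !setequal(names(vip), tab$metabolite_id) ||
        anyDuplicated(names(vip))) {
      stop("`vip` names do not align with `stats` metabolite ids",
           call. = FALSE)
    }
    vip_vec <- unname(vip[tab$metabolite_id])
  }
  if (fc_threshold <= 0) stop("`fc_threshold` must be > 0", call. = FALSE)
  fc_ok <- if (fc_mode == "two_sided") {
    tab$fc > fc_threshold | tab$fc < 1 / fc_threshold
  } else {
    tab$fc > fc_threshold
  }
  passes <- vip_vec > vip_threshold & tab$p_value < p_threshold & fc_ok
  passes[is.na(passes)] <- FALSE
  out <- data.frame(metabolite_id = tab$metabolite_id, vip = vip_vec,
                    p_value = tab$p_value, fc = tab$fc,
                    trend = ifelse(tab$fc > 1, "up", "down"),
                    passes = passes, stringsAsFactors = FALSE,
                    row.names = NULL)
  attr(out, "summary") <- c(n_pass = sum(passes),
                            n_up = sum(passes & out$fc > 1),
                            n_down = sum(passes & out$fc < 1))
  out
}

#' Hierarchical-clustering heatmap ordering
#'
#' Z-scores every metabolite across samples, then clusters rows
#' (metabolites) and columns (samples) by average-linkage hierarchical
#' clustering on Euclidean distances — the deterministic ordering behind
#' a standard metabolomics heatmap. Zero-variance metabolites cannot be
#' z-scored and are excluded with a warning.
#'
#' @param intensities Numeric matrix, metabolites x samples.
#' @return List: `z` (z-scored matrix, reduced to non-constant rows),
#'   `row_order` / `col_order` (dendrogram leaf orders), `row_hclust` /
#'   `col_hclust` (the `hclust` objects).
#' @export
hclust_heatmap_order <- function(intensities) {
  if (!is.matrix(intensities) || nrow(intensities) < 2) {
    stop("`intensities` must be a matrix with at least two rows",
         call. = FALSE)
  }
  sds <- apply(intensities, 1, stats::sd)
  if (any(sds == 0)) {
    warning(sprintf("excluding %d zero-variance metabolite(s)",
                    sum(sds == 0)), call. = FALSE)
    intensities <- intensities[sds > 0, , drop = FALSE]
    sds <- sds[sds > 0]
  }
  z <- (intensities - rowMeans(intensities)) / sds
  rh <- stats::hclust(stats::dist(z), method = "average")
  ch <- stats::hclust(stats::dist(t(z)), method = "average")
  list(z = z, row_order = rh$order, col_order = ch$order,
       row_hclust = rh, col_hclust = ch)
}

#' Hypergeometric pathway over-representation analysis
#'
#' One-sided hypergeometric tail test per pathway: with `N` universe
#' metabolites, `K` of them in the pathway and `n` screen hits of which
#' `k` fall in the pathway, the p-value is `P(X >= k)` for
#' hypergeometric `X`. Pathway members outside the universe are ignored.
#'
#' @param hits Character vector of screened-in metabolites; must be a
#'   subset of `universe`.
#' @param universe Character vector of all measured metabolites.
#' @param pathways Named list of character vectors (pathway members).
#' @param adjust If `TRUE`, add a Benjamini-Hochberg `p_adj` column.
#' @return Data frame sorted by p-value: `pathway`, `pathway_size`,
#'   `n_hits`, `overlap`, `p_value` (and optionally `p_adj`).
#' @export
ora_enrichment <- function(hits, universe, pathways, adjust = FALSE) {
  hits <- unique(as.character(hits))
  universe <- unique(as.character(universe))
  if (!all(hits %in% universe)) {
    stop("`hits` must be a subset of `universe`", call. = FALSE)
  }
  if (is.null(names(pathways)) || any(names(pathways) == "")) {
    stop("`pathways` must be a named list", call. = FALSE)
  }
  n_univ <- length(universe)
  n_hits <- length(hits)
  rows <- lapply(names(pathways), function(nm) {
    pw <- intersect(unique(as.character(pathways[[nm]])), universe)
    k <- length(intersect(hits, pw))
    p <- stats::phyper(k - 1, length(pw), n_univ - length(pw), n_hits,
                       lower.tail = FALSE)
    data.frame(pathway = nm, pathway_size = length(pw), n_hits = n_hits,
               overlap = k, p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (adjust) out$p_adj <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[order(out$p_value, out$pathway), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Published differential-metabolite panel (formononetin vs control,
#' HepG2 cells)
#'
#' Loads the packaged 47-metabolite panel reported for
#' formononetin-treated versus control HepG2 cell extracts (UPLC-MS/MS;
#' VIP from a PLS-DA model, Welch t-test p-value, treated/control fold
#' change, and trend direction). Useful as a realistic worked example
#' for [screen_metabolites()] and [ora_enrichment()].
#'
#' @return Data frame with columns `metabolite`, `formula`, `mz`, `rt`,
#'   `hmdb`, `vip`, `p_value`, `fc`, `trend`, `scan_mode`.
#' @export
fm_metabolite_panel <- function() {
  path <- system.file("extdata", "fm_hepg2_diff_metabolites.tsv",
                      package = "herbnet", mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  tab$trend <- ifelse(tab$trend == "up", "up", "down")
  tab
}
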