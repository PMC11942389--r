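sim_default <- function(seed = 42, ...) {
  gen_metabolites(metabo_sim_spec(seed = seed, ...))
}

test_that("NIPALS PLS-DA separates groups and keeps its invariants", {
  sim <- sim_default()
  m <- fit_plsda(sim$intensities, sim$groups, n_components = 3)
  y <- ifelse(sim$groups == "treated", 1, -1)
  expect_gt(abs(cor(m$scores[, 1], y)), 0.99)
  # unit-norm weights and orthogonal scores
  expect_equal(colSums(m$weights^2), rep(1, 3), ignore_attr = TRUE)
  g <- crossprod(m$scores)
  expect_lt(max(abs(g[upper.tri(g)])), 1e-8)
  # explained-variance monotonicity and bounds
  expect_true(all(diff(m$r2x_cum) >= 0))
  expect_true(all(diff(m$r2y_cum) >= 0))
  expect_true(m$r2x >= 0 && m$r2x <= 1)
  # sample permutation equivariance
  set.seed(8)
  perm <- sample(ncol(sim$intensities))
  m2 <- fit_plsda(sim$intensities[, perm], sim$groups[perm], 3)
  expect_equal(unname(m2$scores[order(perm), ]), unname(m$scores))
  expect_equal(m2$r2x, m$r2x)
  expect_equal(m2$r2y, m$r2y)
})

test_that("full-rank PLS reconstructs X and constant variables error", {
  set.seed(12)
  x <- matrix(rnorm(8 * 6), nrow = 8,
              dimnames = list(paste0("m", 1:8), paste0("s", 1:6)))
  g <- rep(c("control", "treated"), each = 3)
  m <- fit_plsda(x, g, n_components = 5)
  expect_gte(m$r2x, 1 - 1e-6)
  x2 <- x
  x2[1, ] <- 5
  expect_error(fit_plsda(x2, g, 2), "constant variable.*m1")
})

test_that("PLS-DA agrees with an independent NIPALS implementation", {
  sim <- sim_default(7)
  m <- fit_plsda(sim$intensities, sim$groups, 2)
  suppressMessages(requireNamespace("mixOmics", quietly = TRUE))
  mo <- mixOmics::plsda(t(sim$intensities), factor(sim$groups),
                        ncomp = 2, scale = TRUE)
  expect_gt(abs(cor(m$scores[, 1], mo$variates$X[, 1])), 0.999)
  v_ours <- vip_scores(m)
  v_ref <- mixOmics::vip(mo)[, 2]
  expect_gt(cor(v_ours, v_ref[names(v_ours)]), 0.999)
})

test_that("VIP follows Wold's formula and its algebraic identity", {
  # one-component model with all weight on variable 1 of 4 -> VIP (2,0,0,0)
  model <- structure(
    list(weights = matrix(c(1, 0, 0, 0), ncol = 1,
                          dimnames = list(paste0("v", 1:4), "w1")),
         ssy_comp = 1),
    class = "pls_model")
  expect_equal(unname(vip_scores(model)), c(2, 0, 0, 0))
  # literal-formula oracle on random fitted models
  for (s in 1:10) {
    sim <- sim_default(200 + s, n_metabolites = 30, n_per_group = 8)
    m <- fit_plsda(sim$intensities, sim$groups, 3)
    p <- nrow(m$weights)
    oracle <- sqrt(p * colSums(t(m$weights^2) * m$ssy_comp) /
                     sum(m$ssy_comp))
    expect_equal(unname(vip_scores(m)), unname(oracle), tolerance = 1e-12)
    expect_equal(mean(vip_scores(m)^2), 1, tolerance = 1e-8)
  }
  model$ssy_comp <- 0
  expect_error(vip_scores(model), "no Y-variance")
})

test_that("Q2 separates signal from noise and never exceeds R2Y", {
  noise <- sim_default(3, n_diff = 0)
  expect_lt(q2_cross_validation(noise$intensities, noise$groups, 2), 0.2)
  strong <- sim_default(5, n_diff = 40)
  expect_gt(q2_cross_validation(strong$intensities, strong$groups, 2), 0.7)
  for (s in 1:5) {
    sim <- sim_default(300 + s, n_metabolites = 40, n_per_group = 6)
    m <- fit_plsda(sim$intensities, sim$groups, 2)
    q2 <- q2_cross_validation(sim$intensities, sim$groups, 2)
    expect_lte(q2, m$r2y)
  }
  # a fold that would empty one group errors (single treated sample
  # lands in the same fold as a control under 3 venetian blinds)
  set.seed(2)
  unb <- matrix(rexp(4 * 6, 1 / 100), nrow = 6,
                dimnames = list(paste0("m", 1:6), paste0("s", 1:4)))
  expect_error(q2_cross_validation(unb, c("control", "control", "control",
                                          "treated"),
                                   n_components = 1, n_folds = 3),
               "removes every sample")
})

test_that("permutation validation flags signal and is reproducible", {
  sim <- sim_default(5, n_diff = 10)
  rec <- permutation_validate(sim$intensities, sim$groups,
                              n_permutations = 100, seed = 5)
  expect_true(rec$valid)
  expect_length(rec$permuted_q2, 100)
  expect_length(rec$permuted_r2y, 100)
  rec2 <- permutation_validate(sim$intensities, sim$groups,
                               n_permutations = 100, seed = 5)
  expect_identical(rec$permuted_q2, rec2$permuted_q2)
  expect_error(permutation_validate(sim$intensities, sim$groups,
                                    n_permutations = 5, seed = 1),
               "at least 20")
  # intercept criterion also reaches a verdict on strong signal
  rec3 <- permutation_validate(sim$intensities, sim$groups,
                               n_permutations = 20, seed = 2,
                               criterion = "intercept")
  expect_true(rec3$valid)
})

test_that("OPLS-DA yields bounded S-plot coordinates that rank markers", {
  sim <- sim_default(13)
  o <- fit_oplsda(sim$intensities, sim$groups)
  expect_true(all(abs(o$s_plot$correlation) <= 1 + 1e-12))
  planted <- o$s_plot$variable %in% sim$truth
  thr <- quantile(abs(o$s_plot$correlation[!planted]), 0.9)
  expect_true(all(abs(o$s_plot$correlation[planted]) > thr))
  # predictive scores still separate the groups
  y <- ifelse(sim$groups == "treated", 1, -1)
  expect_gt(abs(cor(o$scores_pred, y)), 0.99)
})

test_that("univariate stats produce Welch p, raw FC and trend", {
  x <- matrix(c(10, 12, 11, 40, 44, 42,
                30, 29, 31, 30.5, 29.5, 30),
              nrow = 2, byrow = TRUE,
              dimnames = list(c("up4", "flat"), paste0("s", 1:6)))
  g <- rep(c("control", "treated"), each = 3)
  st <- univariate_stats(x, g)
  expect_equal(st$fc[st$metabolite_id == "up4"], 42 / 11)
  expect_identical(st$trend, c("up", "down"))
  expect_equal(st$p_value[1],
               t.test(x[1, 4:6], x[1, 1:3])$p.value)
  same <- matrix(rep(c(1, 2, 3), 4), nrow = 2, byrow = TRUE,
                 dimnames = list(c("a", "b"), paste0("s", 1:6)))
  st2 <- univariate_stats(same, g)
  expect_equal(st2$fc, c(1, 1))
  expect_true(all(st2$p_value > 0.9))
})

test_that("metabolite screen honours thresholds and counts trends", {
  tab <- data.frame(metabolite_id = c("a", "b", "c", "d"),
                    p_value = c(0.01, 0.01, 0.2, 0.01),
                    fc = c(3, 0.2, 4, 1))
  vip <- c(a = 2, b = 1.5, c = 2, d = 3)
  out <- screen_metabolites(tab, vip)
  expect_equal(out$passes, c(TRUE, TRUE, FALSE, FALSE))
  s <- attr(out, "summary")
  expect_equal(unname(s), c(2, 1, 1))
  # literal one-sided rule drops the down-regulated metabolite
  lit <- screen_metabolites(tab, vip, fc_mode = "greater")
  expect_equal(lit$passes, c(TRUE, FALSE, FALSE, FALSE))
  expect_error(screen_metabolites(tab, vip[-1]), "align")
})

test_that("screen recovers planted metabolites on synthetic data", {
  sim <- sim_default(11)
  m <- fit_plsda(sim$intensities, sim$groups, 2)
  st <- univariate_stats(sim$intensities, sim$groups)
  out <- screen_metabolites(st, vip_scores(m))
  hits <- out$metabolite_id[out$passes]
  sens <- mean(sim$truth %in% hits)
  spec <- 1 - sum(!hits %in% sim$truth) /
    (nrow(sim$intensities) - length(sim$truth))
  expect_gte(sens, 0.9)
  expect_gte(spec, 0.95)
})

test_that("heatmap ordering z-scores rows and clusters groups", {
  sim <- sim_default(9, n_diff = 40)
  ord <- hclust_heatmap_order(sim$intensities)
  expect_equal(unname(rowMeans(ord$z)), rep(0, nrow(ord$z)),
               tolerance = 1e-12)
  expect_equal(unname(apply(ord$z, 1, sd)), rep(1, nrow(ord$z)),
               tolerance = 1e-12)
  k2 <- cutree(ord$col_hclust, k = 2)
  expect_identical(length(unique(tapply(k2, sim$groups, paste,
                                        collapse = ""))), 2L)
  expect_true(all(tapply(k2, sim$groups,
                         function(v) length(unique(v))) == 1))
  # identical samples sit at zero distance, adjacent leaves
  x <- cbind(a = c(1, 5, 9), b = c(1, 5, 9), c = c(7, 2, 4))
  rownames(x) <- paste0("m", 1:3)
  oc <- hclust_heatmap_order(x)
  pos <- match(c("a", "b"), colnames(x)[oc$col_order])
  expect_equal(abs(diff(pos)), 1)
  # zero-variance row excluded with a warning
  x2 <- rbind(x, m4 = c(3, 3, 3))
  expect_warning(o2 <- hclust_heatmap_order(x2), "zero-variance")
  expect_false("m4" %in% rownames(o2$z))
})

test_that("hypergeometric ORA matches closed form and enumeration", {
  universe <- paste0("m", 1:10)
  pw <- list(path1 = paste0("m", 1:5))
  res <- ora_enrichment(paste0("m", 1:3), universe, pw)
  expect_equal(res$p_value, choose(5, 3) / choose(10, 3))
  # pathway = universe and empty hits are certain events
  expect_equal(ora_enrichment(paste0("m", 1:3), universe,
                              list(all = universe))$p_value, 1)
  expect_equal(ora_enrichment(character(0), universe, pw)$p_value, 1)
  expect_error(ora_enrichment("zz", universe, pw), "subset")
  # exact combinatorial enumeration oracle on a small universe
  set.seed(4)
  for (rep in 1:10) {
    n_univ <- sample(6:12, 1)
    univ <- paste0("u", seq_len(n_univ))
    pset <- sample(univ, sample(2:(n_univ - 1), 1))
    hits <- sample(univ, sample(1:(n_univ - 1), 1))
    k_obs <- length(intersect(hits, pset))
    combos <- combn(n_univ, length(hits))
    overlap <- apply(combos, 2,
                     function(ix) sum(univ[ix] %in% pset))
    p_enum <- mean(overlap >= k_obs)
    res <- ora_enrichment(hits, univ, list(p = pset))
    expect_equal(res$p_value, p_enum, tolerance = 1e-12)
  }
})

test_that("the packaged metabolite panel matches its published screen", {
  tab <- fm_metabolite_panel()
  expect_identical(nrow(tab), 47L)
  out <- screen_metabolites(tab)
  expect_true(all(out$passes))
  expect_identical(out$trend, tab$trend)
})
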