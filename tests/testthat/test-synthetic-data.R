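test_that("count generator is deterministic and respects the null case", {
  spec <- count_sim_spec(n_genes = 200, n_tumor = 20, n_normal = 20,
                         n_deg = 20, planted_log2fc = 3, seed = 7)
  a <- gen_counts(spec)
  b <- gen_counts(spec)
  expect_identical(a$counts, b$counts)
  expect_identical(a$truth, b$truth)
  expect_true(all(a$counts >= 0))
  expect_length(a$truth, 20)

  null <- gen_counts(count_sim_spec(n_genes = 50, n_tumor = 5,
                                    n_normal = 5, n_deg = 0, seed = 1))
  expect_length(null$truth, 0)
})

test_that("planted genes show the requested mean fold change", {
  sim <- gen_counts(count_sim_spec(n_genes = 200, n_tumor = 20,
                                   n_normal = 20, n_deg = 20,
                                   planted_log2fc = 3, seed = 7))
  tum <- sim$counts[sim$truth, sim$groups == "tumor", drop = FALSE]
  nor <- sim$counts[sim$truth, sim$groups == "normal", drop = FALSE]
  ratio <- rowMeans(tum) / rowMeans(nor)
  # law-of-large-numbers check: the sample mean ratio is near 2^3 = 8
  expect_true(mean(ratio) > 8 * 0.75 && mean(ratio) < 8 * 1.25)
  expect_true(all(ratio > 8 * 0.5 & ratio < 8 * 1.5))
  non <- setdiff(rownames(sim$counts), sim$truth)
  r0 <- rowMeans(sim$counts[non, sim$groups == "tumor"]) /
    rowMeans(sim$counts[non, sim$groups == "normal"])
  expect_lt(median(abs(log2(r0))), 0.5)
})

test_that("count spec rejects invalid parameters", {
  expect_error(count_sim_spec(n_genes = 0, seed = 1), "positive integer")
  expect_error(count_sim_spec(n_genes = 10, n_deg = 11, seed = 1),
               "cannot exceed")
  expect_error(count_sim_spec(dispersion = -1, seed = 1), "positive real")
  expect_error(count_sim_spec(), "`seed` is required")
})

test_that("network generator plants a dominant core and is reproducible", {
  spec <- network_sim_spec(core_component_degree = 15,
                           background_degree_mean = 3, seed = 1)
  a <- gen_ct_network(spec)
  b <- gen_ct_network(spec)
  expect_identical(a$edges, b$edges)
  deg <- table(a$edges$component_id)
  expect_identical(names(which.max(deg)), a$core_id)
  expect_identical(unname(deg[a$core_id]), 15L)
  # every component keeps at least one edge
  expect_setequal(unique(a$edges$component_id), a$components$component_id)
  # core always passes the OB/DL filter
  core <- a$components[a$components$component_id == a$core_id, ]
  expect_true(core$ob >= 30 && core$dl >= 0.18)
  n_pass <- sum(a$components$ob >= 30 & a$components$dl >= 0.18)
  expect_equal(n_pass, round(0.7 * nrow(a$components)))
})

test_that("degenerate single-edge network and invalid specs are handled", {
  one <- gen_ct_network(network_sim_spec(n_components_A = 1,
                                         n_components_B = 0, n_targets = 1,
                                         core_component_degree = 1,
                                         seed = 4))
  expect_identical(nrow(one$edges), 1L)
  expect_error(network_sim_spec(n_targets = 5, core_component_degree = 6,
                                seed = 1),
               "cannot exceed")
})

test_that("metabolite generator plants the requested fold change", {
  spec <- metabo_sim_spec(n_metabolites = 200, n_per_group = 10,
                          n_diff = 10, planted_fc = 4, cv_noise = 0.1,
                          seed = 21)
  a <- gen_metabolites(spec)
  expect_identical(a$intensities, gen_metabolites(spec)$intensities)
  expect_true(all(a$intensities > 0))
  trt <- a$intensities[a$truth, a$groups == "treated", drop = FALSE]
  ctl <- a$intensities[a$truth, a$groups == "control", drop = FALSE]
  fc <- rowMeans(trt) / rowMeans(ctl)
  expect_true(all(fc > 3 & fc < 5.3))

  null <- gen_metabolites(metabo_sim_spec(n_diff = 0, seed = 2))
  expect_length(null$truth, 0)
  expect_error(metabo_sim_spec(planted_fc = -2, seed = 1), "positive real")
  expect_error(metabo_sim_spec(planted_fc = 1, seed = 1), "differ from 1")
})

test_that("observed fold change concentrates around the planted value", {
  # Monte-Carlo across seeds: with fc = 4, cv = 0.1, n = 10 the observed
  # ratio stays well inside [3, 5.3]
  fcs <- vapply(1:50, function(s) {
    sim <- gen_metabolites(metabo_sim_spec(n_metabolites = 20, n_diff = 5,
                                           planted_fc = 4, cv_noise = 0.1,
                                           n_per_group = 10, seed = s))
    trt <- sim$intensities[sim$truth, sim$groups == "treated", drop = FALSE]
    ctl <- sim$intensities[sim$truth, sim$groups == "control", drop = FALSE]
    range(rowMeans(trt) / rowMeans(ctl))
  }, numeric(2))
  expect_true(all(fcs[1, ] > 3) && all(fcs[2, ] < 5.3))
})
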