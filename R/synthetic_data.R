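#' Specification for a synthetic RNA-seq count matrix
#'
#' Describes a two-group (tumor vs normal) gene-by-sample count simulation
#' with a planted set of differentially expressed genes. Counts are drawn
#' from a gamma-Poisson (negative binomial) model so the downstream
#' Wilcoxon screen sees realistic overdispersion.
#'
#' @param n_genes Number of genes simulated.
#' @param n_tumor,n_normal Samples per group.
#' @param n_deg Number of planted differential genes (`<= n_genes`).
#' @param planted_log2fc Planted effect size in log2 units: planted genes
#'   have tumor/normal mean ratio `2^planted_log2fc`.
#' @param dispersion Negative-binomial dispersion (1/size); variance is
#'   `mu + dispersion * mu^2`.
#' @param base_mean_range Length-2 positive range; baseline gene means are
#'   drawn log-uniformly over it.
#' @param seed Integer seed; identical specs give bit-identical output.
#' @return An object of class `count_sim_spec`.
#' @seealso [gen_counts()]
#' @export
count_sim_spec <- function(n_genes = 1000, n_tumor = 50, n_normal = 50,
                           n_deg = 100, planted_log2fc = 3,
                           dispersion = 0.1,
                           base_mean_range = c(10, 1000), seed) {
  n_genes <- check_positive_int(n_genes, "n_genes")
  n_tumor <- check_positive_int(n_tumor, "n_tumor")
  n_normal <- check_positive_int(n_normal, "n_normal")
  if (!is.numeric(n_deg) || length(n_deg) != 1L || n_deg < 0 ||
      n_deg != floor(n_deg)) {
    stop("`n_deg` must be a non-negative integer", call. = FALSE)
  }
  if (n_deg > n_genes) stop("`n_deg` cannot exceed `n_genes`", call. = FALSE)
  dispersion <- check_positive_real(dispersion, "dispersion")
  if (length(base_mean_range) != 2L || any(base_mean_range <= 0) ||
      base_mean_range[1] > base_mean_range[2]) {
    stop("`base_mean_range` must be an increasing pair of positive reals",
         call. = FALSE)
  }
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  structure(
    list(n_genes = n_genes, n_tumor = n_tumor, n_normal = n_normal,
         n_deg = as.integer(n_deg), planted_log2fc = as.numeric(planted_log2fc),
         dispersion = dispersion, base_mean_range = as.numeric(base_mean_range),
         seed = as.integer(seed)),
    class = "count_sim_spec"
  )
}

#' Simulate a two-group count matrix with planted fold changes
#'
#' Draws gamma-Poisson counts for `n_tumor + n_normal` samples. Exactly
#' `n_deg` genes (the truth set) have tumor-group mean equal to
#' `2^planted_log2fc` times their normal-group mean; all other genes share
#' one mean across groups.
#'
#' @param spec A [count_sim_spec()].
#' @return A list with `counts` (integer matrix, genes x samples),
#'   `groups` (character vector, `"tumor"`/`"normal"`, aligned with
#'   columns), and `truth` (character vector of planted gene ids; empty
#'   when `n_deg = 0`).
#' @export
gen_counts <- function(spec) {
  stopifnot(inherits(spec, "count_sim_spec"))
  with_seed(spec$seed, {
    gene_ids <- sprintf("gene_%04d", seq_len(spec$n_genes))
    groups <- c(rep("tumor", spec$n_tumor), rep("normal", spec$n_normal))
    sample_ids <- c(sprintf("tumor_%02d", seq_len(spec$n_tumor)),
                    sprintf("normal_%02d", seq_len(spec$n_normal)))
    lr <- log(spec$base_mean_range)
    base_mean <- exp(stats::runif(spec$n_genes, lr[1], lr[2]))
    truth <- if (spec$n_deg > 0) {
      sort(sample(gene_ids, spec$n_deg))
    } else {
      character(0)
    }
    mu <- matrix(base_mean, nrow = spec$n_genes, ncol = length(groups))
    planted <- gene_ids %in% truth
    mu[planted, groups == "tumor"] <-
      mu[planted, groups == "tumor"] * 2^spec$planted_log2fc
    counts <- matrix(
      stats::rnbinom(length(mu), mu = mu, size = 1 / spec$dispersion),
      nrow = spec$n_genes,
      dimnames = list(gene_ids, sample_ids)
    )
    list(counts = counts, groups = groups, truth = truth, spec = spec)
  })
}

#' Specification for a synthetic two-herb component-target network
#'
#' Describes a bipartite network between compounds of two herbs (A and B)
#' and protein targets, with one designated high-degree "core" compound
#' planted in herb A. Background compound degrees are Poisson with the
#' given mean, truncated below at 1 so no compound is isolated. Oral
#' bioavailability (OB, percent) and drug-likeness (DL) values are
#' assigned so that the requested fraction of compounds passes the usual
#' ADME filter (OB >= 30, DL >= 0.18); the core always passes.
#'
#' @param n_components_A,n_components_B Compounds per herb
#'   (`n_components_A >= 1`; the core belongs to herb A).
#' @param n_targets Number of targets.
#' @param core_component_degree Degree planted on the core compound; must
#'   not exceed `n_targets` and should exceed `background_degree_mean`.
#' @param background_degree_mean Poisson mean for background degrees.
#' @param ob_dl_pass_fraction Fraction of compounds passing the OB/DL
#'   filter, in \[0, 1\].
#' @param seed Integer seed.
#' @return An object of class `network_sim_spec`.
#' @seealso [gen_ct_network()]
#' @export
network_sim_spec <- function(n_components_A = 20, n_components_B = 16,
                             n_targets = 80, core_component_degree = 15,
                             background_degree_mean = 3,
                             ob_dl_pass_fraction = 0.7, seed) {
  n_components_A <- check_positive_int(n_components_A, "n_components_A")
  if (!is.numeric(n_components_B) || n_components_B < 0 ||
      n_components_B != floor(n_components_B)) {
    stop("`n_components_B` must be a non-negative integer", call. = FALSE)
  }
  n_targets <- check_positive_int(n_targets, "n_targets")
  core_component_degree <- check_positive_int(core_component_degree,
                                              "core_component_degree")
  if (core_component_degree > n_targets) {
    stop("`core_component_degree` cannot exceed `n_targets`", call. = FALSE)
  }
  background_degree_mean <- check_positive_real(background_degree_mean,
                                                "background_degree_mean")
  if (ob_dl_pass_fraction < 0 || ob_dl_pass_fraction > 1) {
    stop("`ob_dl_pass_fraction` must lie in [0, 1]", call. = FALSE)
  }
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  structure(
    list(n_components_A = n_components_A,
         n_components_B = as.integer(n_components_B),
         n_targets = n_targets,
         core_component_degree = core_component_degree,
         background_degree_mean = background_degree_mean,
         ob_dl_pass_fraction = as.numeric(ob_dl_pass_fraction),
         seed = as.integer(seed)),
    class = "network_sim_spec"
  )
}

#' Simulate a component-target bipartite network with a planted core
#'
#' @param spec A [network_sim_spec()].
#' @return A list with `components` (data frame: `component_id`, `herb`,
#'   `ob`, `dl`), `edges` (data frame: `component_id`, `target_id`),
#'   and `core_id` (the planted core compound, always the first herb-A
#'   compound).
#' @export
gen_ct_network <- function(spec) {
  stopifnot(inherits(spec, "network_sim_spec"))
  with_seed(spec$seed, {
    ids_a <- sprintf("A_%02d", seq_len(spec$n_components_A))
    ids_b <- if (spec$n_components_B > 0) {
      sprintf("B_%02d", seq_len(spec$n_components_B))
    } else {
      character(0)
    }
    ids <- c(ids_a, ids_b)
    herb <- c(rep("A", length(ids_a)), rep("B", length(ids_b)))
    n_comp <- length(ids)
    core_id <- ids_a[1]
    targets <- sprintf("T_%03d", seq_len(spec$n_targets))

    # Background degrees: Poisson truncated below at 1 (zeros lifted to 1
    # so the graph has no isolated compound), capped at n_targets.
    deg <- pmax(stats::rpois(n_comp, spec$background_degree_mean), 1L)
    deg <- pmin(deg, spec$n_targets)
    deg[1] <- spec$core_component_degree
    edges <- do.call(rbind, lapply(seq_len(n_comp), function(i) {
      data.frame(component_id = ids[i],
                 target_id = sample(targets, deg[i]),
                 stringsAsFactors = FALSE)
    }))

    n_pass <- max(1L, round(spec$ob_dl_pass_fraction * n_comp))
    pass <- rep(FALSE, n_comp)
    pass[1] <- TRUE                       # core always passes
    extra <- setdiff(seq_len(n_comp), 1L)
    if (n_pass > 1L) pass[sample(extra, n_pass - 1L)] <- TRUE
    ob <- dl <- numeric(n_comp)
    ob[pass] <- stats::runif(sum(pass), 30, 100)
    dl[pass] <- stats::runif(sum(pass), 0.18, 1)
    ob[!pass] <- stats::runif(sum(!pass), 5, 29.5)
    dl[!pass] <- stats::runif(sum(!pass), 0.02, 0.17)

    components <- data.frame(component_id = ids, herb = herb,
                             ob = ob, dl = dl, stringsAsFactors = FALSE)
    list(components = components, edges = edges, core_id = core_id,
         spec = spec)
  })
}

#' Specification for a synthetic metabolite intensity matrix
#'
#' Describes a two-group (control vs treated) metabolite-by-sample
#' intensity simulation with a planted set of differential metabolites.
#' Noise is multiplicative log-normal, matching positive, right-skewed MS
#' intensities; `cv_noise` is the per-measurement coefficient of
#' variation.
#'
#' @param n_metabolites Number of metabolites.
#' @param n_per_group Samples per group.
#' @param n_diff Number of planted differential metabolites.
#' @param planted_fc Planted treated/control group-mean ratio (positive,
#'   not 1).
#' @param cv_noise Coefficient of variation of the multiplicative noise.
#' @param seed Integer seed.
#' @return An object of class `metabo_sim_spec`.
#' @seealso [gen_metabolites()]
#' @export
metabo_sim_spec <- function(n_metabolites = 200, n_per_group = 10,
                            n_diff = 10, planted_fc = 4, cv_noise = 0.1,
                            seed) {
  n_metabolites <- check_positive_int(n_metabolites, "n_metabolites")
  n_per_group <- check_positive_int(n_per_group, "n_per_group")
  if (!is.numeric(n_diff) || n_diff < 0 || n_diff != floor(n_diff)) {
    stop("`n_diff` must be a non-negative integer", call. = FALSE)
  }
  if (n_diff > n_metabolites) {
    stop("`n_diff` cannot exceed `n_metabolites`", call. = FALSE)
  }
  planted_fc <- check_positive_real(planted_fc, "planted_fc")
  if (planted_fc == 1) stop("`planted_fc` must differ from 1", call. = FALSE)
  cv_noise <- check_positive_real(cv_noise, "cv_noise")
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  structure(
    list(n_metabolites = n_metabolites, n_per_group = n_per_group,
         n_diff = as.integer(n_diff), planted_fc = planted_fc,
         cv_noise = cv_noise, seed = as.integer(seed)),
    class = "metabo_sim_spec"
  )
}

#' Simulate a two-group metabolite intensity matrix
#'
#' Control-group means are drawn log-uniformly over \eqn{[10^3, 10^6]}
#' (typical LC-MS peak-area scale); planted metabolites have their
#' treated-group mean multiplied by `planted_fc`. Every intensity is the
#' group mean times a log-normal factor with coefficient of variation
#' `cv_noise`, so all intensities are strictly positive and the expected
#' group-mean ratio of a planted metabolite is exactly `planted_fc`.
#'
#' @param spec A [metabo_sim_spec()].
#' @return A list with `intensities` (matrix, metabolites x samples),
#'   `groups` (`"control"`/`"treated"` per column), and `truth` (planted
#'   metabolite ids).
#' @export
gen_metabolites <- function(spec) {
  stopifnot(inherits(spec, "metabo_sim_spec"))
  with_seed(spec$seed, {
    met_ids <- sprintf("met_%03d", seq_len(spec$n_metabolites))
    groups <- rep(c("control", "treated"), each = spec$n_per_group)
    sample_ids <- c(sprintf("control_%02d", seq_len(spec$n_per_group)),
                    sprintf("treated_%02d", seq_len(spec$n_per_group)))
    base <- 10^stats::runif(spec$n_metabolites, 3, 6)
    truth <- if (spec$n_diff > 0) sort(sample(met_ids, spec$n_diff)) else character(0)
    mu <- matrix(base, nrow = spec$n_metabolites, ncol = length(groups))
    planted <- met_ids %in% truth
    mu[planted, groups == "treated"] <-
      mu[planted, groups == "treated"] * spec$planted_fc
    sdlog <- sqrt(log(1 + spec$cv_noise^2))
    noise <- exp(stats::rnorm(length(mu), -sdlog^2 / 2, sdlog))
    intensities <- matrix(mu * noise, nrow = spec$n_metabolites,
                          dimnames = list(met_ids, sample_ids))
    list(intensities = intensities, groups = groups, truth = truth,
         spec = spec)
  })
}
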