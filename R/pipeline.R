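# End-to-end orchestration: simulate -> deg -> network -> ci -> metabo
# -> report, driven by a validated YAML/list config. Every table is
# plain delimited text with a header; every random draw flows from the
# config seeds.

#' Default pipeline configuration
#'
#' @return A named list holding the default stage list, thresholds
#'   (p < 0.05 and |log2FC| > 2 for the expression screen; OB >= 30 and
#'   DL >= 0.18 for compounds; VIP > 1, p < 0.05 and two-sided FC for
#'   metabolites), contribution-index normalization, simulation specs
#'   and seed.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    out_dir = "herbnet_run",
    stages = c("simulate", "deg", "network", "ci", "metabo", "report"),
    thresholds = list(p_deg = 0.05, log2fc = 2, ob_min = 30,
                      dl_min = 0.18, vip = 1, p_metabo = 0.05, fc = 1),
    ci_normalization = "mean",
    n_pls_components = 2,
    top_k = 10,
    simulate = list(
      counts = list(n_genes = 1000, n_tumor = 50, n_normal = 50,
                    n_deg = 100, planted_log2fc = 3, dispersion = 0.1,
                    base_mean_range = c(10, 1000)),
      network = list(n_components_A = 20, n_components_B = 16,
                     n_targets = 80, core_component_degree = 15,
                     background_degree_mean = 3,
                     ob_dl_pass_fraction = 0.7),
      metabolites = list(n_metabolites = 200, n_per_group = 10,
                         n_diff = 10, planted_fc = 4, cv_noise = 0.1)
    )
  )
}

config_schema <- function() {
  list(
    top = c("seed", "out_dir", "stages", "thresholds", "ci_normalization",
            "n_pls_components", "top_k", "simulate"),
    thresholds = c("p_deg", "log2fc", "ob_min", "dl_min", "vip",
                   "p_metabo", "fc"),
    simulate = c("counts", "network", "metabolites"),
    counts = c("n_genes", "n_tumor", "n_normal", "n_deg",
               "planted_log2fc", "dispersion", "base_mean_range"),
    network = c("n_components_A", "n_components_B", "n_targets",
                "core_component_degree", "background_degree_mean",
                "ob_dl_pass_fraction"),
    metabolites = c("n_metabolites", "n_per_group", "n_diff",
                    "planted_fc", "cv_noise")
  )
}

#' Validate a pipeline configuration
#'
#' Reads a YAML file (or takes a list), merges it over the defaults and
#' checks it: unknown keys anywhere are rejected, thresholds must be
#' positive (p-value cutoffs within (0, 1]), and stage names must be
#' known. All violations are collected and reported together, not just
#' the first.
#'
#' @param config Path to a YAML file, or a named list of overrides.
#' @return A validated config list of class `pipeline_config`.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      stop(sprintf("config file not found: %s", config), call. = FALSE)
    }
    config <- yaml::read_yaml(config)
    if (is.null(config)) config <- list()
  }
  if (!is.list(config)) {
    stop("`config` must be a YAML file path or a list", call. = FALSE)
  }
  schema <- config_schema()
  problems <- character(0)
  note <- function(fmt, ...) {
    problems <<- c(problems, sprintf(fmt, ...))
  }
  unknown <- setdiff(names(config), schema$top)
  if (length(unknown) > 0) note("unknown key(s): %s",
                                paste(unknown, collapse = ", "))
  for (grp in c("thresholds", "simulate")) {
    if (!is.null(config[[grp]])) {
      bad <- setdiff(names(config[[grp]]), schema[[grp]])
      if (length(bad) > 0) note("unknown key(s) under %s: %s", grp,
                                paste(bad, collapse = ", "))
    }
  }
  if (!is.null(config$simulate)) {
    for (grp in intersect(names(config$simulate), schema$simulate)) {
      bad <- setdiff(names(config$simulate[[grp]]), schema[[grp]])
      if (length(bad) > 0) note("unknown key(s) under simulate$%s: %s",
                                grp, paste(bad, collapse = ", "))
    }
  }

  merged <- utils::modifyList(default_config(), config)
  bad_stage <- setdiff(merged$stages,
                       c("simulate", "deg", "network", "ci", "metabo",
                         "report"))
  if (length(bad_stage) > 0) note("unknown stage(s): %s",
                                  paste(bad_stage, collapse = ", "))
  th <- merged$thresholds
  for (k in schema$thresholds) {
    v <- th[[k]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0) {
      note("threshold `%s` must be a positive number", k)
    }
  }
  for (k in c("p_deg", "p_metabo")) {
    v <- th[[k]]
    if (is.numeric(v) && length(v) == 1L && !is.na(v) && v > 1) {
      note("threshold `%s` must lie in (0, 1]", k)
    }
  }
  if (!merged$ci_normalization %in% c("mean", "literal", "sum")) {
    note("`ci_normalization` must be one of mean, literal, sum")
  }
  if (!is.numeric(merged$seed) || length(merged$seed) != 1L ||
      is.na(merged$seed)) {
    note("`seed` must be a single integer")
  }
  for (k in c("n_pls_components", "top_k")) {
    v <- merged[[k]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 1 ||
        v != floor(v)) {
      note("`%s` must be a positive integer", k)
    }
  }
  if (length(problems) > 0) {
    stop(paste(c("invalid configuration:",
                 paste0("  - ", problems)), collapse = "\n"),
         call. = FALSE)
  }
  merged$seed <- as.integer(merged$seed)
  class(merged) <- c("pipeline_config", "list")
  merged
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

write_matrix_tsv <- function(m, path, id_col) {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  write_tsv(df, path)
}

#' Read a delimited feature-by-sample matrix
#'
#' First column holds feature ids, remaining columns one sample each
#' (header row of sample ids).
#'
#' @param path TSV file path.
#' @return Numeric matrix with dimnames.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

log_stage <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order — `simulate` (write seeded
#' synthetic inputs), `deg` (Wilcoxon/fold-change expression screen),
#' `network` (OB/DL compound filter + component-target network build),
#' `ci` (contribution-index ranking), `metabo` (PLS-DA, VIP, Q2 and the
#' differential-metabolite screen) and `report` — writing one delimited
#' table per stage plus a JSON run report into `config$out_dir`. A rerun
#' with the same config and seed reproduces every output byte for byte.
#' Any stage failure aborts the run with the stage named in the error.
#'
#' @param config A `pipeline_config`, a YAML path, or a list of
#'   overrides (see [validate_config()]).
#' @return Invisibly, the run report (also written as
#'   `run_report.json`): per-stage record counts, the parameter echo,
#'   package version and seed.
#' @export
run_pipeline <- function(config = list()) {
  if (!inherits(config, "pipeline_config")) config <- validate_config(config)
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(version = as.character(utils::packageVersion("herbnet")),
                 seed = config$seed, parameters = config$thresholds,
                 ci_normalization = config$ci_normalization,
                 stages = list())
  t0 <- proc.time()[["elapsed"]]
  run_stage <- function(stage, fn) {
    if (!stage %in% config$stages) return(invisible(NULL))
    t1 <- proc.time()[["elapsed"]]
    rec <- tryCatch(fn(), error = function(e) {
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE)
    })
    rec$seconds <- round(proc.time()[["elapsed"]] - t1, 3)
    report$stages[[stage]] <<- rec
  }
  env <- new.env()

  run_stage("simulate", function() {
    sp <- config$simulate
    env$sim_counts <- gen_counts(do.call(count_sim_spec,
                                         c(sp$counts, seed = config$seed)))
    env$sim_net <- gen_ct_network(do.call(network_sim_spec,
                                          c(sp$network,
                                            seed = config$seed + 1L)))
    env$sim_metabo <- gen_metabolites(do.call(metabo_sim_spec,
                                              c(sp$metabolites,
                                                seed = config$seed + 2L)))
    write_matrix_tsv(env$sim_counts$counts,
                     file.path(out_dir, "counts.tsv"), "gene_id")
    write_tsv(data.frame(sample_id = colnames(env$sim_counts$counts),
                         group = env$sim_counts$groups),
              file.path(out_dir, "count_groups.tsv"))
    write_tsv(env$sim_net$components, file.path(out_dir, "components.tsv"))
    write_tsv(env$sim_net$edges, file.path(out_dir, "edges.tsv"))
    write_matrix_tsv(env$sim_metabo$intensities,
                     file.path(out_dir, "intensities.tsv"), "metabolite_id")
    write_tsv(data.frame(sample_id = colnames(env$sim_metabo$intensities),
                         group = env$sim_metabo$groups),
              file.path(out_dir, "metabo_groups.tsv"))
    jsonlite::write_json(
      list(deg = env$sim_counts$truth, core = env$sim_net$core_id,
           metabolites = env$sim_metabo$truth),
      file.path(out_dir, "truth.json"))
    log_stage("simulate", "%d genes, %d compounds, %d metabolites",
              nrow(env$sim_counts$counts), nrow(env$sim_net$components),
              nrow(env$sim_metabo$intensities))
    list(n_genes = nrow(env$sim_counts$counts),
         n_components = nrow(env$sim_net$components),
         n_metabolites = nrow(env$sim_metabo$intensities))
  })

  run_stage("deg", function() {
    counts <- env$sim_counts$counts %||%
      read_matrix_tsv(file.path(out_dir, "counts.tsv"))
    groups <- env$sim_counts$groups %||%
      utils::read.delim(file.path(out_dir, "count_groups.tsv"))$group
    deg <- screen_degs(counts, groups,
                       p_threshold = config$thresholds$p_deg,
                       fc_threshold = config$thresholds$log2fc)
    write_tsv(deg, file.path(out_dir, "deg_table.tsv"))
    env$deg <- deg
    log_stage("deg", "%d / %d genes pass p < %g and |log2FC| > %g",
              sum(deg$is_deg), nrow(deg), config$thresholds$p_deg,
              config$thresholds$log2fc)
    list(input = nrow(deg), passing = sum(deg$is_deg),
         dropped = sum(!deg$is_deg))
  })

  run_stage("network", function() {
    comps <- env$sim_net$components %||%
      utils::read.delim(file.path(out_dir, "components.tsv"),
                        stringsAsFactors = FALSE)
    edges <- env$sim_net$edges %||%
      utils::read.delim(file.path(out_dir, "edges.tsv"),
                        stringsAsFactors = FALSE)
    keep <- filter_components(comps, config$thresholds$ob_min,
                              config$thresholds$dl_min)
    edges_kept <- edges[edges$component_id %in% keep$component_id, ,
                        drop = FALSE]
    env$net <- build_ct_network(keep, edges_kept)
    write_tsv(env$net$edges, file.path(out_dir, "network_edges.tsv"))
    nodes <- rbind(
      data.frame(id = names(env$net$Ci), type = "component",
                 degree = unname(env$net$Ci)),
      data.frame(id = names(env$net$Pj), type = "target",
                 degree = unname(env$net$Pj)))
    write_tsv(nodes, file.path(out_dir, "network_nodes.tsv"))
    log_stage("network", "%d / %d compounds pass OB/DL; %d targets, %d edges",
              nrow(keep), nrow(comps), length(env$net$targets),
              env$net$Tedge)
    list(input = nrow(comps), passing = nrow(keep),
         dropped = nrow(comps) - nrow(keep), Tedge = env$net$Tedge)
  })

  run_stage("ci", function() {
    if (is.null(env$net)) stop("network stage output missing")
    res <- compute_ci(env$net, normalization = config$ci_normalization)
    write_tsv(res, file.path(out_dir, "ci_table.tsv"))
    k <- min(config$top_k, nrow(res))
    summary <- list(n_components = length(env$net$Ci),
                    n_targets = length(env$net$Pj),
                    Tedge = env$net$Tedge, top_k = k,
                    cumulative = top_k_cumulative(res, k))
    jsonlite::write_json(summary, file.path(out_dir, "ci_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    env$ci <- res
    log_stage("ci", "top-%d cumulative CI = %.2f%%", k, summary$cumulative)
    list(input = nrow(res), top_k = k,
         cumulative_ci = summary$cumulative)
  })

  run_stage("metabo", function() {
    intens <- env$sim_metabo$intensities %||%
      read_matrix_tsv(file.path(out_dir, "intensities.tsv"))
    groups <- env$sim_metabo$groups %||%
      utils::read.delim(file.path(out_dir, "metabo_groups.tsv"))$group
    model <- fit_plsda(intens, groups,
                       n_components = config$n_pls_components)
    q2 <- q2_cross_validation(intens, groups,
                              n_components = config$n_pls_components)
    uni <- univariate_stats(intens, groups)
    screen <- screen_metabolites(uni, vip_scores(model),
                                 vip_threshold = config$thresholds$vip,
                                 p_threshold = config$thresholds$p_metabo,
                                 fc_threshold = config$thresholds$fc)
    write_tsv(screen, file.path(out_dir, "metabo_screen.tsv"))
    jsonlite::write_json(list(r2x = model$r2x, r2y = model$r2y, q2 = q2),
                         file.path(out_dir, "pls_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    env$metabo <- screen
    s <- attr(screen, "summary")
    log_stage("metabo", "R2X %.3f R2Y %.3f Q2 %.3f; %d pass (%d up, %d down)",
              model$r2x, model$r2y, q2, s["n_pass"], s["n_up"], s["n_down"])
    list(input = nrow(screen), passing = unname(s["n_pass"]),
         up = unname(s["n_up"]), down = unname(s["n_down"]),
         r2x = model$r2x, r2y = model$r2y, q2 = q2)
  })

  report$seconds <- round(proc.time()[["elapsed"]] - t0, 3)
  if ("report" %in% config$stages) {
    jsonlite::write_json(report, file.path(out_dir, "run_report.json"),
                         auto_unbox = TRUE, digits = NA)
    log_stage("report", "written to %s",
              file.path(out_dir, "run_report.json"))
  }
  invisible(report)
}
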