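# End-to-end orchestration: a configuration (R list or YAML file) names the
# stages to run and their parameters; every stochastic stage requires an
# explicit seed, and a JSON manifest records versions, seeds, parameters and
# output digests so a run can be replayed and compared byte for byte.

.require_fields <- function(x, fields, where) {
  missing_f <- setdiff(fields, names(x))
  if (length(missing_f)) {
    stop(sprintf("config section '%s' is missing field(s): %s", where,
                 paste(missing_f, collapse = ", ")), call. = FALSE)
  }
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in order and writes their artifacts plus a
#' run manifest under `out_dir`.  Supported stages:
#'
#' * `"simulate"` — phantom parcellation and two-group regional time series
#'   with optional planted edges (section `simulate`: `dims`, `n_rois`,
#'   `n_time`, `n_per_group`, `effect_size`, optional `edges`, `bins`).
#' * `"connectome"` — per-subject mutual-information connectivity matrices
#'   (section `connectome`: optional `bins`), written as TSV.
#' * `"compare"` — edgewise group comparison with FDR control and the
#'   subnetwork block summary (section `compare`: optional `fdr`,
#'   `covariates` TSV path).
#' * `"surface"` — factor-surface generation and formula distillation
#'   (section `surface`: `formula`, optional `n_rows`, `n_cols`,
#'   `noise_frac`, `epochs`, `restarts`, `lambda`, `tau`).
#'
#' A top-level integer `seed` is required.  Configuration may be an R list
#' or a YAML file path; the manifest (`manifest.json`) records the package
#' version, R version, seed, per-stage parameters, status, and MD5 digests
#' of every written artifact, so identical configs give identical digests
#' for the deterministic stages.
#'
#' @param config an R list or the path to a YAML config file.
#' @return Invisibly, a list with `manifest` and the in-memory stage
#'   `results`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config, call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  .require_fields(config, c("seed", "out_dir", "stages"), "top level")
  seed <- as.integer(config$seed)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- config$stages
  known <- c("simulate", "connectome", "compare", "surface")
  if (!all(stages %in% known)) {
    stop("unknown stage(s): ", paste(setdiff(stages, known), collapse = ", "),
         call. = FALSE)
  }

  manifest <- list(package = "factorlens",
                   version = as.character(packageVersion("factorlens")),
                   r_version = as.character(getRversion()),
                   seed = seed, stages = list())
  results <- list()
  artifacts <- character(0)
  log_stage <- function(stage, msg) {
    message(sprintf("[%s] %s | %s", format(Sys.time(), "%H:%M:%S"), stage, msg))
  }

  if ("simulate" %in% stages) {
    sim <- config$simulate
    .require_fields(sim, c("dims", "n_rois", "n_time", "n_per_group",
                           "effect_size"), "simulate")
    log_stage("simulate", "generating parcellation and group time series")
    parc <- phantom_parcellation(unlist(sim$dims), n_rois = sim$n_rois,
                                 seed = seed)
    edges <- if (!is.null(sim$edges)) matrix(unlist(sim$edges), ncol = 2L,
                                             byrow = TRUE)
    spec <- planted_difference_spec(n_rois = sim$n_rois, n_time = sim$n_time,
                                    n_per_group = sim$n_per_group,
                                    edges = edges,
                                    effect_size = sim$effect_size,
                                    bins = sim$bins %||% 16L, seed = seed)
    groups <- group_timeseries(spec)
    paths <- write_parcellation(parc, file.path(out_dir, "parcellation.nii.gz"),
                                file.path(out_dir, "subnetworks.tsv"))
    artifacts <- c(artifacts, paths)
    results$simulate <- list(parcellation = parc, groups = groups, spec = spec)
    manifest$stages$simulate <- list(status = "ok",
                                     params = sim,
                                     mixing_weight = groups$mixing_weight)
  }

  if ("connectome" %in% stages) {
    if (is.null(results$simulate)) {
      stop("stage 'connectome' needs the 'simulate' stage (or precomputed series)",
           call. = FALSE)
    }
    bins <- config$connectome$bins %||% 16L
    log_stage("connectome", sprintf("building MI matrices (bins = %d)", bins))
    conn <- lapply(c(results$simulate$groups$groupA,
                     results$simulate$groups$groupB),
                   build_connectivity, bins = bins)
    nA <- length(results$simulate$groups$groupA)
    for (k in seq_along(conn)) {
      p <- file.path(out_dir, sprintf("connectivity_%s.tsv",
                                      if (k <= nA) sprintf("A%02d", k)
                                      else sprintf("B%02d", k - nA)))
      write_connectivity(conn[[k]], p)
      artifacts <- c(artifacts, p)
    }
    results$connectome <- list(groupA = conn[seq_len(nA)],
                               groupB = conn[-seq_len(nA)], bins = bins)
    manifest$stages$connectome <- list(status = "ok", bins = bins,
                                       n_matrices = length(conn))
  }

  if ("compare" %in% stages) {
    if (is.null(results$connectome)) {
      stop("stage 'compare' needs the 'connectome' stage", call. = FALSE)
    }
    fdr <- config$compare$fdr %||% 0.05
    covariates <- NULL
    if (!is.null(config$compare$covariates)) {
      if (!file.exists(config$compare$covariates)) {
        stop("covariate file not found (config field compare$covariates): ",
             config$compare$covariates, call. = FALSE)
      }
      covariates <- read.table(config$compare$covariates, header = TRUE,
                               sep = "\t")
    }
    log_stage("compare", sprintf("edgewise comparison at FDR q = %g", fdr))
    cmp <- edgewise_group_comparison(results$connectome$groupA,
                                     results$connectome$groupB,
                                     covariates = covariates, q = fdr)
    p_edges <- file.path(out_dir, "edges.tsv")
    write.table(cmp$edges, p_edges, sep = "\t", row.names = FALSE, quote = FALSE)
    artifacts <- c(artifacts, p_edges)
    blocks <- NULL
    if (!is.null(results$simulate)) {
      blocks <- subnetwork_summary(cmp, results$simulate$parcellation)
      p_blocks <- file.path(out_dir, "subnetwork_blocks.tsv")
      write.table(blocks, p_blocks, sep = "\t", quote = FALSE)
      artifacts <- c(artifacts, p_blocks)
    }
    results$compare <- list(comparison = cmp, blocks = blocks)
    manifest$stages$compare <- list(status = "ok", fdr = fdr,
                                    n_significant = sum(cmp$edges$significant))
  }

  if ("surface" %in% stages) {
    surf <- config$surface
    .require_fields(surf, "formula", "surface")
    log_stage("surface", sprintf("distilling '%s'", surf$formula))
    s <- formula_surface(surf$formula,
                         n_rows = surf$n_rows %||% 50L,
                         n_cols = surf$n_cols %||% 50L,
                         noise_frac = surf$noise_frac %||% 0.01,
                         seed = seed)
    fit <- fit_surface_formula(s$triplets, seed = seed,
                               restarts = surf$restarts %||% 2L,
                               epochs = surf$epochs %||% 800L,
                               lambda = surf$lambda %||% 1e-3,
                               tau = surf$tau %||% 0.05)
    p_formula <- file.path(out_dir, "formula.json")
    write_formula_json(fit$formula, p_formula, accuracy = fit$report)
    artifacts <- c(artifacts, p_formula)
    results$surface <- fit
    manifest$stages$surface <- list(status = "ok", formula = surf$formula,
                                    accuracy = fit$report$accuracy)
  }

  manifest$artifacts <- lapply(stats::setNames(nm = basename(unname(artifacts))),
                               function(nm) {
                                 p <- artifacts[basename(unname(artifacts)) == nm][1]
                                 list(path = unname(p),
                                      md5 = unname(tools::md5sum(unname(p))))
                               })
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  log_stage("done", sprintf("manifest written to %s", manifest_path))
  invisible(list(manifest = manifest, results = results))
}
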