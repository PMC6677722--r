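# Pipeline runner behind the command-line interface.
#
# A flat YAML config drives six stages (simulate, smooth, build-module,
# validate, proximity, screen).  A single global seed fans out to per-stage
# streams (seed + fixed offset) so stages can be rerun in isolation and the
# whole pipeline is byte-reproducible.  Every tabular output carries a
# header comment naming the config hash and seed; no timestamps are written.

.gps_commands <- c("simulate", "smooth", "build-module", "validate",
                   "proximity", "screen")
.stage_offset <- function(command) {
  match(command, .gps_commands) * 1000L
}

.config_error <- function(msg) {
  stop(structure(class = c("gps_config_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}
.input_error <- function(msg) {
  stop(structure(class = c("gps_input_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

#' Default run configuration
#'
#' All thresholds default to the values used throughout the package:
#' restart probability 0.5, connectivity / co-expression / edge-retention
#' cuts at 0.05, minimum raw-module size 10, top 1% of raw modules, gene
#' confidence 0.5%, signature amplitude threshold 0.67 and 1000
#' permutations.
#'
#' @return Named list of defaults.
#' @export
default_run_config <- function() {
  list(
    seed = 1L,
    out_dir = "gpsnet_out",
    alpha = 0.5,
    coexpression_p_thresh = 0.05,
    connectivity_p = 0.05,
    coexpression_p = 0.05,
    min_module_size = 10L,
    seeds_per_gene = 5,
    top_fraction = 0.01,
    confidence_threshold = 0.005,
    up_threshold = 0.67,
    n_perm = 1000L,
    counts = FALSE,
    # simulate-stage generator settings
    n_genes = 500L,
    mean_degree = 6,
    planted_size = 20L,
    base_rate = 0.002,
    effect_fold = 10,
    n_samples = 100L,
    within_correlation = 0.6,
    n_drugs = 12L,
    n_proximal = 3L,
    n_concordant = 3L,
    targets_per_drug = 3L,
    # input paths (simulate writes them; later stages read them)
    interactome = NULL,
    mutations = NULL,
    expression = NULL,
    scores = NULL,
    module = NULL,
    drug_targets = NULL,
    drug_signatures = NULL,
    reference_genes = NULL
  )
}

#' Read a run configuration
#'
#' YAML key-value file merged over [default_run_config()]; unknown keys are
#' rejected.
#'
#' @param path YAML file path.
#' @return Configuration list with attribute `config_hash`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) .config_error(paste("config file not found:",
                                              path))
  user <- yaml::read_yaml(path)
  conf <- default_run_config()
  unknown <- setdiff(names(user), names(conf))
  if (length(unknown) > 0L) {
    .config_error(paste("unknown config key(s):",
                        paste(unknown, collapse = ", ")))
  }
  conf[names(user)] <- user
  .validate_config(conf)
  conf
}

#' Write a run configuration as YAML
#'
#' @param config Configuration list.
#' @param path Output path.
#' @export
write_run_config <- function(config, path) {
  config <- config[!vapply(config, is.null, logical(1))]
  yaml::write_yaml(config, path)
  invisible(path)
}

.validate_config <- function(conf) {
  if (!is.numeric(conf$seed) || conf$seed != round(conf$seed)) {
    .config_error("seed must be an integer")
  }
  if (!(conf$alpha > 0 && conf$alpha <= 1)) {
    .config_error("alpha must be in (0, 1]")
  }
  for (key in c("coexpression_p_thresh", "connectivity_p",
                "coexpression_p", "top_fraction",
                "confidence_threshold")) {
    if (!(conf[[key]] > 0 && conf[[key]] < 1)) {
      .config_error(paste(key, "must be in (0, 1)"))
    }
  }
  invisible(conf)
}

# Hash of the scientific parameters only: input/output locations are
# machine-specific and must not break byte-reproducibility across hosts.
.config_path_keys <- c("out_dir", "interactome", "mutations", "expression",
                       "scores", "module", "drug_targets",
                       "drug_signatures", "reference_genes")

.config_hash <- function(config) {
  params <- config[setdiff(names(default_run_config()),
                           .config_path_keys)]
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(params, tmp)
  unname(tools::md5sum(tmp))
}

.require_inputs <- function(config, keys) {
  for (key in keys) {
    path <- config[[key]]
    if (is.null(path)) {
      .config_error(paste0("config key '", key,
                           "' is required for this command"))
    }
    if (!file.exists(path)) {
      .input_error(paste0("input file for '", key, "' not found: ", path))
    }
  }
}

.run_log <- function(config, command, extra = list()) {
  c(list(command = command,
         seed = config$seed,
         stage_seed = config$seed + .stage_offset(command),
         config_hash = .config_hash(config),
         package_version = as.character(utils::packageVersion("gpsnet"))),
    extra)
}

#' Run a pipeline stage
#'
#' Commands: `simulate` (write a complete seeded synthetic study),
#' `smooth` (initial + smoothed scores), `build-module` (co-expression
#' network, raw modules, final module), `validate` (LCC significance and
#' optional reference-set enrichment), `proximity` (per-drug proximity
#' z-scores), `screen` (full ranked repurposing screen).  Each stage writes
#' its artifacts plus a machine-readable JSON run log into `out_dir`.
#'
#' @param command One of the six stage names.
#' @param config A configuration list (see [default_run_config()]) or the
#'   path to a YAML config file.
#' @return Invisibly, a list of the paths written.
#' @export
gps_run <- function(command, config) {
  if (!command %in% .gps_commands) {
    stop(structure(class = c("gps_command_error", "error", "condition"),
                   list(message = paste("unknown command:", command),
                        call = NULL)))
  }
  if (is.character(config)) config <- read_run_config(config)
  .validate_config(config)
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  header <- c(paste0("gpsnet config_hash=", .config_hash(config)),
              paste0("seed=", config$seed))
  stage_seed <- config$seed + .stage_offset(command)
  paths <- switch(command,
    "simulate" = .stage_simulate(config, out_dir, header, stage_seed),
    "smooth" = .stage_smooth(config, out_dir, header),
    "build-module" = .stage_build_module(config, out_dir, header,
                                         stage_seed),
    "validate" = .stage_validate(config, out_dir, header, stage_seed),
    "proximity" = .stage_proximity(config, out_dir, header, stage_seed),
    "screen" = .stage_screen(config, out_dir, header, stage_seed)
  )
  log_path <- file.path(out_dir, paste0(gsub("-", "_", command),
                                        "_log.json"))
  jsonlite::write_json(.run_log(config, command,
                                list(outputs = basename(unname(paths)))),
                       log_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(paths, log = log_path))
}

.stage_simulate <- function(config, out_dir, header, stage_seed) {
  study <- generate_study(
    seed = stage_seed, n_genes = config$n_genes,
    mean_degree = config$mean_degree, planted_size = config$planted_size,
    base_rate = config$base_rate, effect_fold = config$effect_fold,
    n_samples = config$n_samples,
    within_correlation = config$within_correlation,
    n_drugs = config$n_drugs, n_proximal = config$n_proximal,
    n_concordant = config$n_concordant,
    targets_per_drug = config$targets_per_drug)

  p <- c(interactome = file.path(out_dir, "interactome.tsv"),
         mutations = file.path(out_dir, "mutations.tsv"),
         expression = file.path(out_dir, "expression.tsv"),
         drug_targets = file.path(out_dir, "drug_targets.tsv"),
         drug_signatures = file.path(out_dir, "drug_signatures.gmt"),
         truth = file.path(out_dir, "truth.json"))

  el <- igraph::as_edgelist(study$graph)
  .write_tsv_with_header(data.frame(gene_a = el[, 1L], gene_b = el[, 2L]),
                         p[["interactome"]], header)
  .write_tsv_with_header(
    data.frame(gene = names(study$profile$mutation_count),
               mutation_count = as.integer(study$profile$mutation_count),
               cdna_length = as.integer(study$profile$cdna_length)),
    p[["mutations"]], header)
  .write_tsv_with_header(
    data.frame(gene = rownames(study$expr),
               round(study$expr, 6), check.names = FALSE),
    p[["expression"]], header)
  tt <- do.call(rbind, lapply(study$drugs, function(d) {
    data.frame(drug = d$drug, target = d$targets)
  }))
  .write_tsv_with_header(tt, p[["drug_targets"]], header)
  sig_sets <- list()
  for (d in study$drugs) {
    sig_sets[[paste0(d$drug, "_UP")]] <- d$signature$up
    sig_sets[[paste0(d$drug, "_DOWN")]] <- d$signature$down
  }
  write_gmt(sig_sets, p[["drug_signatures"]])
  jsonlite::write_json(unclass(study$truth), p[["truth"]],
                       auto_unbox = TRUE, pretty = TRUE)
  p
}

.stage_smooth <- function(config, out_dir, header) {
  .require_inputs(config, c("interactome", "mutations"))
  graph <- load_edge_list(config$interactome)
  profile <- read_mutation_table(config$mutations)
  s0 <- initial_scores(profile, igraph::V(graph)$name)
  s <- rwr_smooth(graph, s0, alpha = config$alpha)
  path <- file.path(out_dir, "scores.tsv")
  write_score_table(path, s0, s,
                    header = c(header,
                               paste0("alpha=", config$alpha),
                               paste0("iterations=",
                                      attr(s, "iterations"))))
  c(scores = path)
}

.stage_build_module <- function(config, out_dir, header, stage_seed) {
  .require_inputs(config, c("interactome", "mutations", "expression"))
  graph <- load_edge_list(config$interactome)
  profile <- read_mutation_table(config$mutations)
  expr <- read_expression_matrix(config$expression)
  params <- growth_params(
    connectivity_p = config$connectivity_p,
    coexpression_p = config$coexpression_p,
    min_module_size = config$min_module_size,
    seeds_per_gene = config$seeds_per_gene,
    top_fraction = config$top_fraction,
    confidence_threshold = config$confidence_threshold,
    rng_seed = stage_seed)
  res <- find_disease_module(graph, profile, expr, alpha = config$alpha,
                             p_thresh = config$coexpression_p_thresh,
                             counts = isTRUE(config$counts),
                             params = params)
  module_path <- file.path(out_dir, "module.tsv")
  genes <- res$final$genes
  .write_tsv_with_header(
    data.frame(gene = genes,
               confidence = as.numeric(res$final$confidence[genes]),
               s_smoothed = as.numeric(res$scores[genes])),
    module_path, header)
  zq <- stats::quantile(vapply(res$ensemble$raw_modules, `[[`,
                               numeric(1), "score"),
                        c(0.25, 0.5, 0.75))
  meta_path <- file.path(out_dir, "module_meta.json")
  jsonlite::write_json(
    list(params = unclass(params), mu = res$mu,
         n_raw_modules = res$final$n_raw,
         n_surviving = res$final$n_surviving,
         n_top = res$final$n_top,
         n_module_genes = length(genes),
         raw_score_quartiles = as.list(zq),
         mutation_count_semantics = "as provided (patients or events)"),
    meta_path, auto_unbox = TRUE, pretty = TRUE)
  c(module = module_path, meta = meta_path)
}

.read_module_genes <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           comment.char = "#")
  as.character(tab$gene)
}

.stage_validate <- function(config, out_dir, header, stage_seed) {
  .require_inputs(config, c("interactome", "module"))
  graph <- load_edge_list(config$interactome)
  genes <- .read_module_genes(config$module)
  set.seed(stage_seed)
  lcc <- lcc_significance(graph, genes, n_perm = config$n_perm)
  out <- list(lcc = list(observed = lcc$observed, p_value = lcc$p_value,
                         z_score = lcc$z_score,
                         n_permutations = lcc$n_permutations))
  if (!is.null(config$reference_genes)) {
    .require_inputs(config, "reference_genes")
    ref <- read_gene_set(config$reference_genes)
    enr <- overlap_enrichment_permutation(graph, genes, ref,
                                          n_perm = config$n_perm)
    out$reference_enrichment <- list(observed = enr$observed,
                                     p_value = enr$p_value,
                                     z_score = enr$z_score,
                                     n_permutations = enr$n_permutations)
  }
  path <- file.path(out_dir, "validation.json")
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE)
  c(validation = path)
}

.stage_proximity <- function(config, out_dir, header, stage_seed) {
  .require_inputs(config, c("interactome", "module", "drug_targets"))
  graph <- load_edge_list(config$interactome)
  genes <- .read_module_genes(config$module)
  targets <- read_drug_targets(config$drug_targets)
  binning <- degree_binning(graph)
  set.seed(stage_seed)
  rows <- lapply(names(targets), function(d) {
    pz <- proximity_z(graph, genes, targets[[d]], binning,
                      n_perm = config$n_perm)
    data.frame(drug = d, n_targets = pz$n_targets,
               n_reachable = pz$n_reachable,
               distance = round(pz$distance, 6),
               null_mean = round(pz$null_mean, 6),
               null_sd = round(pz$null_sd, 6),
               z = round(pz$z_score, 6), p = round(pz$p_value, 6))
  })
  path <- file.path(out_dir, "proximity.tsv")
  .write_tsv_with_header(do.call(rbind, rows), path, header)
  c(proximity = path)
}

.stage_screen <- function(config, out_dir, header, stage_seed) {
  .require_inputs(config, c("interactome", "module", "drug_targets",
                            "drug_signatures"))
  graph <- load_edge_list(config$interactome)
  genes <- .read_module_genes(config$module)
  targets <- read_drug_targets(config$drug_targets)
  signatures <- read_signature_gmt(config$drug_signatures)
  ids <- union(names(targets), names(signatures))
  drugs <- lapply(ids, function(d) {
    list(drug = d, targets = targets[[d]], signature = signatures[[d]])
  })
  set.seed(stage_seed)
  tab <- repurpose_screen(drugs, genes, graph, n_perm = config$n_perm)
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], round, 6)
  path <- file.path(out_dir, "screen.tsv")
  .write_tsv_with_header(tab, path, header)
  c(screen = path)
}
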