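# Orchestration: one config drives simulate -> batch-adjust -> network
# inference (x2 conditions) -> meta-analysis -> gene ranking -> module ->
# characterisation -> drugs, with every stage's inputs/outputs on disk and a
# JSON provenance record (config hash, seed, stage checksums).

#' Default pipeline configuration
#'
#' All tunable parameters of the synthetic-to-drugs pipeline with their
#' defaults, sized for the generator's standard study conditions (200 genes,
#' 3 studies, 50 samples per condition, 20-gene planted module).
#'
#' @return Nested named list (YAML-serialisable).
#' @export
default_config <- function() {
  list(
    synth = list(n_genes = 200, n_studies = 3, samples_per_condition = 50,
                 module_size = 20, rho_in = 0.8, rho_out = 0,
                 effect_size = 1, batch_sd = 1, noise_sd = 1,
                 overlap_frac = 0.8, n_decoys = 10),
    network = list(estimators = c("pearson", "spearman", "kendall",
                                  "mi_empirical", "mi_millermadow",
                                  "mi_shrink", "mi_sg"),
                   algorithms = c("clr", "aracne", "mrnet"),
                   mean_degree = 20, dpi_eps = 0, walk_length = 4),
    meta = list(n_perm = 200),
    evidence = list(top_n = 30, min_evidence = 3),
    module = list(alpha = 0.05, n_iterations = NULL),
    drugs = list(min_genes = 5, use_distances = FALSE)
  )
}

.required_keys <- list(
  synth = c("n_genes", "n_studies", "samples_per_condition", "module_size",
            "rho_in", "rho_out", "effect_size", "overlap_frac"),
  network = c("estimators", "algorithms", "mean_degree"),
  meta = "n_perm",
  evidence = c("top_n", "min_evidence"),
  module = "alpha",
  drugs = "min_genes")

#' Validate a pipeline configuration
#'
#' @param config nested list, or a path to a YAML file.
#' @return The validated config (invisibly usable); missing required keys
#'   raise an error naming the key.
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  for (sect in names(.required_keys)) {
    if (is.null(config[[sect]]))
      stop("config is missing section '", sect, "'")
    for (key in .required_keys[[sect]]) {
      if (is.null(config[[sect]][[key]]))
        stop("config is missing key '", sect, ".", key, "'")
    }
  }
  config
}

# stable per-stage child seeds below 2^31
.stage_seed <- function(seed, stage_index) {
  (as.integer(seed) + 7919L * as.integer(stage_index)) %% 2147483629L
}

.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full synthetic-to-drugs pipeline
#'
#' Executes all stages and writes each stage's outputs as plain-text files
#' under `out_dir`, plus `provenance.json` (config hash, seed, file
#' checksums). Reruns with the same config and seed are byte-identical.
#'
#' @param config nested list (see [default_config()]) or YAML path.
#' @param seed integer master seed; per-stage seeds are derived from it.
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with all in-memory stage results (`truth`,
#'   `networks`, `meta`, `evidence`, `seeds`, `module`, `enrichment`,
#'   `edges`, `disease_rank`, `drugs`, `paths`).
#' @export
run_pipeline <- function(config = default_config(), seed, out_dir) {
  if (missing(seed)) stop("seed must be given")
  config <- validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  keep <- function(p) { paths <<- c(paths, p); p }

  ## stage 1: simulate
  sy <- config$synth
  sim <- generate_synthetic_study(
    n_genes = sy$n_genes, n_studies = sy$n_studies,
    samples_per_condition = sy$samples_per_condition,
    params = truth_params(module_size = sy$module_size, rho_in = sy$rho_in,
                          rho_out = sy$rho_out, effect_size = sy$effect_size,
                          batch_sd = sy$batch_sd %||% 1,
                          noise_sd = sy$noise_sd %||% 1),
    seed = .stage_seed(seed, 1))
  know <- generate_knowledge(
    sim$truth, universe = sim$expr$genes,
    overlap_fracs = c(gwas = sy$overlap_frac, disease_gene = sy$overlap_frac,
                      drug_target = sy$overlap_frac),
    n_decoys = sy$n_decoys %||% 10, seed = .stage_seed(seed, 2))
  write_expression(sim$expr, keep(file.path(out_dir, "expression.tsv")),
                   keep(file.path(out_dir, "samples.tsv")))
  write_gene_list(know$gwas, keep(file.path(out_dir, "gwas.txt")))
  write_gene_list(know$disease_genes,
                  keep(file.path(out_dir, "disease_genes.txt")))
  write_gene_list(know$drug_targets,
                  keep(file.path(out_dir, "drug_targets.txt")))
  write_disease_catalog(know$catalog,
                        keep(file.path(out_dir, "disease_catalog.tsv")))
  write_triples(know$triples, keep(file.path(out_dir, "triples.tsv")))
  write_gmt(know$gene_sets, keep(file.path(out_dir, "gene_sets.gmt")))
  jsonlite::write_json(sim$truth, keep(file.path(out_dir, "truth.json")),
                       auto_unbox = TRUE, digits = NA)

  ## stage 2: batch adjustment of the combined matrix
  comb <- combine_studies(sim$expr)
  adj <- batch_adjust(comb$matrix, comb$batch)

  ## stage 3: consensus network per condition
  nw <- config$network
  top_edges <- default_top_edges(nrow(adj), nw$mean_degree)
  networks <- lapply(c(lesional = "lesional", nonlesional = "nonlesional"),
                     function(cond) {
    infer_consensus_network(adj[, comb$condition == cond, drop = FALSE],
                            estimators = nw$estimators,
                            algorithms = nw$algorithms,
                            top_edges = top_edges,
                            dpi_eps = nw$dpi_eps %||% 0)
  })
  write_edges(networks$lesional,
              keep(file.path(out_dir, "network_lesional.tsv")))
  write_edges(networks$nonlesional,
              keep(file.path(out_dir, "network_nonlesional.tsv")))

  ## stage 4: meta-analysis
  meta <- meta_analyze(sim$expr, n_perm = config$meta$n_perm,
                       seed = .stage_seed(seed, 4))
  .write_tsv(meta$consensus, keep(file.path(out_dir, "meta_consensus.tsv")))

  ## stage 5: gene ranks and evidence
  med_les <- centrality_median_rank(networks$lesional)
  med_non <- centrality_median_rank(networks$nonlesional)
  dc <- differential_centrality(med_les, med_non)
  bridges <- sort(union(
    bridge_genes(networks$lesional, know$disease_genes),
    bridge_genes(networks$nonlesional, know$disease_genes)))
  evidence <- build_evidence(
    meta_rank = setNames(meta$consensus$borda_rank, meta$consensus$gene),
    diffcent_rank = setNames(dc$rank, dc$gene),
    bridge_set = bridges, gwas_set = know$gwas,
    disease_gene_set = know$disease_genes,
    drug_target_set = know$drug_targets,
    universe = sim$expr$genes, top_n = config$evidence$top_n)
  .write_tsv(evidence, keep(file.path(out_dir, "evidence.tsv")))
  seeds <- select_seeds(evidence, config$evidence$min_evidence)
  write_gene_list(seeds, keep(file.path(out_dir, "seeds.txt")))

  ## stage 6: DIAMOnD + differential module
  n_iter <- config$module$n_iterations %||% (2L * length(seeds))
  tr_les <- diamond_expand(networks$lesional, seeds, n_iter)
  tr_non <- diamond_expand(networks$nonlesional, seeds, n_iter)
  module <- differential_module(tr_les, tr_non, seeds,
                                alpha = config$module$alpha)
  .write_tsv(tr_les, keep(file.path(out_dir, "diamond_lesional.tsv")))
  .write_tsv(tr_non, keep(file.path(out_dir, "diamond_nonlesional.tsv")))
  .write_tsv(module, keep(file.path(out_dir, "module.tsv")))

  ## stage 7: characterisation
  mod_genes <- module_genes(module)
  enrichment <- overrepresentation(mod_genes, know$gene_sets,
                                   universe = sim$expr$genes)
  .write_tsv(enrichment, keep(file.path(out_dir, "enrichment.tsv")))
  edges <- rank_module_edges(networks$lesional, mod_genes, evidence, seeds)
  .write_tsv(edges, keep(file.path(out_dir, "module_edges.tsv")))

  ## stage 8: drugs
  catalog <- filter_catalog(know$catalog,
                            min_genes = config$drugs$min_genes)
  sims <- similarity_matrices(catalog)
  cons <- hierarchical_consensus(sims,
                                 use_distances = config$drugs$use_distances %||% FALSE)
  disease_rank <- rank_diseases(cons$consensus, catalog$query)
  drugs <- prioritize_drugs(know$triples, disease_rank, mod_genes,
                            catalog$query)
  .write_tsv(disease_rank, keep(file.path(out_dir, "disease_rank.tsv")))
  .write_tsv(drugs, keep(file.path(out_dir, "drug_rank.tsv")))

  ## provenance
  cfg_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(config, cfg_path)
  prov <- list(
    seed = seed,
    config_md5 = unname(tools::md5sum(cfg_path)),
    package_version = as.character(utils::packageVersion("admodnet")),
    stage_checksums = {
      cs <- tools::md5sum(sort(paths))
      names(cs) <- basename(names(cs))
      as.list(cs)
    })
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(truth = sim$truth, expr = sim$expr, knowledge = know,
                 networks = networks, meta = meta, evidence = evidence,
                 seeds = seeds, traces = list(lesional = tr_les,
                                              nonlesional = tr_non),
                 module = module, enrichment = enrichment, edges = edges,
                 disease_rank = disease_rank, drugs = drugs,
                 paths = c(paths, cfg_path,
                           file.path(out_dir, "provenance.json"))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
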