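# Synthetic multi-study expression data and knowledge bases with planted
# ground truth. The generator is the package's stand-in for the kind of
# compendium the pipeline targets: multi-study two-condition expression with
# batch effects, a planted differentially co-expressed module, and prior
# knowledge sources with controlled overlap with the planted module.

#' Default parameters of the synthetic ground truth
#'
#' The planted module is co-expressed through a shared latent factor in the
#' lesional condition only (`x = lambda * f + eps`), giving an expected
#' within-module correlation `rho_in = lambda^2 / (lambda^2 + sigma^2)`
#' in lesional samples and `rho_out` in non-lesional ones. Module genes also
#' carry a differential-expression shift (Hedges' g scale) in lesional
#' samples; studies differ by additive per-gene batch mean shifts.
#'
#' @param module_size number of planted module genes.
#' @param rho_in target within-module correlation in the lesional condition.
#' @param rho_out background correlation (latent-factor loading shared by all
#'   genes in both conditions; 0 = independent background).
#' @param effect_size true standardised DE effect of module genes
#'   (lesional minus non-lesional, units of residual SD).
#' @param batch_sd standard deviation of per-gene, per-study batch mean
#'   shifts (log2 units).
#' @param noise_sd residual (within-condition) standard deviation.
#' @return A list of truth parameters.
#' @export
truth_params <- function(module_size = 20, rho_in = 0.8, rho_out = 0,
                         effect_size = 1, batch_sd = 1, noise_sd = 1) {
  stopifnot(rho_in > rho_out, rho_out >= 0, rho_in < 1)
  list(module_size = module_size, rho_in = rho_in, rho_out = rho_out,
       effect_size = effect_size, batch_sd = batch_sd, noise_sd = noise_sd)
}

# loading that yields correlation rho for residual sd sigma
.lambda_for_rho <- function(rho, sigma) {
  if (rho <= 0) return(0)
  sigma * sqrt(rho / (1 - rho))
}

#' Generate a synthetic multi-study expression set with a planted module
#'
#' Gene universe `g0001..gNNNN`; the planted module genes are a random subset
#' of the universe. In lesional samples the module genes load on a shared
#' latent factor (target correlation `rho_in`) and are mean-shifted by
#' `effect_size`; in non-lesional samples they behave as background
#' (`rho_out`). Each study adds independent per-gene batch mean shifts.
#'
#' @param n_genes size of the gene universe (>= module size).
#' @param n_studies number of studies (each one batch).
#' @param samples_per_condition samples per condition per study (>= 3).
#' @param params a [truth_params()] list.
#' @param seed integer random seed (mandatory: results are reproducible).
#' @return A list with `expr` (an [expression_study_set()]) and `truth`
#'   (a `SyntheticTruth` list: module genes, effect sizes, rho_in/rho_out,
#'   batch shifts, seed).
#' @export
generate_synthetic_study <- function(n_genes = 200, n_studies = 3,
                                     samples_per_condition = 50,
                                     params = truth_params(), seed) {
  if (missing(seed)) stop("seed must be given")
  if (samples_per_condition < 3)
    stop("samples_per_condition must be >= 3 (DE statistics undefined)")
  if (n_genes < params$module_size || params$module_size < 5)
    stop("n_genes >= module_size >= 5 required")
  set.seed(seed)
  genes <- sprintf("g%04d", seq_len(n_genes))
  module <- sort(sample(genes, params$module_size))
  effect <- setNames(rep(0, n_genes), genes)
  effect[module] <- params$effect_size
  sigma <- params$noise_sd
  lam_in <- .lambda_for_rho(params$rho_in, sigma)
  lam_out <- .lambda_for_rho(params$rho_out, sigma)
  base_mean <- setNames(rnorm(n_genes, mean = 8, sd = 1.5), genes)

  batch_shift <- list()
  studies <- list()
  for (s in seq_len(n_studies)) {
    sid <- sprintf("study%02d", s)
    shift <- setNames(rnorm(n_genes, 0, params$batch_sd), genes)
    batch_shift[[sid]] <- shift
    n_per <- samples_per_condition
    cond <- rep(c("lesional", "nonlesional"), each = n_per)
    n_tot <- 2L * n_per
    eps <- matrix(rnorm(n_genes * n_tot, 0, sigma), nrow = n_genes)
    f_bg <- rnorm(n_tot)            # background factor, both conditions
    f_mod <- rnorm(n_tot)           # module factor, lesional only
    m <- eps + outer(rep(lam_out, n_genes), f_bg)
    is_mod <- genes %in% module
    les <- cond == "lesional"
    m[is_mod, les] <- eps[is_mod, les] +
      lam_in * matrix(f_mod[les], nrow = sum(is_mod), ncol = sum(les),
                      byrow = TRUE)
    # DE shift in lesional samples, scaled to the marginal SD so the
    # standardised effect matches effect_size
    sd_mod <- sqrt(lam_in^2 + sigma^2)
    m[is_mod, les] <- m[is_mod, les] + effect[genes[is_mod]] * sd_mod
    m <- m + base_mean + shift
    rownames(m) <- genes
    colnames(m) <- sprintf("%s_s%03d", sid, seq_len(n_tot))
    studies[[sid]] <- list(matrix = m, condition = cond,
                           batch = rep(sid, n_tot))
  }
  truth <- list(module = module, effect = effect,
                rho_in = params$rho_in, rho_out = params$rho_out,
                batch_shift = batch_shift, params = params, seed = seed)
  list(expr = expression_study_set(studies), truth = truth)
}

#' Generate synthetic knowledge bases with controlled module overlap
#'
#' Emulates the prior-knowledge inputs of the pipeline: GWAS hits, disease
#' genes and drug targets (each containing a controlled fraction of the
#' planted module plus uniform decoys), a disease-gene catalogue holding the
#' query disease plus diseases at a controlled similarity gradient, and
#' disease-drug-target triples linking those diseases to drugs whose targets
#' are module or non-module genes.
#'
#' @param truth the `SyntheticTruth` from [generate_synthetic_study()].
#' @param universe full gene universe (character).
#' @param overlap_fracs named numeric in \[0,1\] for `gwas`, `disease_gene`,
#'   `drug_target`: fraction of the planted module included in each source.
#' @param n_decoys number of non-module decoy genes added per source.
#' @param n_similar number of diseases on the similarity gradient.
#' @param n_decoy_diseases number of unrelated diseases in the catalogue.
#' @param n_gene_sets number of synthetic cell-type/pathway gene sets.
#' @param seed integer random seed.
#' @return A list: `gwas`, `disease_genes`, `drug_targets` (character
#'   vectors), `catalog` (a [disease_gene_catalog()] with query `"QUERY"`),
#'   `triples` (data.frame), `gene_sets` (a `GeneSetCollection`).
#' @export
generate_knowledge <- function(truth, universe,
                               overlap_fracs = c(gwas = 0.8,
                                                 disease_gene = 0.8,
                                                 drug_target = 0.8),
                               n_decoys = 10, n_similar = 6,
                               n_decoy_diseases = 8, n_gene_sets = 6, seed) {
  if (missing(seed)) stop("seed must be given")
  stopifnot(all(overlap_fracs >= 0 & overlap_fracs <= 1))
  set.seed(seed)
  module <- truth$module
  nonmod <- setdiff(universe, module)

  pick_source <- function(frac) {
    k <- round(frac * length(module))
    planted <- if (k > 0) sort(sample(module, k)) else character(0)
    decoys <- if (n_decoys > 0) sort(sample(nonmod, n_decoys)) else character(0)
    sort(unique(c(planted, decoys)))
  }
  gwas <- pick_source(overlap_fracs[["gwas"]])
  disease_genes <- pick_source(overlap_fracs[["disease_gene"]])
  drug_targets <- pick_source(overlap_fracs[["drug_target"]])

  # catalogue: query = module-derived gene set; similar diseases share a
  # decreasing fraction of the query's genes, topped up with decoys
  query_genes <- module
  nq <- length(query_genes)
  sim_fracs <- seq(0.9, 0.3, length.out = n_similar)
  diseases <- list(QUERY = query_genes)
  for (i in seq_len(n_similar)) {
    k <- max(1L, round(sim_fracs[i] * nq))
    shared <- sample(query_genes, k)
    extra <- sample(nonmod, nq - k)
    diseases[[sprintf("SIM%02d", i)]] <- sort(c(shared, extra))
  }
  for (i in seq_len(n_decoy_diseases)) {
    sz <- sample(5:25, 1)
    diseases[[sprintf("DEC%02d", i)]] <- sort(sample(nonmod, sz))
  }
  catalog <- disease_gene_catalog(diseases, "QUERY")

  # triples: drugs for the query and for each similar/decoy disease, with a
  # mix of module and non-module targets
  rows <- list()
  add_drug <- function(disease, drug, targets, source = "synthetic") {
    rows[[length(rows) + 1L]] <<- data.frame(
      disease_id = disease, drug_id = drug, target = targets,
      source = source, stringsAsFactors = FALSE)
  }
  for (d in seq_len(3)) {
    add_drug("QUERY", sprintf("drugQ%02d", d), sample(module, 3))
  }
  ids <- setdiff(names(diseases), "QUERY")
  for (j in seq_along(ids)) {
    tg_mod <- sample(module, 2)
    tg_non <- sample(nonmod, 2)
    add_drug(ids[j], sprintf("drugS%02d", j), c(tg_mod, tg_non))
  }
  triples <- do.call(rbind, rows)

  # gene sets: half overlap the module heavily, half are random background
  sets <- list(); descs <- character(0)
  for (i in seq_len(n_gene_sets)) {
    id <- sprintf("SET%02d", i)
    if (i <= n_gene_sets %/% 2) {
      g <- c(sample(module, min(10, length(module))), sample(nonmod, 5))
      descs[id] <- "module-enriched"
    } else {
      g <- sample(universe, 15)
      descs[id] <- "background"
    }
    sets[[id]] <- sort(unique(g))
  }
  gene_sets <- structure(sets, category = "cell_type", descriptions = descs,
                         class = "GeneSetCollection")

  list(gwas = gwas, disease_genes = disease_genes,
       drug_targets = drug_targets, catalog = catalog, triples = triples,
       gene_sets = gene_sets)
}
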