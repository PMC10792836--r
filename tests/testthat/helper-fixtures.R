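# Shared in-code fixtures for the suite.

# tiny two-study expression set built by hand
tiny_study_set <- function() {
  mk <- function(genes, seed, n = 8) {
    set.seed(seed)
    m <- matrix(rnorm(length(genes) * n, 8), nrow = length(genes),
                dimnames = list(genes, sprintf("s%d_%d", seed, seq_len(n))))
    list(matrix = m,
         condition = rep(c("lesional", "nonlesional"), each = n / 2),
         batch = rep(sprintf("b%d", seed), n))
  }
  expression_study_set(list(st1 = mk(c("A", "B", "C"), 1),
                            st2 = mk(c("B", "C", "D"), 2)))
}

# small deterministic network from an explicit edge list
toy_network <- function(edges, nodes = NULL) {
  if (is.null(nodes)) nodes <- sort(unique(c(edges$gene_a, edges$gene_b)))
  n <- nrow(edges)
  if (is.null(edges$weight)) edges$weight <- seq(1, 0.5, length.out = n)
  if (is.null(edges$rank)) edges$rank <- seq_len(n)
  weighted_gene_network(edges, nodes)
}

edge_df <- function(a, b) {
  data.frame(gene_a = a, gene_b = b, stringsAsFactors = FALSE)
}

# cached medium synthetic scenario + consensus networks, shared by the
# network-level tests and the acceptance suite (built once per test run)
recovery_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    sim <- generate_synthetic_study(
      n_genes = 200, n_studies = 3, samples_per_condition = 50,
      params = truth_params(module_size = 20, rho_in = 0.8), seed = 101)
    comb <- combine_studies(sim$expr)
    adj <- batch_adjust(comb$matrix, comb$batch)
    nets <- lapply(c(lesional = "lesional", nonlesional = "nonlesional"),
                   function(cond) infer_consensus_network(
                     adj[, comb$condition == cond, drop = FALSE],
                     top_edges = default_top_edges(200, 20)))
    cache <<- list(sim = sim, comb = comb, adj = adj, networks = nets)
    cache
  }
})
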