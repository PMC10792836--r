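# Data-driven network gene ranks (differential centrality, bridge genes),
# evidence-table assembly over six sources, and seed selection.

EVIDENCE_SOURCES <- c("meta_analysis", "differential_centrality", "bridge",
                      "gwas", "disease_gene", "drug_target")

#' Per-gene median centrality rank of a network
#'
#' Betweenness (unweighted shortest paths), harmonic closeness (valid on
#' disconnected graphs) and degree are each converted to ranks (1 = most
#' central, average ranks for ties); the per-gene median of the three is
#' returned.
#'
#' @param network a `WeightedGeneNetwork`.
#' @return Named numeric vector of median ranks (names = genes).
#' @export
centrality_median_rank <- function(network) {
  if (length(network$nodes) == 0) stop("empty graph")
  g <- as_igraph(network, weighted = FALSE)
  btw <- igraph::betweenness(g, weights = NA)
  cls <- igraph::harmonic_centrality(g, weights = NA)
  deg <- igraph::degree(g)
  to_rank <- function(x) rank(-x, ties.method = "average")
  r <- cbind(to_rank(btw), to_rank(cls), to_rank(deg))
  med <- apply(r, 1, median)
  setNames(med[network$nodes], network$nodes)
}

#' Differential centrality ranking between two networks
#'
#' Genes are ranked by the absolute difference of their median centrality
#' ranks in the two condition-specific networks (largest change first,
#' lexicographic tie-break).
#'
#' @param rank_lesional,rank_nonlesional named median-rank vectors from
#'   [centrality_median_rank()] on the same gene universe.
#' @return data.frame `gene`, `delta` (|difference|), `rank`, sorted by rank.
#' @export
differential_centrality <- function(rank_lesional, rank_nonlesional) {
  genes <- sort(names(rank_lesional))
  if (!setequal(genes, names(rank_nonlesional)))
    stop("the two networks must cover the same gene universe")
  delta <- abs(rank_lesional[genes] - rank_nonlesional[genes])
  ord <- order(-delta, genes)
  r <- integer(length(genes)); r[ord] <- seq_along(genes)
  data.frame(gene = genes, delta = as.numeric(delta), rank = r,
             stringsAsFactors = FALSE, row.names = NULL)[ord, ]
}

#' Bridge genes: common neighbours of known disease-gene pairs
#'
#' Returns the non-disease genes adjacent to at least two distinct disease
#' genes, i.e. genes bridging a pair of known disease genes in one hop.
#'
#' @param network a `WeightedGeneNetwork`.
#' @param disease_genes character vector of known disease genes.
#' @return Sorted character vector of bridge genes.
#' @export
bridge_genes <- function(network, disease_genes) {
  disease_genes <- intersect(disease_genes, network$nodes)
  if (length(disease_genes) < 2) {
    warning("fewer than 2 disease genes present in the network")
    return(character(0))
  }
  e <- network$edges
  touch <- rbind(data.frame(g = e$gene_a, other = e$gene_b,
                            stringsAsFactors = FALSE),
                 data.frame(g = e$gene_b, other = e$gene_a,
                            stringsAsFactors = FALSE))
  touch <- touch[touch$other %in% disease_genes &
                   !(touch$g %in% disease_genes), , drop = FALSE]
  if (nrow(touch) == 0) return(character(0))
  n_links <- tapply(touch$other, touch$g, function(x) length(unique(x)))
  sort(as.character(names(n_links)[n_links >= 2]))
}

#' Assemble the per-gene evidence table
#'
#' Six evidence sources: the two ranked data-driven sources (consensus
#' meta-analysis and differential centrality) grant evidence to genes within
#' their `top_n`; the bridge set and the three prior-knowledge sets grant
#' evidence by membership. The count is the number of granted flags (0-6).
#'
#' @param meta_rank named integer vector, consensus meta-analysis rank per
#'   gene (1 = best).
#' @param diffcent_rank named integer vector, differential-centrality rank.
#' @param bridge_set,gwas_set,disease_gene_set,drug_target_set character
#'   vectors of genes.
#' @param universe gene universe of the table (default: union of rank
#'   names).
#' @param top_n rank cut-off for the two ranked sources (default 1000).
#' @return data.frame of class `EvidenceTable`: `gene`, one logical column
#'   per source, `count`.
#' @export
build_evidence <- function(meta_rank, diffcent_rank, bridge_set, gwas_set,
                           disease_gene_set, drug_target_set,
                           universe = NULL, top_n = 1000) {
  stopifnot(top_n >= 1)
  if (is.null(universe))
    universe <- union(names(meta_rank), names(diffcent_rank))
  universe <- sort(universe)
  flag_rank <- function(r) {
    f <- !is.na(r[universe]) & r[universe] <= top_n
    unname(f)
  }
  tab <- data.frame(
    gene = universe,
    meta_analysis = flag_rank(meta_rank),
    differential_centrality = flag_rank(diffcent_rank),
    bridge = universe %in% bridge_set,
    gwas = universe %in% gwas_set,
    disease_gene = universe %in% disease_gene_set,
    drug_target = universe %in% drug_target_set,
    stringsAsFactors = FALSE)
  tab$count <- rowSums(tab[, EVIDENCE_SOURCES])
  class(tab) <- c("EvidenceTable", "data.frame")
  tab
}

#' Select seed genes from an evidence table
#'
#' @param evidence an `EvidenceTable`.
#' @param min_evidence minimum evidence count (default 3, range 1-6).
#' @return Sorted character vector of seed genes (the `SeedSet`).
#' @export
select_seeds <- function(evidence, min_evidence = 3) {
  stopifnot(min_evidence >= 1, min_evidence <= 6)
  seeds <- sort(evidence$gene[evidence$count >= min_evidence])
  if (length(seeds) == 0)
    stop("no gene reaches ", min_evidence,
         " pieces of evidence; the module is undefined")
  seeds
}
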