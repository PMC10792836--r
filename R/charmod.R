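# Module characterisation: gene-set overrepresentation (one-sided Fisher
# exact + BH), one-tailed Kolmogorov-Smirnov gene set enrichment, and
# evidence-based ranking/partition of within-module edges.

#' Gene-set overrepresentation of a module
#'
#' One-sided Fisher's exact test per gene set on the 2x2 table
#' (in-module x in-set) against the given universe, with Benjamini-Hochberg
#' adjustment across sets. Sets with empty intersection with the universe
#' are skipped with a warning.
#'
#' @param module character vector of module genes (subset of universe).
#' @param collection a `GeneSetCollection` (named list of gene vectors).
#' @param universe character vector: the enrichment background (typically
#'   the network gene set).
#' @return data.frame: `set_id`, `overlap`, `set_size`, `module_size`,
#'   `universe_size`, `odds_ratio`, `p`, `p_adj`.
#' @export
overrepresentation <- function(module, collection, universe) {
  module <- intersect(module, universe)
  rows <- list()
  for (id in names(collection)) {
    set <- intersect(collection[[id]], universe)
    if (length(set) == 0) {
      warning("set '", id, "' has no genes in the universe; skipped")
      next
    }
    a <- length(intersect(module, set))
    b <- length(module) - a
    c_ <- length(set) - a
    d <- length(universe) - a - b - c_
    ft <- fisher.test(matrix(c(a, b, c_, d), nrow = 2),
                      alternative = "greater")
    rows[[id]] <- data.frame(
      set_id = id, overlap = a, set_size = length(set),
      module_size = length(module), universe_size = length(universe),
      odds_ratio = unname(ft$estimate), p = ft$p.value,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no gene set overlaps the universe")
  out$p_adj <- p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out[order(out$p, out$set_id), ]
}

#' One-tailed Kolmogorov-Smirnov gene set enrichment
#'
#' Tests whether the members of a gene set concentrate at the top of a
#' gene-level ranking: their normalised rank positions are compared against
#' the uniform distribution with a one-sided KS test (alternative: positions
#' stochastically smaller, i.e. shifted toward the top).
#'
#' @param ranking character vector of genes, best first (the universe).
#' @param set character vector of genes.
#' @return list: `statistic` (D+), `p` (one-sided), `n_set`.
#' @export
ks_gsea <- function(ranking, set) {
  pos <- match(intersect(set, ranking), ranking)
  if (length(pos) == 0) stop("gene set does not intersect the ranking")
  u <- pos / length(ranking)
  kt <- suppressWarnings(ks.test(u, "punif", alternative = "greater"))
  p <- kt$p.value
  if (is.na(p)) p <- 1          # D+ == 0: no mass in the tested tail
  list(statistic = unname(kt$statistic), p = p, n_set = length(pos))
}

#' Evidence-based ranking of within-module edges
#'
#' Keeps the network edges with both endpoints in the module and scores each
#' edge by the sum of its endpoints' evidence counts. Edges are ordered by
#' descending score, then descending consensus edge weight, then
#' lexicographic gene pair; each edge carries a partition label
#' (`"seed_seed"`, `"seed_other"` or `"other_other"`).
#'
#' @param network a `WeightedGeneNetwork`.
#' @param module character vector of module genes.
#' @param evidence an `EvidenceTable` covering the module genes.
#' @param seeds character vector of seed genes (for the partition label).
#' @return data.frame of class `RankedEdgeList`: `gene_a`, `gene_b`,
#'   `score`, `weight`, `partition`, `rank`.
#' @export
rank_module_edges <- function(network, module, evidence, seeds = character(0)) {
  e <- network$edges
  keep <- e$gene_a %in% module & e$gene_b %in% module
  e <- e[keep, , drop = FALSE]
  cnt <- setNames(evidence$count, evidence$gene)
  score_a <- cnt[e$gene_a]; score_b <- cnt[e$gene_b]
  score_a[is.na(score_a)] <- 0; score_b[is.na(score_b)] <- 0
  score <- as.integer(score_a + score_b)
  a_seed <- e$gene_a %in% seeds
  b_seed <- e$gene_b %in% seeds
  partition <- ifelse(a_seed & b_seed, "seed_seed",
                      ifelse(a_seed | b_seed, "seed_other", "other_other"))
  ord <- order(-score, -e$weight, e$gene_a, e$gene_b)
  out <- data.frame(gene_a = e$gene_a, gene_b = e$gene_b, score = score,
                    weight = e$weight, partition = partition,
                    stringsAsFactors = FALSE)[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("RankedEdgeList", "data.frame")
  out
}

#' Partition a ranked edge list by seed membership of endpoints
#'
#' @param ranked_edges a `RankedEdgeList` from [rank_module_edges()].
#' @param seeds character vector of seed genes.
#' @return list of data.frames: `seed_seed` (both endpoints seeds),
#'   `seed_other` (exactly one endpoint a seed), `other_other` (no seed
#'   endpoint, reported separately).
#' @export
partition_edges <- function(ranked_edges, seeds) {
  a_seed <- ranked_edges$gene_a %in% seeds
  b_seed <- ranked_edges$gene_b %in% seeds
  list(seed_seed = ranked_edges[a_seed & b_seed, , drop = FALSE],
       seed_other = ranked_edges[xor(a_seed, b_seed), , drop = FALSE],
       other_other = ranked_edges[!a_seed & !b_seed, , drop = FALSE])
}
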