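# DIAMOnD connectivity-significance expansion on the two condition-specific
# networks and differential module assembly.

#' DIAMOnD connectivity p-value
#'
#' Probability, under random wiring, that a node of degree `k` in a graph of
#' `N` nodes containing `s` seed nodes holds at least `k_s` links to seeds:
#' the hypergeometric upper tail
#' `p = sum_{i = ks}^{k} C(s, i) C(N - s, k - i) / C(N, k)`.
#' A degree-0 node has `p = 1`.
#'
#' @param N number of nodes in the graph.
#' @param s number of seed nodes.
#' @param k degree of the candidate node.
#' @param ks number of the candidate's links into the seed set.
#' @return The connectivity p-value.
#' @export
diamond_pvalue <- function(N, s, k, ks) {
  stopifnot(ks <= k, ks <= s, k <= N)
  if (k == 0) return(1)
  phyper(ks - 1, m = s, n = N - s, k = k, lower.tail = FALSE)
}

#' DIAMOnD module expansion
#'
#' Iteratively adds to the seed set the non-seed node with the smallest
#' connectivity p-value ([diamond_pvalue()]); ties break first by more links
#' to seeds, then lexicographically. The trace records each added gene, its
#' iteration index and its p-value at addition. Expansion stops early if no
#' candidate remains.
#'
#' @param network a `WeightedGeneNetwork` (used as an unweighted graph).
#' @param seeds character vector of seed genes (must intersect the nodes).
#' @param n_iterations number of genes to add (default `2 * |seeds|`).
#' @return data.frame of class `DiamondTrace`: `gene`, `iteration`, `p`.
#' @export
diamond_expand <- function(network, seeds, n_iterations = NULL) {
  nodes <- network$nodes
  seeds <- intersect(seeds, nodes)
  if (length(seeds) == 0) stop("no seed gene is present in the network")
  if (is.null(n_iterations)) n_iterations <- 2L * length(seeds)
  stopifnot(n_iterations >= 1)
  N <- length(nodes)
  deg <- setNames(integer(N), nodes)
  e <- network$edges
  td <- table(c(e$gene_a, e$gene_b))
  deg[names(td)] <- as.integer(td)
  # adjacency as index list for fast k_s updates
  adj <- lapply(setNames(nodes, nodes), function(x) character(0))
  for (r in seq_len(nrow(e))) {
    a <- e$gene_a[r]; b <- e$gene_b[r]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  in_seed <- setNames(nodes %in% seeds, nodes)
  ks <- setNames(vapply(nodes, function(g)
    sum(in_seed[adj[[g]]]), integer(1)), nodes)
  trace <- vector("list", n_iterations)
  for (it in seq_len(n_iterations)) {
    cand <- nodes[!in_seed]
    if (length(cand) == 0) break
    s <- sum(in_seed)
    p <- phyper(ks[cand] - 1, m = s, n = N - s, k = deg[cand],
                lower.tail = FALSE)
    p[deg[cand] == 0] <- 1
    ord <- order(p, -ks[cand], cand)
    best <- cand[ord[1]]
    trace[[it]] <- data.frame(gene = best, iteration = it, p = p[ord[1]],
                              stringsAsFactors = FALSE)
    in_seed[best] <- TRUE
    nb <- adj[[best]]
    ks[nb] <- ks[nb] + 1L
  }
  out <- do.call(rbind, trace[!vapply(trace, is.null, logical(1))])
  rownames(out) <- NULL
  class(out) <- c("DiamondTrace", "data.frame")
  out
}

#' Differential disease module
#'
#' Genes significant (`p <= alpha`) in the lesional DIAMOnD trace but not in
#' the non-lesional one, merged with the seed genes. "Not significant in the
#' non-lesional network" covers both absence from the trace and `p > alpha`.
#'
#' @param trace_lesional,trace_nonlesional `DiamondTrace` tables produced
#'   with the same seed set.
#' @param seeds the seed genes.
#' @param alpha significance threshold on the connectivity p-value
#'   (default 0.05).
#' @return data.frame of class `DiseaseModule`: `gene`, `provenance`
#'   (`"seed"` or `"diamond_lesional_specific"`), `p` (NA for seeds).
#' @export
differential_module <- function(trace_lesional, trace_nonlesional, seeds,
                                alpha = 0.05) {
  sig <- function(tr) tr$gene[tr$p <= alpha]
  s_les <- setdiff(sig(trace_lesional), seeds)
  s_non <- setdiff(sig(trace_nonlesional), seeds)
  specific <- sort(setdiff(s_les, s_non))
  p_les <- setNames(trace_lesional$p, trace_lesional$gene)
  out <- rbind(
    data.frame(gene = sort(seeds), provenance = "seed", p = NA_real_,
               stringsAsFactors = FALSE),
    data.frame(gene = specific, provenance = "diamond_lesional_specific",
               p = unname(p_les[specific]), stringsAsFactors = FALSE))
  rownames(out) <- NULL
  class(out) <- c("DiseaseModule", "data.frame")
  out
}

#' Genes of a disease module
#'
#' @param module a `DiseaseModule`.
#' @return Sorted character vector of all module genes.
#' @export
module_genes <- function(module) sort(module$gene)
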