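# Co-expression network inference: seven association estimators (three
# correlations, four mutual-information variants on equal-frequency bins),
# three network algorithms (CLR, ARACNE, MRNET), and a Borda-rank ensemble
# consensus, one network per condition.

#' The seven association estimators of the network ensemble
#' @export
ESTIMATORS <- c("pearson", "spearman", "kendall", "mi_empirical",
                "mi_millermadow", "mi_shrink", "mi_sg")

# canonical pair index for a lexicographically sorted gene vector: rows
# (i, j) with i < j ordered by gene_a then gene_b
.pair_index <- function(genes) {
  p <- length(genes)
  idx <- which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  data.frame(i = idx[, 1], j = idx[, 2],
             gene_a = genes[idx[, 1]], gene_b = genes[idx[, 2]],
             stringsAsFactors = FALSE)
}

# equal-frequency discretisation into nb bins; deterministic under ties
.discretize_ef <- function(x, nb) {
  n <- length(x)
  ceiling(rank(x, ties.method = "first") * nb / n)
}

# plug-in entropy terms from a joint contingency table
.entropy_ml <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

.mi_from_joint <- function(pxy) {
  px <- rowSums(pxy); py <- colSums(pxy)
  .entropy_ml(px) + .entropy_ml(py) - .entropy_ml(pxy)
}

# pairwise MI matrix for a discretised genes x samples matrix
.mi_matrix <- function(disc, nb, estimator) {
  p <- nrow(disc); n <- ncol(disc)
  out <- matrix(0, p, p, dimnames = list(rownames(disc), rownames(disc)))
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      tab <- table(factor(disc[i, ], levels = 1:nb),
                   factor(disc[j, ], levels = 1:nb))
      mi <- switch(estimator,
        mi_empirical = .mi_from_joint(tab / n),
        mi_millermadow = {
          mm <- function(counts) {
            m_occ <- sum(counts > 0)
            .entropy_ml(counts / n) + (m_occ - 1) / (2 * n)
          }
          mm(rowSums(tab)) + mm(colSums(tab)) - mm(tab)
        },
        mi_sg = {
          # Dirichlet-smoothed plug-in entropies, pseudocount 1/m per cell
          hd <- function(counts) {
            m <- length(counts)
            pt <- (counts + 1 / m) / (n + 1)
            .entropy_ml(pt)
          }
          hd(rowSums(tab)) + hd(colSums(tab)) - hd(as.vector(tab))
        },
        mi_shrink = {
          # James-Stein shrinkage of joint cell probabilities toward uniform
          cnt <- as.vector(tab)
          m <- length(cnt)
          ph <- cnt / n
          tgt <- rep(1 / m, m)
          denom <- (n - 1) * sum((tgt - ph)^2)
          lam <- if (denom <= 0) 1 else min(1, max(0, (1 - sum(ph^2)) / denom))
          ps <- lam * tgt + (1 - lam) * ph
          pxy <- matrix(ps, nrow = nrow(tab))
          .mi_from_joint(pxy)
        },
        stop("unknown MI estimator: ", estimator))
      out[i, j] <- out[j, i] <- max(0, mi)
    }
  }
  out
}

#' Pairwise association matrix under one estimator
#'
#' Correlation estimators return absolute correlations (negative
#' co-expression counts as strong association); mutual-information
#' estimators discretise each gene into `n_bins` equal-frequency bins and
#' estimate MI in nats. The diagonal is set to 0. A constant gene yields 0
#' association with all partners (with a warning).
#'
#' @param expr genes x samples numeric matrix (>= 3 samples).
#' @param estimator one of `r paste0('"', ESTIMATORS, '"', collapse = ", ")`.
#' @param n_bins bins for MI estimators; default
#'   `floor(sqrt(n_samples))`.
#' @return Symmetric non-negative matrix with attribute `estimator`.
#' @export
association <- function(expr, estimator = "pearson", n_bins = NULL) {
  estimator <- match.arg(estimator, ESTIMATORS)
  if (ncol(expr) < 3) stop("at least 3 samples required")
  const <- apply(expr, 1, function(x) sd(x) == 0)
  if (any(const))
    warning(sum(const), " constant gene(s); association set to 0")
  if (estimator %in% c("pearson", "spearman", "kendall")) {
    a <- abs(suppressWarnings(cor(t(expr), method = estimator)))
    a[!is.finite(a)] <- 0
  } else {
    if (is.null(n_bins)) n_bins <- max(2L, floor(sqrt(ncol(expr))))
    disc <- t(apply(expr, 1, .discretize_ef, nb = n_bins))
    rownames(disc) <- rownames(expr)
    a <- .mi_matrix(disc, n_bins, estimator)
    if (any(const)) a[const, ] <- a[, const] <- 0
  }
  diag(a) <- 0
  attr(a, "estimator") <- estimator
  a
}

#' Context Likelihood of Relatedness (CLR) background correction
#'
#' Each association value is z-scored against its row and column
#' backgrounds: `z_ij = sqrt(max(0, zi)^2 + max(0, zj)^2)` where `zi` is the
#' z-score of `mi[i, j]` within row `i` (off-diagonal entries). Rows with
#' zero spread contribute 0.
#'
#' @param mi symmetric non-negative association matrix.
#' @return Symmetric non-negative CLR score matrix.
#' @export
clr <- function(mi) {
  p <- nrow(mi)
  offdiag <- function(k) mi[k, -k]
  mu <- vapply(seq_len(p), function(k) mean(offdiag(k)), numeric(1))
  sg <- vapply(seq_len(p), function(k) sd(offdiag(k)), numeric(1))
  z <- (mi - mu) / ifelse(sg > 0, sg, Inf)       # row-wise z, zero if sd == 0
  z[!is.finite(z)] <- 0
  zp <- pmax(z, 0)
  out <- sqrt(zp^2 + t(zp)^2)
  diag(out) <- 0
  dimnames(out) <- dimnames(mi)
  out
}

#' ARACNE data-processing-inequality pruning
#'
#' For every triangle `(i, j, k)` with all three associations positive, the
#' edge `(i, j)` is removed when
#' `mi_ij < min(mi_ik, mi_jk) - dpi_eps` (strict inequality: equal-weight
#' triangles are kept). Removals are evaluated simultaneously on the input
#' matrix; surviving edges keep their weights.
#'
#' @param mi symmetric association matrix.
#' @param dpi_eps DPI tolerance (>= 0, default 0).
#' @return Pruned matrix (removed entries set to 0).
#' @export
aracne <- function(mi, dpi_eps = 0) {
  stopifnot(dpi_eps >= 0)
  p <- nrow(mi)
  remove <- matrix(FALSE, p, p)
  for (k in seq_len(p)) {
    mk <- mi[, k]
    # pmin over pairs (i, j): min(mi_ik, mi_jk), valid only if both edges exist
    lo <- outer(mk, mk, pmin)
    exists_k <- outer(mk > 0, mk > 0, "&")
    remove <- remove | (exists_k & mi > 0 & mi < lo - dpi_eps)
  }
  out <- mi
  out[remove | t(remove)] <- 0
  diag(out) <- 0
  out
}

#' MRNET: maximum-relevance minimum-redundancy network scores
#'
#' For each target gene, predictors are greedily forward-selected by the
#' MRMR score `s(X) = I(X; Y) - mean_{Z in selected} I(X; Z)` (first pick =
#' plain relevance); every predictor records its score at selection time.
#' The network weight is `w_ij = max(s_i(j), s_j(i))` floored at 0.
#' Selection ties break lexicographically by gene.
#'
#' @param mi symmetric non-negative association matrix with gene dimnames.
#' @return Symmetric non-negative MRNET weight matrix.
#' @export
mrnet <- function(mi) {
  p <- nrow(mi)
  genes <- rownames(mi)
  if (is.null(genes)) genes <- as.character(seq_len(p))
  s_mat <- matrix(-Inf, p, p)       # s_mat[x, y] = score of predictor x for y
  for (y in seq_len(p)) {
    cand <- setdiff(seq_len(p), y)
    sel <- integer(0)
    red_sum <- rep(0, p)            # running sum of I(X; Z) over selected Z
    while (length(cand) > 0) {
      s <- mi[cand, y] - if (length(sel) == 0) 0 else red_sum[cand] / length(sel)
      best <- which(s == max(s))
      if (length(best) > 1) best <- best[order(genes[cand[best]])[1]]
      x <- cand[best]
      s_mat[x, y] <- max(s)
      sel <- c(sel, x)
      cand <- setdiff(cand, x)
      red_sum <- red_sum + mi[, x]
    }
  }
  out <- pmax(pmax(s_mat, t(s_mat)), 0)
  diag(out) <- 0
  dimnames(out) <- dimnames(mi)
  out
}

# per-matrix edge ranking over the canonical pair order: descending score,
# average ranks for ties (tied edges are exchangeable, which keeps the
# consensus permutation-equivariant; sparse matrices tie most pairs at 0)
.edge_ranks <- function(score_vec) {
  rank(-score_vec, ties.method = "average")
}

# strict final ranking: ties broken by canonical (lexicographic) pair order
.edge_ranks_strict <- function(score_vec) {
  ord <- order(-score_vec, seq_along(score_vec))
  r <- integer(length(score_vec))
  r[ord] <- seq_along(score_vec)
  r
}

#' Borda-rank ensemble consensus network
#'
#' Each input matrix induces a ranking of all gene pairs (descending score;
#' ties share their average rank, so tied edges stay exchangeable and the
#' consensus is permutation-equivariant); the per-edge Borda score is the
#' mean rank across matrices. The consensus keeps the `top_edges` edges with
#' the lowest mean rank (lexicographic gene-pair tie-break in the final
#' ordering only); consensus weight is `1 - (mean_rank - 1) / (P - 1)` with
#' `P` the number of candidate pairs, so the best possible edge has weight 1.
#'
#' @param matrices list (>= 2) of association matrices on the same genes.
#' @param top_edges number of edges to retain.
#' @return A [weighted_gene_network()].
#' @export
ensemble_consensus <- function(matrices, top_edges) {
  stopifnot(length(matrices) >= 2)
  genes <- rownames(matrices[[1]])
  stopifnot(!is.null(genes),
            all(vapply(matrices, function(m)
              identical(rownames(m), genes), logical(1))))
  ord_g <- order(genes)
  pairs <- .pair_index(genes[ord_g])
  ranks <- vapply(matrices, function(m) {
    m <- m[ord_g, ord_g]
    .edge_ranks(m[cbind(pairs$i, pairs$j)])
  }, numeric(nrow(pairs)))
  mean_rank <- rowMeans(ranks)
  P <- nrow(pairs)
  if (top_edges > P) {
    warning("top_edges exceeds the number of gene pairs; keeping all ", P)
    top_edges <- P
  }
  keep <- order(mean_rank, seq_len(P))[seq_len(top_edges)]
  keep <- keep[order(keep)]         # canonical pair order within kept set
  w <- 1 - (mean_rank[keep] - 1) / (P - 1)
  final_rank <- .edge_ranks_strict(w)   # ranks 1..top_edges, lexicographic ties
  weighted_gene_network(
    data.frame(gene_a = pairs$gene_a[keep], gene_b = pairs$gene_b[keep],
               weight = w, rank = final_rank, stringsAsFactors = FALSE),
    nodes = genes)
}

#' Default edge retention count for a target mean degree
#'
#' @param n_genes number of genes.
#' @param mean_degree target mean degree (default 20).
#' @return Number of edges, capped at the number of gene pairs.
#' @export
default_top_edges <- function(n_genes, mean_degree = 20) {
  min(round(n_genes * mean_degree / 2), choose(n_genes, 2))
}

#' Infer a consensus co-expression network for one condition
#'
#' Runs the estimator x algorithm ensemble (each estimator's association
#' matrix, plus its CLR, ARACNE and MRNET transforms as requested) and fuses
#' all resulting matrices by [ensemble_consensus()].
#'
#' @param expr genes x samples matrix for one condition.
#' @param estimators subset of the seven estimators.
#' @param algorithms subset of `c("raw", "clr", "aracne", "mrnet")`;
#'   `"raw"` enters the association matrix itself into the ensemble.
#' @param top_edges edges retained; default [default_top_edges()].
#' @param n_bins MI discretisation bins (NULL = `floor(sqrt(n))`).
#' @param dpi_eps ARACNE DPI tolerance.
#' @return A `WeightedGeneNetwork`.
#' @export
infer_consensus_network <- function(expr,
                                    estimators = ESTIMATORS,
                                    algorithms = c("clr", "aracne", "mrnet"),
                                    top_edges = NULL, n_bins = NULL,
                                    dpi_eps = 0) {
  estimators <- match.arg(estimators, ESTIMATORS, several.ok = TRUE)
  algorithms <- match.arg(algorithms, c("raw", "clr", "aracne", "mrnet"),
                          several.ok = TRUE)
  if (is.null(top_edges)) top_edges <- default_top_edges(nrow(expr))
  mats <- list()
  for (est in estimators) {
    a <- association(expr, est, n_bins = n_bins)
    for (alg in algorithms) {
      mats[[paste(est, alg, sep = "_")]] <- switch(alg,
        raw = a, clr = clr(a), aracne = aracne(a, dpi_eps), mrnet = mrnet(a))
    }
  }
  ensemble_consensus(mats, top_edges)
}

#' Walktrap community detection on a consensus network
#'
#' Agglomerative merging by t-step random-walk distance, cut at maximum
#' modularity (igraph's walktrap). Provided for network exploration; the
#' module stage operates on the whole network.
#'
#' @param network a `WeightedGeneNetwork`.
#' @param walk_length random-walk length (default 4).
#' @return Named integer vector: community id per node.
#' @export
walktrap_communities <- function(network, walk_length = 4) {
  if (length(network$nodes) == 0) return(setNames(integer(0), character(0)))
  g <- as_igraph(network)
  cm <- igraph::cluster_walktrap(g, steps = walk_length)
  setNames(igraph::membership(cm)[network$nodes], network$nodes)
}
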