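# Disease-disease similarity ensemble (six distance measures), their fusion
# by hierarchical-clustering-guided averaging under the Ipsen-Mikhailov
# spectral graph distance, and disease-drug-target prioritisation restricted
# to module genes.

#' The six disease-disease distance measures
#' @export
DISTANCE_MEASURES <- c("jaccard", "cosine", "dice", "overlap",
                       "euclidean", "hamming")

#' Filter and merge a disease-gene catalogue
#'
#' Synonym diseases are unioned into the query; diseases with fewer than
#' `min_genes` genes are removed. Removing the query is fatal.
#'
#' @param catalog a `DiseaseGeneCatalog`.
#' @param min_genes minimum genes per disease (default 5).
#' @return A filtered `DiseaseGeneCatalog`.
#' @export
filter_catalog <- function(catalog, min_genes = 5) {
  d <- catalog$diseases
  syn <- intersect(catalog$synonyms, names(d))
  if (!(catalog$query %in% names(d)) && length(syn) == 0)
    stop("query disease (or a synonym) must be present in the catalogue")
  merged <- sort(unique(unlist(c(d[intersect(catalog$query, names(d))],
                                 d[syn]))))
  d[syn] <- NULL
  d[[catalog$query]] <- merged
  sizes <- lengths(d)
  d <- d[sizes >= min_genes]
  if (!(catalog$query %in% names(d)))
    stop("query disease removed by the min_genes filter")
  disease_gene_catalog(d, catalog$query)
}

#' Six pairwise disease-disease distance matrices
#'
#' On binary gene-membership vectors over the union of all catalogue genes:
#' Jaccard, cosine, Sorensen-Dice and overlap similarities inverted to
#' distances by `1 - s`; Euclidean and Hamming distances scaled to \[0,1\]
#' by division by their matrix maximum (an all-zero distance matrix stays
#' zero). All matrices are symmetric with zero diagonal.
#'
#' @param catalog a (filtered) `DiseaseGeneCatalog`.
#' @return Named list of six disease x disease matrices.
#' @export
similarity_matrices <- function(catalog) {
  d <- catalog$diseases
  if (length(d) < 2) stop("at least 2 diseases required")
  ids <- names(d)
  genes <- sort(unique(unlist(d)))
  B <- vapply(d, function(g) as.numeric(genes %in% g), numeric(length(genes)))
  sizes <- colSums(B)
  inter <- crossprod(B)                       # |A . B|
  uni <- outer(sizes, sizes, "+") - inter
  mk <- function(m) {
    dimnames(m) <- list(ids, ids)
    diag(m) <- 0
    m
  }
  d_jac <- mk(1 - inter / uni)
  d_dice <- mk(1 - 2 * inter / outer(sizes, sizes, "+"))
  d_overlap <- mk(1 - inter / outer(sizes, sizes, pmin))
  d_cos <- mk(1 - inter / sqrt(outer(sizes, sizes)))
  d_euc <- as.matrix(dist(t(B), method = "euclidean"))
  d_ham <- as.matrix(dist(t(B), method = "manhattan"))  # Hamming on binary
  scale_max <- function(m) if (max(m) > 0) m / max(m) else m
  list(jaccard = d_jac, cosine = d_cos, dice = d_dice, overlap = d_overlap,
       euclidean = mk(scale_max(d_euc)), hamming = mk(scale_max(d_ham)))
}

# Lorentzian spectral density machinery -------------------------------------

# vibrational frequencies of a weighted adjacency matrix: sqrt of the
# Laplacian eigenvalues with the smallest (0) removed
.im_frequencies <- function(adj) {
  L <- diag(rowSums(adj)) - adj
  ev <- sort(eigen(L, symmetric = TRUE, only.values = TRUE)$values)
  sqrt(pmax(ev[-1], 0))
}

# normalisation constant K: integral of the Lorentzian sum over [0, Inf)
.im_K <- function(omega, gamma) {
  1 / sum(pi / 2 + atan(omega / gamma))
}

# squared-difference integral between two Lorentzian spectral densities
.im_dist_freq <- function(om_a, om_b, gamma) {
  Ka <- .im_K(om_a, gamma); Kb <- .im_K(om_b, gamma)
  rho <- function(w, om, K)
    K * vapply(w, function(x) sum(gamma / ((x - om)^2 + gamma^2)), numeric(1))
  f <- function(w) (rho(w, om_a, Ka) - rho(w, om_b, Kb))^2
  sqrt(integrate(f, 0, Inf, rel.tol = 1e-8, subdivisions = 500L)$value)
}

# per-n cache of the calibrated Lorentzian width
.im_gamma_cache <- new.env(parent = emptyenv())

#' Calibrated Lorentzian width for the Ipsen-Mikhailov distance
#'
#' Solves for the half-width gamma at which the distance between the empty
#' and the complete graph on `n` nodes equals 1 (the canonical
#' normalisation), by root finding; values are cached per `n`.
#'
#' @param n number of nodes.
#' @return The calibrated gamma.
#' @export
im_gamma <- function(n) {
  key <- as.character(n)
  if (!is.null(.im_gamma_cache[[key]])) return(.im_gamma_cache[[key]])
  om_empty <- rep(0, n - 1)
  om_full <- rep(sqrt(n), n - 1)
  g <- uniroot(function(gam) .im_dist_freq(om_empty, om_full, gam) - 1,
               interval = c(0.01, 1), tol = 1e-10)$root
  .im_gamma_cache[[key]] <- g
  g
}

#' Ipsen-Mikhailov spectral distance between two matrices
#'
#' Each disease x disease distance matrix is interpreted as a weighted
#' graph; by default adjacency `A = 1 - d` off-diagonal (similarity
#' weights), or `A = d` with `use_distances = TRUE`. The distance compares
#' the Lorentzian-smoothed spectral densities of the two graph Laplacians,
#' with the width gamma calibrated per node count so that
#' distance(empty, complete) = 1.
#'
#' @param matrix_a,matrix_b symmetric matrices on the same disease set.
#' @param use_distances use the matrix entries directly as edge weights
#'   instead of `1 - d` (default FALSE).
#' @return Non-negative spectral distance.
#' @export
ipsen_mikhailov <- function(matrix_a, matrix_b, use_distances = FALSE) {
  check <- function(m) {
    if (!isSymmetric(unname(m), tol = 1e-8)) stop("matrix must be symmetric")
    a <- if (use_distances) m else 1 - m
    diag(a) <- 0
    a
  }
  a <- check(matrix_a); b <- check(matrix_b)
  stopifnot(nrow(a) == nrow(b))
  gam <- im_gamma(nrow(a))
  .im_dist_freq(.im_frequencies(a), .im_frequencies(b), gam)
}

#' Hierarchical consensus of the six distance matrices
#'
#' Computes the 6x6 Ipsen-Mikhailov distance matrix between the measures,
#' clusters the measures by average linkage, and fuses the matrices
#' bottom-up along the dendrogram: each merge replaces its two children by
#' their elementwise mean; the root is the consensus.
#'
#' @param matrices named list of six disease x disease distance matrices.
#' @param use_distances passed to [ipsen_mikhailov()].
#' @return list: `consensus` matrix, `im` (6x6 IM distances), `hclust`
#'   (the measure dendrogram).
#' @export
hierarchical_consensus <- function(matrices, use_distances = FALSE) {
  k <- length(matrices)
  stopifnot(k >= 2)
  im <- matrix(0, k, k, dimnames = list(names(matrices), names(matrices)))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      im[i, j] <- im[j, i] <-
        ipsen_mikhailov(matrices[[i]], matrices[[j]],
                        use_distances = use_distances)
    }
  }
  hc <- hclust(as.dist(im), method = "average")
  fused <- vector("list", k - 1)
  child <- function(x, step) {
    if (x < 0) matrices[[-x]] else fused[[x]]
  }
  for (s in seq_len(k - 1)) {
    fused[[s]] <- (child(hc$merge[s, 1], s) + child(hc$merge[s, 2], s)) / 2
  }
  list(consensus = fused[[k - 1]], im = im, hclust = hc)
}

#' Rank diseases by consensus distance to the query
#'
#' @param consensus disease x disease consensus distance matrix.
#' @param query query disease id (present in the matrix).
#' @return data.frame `disease_id`, `distance`, `rank` (ascending distance,
#'   lexicographic tie-break; the query itself is excluded).
#' @export
rank_diseases <- function(consensus, query) {
  ids <- rownames(consensus)
  if (!(query %in% ids)) stop("query disease not in the consensus matrix")
  others <- setdiff(ids, query)
  dst <- consensus[query, others]
  ord <- order(dst, others)
  data.frame(disease_id = others[ord], distance = unname(dst[ord]),
             rank = seq_along(others), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Prioritise disease-drug-target triples against the module
#'
#' Triples whose target is outside the disease module are dropped. The
#' survivors are sorted by: query disease first, then disease similarity
#' rank ascending; within a disease, by the drug's number of distinct module
#' targets descending, then drug id, then target (lexicographic).
#'
#' @param triples data.frame `disease_id`, `drug_id`, `target`, `source`.
#' @param disease_rank data.frame from [rank_diseases()].
#' @param module character vector of module genes.
#' @param query query disease id.
#' @return The filtered, sorted triples with a `priority` column.
#' @export
prioritize_drugs <- function(triples, disease_rank, module, query) {
  keep <- triples$target %in% module
  t2 <- triples[keep, , drop = FALSE]
  if (nrow(t2) == 0) {
    warning("no triple has a module target")
    t2$priority <- integer(0)
    return(t2)
  }
  rk <- setNames(disease_rank$rank, disease_rank$disease_id)
  drank <- ifelse(t2$disease_id == query, 0L, rk[t2$disease_id])
  drank[is.na(drank)] <- Inf            # diseases absent from the ranking last
  n_targets <- tapply(t2$target, t2$drug_id,
                      function(x) length(unique(x)))
  nt <- as.integer(n_targets[t2$drug_id])
  ord <- order(drank, -nt, t2$drug_id, t2$target)
  out <- t2[ord, , drop = FALSE]
  out$priority <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
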