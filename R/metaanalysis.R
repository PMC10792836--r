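# Per-study differential expression plus a three-branch consensus
# meta-analysis (Fisher combined p, DerSimonian-Laird pooled Hedges' g,
# rank product), merged into one consensus gene rank by Borda (mean rank).

#' Batch mean-adjustment of a combined expression matrix
#'
#' Per gene and per batch, samples are shifted so every batch is centred at
#' the gene's grand mean: `x' = x - batch_mean + grand_mean`. Per-gene grand
#' means are preserved exactly. Singleton batches are left unchanged with a
#' warning.
#'
#' @param m genes x samples matrix.
#' @param batch character/factor batch label per sample.
#' @return Adjusted matrix of the same shape.
#' @export
batch_adjust <- function(m, batch) {
  stopifnot(ncol(m) == length(batch))
  batch <- as.character(batch)
  grand <- rowMeans(m)
  out <- m
  for (b in unique(batch)) {
    idx <- which(batch == b)
    if (length(idx) < 2) {
      warning("singleton batch '", b, "' left unchanged")
      next
    }
    bm <- rowMeans(m[, idx, drop = FALSE])
    out[, idx] <- m[, idx, drop = FALSE] - bm + grand
  }
  out
}

#' Per-study two-group differential expression
#'
#' Vectorised two-sample (equal-variance) t-test per gene of lesional vs
#' non-lesional samples, with Hedges' g and its sampling variance
#' (small-sample correction `J = 1 - 3 / (4 df - 1)`). Genes with zero
#' pooled variance get `t = 0, p = 1, g = 0` and are flagged.
#'
#' @param expr genes x samples matrix (log2 scale).
#' @param condition per-sample labels, `"lesional"` / `"nonlesional"`.
#' @return data.frame (one row per gene): `gene`, `g` (Hedges), `g_var`,
#'   `t`, `p`, `log2fc`, `flag_zero_var`.
#' @export
study_de <- function(expr, condition) {
  les <- condition == "lesional"
  non <- condition == "nonlesional"
  n1 <- sum(les); n0 <- sum(non)
  if (n1 < 3 || n0 < 3) stop("at least 3 samples per condition required")
  m1 <- rowMeans(expr[, les, drop = FALSE])
  m0 <- rowMeans(expr[, non, drop = FALSE])
  v1 <- apply(expr[, les, drop = FALSE], 1, var)
  v0 <- apply(expr[, non, drop = FALSE], 1, var)
  df <- n1 + n0 - 2
  sp2 <- ((n1 - 1) * v1 + (n0 - 1) * v0) / df
  zero <- sp2 <= 0
  se <- sqrt(sp2 * (1 / n1 + 1 / n0))
  tt <- ifelse(zero, 0, (m1 - m0) / se)
  p <- ifelse(zero, 1, 2 * pt(abs(tt), df, lower.tail = FALSE))
  J <- 1 - 3 / (4 * df - 1)
  g <- ifelse(zero, 0, J * (m1 - m0) / sqrt(sp2))
  g_var <- (n1 + n0) / (n1 * n0) + g^2 / (2 * (n1 + n0))
  data.frame(gene = rownames(expr), g = g, g_var = g_var, t = tt, p = p,
             log2fc = m1 - m0, flag_zero_var = zero,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Fisher's method for combining p-values across studies
#'
#' `X = -2 sum(log p_k)` is chi-squared with `2K` degrees of freedom under
#' the null; the combined p-value is its upper tail. Zero p-values are
#' clamped to the smallest positive double with a warning.
#'
#' @param p numeric vector (one study each) or genes x studies matrix.
#' @return For a vector: list `statistic`, `p`. For a matrix: data.frame
#'   with per-gene `statistic` and `p`.
#' @export
fisher_combine <- function(p) {
  clamp <- function(v) {
    if (any(v <= 0)) {
      warning("p-value(s) <= 0 clamped to smallest positive double")
      v[v <= 0] <- .Machine$double.xmin
    }
    if (any(v > 1)) stop("p-values must be <= 1")
    v
  }
  if (is.matrix(p)) {
    p <- clamp(p)
    X <- -2 * rowSums(log(p))
    data.frame(gene = rownames(p), statistic = X,
               p = pchisq(X, df = 2 * ncol(p), lower.tail = FALSE),
               stringsAsFactors = FALSE, row.names = NULL)
  } else {
    p <- clamp(p)
    X <- -2 * sum(log(p))
    list(statistic = X, p = pchisq(X, df = 2 * length(p), lower.tail = FALSE))
  }
}

#' DerSimonian-Laird random-effects pooling of effect sizes
#'
#' Between-study variance `tau2 = max(0, (Q - df) / C)` with Cochran's Q on
#' fixed-effect weights `1/v`; random-effects weights `1/(v + tau2)`.
#'
#' @param g numeric vector (per study) or genes x studies matrix of effects.
#' @param v matching sampling variances.
#' @return For vectors: list `g`, `se`, `z`, `p`, `tau2`. For matrices:
#'   per-gene data.frame of the same quantities.
#' @export
effect_combine <- function(g, v) {
  pool1 <- function(gk, vk) {
    stopifnot(length(gk) >= 2, all(vk > 0))
    w <- 1 / vk
    gw <- sum(w * gk) / sum(w)
    Q <- sum(w * (gk - gw)^2)
    df <- length(gk) - 1
    C <- sum(w) - sum(w^2) / sum(w)
    tau2 <- max(0, (Q - df) / C)
    ws <- 1 / (vk + tau2)
    est <- sum(ws * gk) / sum(ws)
    se <- sqrt(1 / sum(ws))
    z <- est / se
    c(g = est, se = se, z = z, p = 2 * pnorm(abs(z), lower.tail = FALSE),
      tau2 = tau2)
  }
  if (is.matrix(g)) {
    res <- t(vapply(seq_len(nrow(g)),
                    function(i) pool1(g[i, ], v[i, ]), numeric(5)))
    data.frame(gene = rownames(g), res, stringsAsFactors = FALSE,
               row.names = NULL)
  } else {
    as.list(pool1(g, v))
  }
}

# deterministic complete ranking: largest x first, gene-name tie-break
.rank_desc <- function(x, genes) {
  ord <- order(-x, genes)
  r <- integer(length(x))
  r[ord] <- seq_along(x)
  r
}

#' Rank product across studies with permutation p-values
#'
#' Per study, genes are ranked by log2 fold change; the rank product is the
#' geometric mean of a gene's ranks. Directions are handled separately
#' (up-regulation ranks and down-regulation ranks) and the best of the two
#' is taken per gene (`mode = "best"`), or a single direction can be
#' requested. Permutation p-values come from `n_perm` within-study rank
#' permutations, pooled over genes.
#'
#' @param fc genes x studies matrix of log2 fold changes (rownames = genes).
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed for the permutations.
#' @param mode `"best"`, `"up"` or `"down"`.
#' @return data.frame: `gene`, `rp` (geometric-mean rank), `p` (permutation).
#' @export
rank_product <- function(fc, n_perm = 200, seed, mode = "best") {
  if (missing(seed)) stop("seed must be given")
  stopifnot(n_perm >= 100)
  mode <- match.arg(mode, c("best", "up", "down"))
  genes <- rownames(fc)
  G <- nrow(fc); K <- ncol(fc)
  rp_of <- function(rank_mat) exp(rowMeans(log(rank_mat)))
  ranks_up <- apply(fc, 2, .rank_desc, genes = genes)
  ranks_dn <- apply(-fc, 2, .rank_desc, genes = genes)
  rp <- switch(mode,
               up = rp_of(ranks_up),
               down = rp_of(ranks_dn),
               best = pmin(rp_of(ranks_up), rp_of(ranks_dn)))
  set.seed(seed)
  exceed <- 0
  for (b in seq_len(n_perm)) {
    perm <- vapply(seq_len(K), function(k) sample.int(G), integer(G))
    rp_perm <- switch(mode,
                      up = , down = rp_of(perm),
                      best = pmin(rp_of(perm),
                                  rp_of(G + 1L - perm)))
    exceed <- exceed + findInterval(rp, sort(rp_perm))
  }
  p <- (exceed + 1) / (G * n_perm + 1)
  data.frame(gene = genes, rp = rp, p = p, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Borda merge of rank lists
#'
#' Mean rank across input rankings; final order ascending mean rank with
#' lexicographic gene tie-break.
#'
#' @param rank_lists list of named numeric rank vectors over the same gene
#'   universe (1 = best).
#' @return data.frame `gene`, `mean_rank`, `borda_rank` sorted by
#'   `borda_rank`.
#' @export
borda_merge <- function(rank_lists) {
  stopifnot(length(rank_lists) >= 1)
  genes <- sort(names(rank_lists[[1]]))
  for (rl in rank_lists) {
    if (!setequal(names(rl), genes))
      stop("all rank lists must cover the same gene universe")
  }
  mr <- rowMeans(vapply(rank_lists, function(rl) rl[genes],
                        numeric(length(genes))))
  ord <- order(mr, genes)
  br <- integer(length(genes)); br[ord] <- seq_along(genes)
  data.frame(gene = genes, mean_rank = mr, borda_rank = br,
             stringsAsFactors = FALSE, row.names = NULL)[ord, ]
}

#' Three-branch consensus meta-analysis of a multi-study expression set
#'
#' Runs [study_de()] per study, combines p-values by [fisher_combine()],
#' effects by [effect_combine()] and fold-change ranks by [rank_product()],
#' ranks genes within each branch (ascending combined p, descending pooled
#' |g|, ascending rank product; lexicographic tie-breaks) and merges the
#' three rankings with [borda_merge()].
#'
#' @param study_set an `ExpressionStudySet`.
#' @param n_perm rank-product permutations.
#' @param seed integer seed (rank-product permutations).
#' @return List: `per_study` (list of [study_de()] tables), `consensus`
#'   (data.frame `gene`, `fisher_rank`, `effect_rank`, `rp_rank`,
#'   `borda_rank`, sorted by consensus rank).
#' @export
meta_analyze <- function(study_set, n_perm = 200, seed) {
  if (missing(seed)) stop("seed must be given")
  stopifnot(inherits(study_set, "ExpressionStudySet"))
  genes <- study_set$genes
  per_study <- lapply(study_set$studies, function(s)
    study_de(s$matrix, s$condition))
  pm <- vapply(per_study, function(d) d$p, numeric(length(genes)))
  gm <- vapply(per_study, function(d) d$g, numeric(length(genes)))
  vm <- vapply(per_study, function(d) d$g_var, numeric(length(genes)))
  fcm <- vapply(per_study, function(d) d$log2fc, numeric(length(genes)))
  rownames(pm) <- rownames(gm) <- rownames(vm) <- rownames(fcm) <- genes

  fisher <- fisher_combine(pm)
  eff <- effect_combine(gm, vm)
  rp <- rank_product(fcm, n_perm = n_perm, seed = seed)

  fisher_rank <- .rank_desc(-fisher$p, genes)         # smallest p first
  effect_rank <- .rank_desc(abs(eff$g), genes)        # largest |g| first
  rp_rank <- .rank_desc(-rp$rp, genes)                # smallest RP first
  merged <- borda_merge(list(fisher = setNames(fisher_rank, genes),
                             effect = setNames(effect_rank, genes),
                             rp = setNames(rp_rank, genes)))
  consensus <- data.frame(
    gene = genes,
    fisher_rank = fisher_rank, effect_rank = effect_rank, rp_rank = rp_rank,
    stringsAsFactors = FALSE)
  consensus <- merge(consensus, merged[, c("gene", "borda_rank")],
                     by = "gene", sort = TRUE)
  consensus <- consensus[order(consensus$borda_rank), ]
  rownames(consensus) <- NULL
  list(per_study = per_study, consensus = consensus,
       fisher = fisher, effect = eff, rank_product = rp)
}
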