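# Association estimators, CLR / ARACNE / MRNET, and the Borda consensus.

test_that("correlation estimators: perfect dependence and absolute values", {
  x <- seq_len(10)
  m <- rbind(a = x, b = x * 2 + 3, c = -x)
  a <- association(m, "pearson")
  expect_equal(a["a", "b"], 1)
  expect_equal(a["a", "c"], 1)        # negative correlation stored absolute
  expect_equal(diag(a), setNames(rep(0, 3), rownames(m)))
  expect_true(isSymmetric(a))
})

test_that("constant gene yields zero association with a warning", {
  m <- rbind(a = seq_len(8), b = rep(1, 8), c = rnorm(8))
  expect_warning(a <- association(m, "pearson"), "constant")
  expect_equal(unname(a["b", ]), rep(0, 3))
})

test_that("empirical MI of independent variables is near zero (bias-bounded)", {
  set.seed(42)
  n <- 1000
  m <- rbind(x = runif(n), y = runif(n))
  a <- association(m, "mi_empirical", n_bins = 10)
  # plug-in MI bias is about (b - 1)^2 / (2n) ~ 0.04 nats here
  expect_lte(a["x", "y"], 0.1)
  expect_gte(a["x", "y"], 0)
})

test_that("Miller-Madow equals plug-in plus occupancy corrections on a fixed table", {
  # 2 genes, 8 samples, 4 equal-frequency bins -> known contingency table
  x <- c(1, 1, 2, 2, 3, 3, 4, 4)
  y <- c(1, 2, 1, 2, 3, 4, 3, 4)
  m <- rbind(gx = x, gy = y)
  n <- 8
  tab <- table(x, y)
  h_ml <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  h_mm <- function(counts) h_ml(counts / n) + (sum(counts > 0) - 1) / (2 * n)
  expected <- h_mm(rowSums(tab)) + h_mm(colSums(tab)) - h_mm(tab)
  a <- association(m, "mi_millermadow", n_bins = 4)
  expect_equal(a["gx", "gy"], expected, tolerance = 1e-12)
})

test_that("all four MI estimators are symmetric, non-negative and detect dependence", {
  set.seed(7)
  n <- 200
  x <- rnorm(n)
  m <- rbind(a = x, b = x + rnorm(n, sd = 0.3), c = rnorm(n))
  for (est in c("mi_empirical", "mi_millermadow", "mi_shrink", "mi_sg")) {
    a <- association(m, est)
    expect_true(isSymmetric(a), info = est)
    expect_true(all(a >= 0), info = est)
    expect_gt(a["a", "b"], a["a", "c"])
  }
})

test_that("CLR: zero on constant background, correct top edge, shift-invariant", {
  cmat <- matrix(0.5, 4, 4); diag(cmat) <- 0
  expect_equal(max(clr(cmat)), 0)
  mi <- matrix(c(0, .9, .1,
                 .9, 0, .2,
                 .1, .2, 0), 3, 3, dimnames = list(1:3, 1:3))
  z <- clr(mi)
  expect_true(z["1", "2"] == max(z))
  expect_true(all(clr(mi) >= 0))
  expect_equal(clr(mi + 0.3), clr(mi))   # z-scores unaffected by a shift
})

test_that("ARACNE removes exactly the weakest edge of a triangle, keeps paths and ties", {
  tri <- matrix(c(0, .9, .1,
                  .9, 0, .8,
                  .1, .8, 0), 3, 3)
  out <- aracne(tri)
  expect_equal(out[1, 3], 0)
  expect_equal(out[1, 2], 0.9)
  expect_equal(out[2, 3], 0.8)
  path <- matrix(c(0, .5, 0,
                   .5, 0, .4,
                   0, .4, 0), 3, 3)
  expect_equal(aracne(path), path)       # no triangle, nothing removed
  eq <- matrix(0.6, 3, 3); diag(eq) <- 0
  expect_equal(aracne(eq), eq)           # ties survive (strict inequality)
  set.seed(1)
  r <- abs(matrix(rnorm(36), 6)); r <- (r + t(r)) / 2; diag(r) <- 0
  pruned <- aracne(r)
  expect_true(all(pruned[r == 0] == 0) && all(pruned <= r))  # subset of input
})

test_that("MRNET matches brute-force MRMR on small instances", {
  brute_mrnet <- function(mi) {
    p <- nrow(mi)
    s_mat <- matrix(-Inf, p, p)
    for (y in seq_len(p)) {
      cand <- setdiff(seq_len(p), y); sel <- integer(0)
      while (length(cand) > 0) {
        s <- vapply(cand, function(x) {
          mi[x, y] - if (length(sel)) mean(mi[x, sel]) else 0
        }, numeric(1))
        x <- cand[which.max(s)]
        s_mat[x, y] <- max(s)
        sel <- c(sel, x); cand <- setdiff(cand, x)
      }
    }
    w <- pmax(pmax(s_mat, t(s_mat)), 0); diag(w) <- 0; w
  }
  m2 <- matrix(c(0, .7, .7, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(unname(mrnet(m2)), unname(m2))   # 2 genes: w = mi
  set.seed(3)
  for (p in c(3, 4)) {
    for (rep in 1:5) {
      m <- abs(matrix(rnorm(p * p), p)); m <- (m + t(m)) / 2; diag(m) <- 0
      dimnames(m) <- list(letters[1:p], letters[1:p])
      expect_equal(unname(mrnet(m)), unname(brute_mrnet(m)), tolerance = 1e-12)
    }
  }
  # fully tied MI: greedy selection still matches the brute-force oracle
  # (the last-selected predictor per target has a saturated redundancy term)
  eqm <- matrix(0.4, 3, 3); diag(eqm) <- 0
  dimnames(eqm) <- list(letters[1:3], letters[1:3])
  w <- mrnet(eqm)
  expect_equal(unname(w), unname(brute_mrnet(eqm)), tolerance = 1e-12)
  expect_equal(max(w), 0.4)
})

test_that("Borda consensus: idempotence, reversed rankings, permutation equivariance", {
  genes <- c("a", "b", "c", "d")
  set.seed(5)
  m <- abs(matrix(rnorm(16), 4)); m <- (m + t(m)) / 2; diag(m) <- 0
  dimnames(m) <- list(genes, genes)
  net1 <- ensemble_consensus(list(m, m), top_edges = 6)
  expect_equal(nrow(net1$edges), 6)
  # idempotence: consensus ranking equals the single-matrix ranking
  pair_scores <- m[cbind(c(1, 1, 1, 2, 2, 3), c(2, 3, 4, 3, 4, 4))]
  lex1 <- order(net1$edges$gene_a, net1$edges$gene_b)
  expect_equal(net1$edges$rank[lex1], rank(-pair_scores))

  # two exactly reversed rankings -> equal mean ranks, lexicographic order
  m1 <- matrix(0, 4, 4, dimnames = list(genes, genes))
  m1[upper.tri(m1)] <- c(6, 5, 4, 3, 2, 1) / 10
  m1 <- m1 + t(m1)
  m2 <- matrix(0, 4, 4, dimnames = list(genes, genes))
  m2[upper.tri(m2)] <- c(1, 2, 3, 4, 5, 6) / 10
  m2 <- m2 + t(m2)
  net <- ensemble_consensus(list(m1, m2), top_edges = 6)
  lex <- order(net$edges$gene_a, net$edges$gene_b)
  expect_equal(net$edges$rank[lex], seq_len(6))       # resolved lexicographically
  expect_equal(length(unique(net$edges$weight)), 1L)  # all mean ranks equal

  # permutation equivariance: relabelling genes permutes the result
  perm <- c(a = "w3", b = "w1", c = "w4", d = "w2")
  mp <- m; dimnames(mp) <- list(unname(perm), unname(perm))
  netp <- ensemble_consensus(list(mp, mp), top_edges = 6)
  remap <- data.frame(gene_a = pmin(perm[net1$edges$gene_a],
                                    perm[net1$edges$gene_b]),
                      gene_b = pmax(perm[net1$edges$gene_a],
                                    perm[net1$edges$gene_b]),
                      weight = net1$edges$weight,
                      stringsAsFactors = FALSE)
  remap <- remap[order(remap$gene_a, remap$gene_b), ]
  got <- netp$edges[order(netp$edges$gene_a, netp$edges$gene_b),
                    c("gene_a", "gene_b", "weight")]
  rownames(remap) <- rownames(got) <- NULL
  expect_equal(got, remap)

  expect_warning(ensemble_consensus(list(m, m), top_edges = 100),
                 "keeping all")
})

test_that("walktrap: disconnected cliques and singletons", {
  cl <- function(genes) {
    pr <- t(combn(genes, 2))
    edge_df(pr[, 1], pr[, 2])
  }
  e <- rbind(cl(sprintf("a%d", 1:5)), cl(sprintf("b%d", 1:5)))
  e$weight <- 1; e$rank <- seq_len(nrow(e))
  net <- toy_network(e)
  cm <- walktrap_communities(net)
  expect_equal(length(unique(cm)), 2L)
  expect_equal(length(unique(cm[sprintf("a%d", 1:5)])), 1L)
  expect_equal(length(unique(cm[sprintf("b%d", 1:5)])), 1L)
  single <- weighted_gene_network(
    data.frame(gene_a = character(0), gene_b = character(0),
               weight = numeric(0), rank = integer(0)), nodes = "only")
  expect_equal(unname(walktrap_communities(single)), 1)
})

test_that("walktrap recovers a ring of weakly-linked cliques", {
  cl <- function(tag) {
    g <- sprintf("%s%d", tag, 1:6)
    pr <- t(combn(g, 2))
    edge_df(pr[, 1], pr[, 2])
  }
  e <- rbind(cl("a"), cl("b"), cl("c"), cl("d"),
             edge_df(c("a1", "b1", "c1", "d1"), c("b2", "c2", "d2", "a2")))
  e$weight <- c(rep(1, 60), rep(0.1, 4))
  e$rank <- seq_len(nrow(e))
  net <- toy_network(e)
  cm <- walktrap_communities(net)
  expect_equal(length(unique(cm)), 4L)
  for (tag in c("a", "b", "c", "d"))
    expect_equal(length(unique(cm[sprintf("%s%d", tag, 1:6)])), 1L)
})

test_that("lesional consensus holds more planted-module edges than non-lesional", {
  fx <- recovery_fixture()
  mod <- fx$sim$truth$module
  count_mod <- function(net)
    with(net$edges, sum(gene_a %in% mod & gene_b %in% mod))
  n_les <- count_mod(fx$networks$lesional)
  n_non <- count_mod(fx$networks$nonlesional)
  expect_gt(n_les, n_non)
  # strong-signal regime: most planted pairs are recovered at the top
  expect_gte(n_les / choose(length(mod), 2), 0.5)
})
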