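# Batch adjustment, per-study DE, and the three meta-analysis branches.

test_that("batch adjustment centres batches at the grand mean and preserves it", {
  m <- matrix(c(1, 1, 3, 3,
                10, 12, 20, 22), nrow = 2, byrow = TRUE,
              dimnames = list(c("g1", "g2"), sprintf("s%d", 1:4)))
  batch <- c("b1", "b1", "b2", "b2")
  out <- batch_adjust(m, batch)
  # two batches with means 1 and 3 -> both centred at grand mean 2
  expect_equal(unname(out["g1", ]), c(2, 2, 2, 2))
  expect_equal(rowMeans(out), rowMeans(m), tolerance = 1e-12)
  expect_equal(unname(rowMeans(out[, 1:2])), unname(rowMeans(out[, 3:4])))
  # single batch -> identity
  expect_equal(batch_adjust(m, rep("b", 4)), m)
  # singleton batch left unchanged, with warning
  expect_warning(out2 <- batch_adjust(m, c("b1", "b1", "b1", "solo")),
                 "singleton")
  expect_equal(out2[, 4], m[, 4])
})

test_that("study_de: Hedges' g closed form, antisymmetry, degenerate genes", {
  # identical groups -> t = 0, p = 1, g = 0
  m0 <- rbind(g1 = rep(c(1, 2, 3), 2))
  cond <- rep(c("lesional", "nonlesional"), each = 3)
  r0 <- study_de(m0, cond)
  expect_equal(r0$t, 0); expect_equal(r0$p, 1); expect_equal(r0$g, 0)

  # n1 = n2 = 10, mean difference = pooled sd -> g = J, J = 1 - 3/(4*18 - 1)
  set.seed(1)
  base <- rnorm(10)
  base <- (base - mean(base)) / sd(base)        # mean 0, sd 1 exactly
  expr <- rbind(gene = c(base + 1, base))
  cond2 <- rep(c("lesional", "nonlesional"), each = 10)
  r <- study_de(expr, cond2)
  J <- 1 - 3 / (4 * 18 - 1)
  expect_equal(r$g, J, tolerance = 1e-12)
  expect_equal(r$log2fc, 1, tolerance = 1e-12)

  # swapping labels flips g and t, keeps p
  r_sw <- study_de(expr, rev(cond2))
  expect_equal(r_sw$g, -r$g)
  expect_equal(r_sw$t, -r$t)
  expect_equal(r_sw$p, r$p)

  # zero pooled variance flagged
  rz <- study_de(rbind(g = rep(5, 6)), cond)
  expect_true(rz$flag_zero_var)
  expect_equal(rz$p, 1)
})

test_that("study_de matches t.test on random data", {
  set.seed(2)
  m <- matrix(rnorm(5 * 12), nrow = 5,
              dimnames = list(sprintf("g%d", 1:5), NULL))
  cond <- rep(c("lesional", "nonlesional"), each = 6)
  r <- study_de(m, cond)
  for (i in 1:5) {
    tt <- t.test(m[i, cond == "lesional"], m[i, cond == "nonlesional"],
                 var.equal = TRUE)
    expect_equal(r$t[i], unname(tt$statistic), tolerance = 1e-12)
    expect_equal(r$p[i], tt$p.value, tolerance = 1e-12)
  }
})

test_that("Fisher combination: closed-form example and chi-square tail", {
  expect_equal(fisher_combine(c(1, 1, 1))$statistic, 0)
  expect_equal(fisher_combine(c(1, 1, 1))$p, 1)
  r <- fisher_combine(c(0.5, 0.5))
  expect_equal(r$statistic, -2 * 2 * log(0.5), tolerance = 1e-6)
  expect_equal(r$p, pchisq(2.7726, df = 4, lower.tail = FALSE),
               tolerance = 1e-4)
  expect_warning(rc <- fisher_combine(c(0, 0.5)), "clamped")
  expect_true(rc$p < 1e-100)
})

test_that("Fisher combined p is uniform under the null", {
  set.seed(3)
  pm <- matrix(runif(2000 * 4), nrow = 2000,
               dimnames = list(sprintf("g%04d", 1:2000), NULL))
  comb <- fisher_combine(pm)
  ks <- ks.test(comb$p, "punif")
  expect_gt(ks$p.value, 0.01)
  expect_lt(abs(mean(comb$p < 0.05) - 0.05), 0.02)
})

test_that("DerSimonian-Laird pooling: limits and agreement with metafor", {
  # identical studies: pooled estimate equals the common one
  r <- effect_combine(c(0.7, 0.7, 0.7), c(0.1, 0.1, 0.1))
  expect_equal(r$g, 0.7)
  # homogeneous two-study case Q <= df -> tau2 = 0, plain average
  r2 <- effect_combine(c(0, 1), c(2, 2))   # Q = 0.25 <= 1
  expect_equal(r2$tau2, 0)
  expect_equal(r2$g, 0.5)
  skip_if_not_installed("metafor")
  set.seed(4)
  for (i in 1:5) {
    g <- rnorm(6); v <- runif(6, 0.05, 0.3)
    mine <- effect_combine(g, v)
    ref <- metafor::rma(yi = g, vi = v, method = "DL")
    expect_equal(mine$g, unname(ref$beta[1]), tolerance = 1e-8)
    expect_equal(mine$tau2, unname(ref$tau2), tolerance = 1e-8)
  }
})

test_that("random-effects pooling recovers a simulated common effect", {
  set.seed(5)
  truth <- 0.8
  n <- 30
  g <- numeric(10); v <- numeric(10)
  for (k in 1:10) {
    a <- rnorm(n, truth); b <- rnorm(n)
    sp <- sqrt((var(a) + var(b)) / 2)
    J <- 1 - 3 / (4 * (2 * n - 2) - 1)
    g[k] <- J * (mean(a) - mean(b)) / sp
    v[k] <- 2 / n + g[k]^2 / (4 * n)
  }
  expect_equal(effect_combine(g, v)$g, truth, tolerance = 0.15)
})

test_that("rank product: exact small cases and permutation p behaviour", {
  fc <- matrix(c(5, 1, 0.5, 4, 2, 0.1), nrow = 3,
               dimnames = list(c("gA", "gB", "gC"), NULL))
  rp <- rank_product(fc, n_perm = 100, seed = 1, mode = "up")
  expect_equal(rp$rp[rp$gene == "gA"], 1)           # top in both studies
  # K = 2 with up-ranks (2, 8): geometric mean 4
  expect_equal(exp(mean(log(c(2, 8)))), 4)
  set.seed(6)
  fcn <- matrix(rnorm(50 * 3), nrow = 50,
                dimnames = list(sprintf("g%02d", 1:50), NULL))
  rpn <- rank_product(fcn, n_perm = 100, seed = 2)
  expect_true(all(rpn$p > 0 & rpn$p <= 1))
  # best-of-both is never worse than a single direction
  rpu <- rank_product(fcn, n_perm = 100, seed = 2, mode = "up")
  rpd <- rank_product(fcn, n_perm = 100, seed = 2, mode = "down")
  expect_true(all(rpn$rp <= pmin(rpu$rp, rpd$rp) + 1e-12))
})

test_that("Borda merge: idempotence, reversed lists, exchangeability", {
  genes <- c("a", "b", "c", "d")
  r1 <- setNames(1:4, genes)
  out <- borda_merge(list(r1, r1))
  expect_equal(out$gene, genes)                     # identical lists preserved
  r2 <- setNames(4:1, genes)
  out2 <- borda_merge(list(r1, r2))
  expect_equal(out2$gene, genes)                    # ties -> lexicographic
  expect_equal(unique(out2$mean_rank), 2.5)
  expect_equal(borda_merge(list(r2, r1)), out2)     # order of lists irrelevant
  expect_error(borda_merge(list(r1, setNames(1:3, genes[1:3]))),
               "universe")
})

test_that("meta-analysis consensus is invariant to gene input order", {
  x <- tiny_study_set()
  res <- meta_analyze(x, n_perm = 100, seed = 7)
  # shuffle gene rows in each study; canonical ordering restores them
  sh <- lapply(x$studies, function(s) {
    s$matrix <- s$matrix[rev(rownames(s$matrix)), , drop = FALSE]
    s
  })
  res2 <- meta_analyze(expression_study_set(sh), n_perm = 100, seed = 7)
  expect_equal(res$consensus, res2$consensus)
})

test_that("meta-analysis: null calibration and planted-signal recovery", {
  # global null: 2000 genes, 5 studies, no effect
  set.seed(8)
  G <- 2000
  genes <- sprintf("g%04d", 1:G)
  studies <- lapply(1:5, function(k) {
    m <- matrix(rnorm(G * 12), nrow = G, dimnames = list(genes, NULL))
    colnames(m) <- sprintf("st%d_s%d", k, 1:12)
    list(matrix = m, condition = rep(c("lesional", "nonlesional"), each = 6),
         batch = rep(sprintf("b%d", k), 12))
  })
  names(studies) <- sprintf("st%d", 1:5)
  null_set <- expression_study_set(studies)
  pm <- vapply(null_set$studies,
               function(s) study_de(s$matrix, s$condition)$p, numeric(G))
  rownames(pm) <- genes
  frac <- mean(fisher_combine(pm)$p < 0.05)
  expect_lt(abs(frac - 0.05), 0.02)

  # planted effect g = 1 in 10% of genes across 5 studies, n = 30/arm
  set.seed(9)
  G2 <- 500; n <- 30
  genes2 <- sprintf("g%04d", 1:G2)
  de_genes <- genes2[1:50]
  studies2 <- lapply(1:5, function(k) {
    m <- matrix(rnorm(G2 * 2 * n), nrow = G2, dimnames = list(genes2, NULL))
    m[de_genes, 1:n] <- m[de_genes, 1:n] + 1
    colnames(m) <- sprintf("st%d_s%d", k, 1:(2 * n))
    list(matrix = m, condition = rep(c("lesional", "nonlesional"), each = n),
         batch = rep(sprintf("b%d", k), 2 * n))
  })
  names(studies2) <- sprintf("st%d", 1:5)
  res <- meta_analyze(expression_study_set(studies2), n_perm = 100, seed = 10)
  top_decile <- res$consensus$gene[res$consensus$borda_rank <= G2 / 10]
  recall <- length(intersect(top_decile, de_genes)) / length(de_genes)
  expect_gte(recall, 0.8)
})
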