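random_em <- function(n_genes, n_samples, seed) {
  set.seed(seed)
  md <- data.frame(sample_id = sprintf("s%d", seq_len(n_samples)),
                   group = "G", kind = "tumor", stringsAsFactors = FALSE)
  v <- matrix(rnorm(n_genes * n_samples), n_genes, n_samples,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              md$sample_id))
  expression_matrix(v, md)
}

test_that("adjacency and TOM live in [0,1] with unit diagonal", {
  m <- random_em(25, 12, 71)
  for (type in c("unsigned", "signed")) {
    a <- adjacency_matrix(m, 6, type)
    expect_true(all(a >= 0 & a <= 1 + 1e-12))
    expect_equal(a, t(a))
    expect_equal(unname(diag(a)), rep(1, 25))
    tom <- tom_similarity(a)
    expect_true(all(tom >= -1e-12 & tom <= 1 + 1e-12))
    expect_equal(tom, t(tom))
    expect_equal(unname(diag(tom)), rep(1, 25))
  }
})

test_that("TOM matches the hand-computed triple sum on a small adjacency", {
  a <- matrix(c(1, .8, .2, .1,
                .8, 1, .3, .2,
                .2, .3, 1, .7,
                .1, .2, .7, 1), 4, 4)
  tom <- tom_similarity(a)
  k <- colSums(a) - 1
  for (i in 1:4) for (j in 1:4) {
    if (i == j) next
    l <- sum(a[i, -c(i, j)] * a[-c(i, j), j])
    expect_equal(tom[i, j], (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j]),
                 tolerance = 1e-12)
  }
})

test_that("scale-free fit table matches an independent regression oracle", {
  m <- random_em(60, 15, 72)
  res <- select_soft_power(m, powers = 1:6, n_bins = 8)
  for (b in 1:6) {
    cc <- abs(cor(t(m$values)))^b
    diag(cc) <- 1
    k <- colSums(cc) - 1
    breaks <- seq(min(k), max(k), length.out = 9)
    freq <- as.vector(table(cut(k, breaks, include.lowest = TRUE))) / length(k)
    centers <- (breaks[-1] + breaks[-9]) / 2
    use <- freq > 0 & centers > 0
    row <- res$fit_table[res$fit_table$power == b, ]
    if (sum(use) < 3) {
      expect_true(is.na(row$r_squared))
    } else {
      fit <- summary(lm(log10(freq[use]) ~ log10(centers[use])))
      expect_equal(row$r_squared, fit$r.squared, tolerance = 1e-10)
      expect_equal(row$mean_k, mean(k), tolerance = 1e-10)
    }
  }
})

test_that("a histogram lying exactly on a power law fits with R^2 = 1", {
  # bin frequencies proportional to 1/center are exactly collinear in
  # log-log space
  k <- c(1, 1, 1, 1, 1, 3, 4, 4, 5, 6, 7)  # counts 6, 3, 2 in bins [1,3],(3,5],(5,7]
  fit <- suppressWarnings(devalign:::scale_free_fit(k, n_bins = 3))
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$slope, -1, tolerance = 1e-12)
})

test_that("degenerate equal-connectivity networks fall back with a warning", {
  md <- data.frame(sample_id = sprintf("s%d", 1:8), group = "G",
                   kind = "tumor", stringsAsFactors = FALSE)
  set.seed(73)
  pattern <- rnorm(8)
  v <- outer(1:5, pattern)          # all genes perfectly correlated
  dimnames(v) <- list(sprintf("g%d", 1:5), md$sample_id)
  m <- expression_matrix(v, md)
  expect_warning(res <- select_soft_power(m, powers = 1:3), "undefined")
  expect_true(all(is.na(res$fit_table$r_squared)))
  expect_equal(res$power, 1)
})

test_that("two planted orthogonal modules are recovered exactly at zero noise", {
  md <- data.frame(sample_id = sprintf("s%d", 1:12), group = "G",
                   kind = "tumor", stringsAsFactors = FALSE)
  set.seed(74)
  v1 <- rnorm(12); v1 <- v1 - mean(v1)
  v2 <- rnorm(12); v2 <- v2 - mean(v2)
  v2 <- v2 - v1 * sum(v1 * v2) / sum(v1^2)   # orthogonalize
  loads <- runif(20, 0.5, 2)
  v <- rbind(outer(loads[1:10], v1), outer(loads[11:20], v2))
  dimnames(v) <- list(sprintf("g%02d", 1:20), md$sample_id)
  m <- expression_matrix(v, md)
  mod <- detect_modules(m, power = 6, min_module_size = 5)
  planted <- rep(1:2, each = 10)
  names(planted) <- rownames(v)
  expect_equal(ari_of(planted, mod$labels), 1)
})

test_that("module labels are invariant to gene-order permutation", {
  sim <- small_sim(seed = 75)
  pre <- network_prefilter(detection_filter(sim$matrix)$matrix)$matrix
  mod1 <- suppressWarnings(detect_modules(pre, 6))
  set.seed(1)
  perm <- sample(nrow(pre$values))
  pre2 <- em_subset(pre, genes = rownames(pre$values)[perm])
  mod2 <- suppressWarnings(detect_modules(pre2, 6))
  expect_equal(ari_of(mod1$labels, mod2$labels), 1)
})

test_that("eigengenes are the dominant unit-norm pattern of their module", {
  # rank-1 module: eigengene correlates perfectly with the pattern
  md <- data.frame(sample_id = sprintf("s%d", 1:10), group = "G",
                   kind = "tumor", stringsAsFactors = FALSE)
  set.seed(76)
  pattern <- rnorm(10)
  v <- outer(runif(6, 0.5, 2), pattern) + 0
  dimnames(v) <- list(sprintf("g%d", 1:6), md$sample_id)
  m <- expression_matrix(v, md)
  labels <- setNames(rep(1L, 6), rownames(v))
  eg <- module_eigengenes(m, labels)
  expect_equal(abs(cor(eg[1, ], pattern)), 1, tolerance = 1e-10)
  expect_equal(sum(eg[1, ]^2), 1, tolerance = 1e-12)

  # random module: matches an independent eigendecomposition up to sign,
  # and the sign convention keeps mean member correlation non-negative
  m2 <- random_em(8, 12, 77)
  labels2 <- setNames(rep(1L, 8), rownames(m2$values))
  eg2 <- module_eigengenes(m2, labels2)
  xs <- t(scale(t(m2$values)))
  oracle <- eigen(crossprod(xs), symmetric = TRUE)$vectors[, 1]
  expect_equal(abs(as.vector(eg2[1, ])), abs(oracle), tolerance = 1e-8)
  expect_gte(mean(cor(t(xs), eg2[1, ])), 0)

  # variance dominance: no random unit-norm combination of members beats
  # the eigengene direction
  set.seed(78)
  proj_var <- function(w) var(as.vector(t(xs) %*% w))
  best <- proj_var(svd(xs, nu = 1)$u[, 1])
  for (i in 1:25) {
    w <- rnorm(8); w <- w / sqrt(sum(w^2))
    expect_lte(proj_var(w), best + 1e-10)
  }

  # single-gene module: standardized gene, unit norm
  labels3 <- setNames(1L, rownames(m2$values)[1])
  eg3 <- module_eigengenes(m2, labels3)
  expect_equal(sum(eg3[1, ]^2), 1, tolerance = 1e-12)
  expect_equal(abs(cor(eg3[1, ], m2$values[1, ])), 1, tolerance = 1e-10)
})

test_that("cluster families group correlated eigengenes", {
  set.seed(79)
  base <- rnorm(20)
  e1 <- base / sqrt(sum(base^2))
  e2 <- e1                               # perfectly correlated with e1
  noise <- rnorm(20); noise <- noise - mean(noise)
  e3 <- -e1 + 0.001 * noise              # anti-correlated
  e3 <- e3 / sqrt(sum(e3^2))
  eg <- rbind(ME1 = e1, ME2 = e2, ME3 = e3)
  colnames(eg) <- sprintf("s%d", 1:20)
  fam <- cluster_families(eg, cut_height = 0.5)
  expect_equal(fam$families[["ME1"]], fam$families[["ME2"]])
  expect_false(fam$families[["ME1"]] == fam$families[["ME3"]])
  # anti-correlated eigengenes sit at distance ~2: same family only when
  # the cut exceeds it
  fam2 <- cluster_families(eg, cut_height = 1)
  expect_false(fam2$families[["ME1"]] == fam2$families[["ME3"]])
  phy <- ape::read.tree(text = fam$newick)
  expect_setequal(phy$tip.label, c("ME1", "ME2", "ME3"))
})

test_that("cluster families reproduce hand-computed average linkage", {
  # three tight pairs of eigengenes with known cross-correlations
  set.seed(80)
  n <- 30
  b1 <- scale(rnorm(n))[, 1]
  b2 <- scale(residuals(lm(rnorm(n) ~ b1)))[, 1]
  b3 <- scale(residuals(lm(rnorm(n) ~ b1 + b2)))[, 1]
  jitter_of <- function(b) {
    e <- scale(residuals(lm(rnorm(n) ~ b)))[, 1]
    v <- 0.995 * b + sqrt(1 - 0.995^2) * e
    v / sqrt(sum(v^2))
  }
  eg <- rbind(A1 = b1 / sqrt(sum(b1^2)), A2 = jitter_of(b1),
              B1 = b2 / sqrt(sum(b2^2)), B2 = jitter_of(b2),
              C1 = b3 / sqrt(sum(b3^2)), C2 = jitter_of(b3))
  colnames(eg) <- sprintf("s%d", 1:n)
  fam <- cluster_families(eg, cut_height = 0.5)
  expect_equal(unname(fam$families[c("A1", "A2")]),
               rep(fam$families[["A1"]], 2))
  expect_equal(length(unique(fam$families)), 3)
  # oracle: stats::hclust on the same correlation distance
  oracle <- cutree(hclust(as.dist(1 - cor(t(eg))), "average"), h = 0.5)
  expect_equal(ari_of(fam$families, oracle), 1)
})

test_that("trait association matches cor.test and flags constant traits", {
  m <- random_em(30, 20, 81)
  labels <- setNames(rep(1:3, each = 10), rownames(m$values))
  eg <- module_eigengenes(m, labels)
  set.seed(82)
  traits <- cbind(t1 = rbinom(20, 1, 0.5), t2 = rbinom(20, 1, 0.4),
                  flat = rep(1, 20))
  rownames(traits) <- colnames(m$values)
  ta <- trait_association(eg, traits)
  for (mod in rownames(eg)) for (tr in c("t1", "t2")) {
    oracle <- cor.test(eg[mod, ], traits[, tr])
    expect_equal(ta$r[mod, tr], unname(oracle$estimate), tolerance = 1e-10)
    expect_equal(ta$p[mod, tr], oracle$p.value, tolerance = 1e-10)
  }
  expect_true(all(is.na(ta$r[, "flat"])))
  # an eigengene equal to a standardized trait correlates perfectly
  e <- scale(traits[, "t1"])[, 1]
  eg2 <- rbind(ME1 = e / sqrt(sum(e^2)))
  colnames(eg2) <- colnames(m$values)
  ta2 <- trait_association(eg2, traits)
  expect_equal(unname(ta2$r["ME1", "t1"]), 1, tolerance = 1e-12)
  expect_equal(unname(ta2$p["ME1", "t1"]), 0)
})

test_that("alignment scoring recovers an exact stage trait and its reversal", {
  sim <- small_sim(seed = 83, noise_sd = 0, module_loading_sd = 0,
                   module_activity_sd = 0)
  m <- sim$matrix
  true_map <- sim$truth$stage_map
  trait <- alignment_trait(m, true_map)
  e <- scale(trait)[, 1]; e <- e / sqrt(sum(e^2))
  eg <- rbind(ME1 = e)
  colnames(eg) <- m$metadata$sample_id
  ranked <- score_alignment_orders(eg, m)
  expect_equal(ranked$map[1], map_string(true_map))
  expect_equal(ranked$score[1], 1, tolerance = 1e-10)
  expect_equal(nrow(ranked), 24)
  # the reversed map scores exactly the correlation of the eigengene with
  # the reversed trait; control samples keep their own stages, so the
  # reversal is not a global sign flip but still scores strictly lower
  rev_map <- setNames(5 - true_map, names(true_map))
  rev_r <- cor(e, alignment_trait(m, rev_map))
  expect_lt(rev_r, 0)
  expect_equal(ranked$score[ranked$map == map_string(rev_map)], rev_r,
               tolerance = 1e-10)
  ranked_abs <- score_alignment_orders(eg, m, positive_only = FALSE)
  expect_equal(ranked_abs$score[ranked_abs$map == map_string(rev_map)],
               abs(rev_r), tolerance = 1e-10)
  expect_equal(ranked_abs$map[1], map_string(true_map))
  # non-injective maps are rejected
  bad <- setNames(c(1, 1, 2, 3), names(true_map))
  expect_error(score_alignment_orders(eg, m, candidate_maps = list(bad)),
               "injective")
})

test_that("on noise-free planted data the true order wins every alternative", {
  sim <- small_sim(seed = 84, noise_sd = 0, module_loading_sd = 0,
                   module_activity_sd = 0)
  pre <- network_prefilter(detection_filter(sim$matrix)$matrix)$matrix
  mod <- suppressWarnings(detect_modules(pre, 6))
  eg <- module_eigengenes(pre, mod)
  ranked <- score_alignment_orders(eg, pre)
  expect_equal(ranked$map[1], map_string(sim$truth$stage_map))
  expect_equal(ranked$score[1], 1, tolerance = 1e-8)
  expect_gt(ranked$score[1], max(ranked$score[-1]))
})
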