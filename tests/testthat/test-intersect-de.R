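test_that("group statistics match hand arithmetic and a naive-loop oracle", {
  md <- data.frame(sample_id = sprintf("s%d", 1:4),
                   group = c("A", "A", "A", "B"),
                   kind = c("tumor", "tumor", "tumor", "control"),
                   stage_index = c(NA, NA, NA, 1), stringsAsFactors = FALSE)
  v <- rbind(g1 = c(2, 4, 6, 10), g2 = c(1, 1, 1, 5))
  colnames(v) <- md$sample_id
  st <- compute_group_stats(expression_matrix(v, md))
  a1 <- st[st$gene_id == "g1" & st$group == "A", ]
  expect_equal(a1$mean, 4)
  expect_equal(a1$median, 4)
  expect_equal(a1$variance, 4)
  expect_equal(a1$sd, 2)
  b1 <- st[st$gene_id == "g1" & st$group == "B", ]
  expect_equal(b1$mean, 10)
  expect_true(is.na(b1$sd) && is.na(b1$variance))

  # naive per-gene loop oracle on a random cohort
  m <- tiny_cohort(n_genes = 40, seed = 61)
  st <- compute_group_stats(m)
  for (g in sample(rownames(m$values), 5)) {
    for (grp in unique(m$metadata$group)) {
      vals <- m$values[g, m$metadata$group == grp]
      row <- st[st$gene_id == g & st$group == grp, ]
      expect_equal(row$mean, mean(vals))
      expect_equal(row$median, median(vals))
      if (length(vals) > 1) expect_equal(row$sd, sd(vals))
    }
  }
})

test_that("pairwise t tests reproduce the textbook pooled case", {
  md <- data.frame(sample_id = sprintf("s%d", 1:6),
                   group = rep(c("A", "B"), each = 3),
                   kind = c(rep("tumor", 3), rep("control", 3)),
                   stage_index = c(NA, NA, NA, 1, 1, 1),
                   stringsAsFactors = FALSE)
  v <- rbind(g1 = c(8, 9, 10, 4, 5, 6),
             g2 = c(1, 2, 3, 1, 2, 3))
  colnames(v) <- md$sample_id
  res <- pairwise_test(expression_matrix(v, md), "A", "B")
  g1 <- res[res$gene_id == "g1", ]
  expect_equal(g1$t, 4.898979, tolerance = 1e-6)
  expect_equal(g1$df, 4)
  expect_equal(g1$p, 0.0080499, tolerance = 1e-4)
  expect_equal(g1$direction, "up")
  oracle <- t.test(c(8, 9, 10), c(4, 5, 6), var.equal = TRUE)
  expect_equal(g1$t, unname(oracle$statistic), tolerance = 1e-10)
  expect_equal(g1$p, oracle$p.value, tolerance = 1e-10)
  # identical groups: t = 0, p = 1, ns
  g2 <- res[res$gene_id == "g2", ]
  expect_equal(g2$t, 0)
  expect_equal(g2$p, 1)
  expect_equal(g2$direction, "ns")
  # log2 means 10 vs 8 give a 4-fold change
  expect_equal(g1$fold_change, 2^(9 - 5))
})

test_that("both t variants agree with t.test across random genes", {
  m <- tiny_cohort(n_genes = 25, seed = 62)
  for (variant in c("student", "welch")) {
    res <- pairwise_test(m, "S1", "C1", variant = variant)
    for (g in sample(rownames(m$values), 6)) {
      a <- m$values[g, m$metadata$group == "S1"]
      b <- m$values[g, m$metadata$group == "C1"]
      oracle <- t.test(a, b, var.equal = (variant == "student"))
      row <- res[res$gene_id == g, ]
      expect_equal(row$t, unname(oracle$statistic), tolerance = 1e-10)
      expect_equal(row$p, oracle$p.value, tolerance = 1e-10)
      expect_equal(row$df, unname(oracle$parameter), tolerance = 1e-8)
    }
  }
  expect_error(pairwise_test(m, "S1", "C3"),
               "single_reference_membership")
})

test_that("sigma-fold membership applies the stdev cutoff", {
  md <- data.frame(sample_id = c(sprintf("s%d", 1:4), "ref"),
                   group = c(rep("S", 4), "NFB"),
                   kind = c(rep("tumor", 4), "control"),
                   stage_index = c(NA, NA, NA, NA, 4),
                   stringsAsFactors = FALSE)
  # g1: mean 10, sd 1, ref 10 -> inside; g2: ref 12.5 -> outside, S under
  # g3: ref far below -> S over-expressed; g4: zero sd, exact equality
  base <- c(8.5, 9.5, 10.5, 11.5)
  unit <- (base - mean(base)) / sd(base) + 10   # mean 10, sd exactly 1
  v <- rbind(g1 = c(unit, 10),
             g2 = c(unit, 12.5),
             g3 = c(unit, 4),
             g4 = c(7, 7, 7, 7, 7))
  colnames(v) <- md$sample_id
  m <- expression_matrix(v, md)
  res <- single_reference_membership(m, "S", "NFB", k = 2)
  expect_equal(res$sigma_fold[1], 0)
  expect_equal(res$membership[1], "inside")
  expect_equal(res$direction[1], "ns")
  expect_equal(res$sigma_fold[2], 2.5, tolerance = 1e-12)
  expect_equal(res$membership[2], "outside")
  expect_equal(res$direction[2], "down")   # subgroup under-expressed vs ref
  expect_equal(res$direction[3], "up")
  expect_equal(res$membership[4], "inside")
  expect_equal(res$sigma_fold[4], 0)
})

test_that("membership outside-rate matches the closed-form t tail", {
  # subgroup of n draws and an independent reference from the same normal:
  # (ref - mean)/sd is t_{n-1} scaled by sqrt(1 + 1/n)
  set.seed(63)
  n <- 21
  n_genes <- 10000
  md <- data.frame(sample_id = c(sprintf("s%d", 1:n), "ref"),
                   group = c(rep("S", n), "NFB"),
                   kind = c(rep("tumor", n), "control"),
                   stage_index = c(rep(NA, n), 4), stringsAsFactors = FALSE)
  v <- matrix(rnorm(n_genes * (n + 1)), n_genes, n + 1,
              dimnames = list(sprintf("g%05d", 1:n_genes), md$sample_id))
  res <- single_reference_membership(expression_matrix(v, md), "S", "NFB",
                                     k = 2)
  expected <- 2 * pt(-2 / sqrt(1 + 1 / n), n - 1)
  rate <- mean(res$membership == "outside")
  mc_sd <- sqrt(expected * (1 - expected) / n_genes)
  expect_lt(abs(rate - expected), 4 * mc_sd)
})

test_that("step-wise exclusivity implements the intersect rule on toy tables", {
  genes <- c("g1", "g2", "g3")
  res <- fake_comparisons(list(
    fake_test_result(genes, c("up", "up", "ns"), "S1", "C1"),
    fake_test_result(genes, c("up", "up", "ns"), "S1", "C2"),
    fake_test_result(genes, c("ns", "up", "ns"), "S2", "C1"),
    fake_test_result(genes, c("ns", "up", "down"), "S2", "C2")),
    subgroups = c("S1", "S2"), controls = c("C1", "C2"))
  calls <- stepwise_exclusive(res, direction = "up")
  cls <- function(g, s) calls$class[calls$gene_id == g & calls$subgroup == s]
  expect_equal(cls("g1", "S1"), "exclusive")   # the "$" class
  expect_equal(cls("g1", "S2"), "none")
  expect_equal(cls("g2", "S1"), "shared")      # the "^" class
  expect_equal(cls("g2", "S2"), "shared")
  expect_equal(cls("g3", "S1"), "none")
  # a missing comparison is named
  expect_error(stepwise_exclusive(res[c(1, 2, 3)]), "S2 vs C2")
})

test_that("single-sample controls corroborate but cannot veto", {
  genes <- c("g1", "g2")
  res <- fake_comparisons(list(
    fake_test_result(genes, c("up", "up"), "S1", "C1"),
    fake_test_result(genes, c("up", "up"), "S1", "C2"),
    fake_membership_result(genes, c("outside", "inside"), c("up", "ns"),
                           "S1", "NFB"),
    fake_test_result(genes, c("ns", "ns"), "S2", "C1"),
    fake_test_result(genes, c("ns", "ns"), "S2", "C2"),
    fake_membership_result(genes, c("inside", "inside"), c("ns", "ns"),
                           "S2", "NFB")),
    subgroups = c("S1", "S2"), controls = c("C1", "C2", "NFB"))
  calls <- stepwise_exclusive(res, direction = "up")
  s1 <- calls[calls$subgroup == "S1", ]
  # both genes are exclusive (the n=1 control cannot veto), but only g1
  # is corroborated by the reference profile
  expect_equal(s1$class, c("exclusive", "exclusive"))
  expect_equal(s1$corroborated, c(TRUE, FALSE))
})

test_that("exclusivity equals brute-force enumeration on random patterns", {
  set.seed(64)
  genes <- sprintf("g%02d", 1:50)
  subgroups <- paste0("S", 1:4)
  controls <- paste0("C", 1:3)
  dirs <- c("up", "down", "ns")
  results <- list()
  pattern <- array("", c(50, 4, 3), dimnames = list(genes, subgroups, controls))
  for (si in seq_along(subgroups)) for (ci in seq_along(controls)) {
    d <- sample(dirs, 50, replace = TRUE)
    pattern[, si, ci] <- d
    results <- c(results, list(
      fake_test_result(genes, d, subgroups[si], controls[ci])))
  }
  res <- fake_comparisons(results, subgroups, controls)
  calls <- stepwise_exclusive(res, direction = "up")
  for (g in genes) {
    passed <- vapply(subgroups, function(s) all(pattern[g, s, ] == "up"),
                     logical(1))
    for (s in subgroups) {
      expected <- if (!passed[s]) "none"
      else if (sum(passed) == 1) "exclusive" else "shared"
      expect_identical(
        calls$class[calls$gene_id == g & calls$subgroup == s], expected)
    }
  }
  # partition property: at most one subgroup is exclusive per gene
  n_excl <- tapply(calls$class == "exclusive", calls$gene_id, sum)
  expect_true(all(n_excl <= 1))
})

test_that("tightening alpha shrinks the step-1 pass sets monotonically", {
  sim <- small_sim(seed = 65)
  m <- detection_filter(sim$matrix)$matrix
  pass_set <- function(alpha) {
    calls <- stepwise_exclusive(dia_comparisons(m, alpha = alpha))
    paste(calls$gene_id, calls$subgroup)[calls$class != "none"]
  }
  loose <- pass_set(0.05)
  tight <- pass_set(0.005)
  expect_true(all(tight %in% loose))
})

test_that("top tables rank by absolute fold change with signed-fold rendering", {
  md <- data.frame(sample_id = sprintf("s%d", 1:6),
                   group = rep(c("A", "B"), each = 3),
                   kind = c(rep("tumor", 3), rep("control", 3)),
                   stage_index = c(NA, NA, NA, 1, 1, 1),
                   stringsAsFactors = FALSE)
  v <- rbind(up_big = c(12, 12.1, 11.9, 10, 10.1, 9.9),
             up_small = c(11, 11.1, 10.9, 10, 10.1, 9.9),
             down_two = c(9, 9.1, 8.9, 10, 10.1, 9.9),
             flat = c(10, 10.1, 9.9, 10, 10.1, 9.9))
  colnames(v) <- md$sample_id
  res <- pairwise_test(expression_matrix(v, md), "A", "B")
  up <- top_table(res, direction = "up")
  expect_equal(up$gene_id, c("up_big", "up_small"))
  expect_equal(up$fch, c(4, 2), tolerance = 1e-12)
  down <- top_table(res, direction = "down")
  expect_equal(down$gene_id, "down_two")
  expect_equal(down$fch, -2, tolerance = 1e-12)
  limited <- top_table(res, n = 1, direction = "up")
  expect_equal(nrow(limited), 1)
  over <- top_table(res, n = 10, direction = "up")
  expect_equal(nrow(over), 2)
  expect_match(attr(over, "note"), "only 2 available")
})

test_that("planted markers head the synthetic top tables", {
  sim <- small_sim(seed = 66)
  m <- detection_filter(sim$matrix)$matrix
  res <- pairwise_test(m, "WNT", "NSC")
  top <- top_table(res, n = 10, direction = "up")
  expect_gte(mean(top$gene_id %in% sim$truth$marker_sets[["WNT"]]), 0.9)
})
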