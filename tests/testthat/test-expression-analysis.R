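make_expr2 <- function(m, probes_used = 11L) {
  out <- tibble::as_tibble(m)
  tibble::add_column(out, probeset_id = rownames(m),
                     probes_used = probes_used, .before = 1)
}

de_design <- function() toy_design(species = "Pv",
                                   tissues = c("leaf", "nodule", "root"),
                                   replicates = 3)

test_that("one-way ANOVA matches the closed form and stats oracles", {
  design <- de_design()
  # the textbook case: groups (1,2,3), (2,3,4), (3,4,5) -> F = 3 on (2, 6)
  m <- matrix(c(1, 2, 3, 2, 3, 4, 3, 4, 5), 1,
              dimnames = list("g1", design$sample_id))
  de <- anova_de(make_expr2(m), design, p_cut = 0.05, fold_cut = 1)
  expect_equal(de$f_statistic, 3)
  expect_equal(de$p_value, pf(3, 2, 6, lower.tail = FALSE))

  # equal tissue means with spread: F = 0
  m0 <- matrix(c(1, 2, 3, 1, 2, 3, 1, 2, 3), 1,
               dimnames = list("g1", design$sample_id))
  de0 <- anova_de(make_expr2(m0), design)
  expect_equal(de0$f_statistic, 0)
  expect_false(de0$significant)

  # random probe sets against stats::aov / oneway.test
  set.seed(17)
  m <- matrix(rnorm(20 * 9, 8), 20, 9,
              dimnames = list(sprintf("g%02d", 1:20), design$sample_id))
  de <- anova_de(make_expr2(m), design)
  tissue <- factor(design$tissue[match(colnames(m), design$sample_id)])
  for (i in c(1, 7, 20)) {
    ref <- oneway.test(m[i, ] ~ tissue, var.equal = TRUE)
    expect_equal(de$f_statistic[i], unname(ref$statistic))
    expect_equal(de$p_value[i], ref$p.value)
    aov_f <- summary(aov(m[i, ] ~ tissue))[[1]]$`F value`[1]
    expect_equal(de$f_statistic[i], aov_f)
  }
  expect_equal(de$fdr, p.adjust(de$p_value, "BH"))

  # shift invariance of F
  de_shift <- anova_de(make_expr2(m + 5), design)
  expect_equal(de_shift$f_statistic, de$f_statistic)
})

test_that("ANOVA applies the fold filter and the organism exclusion", {
  design <- de_design()
  set.seed(18)
  base <- matrix(rnorm(3 * 9, 8, 0.01), 3, 9,
                 dimnames = list(c("gA", "gB", "pathogen1"),
                                 design$sample_id))
  # gA: big tissue effect; gB: significant but < 2-fold
  base["gA", design$tissue == "nodule"] <-
    base["gA", design$tissue == "nodule"] + 3
  base["gB", design$tissue == "nodule"] <-
    base["gB", design$tissue == "nodule"] + 0.5
  layout <- tibble::tibble(
    probeset_id = rep(rownames(base), each = 2),
    probe_id = paste0(rep(rownames(base), each = 2), ":", 1:2),
    probe_index = rep(1:2, 3),
    organism = rep(c("Pv", "Pv", "Phytophthora sojae"), each = 2)
  )
  de <- anova_de(make_expr2(base), design, layout = layout)
  expect_false("pathogen1" %in% de$probeset_id)
  expect_true(de$significant[de$probeset_id == "gA"])
  expect_false(de$significant[de$probeset_id == "gB"])
  expect_lt(de$p_value[de$probeset_id == "gB"], 1e-4) # failed only on fold
  expect_named(de, c("probeset_id", "f_statistic", "p_value", "fdr",
                     "log2fc_leaf_vs_nodule", "log2fc_leaf_vs_root",
                     "log2fc_nodule_vs_root", "max_abs_log2fc",
                     "significant"))

  g <- glance(de)
  expect_equal(g$n_tested, 2L)
  expect_equal(g$n_significant, 1L)

  # a tissue with one replicate is a design error
  bad <- design[-(1:2), ] # first tissue keeps a single replicate
  expect_error(anova_de(make_expr2(base[, bad$sample_id]), bad),
               "fewer than 2 replicates")
})

test_that("Benjamini-Hochberg matches the step-up definition", {
  bh_direct <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- numeric(m)
    adj[o] <- rev(cummin(rev(m * p[o] / seq_len(m))))
    pmin(adj, 1)
  }
  set.seed(19)
  for (i in 1:5) {
    p <- runif(50)^2
    expect_equal(p.adjust(p, "BH"), bh_direct(p))
  }
})

test_that("PCA overview decomposes variance as the eigen oracle does", {
  design <- de_design()
  set.seed(20)
  m <- matrix(rnorm(50 * 9, 8), 50, 9,
              dimnames = list(sprintf("g%02d", 1:50), design$sample_id))
  pca <- pca_overview(make_expr2(m), design, n_components = 4)
  expect_equal(sum(pca$var_explained), 1, tolerance = 1e-10)

  # eigen oracle on the covariance of samples x probe sets
  centered <- scale(t(m), center = TRUE, scale = FALSE)
  ev <- eigen(stats::cov(centered))$values
  expect_equal(pca$var_explained[1:8], (ev / sum(ev))[1:8], tolerance = 1e-8)

  # orthogonal scores
  sc <- as.matrix(pca$scores[paste0("PC", 1:4)])
  gram <- crossprod(sc)
  expect_lt(max(abs(gram[upper.tri(gram)])), 1e-8)

  # sign convention: dominant loading positive
  expect_true(all(apply(pca$loadings, 2,
                        function(v) v[which.max(abs(v))] > 0)))

  # two samples: PC1 explains everything
  two <- pca_overview(make_expr2(m[, 1:2]))
  expect_equal(two$var_explained[1], 1)

  expect_error(pca_overview(make_expr2(matrix(3, 4, 5,
    dimnames = list(paste0("g", 1:4), design$sample_id[1:5])))),
    "constant")

  expect_s3_class(autoplot(pca), "ggplot")
  expect_equal(glance(pca)$pc1_var_explained, pca$var_explained[1])
})

test_that("conservation classes partition the retained-count range", {
  l <- toy_layout(n_sets = 12, k = 11)
  # probe set i retains exactly i - 1 probes (0..11)
  masked <- unlist(lapply(1:12, function(i) {
    ps <- sprintf("TS%03d", i)
    paste0(ps, ":", seq_len(11))[seq_len(11 - (i - 1))]
  }))
  cls <- classify_conservation(mask_of(l, masked), l)
  got <- setNames(as.character(cls$group), cls$probeset_id)
  expected <- c("all_masked", "hyper_variable", "hyper_variable",
                rep("intermediate", 7), "highly_conserved",
                "highly_conserved")
  expect_equal(unname(got[sprintf("TS%03d", 1:12)]), expected)
  expect_equal(cls$retained[order(cls$probeset_id)], 0:11)
  # every probe set with >= 1 retained probe falls in exactly one group
  expect_false(any(is.na(cls$group)))
  expect_error(classify_conservation(mask_of(l, masked), l,
                                     hi_min = 2, hyper_max = 2),
               "must exceed")
})

test_that("Fisher over-representation matches hypergeometric enumeration", {
  # universe of 20, class of 5, selection of 10 containing the whole class:
  # one-sided tail P(X >= 5) = C(15,5)/C(20,10) = 3003/184756
  universe <- sprintf("g%02d", 1:20)
  cls <- tibble::tibble(probeset_id = universe[1:5], class_id = "A")
  selection <- universe[1:10]
  res <- fisher_overrep(selection, cls, universe)
  tail1 <- choose(15, 5) / choose(20, 10)
  expect_equal(tail1, 3003 / 184756)
  # two-sided p: sum of hypergeometric point masses <= the observed one
  dens <- dhyper(0:5, 5, 15, 10)
  p2 <- sum(dens[dens <= dhyper(5, 5, 15, 10) * (1 + 1e-7)])
  expect_equal(res$fisher_p, p2)
  expect_equal(res$direction, "over")
  expect_equal(res$bonferroni_p, min(1, p2)) # single class tested
  expect_equal(res$z_value, qnorm(1 - res$bonferroni_p / 2))

  # empty selection flags nothing
  none <- fisher_overrep(character(), cls, universe)
  expect_false(any(none$flagged))

  expect_error(fisher_overrep("zz", cls, universe), "outside the universe")
  expect_error(fisher_overrep(character(), cls, character()),
               "empty universe")
})

test_that("Fisher p-values equal brute-force hypergeometric sums on random
           tables", {
  set.seed(22)
  for (i in 1:10) {
    N <- sample(10:50, 1)
    universe <- sprintf("u%02d", seq_len(N))
    m <- sample(2:(N - 2), 1)
    k <- sample(2:(N - 2), 1)
    cls <- tibble::tibble(probeset_id = sample(universe, m), class_id = "C")
    selection <- sample(universe, k)
    res <- fisher_overrep(selection, cls, universe)
    a <- length(intersect(selection, cls$probeset_id))
    lo <- max(0, k - (N - m)); hi <- min(k, m)
    dens <- dhyper(lo:hi, m, N - m, k)
    p_oracle <- sum(dens[dens <= dhyper(a, m, N - m, k) * (1 + 1e-7)])
    expect_equal(res$fisher_p, p_oracle, tolerance = 1e-10)
  }
})

test_that("swapping the selection for its complement flips the direction", {
  set.seed(23)
  universe <- sprintf("u%02d", 1:30)
  cls <- tibble::tibble(probeset_id = sample(universe, 8), class_id = "C")
  selection <- sample(universe, 11)
  res <- fisher_overrep(selection, cls, universe)
  comp <- fisher_overrep(setdiff(universe, selection), cls, universe)
  expect_equal(res$fisher_p, comp$fisher_p, tolerance = 1e-12)
  if (res$count_in_selection * 1 != res$count_in_universe * 11 / 30) {
    expect_false(res$direction == comp$direction)
  }
})
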