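# independent sort-and-average quantile normalization oracle
qn_oracle <- function(m) {
  ref <- rowMeans(apply(m, 2, sort))
  out <- m
  for (j in seq_len(ncol(m))) {
    o <- order(m[, j])
    out[o, j] <- ref
    # ties: mean of reference values at the tied ranks
    for (v in unique(m[, j][duplicated(m[, j])])) {
      idx <- which(m[, j] == v)
      out[idx, j] <- mean(out[idx, j])
    }
  }
  out
}

test_that("quantile normalization matches the sort-and-average oracle", {
  x <- toy_intensities(matrix(c(1, 2, 3, 4), 2,
                              dimnames = list(c("p1", "p2"), c("s1", "s2"))))
  qn <- quantile_normalize(x)
  expect_equal(unname(as.matrix(qn[-1])),
               matrix(c(2, 3, 2, 3), 2))

  set.seed(11)
  m <- matrix(rlnorm(600, 5, 1), 100, 6,
              dimnames = list(sprintf("p%03d", 1:100), paste0("s", 1:6)))
  qn <- quantile_normalize(toy_intensities(m))
  mq <- as.matrix(qn[-1])
  expect_equal(unname(mq), unname(qn_oracle(m)))
  # identical distribution in every column: Kolmogorov distance 0
  sorted <- apply(mq, 2, sort)
  for (j in 2:6) expect_equal(sorted[, j], sorted[, 1])
  # idempotence, exact
  expect_equal(quantile_normalize(qn), qn)
})

test_that("quantile normalization handles ties and degenerate input", {
  m <- matrix(c(1, 1, 5, 2, 4, 9), 3,
              dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  qn <- as.matrix(quantile_normalize(toy_intensities(m))[-1])
  ref <- rowMeans(apply(m, 2, sort)) # 1.5, 2.5, 7
  expect_equal(unname(qn[, 2]), unname(ref))
  expect_equal(unname(qn[1:2, 1]), rep(mean(ref[1:2]), 2))

  # identical columns are already normalized
  same <- matrix(c(3, 1, 2, 3, 1, 2), 3,
                 dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  out <- as.matrix(quantile_normalize(toy_intensities(same))[-1])
  expect_equal(unname(out), unname(same))

  one <- toy_intensities(matrix(1:3, 3, dimnames = list(letters[1:3], "s1")))
  expect_warning(res <- quantile_normalize(one), "single-column")
  expect_equal(res, one)
})

test_that("normexp posterior mean matches a quadrature oracle", {
  mu <- 50; sigma <- 5; theta <- 200
  oracle <- function(x) {
    num <- integrate(function(s) s * dexp(s, 1 / theta) * dnorm(x - s, mu, sigma),
                     0, Inf, rel.tol = 1e-12)$value
    den <- integrate(function(s) dexp(s, 1 / theta) * dnorm(x - s, mu, sigma),
                     0, Inf, rel.tol = 1e-12)$value
    num / den
  }
  set.seed(4)
  xs <- c(sort(rnorm(20, mu, sigma) + rexp(20, 1 / theta))[1:15], 35, 50, 80)
  xs <- xs[xs < mu + 10 * sigma] # keep the quadrature well-conditioned
  expect_equal(normexp_signal_mean(xs, mu, sigma, theta),
               vapply(xs, oracle, 0), tolerance = 1e-6)
})

test_that("background correction is positive, monotone, and subtracts the
           background in the high-signal limit", {
  set.seed(5)
  bg <- rnorm(2000, 60, 8)
  bg[bg < 1] <- 60
  signal <- rexp(2000, 1 / 300)
  on <- runif(2000) < 0.5
  m <- matrix(bg + ifelse(on, signal, 0), ncol = 2)
  rownames(m) <- sprintf("p%04d", seq_len(nrow(m)))
  colnames(m) <- c("s1", "s2")
  x <- toy_intensities(m)
  corrected <- background_correct(x)
  cm <- as.matrix(corrected[-1])
  expect_true(all(cm > 0))
  # within-column ranks preserved
  for (j in 1:2) expect_equal(rank(cm[, j]), unname(rank(m[, j])))
  # far above background: corrected ~ x - background_mean within 1%
  hi <- m[, 1] > 60 + 8 * 8
  expect_true(any(hi))
  expect_equal(cm[hi, 1], unname(m[hi, 1] - 60), tolerance = 0.04)

  flat <- toy_intensities(matrix(5, 4, 1, dimnames = list(letters[1:4], "sA")))
  expect_error(background_correct(flat), "'sA' has zero variance")
})

test_that("median polish fits additive data exactly and honors the contract", {
  # exactly additive 2x2: expression (2, 3)
  mp <- median_polish(matrix(c(1, 3, 2, 4), 2, 2))
  expect_equal(mp$fitted, c(2, 3))

  # constant probe set: expression equals the constant
  mp <- median_polish(matrix(7.25, 5, 4))
  expect_equal(mp$fitted, rep(7.25, 4))
  expect_equal(max(abs(mp$residuals)), 0)

  # residual row and column medians near zero at convergence
  set.seed(6)
  y <- matrix(rnorm(11 * 9, 8), 11, 9)
  mp <- median_polish(y, tol = 1e-9, max_iter = 100)
  expect_lt(max(abs(apply(mp$residuals, 1, median))), 1e-6)
  expect_lt(max(abs(apply(mp$residuals, 2, median))), 1e-6)
})

test_that("R and C++ median polish agree with each other and stats::medpolish", {
  set.seed(7)
  for (dims in list(c(11, 9), c(4, 6), c(1, 9), c(8, 2))) {
    y <- matrix(rnorm(prod(dims), 8, 1.5), dims[1], dims[2])
    mine <- median_polish(y, tol = 1e-10, max_iter = 200)
    cpp <- crossmask:::medpolish_sets_cpp(y, 0L, nrow(y), 1e-10, 200L)
    expect_equal(as.numeric(cpp), mine$fitted, tolerance = 1e-8)
    ref <- stats::medpolish(y, eps = 1e-10, maxiter = 200, trace.iter = FALSE)
    expect_equal(mine$fitted, unname(ref$overall + ref$col), tolerance = 0.05)
  }
})

test_that("summarize_rma drops masked probes and degenerates gracefully", {
  l <- toy_layout(n_sets = 2, k = 3)
  set.seed(8)
  m <- matrix(2^rnorm(6 * 4, 8), 6, 4,
              dimnames = list(l$probe_id, paste0("s", 1:4)))
  x <- toy_intensities(m)

  # empty mask equals no mask
  e0 <- summarize_rma(x, l)
  e_empty <- summarize_rma(x, l, mask_of(l, character()))
  expect_equal(e0, e_empty)

  # masking one probe equals summarizing the submatrix without it
  masked <- summarize_rma(x, l, mask_of(l, "TS001:2"))
  sub <- toy_intensities(m[-2, , drop = FALSE])
  direct <- summarize_rma(sub, l)
  expect_equal(masked, direct)
  expect_equal(masked$probes_used, c(2L, 3L))

  # single retained probe: expression is that probe's log2 values
  one <- summarize_rma(x, l, mask_of(l, c("TS001:1", "TS001:2")))
  expect_equal(unname(as.matrix(one[one$probeset_id == "TS001", -(1:2)])[1, ]),
               unname(log2(m["TS001:3", ])))

  # fully masked probe set is absent
  none <- summarize_rma(x, l, mask_of(l, paste0("TS001:", 1:3)))
  expect_equal(none$probeset_id, "TS002")
})

# brute-force signed-rank tail over all sign assignments
signed_rank_enum <- function(d, mu) {
  z <- d - mu
  z <- z[z != 0]
  n <- length(z)
  r <- rank(abs(z))
  w <- sum(r[z > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  ws <- as.matrix(signs) %*% r
  mean(ws >= w)
}

test_that("signed-rank p-values match exhaustive enumeration", {
  # 11 pairs all at d = 0.5: p = 1/2^11, the strongest possible evidence
  expect_equal(signed_rank_p(rep(0.5, 11), mu = 0.015), 1 / 2048)
  # no informative pairs
  expect_equal(signed_rank_p(rep(0.015, 7), mu = 0.015), 1)

  set.seed(9)
  for (n in c(3, 5, 8, 12)) {
    d <- round(rnorm(n, 0.05, 0.2), 2) # rounding plants ties
    expect_equal(signed_rank_p(d, mu = 0.015),
                 signed_rank_enum(d, 0.015))
  }
})

test_that("detection calls follow the discrimination-score test", {
  l <- toy_layout(n_sets = 2, k = 11, mm = TRUE)
  design <- toy_design(replicates = 1, tissues = "leaf")
  pm <- matrix(300, 22, 1, dimnames = list(l$probe_id, design$sample_id[1]))
  mm <- matrix(100, 22, 1, dimnames = list(l$mm_probe_id, design$sample_id[1]))
  # second probe set: PM == MM, no evidence
  pm[12:22, ] <- 100
  x <- toy_intensities(rbind(pm, mm))
  calls <- detect_calls(x, l)
  c1 <- calls[calls$probeset_id == "TS001", ]
  expect_equal(c1$p_value, 1 / 2048)
  expect_equal(as.character(c1$call), "Present")
  c2 <- calls[calls$probeset_id == "TS002", ]
  expect_equal(as.character(c2$call), "Absent")

  # without MM probes the call is NA, not an error
  l_nomm <- toy_layout(n_sets = 1, k = 11)
  x_pm <- toy_intensities(pm[1:11, , drop = FALSE])
  calls <- detect_calls(x_pm, l_nomm)
  expect_true(all(is.na(calls$p_value)))
  expect_true(all(is.na(calls$call)))
})
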