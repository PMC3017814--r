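#' Background-correct probe intensities
#'
#' Models each sample column as signal plus optical background,
#' X = S + B with S ~ Exponential(mean `theta`) and B ~ Normal(`mu`,
#' `sigma^2`), and replaces every observed intensity by the posterior mean
#' E\[S | X = x\] of the convolution model (the "normexp" correction used
#' throughout single-channel array preprocessing). Parameters are estimated
#' per column by method of moments around the column mode: `mu` is the mode
#' of a kernel density fit, `sigma` the root-mean-square deviation of the
#' sub-mode values around the mode, and `theta` the mean excess of the
#' above-mode values. Corrected values are strictly positive and monotone
#' increasing in the input within a column.
#'
#' @param x Intensity tibble (`probe_id` + sample columns).
#' @return Tibble of the same shape with corrected intensities.
#' @export
background_correct <- function(x) {
  m <- wide_to_matrix(x, "probe_id")
  out <- m
  for (j in seq_len(ncol(m))) {
    v <- m[, j]
    if (stats::sd(v) == 0) {
      stop("cannot estimate background: column '", colnames(m)[j],
           "' has zero variance")
    }
    par <- normexp_mom(v)
    out[, j] <- normexp_signal_mean(v, par$mu, par$sigma, par$theta)
  }
  matrix_to_wide(out, "probe_id")
}

# Method-of-moments normexp parameter estimates around the column mode.
# The mode is located on the log2 scale, where the optical-background
# component forms a sharp peak while the signal spreads over many octaves;
# a linear-scale kernel would smooth the peak away whenever strong signals
# stretch the range.
normexp_mom <- function(v) {
  d <- stats::density(log2(v))
  mu <- 2^d$x[which.max(d$y)]
  below <- v[v <= mu]
  sigma <- sqrt(mean((below - mu)^2))
  if (!is.finite(sigma) || sigma <= 0) sigma <- stats::sd(v) / 10
  above <- v[v > mu]
  theta <- if (length(above)) mean(above) - mu else sigma
  theta <- max(theta, sigma / 10, .Machine$double.eps)
  list(mu = mu, sigma = sigma, theta = theta)
}

#' Posterior mean signal under the normal + exponential convolution
#'
#' E\[S | X = x\] for X = S + B, S ~ Exp(mean `theta`),
#' B ~ N(`mu`, `sigma^2`): a truncated-normal mean with location
#' `x - mu - sigma^2 / theta` and scale `sigma`. Computation is delegated to
#' `limma::normexp.signal()`, the standard implementation of this formula.
#'
#' @param x Observed intensities.
#' @param mu,sigma Background mean and standard deviation.
#' @param theta Mean of the exponential signal component.
#' @return Corrected intensities, same length as `x`, strictly positive.
#' @export
normexp_signal_mean <- function(x, mu, sigma, theta) {
  stopifnot(sigma > 0, theta > 0)
  limma::normexp.signal(c(mu, log(sigma), log(theta)), x)
}

#' Quantile-normalize sample columns
#'
#' Forces every sample to share one intensity distribution: the value at
#' rank r in each column is replaced by the mean, across columns, of the
#' rank-r order statistics. Tied values within a column receive the mean of
#' the reference values at their tied ranks, so the result does not depend
#' on input row order. Applying the transform twice equals applying it once.
#'
#' @param x Intensity tibble (`probe_id` + sample columns).
#' @return Tibble of the same shape with normalized intensities.
#' @export
quantile_normalize <- function(x) {
  m <- wide_to_matrix(x, "probe_id")
  if (ncol(m) == 1L) {
    warning("single-column matrix: quantile normalization is a no-op")
    return(x)
  }
  ref <- rowMeans(apply(m, 2, sort))
  out <- apply(m, 2, function(v) {
    val <- ref[rank(v, ties.method = "first")]
    ave(val, v, FUN = mean)
  })
  rownames(out) <- rownames(m)
  matrix_to_wide(out, "probe_id")
}

#' Two-way median polish
#'
#' Fits the additive model `y[i, j] = overall + row[i] + col[j]` by
#' alternately sweeping out row and column medians (row sweep first),
#' stopping when the total absolute change in one full sweep falls below
#' `tol` or after `max_iter` iterations. This is the robust fit at the heart
#' of RMA probe-set summarization: rows are probes, columns samples, and the
#' per-sample expression value is `overall + col[j]`.
#'
#' @param y Numeric matrix (rows = probes, columns = samples) of log2
#'   intensities.
#' @param tol Convergence tolerance on the total absolute change per
#'   iteration.
#' @param max_iter Maximum number of row+column sweep iterations.
#' @return A list with `overall`, `row`, `col`, `residuals`, `fitted`
#'   (per-sample expression `overall + col`), and `iterations`.
#' @export
median_polish <- function(y, tol = 0.01, max_iter = 10L) {
  y <- as.matrix(y)
  r <- y
  overall <- 0
  row_eff <- rep(0, nrow(y))
  col_eff <- rep(0, ncol(y))
  iter <- 0L
  repeat {
    iter <- iter + 1L
    change <- 0
    rm <- apply(r, 1, median)
    row_eff <- row_eff + rm
    r <- r - rm
    change <- change + sum(abs(rm))
    delta <- median(row_eff)
    overall <- overall + delta
    row_eff <- row_eff - delta
    cm <- apply(r, 2, median)
    col_eff <- col_eff + cm
    r <- sweep(r, 2, cm)
    change <- change + sum(abs(cm))
    delta <- median(col_eff)
    overall <- overall + delta
    col_eff <- col_eff - delta
    if (change < tol || iter >= max_iter) break
  }
  list(overall = overall, row = row_eff, col = col_eff, residuals = r,
       fitted = overall + col_eff, iterations = iter)
}

#' Summarize probe-level intensities into probe-set expression values
#'
#' The summarization step of RMA, with optional probe masking: for each
#' probe set, masked probes are dropped; if no probes remain the probe set
#' is absent from the output; otherwise the additive model
#' `log2(y) = mu + probe + sample` is fitted by median polish and the
#' expression value of sample s is `mu + sample[s]`. A probe set with a
#' single retained probe degenerates to that probe's log2 values. Input is
#' expected to be background-corrected and quantile-normalized already
#' (see [background_correct()], [quantile_normalize()]).
#'
#' @param x Intensity tibble (`probe_id` + sample columns), linear scale.
#' @param layout Layout tibble (see [read_layout()]).
#' @param mask Optional `probe_mask`; `NULL` means no masking.
#' @param tol,max_iter Median-polish convergence controls, see
#'   [median_polish()].
#' @return Expression tibble with columns `probeset_id`, `probes_used`, then
#'   one log2-expression column per sample.
#' @export
summarize_rma <- function(x, layout, mask = NULL, tol = 0.01, max_iter = 10L) {
  layout <- validate_layout(layout)
  keep_ids <- layout$probe_id
  if (!is.null(mask)) {
    stopifnot(inherits(mask, "probe_mask"))
    unknown <- setdiff(mask$probe_id, layout$probe_id)
    if (length(unknown)) {
      stop("mask names probe(s) absent from layout: ",
           paste(head(unknown, 5), collapse = ", "))
    }
    keep_ids <- setdiff(keep_ids, mask$probe_id)
  }
  lay <- layout[layout$probe_id %in% keep_ids, c("probeset_id", "probe_id")]
  m <- wide_to_matrix(x, "probe_id")
  present <- lay$probe_id %in% rownames(m)
  lay <- lay[present, , drop = FALSE]
  if (nrow(lay) == 0) {
    return(tibble::tibble(probeset_id = character(), probes_used = integer()))
  }
  logm <- log2(m[lay$probe_id, , drop = FALSE])
  # rows are already grouped by probe set (layout is sorted)
  lens <- rle(lay$probeset_id)
  set_len <- lens$lengths
  set_start <- cumsum(c(0L, set_len[-length(set_len)]))
  exprm <- medpolish_sets_cpp(logm, as.integer(set_start),
                              as.integer(set_len), tol, as.integer(max_iter))
  colnames(exprm) <- colnames(logm)
  rownames(exprm) <- lens$values
  out <- matrix_to_wide(exprm, "probeset_id")
  tibble::add_column(out, probes_used = as.integer(set_len), .after = 1)
}

#' MAS5-style present/absent detection calls
#'
#' For each probe set and sample, discrimination scores
#' `d = (PM - MM) / (PM + MM)` are tested against the threshold `tau` with a
#' one-sided Wilcoxon signed-rank test (exact for up to 12 informative
#' pairs, normal approximation with continuity and tie correction above).
#' Calls: Present if p < `alpha1`, Marginal if `alpha1 <= p < alpha2`,
#' otherwise Absent. Pairs with `PM + MM = 0` are dropped; probe sets
#' without MM probes get `NA` calls.
#'
#' @param x Intensity tibble containing both PM and MM probe rows.
#' @param layout Layout tibble with an `mm_probe_id` column.
#' @param tau Discrimination-score threshold.
#' @param alpha1,alpha2 Present/Marginal p-value cutpoints
#'   (`alpha1 < alpha2`).
#' @return A long tibble: `probeset_id`, `sample_id`, `p_value`, `call`
#'   (factor Present/Marginal/Absent).
#' @export
detect_calls <- function(x, layout, tau = 0.015, alpha1 = 0.04, alpha2 = 0.06) {
  stopifnot(alpha1 > 0, alpha1 < alpha2, alpha2 < 1)
  layout <- validate_layout(layout)
  if (!"mm_probe_id" %in% names(layout)) {
    layout$mm_probe_id <- NA_character_
  }
  m <- wide_to_matrix(x, "probe_id")
  samples <- colnames(m)
  sets <- split(layout, layout$probeset_id)
  res <- purrr::map(sets, function(l) {
    has_mm <- !is.na(l$mm_probe_id) &
      l$probe_id %in% rownames(m) & l$mm_probe_id %in% rownames(m)
    if (!any(has_mm)) {
      return(tibble::tibble(sample_id = samples, p_value = NA_real_))
    }
    pm <- m[l$probe_id[has_mm], , drop = FALSE]
    mm <- m[l$mm_probe_id[has_mm], , drop = FALSE]
    p <- vapply(seq_along(samples), function(j) {
      tot <- pm[, j] + mm[, j]
      ok <- tot > 0
      if (!any(ok)) return(NA_real_)
      d <- (pm[ok, j] - mm[ok, j]) / tot[ok]
      signed_rank_p(d, mu = tau)
    }, 0)
    tibble::tibble(sample_id = samples, p_value = p)
  })
  out <- dplyr::bind_rows(res, .id = "probeset_id")
  out$call <- factor(
    dplyr::case_when(
      is.na(out$p_value) ~ NA_character_,
      out$p_value < alpha1 ~ "Present",
      out$p_value < alpha2 ~ "Marginal",
      TRUE ~ "Absent"
    ),
    levels = c("Present", "Marginal", "Absent")
  )
  out
}

#' One-sided Wilcoxon signed-rank p-value
#'
#' Tests H1: median of `d` exceeds `mu`. Zero differences are dropped;
#' absolute differences are ranked with midranks for ties. For n <= 12
#' informative pairs the tail probability P(W+ >= w) is computed exactly by
#' dynamic programming over the rank multiset (so midranks are handled
#' exactly); for larger n a normal approximation with tie correction and
#' continuity correction is used.
#'
#' @param d Numeric vector of differences (or scores).
#' @param mu Null location.
#' @return The one-sided p-value; 1 when no informative pairs remain.
#' @export
signed_rank_p <- function(d, mu = 0) {
  z <- d - mu
  z <- z[z != 0 & !is.na(z)]
  n <- length(z)
  if (n == 0) return(1)
  r <- rank(abs(z))
  w <- sum(r[z > 0])
  if (n <= 12L) {
    # distribution of W+ over all 2^n sign assignments; ranks doubled so
    # midranks (k + 0.5) stay integral
    r2 <- as.integer(round(2 * r))
    total <- sum(r2)
    counts <- numeric(total + 1L)
    counts[1L] <- 1
    for (ri in r2) {
      shifted <- c(numeric(ri), counts[seq_len(total + 1L - ri)])
      counts <- counts + shifted
    }
    w2 <- as.integer(round(2 * w))
    sum(counts[(w2 + 1L):(total + 1L)]) / 2^n
  } else {
    mean_w <- n * (n + 1) / 4
    ties <- table(r)
    var_w <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(ties^3 - ties) / 48
    pnorm(w - 0.5, mean = mean_w, sd = sqrt(var_w), lower.tail = FALSE)
  }
}
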