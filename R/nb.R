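#' Median-of-ratios size factors
#'
#' Per sample, the median over all-positive genes of the ratio of the count
#' to the gene's geometric mean across samples, rescaled so the reported
#' factors have geometric mean 1 (any fixed convention is equivalent for
#' the test; geometric mean 1 makes factors comparable across runs).
#'
#' @param counts a [count_matrix()] or gene x sample matrix.
#' @return named numeric vector of positive factors, one per sample.
#' @export
size_factors <- function(counts) {
  m <- unclass(counts)
  keep <- rowSums(m > 0) == ncol(m)
  if (!any(keep))
    stop("size_factors: no gene has nonzero counts in all samples; ",
         "filter samples or genes before normalization")
  logm <- log(m[keep, , drop = FALSE])
  log_geo <- rowMeans(logm)
  sf <- exp(apply(logm - log_geo, 2, stats::median))
  sf <- sf / exp(mean(log(sf)))
  stats::setNames(sf, colnames(m))
}

#' Method-of-moments NB dispersion with decile shrinkage
#'
#' Gene-wise estimate on size-factor-normalized counts pooled within
#' groups: `alpha = max(0, (s2 - mu) / mu^2)` with `s2` the pooled
#' within-group sample variance and `mu` the overall normalized mean; genes
#' with `mu = 0` get 0.  With `shrink = TRUE` (default) the raw estimate is
#' averaged 50/50 with the mean raw estimate of the gene's expression
#' decile and then floored at that decile mean — a documented simple
#' surrogate for trend-based shrinkage, needed because two replicates per
#' group make raw moments unstable.  The floor exists because with so few
#' residual degrees of freedom the gene-wise moment estimate is mostly
#' noise, and genes whose dispersion it understates are exactly the genes
#' whose Wald statistics get inflated: letting gene-wise evidence raise a
#' gene above its expression-stratum trend but never lower it below keeps
#' the null test calibrated while preserving robustness to genuinely
#' overdispersed genes.
#'
#' @param counts a [count_matrix()].
#' @param groups factor/character vector of group labels, one per sample.
#' @param sf size factors from [size_factors()].
#' @param shrink average with expression-decile means (logical).
#' @return named numeric vector of per-gene dispersions (>= 0).
#' @export
estimate_dispersion <- function(counts, groups, sf = size_factors(counts),
                                shrink = TRUE) {
  m <- unclass(counts)
  if (ncol(m) < 2) stop("estimate_dispersion: need >= 2 samples")
  if (length(groups) != ncol(m))
    stop("estimate_dispersion: groups must match samples")
  groups <- as.factor(groups)
  y <- sweep(m, 2, sf, "/")
  mu <- rowMeans(y)
  # pooled within-group variance, n - G denominator
  ss <- 0
  df <- ncol(m) - nlevels(droplevels(groups))
  for (g in levels(droplevels(groups))) {
    yg <- y[, groups == g, drop = FALSE]
    ss <- ss + rowSums((yg - rowMeans(yg))^2)
  }
  s2 <- if (df > 0) ss / df else rep(0, nrow(m))
  raw <- ifelse(mu > 0, pmax(0, (s2 - mu) / mu^2), 0)
  if (!shrink) return(stats::setNames(raw, rownames(m)))
  n_bins <- min(10L, nrow(m))
  dec <- ceiling(rank(mu, ties.method = "first") / nrow(m) * n_bins)
  trend <- as.numeric(tapply(raw, dec, mean)[dec])
  alpha <- pmax(0.5 * raw + 0.5 * trend, trend)
  stats::setNames(alpha, rownames(m))
}

# NB GLM by IRLS: log mu = b0 + b1 x + log s, Fisher weights mu/(1+alpha mu).
# Returns coefficients, standard errors (expected information) and a
# convergence flag; exact Poisson GLM when alpha = 0.
nb_irls <- function(y, x, sf, alpha, max_iter = 50, tol = 1e-10) {
  off <- log(sf)
  X <- cbind(1, x)
  eps <- 0.5
  m1 <- (sum(y[x == 1]) + eps) / sum(sf[x == 1])
  m0 <- (sum(y[x == 0]) + eps) / sum(sf[x == 0])
  beta <- c(log(m0), log(m1 / m0))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta) + off
    mu <- exp(eta)
    w <- mu / (1 + alpha * mu)
    z <- (eta - off) + (y - mu) / mu
    XtW <- t(X * w)
    fit <- tryCatch(solve(XtW %*% X, XtW %*% z), error = function(e) NULL)
    if (is.null(fit) || any(!is.finite(fit))) break
    delta <- max(abs(fit - beta))
    beta <- drop(fit)
    if (delta < tol) { converged <- TRUE; break }
  }
  eta <- drop(X %*% beta) + off
  mu <- exp(eta)
  w <- mu / (1 + alpha * mu)
  info <- t(X * w) %*% X
  se <- tryCatch(sqrt(diag(solve(info))), error = function(e) rep(NA_real_, 2))
  list(beta = beta, se = se, converged = converged)
}

# closed-form two-group ratio estimate with +0.5 continuity on both group
# totals; used when one group is all zero (D5) or IRLS fails (D4)
nb_ratio_fallback <- function(y, x, sf, alpha) {
  k1 <- sum(y[x == 1]); k0 <- sum(y[x == 0])
  s1 <- sum(sf[x == 1]); s0 <- sum(sf[x == 0])
  m1 <- (k1 + 0.5) / s1
  m0 <- (k0 + 0.5) / s0
  b1 <- log(m1 / m0)
  # delta method on log of NB-summed totals
  v1 <- sum(sf[x == 1] * m1 + alpha * (sf[x == 1] * m1)^2)
  v0 <- sum(sf[x == 0] * m0 + alpha * (sf[x == 0] * m0)^2)
  se <- sqrt(v1 / (k1 + 0.5)^2 + v0 / (k0 + 0.5)^2)
  list(beta = c(log(m0), b1), se = c(NA_real_, se))
}

#' Two-group negative-binomial Wald test
#'
#' Per gene, an NB GLM with log link, design = group indicator plus
#' log-size-factor offset, gene-wise dispersion held fixed.  The reported
#' `log2fc` is the group coefficient in log2 units (numerator = second
#' level of `groups`, i.e. IP over INPUT or KO over WT by contract), `se`
#' its standard error from the expected Fisher information, `wald_stat =
#' log2fc / se`, and `p_value` the two-sided normal tail.  Genes whose
#' total count over the contrast is below `min_total_count` are excluded
#' from the universe (they come back as "missing", never as "not
#' enriched").  A group that is all zero gets a +0.5 continuity correction
#' on both group totals and is flagged; non-convergent fits fall back to
#' the closed-form ratio estimate and are flagged, never dropped silently.
#'
#' @param counts a [count_matrix()].
#' @param groups two-level factor (or character) per sample; the second
#'   level is the numerator of the fold change.
#' @param sf size factors.
#' @param dispersion per-gene dispersion vector (see
#'   [estimate_dispersion()]).
#' @param min_total_count low-count filter threshold (total across the
#'   contrast's samples).
#' @return data.frame of class `enrichment_result`: gene, base_mean,
#'   log2fc, se, wald_stat, p_value, n_eff, flag.
#' @export
nb_wald_test <- function(counts, groups, sf = size_factors(counts),
                         dispersion = NULL, min_total_count = 10) {
  m <- unclass(counts)
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) != 2)
    stop("nb_wald_test: groups must have exactly two levels")
  groups <- droplevels(groups)
  if (any(table(groups) == 0)) stop("nb_wald_test: both groups must be non-empty")
  if (is.null(dispersion))
    dispersion <- estimate_dispersion(counts, groups, sf)
  x <- as.integer(groups == levels(groups)[2])
  keep <- rowSums(m) >= min_total_count
  genes <- rownames(m)[keep]
  ln2 <- log(2)
  res <- lapply(genes, function(g) {
    y <- m[g, ]
    alpha <- unname(dispersion[g])
    base_mean <- mean(y / sf)
    flag <- ""
    zero_group <- sum(y[x == 1]) == 0 || sum(y[x == 0]) == 0
    if (zero_group) {
      fit <- nb_ratio_fallback(y, x, sf, alpha)
      flag <- "zero_group"
    } else {
      fit <- nb_irls(y, x, sf, alpha)
      if (!fit$converged) {
        fit <- nb_ratio_fallback(y, x, sf, alpha)
        flag <- "irls_fallback"
      }
    }
    b1 <- fit$beta[2]; se1 <- fit$se[2]
    if (!is.finite(b1) || !is.finite(se1) || se1 <= 0) {
      data.frame(gene = g, base_mean = base_mean, log2fc = 0, se = NA_real_,
                 wald_stat = 0, p_value = 1, n_eff = length(y),
                 flag = "degenerate", stringsAsFactors = FALSE)
    } else {
      z <- b1 / se1
      data.frame(gene = g, base_mean = base_mean, log2fc = b1 / ln2,
                 se = se1 / ln2, wald_stat = z,
                 p_value = 2 * stats::pnorm(-abs(z)), n_eff = length(y),
                 flag = flag, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(gene = character(0), base_mean = numeric(0),
                      log2fc = numeric(0), se = numeric(0),
                      wald_stat = numeric(0), p_value = numeric(0),
                      n_eff = integer(0), flag = character(0))
  class(out) <- c("enrichment_result", class(out))
  attr(out, "numerator") <- levels(groups)[2]
  attr(out, "denominator") <- levels(groups)[1]
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard step-up FDR adjustment: monotone, capped at 1.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values in the input order.
#' @export
benjamini_hochberg <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("benjamini_hochberg: p-values must be in [0, 1]")
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  adj <- pmin(1, cummin(n / (n:1) * p[o]))[ro]
  adj
}
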