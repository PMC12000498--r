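#' Fit first-order mRNA decay to a transcription-arrest time course
#'
#' Under first-order decay dC/dt = -k C, relative abundance obeys
#' ln(C/C0) = -k t; `decay_fit` estimates k by least squares of ln(C/C0)
#' on t.  With `intercept = "fixed_zero"` (default) the line is forced
#' through the origin, since C0 is the t = 0 normalizer; a free intercept
#' is available for robustness to a constant pipetting offset.  Replicate
#' measurements at the same time point are averaged on the log scale
#' (multiplicative noise model) before fitting.  A negative estimated
#' decay rate (apparent growth) is clamped to k = 0 and flagged rather
#' than reported as a negative half-life.  The half-life is t1/2 = ln2 / k
#' (infinite, flagged `stable`, at k = 0).
#'
#' @param times numeric vector of times in hours (must include 0 if any
#'   `rel_abundance` is interpreted as C/C0; only t > 0 points inform the
#'   fixed-zero slope).
#' @param rel_abundance relative abundance C/C0 at each time (> 0).
#' @param intercept `"fixed_zero"` or `"free"`.
#' @return object of class `decay_fit`: list with `k_decay` (per hour),
#'   `t_half` (hours), `r_squared`, `n_points`, `intercept`, `flag`.
#' @export
decay_fit <- function(times, rel_abundance,
                      intercept = c("fixed_zero", "free")) {
  intercept <- match.arg(intercept)
  if (length(times) != length(rel_abundance))
    stop("decay_fit: times and rel_abundance must have equal length")
  if (any(rel_abundance <= 0))
    stop("decay_fit: relative abundance must be positive (log model)")
  if (all(times == 0)) stop("decay_fit: all time points are zero")
  # replicate rows at one time: average on the log scale (D: multiplicative noise)
  y_all <- tapply(log(rel_abundance), times, mean)
  t_u <- as.numeric(names(y_all))
  y <- as.numeric(y_all)
  n_pos <- sum(t_u > 0)
  if (intercept == "fixed_zero") {
    if (n_pos < 2) stop("decay_fit: fixed_zero needs >= 2 time points with t > 0")
    slope <- sum(t_u * y) / sum(t_u^2)
    fitted <- slope * t_u
    ss_tot <- sum(y^2)                       # uncentered, through-origin model
  } else {
    if (length(t_u) < 3) stop("decay_fit: free intercept needs >= 3 time points")
    fit <- stats::lm.fit(cbind(1, t_u), y)
    slope <- fit$coefficients[2]
    fitted <- cbind(1, t_u) %*% fit$coefficients
    ss_tot <- sum((y - mean(y))^2)
  }
  ss_res <- sum((y - fitted)^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  flag <- ""
  k <- -slope
  if (k < 0) { k <- 0; flag <- "clamped_growth" }
  t_half <- if (k > 0) log(2) / k else Inf
  if (k == 0) flag <- paste0(flag, if (nzchar(flag)) ";" else "", "stable")
  structure(list(k_decay = unname(k), t_half = unname(t_half),
                 r_squared = unname(r2), n_points = length(t_u),
                 intercept = intercept, flag = flag),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("decay_fit: k = %.4g /h, t1/2 = %.4g h, r^2 = %.4f (%s)\n",
              x$k_decay, x$t_half, x$r_squared,
              if (nzchar(x$flag)) x$flag else "ok"))
  invisible(x)
}

#' Half-life from a first-order decay constant
#'
#' t1/2 = ln2 / k; infinite (stable transcript) at k = 0.
#'
#' @param k_decay decay constant in per hour (>= 0).
#' @return half-life in hours.
#' @export
half_life <- function(k_decay) {
  if (any(k_decay < 0)) stop("half_life: k_decay must be >= 0")
  ifelse(k_decay > 0, log(2) / k_decay, Inf)
}

#' Fit decay curves for many genes from a long table
#'
#' @param df data.frame with columns gene, time_h, rel_abundance
#'   (replicate rows allowed).
#' @param intercept passed to [decay_fit()].
#' @return data.frame gene, k_decay, t_half, r_squared, n_points, flag.
#' @export
decay_fit_table <- function(df, intercept = "fixed_zero") {
  req <- c("gene", "time_h", "rel_abundance")
  if (!all(req %in% names(df)))
    stop("decay_fit_table: need columns ", paste(req, collapse = ", "))
  out <- lapply(split(df, df$gene), function(sub) {
    fit <- decay_fit(sub$time_h, sub$rel_abundance, intercept)
    data.frame(gene = sub$gene[1], k_decay = fit$k_decay,
               t_half = fit$t_half, r_squared = fit$r_squared,
               n_points = fit$n_points, flag = fit$flag,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$gene), ]
}

#' Delta-delta-Ct quantification
#'
#' MeRIP/RT-qPCR relative quantification against a reference gene and the
#' non-immunoprecipitated input: ddCt = (Ct_target_IP - Ct_ref_IP) -
#' (Ct_target_input - Ct_ref_input); fold = 2^(-ddCt).  For expression
#' qPCR, substitute treated/control for IP/input.
#'
#' @param ct_target_ip,ct_target_input,ct_ref_ip,ct_ref_input finite
#'   cycle-threshold values (vectors recycle).
#' @param normalizer free-text description of the reference, recorded in
#'   the result.
#' @return data.frame delta_delta_ct, fold, normalizer.
#' @export
ddct_quantify <- function(ct_target_ip, ct_target_input, ct_ref_ip,
                          ct_ref_input, normalizer = "input") {
  cts <- c(ct_target_ip, ct_target_input, ct_ref_ip, ct_ref_input)
  if (any(!is.finite(cts))) stop("ddct_quantify: Ct values must be finite")
  ddct <- (ct_target_ip - ct_ref_ip) - (ct_target_input - ct_ref_input)
  data.frame(delta_delta_ct = ddct, fold = 2^(-ddct),
             normalizer = normalizer, stringsAsFactors = FALSE)
}
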