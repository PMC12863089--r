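# RT-qPCR quantification: standard-curve efficiency estimation, Pfaffl
# relative expression with single or geometric-mean multi-reference
# normalization, technical-replicate handling, group comparison with a
# Shapiro-Wilk normality gate, and standard-curve absolute transcript
# proxies.

#' Fit a qPCR standard curve
#'
#' Ordinary least squares of Ct on log10 template quantity over a
#' dilution series. The amplification efficiency is `E = 10^(-1/slope)`;
#' the ideal `E = 2` corresponds to a slope of -3.3219 cycles per decade.
#' A QC warning (never an error) is raised when `E` falls outside
#' (1.8, 2.1) or r-squared drops below 0.98.
#'
#' @param log10_quantity Numeric vector of log10 relative template
#'   quantities (at least 3 distinct values).
#' @param ct Numeric vector of Ct values, parallel to `log10_quantity`.
#' @param gene Gene name carried along for reporting.
#' @return A list of class `standard_curve`: `gene`, `slope`,
#'   `intercept`, `r_squared`, `efficiency`, `n_points`.
#' @export
fit_standard_curve <- function(log10_quantity, ct, gene = "") {
  stopifnot(length(log10_quantity) == length(ct))
  if (length(unique(log10_quantity)) < 3L) {
    stop("standard curve needs >= 3 distinct dilution points", call. = FALSE)
  }
  if (stats::var(log10_quantity) == 0) {
    stop("zero variance in template quantities", call. = FALSE)
  }
  fit <- stats::lm(ct ~ log10_quantity)
  m <- unname(stats::coef(fit)[2L])
  b <- unname(stats::coef(fit)[1L])
  ss_tot <- sum((ct - mean(ct))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - sum(stats::residuals(fit)^2) / ss_tot
  eff <- if (m < 0) 10^(-1 / m) else NA_real_
  if (m >= 0) {
    warning("standard curve for '", gene, "' has non-negative slope; ",
            "efficiency undefined", call. = FALSE)
  } else if (eff < 1.8 || eff > 2.1) {
    warning(sprintf("amplification efficiency %.3f for '%s' outside (1.8, 2.1)",
                    eff, gene), call. = FALSE)
  }
  if (r2 < 0.98) {
    warning(sprintf("standard curve r^2 = %.4f for '%s' below 0.98",
                    r2, gene), call. = FALSE)
  }
  structure(list(gene = gene, slope = m, intercept = b, r_squared = r2,
                 efficiency = eff, n_points = length(ct)),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("Standard curve [%s]: Ct = %.4f %+.4f * log10(q), r^2 = %.4f, E = %.4f\n",
              x$gene, x$intercept, x$slope, x$r_squared, x$efficiency))
  invisible(x)
}

#' Average technical replicates
#'
#' Collapses a long-format Ct table to one arithmetic-mean Ct per
#' (gene, condition[, phase], biological replicate). A warning is raised
#' when technical replicates of one biological replicate diverge by more
#' than 0.5 cycles.
#'
#' @param ct_data `data.frame` with columns `gene`, `condition`,
#'   `bio_rep`, `tech_rep`, `ct`, and optionally `phase`.
#' @param divergence_warn Cycle range above which a divergence warning is
#'   emitted (default 0.5).
#' @return `data.frame` keyed by the grouping columns with mean `ct` and
#'   `n_tech`.
#' @export
collapse_technical <- function(ct_data, divergence_warn = 0.5) {
  keys <- intersect(c("gene", "condition", "phase", "bio_rep"),
                    names(ct_data))
  stopifnot(all(c("gene", "condition", "bio_rep", "ct") %in% names(ct_data)))
  f <- interaction(ct_data[keys], drop = TRUE, lex.order = TRUE)
  agg <- do.call(rbind, lapply(split(ct_data, f), function(g) {
    rng <- diff(range(g$ct))
    if (rng > divergence_warn) {
      warning(sprintf("technical replicates diverge by %.2f cycles for %s/%s bio %s",
                      rng, g$gene[1L], g$condition[1L], g$bio_rep[1L]),
              call. = FALSE)
    }
    out <- g[1L, keys, drop = FALSE]
    out$ct <- mean(g$ct)
    out$n_tech <- nrow(g)
    out
  }))
  rownames(agg) <- NULL
  agg
}

#' Reference-gene normalization factor
#'
#' A single reference gene contributes its relative quantity unchanged;
#' multiple reference genes are combined by geometric mean (geNorm-style).
#'
#' @param ref_quantities Named numeric vector of per-reference relative
#'   quantities (all positive).
#' @return The normalization factor.
#' @export
reference_normalization_factor <- function(ref_quantities) {
  q <- as.numeric(ref_quantities)
  if (length(q) == 0L) stop("no reference quantities", call. = FALSE)
  if (any(!is.finite(q)) || any(q <= 0)) {
    stop("reference quantities must be positive", call. = FALSE)
  }
  exp(mean(log(q)))
}

curve_efficiency <- function(curves, gene) {
  cv <- curves[[gene]]
  if (is.null(cv)) stop("no efficiency available for gene '", gene, "'",
                        call. = FALSE)
  e <- if (inherits(cv, "standard_curve")) cv$efficiency else as.numeric(cv)
  if (!is.finite(e) || e <= 1) {
    stop("invalid amplification efficiency for gene '", gene, "'",
         call. = FALSE)
  }
  e
}

#' Pfaffl relative expression ratio
#'
#' Efficiency-corrected relative expression of a target gene between two
#' conditions: `R = E_target^dCt_target / NF`, where
#' `dCt = mean Ct(control) - mean Ct(sample)` and `NF` is the geometric
#' mean over reference genes of `E_ref^dCt_ref`. With a single reference
#' this reduces to the classical Pfaffl ratio; with all efficiencies
#' exactly 2 it reduces to `2^ddCt`.
#'
#' Per-biological-replicate ratios (for the spread) pair each sample
#' biological replicate against the control-condition mean; the reported
#' `ratio_sd` is their standard deviation. The p-value comes from an
#' unpaired t-test on per-replicate reference-normalized Ct values via
#' [compare_conditions()].
#'
#' @param ct_data Long-format Ct table (`gene`, `condition`, `bio_rep`,
#'   `tech_rep`, `ct`; technical replicates are averaged internally).
#' @param gene Target gene name.
#' @param reference_genes Character vector of reference gene names.
#' @param curves Named list mapping gene to a `standard_curve` or a bare
#'   numeric efficiency.
#' @param control,sample Condition labels; `control` is the calibrator.
#' @return A list of class `expression_comparison`: `gene`, `control`,
#'   `sample`, `ratio`, `ratio_sd`, `per_replicate`, `p_value`,
#'   `normality_ok`, `references_used`.
#' @export
pfaffl_ratio <- function(ct_data, gene, reference_genes, curves,
                         control, sample) {
  stopifnot(length(reference_genes) >= 1L)
  tech <- collapse_technical(ct_data)
  grab <- function(g, cond) {
    v <- tech$ct[tech$gene == g & tech$condition == cond]
    if (length(v) == 0L) {
      stop("no Ct measurements for gene '", g, "' in condition '", cond,
           "'", call. = FALSE)
    }
    v[order(tech$bio_rep[tech$gene == g & tech$condition == cond])]
  }
  e_t <- curve_efficiency(curves, gene)
  t_ctrl <- grab(gene, control)
  t_samp <- grab(gene, sample)
  ref_dat <- lapply(reference_genes, function(r) {
    list(e = curve_efficiency(curves, r),
         ctrl = grab(r, control), samp = grab(r, sample))
  })
  # point estimate from condition means
  dct_t <- mean(t_ctrl) - mean(t_samp)
  nf <- reference_normalization_factor(vapply(ref_dat, function(r) {
    r$e^(mean(r$ctrl) - mean(r$samp))
  }, numeric(1)))
  ratio <- e_t^dct_t / nf
  # per-sample-bio-replicate ratios against the control mean
  nb <- length(t_samp)
  per_rep <- vapply(seq_len(nb), function(b) {
    num <- e_t^(mean(t_ctrl) - t_samp[b])
    den <- reference_normalization_factor(vapply(ref_dat, function(r) {
      sb <- if (length(r$samp) >= b) r$samp[b] else mean(r$samp)
      r$e^(mean(r$ctrl) - sb)
    }, numeric(1)))
    num / den
  }, numeric(1))
  ratio_sd <- if (nb > 1L) stats::sd(per_rep) else NA_real_
  # group test on reference-normalized Ct values
  norm_ct <- function(target, refs) {
    ref_mean <- rowMeans(do.call(cbind, refs))
    target - ref_mean
  }
  cmp <- tryCatch(
    compare_conditions(norm_ct(t_ctrl, lapply(ref_dat, `[[`, "ctrl")),
                       norm_ct(t_samp, lapply(ref_dat, `[[`, "samp"))),
    error = function(e) list(p_value = NA_real_,
                             normality_ok = c(a = NA, b = NA)))
  structure(list(gene = gene, control = control, sample = sample,
                 ratio = ratio, ratio_sd = ratio_sd,
                 per_replicate = per_rep, p_value = cmp$p_value,
                 normality_ok = cmp$normality_ok,
                 references_used = reference_genes),
            class = "expression_comparison")
}

#' @export
print.expression_comparison <- function(x, ...) {
  cat(sprintf("Pfaffl ratio [%s] %s vs %s: R = %.3f (sd %.3f), p = %.4g\n",
              x$gene, x$sample, x$control, x$ratio, x$ratio_sd, x$p_value))
  invisible(x)
}

#' Absolute template quantity from a standard curve
#'
#' Inverts the standard curve: `Q = 10^((ct - intercept)/slope)`. The
#' result is a relative template quantity on the dilution-series scale —
#' a proxy for transcript level that is comparable across genes when all
#' curves share a quantity unit. Strictly decreasing in Ct for valid
#' (negative-slope) curves.
#'
#' @param ct Numeric vector of Ct values.
#' @param curve A `standard_curve`.
#' @return Numeric vector of quantities.
#' @export
absolute_quantity <- function(ct, curve) {
  stopifnot(inherits(curve, "standard_curve"))
  if (!is.finite(curve$slope) || curve$slope >= 0) {
    stop("standard curve slope must be negative", call. = FALSE)
  }
  10^((ct - curve$intercept) / curve$slope)
}

#' Compare two measurement groups
#'
#' Two-sided unpaired equal-variance (pooled) Student's t-test, with a
#' per-group Shapiro-Wilk normality check. A normality failure
#' (p < 0.05) sets the group's flag to `FALSE` and logs a warning but
#' does not block the t-test. Degenerate zero-variance groups are
#' handled explicitly: identical groups give p = 1, separated constant
#' groups give p = 0.
#'
#' @param group_a,group_b Numeric vectors (at least 2 values each).
#' @param welch Use Welch's unequal-variance t-test instead (default
#'   `FALSE`).
#' @return A list: `p_value`, `t`, `df`, `normality_ok` (named logical,
#'   `NA` when a group is too small or constant for the test).
#' @export
compare_conditions <- function(group_a, group_b, welch = FALSE) {
  na <- length(group_a); nb <- length(group_b)
  if (na < 2L || nb < 2L) {
    stop("each group needs >= 2 biological replicates", call. = FALSE)
  }
  shapiro_flag <- function(x, label) {
    if (length(x) < 3L || stats::sd(x) == 0) return(NA)
    p <- stats::shapiro.test(x)$p.value
    if (p < 0.05) {
      warning("Shapiro-Wilk normality check failed for group ", label,
              sprintf(" (p = %.3g)", p), call. = FALSE)
      FALSE
    } else TRUE
  }
  norm_ok <- c(a = shapiro_flag(group_a, "a"), b = shapiro_flag(group_b, "b"))
  va <- stats::var(group_a); vb <- stats::var(group_b)
  if (va == 0 && vb == 0) {
    if (mean(group_a) == mean(group_b)) {
      return(list(p_value = 1, t = 0, df = na + nb - 2,
                  normality_ok = norm_ok))
    }
    return(list(p_value = 0, t = Inf, df = na + nb - 2,
                normality_ok = norm_ok))
  }
  if (welch) {
    se2a <- va / na; se2b <- vb / nb
    tstat <- (mean(group_a) - mean(group_b)) / sqrt(se2a + se2b)
    df <- (se2a + se2b)^2 /
      (se2a^2 / (na - 1) + se2b^2 / (nb - 1))
  } else {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    tstat <- (mean(group_a) - mean(group_b)) / sqrt(sp2 * (1/na + 1/nb))
    df <- na + nb - 2
  }
  p <- 2 * stats::pt(-abs(tstat), df)
  list(p_value = p, t = tstat, df = df, normality_ok = norm_ok)
}
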