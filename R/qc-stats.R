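# Normalization, replicate statistics, Welch tests, Sidak-adjusted
# significance and Z'-factor quality control.

#' Test parameters for the screen
#'
#' Bundles the nominal significance level, the number of independent
#' comparisons (93 test compounds plus the two non-DMSO controls on a
#' standard rack, i.e. m = 95), the Sidak-adjusted level derived from
#' them, the OD600 growth-failure floor, and the t-test variant.
#'
#' @param alpha nominal family significance level (default 0.05).
#' @param m number of independent tests (default 95; recomputed from the
#'   manifest by [run_screen()] when the rack differs).
#' @param od_floor OD600 below which a well is treated as a growth
#'   failure and excluded from ratio statistics (default 0.05
#'   absorbance units).
#' @param t_variant `"pooled"` (Student's equal-variance test, default)
#'   or `"welch"`.  With quadruplicate wells the pooled test holds its
#'   nominal size at the heavily Sidak-adjusted level, where the Welch
#'   approximation is markedly conservative.
#' @return object of class `test_params` with element `alpha_adj`.
#' @export
test_params <- function(alpha = 0.05, m = 95L, od_floor = 0.05,
                        t_variant = c("pooled", "welch")) {
  t_variant <- match.arg(t_variant)
  if (od_floor < 0) stop("od_floor must be non-negative")
  structure(list(alpha = alpha, m = as.integer(m),
                 alpha_adj = sidak_alpha(alpha, m),
                 od_floor = od_floor, t_variant = t_variant),
            class = "test_params")
}

#' @export
print.test_params <- function(x, ...) {
  cat("Screen test parameters\n")
  cat(sprintf("  alpha = %g over m = %d tests -> alpha_adj = %.3g (Sidak)\n",
              x$alpha, x$m, x$alpha_adj))
  cat(sprintf("  OD600 growth floor = %g; t-test variant = %s\n",
              x$od_floor, x$t_variant))
  invisible(x)
}

#' Sidak-adjusted per-test significance level
#'
#' `alpha_adj = 1 - (1 - alpha)^(1/m)`, the per-comparison level that
#' keeps the family-wise error at `alpha` over `m` independent tests.
#' At the screen's defaults (alpha 0.05, m 95) this is 5.40e-4.
#'
#' @param alpha family-wise significance level in (0, 1).
#' @param m number of tests (>= 1).
#' @return adjusted per-test level.
#' @export
sidak_alpha <- function(alpha, m) {
  if (!is.numeric(alpha) || any(alpha <= 0) || any(alpha >= 1)) {
    stop("alpha must lie strictly between 0 and 1")
  }
  if (any(m < 1)) stop("m must be >= 1")
  # -expm1(log1p(-alpha)/m), written via log/expm1 for small-alpha accuracy
  -expm1(log1p(-alpha) / m)
}

#' Fluorescence-to-density ratio of a well
#'
#' The assay's response measure: end-point fluorescence divided by
#' culture density, RFU per OD600 unit.  Wells whose OD600 does not
#' exceed the growth-failure floor carry no interpretable ratio and
#' raise a `cytoscreen_growth_failure` error; the pipeline excludes such
#' wells and routes fully failed compounds to `indeterminate_growth`.
#'
#' @param rfu non-negative end-point fluorescence.
#' @param od positive OD600.
#' @param od_floor growth-failure floor (default 0.05).
#' @return `rfu / od` (vectorized).
#' @export
rfu_od_ratio <- function(rfu, od, od_floor = 0.05) {
  if (any(rfu < 0, na.rm = TRUE)) stop("rfu must be non-negative")
  if (any(od <= od_floor, na.rm = TRUE)) {
    stop(structure(class = c("cytoscreen_growth_failure", "error", "condition"),
                   list(message = paste0("OD600 at or below the growth floor (",
                                         od_floor, "): growth failure"),
                        call = sys.call(-1))))
  }
  rfu / od
}

#' Mean, sample SD and count of replicate values
#'
#' @param values numeric vector, length >= 2, finite.
#' @return list with `mean`, `sd` (n-1 denominator), `n`.
#' @export
replicate_summary <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L) {
    stop("at least 2 replicate values are required")
  }
  if (!all(is.finite(values))) stop("replicate values must be finite")
  list(mean = mean(values), sd = stats::sd(values), n = length(values))
}

# Vectorized Welch / pooled two-sample t machinery working from group
# summaries; the scalar welch_t_test() wraps it and adds the degenerate
# conventions.  Used directly by run_screen so that thousand-plate
# simulations stay fast.
t_test_stats <- function(m1, v1, n1, m2, v2, n2, pooled = FALSE) {
  if (pooled) {
    df <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
    se2 <- sp2 * (1 / n1 + 1 / n2)
  } else {
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  t <- (m1 - m2) / sqrt(se2)
  degenerate <- !is.na(se2) & se2 == 0
  if (any(degenerate)) {
    eq <- degenerate & (m1 == m2)
    t[eq] <- 0
    t[degenerate & !eq] <- sign(m1 - m2)[degenerate & !eq] * Inf
    df[degenerate] <- NA_real_
  }
  p <- ifelse(degenerate, ifelse(t == 0, 1, 0),
              2 * stats::pt(-abs(t), df))
  p[is.na(se2)] <- NA_real_
  list(t = t, df = df, p = p, degenerate = degenerate)
}

#' Two-sample t-test on replicate groups
#'
#' Welch's unequal-variance statistic with Welch-Satterthwaite degrees of
#' freedom and a two-sided p-value (the pooled Student variant is
#' selectable).  Degenerate groups follow fixed conventions: both
#' variances zero with equal means gives p = 1; with unequal means p = 0,
#' flagged as degenerate.
#'
#' @param a,b numeric vectors, each of length >= 2 with finite values.
#' @param var_equal use the pooled-variance statistic (default FALSE).
#' @return list with `statistic`, `df`, `p_value`, `degenerate`.
#' @export
welch_t_test <- function(a, b, var_equal = FALSE) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L) {
    stop("each group needs at least 2 values")
  }
  if (!all(is.finite(a)) || !all(is.finite(b))) {
    stop("group values must be finite")
  }
  s <- t_test_stats(mean(a), stats::var(a), length(a),
                    mean(b), stats::var(b), length(b),
                    pooled = var_equal)
  list(statistic = s$t, df = s$df, p_value = s$p, degenerate = s$degenerate)
}

#' Z'-factor separating two control populations
#'
#' `1 - 3 (sd_p + sd_n) / |mu_p - mu_n|`.  Values near 1 indicate wide
#' separation between the control bands; the statistic never exceeds 1.
#'
#' @param mu_p,sd_p mean and SD of one control population.
#' @param mu_n,sd_n mean and SD of the other.
#' @return the Z'-factor (full precision; conventionally reported to two
#'   decimals).
#' @export
z_prime_factor <- function(mu_p, sd_p, mu_n, sd_n) {
  if (any(sd_p < 0) || any(sd_n < 0)) stop("SDs must be non-negative")
  if (any(mu_p == mu_n)) {
    stop("Z'-factor undefined: control means coincide")
  }
  1 - 3 * (sd_p + sd_n) / abs(mu_p - mu_n)
}

#' Control summary and Z' quality control for one plate
#'
#' Summarizes the RFU/OD600 responses of the three control groups --
#' internal standard (DMSO wells, 50 nM tZ only), positive control
#' (50 uM tZ) and negative control (receptor antagonist) -- and computes
#' the two Z'-factors: positive vs internal standard, and internal
#' standard vs negative.
#'
#' @param ratios named list with numeric elements `neutral_control`,
#'   `positive_control`, `negative_control` (each >= 2 usable wells).
#' @return object of class `control_summary` with elements `mu_is`,
#'   `sd_is`, `n_is`, `mu_pos`, `sd_pos`, `n_pos`, `mu_neg`, `sd_neg`,
#'   `n_neg`, `z_prime_pos`, `z_prime_neg`.
#' @export
control_summary <- function(ratios) {
  for (ctrl in CONTROL_ROLES) {
    if (is.null(ratios[[ctrl]]) || length(ratios[[ctrl]]) < 2L) {
      stop("control role ", ctrl,
           " needs at least 2 usable wells (growth failure or missing wells?)")
    }
  }
  is_ <- replicate_summary(ratios$neutral_control)
  pos <- replicate_summary(ratios$positive_control)
  neg <- replicate_summary(ratios$negative_control)
  structure(list(
    mu_is = is_$mean, sd_is = is_$sd, n_is = is_$n,
    mu_pos = pos$mean, sd_pos = pos$sd, n_pos = pos$n,
    mu_neg = neg$mean, sd_neg = neg$sd, n_neg = neg$n,
    z_prime_pos = z_prime_factor(pos$mean, pos$sd, is_$mean, is_$sd),
    z_prime_neg = z_prime_factor(is_$mean, is_$sd, neg$mean, neg$sd)
  ), class = "control_summary")
}

#' @export
print.control_summary <- function(x, ...) {
  cat("Plate controls (RFU/OD600)\n")
  cat(sprintf("  internal standard: %8.0f +/- %5.0f (n=%d)\n",
              x$mu_is, x$sd_is, x$n_is))
  cat(sprintf("  positive (tZ)    : %8.0f +/- %5.0f (n=%d)\n",
              x$mu_pos, x$sd_pos, x$n_pos))
  cat(sprintf("  negative         : %8.0f +/- %5.0f (n=%d)\n",
              x$mu_neg, x$sd_neg, x$n_neg))
  cat(sprintf("  Z' (pos vs IS) = %.2f; Z' (IS vs neg) = %.2f\n",
              x$z_prime_pos, x$z_prime_neg))
  invisible(x)
}

#' Growth-effect flags for one compound
#'
#' Compares the compound's OD600 replicates with the DMSO wells' OD600 at
#' the Sidak-adjusted level: a significant decrease flags
#' `growth_suppressed`, a significant increase `growth_promoted`.  When
#' every well sits at or below the OD floor the compound is a
#' `growth_failure` (no fluorescence can be read) and no suppression
#' test is attempted.
#'
#' @param od compound OD600 replicates.
#' @param dmso_od DMSO-well OD600 replicates.
#' @param params a [test_params()] object.
#' @return character vector, a subset of
#'   `c("growth_failure", "growth_suppressed", "growth_promoted")`.
#' @export
growth_flags <- function(od, dmso_od, params = test_params()) {
  od <- as.numeric(od)
  dmso_od <- as.numeric(dmso_od)
  if (all(od <= params$od_floor)) {
    return("growth_failure")
  }
  if (length(od) < 2L || length(dmso_od) < 2L) {
    return(character(0))
  }
  tt <- welch_t_test(od, dmso_od, var_equal = params$t_variant == "pooled")
  if (tt$p_value < params$alpha_adj) {
    if (mean(od) < mean(dmso_od)) return("growth_suppressed")
    return("growth_promoted")
  }
  character(0)
}
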