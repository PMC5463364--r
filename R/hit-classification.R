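# Five-class hit sorting anchored to the plate's own controls, and the
# full dual-plate screen pipeline.

HIT_CATEGORIES <- c("strong_agonist", "agonist", "neutral", "antagonist",
                    "strong_antagonist", "interference",
                    "indeterminate_growth")

#' Hit-defining response levels from the plate controls
#'
#' Strong agonists must respond at least mid-way between the internal
#' standard and the 50 uM tZ positive control; strong antagonists below
#' mid-way between the internal standard and the negative control.  Both
#' levels are arithmetic midpoints of the control mean responses on the
#' RFU/OD600 scale.
#'
#' @param controls a [control_summary()].
#' @return object of class `hit_thresholds` with
#'   `strong_agonist_level`, `strong_antagonist_level` and `mu_is`.
#'   Signals a `cytoscreen_qc_failure` error when the controls are not
#'   separated (positive below the internal standard, or negative above
#'   it): such a plate cannot anchor classification.
#' @export
hit_thresholds <- function(controls) {
  if (controls$mu_pos <= controls$mu_is || controls$mu_neg >= controls$mu_is) {
    stop(structure(
      class = c("cytoscreen_qc_failure", "error", "condition"),
      list(message = sprintf(
        paste0("plate QC failure: control responses not separated ",
               "(IS %.0f, pos %.0f, neg %.0f)"),
        controls$mu_is, controls$mu_pos, controls$mu_neg),
        call = sys.call(-1), controls = controls)))
  }
  structure(list(
    strong_agonist_level = (controls$mu_is + controls$mu_pos) / 2,
    strong_antagonist_level = (controls$mu_is + controls$mu_neg) / 2,
    mu_is = controls$mu_is
  ), class = "hit_thresholds")
}

#' Assign a compound to one of the screen's categories
#'
#' Precedence: (1) complete growth failure makes the receptor effect
#' unreadable (`indeterminate_growth`); (2) any fluorescence artifact
#' flag demotes to `interference`; (3) a response not significantly
#' different from the DMSO internal-standard baseline is `neutral`;
#' otherwise the mean RFU/OD600 ratio is placed against the control
#' anchors: at or above the strong-agonist level -> `strong_agonist`;
#' above the internal standard -> `agonist`; at or below the
#' strong-antagonist level -> `strong_antagonist`; otherwise
#' `antagonist`.
#'
#' @param mean_ratio compound mean RFU/OD600 response.
#' @param p_value two-sided p-value against the DMSO wells.
#' @param thresholds a [hit_thresholds()] object.
#' @param params a [test_params()] object (supplies `alpha_adj`).
#' @param interference any fluorescence artifact flag set?
#' @param growth_failure all wells below the OD floor (or fewer than two
#'   usable wells)?
#' @return one of `r paste0('\x60', HIT_CATEGORIES, '\x60', collapse = ", ")`.
#' @export
classify_compound <- function(mean_ratio, p_value, thresholds,
                              params = test_params(),
                              interference = FALSE,
                              growth_failure = FALSE) {
  if (isTRUE(growth_failure)) return("indeterminate_growth")
  if (isTRUE(interference)) return("interference")
  if (is.na(p_value) || p_value >= params$alpha_adj) return("neutral")
  if (mean_ratio >= thresholds$strong_agonist_level) return("strong_agonist")
  if (mean_ratio > thresholds$mu_is) return("agonist")
  if (mean_ratio <= thresholds$strong_antagonist_level) {
    return("strong_antagonist")
  }
  "antagonist"
}

#' Run the full dual-plate screen
#'
#' Normalizes the screening plate to RFU/OD600 ratios, summarizes the
#' controls and checks Z' quality, tests every non-DMSO compound against
#' the DMSO internal-standard wells at the Sidak-adjusted level, runs the
#' reference-plate artifact tests and growth flags, and sorts compounds
#' into the five response categories (plus `interference` and
#' `indeterminate_growth`).
#'
#' @param screening data.frame with columns `well`, `od600`, `rfu_end`
#'   (see [read_screening_plate()]).
#' @param reference data.frame with columns `well`, `rfu_pre_spike`,
#'   `rfu_post_spike` (see [read_reference_plate()]); both plates share
#'   the layout.
#' @param manifest rack manifest (see [read_rack_manifest()]).
#' @param params a [test_params()]; when `NULL`, `m` is derived from the
#'   manifest as the number of non-DMSO entries.
#' @param layout optional pre-built [assign_quadruplicate_layout()]
#'   result; must match the manifest.
#' @param scheme stamping scheme used when `layout` is `NULL`.
#' @return object of class `screen_result`: list with `controls`,
#'   `thresholds`, `params`, `results` (one row per non-DMSO compound)
#'   and `category_counts` (test compounds only).
#' @export
run_screen <- function(screening, reference, manifest, params = NULL,
                       layout = NULL, scheme = c("block2x2", "quadrant")) {
  manifest <- validate_rack(manifest)
  if (is.null(layout)) {
    layout <- assign_quadruplicate_layout(manifest, match.arg(scheme))
  } else if (!setequal(layout$compound_id, manifest$compound_id)) {
    stop("layout and manifest disagree on compound ids")
  }
  if (is.null(reference)) {
    stop("reference plate is required to exclude fluorescence artifacts")
  }
  if (is.null(params)) {
    params <- test_params(m = sum(manifest$role != "neutral_control"))
  }
  pooled <- params$t_variant == "pooled"

  si <- match(layout$well, screening$well)
  ri <- match(layout$well, reference$well)
  if (anyNA(si)) stop("screening plate lacks wells present in the layout")
  if (anyNA(ri)) stop("reference plate lacks wells present in the layout")
  od <- screening$od600[si]
  rfu <- screening$rfu_end[si]
  pre <- reference$rfu_pre_spike[ri]
  post <- reference$rfu_post_spike[ri]
  if (!all(is.finite(od)) || !all(is.finite(rfu)) ||
      !all(is.finite(pre)) || !all(is.finite(post))) {
    stop("non-finite measurements on the plates")
  }

  groups <- split(seq_len(nrow(layout)),
                  factor(layout$compound_id, levels = manifest$compound_id))
  usable <- od > params$od_floor
  ratio <- ifelse(usable, rfu / od, NA_real_)

  gstat <- function(values, keep = NULL) {
    t(vapply(groups, function(ix) {
      v <- values[ix]
      if (!is.null(keep)) v <- v[keep[ix]]
      if (length(v) < 2L) {
        return(c(mean = if (length(v)) mean(v) else NA_real_,
                 var = NA_real_, n = length(v)))
      }
      c(mean = mean(v), var = stats::var(v), n = length(v))
    }, c(mean = 0, var = 0, n = 0)))
  }
  ratio_s <- gstat(ratio, keep = usable)
  od_s <- gstat(od)
  pre_s <- gstat(pre)
  post_s <- gstat(post)

  dmso_id <- manifest$compound_id[manifest$role == "neutral_control"]
  pos_id <- manifest$compound_id[manifest$role == "positive_control"]
  neg_id <- manifest$compound_id[manifest$role == "negative_control"]
  dmso_ratio <- ratio[groups[[dmso_id]]]
  dmso_ratio <- dmso_ratio[!is.na(dmso_ratio)]
  if (length(dmso_ratio) < 2L) {
    stop("fewer than 2 usable DMSO wells: internal-standard baseline ",
         "cannot be estimated")
  }
  controls <- control_summary(list(
    neutral_control = dmso_ratio,
    positive_control = ratio[groups[[pos_id]]][!is.na(ratio[groups[[pos_id]]])],
    negative_control = ratio[groups[[neg_id]]][!is.na(ratio[groups[[neg_id]]])]
  ))
  thresholds <- hit_thresholds(controls)

  tested <- manifest$compound_id[manifest$role != "neutral_control"]
  ti <- match(tested, manifest$compound_id)
  dm <- controls$mu_is
  dv <- controls$sd_is^2
  dn <- controls$n_is

  main <- t_test_stats(ratio_s[ti, "mean"], ratio_s[ti, "var"],
                       ratio_s[ti, "n"], dm, dv, dn, pooled = pooled)
  dmso_ix <- groups[[dmso_id]]
  od_dmso <- od[dmso_ix]
  odt <- t_test_stats(od_s[ti, "mean"], od_s[ti, "var"], od_s[ti, "n"],
                      mean(od_dmso), stats::var(od_dmso), length(od_dmso),
                      pooled = pooled)
  pre_dmso <- pre[dmso_ix]
  post_dmso <- post[dmso_ix]
  pret <- t_test_stats(pre_s[ti, "mean"], pre_s[ti, "var"], pre_s[ti, "n"],
                       mean(pre_dmso), stats::var(pre_dmso), length(pre_dmso),
                       pooled = pooled)
  postt <- t_test_stats(post_s[ti, "mean"], post_s[ti, "var"],
                        post_s[ti, "n"], mean(post_dmso),
                        stats::var(post_dmso), length(post_dmso),
                        pooled = pooled)

  a <- params$alpha_adj
  autofluorescent <- pret$p < a & pre_s[ti, "mean"] > mean(pre_dmso)
  quencher <- postt$p < a & post_s[ti, "mean"] < mean(post_dmso)
  additive <- postt$p < a & post_s[ti, "mean"] > mean(post_dmso)
  interference <- autofluorescent | quencher | additive

  all_failed <- vapply(groups[ti], function(ix) all(!usable[ix]), logical(1))
  too_few <- ratio_s[ti, "n"] < 2L
  growth_fail <- all_failed | too_few
  growth_sup <- !growth_fail & odt$p < a & od_s[ti, "mean"] < mean(od_dmso)
  growth_pro <- !growth_fail & odt$p < a & od_s[ti, "mean"] > mean(od_dmso)

  p_value <- main$p
  p_value[growth_fail] <- NA_real_
  significant <- !is.na(p_value) & p_value < a

  n_t <- length(tested)
  category <- character(n_t)
  for (i in seq_len(n_t)) {
    category[i] <- classify_compound(ratio_s[ti[i], "mean"], p_value[i],
                                     thresholds, params,
                                     interference = interference[i],
                                     growth_failure = growth_fail[i])
  }
  secondary <- growth_sup & category %in% c("agonist", "strong_agonist")

  flags <- mapply(function(af, q, ad, gf, gs, gp, sm) {
    paste(c("autofluorescent"[af], "quencher"[q],
            "additive_interaction"[ad], "growth_failure"[gf],
            "growth_suppressed"[gs], "growth_promoted"[gp],
            "secondary_od_marker"[sm]), collapse = ";")
  }, autofluorescent, quencher, additive, growth_fail, growth_sup,
     growth_pro, secondary)

  results <- data.frame(
    compound_id = tested,
    rack_position = manifest$rack_position[ti],
    role = manifest$role[ti],
    n = as.integer(ratio_s[ti, "n"]),
    mean_ratio = ratio_s[ti, "mean"],
    sd_ratio = sqrt(ratio_s[ti, "var"]),
    mean_od = od_s[ti, "mean"],
    sd_od = sqrt(od_s[ti, "var"]),
    t_statistic = main$t,
    df = main$df,
    p_value = p_value,
    significant = significant,
    effect_size_pre = pre_s[ti, "mean"] / mean(pre_dmso),
    effect_size_post = post_s[ti, "mean"] / mean(post_dmso),
    autofluorescent = autofluorescent,
    quencher = quencher,
    additive_interaction = additive,
    interference = interference,
    growth_failure = growth_fail,
    growth_suppressed = growth_sup,
    growth_promoted = growth_pro,
    secondary_od_marker = secondary,
    category = category,
    flags = unname(flags),
    stringsAsFactors = FALSE,
    row.names = NULL
  )

  counts <- table(factor(category[results$role == "test"],
                         levels = HIT_CATEGORIES))
  structure(list(controls = controls, thresholds = thresholds,
                 params = params, results = results,
                 category_counts = counts),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  print(x$controls)
  cat(sprintf("Hit-defining levels: strong agonist >= %.1f, strong antagonist <= %.1f\n",
              x$thresholds$strong_agonist_level,
              x$thresholds$strong_antagonist_level))
  cat(sprintf("alpha_adj = %.3g (alpha %g, m %d)\n",
              x$params$alpha_adj, x$params$alpha, x$params$m))
  cat("Test-compound categories:\n")
  print(x$category_counts)
  invisible(x)
}
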