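# Hit validation against the live-cell radioligand competition assay:
# percent displacement of [3H]tZ from the receptor, normalized to the
# tracer-only control (0%) and the saturating 10 uM tZ reference (100%),
# plus a rank-trend test of dose-dependent competition.

#' Specific binding from total and non-specific counts
#'
#' `max(cpm_total - cpm_nonspecific, 0)`; a negative difference is
#' clamped to zero with a warning (the non-specific estimate exceeded
#' the total, which indicates an assay problem).
#'
#' @param cpm_total total bound counts per minute.
#' @param cpm_nonspecific counts in the presence of a large unlabeled
#'   excess.
#' @return specific counts (vectorized).
#' @export
specific_binding <- function(cpm_total, cpm_nonspecific) {
  if (any(cpm_total < 0) || any(cpm_nonspecific < 0)) {
    stop("counts must be non-negative")
  }
  d <- cpm_total - cpm_nonspecific
  if (any(d < 0)) {
    warning("negative specific binding clamped to 0")
  }
  pmax(d, 0)
}

#' Control anchors of the competition assay
#'
#' @param cpm_total mean tracer-only (DMSO) binding, the 0% anchor.
#' @param cpm_reference mean binding with the saturating reference
#'   competitor (10 uM tZ), the 100% anchor.
#' @return object of class `binding_controls`.
#' @export
binding_controls <- function(cpm_total, cpm_reference) {
  if (cpm_total <= cpm_reference) {
    stop("cpm_total must exceed cpm_reference for a working assay")
  }
  structure(list(cpm_total = cpm_total, cpm_reference = cpm_reference),
            class = "binding_controls")
}

#' Percent displacement of the tracer
#'
#' `100 * (cpm_total - cpm_compound) / (cpm_total - cpm_reference)`:
#' 0% at the tracer-only control, 100% at the saturating reference
#' competitor.  Values outside [0, 100] are reported unclamped so assay
#' problems stay visible.  Adding a constant background to every cpm
#' (controls included) leaves the result unchanged.
#'
#' @param cpm_compound bound counts in the compound's presence.
#' @param controls a [binding_controls()] object.
#' @return percent displacement (vectorized over `cpm_compound`).
#' @export
percent_displacement <- function(cpm_compound, controls) {
  span <- controls$cpm_total - controls$cpm_reference
  if (span == 0) stop("displacement undefined: control anchors coincide")
  100 * (controls$cpm_total - cpm_compound) / span
}

#' Test for dose-dependent competition
#'
#' One-sided Kendall rank correlation of percent displacement against
#' log10 competitor concentration (increasing), at level `alpha`.  When
#' the per-concentration mean displacements bracket 50%, the
#' half-displacement concentration is obtained by log-linear
#' interpolation between the bracketing concentrations.
#'
#' @param concentration competitor concentrations (> 0), at least 4
#'   distinct values spanning >= 2 orders of magnitude.
#' @param displacement percent displacement per measurement.
#' @param alpha significance level of the trend test (default 0.05).
#' @return list with `dose_dependent` (logical verdict), `p_value`,
#'   `tau`, and `half_displacement` (same unit as `concentration`;
#'   `NA` when 50% is not bracketed).
#' @export
dose_dependence_check <- function(concentration, displacement,
                                  alpha = 0.05) {
  if (length(concentration) != length(displacement)) {
    stop("concentration and displacement lengths differ")
  }
  if (any(concentration <= 0)) stop("concentrations must be positive")
  conc_levels <- sort(unique(concentration))
  if (length(conc_levels) < 4L) {
    stop("at least 4 distinct competitor concentrations are required")
  }
  if (max(conc_levels) / min(conc_levels) < 100) {
    stop("concentrations must span at least 2 orders of magnitude")
  }
  if (length(unique(displacement)) == 1L) {
    stop("all displacements equal: no trend can be assessed")
  }
  ct <- suppressWarnings(stats::cor.test(log10(concentration), displacement,
                                         method = "kendall",
                                         alternative = "greater"))
  means <- tapply(displacement, factor(concentration, levels = conc_levels),
                  mean)
  half <- NA_real_
  for (i in seq_len(length(conc_levels) - 1L)) {
    d1 <- means[[i]]; d2 <- means[[i + 1L]]
    if (d1 <= 50 && d2 >= 50 && d2 > d1) {
      lc <- log10(conc_levels[i]) +
        (50 - d1) / (d2 - d1) * (log10(conc_levels[i + 1L]) -
                                   log10(conc_levels[i]))
      half <- 10^lc
      break
    }
  }
  list(dose_dependent = ct$p.value < alpha,
       p_value = unname(ct$p.value),
       tau = unname(ct$estimate),
       half_displacement = half)
}

#' Read a competition-binding data file
#'
#' CSV with columns `compound_id`, `concentration_uM`, `cpm`,
#' `replicate`.  Rows with the reserved ids `TOTAL` (tracer-only/DMSO)
#' and `REF_TZ_10UM` (saturating 10 uM tZ) define the control anchors.
#'
#' @param path CSV file.
#' @return list with `controls` (a [binding_controls()]) and `series`
#'   (data.frame of test-compound rows).
#' @export
read_binding_data <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(tab) <- tolower(names(tab))
  needed <- c("compound_id", "concentration_um", "cpm")
  if (!all(needed %in% names(tab))) {
    stop("binding file needs columns compound_id, concentration_uM, cpm")
  }
  if (any(tab$cpm < 0)) stop("cpm must be non-negative")
  total <- tab$cpm[tab$compound_id == "TOTAL"]
  ref <- tab$cpm[tab$compound_id == "REF_TZ_10UM"]
  if (!length(total) || !length(ref)) {
    stop("binding file must contain TOTAL and REF_TZ_10UM control rows")
  }
  series <- tab[!tab$compound_id %in% c("TOTAL", "REF_TZ_10UM"), ]
  list(controls = binding_controls(mean(total), mean(ref)),
       series = series)
}

#' Validate hits by competition binding
#'
#' Normalizes each compound's series to percent displacement and runs
#' the dose-dependence check.
#'
#' @param binding list from [read_binding_data()], or a path to the CSV.
#' @param alpha trend-test level (default 0.05).
#' @return data.frame with one row per compound: `compound_id`,
#'   `n_concentrations`, `max_displacement`, `tau`, `p_value`,
#'   `dose_dependent`, `half_displacement_uM`.
#' @export
validate_binding <- function(binding, alpha = 0.05) {
  if (is.character(binding)) binding <- read_binding_data(binding)
  series <- binding$series
  out <- lapply(split(series, series$compound_id), function(d) {
    disp <- percent_displacement(d$cpm, binding$controls)
    res <- tryCatch(
      dose_dependence_check(d$concentration_um, disp, alpha = alpha),
      error = function(e) list(dose_dependent = NA, p_value = NA_real_,
                               tau = NA_real_, half_displacement = NA_real_))
    data.frame(compound_id = d$compound_id[1],
               n_concentrations = length(unique(d$concentration_um)),
               max_displacement = max(disp),
               tau = res$tau, p_value = res$p_value,
               dose_dependent = res$dose_dependent,
               half_displacement_uM = res$half_displacement,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  row.names(res) <- NULL
  res
}
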