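# Generative model of paired screening/reference plates with ground
# truth, calibrated to the assay's printed control statistics
# (internal standard 42,427 +/- 1,292; 50 uM tZ 125,728 +/- 3,235;
# antagonist control 898 +/- 143 RFU/OD600) so every pipeline stage is
# testable without instrument data.

TRUE_CLASSES <- c("neutral", "agonist", "strong_agonist", "antagonist",
                  "strong_antagonist", "growth_suppressor")

#' Parameters of the synthetic plate generator
#'
#' Control response means and coefficients of variation default to the
#' assay's printed run statistics (CVs 3.0%, 2.6% and 15.9%).  OD600 and
#' reference-plate magnitudes are free parameters of the model: a 5-h
#' 384-well culture baseline OD of 0.5 with 5% log-normal noise, a ~20%
#' OD drop under full receptor activation, a reference-plate background
#' of 1,000 RFU dominated 50:1 by the 4-MU spike, and a 2% technical CV
#' on reference-plate reads.
#'
#' @param mu_is,sd_is internal-standard (DMSO wells) response mean/SD.
#' @param mu_pos,sd_pos positive-control (50 uM tZ) response mean/SD.
#' @param mu_neg,sd_neg negative-control (antagonist) response mean/SD.
#' @param od_mean,od_cv baseline culture density and its log-normal CV.
#' @param agonist_od_drop fractional OD decrease under full activation.
#' @param background_rfu reference-plate pre-spike background signal.
#' @param spike_rfu added signal from the 4-MU spike.
#' @param ref_cv technical CV of reference-plate fluorescence reads.
#' @return object of class `generator_params` (includes derived CVs
#'   `cv_is`, `cv_pos`, `cv_neg`).
#' @export
generator_params <- function(mu_is = 42427, sd_is = 1292,
                             mu_pos = 125728, sd_pos = 3235,
                             mu_neg = 898, sd_neg = 143,
                             od_mean = 0.5, od_cv = 0.05,
                             agonist_od_drop = 0.20,
                             background_rfu = 1000, spike_rfu = 50000,
                             ref_cv = 0.02) {
  stopifnot(mu_is > 0, mu_pos > 0, mu_neg > 0, od_mean > 0,
            sd_is >= 0, sd_pos >= 0, sd_neg >= 0, od_cv >= 0,
            agonist_od_drop >= 0, agonist_od_drop < 1,
            background_rfu > 0, spike_rfu >= 0, ref_cv >= 0)
  structure(list(mu_is = mu_is, sd_is = sd_is, cv_is = sd_is / mu_is,
                 mu_pos = mu_pos, sd_pos = sd_pos, cv_pos = sd_pos / mu_pos,
                 mu_neg = mu_neg, sd_neg = sd_neg, cv_neg = sd_neg / mu_neg,
                 od_mean = od_mean, od_cv = od_cv,
                 agonist_od_drop = agonist_od_drop,
                 background_rfu = background_rfu, spike_rfu = spike_rfu,
                 ref_cv = ref_cv),
            class = "generator_params")
}

# Response SD as a function of the expected ratio: piecewise-linear
# through the three control anchors, held constant outside their span.
# At the anchors this reproduces the printed control dispersions
# exactly; in between it models the assay's variance growing with the
# mean (the negative control's large CV reflects only its near-zero
# mean, not mid-range noise).
sd_at_ratio <- function(ratio, params) {
  stats::approx(x = c(params$mu_neg, params$mu_is, params$mu_pos),
                y = c(params$sd_neg, params$sd_is, params$sd_pos),
                xout = ratio, rule = 2)$y
}

#' Ground-truth record(s) for synthetic compounds
#'
#' @param compound_id character ids.
#' @param true_class one of `r paste0('\x60', TRUE_CLASSES, '\x60', collapse = ", ")`.
#' @param true_ratio expected RFU/OD600 response.
#' @param fluor_offset additive RFU contributed by the compound itself.
#' @param quench_factor multiplicative factor in (0, 1] on fluorescence
#'   in the compound's wells.
#' @param od_effect multiplicative factor on OD600.
#' @return data.frame, one row per compound.
#' @export
synthetic_truth <- function(compound_id, true_class = "neutral",
                            true_ratio = NA_real_, fluor_offset = 0,
                            quench_factor = 1, od_effect = 1) {
  n <- length(compound_id)
  out <- data.frame(compound_id = as.character(compound_id),
                    true_class = rep_len(true_class, n),
                    true_ratio = rep_len(as.numeric(true_ratio), n),
                    fluor_offset = rep_len(as.numeric(fluor_offset), n),
                    quench_factor = rep_len(as.numeric(quench_factor), n),
                    od_effect = rep_len(as.numeric(od_effect), n),
                    stringsAsFactors = FALSE)
  if (!all(out$true_class %in% TRUE_CLASSES)) {
    stop("unknown true_class")
  }
  if (any(out$quench_factor <= 0 | out$quench_factor > 1)) {
    stop("quench_factor must lie in (0, 1]")
  }
  if (any(out$od_effect < 0) || any(out$true_ratio < 0, na.rm = TRUE)) {
    stop("true_ratio and od_effect must be non-negative")
  }
  out
}

#' Simulate the screening-plate channels of one well
#'
#' OD600 is the baseline density times the compound's OD effect, reduced
#' by the agonist growth drop in proportion to the activation fraction
#' (the compound's position between the negative and positive control
#' responses), under multiplicative log-normal noise.  End-point
#' fluorescence is the expected ratio times the realized OD, plus the
#' compound's own fluorescence, times its quench factor, under
#' multiplicative Gaussian noise whose CV interpolates the printed
#' control dispersions.  Draws come from the current RNG state.
#'
#' @param truth one-row data.frame (or list) as from [synthetic_truth()].
#' @param params a [generator_params()] object.
#' @return list with `od600` and `rfu_end` (both truncated at zero).
#' @export
simulate_well <- function(truth, params = generator_params()) {
  activation <- (truth$true_ratio - params$mu_neg) /
    (params$mu_pos - params$mu_neg)
  activation <- min(max(activation, 0), 1)
  sdlog <- sqrt(log1p(params$od_cv^2))
  od <- params$od_mean * truth$od_effect *
    (1 - params$agonist_od_drop * activation) *
    exp(stats::rnorm(1, 0, sdlog))
  cv <- sd_at_ratio(truth$true_ratio, params) / truth$true_ratio
  rfu <- (truth$true_ratio * od + truth$fluor_offset) *
    truth$quench_factor * stats::rnorm(1, 1, cv)
  list(od600 = max(od, 0), rfu_end = max(rfu, 0))
}

# Deterministic per-(plate, well) seed stream: a run seed plus a string
# key hashed into [1, 2^31 - 2], so adding compounds or plates never
# perturbs the draws of existing wells.
well_seed <- function(seed, key) {
  h <- as.double(seed %% 2147483647L)
  for (code in utf8ToInt(key)) {
    h <- (h * 31 + code) %% 2147483629
  }
  as.integer(h + 1)
}

with_preserved_rng <- function(expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  expr
}

#' The calibrated reference screening scenario
#'
#' The planted ground truth mirroring the assay's demonstration run: of
#' 93 unknown compounds, 19 agonists, 12 antagonists of which 3 strong,
#' 1 growth suppressor, and 61 neutral.  Planted responses are spread
#' across each category's band but kept at least ~5 internal-standard
#' SDs away from every decision boundary, so recovery is a property of
#' the pipeline rather than of boundary luck.
#'
#' @param params a [generator_params()] object.
#' @return truth data.frame for 93 test compounds (`CMP-001` ..
#'   `CMP-093`).
#' @export
reference_truth <- function(params = generator_params()) {
  ids <- sprintf("CMP-%03d", 1:93)
  ag_level <- (params$mu_is + params$mu_pos) / 2
  ant_level <- (params$mu_is + params$mu_neg) / 2
  s <- params$sd_is
  classes <- rep("neutral", 93)
  ratios <- rep(params$mu_is, 93)
  ag <- 1:19
  classes[ag] <- "agonist"
  ratios[ag] <- seq(params$mu_is + 10 * s, ag_level - 5.5 * s,
                    length.out = length(ag))
  an <- 20:28
  classes[an] <- "antagonist"
  ratios[an] <- seq(ant_level + 5.7 * s, params$mu_is - 7.3 * s,
                    length.out = length(an))
  st <- 29:31
  classes[st] <- "strong_antagonist"
  ratios[st] <- seq(max(params$mu_neg, ant_level - 13 * s),
                    ant_level - 5.2 * s, length.out = length(st))
  gs <- 32L
  classes[gs] <- "growth_suppressor"
  truth <- synthetic_truth(ids, classes, ratios)
  truth$od_effect[gs] <- 0.01
  truth
}

# Draw a truth table for an arbitrary class mix; ratios are placed
# uniformly within each class band, clear of the decision boundaries.
class_mix_truth <- function(n_compounds, class_mix, params) {
  if (is.null(names(class_mix)) || !all(names(class_mix) %in% TRUE_CLASSES)) {
    stop("class_mix must be a named vector over the true classes")
  }
  if (any(class_mix < 0) || sum(class_mix) <= 0) stop("invalid class mix")
  counts <- round(class_mix / sum(class_mix) * n_compounds)
  # fix rounding drift on the largest class
  counts[which.max(counts)] <- counts[which.max(counts)] +
    n_compounds - sum(counts)
  if (any(counts < 0)) stop("invalid class mix")
  classes <- rep(names(counts), counts)
  ag_level <- (params$mu_is + params$mu_pos) / 2
  ant_level <- (params$mu_is + params$mu_neg) / 2
  s <- params$sd_is
  band <- list(
    neutral = c(params$mu_is, params$mu_is),
    agonist = c(params$mu_is + 10 * s, ag_level - 5.5 * s),
    strong_agonist = c(ag_level + 5 * s, params$mu_pos),
    antagonist = c(ant_level + 5.7 * s, params$mu_is - 7.3 * s),
    strong_antagonist = c(max(params$mu_neg, ant_level - 13 * s),
                          ant_level - 5.2 * s),
    growth_suppressor = c(params$mu_is, params$mu_is)
  )
  ratios <- vapply(classes, function(cl) {
    stats::runif(1, band[[cl]][1], band[[cl]][2])
  }, numeric(1))
  truth <- synthetic_truth(sprintf("CMP-%03d", seq_along(classes)),
                           classes, ratios)
  truth$od_effect[truth$true_class == "growth_suppressor"] <- 0.01
  truth
}

#' Generate a paired screening/reference plate set with ground truth
#'
#' Builds a full 96-position rack (the planted test compounds plus the
#' three controls; unused positions, if any, are filled with neutral
#' blanks), stamps it in quadruplicate, and simulates both plates from
#' one seed.  Per-well random streams are keyed by (plate, well), so the
#' draws for a given well never depend on what else is on the plate.
#' Reference channels: pre-spike = background + compound fluorescence;
#' post-spike = (background + spike + compound fluorescence) x quench
#' factor; both under the technical CV.
#'
#' @param truth explicit truth table from [synthetic_truth()] /
#'   [reference_truth()] (<= 93 rows), or `NULL` to draw one from
#'   `class_mix`.
#' @param n_compounds number of planted compounds when drawing from
#'   `class_mix`.
#' @param class_mix named proportions over the true classes.
#' @param params a [generator_params()] object.
#' @param seed integer run seed; all randomness derives from it.
#' @param dir when given, the plate CSVs (`od600.csv`, `rfu_end.csv`,
#'   `rfu_pre_spike.csv`, `rfu_post_spike.csv`), `manifest.csv` and
#'   `truth.tsv` are written there.
#' @param scheme stamping scheme (see [assign_quadruplicate_layout()]).
#' @return object of class `screen_pair`: list with `manifest`,
#'   `layout`, `truth` (controls included), `screening`, `reference`,
#'   `params`, `seed` and, when written, `dir`.
#' @export
generate_screen_pair <- function(truth = NULL, n_compounds = 93,
                                 class_mix = NULL,
                                 params = generator_params(), seed = 1,
                                 dir = NULL,
                                 scheme = c("block2x2", "quadrant")) {
  scheme <- match.arg(scheme)
  with_preserved_rng({
    if (is.null(truth)) {
      if (is.null(class_mix)) {
        stop("provide either an explicit truth table or a class_mix")
      }
      if (n_compounds > 93) stop("at most 93 test compounds fit a rack")
      set.seed(well_seed(seed, "truth"))
      truth <- class_mix_truth(n_compounds, class_mix, params)
    }
    if (nrow(truth) > 93) stop("at most 93 test compounds fit a rack")
    if (nrow(truth) < 93) {
      blanks <- synthetic_truth(
        sprintf("BLANK-%02d", seq_len(93 - nrow(truth))),
        "neutral", params$mu_is)
      truth <- rbind(truth, blanks)
    }
    truth$true_ratio[is.na(truth$true_ratio)] <- params$mu_is

    ctrl <- synthetic_truth(
      c("CTRL-TZ", "CTRL-ANT", "CTRL-DMSO"),
      "neutral", c(params$mu_pos, params$mu_neg, params$mu_is))
    full <- rbind(truth, ctrl)
    manifest <- data.frame(
      compound_id = full$compound_id,
      rack_position = rack_positions(),
      role = c(rep("test", 93), "positive_control", "negative_control",
               "neutral_control"),
      stock_concentration_mM = 5,
      stringsAsFactors = FALSE
    )
    layout <- assign_quadruplicate_layout(manifest, scheme)

    tix <- match(layout$compound_id, full$compound_id)
    n_wells <- nrow(layout)
    od <- rfu <- pre <- post <- numeric(n_wells)
    sdlog <- sqrt(log1p(params$od_cv^2))
    for (i in seq_len(n_wells)) {
      tr <- full[tix[i], ]
      set.seed(well_seed(seed, paste0("S:", layout$well[i])))
      w <- simulate_well(tr, params)
      od[i] <- w$od600
      rfu[i] <- w$rfu_end
      set.seed(well_seed(seed, paste0("R:", layout$well[i])))
      pre[i] <- max((params$background_rfu + tr$fluor_offset) *
                      stats::rnorm(1, 1, params$ref_cv), 0)
      post[i] <- max((params$background_rfu + params$spike_rfu +
                        tr$fluor_offset) * tr$quench_factor *
                       stats::rnorm(1, 1, params$ref_cv), 0)
    }
    screening <- data.frame(well = layout$well, od600 = od, rfu_end = rfu,
                            stringsAsFactors = FALSE)
    reference <- data.frame(well = layout$well, rfu_pre_spike = pre,
                            rfu_post_spike = post, stringsAsFactors = FALSE)
    out <- structure(list(manifest = manifest, layout = layout,
                          truth = full, screening = screening,
                          reference = reference, params = params,
                          seed = seed),
                     class = "screen_pair")
    if (!is.null(dir)) {
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      write_plate_matrix(stats::setNames(od, layout$well),
                         file.path(dir, "od600.csv"))
      write_plate_matrix(stats::setNames(rfu, layout$well),
                         file.path(dir, "rfu_end.csv"))
      write_plate_matrix(stats::setNames(pre, layout$well),
                         file.path(dir, "rfu_pre_spike.csv"))
      write_plate_matrix(stats::setNames(post, layout$well),
                         file.path(dir, "rfu_post_spike.csv"))
      write_rack_manifest(manifest, file.path(dir, "manifest.csv"))
      write_truth_table(full, file.path(dir, "truth.tsv"))
      out$dir <- dir
    }
    out
  })
}

#' Write a ground-truth table
#'
#' @param truth truth data.frame.
#' @param path TSV file to write.
#' @export
write_truth_table <- function(truth, path) {
  out <- truth
  for (col in c("true_ratio", "fluor_offset", "quench_factor", "od_effect")) {
    out[[col]] <- format_full(as.numeric(out[[col]]))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a ground-truth table written by [write_truth_table()]
#'
#' @param path TSV file.
#' @return truth data.frame.
#' @export
read_truth_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(compound_id = "character",
                                          true_class = "character"))
  tab$true_ratio <- as.numeric(tab$true_ratio)
  tab
}
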