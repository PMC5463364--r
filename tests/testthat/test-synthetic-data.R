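p <- generator_params()

test_that("noise-free wells reproduce the expected ratio exactly", {
  p0 <- generator_params(sd_is = 0, sd_pos = 0, sd_neg = 0, od_cv = 0)
  tr <- synthetic_truth("X", "neutral", p0$mu_is)
  w <- simulate_well(tr[1, ], p0)
  expect_equal(w$rfu_end / w$od600, p0$mu_is, tolerance = 1e-12)
  # the internal-standard response carries its partial activation OD drop
  act <- (p0$mu_is - p0$mu_neg) / (p0$mu_pos - p0$mu_neg)
  expect_equal(w$od600, p0$od_mean * (1 - p0$agonist_od_drop * act))
  # full activation drops OD by the agonist drop
  tz <- synthetic_truth("TZ", "strong_agonist", p0$mu_pos)
  expect_equal(simulate_well(tz[1, ], p0)$od600,
               p0$od_mean * (1 - p0$agonist_od_drop))
})

test_that("growth suppressors fall below the OD floor", {
  tr <- synthetic_truth("GS", "growth_suppressor", p$mu_is,
                        od_effect = 0.01)
  set.seed(41)
  for (i in 1:20) {
    w <- simulate_well(tr[1, ], p)
    expect_lt(w$od600, 0.05)
  }
})

test_that("the neutral-class ratio distribution matches the calibration", {
  tr <- synthetic_truth("N", "neutral", p$mu_is)
  set.seed(42)
  ratios <- vapply(1:10000, function(i) {
    w <- simulate_well(tr[1, ], p)
    w$rfu_end / w$od600
  }, numeric(1))
  expect_equal(mean(ratios), p$mu_is, tolerance = 0.01 * p$mu_is)
  cv <- sd(ratios) / mean(ratios)
  expect_equal(cv, p$cv_is, tolerance = 0.2 * p$cv_is)
})

test_that("response SD interpolates the three printed control anchors", {
  expect_equal(cytoscreen:::sd_at_ratio(p$mu_is, p), p$sd_is)
  expect_equal(cytoscreen:::sd_at_ratio(p$mu_pos, p), p$sd_pos)
  expect_equal(cytoscreen:::sd_at_ratio(p$mu_neg, p), p$sd_neg)
  mid <- cytoscreen:::sd_at_ratio((p$mu_is + p$mu_pos) / 2, p)
  expect_true(mid > p$sd_is && mid < p$sd_pos)
  expect_equal(cytoscreen:::sd_at_ratio(2 * p$mu_pos, p), p$sd_pos)
})

test_that("generation is deterministic and byte-identical from one seed", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  truth <- synthetic_truth(sprintf("CMP-%03d", 1:93), "neutral", p$mu_is)
  generate_screen_pair(truth = truth, params = p, seed = 5, dir = d1)
  generate_screen_pair(truth = truth, params = p, seed = 5, dir = d2)
  for (f in c("od600.csv", "rfu_end.csv", "rfu_pre_spike.csv",
              "rfu_post_spike.csv", "manifest.csv", "truth.tsv")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  }
  d3 <- withr::local_tempdir()
  generate_screen_pair(truth = truth, params = p, seed = 6, dir = d3)
  expect_false(identical(readLines(file.path(d1, "rfu_end.csv")),
                         readLines(file.path(d3, "rfu_end.csv"))))
})

test_that("per-well streams do not depend on the rest of the plate", {
  # changing one compound's truth leaves every other well untouched
  t1 <- reference_truth(p)
  t2 <- t1
  t2$true_ratio[5] <- 100000
  s1 <- generate_screen_pair(truth = t1, params = p, seed = 8)
  s2 <- generate_screen_pair(truth = t2, params = p, seed = 8)
  changed <- s1$layout$well[s1$layout$compound_id == "CMP-005"]
  keep <- !(s1$screening$well %in% changed)
  expect_identical(s1$screening$od600[keep], s2$screening$od600[keep])
  expect_identical(s1$screening$rfu_end[keep], s2$screening$rfu_end[keep])
})

test_that("planted class mixes are honoured and written files round-trip", {
  mix <- c(neutral = 0.65, agonist = 0.2, antagonist = 0.13,
           growth_suppressor = 0.02)
  sp <- generate_screen_pair(n_compounds = 93, class_mix = mix,
                             params = p, seed = 11)
  counts <- table(sp$truth$true_class[sp$truth$compound_id %in%
                                        sprintf("CMP-%03d", 1:93)])
  expect_equal(unname(counts["agonist"]), round(0.2 * 93))
  expect_equal(unname(counts["growth_suppressor"]), round(0.02 * 93))
  expect_equal(sum(counts), 93)
  expect_error(generate_screen_pair(n_compounds = 93,
                                    class_mix = c(bogus = 1), params = p),
               "class_mix")

  d <- withr::local_tempdir()
  ref_truth <- reference_truth(p)
  generate_screen_pair(truth = ref_truth, params = p, seed = 12, dir = d)
  back <- read_truth_table(file.path(d, "truth.tsv"))
  expect_equal(back$compound_id[1:93], ref_truth$compound_id)
  expect_equal(back$true_ratio[1:93], ref_truth$true_ratio)
  expect_equal(table(back$true_class[1:93]), table(ref_truth$true_class))
  # the emitted files feed straight back into the screen
  scr <- read_screening_plate(d)
  ref <- read_reference_plate(d)
  man <- read_rack_manifest(file.path(d, "manifest.csv"))
  res <- run_screen(scr, ref, man)
  expect_equal(class_accuracy(res, back[back$compound_id %in%
                                          sprintf("CMP-%03d", 1:93), ]), 1)
})

test_that("truth tables round-trip including the empty table", {
  path <- withr::local_tempfile(fileext = ".tsv")
  truth <- reference_truth(p)
  write_truth_table(truth, path)
  expect_equal(read_truth_table(path), truth)
  write_truth_table(truth[0, ], path)
  expect_equal(nrow(read_truth_table(path)), 0)
  expect_equal(length(readLines(path)), 1)
})

test_that("simulated control statistics stay faithful across plates", {
  truth <- synthetic_truth(sprintf("CMP-%03d", 1:93), "neutral", p$mu_is)
  n_plates <- 300
  is_ratio <- matrix(NA_real_, n_plates, 4)
  zp <- zn <- numeric(n_plates)
  for (i in seq_len(n_plates)) {
    sp <- generate_screen_pair(truth = truth, params = p, seed = 2000 + i)
    lay <- sp$layout
    ratios <- sp$screening$rfu_end / sp$screening$od600
    by_role <- split(ratios[match(lay$well, sp$screening$well)], lay$role)
    cs <- control_summary(list(
      neutral_control = by_role$neutral_control,
      positive_control = by_role$positive_control,
      negative_control = by_role$negative_control))
    is_ratio[i, ] <- by_role$neutral_control
    zp[i] <- cs$z_prime_pos
    zn[i] <- cs$z_prime_neg
  }
  expect_equal(mean(is_ratio), p$mu_is, tolerance = 0.005 * p$mu_is)
  expect_equal(sd(is_ratio), p$sd_is, tolerance = 0.1 * p$sd_is)
  expect_equal(median(zp), 0.8370, tolerance = 0.03)
  expect_equal(median(zn), 0.8963, tolerance = 0.03)
})

test_that("generator parameter validation rejects impossible settings", {
  expect_error(generator_params(agonist_od_drop = 1.2))
  expect_error(generator_params(mu_is = -5))
  expect_error(synthetic_truth("A", "neutral", 100, quench_factor = 0))
  expect_error(synthetic_truth("A", "wizard", 100), "unknown true_class")
})
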