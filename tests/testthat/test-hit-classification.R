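params <- test_params()

printed_controls <- control_summary(list(
  neutral_control = c(42427, 42427, 42427, 42427),
  positive_control = c(125728, 125728, 125728, 125728),
  negative_control = c(898, 898, 898, 898)))

test_that("hit-defining levels are control midpoints", {
  th <- hit_thresholds(printed_controls)
  expect_equal(th$strong_agonist_level, (42427 + 125728) / 2)  # 84077.5
  expect_equal(th$strong_antagonist_level, (42427 + 898) / 2)  # 21662.5
  expect_equal(th$mu_is, 42427)

  bad <- printed_controls
  bad$mu_pos <- bad$mu_is
  expect_error(hit_thresholds(bad), class = "cytoscreen_qc_failure")
  bad2 <- printed_controls
  bad2$mu_neg <- bad2$mu_is + 1
  expect_error(hit_thresholds(bad2), class = "cytoscreen_qc_failure")
})

test_that("classification applies the precedence and boundary rules", {
  th <- hit_thresholds(printed_controls)
  sig <- 1e-6
  cases <- list(
    list(ratio = 90000, p = sig, cat = "strong_agonist"),
    list(ratio = 84077.5, p = sig, cat = "strong_agonist"),  # closed bound
    list(ratio = 84077, p = sig, cat = "agonist"),
    list(ratio = 50000, p = sig, cat = "agonist"),
    list(ratio = 30000, p = sig, cat = "antagonist"),
    list(ratio = 21662.5, p = sig, cat = "strong_antagonist"),  # closed
    list(ratio = 5000, p = sig, cat = "strong_antagonist"),
    list(ratio = 150000, p = 0.01, cat = "neutral")  # significance gate
  )
  for (cs in cases) {
    expect_equal(classify_compound(cs$ratio, cs$p, th, params), cs$cat,
                 info = paste("ratio", cs$ratio, "p", cs$p))
  }
  # precedence: growth failure > artifact > significance > magnitude
  expect_equal(classify_compound(150000, sig, th, params,
                                 interference = TRUE), "interference")
  expect_equal(classify_compound(150000, sig, th, params,
                                 interference = TRUE,
                                 growth_failure = TRUE),
               "indeterminate_growth")
  expect_equal(classify_compound(NA, NA, th, params), "neutral")
})

test_that("classification is monotone in the response", {
  th <- hit_thresholds(printed_controls)
  ranks <- c(strong_antagonist = 1, antagonist = 2, neutral = 3,
             agonist = 4, strong_agonist = 5)
  ratios <- seq(500, 130000, by = 750)
  cats <- vapply(ratios, classify_compound, character(1),
                 p_value = 1e-9, thresholds = th, params = params)
  expect_true(all(diff(ranks[cats]) >= 0))
})

test_that("a full synthetic screen recovers the planted classes", {
  p <- generator_params()
  sp <- generate_screen_pair(truth = reference_truth(p), params = p,
                             seed = 7)
  res <- run_screen(sp$screening, sp$reference, sp$manifest)
  expect_s3_class(res, "screen_result")
  expect_equal(res$params$m, 95)
  truth93 <- sp$truth[sp$truth$compound_id %in%
                        sprintf("CMP-%03d", 1:93), ]
  expect_equal(class_accuracy(res, truth93), 1)
  expect_equal(unname(res$category_counts["agonist"]), 19)
  expect_equal(unname(res$category_counts["antagonist"]), 9)
  expect_equal(unname(res$category_counts["strong_antagonist"]), 3)
  expect_equal(unname(res$category_counts["indeterminate_growth"]), 1)
  # the on-plate controls behave as the strongest agonist/antagonist
  ctrl <- res$results[res$results$role != "test", ]
  expect_equal(ctrl$category[ctrl$role == "positive_control"],
               "strong_agonist")
  expect_equal(ctrl$category[ctrl$role == "negative_control"],
               "strong_antagonist")
  # Z' close to the calibrated values
  expect_equal(res$controls$z_prime_pos, 0.84, tolerance = 0.1)
  expect_equal(res$controls$z_prime_neg, 0.90, tolerance = 0.1)
})

test_that("quenchers and fluorophores on the screening plate are demoted to interference", {
  p <- generator_params()
  truth <- reference_truth(p)
  truth$quench_factor[1] <- 0.7   # planted agonist that also quenches
  truth$fluor_offset[20] <- 5000  # planted antagonist that fluoresces
  sp <- generate_screen_pair(truth = truth, params = p, seed = 9)
  res <- run_screen(sp$screening, sp$reference, sp$manifest)
  r <- res$results
  expect_equal(r$category[r$compound_id == "CMP-001"], "interference")
  expect_true(r$quencher[r$compound_id == "CMP-001"])
  expect_equal(r$category[r$compound_id == "CMP-020"], "interference")
  expect_true(r$autofluorescent[r$compound_id == "CMP-020"])
})

test_that("an all-neutral plate yields (almost) only neutral calls", {
  p <- generator_params()
  truth <- synthetic_truth(sprintf("CMP-%03d", 1:93), "neutral", p$mu_is)
  hits <- 0
  for (s in 1:5) {
    sp <- generate_screen_pair(truth = truth, params = p, seed = 100 + s)
    res <- run_screen(sp$screening, sp$reference, sp$manifest)
    r <- res$results[res$results$role == "test", ]
    hits <- hits + sum(r$category != "neutral")
  }
  # expected false hits over 5 plates: 5 * 93 * alpha_adj ~ 0.25
  expect_lte(hits, 3)
})

test_that("screen-level input errors are caught", {
  p <- generator_params()
  sp <- generate_screen_pair(truth = reference_truth(p), params = p,
                             seed = 3)
  expect_error(run_screen(sp$screening, NULL, sp$manifest),
               "reference plate is required")
  expect_error(run_screen(sp$screening[-(1:4), ], sp$reference,
                          sp$manifest), "lacks wells")
  # positive-control wells collapsed below the internal standard -> QC failure
  broken <- sp$screening
  pos_wells <- sp$layout$well[sp$layout$role == "positive_control"]
  ix <- match(pos_wells, broken$well)
  broken$rfu_end[ix] <- broken$od600[ix] * 10000
  expect_error(run_screen(broken, sp$reference, sp$manifest),
               class = "cytoscreen_qc_failure")
})

test_that("the written screen report matches the in-memory results", {
  p <- generator_params()
  sp <- generate_screen_pair(truth = reference_truth(p), params = p,
                             seed = 13)
  res <- run_screen(sp$screening, sp$reference, sp$manifest)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_screen_report(res$results, path)
  back <- read_screen_report(path)
  expect_equal(back$compound_id, res$results$compound_id)
  expect_equal(back$mean_ratio, res$results$mean_ratio)
  expect_equal(back$category, res$results$category)
  expect_equal(back$flags, res$results$flags)
})
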