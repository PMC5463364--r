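# Shared fixtures, built in code.

# A minimal valid 96-position rack: 93 test compounds + 3 controls.
make_rack <- function() {
  data.frame(
    compound_id = c(sprintf("CMP-%03d", 1:93),
                    "CTRL-TZ", "CTRL-ANT", "CTRL-DMSO"),
    rack_position = rack_positions(),
    role = c(rep("test", 93), "positive_control", "negative_control",
             "neutral_control"),
    stock_concentration_mM = 5,
    stringsAsFactors = FALSE
  )
}

# Expected screen category for each planted true class.
expected_category <- c(neutral = "neutral", agonist = "agonist",
                       strong_agonist = "strong_agonist",
                       antagonist = "antagonist",
                       strong_antagonist = "strong_antagonist",
                       growth_suppressor = "indeterminate_growth")

# Independent t-distribution upper-tail probability by numerical
# integration of the density (no calls to pt); oracle for the Welch test.
t_upper_tail <- function(q, df) {
  dens <- function(x) {
    exp(lgamma((df + 1) / 2) - lgamma(df / 2)) / sqrt(df * pi) *
      (1 + x^2 / df)^(-(df + 1) / 2)
  }
  stats::integrate(dens, q, Inf, rel.tol = 1e-13, abs.tol = 0)$value
}

# Classification accuracy of a screen result against a planted truth.
class_accuracy <- function(result, truth) {
  m <- merge(result$results[, c("compound_id", "category")],
             truth, by = "compound_id")
  mean(m$category == expected_category[m$true_class])
}
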