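# The slope analysis of the study pools its risk-neutral and risk-averse
# arms. This builds the pooled relative-aim cloud from two synthetic cohorts:
# the risk-averse arm (8 subjects, the recovery target) and its risk-neutral
# companion (9 subjects; baseline bias 0.68 cm, that group's reported value).
pooled_relative_aims <- function(seed, slope_pos = 0.63, slope_neg = 0.21,
                                 bias_averse = 1.0, bias_neutral = 0.68) {
  m_b <- subject_model(baseline_bias = bias_averse, slope_pos = slope_pos,
                       slope_neg = slope_neg)
  m_a <- subject_model(baseline_bias = bias_neutral, slope_pos = slope_pos,
                       slope_neg = slope_neg)
  dplyr::bind_rows(
    relative_aims(compute_aim_points(
      generate_cohort("exp1b", 8, m_b, seed = seed))),
    relative_aims(compute_aim_points(
      generate_cohort("exp1a", 9, m_a, seed = seed + 500000,
                      subject_prefix = "a"))))
}
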