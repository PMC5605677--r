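# shared fixtures: one moderately sized default cohort reused across files
default_cohort <- local({
  cache <- NULL
  function(n = 5000, seed = 20260101) {
    if (is.null(cache)) cache <<- generate_cohort(default_config(), n, seed)
    cache
  }
})

# small hand-built cohort rows for rule tests
make_records <- function(n, sex = "F", ga = 39, exam_age = 10, fm = 330,
                         ffm = 2800, length = 48.5, low_risk = TRUE,
                         malformation = FALSE, ultrasound_z = "") {
  data.frame(id = sprintf("X%03d", seq_len(n)), sex = sex,
             ga_birth_weeks = ga, exam_age_hours = exam_age,
             birth_weight_g = fm + ffm + 50, exam_weight_g = fm + ffm,
             length_cm = length, head_circ_cm = 34,
             body_volume_ml = NA_real_, fm_g = fm, ffm_g = ffm,
             bf_pct = 100 * fm / (fm + ffm), low_risk = low_risk,
             malformation = malformation, ultrasound_z = ultrasound_z,
             stringsAsFactors = FALSE)
}
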