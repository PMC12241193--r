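# Shared fixtures: a small three-tissue parameter set (fast to integrate)
# and reduced search grids sized for test runtime.

tiny_params <- function() {
  pbpk_params(
    volumes = c(arterial = 1.0, venous = 2.0, liver = 1.5, muscle = 20.0),
    flows = c(liver = 2.0, muscle = 3.0),
    partitions = c(liver = 1.0, muscle = 1.2),
    k_met = c(liver = 0.2),
    cardiac_output = 5.0,
    alveolar_ventilation = 4.0,
    blood_air_partition = 150
  )
}

small_grid <- function() {
  inversion_grid(conc_min = 0, conc_max = 3000, conc_step = 150,
                 time_min = 0, time_max = 6, time_step = 0.2)
}

# case table built in code (no file): mirrors the interchange schema
make_case_table <- function(cn_right, cn_left,
                            cohb_right = rep("50", length(cn_right)),
                            cohb_left = cohb_right,
                            scn_right = rep("2.0", length(cn_right)),
                            scn_left = scn_right) {
  n <- length(cn_right)
  tmp <- tempfile(fileext = ".csv")
  df <- data.frame(
    case_id = as.character(seq_len(n)), age = rep("60", n),
    sex = rep("M", n), cn_right = cn_right, cn_left = cn_left,
    cohb_right = cohb_right, cohb_left = cohb_left,
    scn_right = scn_right, scn_left = scn_left
  )
  utils::write.csv(df, tmp, row.names = FALSE)
  on.exit(unlink(tmp))
  read_case_table(tmp)
}
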