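# Shared fixtures built in code.

write_toy_log <- function(rows, path = tempfile(fileext = ".csv")) {
  utils::write.csv(rows, path, row.names = FALSE)
  path
}

toy_log_df <- function() {
  data.frame(object_label = c("novel", "familiar"),
             t_start_s = c(3.0, 1.0), t_stop_s = c(5.0, 2.0))
}

# closed-form hemisphere terms plus numerically integrated frustum solid of
# revolution: the independent oracle for frustum_geometry()
oracle_geometry <- function(r_a, r_t, h) {
  radius <- function(z) r_a + (r_t - r_a) * z / h
  v_frustum <- stats::integrate(function(z) pi * radius(z)^2, 0, h,
                                rel.tol = 1e-10)$value
  slope <- (r_t - r_a) / h
  a_frustum <- stats::integrate(function(z) 2 * pi * radius(z) * sqrt(1 + slope^2),
                                0, h, rel.tol = 1e-10)$value
  c(volume = v_frustum + 2 / 3 * pi * r_t^3 - 2 / 3 * pi * r_a^3,
    area = a_frustum + 2 * pi * r_t^2 - 2 * pi * r_a^2)
}

# a spine table row with every raw feature present
full_spine_row <- function(length = 1.2, head_max = 0.7, n = 1) {
  data.frame(spine_id = sprintf("s%d", seq_len(n)), animal_id = "a1",
             neuron_id = "n1", segment_id = "seg1",
             length = length, head_max_diameter = head_max,
             head_mean_diameter = head_max * 0.85, head_length = length * 0.4,
             neck_min_diameter = 0.18, neck_mean_diameter = 0.22,
             neck_length = length * 0.5, attachment_diameter = 0.3,
             straightness = 0.9, dendrite_diameter = 3)
}
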