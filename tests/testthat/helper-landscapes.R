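# shared fixtures: tiny analytic landscapes built in code

flat_landscape <- function(lateral_k = 0) {
  landscape_spec("flat", lateral_k = lateral_k, pair_amplitude = 0)
}

single_well <- function(center = 0, depth = -2, width = 1.5) {
  landscape_spec("well",
                 axial_features = data.frame(center = center, depth = depth,
                                             width = width),
                 lateral_k = 0.5, pair_amplitude = 0)
}

double_well <- function() {
  landscape_spec("double-well",
                 axial_features = data.frame(center = c(-2.5, 2.5),
                                             depth = c(-3, -2),
                                             width = c(1, 1)),
                 lateral_k = 0.5, pair_amplitude = 0)
}

kbt300 <- ionpmf::constants$k_B * 300

# minimal synthetic trajectory table
make_traj <- function(z1, z2, time = seq_along(z1), step = 1L, replica = 1L,
                      x1 = 0, y1 = 0, x2 = 0, y2 = 0) {
  dplyr::bind_rows(
    tibble::tibble(replica = replica, step = step, time = time, ion = 1L,
                   species = "K-like", x = x1, y = y1, z = z1),
    tibble::tibble(replica = replica, step = step, time = time, ion = 2L,
                   species = "K-like", x = x2, y = y2, z = z2))
}
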