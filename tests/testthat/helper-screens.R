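# Small screen configurations used across tests. Unit tests use reduced
# control counts and field numbers for speed; acceptance checks use the
# full 20/20-control, 6-field design.

tiny_config <- function(targets, noise_cv = 0, seed = 1, doses = 4, ...) {
  screen_config(targets, doses = doses, n_replicate_plates = 3,
                fields_per_well = 2, n_pos_controls = 8, n_neg_controls = 4,
                noise_cv = noise_cv, seed = seed, ...)
}

full_config <- function(targets, noise_cv = 0.02, seed = 1, doses = c(0.5, 1, 2, 4), ...) {
  screen_config(targets, doses = doses, noise_cv = noise_cv, seed = seed, ...)
}

# one disc + one straight horizontal neurite, the standard morphometry scene
disc_and_line_field <- function(dim = c(256, 256), radius = 10,
                                line_len = 100, noise_sd = 0, seed = NULL) {
  cell <- field_cell(c(60, 60), radius,
                     list(cbind(60, seq(60 + radius + 2, 60 + radius + 2 + line_len))))
  generate_field_images(list(cell), dim = dim, noise_sd = noise_sd, seed = seed)
}

# straight neurite of given length at an angle, soma far away in a corner
angled_neurite_field <- function(len, angle_deg, dim = c(320, 320)) {
  ang <- angle_deg * pi / 180
  p0 <- c(60, 40)
  p1 <- p0 + len * c(sin(ang), cos(ang))
  generate_field_images(
    list(field_cell(c(dim[1] - 40, dim[2] - 40), 10, list(rbind(p0, p1)))),
    dim = dim)
}
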