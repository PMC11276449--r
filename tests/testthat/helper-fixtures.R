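# Shared fixtures, built in code.

# square grid of points with given spacing inside [0, (n-1)*spacing]^2
grid_points <- function(n = 5, spacing = 10) {
  g <- expand.grid(x_um = seq(0, (n - 1) * spacing, spacing),
                   y_um = seq(0, (n - 1) * spacing, spacing))
  data.frame(x_um = g$x_um, y_um = g$y_um)
}

# bare en-face image wrapper around a matrix
as_enface <- function(m, pixel_size_um = 1) {
  structure(list(intensity = m, pixel_size_um = pixel_size_um,
                 window = c(0, ncol(m) * pixel_size_um,
                            0, nrow(m) * pixel_size_um)),
            class = "enface_image")
}

# analytic hexagonal density for spacing a (um) in cells/mm^2
hex_density <- function(a_um) 2 / (sqrt(3) * a_um^2) * 1e6
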