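# Geometric fixtures built in code.

circle_contour <- function(r = 1, center = c(0, 0), n = 720) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  contour(cbind(center[1] + r * cos(th), center[2] + r * sin(th)),
          check_simple = FALSE)
}

ellipse_contour <- function(a = 2, b = 1, center = c(0, 0), n = 720) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  contour(cbind(center[1] + a * cos(th), center[2] + b * sin(th)),
          check_simple = FALSE)
}

square_contour <- function(side = 1, origin = c(0, 0)) {
  contour(rbind(origin,
                origin + c(side, 0),
                origin + c(side, side),
                origin + c(0, side)))
}

# A minimal valid profile from concentric circles; radii in micrometres.
two_circle_profile <- function(r_out = 2, r_in = 1, center = c(5, 5), n = 720,
                               ...) {
  capillary_profile(group = "SHAM", animal = "a1", profile = "p1",
                    abluminal = circle_contour(r_out, center, n),
                    lumen = circle_contour(r_in, center, n),
                    ...)
}
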