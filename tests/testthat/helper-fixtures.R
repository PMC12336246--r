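# shared fixture builders; everything is generated in code at test time

# dense polar sampling of a superellipse |x/a|^n + |y/b|^n = 1 about the
# origin, using the package's anterior-zero angle convention
# (direction(theta) = (-sin, cos)); closed-form radius for the same angles
superellipse <- function(a, b, n, n_vertices = 2880) {
  theta <- 2 * pi * (seq_len(n_vertices) - 1L) / n_vertices
  r <- (abs(sin(theta) / a)^n + abs(cos(theta) / b)^n)^(-1 / n)
  list(points = cbind(x = -r * sin(theta), y = r * cos(theta)),
       theta = theta, radius = r)
}

superellipse_radius <- function(a, b, n, theta) {
  (abs(sin(theta) / a)^n + abs(cos(theta) / b)^n)^(-1 / n)
}

circle_points <- function(R, center = c(0, 0), n = 360) {
  make_contour(contour_spec(R, center = center, n_vertices = n))
}

# closed-form solutions of m u'' + k u' = F0 (constant force), u(0)=u'(0)=0
const_force_velocity <- function(t, m, k, F0) (F0 / k) * (1 - exp(-k * t / m))
const_force_displacement <- function(t, m, k, F0) {
  (F0 / k) * (t + (m / k) * (exp(-k * t / m) - 1))
}
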