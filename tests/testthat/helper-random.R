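# shared generators for property-style tests

rand_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

rand_transform <- function(t_scale = 20) {
  rigid_transform(rand_rotation(), stats::rnorm(3, sd = t_scale))
}

rand_frame <- function() {
  anatomical_frame(stats::rnorm(3, sd = 20), rand_rotation())
}

xprod <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# a random single-hinge rig with one straight muscle spanning the joint
rand_hinge_rig <- function() {
  ax <- sample(c("x", "y", "z"), 1)
  orig <- stats::rnorm(3, sd = 25)
  ins <- stats::rnorm(3, sd = 10)
  while (sqrt(sum((ins - orig)^2)) < 8) ins <- stats::rnorm(3, sd = 10)
  synthetic_rig("revolute", centre = c(0, 0, 0), axes = rand_rotation(),
                revolute_axis = ax,
                muscles = list(m = list(origin = orig, insertion = ins)))
}
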