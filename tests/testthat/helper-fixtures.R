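# Shared fixtures built in code.

# joint over (ZB, ZC, A) induced on the toy landscape by a fixed strategy
toy_signal_joint <- function(strategy) {
  land <- toy_landscape()
  enc <- toy_encoders(strategy)
  marginalize(induced_joint(land, build_decoder(land, enc$b, enc$c)),
              c("ZB", "ZC", "A"))
}

# Y copies X1, X2 is independent fair-coin noise
copy_table <- function() {
  g <- expand.grid(X1 = 0:1, X2 = 0:1)
  g$Y <- g$X1
  prob_table(g, rep(0.25, 4))
}

# target independent of both sources
independent_table <- function() {
  g <- expand.grid(X1 = 0:1, X2 = 0:1, Y = 0:1)
  prob_table(g, rep(1 / 8, 8))
}

# random small joint over three binary variables, seeded
random_table <- function(seed, vars = c("X", "Z", "Y")) {
  set.seed(seed)
  g <- expand.grid(a = 0:1, b = 0:1, c = 0:1)
  names(g) <- vars
  w <- stats::rexp(8)
  prob_table(g, w / sum(w))
}

random_landscape <- function(seed, m = 4, n = 4) {
  set.seed(seed)
  affordance_landscape(matrix(stats::runif(m * n), m, n))
}

random_encoder <- function(seed, m, L) {
  set.seed(seed)
  encoder_map(sample.int(L, m, replace = TRUE) - 1L, L)
}
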