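test_that("entropy matches worked values and respects its bounds", {
  p4 <- prob_table(data.frame(X = 1:4), c(0.5, 0.2, 0.2, 0.1))
  expect_equal(round(entropy(p4), 2), 1.76)
  expect_equal(entropy(prob_table(data.frame(X = 1:4), rep(0.25, 4))), 2)
  expect_equal(entropy(prob_table(data.frame(X = 1), 1)), 0)
  for (seed in 1:10) {
    p <- random_table(seed)
    for (v in p$vars) {
      h <- entropy(p, v)
      expect_gte(h, 0)
      expect_lte(h, log2(length(p$alphabets[[v]])) + 1e-12)
    }
  }
  expect_error(entropy(p4, "nope"), "unknown")
})

test_that("mutual information reproduces the XOR decomposition", {
  x <- xor_table()
  expect_equal(mutual_information(x, "X1", "Y"), 0)
  expect_equal(mutual_information(x, "X2", "Y"), 0)
  expect_equal(mutual_information(x, c("X1", "X2"), "Y"), 1)
  coins <- prob_table(expand.grid(X = 0:1, Z = 0:1), rep(0.25, 4))
  expect_equal(mutual_information(coins, "X", "Z"), 0)
  expect_error(mutual_information(x, c("X1", "Y"), "Y"), "disjoint")
})

test_that("mutual information is symmetric and non-negative", {
  for (seed in 1:10) {
    p <- random_table(seed)
    ab <- mutual_information(p, "X", c("Z", "Y"))
    ba <- mutual_information(p, c("Z", "Y"), "X")
    expect_equal(ab, ba, tolerance = 1e-12)
    expect_gte(ab, 0)
  }
})

test_that("conditional MI satisfies the chain rule", {
  x <- xor_table()
  expect_equal(conditional_mutual_information(x, "Y", "X2", "X1"), 1)
  expect_equal(
    conditional_mutual_information(independent_table(), "X1", "X2", "Y"), 0)
  for (seed in 1:10) {
    p <- random_table(seed)
    lhs <- conditional_mutual_information(p, "X", "Z", "Y") +
      mutual_information(p, "X", "Y")
    expect_equal(lhs, mutual_information(p, "X", c("Z", "Y")),
                 tolerance = 1e-9)
  }
  expect_error(conditional_mutual_information(x, "Y", "X2", "Y"), "disjoint")
})

test_that("marginalize sums dropped variables and keeps mass normalized", {
  x <- xor_table()
  my <- marginalize(x, "Y")
  expect_equal(sort(my$mass$p), c(0.5, 0.5))
  all3 <- marginalize(x, c("X1", "X2", "Y"))
  expect_equal(sum(all3$mass$p), 1)
  expect_equal(nrow(all3$mass), 4)
  # value frequencies of the toy matrix: 8, 6 and 2 of the 16 cells
  land <- toy_landscape()
  enc <- toy_encoders("direct")
  joint <- induced_joint(land, build_decoder(land, enc$b, enc$c))
  ma <- marginalize(joint, "A")
  expect_equal(ma$mass$p[order(ma$mass$A)], c(0.5, 0.375, 0.125))
  expect_error(marginalize(x, character(0)), "at least one")
})

test_that("probability tables validate their invariants", {
  expect_error(prob_table(data.frame(X = 1:2), c(0.6, 0.6)), "sum to 1")
  expect_error(prob_table(data.frame(X = 1:2), c(1.2, -0.2)), "non-negative")
  expect_error(prob_table(data.frame(X = 1:2), c(0.5, 0.5),
                          alphabets = list(X = 1)), "outside")
  expect_error(prob_table(data.frame(X = 1:2), c(0.5, 0.5),
                          alphabets = list(X = c(1, 1, 2))), "duplicates")
  # duplicate outcome tuples collapse
  p <- prob_table(data.frame(X = c(1, 1, 2)), c(0.25, 0.25, 0.5))
  expect_equal(nrow(p$mass), 2)
})

test_that("spatial entropy matches direct evaluation and its symmetries", {
  expect_equal(spatial_entropy(spatial_support(3.7, 1)), 0)
  two <- spatial_support(c(0, 4), c(0.5, 0.5))
  expect_equal(spatial_entropy(two), 4)
  # direct-strategy sensory estimates collapse to the single value 2.5
  land <- toy_landscape()
  enc <- toy_encoders("direct")
  est <- estimates(build_decoder(land, enc$b, enc$c), land)
  expect_equal(spatial_entropy(value_support(est$sensory_b)), 0)
  # translation invariance and linear scaling
  set.seed(4)
  pts <- stats::runif(5); pr <- rep(0.2, 5)
  h0 <- spatial_entropy(spatial_support(pts, pr))
  expect_equal(spatial_entropy(spatial_support(pts + 11.3, pr)), h0)
  expect_equal(spatial_entropy(spatial_support(3 * pts, pr)), 3 * h0)
  expect_error(spatial_support(numeric(0), numeric(0)), "at least one")
})

test_that("probability tables round-trip through JSON", {
  p <- toy_signal_joint("direct")
  path <- withr::local_tempfile(fileext = ".json")
  write_prob_table(p, path)
  q <- read_prob_table(path)
  expect_equal(q$vars, p$vars)
  ord_p <- do.call(order, p$mass[p$vars])
  ord_q <- do.call(order, q$mass[q$vars])
  expect_equal(q$mass[ord_q, ], p$mass[ord_p, ], ignore_attr = TRUE)
  # reader enforces invariants
  bad <- jsonlite::read_json(path, simplifyVector = FALSE)
  bad$mass[[1]][[2]] <- 0.9
  bad_path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(bad, bad_path, auto_unbox = TRUE, digits = NA)
  expect_error(read_prob_table(bad_path), "sum to 1")
})
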