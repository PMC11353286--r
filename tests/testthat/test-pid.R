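test_that("XOR is fully synergistic", {
  s <- synergy(pid_problem(xor_table(), list("X1", "X2"), "Y"))
  expect_equal(s$joint_mi, 1)
  expect_equal(s$source_mi, c(0, 0))
  expect_equal(s$union, 0, tolerance = 1e-4)
  expect_equal(s$synergy, 1, tolerance = 1e-4)
  expect_equal(s$wms, 1)
  expect_equal(s$smax_synergy, 1)
})

test_that("a copied target pins union information to the informative source", {
  prob <- pid_problem(copy_table(), list("X1", "X2"), "Y")
  un <- union_information(prob)
  expect_equal(un$value, mutual_information(copy_table(), "X1", "Y"),
               tolerance = 1e-4)
  expect_equal(union_information_oracle(prob), 1, tolerance = 1e-3)
  expect_equal(synergy(prob)$synergy, 0, tolerance = 1e-4)
})

test_that("toy-landscape signal joints give the published synergies", {
  s_dir <- synergy(pid_problem(toy_signal_joint("direct"),
                               list("ZB", "ZC"), "A"))
  expect_equal(s_dir$synergy, 0.25, tolerance = 1e-2)
  expect_equal(s_dir$union, s_dir$joint_mi - 0.25, tolerance = 1e-2)
  s_ind <- synergy(pid_problem(toy_signal_joint("indirect"),
                               list("ZB", "ZC"), "A"))
  expect_equal(s_ind$synergy, 1, tolerance = 1e-2)
  expect_equal(s_ind$joint_mi, 1, tolerance = 1e-9)
})

test_that("solver and grid oracle agree on all small fixtures", {
  fixtures <- list(
    pid_problem(xor_table(), list("X1", "X2"), "Y"),
    pid_problem(copy_table(), list("X1", "X2"), "Y"),
    pid_problem(independent_table(), list("X1", "X2"), "Y"),
    pid_problem(toy_signal_joint("direct"), list("ZB", "ZC"), "A"),
    pid_problem(toy_signal_joint("indirect"), list("ZB", "ZC"), "A"),
    pid_problem(random_table(1, c("X1", "X2", "Y")), list("X1", "X2"), "Y"),
    pid_problem(random_table(2, c("X1", "X2", "Y")), list("X1", "X2"), "Y"))
  for (prob in fixtures) {
    solver <- union_information(prob)$value
    oracle <- union_information_oracle(prob)
    expect_lt(abs(solver - oracle), 1e-2)
    expect_gte(oracle, solver - 1e-2)    # both minimize the same objective
  }
})

test_that("pid summaries satisfy the decomposition invariants", {
  fixtures <- list(
    pid_problem(xor_table(), list("X1", "X2"), "Y"),
    pid_problem(copy_table(), list("X1", "X2"), "Y"),
    pid_problem(toy_signal_joint("direct"), list("ZB", "ZC"), "A"),
    pid_problem(random_table(3, c("X1", "X2", "Y")), list("X1", "X2"), "Y"),
    pid_problem(random_table(4, c("X1", "X2", "Y")), list("X1", "X2"), "Y"))
  for (prob in fixtures) {
    s <- synergy(prob)
    expect_equal(s$synergy, s$joint_mi - s$union, tolerance = 1e-4)
    expect_gte(s$synergy, 0)
    expect_lte(s$synergy, s$joint_mi + 1e-9)
    expect_lte(s$wms, s$synergy + 1e-3)
    expect_gte(s$smax_synergy, s$synergy - 1e-3)
    expect_gte(s$union, max(s$source_mi) - 1e-4)
    expect_lte(s$union, s$joint_mi + 1e-9)
    expect_lte(s$residual, 1e-8)
  }
})

test_that("WMS and Smax behave on the degenerate cases", {
  ind <- pid_problem(independent_table(), list("X1", "X2"), "Y")
  expect_equal(wms_synergy(ind), 0, tolerance = 1e-12)
  expect_equal(smax_synergy(ind), 0, tolerance = 1e-12)
  # direct toy: WMS = joint - 2 * source MI, well below the synergy of 0.25
  d <- toy_signal_joint("direct")
  prob <- pid_problem(d, list("ZB", "ZC"), "A")
  joint_mi <- mutual_information(d, c("ZB", "ZC"), "A")
  src <- mutual_information(d, "ZB", "A")
  expect_equal(wms_synergy(prob), joint_mi - 2 * src, tolerance = 1e-12)
  expect_equal(wms_synergy(prob), 0.0944, tolerance = 1e-3)
  expect_lte(wms_synergy(prob), 0.25)
})

test_that("adding a deterministic copy of a source never increases synergy", {
  base <- list(xor_table(), copy_table(),
               random_table(5, c("X1", "X2", "Y")))
  for (p in base) {
    m <- p$mass
    m$X1copy <- m$X1
    p3 <- prob_table(m[c("X1", "X2", "X1copy", "Y")], m$p)
    s2 <- synergy(pid_problem(p, list("X1", "X2"), "Y"))
    s3 <- synergy(pid_problem(p3, list("X1", "X2", "X1copy"), "Y"))
    expect_lte(s3$synergy, s2$synergy + 1e-3)
  }
})

test_that("pid problems validate their structure and the oracle refuses big ones", {
  x <- xor_table()
  expect_error(pid_problem(x, list("X1"), "Y"), "two source groups")
  expect_error(pid_problem(x, list("X1", "X1"), "Y"), "disjoint")
  expect_error(pid_problem(x, list("X1", "Y"), "Y"), "disjoint")
  big <- prob_table(expand.grid(X1 = 1:5, X2 = 1:5, Y = 1:5),
                    rep(1 / 125, 125))
  expect_error(union_information_oracle(pid_problem(big, list("X1", "X2"),
                                                    "Y")),
               "refused")
})
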