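test_that("row and column expectations match the worked example", {
  land <- toy_landscape()
  expect_equal(row_expectations(land), c(0.5, 0.75, 0.75, 0.5))
  expect_equal(column_expectations(land), c(0.5, 0.75, 0.75, 0.5))
  const <- affordance_landscape(matrix(3.2, 3, 5))
  expect_equal(row_expectations(const), rep(3.2, 3))
})

test_that("the conditional-expectation decoder averages signal preimages", {
  land <- toy_landscape()
  enc <- toy_encoders("direct")
  pair <- build_decoder(land, enc$b, enc$c)
  expect_equal(pair$decoder_table[1, 2], 0.5)   # D(ZB=0, ZC=1)
  # identity encoders reproduce the matrix exactly
  id <- encoder_map(0:3, 4)
  pid_pair <- build_decoder(land, id, id)
  expect_equal(pid_pair$decoder_table, land$matrix)
  # indirect D(0,1) averages a13, a14, a23, a24
  enc_i <- toy_encoders("indirect")
  pair_i <- build_decoder(land, enc_i$b, enc_i$c)
  expect_equal(pair_i$decoder_table[1, 2], 1.25)
  # empty preimages are flagged unused
  collapsed <- build_decoder(land, encoder_map(rep(0L, 4), 2), enc$c)
  expect_false(any(collapsed$used[2, ]))
  expect_true(all(is.na(collapsed$decoder_table[2, ])))
})

test_that("estimates reproduce the worked sensory and unidimensional values", {
  land <- toy_landscape()
  enc_d <- toy_encoders("direct")
  est_d <- estimates(build_decoder(land, enc_d$b, enc_d$c), land)
  expect_equal(est_d$sensory_b, rep(2.5, 4))
  expect_equal(est_d$unidim_b, c(0.5, 0.75, 0.75, 0.5))
  enc_i <- toy_encoders("indirect")
  est_i <- estimates(build_decoder(land, enc_i$b, enc_i$c), land)
  expect_equal(est_i$sensory_b, c(1.5, 1.5, 3.5, 3.5))
  expect_equal(est_i$unidim_b, rep(0.625, 4))
})

test_that("mse matches the published distortions", {
  land <- toy_landscape()
  for (s in c("direct", "indirect")) {
    enc <- toy_encoders(s)
    est <- estimates(build_decoder(land, enc$b, enc$c), land)
    expect_equal(mse(land$matrix, est$affordance_estimate),
                 if (s == "direct") 0.4375 else 0.09375)
  }
  expect_equal(mse(land$matrix, land$matrix), 0)
  expect_error(mse(land$matrix, 1:3), "identical shape")
})

test_that("the induced joint carries the model's distributions", {
  land <- toy_landscape()
  enc <- toy_encoders("direct")
  joint <- induced_joint(land, build_decoder(land, enc$b, enc$c))
  expect_equal(sum(joint$mass$p), 1)
  ma <- marginalize(joint, "A")
  expect_equal(ma$mass$p[order(ma$mass$A)], c(0.5, 0.375, 0.125))
  # data processing along the Markov chain
  for (seed in 1:5) {
    land_r <- random_landscape(seed)
    pr <- build_decoder(land_r, random_encoder(seed, 4, 2),
                        random_encoder(seed + 100, 4, 2))
    j <- induced_joint(land_r, pr)
    i_est <- mutual_information(j, "A", "Ahat")
    i_sig <- mutual_information(j, c("ZB", "ZC"), "A")
    i_obs <- mutual_information(j, c("OB", "OC"), "A")
    expect_lte(i_est, i_sig + 1e-9)
    expect_lte(i_sig, i_obs + 1e-9)
  }
})

test_that("metric reports reproduce both strategy rows", {
  land <- toy_landscape()
  enc_d <- toy_encoders("direct")
  md <- metrics_report(land, build_decoder(land, enc_d$b, enc_d$c))
  expect_equal(md$mse_affordance, 0.4375)
  expect_equal(md$synergy, 0.25, tolerance = 1e-2)
  expect_equal(c(md$mi_sensory_b, md$mi_sensory_c), c(0, 0))
  expect_equal(c(md$mi_unidim_b, md$mi_unidim_c), c(1, 1))
  expect_equal(c(md$spatial_entropy_b, md$spatial_entropy_c), c(0, 0))
  enc_i <- toy_encoders("indirect")
  mi <- metrics_report(land, build_decoder(land, enc_i$b, enc_i$c))
  expect_equal(mi$mse_affordance, 0.09375)
  expect_equal(mi$synergy, 1, tolerance = 1e-2)
  expect_equal(c(mi$mi_sensory_b, mi$mi_sensory_c), c(1, 1))
  expect_equal(c(mi$mi_unidim_b, mi$mi_unidim_c), c(0, 0))
  # the trade-off: direct attains I(AB;ABhat)=1 at I(OB;OBhat)=0,
  # indirect the reverse
  expect_identical(c(md$mi_unidim_b, md$mi_sensory_b), c(1, 0))
  expect_identical(c(mi$mi_unidim_b, mi$mi_sensory_b), c(0, 1))
  # lossless regime
  id <- encoder_map(0:3, 4)
  ml <- metrics_report(land, build_decoder(land, id, id))
  expect_equal(ml$mse_affordance, 0)
  expect_equal(ml$mi_sensory_b, 2)
})

test_that("the conditional-mean decoder is a local MSE minimum", {
  for (seed in 1:3) {
    land <- random_landscape(seed)
    pair <- build_decoder(land, random_encoder(seed, 4, 2),
                          random_encoder(seed + 50, 4, 2))
    base <- mse(land$matrix, estimates(pair, land)$affordance_estimate)
    zb <- pair$encoder_b$assignment + 1L
    zc <- pair$encoder_c$assignment + 1L
    for (i in seq_len(nrow(pair$decoder_table))) {
      for (j in seq_len(ncol(pair$decoder_table))) {
        if (!pair$used[i, j]) next
        for (eps in c(-1e-3, 1e-3)) {
          tab <- pair$decoder_table
          tab[i, j] <- tab[i, j] + eps
          expect_gte(mse(land$matrix, tab[zb, zc]), base)
        }
      }
    }
  }
})

test_that("refining a signal's preimage never increases the optimal MSE", {
  for (seed in 1:5) {
    land <- random_landscape(seed, m = 5, n = 4)
    enc_b <- random_encoder(seed, 5, 2)
    enc_c <- random_encoder(seed + 7, 4, 2)
    base <- mse_indirect(enc_b, enc_c, land)
    sig <- which(tabulate(enc_b$assignment + 1L, 2) >= 2)[1]
    split_idx <- which(enc_b$assignment == sig - 1L)[1]
    refined <- enc_b$assignment
    refined[split_idx] <- 2L               # new third signal
    expect_lte(mse_indirect(encoder_map(refined, 3), enc_c, land),
               base + 1e-12)
  }
})

test_that("landscapes and encoders validate and round-trip their files", {
  expect_error(affordance_landscape(matrix(1, 1, 4)), "at least 2 x 2")
  expect_error(affordance_landscape(matrix(c(1, NA, 2, 3), 2, 2)), "finite")
  expect_error(encoder_map(c(0, 2), 2), "0..L-1")
  expect_error(encoder_map(c(0, NA), 2), "complete")
  land <- toy_landscape()
  csv <- withr::local_tempfile(fileext = ".csv")
  write_landscape(land, csv)
  expect_equal(read_landscape(csv)$matrix, land$matrix)
  enc <- encoder_map(c(0L, 1L, 1L, 0L), 2)
  js <- withr::local_tempfile(fileext = ".json")
  write_encoder(enc, js)
  back <- read_encoder(js)
  expect_equal(back$assignment, enc$assignment)
  expect_equal(back$L, enc$L)
})
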