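#' Direct-strategy objective for a single encoder
#'
#' The direct strategy maximizes per-modality affordance information, which
#' (under a Gaussian surrogate for the conditional) is equivalent to
#' minimizing the mean squared error between the unidimensional affordance
#' vector and its per-signal-mean reconstruction: signals are decoded as
#' the mean of the row (or column) affordance expectations over their
#' preimage.
#'
#' @param encoder an [encoder_map()] over the axis.
#' @param unidim_affordance the axis's affordance expectation vector
#'   ([row_expectations()] or [column_expectations()]).
#' @return The reconstruction MSE (squared affordance units).
#' @export
mse_direct <- function(encoder, unidim_affordance) {
  stopifnot(inherits(encoder, "encoder_map"))
  z <- encoder$assignment + 1L
  if (length(z) != length(unidim_affordance)) {
    stop("encoder length must equal the affordance vector length")
  }
  dec <- rowsum_full(unidim_affordance, z, encoder$L) /
    tabulate(z, encoder$L)
  mean((unidim_affordance - dec[z])^2)
}

#' Indirect-strategy objective for an encoder pair
#'
#' The joint affordance reconstruction error: the MSE between the landscape
#' and the conditional-expectation decoder's estimate under the given
#' encoder pair. This is the quantity the indirect strategy minimizes
#' directly.
#'
#' @param encoder_b,encoder_c [encoder_map()]s.
#' @param land an [affordance_landscape()].
#' @return The affordance MSE.
#' @export
mse_indirect <- function(encoder_b, encoder_c, land) {
  stopifnot(inherits(land, "affordance_landscape"))
  mse_indirect_fast(encoder_b$assignment + 1L, encoder_b$L,
                    encoder_c$assignment + 1L, encoder_c$L, land$matrix)
}

# hot path shared with the optimizer: 1-based signal vectors, no class
# dispatch or validation
mse_indirect_fast <- function(zb, LB, zc, LC, A) {
  cb <- tabulate(zb, LB); cc <- tabulate(zc, LC)
  sums <- matrix(0, LB, ncol(A))
  sums[sort(unique(zb)), ] <- rowsum(A, zb)
  sums2 <- matrix(0, LB, LC)
  sums2[, sort(unique(zc))] <- t(rowsum(t(sums), zc))
  decoder <- sums2 / outer(cb, cc)
  mean((A - decoder[zb, zc])^2)
}

mse_direct_fast <- function(z, L, v) {
  dec <- rowsum_full(v, z, L) / tabulate(z, L)
  mean((v - dec[z])^2)
}

#' Stochastic hill climbing over encoder assignments
#'
#' Runs `runs` independent restarts from uniformly random assignments. At
#' each step, every encoder proposes reassigning one uniformly random
#' observation to a uniformly random signal; the proposals are accepted as
#' a unit if and only if the objective strictly decreases (ties are
#' rejected). Traces are therefore non-increasing, and the whole procedure
#' is a pure function of `seed`.
#'
#' @param objective function taking a list of 0-based assignment vectors
#'   and returning the value to minimize.
#' @param n_obs integer vector: number of observation states per encoder.
#' @param L integer vector: signal-alphabet size per encoder.
#' @param runs number of random restarts.
#' @param steps optimization steps per run; `steps = 0` evaluates the
#'   random starting encoders only.
#' @param seed integer seed (mandatory; no silent clock seeding).
#' @return A list of class `strategy_result`: `best_encoders` (list of
#'   [encoder_map()]), `best_value`, `traces` (one numeric vector of length
#'   `steps + 1` per run), `seed`.
#' @export
hill_climb <- function(objective, n_obs, L, runs = 20,
                       steps = 100 * max(n_obs), seed) {
  if (missing(seed)) stop("a seed is required")
  if (runs < 1 || steps < 0) stop("runs must be >= 1 and steps >= 0")
  stopifnot(length(n_obs) == length(L))
  ne <- length(n_obs)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  best_value <- Inf
  best_enc <- NULL
  traces <- vector("list", runs)
  for (run in seq_len(runs)) {
    enc <- lapply(seq_len(ne), function(e) {
      sample.int(L[e], n_obs[e], replace = TRUE) - 1L
    })
    value <- objective(enc)
    trace <- numeric(steps + 1)
    trace[1] <- value
    if (steps > 0) for (s in seq_len(steps)) {
      prop <- enc
      for (e in seq_len(ne)) {
        i <- sample.int(n_obs[e], 1L)
        prop[[e]][i] <- sample.int(L[e], 1L) - 1L
      }
      v <- objective(prop)
      if (v < value) {
        enc <- prop
        value <- v
      }
      trace[s + 1] <- value
    }
    traces[[run]] <- trace
    if (value < best_value) {
      best_value <- value
      best_enc <- enc
    }
  }
  structure(list(
    best_encoders = lapply(seq_len(ne), function(e) {
      encoder_map(best_enc[[e]], L[e])
    }),
    best_value = best_value, traces = traces, seed = seed),
    class = "strategy_result")
}

#' Optimize a landscape's encoders under one strategy
#'
#' Direct: each axis encoder is optimized independently against its own
#' unidimensional affordance vector ([mse_direct()]). Indirect: the pair is
#' optimized jointly against the full affordance MSE ([mse_indirect()]),
#' with both encoders proposing one move per step, accepted or rejected as
#' a unit.
#'
#' @param land an [affordance_landscape()].
#' @param strategy `"direct"` or `"indirect"`.
#' @param L_B,L_C signal counts for the two axes.
#' @param runs,steps hill-climbing budget (see [hill_climb()]).
#' @param seed integer seed.
#' @return A list with `strategy`, `encoder_b`, `encoder_c`, the per-axis
#'   or joint `objective` value(s), and the underlying [hill_climb()]
#'   result(s).
#' @export
optimize_strategy <- function(land, strategy = c("direct", "indirect"),
                              L_B, L_C, runs = 20,
                              steps = 100 * max(dim(land$matrix)), seed) {
  stopifnot(inherits(land, "affordance_landscape"))
  strategy <- match.arg(strategy)
  A <- land$matrix
  m <- nrow(A); n <- ncol(A)
  if (strategy == "direct") {
    ab <- row_expectations(land)
    ac <- column_expectations(land)
    res_b <- hill_climb(function(enc) mse_direct_fast(enc[[1]] + 1L, L_B, ab),
                        m, L_B, runs, steps, seed = seed)
    res_c <- hill_climb(function(enc) mse_direct_fast(enc[[1]] + 1L, L_C, ac),
                        n, L_C, runs, steps, seed = seed + 1L)
    list(strategy = "direct",
         encoder_b = res_b$best_encoders[[1]],
         encoder_c = res_c$best_encoders[[1]],
         objective = c(b = res_b$best_value, c = res_c$best_value),
         runs = list(b = res_b, c = res_c))
  } else {
    res <- hill_climb(function(enc) {
      mse_indirect_fast(enc[[1]] + 1L, L_B, enc[[2]] + 1L, L_C, A)
    }, c(m, n), c(L_B, L_C), runs, steps, seed = seed)
    list(strategy = "indirect",
         encoder_b = res$best_encoders[[1]],
         encoder_c = res$best_encoders[[2]],
         objective = res$best_value,
         runs = list(joint = res))
  }
}

#' Exhaustive search over encoder assignments
#'
#' Enumerates every assignment (or assignment pair) and returns the global
#' optimum; used to certify hill-climbing results on small instances. The
#' search space `prod(L^n_obs)` must not exceed `1e6`.
#'
#' @inheritParams hill_climb
#' @return A list with `best_encoders` (list of [encoder_map()]) and
#'   `best_value`.
#' @export
exhaustive_search <- function(objective, n_obs, L) {
  stopifnot(length(n_obs) == length(L))
  sizes <- as.numeric(L)^as.numeric(n_obs)
  if (prod(sizes) > 1e6) {
    stop(sprintf("search space of %.3g assignments exceeds 1e6",
                 prod(sizes)))
  }
  ne <- length(n_obs)
  decode <- function(idx, m, L) {
    out <- integer(m)
    for (i in seq_len(m)) {
      out[i] <- idx %% L
      idx <- idx %/% L
    }
    out
  }
  best_value <- Inf
  best <- NULL
  counts <- prod(sizes)
  for (flat in seq_len(counts) - 1) {
    rest <- flat
    enc <- vector("list", ne)
    for (e in seq_len(ne)) {
      enc[[e]] <- decode(rest %% sizes[e], n_obs[e], L[e])
      rest <- rest %/% sizes[e]
    }
    v <- objective(enc)
    if (v < best_value) {
      best_value <- v
      best <- enc
    }
  }
  list(best_encoders = lapply(seq_len(ne), function(e) {
    encoder_map(best[[e]], L[e])
  }), best_value = best_value)
}
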