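#' Affordance landscapes
#'
#' An affordance landscape is an `m x n` real matrix `A` whose two axes are
#' ambient energy arrays: entry `a[b, c]` is the affordance value realized
#' when the row array is in state `obs_b[b]` and the column array in state
#' `obs_c[c]`. Observation states are jointly uniform over cells.
#'
#' @param matrix numeric `m x n` matrix with `m, n >= 2` and finite entries.
#' @param obs_b,obs_c numeric observation-state values for the row and
#'   column axes; default to `1..m` and `1..n`.
#' @return An object of class `affordance_landscape`.
#' @examples
#' land <- toy_landscape()
#' row_expectations(land)
#' @export
affordance_landscape <- function(matrix,
                                 obs_b = seq_len(nrow(matrix)),
                                 obs_c = seq_len(ncol(matrix))) {
  matrix <- as.matrix(matrix)
  storage.mode(matrix) <- "double"
  if (nrow(matrix) < 2L || ncol(matrix) < 2L) {
    stop("landscape must be at least 2 x 2")
  }
  if (any(!is.finite(matrix))) stop("landscape entries must be finite")
  if (length(obs_b) != nrow(matrix) || length(obs_c) != ncol(matrix)) {
    stop("observation axes must match the matrix dimensions")
  }
  dimnames(matrix) <- NULL
  structure(list(matrix = matrix, obs_b = as.numeric(obs_b),
                 obs_c = as.numeric(obs_c)),
            class = "affordance_landscape")
}

#' @export
print.affordance_landscape <- function(x, ...) {
  cat(sprintf("affordance_landscape: %d x %d, values in [%g, %g]\n",
              nrow(x$matrix), ncol(x$matrix), min(x$matrix), max(x$matrix)))
  invisible(x)
}

#' Read / write a landscape as a plain numeric matrix
#'
#' CSV/TSV, row-major, no header; the reader validates finiteness.
#'
#' @param path file path.
#' @param sep field separator (`","` or `"\t"`, inferred from the extension
#'   by default).
#' @param land an [affordance_landscape()].
#' @return `read_landscape` returns an `affordance_landscape`.
#' @export
read_landscape <- function(path, sep = NULL) {
  if (is.null(sep)) sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  m <- as.matrix(utils::read.table(path, sep = sep, header = FALSE))
  affordance_landscape(m)
}

#' @rdname read_landscape
#' @export
write_landscape <- function(land, path, sep = NULL) {
  stopifnot(inherits(land, "affordance_landscape"))
  if (is.null(sep)) sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  utils::write.table(land$matrix, path, sep = sep, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Capacity-limited encoder maps
#'
#' A deterministic, total assignment of each observation state of one axis
#' to one of `L` signals (signals are labelled `0..L-1`). The
#' capacity-limited regime of interest has `L` smaller than the number of
#' observation states, so several states share a signal.
#'
#' @param assignment integer vector; entry `b` is the signal of observation
#'   state `b`.
#' @param L signal-alphabet size (`L = 2^R` for a rate of `R` bits).
#' @return An object of class `encoder_map`.
#' @examples
#' encoder_map(c(0, 1, 1, 0), L = 2)  # groups states {1,4} and {2,3}
#' @export
encoder_map <- function(assignment, L) {
  assignment <- as.integer(assignment)
  L <- as.integer(L)
  if (L < 1L) stop("L must be at least 1")
  if (length(assignment) < 1L || anyNA(assignment)) {
    stop("assignment must be a complete integer vector")
  }
  if (any(assignment < 0L | assignment >= L)) {
    stop("signals must lie in 0..L-1")
  }
  structure(list(assignment = assignment, L = L), class = "encoder_map")
}

#' Read / write an encoder as JSON
#'
#' Format: `{"L": int, "assignment": [ints]}`.
#' @param enc an [encoder_map()].
#' @param path file path.
#' @export
write_encoder <- function(enc, path) {
  stopifnot(inherits(enc, "encoder_map"))
  jsonlite::write_json(list(L = enc$L, assignment = enc$assignment), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_encoder
#' @export
read_encoder <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  encoder_map(obj$assignment, obj$L)
}

#' Row / column affordance expectations
#'
#' The unidimensional affordance value seen by the row-axis encoder:
#' `A_B[b]` is the mean affordance over the columns (and symmetrically
#' `A_C[c]` over the rows).
#'
#' @param land an [affordance_landscape()].
#' @return `row_expectations`: numeric vector of length `m`;
#'   `column_expectations`: length `n`.
#' @export
row_expectations <- function(land) {
  stopifnot(inherits(land, "affordance_landscape"))
  rowMeans(land$matrix)
}

#' @rdname row_expectations
#' @export
column_expectations <- function(land) {
  stopifnot(inherits(land, "affordance_landscape"))
  colMeans(land$matrix)
}

#' Build the conditional-expectation decoder for an encoder pair
#'
#' For encoders `E_B`, `E_C`, the decoder maps a signal pair `(i, j)` to the
#' mean affordance over the Cartesian product of the two signal preimages
#' (the MSE-optimal decoder for fixed encoders). Also builds the per-signal
#' sensory decoders (mean observation value over the preimage) and the
#' unidimensional affordance decoders (mean of the row/column expectation
#' vector over the preimage). Signals with empty preimage yield unused
#' decoder cells, which may exist transiently during optimization but must
#' never be looked up.
#'
#' @param land an [affordance_landscape()].
#' @param encoder_b,encoder_c [encoder_map()]s for the row and column axes.
#' @return An object of class `coding_pair` with the decoder tables.
#' @export
build_decoder <- function(land, encoder_b, encoder_c) {
  stopifnot(inherits(land, "affordance_landscape"),
            inherits(encoder_b, "encoder_map"),
            inherits(encoder_c, "encoder_map"))
  m <- nrow(land$matrix); n <- ncol(land$matrix)
  if (length(encoder_b$assignment) != m || length(encoder_c$assignment) != n) {
    stop("encoder lengths must match the landscape axes")
  }
  zb <- encoder_b$assignment + 1L; zc <- encoder_c$assignment + 1L
  LB <- encoder_b$L; LC <- encoder_c$L
  cb <- tabulate(zb, LB); cc <- tabulate(zc, LC)
  sums <- matrix(0, LB, n)
  sums[sort(unique(zb)), ] <- rowsum(land$matrix, zb)
  sums2 <- matrix(0, LB, LC)
  sums2[, sort(unique(zc))] <- t(rowsum(t(sums), zc))
  counts <- outer(cb, cc)
  decoder <- sums2 / counts
  decoder[counts == 0] <- NA_real_
  sens_b <- as.numeric(rowsum_full(land$obs_b, zb, LB) / cb)
  sens_c <- as.numeric(rowsum_full(land$obs_c, zc, LC) / cc)
  uni_b <- as.numeric(rowsum_full(row_expectations(land), zb, LB) / cb)
  uni_c <- as.numeric(rowsum_full(column_expectations(land), zc, LC) / cc)
  structure(list(encoder_b = encoder_b, encoder_c = encoder_c,
                 decoder_table = decoder, used = counts > 0,
                 sensory_decoder_b = sens_b, sensory_decoder_c = sens_c,
                 unidim_decoder_b = uni_b, unidim_decoder_c = uni_c),
            class = "coding_pair")
}

rowsum_full <- function(x, group, L) {
  out <- rep(NA_real_, L)
  out[sort(unique(group))] <- rowsum(x, group)
  out
}

#' Estimates induced by a coding pair
#'
#' Pushes every landscape cell through encode-then-decode: the affordance
#' estimate matrix (constant on each preimage block), the sensory estimates
#' of both axes, and the unidimensional affordance estimates.
#'
#' @param pair a [build_decoder()] result.
#' @param land the landscape the pair was built on.
#' @return A list with `affordance_estimate` (m x n), `sensory_b`,
#'   `sensory_c`, `unidim_b`, `unidim_c`.
#' @export
estimates <- function(pair, land) {
  stopifnot(inherits(pair, "coding_pair"),
            inherits(land, "affordance_landscape"))
  zb <- pair$encoder_b$assignment + 1L
  zc <- pair$encoder_c$assignment + 1L
  if (any(!pair$used[cbind(rep(zb, times = length(zc)),
                           rep(zc, each = length(zb)))])) {
    stop("internal inconsistency: a landscape cell maps to an unused cell")
  }
  ahat <- pair$decoder_table[zb, zc, drop = FALSE]
  list(affordance_estimate = ahat,
       sensory_b = pair$sensory_decoder_b[zb],
       sensory_c = pair$sensory_decoder_c[zc],
       unidim_b = pair$unidim_decoder_b[zb],
       unidim_c = pair$unidim_decoder_c[zc])
}

#' Mean squared error between truth and estimate
#'
#' @param truth,estimate numeric arrays of identical shape.
#' @return Mean of squared elementwise differences (squared affordance
#'   units).
#' @export
mse <- function(truth, estimate) {
  if (!identical(dim(truth), dim(estimate)) ||
      length(truth) != length(estimate)) {
    stop("truth and estimate must have identical shape")
  }
  mean((truth - estimate)^2)
}

#' Joint distribution induced by a coding pair
#'
#' Pushes the uniform cell distribution through the deterministic maps,
#' giving the joint table over observation states (`OB`, `OC`), the
#' affordance value `A`, signals (`ZB`, `ZC`) and the decoded estimate
#' `Ahat`. Every quantity the strategies are scored on is a marginal of
#' this table.
#'
#' @param land an [affordance_landscape()].
#' @param pair a [build_decoder()] result on `land`.
#' @return A [prob_table()] over `OB, OC, A, ZB, ZC, Ahat`.
#' @export
induced_joint <- function(land, pair) {
  stopifnot(inherits(land, "affordance_landscape"),
            inherits(pair, "coding_pair"))
  est <- estimates(pair, land)
  m <- nrow(land$matrix); n <- ncol(land$matrix)
  b <- rep(seq_len(m), times = n); c <- rep(seq_len(n), each = m)
  outcomes <- data.frame(
    OB = land$obs_b[b],
    OC = land$obs_c[c],
    A = as.vector(land$matrix),
    ZB = pair$encoder_b$assignment[b],
    ZC = pair$encoder_c$assignment[c],
    Ahat = as.vector(est$affordance_estimate))
  prob_table(outcomes, rep(1 / (m * n), m * n))
}

#' Full metric report for a coding pair
#'
#' Computes the eight quantities used to compare strategies: the affordance
#' MSE; the synergy of the two signal variables about the raw affordance
#' value `A`; the sensory mutual informations `I(OB; OBhat)`, `I(OC;
#' OChat)`; the unidimensional affordance informations `I(AB; ABhat)`,
#' `I(AC; AChat)`; and the spatial entropies of the two sensory-estimate
#' supports. All are derived from the induced joint distribution; values
#' are stored at full precision (round only when rendering).
#'
#' @param land an [affordance_landscape()].
#' @param pair a [build_decoder()] result on `land`.
#' @param pid_tolerance tolerance handed to the synergy solver, in bits.
#' @return A list of class `metrics_report`.
#' @export
metrics_report <- function(land, pair, pid_tolerance = 1e-4) {
  stopifnot(inherits(land, "affordance_landscape"),
            inherits(pair, "coding_pair"))
  est <- estimates(pair, land)
  joint <- induced_joint(land, pair)
  syn <- synergy(pid_problem(joint, list("ZB", "ZC"), "A"),
                 tolerance = pid_tolerance)
  m <- nrow(land$matrix); n <- ncol(land$matrix)
  sens_b <- prob_table(data.frame(OB = land$obs_b, OBhat = est$sensory_b),
                       rep(1 / m, m))
  sens_c <- prob_table(data.frame(OC = land$obs_c, OChat = est$sensory_c),
                       rep(1 / n, n))
  uni_b <- prob_table(data.frame(AB = row_expectations(land),
                                 ABhat = est$unidim_b), rep(1 / m, m))
  uni_c <- prob_table(data.frame(AC = column_expectations(land),
                                 AChat = est$unidim_c), rep(1 / n, n))
  structure(list(
    mse_affordance = mse(land$matrix, est$affordance_estimate),
    synergy = syn$synergy,
    mi_sensory_b = mutual_information(sens_b, "OB", "OBhat"),
    mi_sensory_c = mutual_information(sens_c, "OC", "OChat"),
    mi_unidim_b = mutual_information(uni_b, "AB", "ABhat"),
    mi_unidim_c = mutual_information(uni_c, "AC", "AChat"),
    spatial_entropy_b = spatial_entropy(value_support(est$sensory_b)),
    spatial_entropy_c = spatial_entropy(value_support(est$sensory_c)),
    mse_sensory_b = mse(land$obs_b, est$sensory_b),
    mse_sensory_c = mse(land$obs_c, est$sensory_c),
    pid = syn), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(paste0("MSE(A,Ahat) %.2f | synergy %.2f | I(OB;OBhat) %.2f | ",
                     "I(OC;OChat) %.2f | I(AB;ABhat) %.2f | I(AC;AChat) %.2f\n"),
              x$mse_affordance, x$synergy, x$mi_sensory_b, x$mi_sensory_c,
              x$mi_unidim_b, x$mi_unidim_c))
  cat(sprintf("spatial entropy: B %.3f, C %.3f\n",
              x$spatial_entropy_b, x$spatial_entropy_c))
  invisible(x)
}
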