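#' Partial information decomposition problems
#'
#' Packages a joint distribution together with a choice of source groups and
#' a target for synergy analysis. Synergy is defined as the joint
#' source--target mutual information minus the union information, where
#' union information is the minimum of \eqn{I^*(X_{1..n};Y)} over all joint
#' distributions \eqn{Pr^*} that preserve every pairwise \eqn{(X_i, Y)}
#' marginal of the original distribution (the BROJA construction).
#'
#' @param joint a [prob_table()] containing all source and target variables.
#' @param sources list of at least two pairwise-disjoint character vectors,
#'   each naming the variables of one source group.
#' @param target character vector naming the target variables, disjoint from
#'   every source group.
#'
#' @return An object of class `pid_problem`.
#' @examples
#' xor <- prob_table(
#'   data.frame(X1 = c(0, 0, 1, 1), X2 = c(0, 1, 0, 1), Y = c(0, 1, 1, 0)),
#'   rep(0.25, 4)
#' )
#' prob <- pid_problem(xor, list("X1", "X2"), "Y")
#' synergy(prob)$synergy
#' @export
pid_problem <- function(joint, sources, target) {
  stopifnot(inherits(joint, "prob_table"))
  if (!is.list(sources) || length(sources) < 2L) {
    stop("at least two source groups are required")
  }
  all_names <- c(unlist(sources), target)
  check_vars(joint, all_names)
  groups <- c(sources, list(target))
  for (i in seq_along(groups)) {
    for (j in seq_along(groups)) {
      if (i < j && length(intersect(groups[[i]], groups[[j]]))) {
        stop("source groups and target must be pairwise disjoint")
      }
    }
  }
  structure(list(joint = joint, sources = sources, target = target),
            class = "pid_problem")
}

# Collapse a pid_problem to integer-coded cells: one code per source group
# and one for the target, with the joint mass aggregated over any unused
# variables. Returns codes (cells x (n+1)), mass, level counts.
pid_codes <- function(prob) {
  joint <- marginalize(prob$joint, c(unlist(prob$sources), prob$target))
  groups <- c(prob$sources, list(prob$target))
  code_of <- function(vars) {
    key <- do.call(paste, c(joint$mass[vars], sep = "\r"))
    as.integer(factor(key, levels = unique(key[order(key)])))
  }
  codes <- vapply(groups, code_of, integer(nrow(joint$mass)))
  if (is.null(dim(codes))) codes <- matrix(codes, nrow = 1)
  key <- apply(codes, 1, paste, collapse = "\r")
  mass <- as.numeric(rowsum(joint$mass$p, key, reorder = FALSE))
  keep <- !duplicated(key)
  codes <- codes[keep, , drop = FALSE]
  n <- length(prob$sources)
  list(codes = codes, mass = mass, n = n,
       levels = apply(codes, 2, max))
}

# Build the BROJA feasible polytope: support cells, the feasible
# conditional-independence start q0 = p(y) prod_i p(x_i|y), and an
# orthonormal basis N of the null space of the pairwise-marginal
# constraints, so q = q0 + N t stays feasible (up to q >= 0) exactly.
pid_polytope <- function(prob) {
  cc <- pid_codes(prob)
  n <- cc$n
  K <- cc$levels
  ky <- K[n + 1]
  # pairwise marginals p(x_i, y) and p(y)
  py <- numeric(ky)
  idxy <- cc$codes[, n + 1]
  py[sort(unique(idxy))] <- as.numeric(rowsum(cc$mass, idxy))
  pm <- lapply(seq_len(n), function(i) {
    m <- matrix(0, K[i], ky)
    sums <- rowsum(cc$mass, paste(cc$codes[, i], idxy, sep = "\r"),
                   reorder = FALSE)
    lab <- do.call(rbind, strsplit(rownames(sums), "\r", fixed = TRUE))
    m[cbind(as.integer(lab[, 1]), as.integer(lab[, 2]))] <- sums
    m
  })
  # support: cells with every pairwise marginal positive, enumerated per y
  sup <- do.call(rbind, lapply(which(py > 0), function(y) {
    ok <- lapply(seq_len(n), function(i) which(pm[[i]][, y] > 0))
    g <- as.matrix(expand.grid(ok))
    cbind(g, y)
  }))
  colnames(sup) <- NULL
  S <- nrow(sup)
  q0 <- py[sup[, n + 1]]
  for (i in seq_len(n)) {
    q0 <- q0 * pm[[i]][cbind(sup[, i], sup[, n + 1])] / py[sup[, n + 1]]
  }
  # constraint rows: one per positive (x_i, y) pairwise-marginal entry
  rows <- list(); b <- numeric(0)
  for (i in seq_len(n)) {
    pos <- which(pm[[i]] > 0, arr.ind = TRUE)
    for (r in seq_len(nrow(pos))) {
      rows[[length(rows) + 1L]] <-
        as.numeric(sup[, i] == pos[r, 1] & sup[, n + 1] == pos[r, 2])
      b <- c(b, pm[[i]][pos[r, 1], pos[r, 2]])
    }
  }
  A <- do.call(rbind, rows)
  sv <- svd(A, nu = 0, nv = ncol(A))
  rank <- sum(sv$d > max(sv$d) * 1e-10)
  N <- if (rank < ncol(A)) sv$v[, (rank + 1):ncol(A), drop = FALSE]
       else matrix(0, S, 0)
  # dense indices of the joint-source cell and target cell of each support
  # cell, used to marginalize q quickly when evaluating I(X_{1..n}; Y)
  xkey <- apply(sup[, seq_len(n), drop = FALSE], 1, paste, collapse = "\r")
  ix <- as.integer(factor(xkey))
  iy <- as.integer(factor(sup[, n + 1]))
  list(sup = sup, q0 = q0, N = N, A = A, b = b, ix = ix, iy = iy)
}

# I(X_{1..n}; Y) in bits for a mass vector q on the polytope support,
# vectorized over the columns of a matrix Q.
pid_joint_mi <- function(Q, ix, iy) {
  if (is.null(dim(Q))) Q <- matrix(Q, ncol = 1)
  Q <- pmax(Q, 0)
  QX <- rowsum(Q, ix)[ix, , drop = FALSE]
  QY <- rowsum(Q, iy)[iy, , drop = FALSE]
  term <- Q * (log2(Q) - log2(QX) - log2(QY))
  term[Q == 0] <- 0
  colSums(term)
}

#' BROJA union information, in bits
#'
#' Minimizes \eqn{I^*(X_{1..n};Y)} over joint distributions that preserve
#' every pairwise source--target marginal. The feasible polytope is
#' parameterized by its free coordinates (a null-space basis of the
#' equality constraints), so marginal feasibility holds exactly; the convex
#' objective is then minimized by a log-barrier interior-point method with
#' analytic gradients and barrier-continuation, starting from the
#' conditional-independence distribution \eqn{p(y)\prod_i p(x_i|y)}.
#'
#' @param prob a [pid_problem()].
#' @param tolerance convergence tolerance on the objective, in bits.
#' @param max_iterations iteration cap across barrier stages.
#' @return A list with `value` (bits), `iterations`, `residual` (maximum
#'   absolute pairwise-marginal violation of the reported optimum),
#'   `converged`, and the optimal mass `q` on the support.
#' @export
union_information <- function(prob, tolerance = 1e-6, max_iterations = 10000) {
  stopifnot(inherits(prob, "pid_problem"))
  if (tolerance <= 0) stop("tolerance must be positive")
  poly <- pid_polytope(prob)
  if (ncol(poly$N) == 0L) {
    # constraints pin the distribution down completely
    return(list(value = as.numeric(pid_joint_mi(poly$q0, poly$ix, poly$iy)),
                iterations = 0L, residual = 0, converged = TRUE, q = poly$q0))
  }
  N <- poly$N; q0 <- poly$q0; ix <- poly$ix; iy <- poly$iy
  fq <- function(theta) {
    q <- q0 + as.numeric(N %*% theta)
    as.numeric(pid_joint_mi(pmax(q, 1e-300), ix, iy))
  }
  gq <- function(theta) {
    q <- pmax(q0 + as.numeric(N %*% theta), 1e-300)
    qx <- rowsum(q, ix)[ix]
    qy <- rowsum(q, iy)[iy]
    as.numeric(crossprod(N, log2(q / (qx * qy))))
  }
  theta <- rep(0, ncol(N))
  iters <- 0L
  value <- fq(theta)
  converged <- TRUE
  for (mu in c(1e-4, 1e-6, 1e-8)) {
    res <- tryCatch(
      stats::constrOptim(theta, f = fq, grad = gq, ui = N, ci = -q0,
                         mu = mu, method = "BFGS",
                         outer.iterations = 60,
                         outer.eps = tolerance / 10,
                         control = list(maxit = max_iterations,
                                        reltol = 1e-14)),
      error = function(e) NULL)
    if (is.null(res)) { converged <- FALSE; break }
    theta <- res$par
    value <- res$value
    iters <- iters + as.integer(res$outer.iterations)
  }
  q <- pmax(q0 + as.numeric(N %*% theta), 0)
  residual <- max(abs(as.numeric(poly$A %*% q) - poly$b))
  value <- as.numeric(pid_joint_mi(q, ix, iy))
  if (!converged && residual > tolerance) {
    stop(sprintf(paste("union information solver did not converge:",
                       "best value %.6f bits, residual %.3g"),
                 value, residual))
  }
  list(value = value, iterations = iters, residual = residual,
       converged = converged, q = q)
}

#' Synergy and companion PID quantities
#'
#' Computes the full decomposition summary: the joint mutual information
#' \eqn{I(X_{1..n};Y)}, each source's own \eqn{I(X_i;Y)}, union
#' information, synergy (joint MI minus union), and the bracketing
#' WholeMinusSum and Smax measures, which bound synergy from below and
#' above respectively.
#'
#' @param prob a [pid_problem()].
#' @param tolerance solver tolerance in bits; synergy is clipped into
#'   `[0, joint_mi]` only when the violation is within this tolerance.
#' @return An object of class `pid_summary`: a list with `joint_mi`,
#'   `source_mi`, `union`, `synergy`, `wms`, `smax_synergy`, `iterations`,
#'   `residual`.
#' @export
synergy <- function(prob, tolerance = 1e-4) {
  stopifnot(inherits(prob, "pid_problem"))
  joint_mi <- mutual_information(prob$joint, unlist(prob$sources),
                                 prob$target)
  source_mi <- vapply(prob$sources, function(s) {
    mutual_information(prob$joint, s, prob$target)
  }, numeric(1))
  un <- union_information(prob, tolerance = min(tolerance, 1e-6))
  syn <- joint_mi - un$value
  if (syn < 0) {
    if (syn < -tolerance) {
      stop(sprintf("negative synergy %.6g beyond tolerance", syn))
    }
    syn <- 0
  }
  if (syn > joint_mi) syn <- joint_mi
  structure(list(joint_mi = joint_mi, source_mi = source_mi,
                 union = un$value, synergy = syn,
                 wms = wms_synergy(prob),
                 smax_synergy = smax_synergy(prob),
                 iterations = un$iterations, residual = un$residual),
            class = "pid_summary")
}

#' @export
print.pid_summary <- function(x, ...) {
  cat(sprintf("PID summary: joint MI %.4f bits; union %.4f; synergy %.4f\n",
              x$joint_mi, x$union, x$synergy))
  cat(sprintf("  bounds: WMS %.4f <= synergy <= Smax %.4f\n",
              x$wms, x$smax_synergy))
  invisible(x)
}

#' WholeMinusSum synergy (lower bound)
#'
#' \eqn{I(X_{1..n};Y) - \sum_i I(X_i;Y)}; may be negative when redundancy
#' dominates.
#'
#' @param prob a [pid_problem()].
#' @return WMS synergy in bits.
#' @export
wms_synergy <- function(prob) {
  stopifnot(inherits(prob, "pid_problem"))
  joint_mi <- mutual_information(prob$joint, unlist(prob$sources),
                                 prob$target)
  joint_mi - sum(vapply(prob$sources, function(s) {
    mutual_information(prob$joint, s, prob$target)
  }, numeric(1)))
}

#' Smax synergy (upper bound)
#'
#' \eqn{I(X_{1..n};Y) - \sum_y p(y) \max_i I_{spec}(X_i; Y = y)}, where the
#' specific information is
#' \eqn{I_{spec}(X_i; Y=y) = \sum_x p(x|y) \log_2 [p(x|y)/p(x)]}.
#'
#' @param prob a [pid_problem()].
#' @return Smax synergy in bits.
#' @export
smax_synergy <- function(prob) {
  stopifnot(inherits(prob, "pid_problem"))
  cc <- pid_codes(prob)
  n <- cc$n
  idxy <- cc$codes[, n + 1]
  ys <- sort(unique(idxy))
  py <- as.numeric(rowsum(cc$mass, idxy))
  joint_mi <- mutual_information(prob$joint, unlist(prob$sources),
                                 prob$target)
  spec <- matrix(0, length(ys), n)
  for (i in seq_len(n)) {
    xi <- cc$codes[, i]
    px <- numeric(max(xi))
    px[sort(unique(xi))] <- as.numeric(rowsum(cc$mass, xi))
    pxy <- rowsum(cc$mass, paste(xi, idxy, sep = "\r"), reorder = FALSE)
    lab <- do.call(rbind, strsplit(rownames(pxy), "\r", fixed = TRUE))
    xs <- as.integer(lab[, 1]); yl <- match(as.integer(lab[, 2]), ys)
    for (r in seq_along(xs)) {
      pcond <- pxy[r] / py[yl[r]]
      spec[yl[r], i] <- spec[yl[r], i] + pcond * log2(pcond / px[xs[r]])
    }
  }
  joint_mi - sum(py * apply(spec, 1, max))
}

#' Brute-force oracle for union information
#'
#' Certifies the iterative solver on small problems by zooming grid search
#' over the free coordinates of the marginal-preserving polytope. Only
#' intended for test fixtures: it refuses supports larger than 64 cells or
#' polytopes with more than 10 free dimensions.
#'
#' @param prob a [pid_problem()].
#' @param grid_resolution points per free dimension per zoom round.
#' @return Union information in bits, within `O(1/grid_resolution)` of the
#'   optimum (in practice far closer after zooming).
#' @export
union_information_oracle <- function(prob, grid_resolution = 21) {
  stopifnot(inherits(prob, "pid_problem"))
  poly <- pid_polytope(prob)
  S <- nrow(poly$sup)
  if (S > 64) {
    stop(sprintf("oracle refused: support of %d cells exceeds 64", S))
  }
  k <- ncol(poly$N)
  if (k == 0L) {
    return(as.numeric(pid_joint_mi(poly$q0, poly$ix, poly$iy)))
  }
  if (k > 10) {
    stop(sprintf("oracle refused: %d free dimensions exceed 10", k))
  }
  r <- max(3L, min(grid_resolution, floor(5e4^(1 / k))))
  centre <- rep(0, k)
  h <- sqrt(2)            # any two points of the simplex are within sqrt(2)
  best_t <- centre
  best <- as.numeric(pid_joint_mi(poly$q0, poly$ix, poly$iy))
  for (round in 1:8) {
    axes <- lapply(seq_len(k), function(j) {
      seq(centre[j] - h, centre[j] + h, length.out = r)
    })
    T <- t(as.matrix(do.call(expand.grid, axes)))
    Q <- poly$q0 + poly$N %*% T
    feas <- colSums(Q < -1e-9) == 0L
    if (any(feas)) {
      vals <- pid_joint_mi(Q[, feas, drop = FALSE], poly$ix, poly$iy)
      if (min(vals) < best) {
        best <- min(vals)
        best_t <- T[, which(feas)[which.min(vals)]]
      }
    }
    centre <- best_t
    h <- h * 2.2 / (r - 1)
  }
  best
}
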