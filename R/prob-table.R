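#' Discrete joint probability tables
#'
#' A `prob_table` is a sparse finite joint distribution over named discrete
#' variables: outcome tuples that are absent carry zero mass. It is the
#' substrate for every information measure in the package (entropy, mutual
#' information, partial information decomposition).
#'
#' @param outcomes data frame with one column per variable; each row is an
#'   outcome tuple. Duplicate tuples are collapsed by summing their mass.
#' @param p numeric vector of probabilities, one per row of `outcomes`.
#'   Must be non-negative and sum to 1 within `1e-9`.
#' @param alphabets optional named list giving the ordered state alphabet of
#'   each variable; defaults to the sorted unique observed values. Alphabets
#'   must be non-empty and duplicate-free.
#'
#' @return An object of class `prob_table` with fields `vars`, `alphabets`
#'   and `mass` (a data frame holding the outcome columns plus `p`).
#' @examples
#' xor <- prob_table(
#'   data.frame(X1 = c(0, 0, 1, 1), X2 = c(0, 1, 0, 1), Y = c(0, 1, 1, 0)),
#'   rep(0.25, 4)
#' )
#' entropy(xor, "Y")
#' @export
prob_table <- function(outcomes, p, alphabets = NULL) {
  outcomes <- as.data.frame(outcomes)
  if (nrow(outcomes) == 0L) stop("prob_table needs at least one outcome")
  vars <- names(outcomes)
  if (anyDuplicated(vars)) stop("variable names must be unique")
  if (length(p) != nrow(outcomes)) {
    stop("length(p) must equal nrow(outcomes)")
  }
  if (any(!is.finite(p)) || any(p < -1e-12)) {
    stop("probabilities must be finite and non-negative")
  }
  p <- pmax(p, 0)
  if (abs(sum(p) - 1) > 1e-9) {
    stop(sprintf("probabilities must sum to 1 (got %.12g)", sum(p)))
  }
  if (is.null(alphabets)) {
    alphabets <- lapply(outcomes, function(col) sort(unique(col)))
  } else {
    if (!setequal(names(alphabets), vars)) {
      stop("alphabets must be named after the variables")
    }
    alphabets <- alphabets[vars]
    for (v in vars) {
      a <- alphabets[[v]]
      if (length(a) == 0L) stop(sprintf("alphabet of '%s' is empty", v))
      if (anyDuplicated(a)) stop(sprintf("alphabet of '%s' has duplicates", v))
      if (!all(outcomes[[v]] %in% a)) {
        stop(sprintf("outcomes of '%s' outside its alphabet", v))
      }
    }
  }
  # collapse duplicate tuples, drop exact-zero mass rows (sparse storage)
  key <- do.call(paste, c(outcomes, sep = "\r"))
  if (anyDuplicated(key)) {
    p <- as.numeric(rowsum(p, key, reorder = FALSE))
    outcomes <- outcomes[!duplicated(key), , drop = FALSE]
  }
  keep <- p > 0
  outcomes <- outcomes[keep, , drop = FALSE]
  p <- p[keep]
  rownames(outcomes) <- NULL
  mass <- outcomes
  mass$p <- p
  structure(list(vars = vars, alphabets = alphabets, mass = mass),
            class = "prob_table")
}

#' @export
print.prob_table <- function(x, ...) {
  cat(sprintf("prob_table over {%s}: %d outcomes with positive mass\n",
              paste(x$vars, collapse = ", "), nrow(x$mass)))
  invisible(x)
}

check_vars <- function(p, vars, what = "variable") {
  bad <- setdiff(vars, p$vars)
  if (length(bad)) {
    stop(sprintf("unknown %s name(s): %s", what, paste(bad, collapse = ", ")))
  }
  invisible(vars)
}

#' Marginalize a probability table
#'
#' Sums the mass over all variables not in `keep`.
#'
#' @param p a [prob_table()].
#' @param keep character vector of variable names to retain (non-empty).
#' @return A `prob_table` over `keep`.
#' @export
marginalize <- function(p, keep) {
  stopifnot(inherits(p, "prob_table"))
  if (length(keep) == 0L) stop("'keep' must name at least one variable")
  check_vars(p, keep)
  keep <- p$vars[p$vars %in% keep]          # preserve table order
  sub <- p$mass[keep]
  key <- do.call(paste, c(sub, sep = "\r"))
  w <- as.numeric(rowsum(p$mass$p, key, reorder = FALSE))
  sub <- sub[!duplicated(key), , drop = FALSE]
  prob_table(sub, w, alphabets = p$alphabets[keep])
}

marginal_mass <- function(p, vars) {
  # internal: marginal probabilities without re-validating, for hot paths
  sub <- p$mass[vars]
  key <- do.call(paste, c(sub, sep = "\r"))
  as.numeric(rowsum(p$mass$p, key, reorder = FALSE))
}

#' Shannon entropy of a marginal, in bits
#'
#' Computes \eqn{H = -\sum_x p(x) \log_2 p(x)} over the marginal on
#' `variables`, with \eqn{0 \log 0 := 0}.
#'
#' @param p a [prob_table()].
#' @param variables variables defining the marginal; defaults to all.
#' @return Entropy in bits, in `[0, log2(alphabet size)]`.
#' @export
entropy <- function(p, variables = p$vars) {
  stopifnot(inherits(p, "prob_table"))
  check_vars(p, variables)
  w <- marginal_mass(p, p$vars[p$vars %in% variables])
  w <- w[w > 0]
  -sum(w * log2(w))
}

#' Mutual information between two groups of variables, in bits
#'
#' \eqn{I(A;B) = H(A) + H(B) - H(A,B)}; symmetric and non-negative (values
#' within `1e-12` of zero are floored at zero).
#'
#' @param p a [prob_table()].
#' @param group_a,group_b disjoint character vectors of variable names.
#' @return Mutual information in bits.
#' @export
mutual_information <- function(p, group_a, group_b) {
  stopifnot(inherits(p, "prob_table"))
  check_vars(p, c(group_a, group_b))
  if (length(intersect(group_a, group_b))) {
    stop("variable groups must be disjoint")
  }
  mi <- entropy(p, group_a) + entropy(p, group_b) -
    entropy(p, c(group_a, group_b))
  if (mi < 0 && mi > -1e-12) mi <- 0
  mi
}

#' Conditional mutual information, in bits
#'
#' \eqn{I(A;B|C) = H(A,C) + H(B,C) - H(A,B,C) - H(C)}. Satisfies the chain
#' rule \eqn{I(A,B;Y) = I(A;Y) + I(B;Y|A)}.
#'
#' @param p a [prob_table()].
#' @param group_a,group_b,conditioning pairwise disjoint variable-name sets.
#' @return Conditional mutual information in bits (non-negative up to a
#'   `1e-12` floor).
#' @export
conditional_mutual_information <- function(p, group_a, group_b, conditioning) {
  stopifnot(inherits(p, "prob_table"))
  groups <- list(group_a, group_b, conditioning)
  check_vars(p, unlist(groups))
  for (i in 1:2) for (j in (i + 1):3) {
    if (length(intersect(groups[[i]], groups[[j]]))) {
      stop("variable groups must be pairwise disjoint")
    }
  }
  cmi <- entropy(p, c(group_a, conditioning)) +
    entropy(p, c(group_b, conditioning)) -
    entropy(p, c(group_a, group_b, conditioning)) -
    entropy(p, conditioning)
  if (cmi < 0 && cmi > -1e-12) cmi <- 0
  cmi
}

#' Spatial (distance-weighted) entropy support
#'
#' A `spatial_support` is a finite set of points in a common coordinate
#' space together with a probability for each point. For this model the
#' points are the unique decoded estimate values placed on the (1-D)
#' observation axis.
#'
#' @param coords numeric vector (1-D) or matrix (one row per point).
#' @param prob probabilities, non-negative, summing to 1 within `1e-9`.
#' @return An object of class `spatial_support`.
#' @export
spatial_support <- function(coords, prob) {
  if (is.null(dim(coords))) coords <- matrix(coords, ncol = 1)
  coords <- as.matrix(coords)
  if (nrow(coords) == 0L) stop("support must contain at least one point")
  if (length(prob) != nrow(coords)) {
    stop("one probability per support point is required")
  }
  if (any(!is.finite(coords))) stop("coordinates must be finite")
  if (any(prob < -1e-12)) stop("probabilities must be non-negative")
  prob <- pmax(prob, 0)
  if (abs(sum(prob) - 1) > 1e-9) stop("probabilities must sum to 1")
  structure(list(coords = coords, prob = prob), class = "spatial_support")
}

#' Spatial entropy of a discrete support, in distance-weighted bits
#'
#' \eqn{H_{Cl} = -\sum_i d_i p_i \log_2 p_i}, where \eqn{d_i} is the mean
#' Euclidean distance from point `i` to every other support point. A
#' single-point support has spatial entropy 0 (its `d` is defined as 0).
#' The measure is invariant under rigid translation of the coordinates and
#' scales linearly under uniform scaling.
#'
#' @param s a [spatial_support()].
#' @return Spatial entropy (distance units times bits).
#' @export
spatial_entropy <- function(s) {
  stopifnot(inherits(s, "spatial_support"))
  n <- nrow(s$coords)
  if (n == 1L) return(0)
  D <- as.matrix(stats::dist(s$coords))
  d <- rowSums(D) / (n - 1)
  pl <- ifelse(s$prob > 0, s$prob * log2(s$prob), 0)
  -sum(d * pl)
}

#' Spatial support of a variable's observed values
#'
#' Builds the [spatial_support()] whose points are the unique values of `x`
#' placed at their numeric value, weighted by relative frequency (or by
#' `weights`).
#'
#' @param x numeric vector of observed values.
#' @param weights optional non-negative weights (defaults to equal).
#' @return A `spatial_support`.
#' @export
value_support <- function(x, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, length(x))
  w <- as.numeric(rowsum(weights, x, reorder = TRUE))
  vals <- sort(unique(x))
  spatial_support(vals, w / sum(w))
}

#' Read / write probability tables as JSON
#'
#' The on-disk format is
#' `{"variables": [...], "alphabets": {...}, "mass": [[[outcome...], p], ...]}`
#' and round-trips losslessly; the reader rejects tables that violate the
#' probability invariants.
#'
#' @param p a [prob_table()].
#' @param path file path.
#' @return `read_prob_table` returns a `prob_table`; `write_prob_table`
#'   returns `path` invisibly.
#' @export
write_prob_table <- function(p, path) {
  stopifnot(inherits(p, "prob_table"))
  mass <- lapply(seq_len(nrow(p$mass)), function(i) {
    list(unname(as.list(p$mass[i, p$vars, drop = FALSE])), p$mass$p[i])
  })
  obj <- list(variables = p$vars, alphabets = p$alphabets, mass = mass)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_prob_table
#' @export
read_prob_table <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  vars <- unlist(obj$variables)
  outs <- lapply(obj$mass, function(m) unlist(m[[1]]))
  outcomes <- as.data.frame(do.call(rbind, outs))
  names(outcomes) <- vars
  p <- vapply(obj$mass, function(m) as.numeric(m[[2]]), numeric(1))
  alphabets <- lapply(obj$alphabets, function(a) unlist(a))
  prob_table(outcomes, p, alphabets = alphabets[vars])
}
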