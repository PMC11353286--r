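#' The worked 4x4 synergistic toy landscape
#'
#' A symmetric 4x4 matrix whose affordance value is carried synergistically
#' by the two observation axes: each axis's row/column expectations take
#' only the values 0.5 and 0.75, so a 1-bit encoder per axis can either
#' track the expectation (direct strategy) or track coarse position
#' (indirect strategy), with very different reconstruction quality.
#'
#' @return An [affordance_landscape()] with axes `1..4`.
#' @export
toy_landscape <- function() {
  affordance_landscape(matrix(c(
    0, 0, 1, 1,
    0, 0, 2, 1,
    1, 2, 0, 0,
    1, 1, 0, 0), nrow = 4, byrow = TRUE))
}

#' The toy landscape with entries a[4,2] and a[2,3] swapped
#'
#' The swap produces a matrix that is still synergistic but on which the
#' direct and indirect strategies attain the same optimal affordance
#' estimate.
#'
#' @return An [affordance_landscape()].
#' @export
toy_swapped <- function() {
  land <- toy_landscape()
  m <- land$matrix
  tmp <- m[4, 2]
  m[4, 2] <- m[2, 3]
  m[2, 3] <- tmp
  affordance_landscape(m)
}

#' XOR landscape
#'
#' The 2x2 matrix `[[0,1],[1,0]]`: the canonical fully synergistic system.
#' With identity (lossless) encoders the two signals carry 1 bit about the
#' affordance jointly and 0 bits individually.
#'
#' @return An [affordance_landscape()].
#' @export
xor_landscape <- function() {
  affordance_landscape(matrix(c(0, 1, 1, 0), nrow = 2))
}

#' The XOR gate as a probability table
#'
#' Truth-table joint over `X1, X2, Y` with uniformly distributed inputs.
#'
#' @return A [prob_table()].
#' @export
xor_table <- function() {
  prob_table(
    data.frame(X1 = c(0, 0, 1, 1), X2 = c(0, 1, 0, 1), Y = c(0, 1, 1, 0)),
    rep(0.25, 4))
}

#' Block-structured synergistic landscape generator
#'
#' Rows and columns are partitioned into `blocks` contiguous groups with
#' labels `r(b)` and `s(c)`; the affordance value of a cell is a function
#' of `(r + s) mod blocks` (an XOR-style interaction), mapped onto `levels`
#' distinct values. A `noise` fraction of cells is resampled uniformly
#' from the value set. The true block labels are recorded so ground-truth
#' indirect encoders are known.
#'
#' @param m,n dimensions.
#' @param blocks blocks per axis (>= 2).
#' @param levels number of distinct affordance values (>= 2).
#' @param noise fraction of cells resampled uniformly at random.
#' @param seed integer seed (the generator is a pure function of it).
#' @return An [affordance_landscape()] with attributes `row_blocks` and
#'   `col_blocks` (0-based ground-truth labels).
#' @export
random_synergistic_landscape <- function(m = 8, n = 8, blocks = 2,
                                         levels = 3, noise = 0, seed) {
  if (missing(seed)) stop("a seed is required")
  if (blocks < 2) stop("at least 2 blocks per axis are required")
  if (levels < 2) stop("at least 2 levels are required")
  if (noise < 0 || noise > 1) stop("noise must be in [0, 1]")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  rb <- sort(rep_len(seq_len(blocks) - 1L, m))
  cb <- sort(rep_len(seq_len(blocks) - 1L, n))
  values <- seq(0, levels - 1)
  g <- sample(values, blocks, replace = blocks > levels)
  A <- outer(rb, cb, function(r, s) g[((r + s) %% blocks) + 1L])
  flip <- which(stats::runif(m * n) < noise)
  A[flip] <- sample(values, length(flip), replace = TRUE)
  land <- affordance_landscape(A)
  attr(land, "row_blocks") <- rb
  attr(land, "col_blocks") <- cb
  land
}

#' Additively separable landscape generator
#'
#' `a[b, c] = f(b) + g(c)` with `f`, `g` drawn i.i.d. continuous; such
#' landscapes carry no synergistic structure (the affordance value
#' determines each axis's contribution almost surely), making them the
#' negative control for the strategy comparison.
#'
#' @param m,n dimensions.
#' @param seed integer seed.
#' @return An [affordance_landscape()].
#' @export
separable_landscape <- function(m = 4, n = 4, seed) {
  if (missing(seed)) stop("a seed is required")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  f <- stats::runif(m)
  g <- stats::runif(n)
  affordance_landscape(outer(f, g, `+`))
}

#' Quantize a matrix's values by 1-D k-means
#'
#' Runs Lloyd's algorithm (k-means++-style multi-start seeding via
#' `stats::kmeans`) on the multiset of matrix values and replaces each
#' value by its cluster centroid, yielding at most `k` unique values. The
#' centroids are real affordance values (not cluster indices), so the
#' conditional-expectation decoder can average them. Values never leave
#' `[min, max]` of the input and the unique-value count never increases.
#'
#' @param matrix numeric matrix.
#' @param k number of clusters (>= 2).
#' @param seed integer seed for the k-means initialization.
#' @return An [affordance_landscape()]; if the input has at most `k`
#'   unique values it is returned unchanged with attribute
#'   `quantize_warning = TRUE`.
#' @export
quantize_matrix <- function(matrix, k = 5, seed) {
  if (missing(seed)) stop("a seed is required")
  if (k < 2) stop("k must be at least 2")
  matrix <- as.matrix(matrix)
  if (any(!is.finite(matrix))) stop("matrix entries must be finite")
  vals <- as.vector(matrix)
  uq <- unique(vals)
  if (length(uq) <= k) {
    land <- affordance_landscape(matrix)
    attr(land, "quantize_warning") <- TRUE
    return(land)
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  km <- stats::kmeans(vals, centers = k, iter.max = 100, nstart = 5,
                      algorithm = "Lloyd")
  out <- km$centers[km$cluster]
  affordance_landscape(base::matrix(out, nrow(matrix), ncol(matrix)))
}

#' Synthetic grayscale blob-image landscapes
#'
#' Emulates small grayscale photographs of standing figures: 1-3
#' vertically elongated bright blobs over low-amplitude background noise,
#' quantized to `levels` unique values by 1-D k-means. Vertical blobs
#' concentrate the value variance in a few columns while spreading it over
#' many rows -- the axis asymmetry that separates the two encoding
#' strategies.
#'
#' @param m,n dimensions (default 32 x 32).
#' @param levels unique affordance values after quantization (default 5).
#' @param max_blobs maximum number of blobs (1 to `max_blobs` are drawn).
#' @param noise_sd standard deviation of the background noise relative to
#'   a unit blob amplitude.
#' @param seed integer seed.
#' @return An [affordance_landscape()].
#' @export
blob_image_landscape <- function(m = 32, n = 32, levels = 5, max_blobs = 3,
                                 noise_sd = 0.1, seed) {
  if (missing(seed)) stop("a seed is required")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  A <- base::matrix(stats::rnorm(m * n, sd = noise_sd), m, n)
  nblobs <- sample.int(max_blobs, 1)
  rows <- seq_len(m); cols <- seq_len(n)
  for (blob in seq_len(nblobs)) {
    cx <- stats::runif(1, 0.15 * n, 0.85 * n)     # column centre
    cy <- stats::runif(1, 0.35 * m, 0.65 * m)     # row centre
    sx <- stats::runif(1, 0.03 * n, 0.08 * n)     # narrow horizontally
    sy <- stats::runif(1, 0.25 * m, 0.45 * m)     # elongated vertically
    amp <- stats::runif(1, 0.7, 1)
    A <- A + amp * outer(exp(-(rows - cy)^2 / (2 * sy^2)),
                         exp(-(cols - cx)^2 / (2 * sx^2)))
  }
  quantize_matrix(A, k = levels, seed = seed + 1L)
}

#' Load a grayscale image file as an affordance landscape
#'
#' Reads a PNG (via the `png` package) and converts RGB to grayscale with
#' the Rec. 601 luma weights (0.299, 0.587, 0.114); optionally quantizes
#' the result with [quantize_matrix()].
#'
#' @param path path to a PNG file.
#' @param levels if not `NULL`, quantize to this many unique values.
#' @param seed seed for the quantization step (required with `levels`).
#' @return An [affordance_landscape()].
#' @export
image_landscape <- function(path, levels = NULL, seed = NULL) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("reading PNG images requires the 'png' package")
  }
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) {
    img <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
  }
  if (is.null(levels)) return(affordance_landscape(img))
  if (is.null(seed)) stop("a seed is required when quantizing")
  quantize_matrix(img, k = levels, seed = seed)
}

#' Generate a landscape from a generator specification
#'
#' Dispatch helper used by the command-line tools and batch experiments.
#'
#' @param kind one of `"toy"`, `"toy_swapped"`, `"xor"`, `"random"`,
#'   `"blobs"`, `"separable"`.
#' @param m,n,levels,noise,blocks,seed forwarded to the generator.
#' @return An [affordance_landscape()].
#' @export
generate_landscape <- function(kind, m = 32, n = 32, levels = 5,
                               noise = 0, blocks = 2, seed = NULL) {
  switch(kind,
    toy = toy_landscape(),
    toy_swapped = toy_swapped(),
    xor = xor_landscape(),
    random = random_synergistic_landscape(m, n, blocks = blocks,
                                          levels = levels, noise = noise,
                                          seed = seed),
    blobs = blob_image_landscape(m, n, levels = levels, seed = seed),
    separable = separable_landscape(m, n, seed = seed),
    stop(sprintf("unknown landscape kind '%s'", kind)))
}
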