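# Divergence-time trends and ordination of the conservation matrix.

#' Per-genome counts of high- or low-alignment REs
#'
#' @param mat conservation matrix (REs x genomes).
#' @param mode `"high"` counts rows with fraction `>= hi` per genome;
#'   `"low"` counts rows with fraction `<= lo`.
#' @param hi,lo thresholds, defaults 0.9 / 0.1 (boundary inclusive).
#' @return named numeric vector, one count per genome column.
#' @export
count_by_genome <- function(mat, mode = c("high", "low"), hi = 0.9, lo = 0.1) {
  mode <- match.arg(mode)
  if (!is.matrix(mat) || !nrow(mat)) stop("matrix must be non-empty", call. = FALSE)
  check_fractions(mat)
  if (mode == "high") colSums(mat >= hi) else colSums(mat <= lo)
}

#' Ordinary least-squares regression of counts on divergence time
#'
#' Plain OLS of `y` on `x` via [stats::lm]; the p-value is the two-sided t
#' test on the slope with `n - 2` degrees of freedom.
#'
#' @param x predictor (divergence times, MYA).
#' @param y response (per-genome RE counts).
#' @return list `slope`, `intercept`, `r_squared`, `p_value`, `n`.
#' @export
fit_regression <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  if (length(x) < 3) stop("need at least 3 points", call. = FALSE)
  if (isTRUE(all.equal(stats::var(x), 0)) || length(unique(x)) == 1)
    stop("x is constant; slope undefined", call. = FALSE)
  fit <- stats::lm(y ~ x)
  co <- stats::coef(suppressWarnings(summary(fit)))  # perfect fits are fine
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  # constant response: define R^2 = 0 (and p = 1) rather than 0/0 noise
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 0
  p <- unname(co["x", "Pr(>|t|)"])
  list(slope = unname(co["x", "Estimate"]),
       intercept = unname(co["(Intercept)", "Estimate"]),
       r_squared = r2,
       p_value = if (ss_tot > 0) p else 1,
       n = length(x))
}

#' PCA of the conservation matrix
#'
#' Columns (genomes) are mean-centred but not variance-scaled: every entry is
#' already a fraction on a common [0, 1] scale, and scaling would inflate the
#' noise of near-constant genomes. Decomposition is by singular values; signs
#' are made deterministic by forcing each loading column's largest-magnitude
#' entry positive.
#'
#' @param mat numeric matrix (REs x genomes), >= 2 rows and columns.
#' @param n_components number of components kept, `<= min(dim(mat))`.
#' @param scale. logical, variance-scale columns (default `FALSE`).
#' @return list `scores` (REs x components), `loadings` (genomes x
#'   components, orthonormal columns), `explained_variance_ratio`
#'   (non-increasing, sums to <= 1), `center` (column means).
#' @export
run_pca <- function(mat, n_components = 2, scale. = FALSE) {
  mat <- unclass(as.matrix(mat))
  if (nrow(mat) < 2 || ncol(mat) < 2)
    stop("matrix must have >= 2 rows and >= 2 columns", call. = FALSE)
  if (n_components > min(dim(mat)))
    stop("n_components exceeds matrix rank bound", call. = FALSE)
  ctr <- colMeans(mat)
  x <- sweep(mat, 2, ctr)
  if (isTRUE(scale.)) {
    s <- apply(x, 2, stats::sd)
    s[s == 0] <- 1
    x <- sweep(x, 2, s, "/")
  }
  sv <- svd(x)
  ev <- sv$d^2
  total <- sum(ev)
  evr <- if (total > 0) ev / total else rep(0, length(ev))
  k <- n_components
  loadings <- sv$v[, seq_len(k), drop = FALSE]
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k, k)
  for (j in seq_len(k)) {
    i_max <- which.max(abs(loadings[, j]))
    if (loadings[i_max, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  rownames(scores) <- rownames(mat)
  rownames(loadings) <- colnames(mat)
  colnames(scores) <- colnames(loadings) <- paste0("PC", seq_len(k))
  list(scores = scores, loadings = loadings,
       explained_variance_ratio = evr[seq_len(k)], center = ctr)
}
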