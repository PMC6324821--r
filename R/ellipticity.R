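# Homolog ellipticity: ellipsoid fits, scores, ratios and the random-pair
# null.

#' Least-squares ellipsoid fit
#'
#' Fits the general quadric `x'Qx + 2 b'x = 1` to the points by linear least
#' squares and extracts the ellipsoid centre and principal semi-axes from
#' the centred quadric's eigendecomposition. The algebraic fit is exact for
#' shell-like samples (points on an ellipsoid surface); for filled clouds
#' it is ill-conditioned and frame-sensitive, so the fit falls back to
#' moment-based axes (square roots of the covariance eigenvalues, exactly
#' rotation-invariant and axis-ratio-preserving for solid clouds) whenever
#' the fitted quadric is not an ellipsoid or the points do not concentrate
#' near its surface (coefficient of variation of the quadric form >= 0.5).
#'
#' @param pts numeric matrix (n x 3), n >= 10 non-degenerate points (nm).
#' @return an object of class `ellipsoid_fit`: `center` (nm), `axes`
#'   (semi-axis lengths, descending, nm), `orientation` (3 x 3 rotation,
#'   columns = principal directions), `method` ("algebraic" or "moment").
#' @export
ellipsoid_fit <- function(pts) {
  pts <- as.matrix(pts)
  if (nrow(pts) < 10L) stop_ct("ellipsoid fit needs >= 10 points")
  sv <- svd(sweep(pts, 2, colMeans(pts)))$d
  if (sv[3] < 1e-9 * sv[1]) stop_ct("rank-deficient point cloud")
  x <- pts[, 1]; y <- pts[, 2]; z <- pts[, 3]
  D <- cbind(x^2, y^2, z^2, 2 * x * y, 2 * x * z, 2 * y * z, 2 * x, 2 * y,
             2 * z)
  v <- tryCatch(qr.solve(crossprod(D), crossprod(D, rep(1, nrow(pts)))),
                error = function(e) NULL)
  if (!is.null(v)) {
    Q <- matrix(c(v[1], v[4], v[5], v[4], v[2], v[6], v[5], v[6], v[3]), 3, 3)
    b <- v[7:9]
    ctr <- tryCatch(-solve(Q, b), error = function(e) NULL)
    if (!is.null(ctr)) {
      k <- 1 + as.numeric(t(ctr) %*% Q %*% ctr) + 2 * sum(b * ctr)
      eg <- eigen(Q / k, symmetric = TRUE)
      if (all(eg$values > 0)) {
        # shell check: the quadric form should be ~1 on all points
        ctd <- sweep(pts, 2, as.numeric(ctr))
        m <- rowSums((ctd %*% (Q / k)) * ctd)
        if (sd(m) / mean(m) < 0.5) {
          ord <- order(1 / sqrt(eg$values), decreasing = TRUE)
          return(structure(list(center = as.numeric(ctr),
                                axes = (1 / sqrt(eg$values))[ord],
                                orientation = eg$vectors[, ord, drop = FALSE],
                                method = "algebraic"),
                           class = "ellipsoid_fit"))
        }
      }
    }
  }
  eg <- eigen(stats::cov(pts), symmetric = TRUE)
  structure(list(center = colMeans(pts), axes = sqrt(eg$values),
                 orientation = eg$vectors, method = "moment"),
            class = "ellipsoid_fit")
}

#' @export
print.ellipsoid_fit <- function(x, ...) {
  cat(sprintf("ellipsoid fit (%s): semi-axes %.4g / %.4g / %.4g nm\n",
              x$method, x$axes[1], x$axes[2], x$axes[3]))
  invisible(x)
}

#' Ellipticity score of a point cloud
#'
#' Ratio of the two largest principal axes of the fitted ellipsoid
#' (always >= 1; 1 for a sphere-symmetric cloud).
#'
#' @param pts numeric matrix (n x 3) or localization table.
#' @return the scalar ellipticity score.
#' @export
ellipticity_score <- function(pts) {
  if (is.data.frame(pts)) pts <- as.matrix(pts[, c("x_nm", "y_nm", "z_nm")])
  fit <- ellipsoid_fit(pts)
  fit$axes[1] / fit$axes[2]
}

#' Ellipticity ratio of two homologs
#'
#' Larger-over-smaller ratio of two ellipticity scores; 1 iff the homologs
#' share the same score; symmetric in argument order.
#'
#' @param scoreA,scoreB ellipticity scores (>= 1).
#' @return the ratio (>= 1).
#' @export
ellipticity_ratio <- function(scoreA, scoreB) {
  if (any(c(scoreA, scoreB) < 1)) stop_ct("ellipticity scores must be >= 1")
  pmax(scoreA, scoreB) / pmin(scoreA, scoreB)
}

#' Random-pair null for the ellipticity ratio
#'
#' Builds the null distribution of ellipticity ratios from homolog scores
#' paired at random across the cell population (ignoring nucleus identity)
#' and compares the observed within-nucleus ratios against it with a
#' two-sided Mann–Whitney rank test.
#'
#' @param scores data frame with columns `nucleus` and `score` (two homolog
#'   scores per nucleus), or a plain numeric vector of scores when only the
#'   null distribution is required.
#' @param n_pairs number of random pairs (default 1000).
#' @param seed RNG seed for the pair draw.
#' @return a list with `null_ratios`, `within_ratios` (NULL for vector
#'   input), and `test` (the `htest`, or NULL).
#' @export
random_pair_null <- function(scores, n_pairs = 1000, seed = NULL) {
  if (n_pairs < 1) stop_ct("n_pairs must be >= 1")
  if (is.data.frame(scores)) {
    if (!all(c("nucleus", "score") %in% names(scores)))
      stop_ct("scores needs columns nucleus, score")
    pool <- scores$score
    within <- vapply(split(scores$score, scores$nucleus), function(s) {
      if (length(s) != 2L) return(NA_real_)
      ellipticity_ratio(s[1], s[2])
    }, numeric(1))
    within <- within[!is.na(within)]
  } else {
    pool <- as.numeric(scores)
    within <- NULL
  }
  if (length(pool) < 4L) stop_ct("need >= 4 homolog scores")
  null_ratios <- with_seed(seed, {
    i <- sample.int(length(pool), n_pairs, replace = TRUE)
    j <- sample.int(length(pool) - 1L, n_pairs, replace = TRUE)
    j <- ifelse(j >= i, j + 1L, j)  # j != i, uniform over the rest
    ellipticity_ratio(pool[i], pool[j])
  })
  test <- NULL
  if (!is.null(within) && length(within))
    test <- wilcox.test(within, null_ratios, alternative = "two.sided",
                        exact = FALSE)
  list(null_ratios = null_ratios, within_ratios = within, test = test)
}
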