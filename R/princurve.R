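#' Project points onto a polyline curve
#'
#' Maps each point to its nearest point on the polyline (orthogonal foot on a
#' segment, clamped to the segment ends). `lambda` is the arc length from the
#' first vertex to the foot; when a point is equidistant from several
#' segments the foot with the smaller `lambda` wins.
#'
#' @param points Numeric matrix, one row per point.
#' @param vertices Numeric matrix of polyline vertices (>= 2 rows), in order.
#' @param extend If `TRUE`, the two end segments are produced beyond the end
#'   vertices so points past the ends project orthogonally instead of piling
#'   onto the end vertex (`lambda` may then be negative or exceed the curve
#'   length). Used internally by the curve fit; the default `FALSE` gives the
#'   plain polyline projection.
#' @return Tibble: `lambda`, `sq_residual`, with the foot coordinates as a
#'   matrix attribute `feet`.
#' @export
project_to_curve <- function(points, vertices, extend = FALSE) {
  points <- as.matrix(points)
  vertices <- as.matrix(vertices)
  if (nrow(vertices) < 2) abort("curve must have at least 2 vertices")
  seg_vec <- diff(vertices)
  seg_len2 <- rowSums(seg_vec^2)
  keep <- seg_len2 > 0
  if (!any(keep)) abort("degenerate curve: all vertices identical")
  seg_start <- vertices[-nrow(vertices), , drop = FALSE][keep, , drop = FALSE]
  seg_vec <- seg_vec[keep, , drop = FALSE]
  seg_len2 <- seg_len2[keep]
  seg_len <- sqrt(seg_len2)
  n_seg <- length(seg_len)
  cum_len <- c(0, cumsum(seg_len))[seq_len(n_seg)]

  n <- nrow(points)
  best_d2 <- rep(Inf, n)
  best_lambda <- numeric(n)
  feet <- matrix(0, n, ncol(points))
  for (s in seq_len(n_seg)) {
    rel <- sweep(points, 2, seg_start[s, ])
    t_par <- (rel %*% seg_vec[s, ] / seg_len2[s])[, 1]
    lo <- if (extend && s == 1) -Inf else 0
    hi <- if (extend && s == n_seg) Inf else 1
    t_par <- pmin(pmax(t_par, lo), hi)
    foot <- seg_start[rep(1, n) * s, , drop = FALSE] + outer(t_par, seg_vec[s, ])
    d2 <- rowSums((points - foot)^2)
    better <- d2 < best_d2                   # strict: ties keep smaller lambda
    best_d2[better] <- d2[better]
    best_lambda[better] <- cum_len[s] + t_par[better] * seg_len[s]
    feet[better, ] <- foot[better, , drop = FALSE]
  }
  out <- tibble::tibble(lambda = best_lambda, sq_residual = best_d2)
  attr(out, "feet") <- feet
  out
}

# project with end extension, then grow the polyline to cover the extreme
# feet and shift lambda so the start-side end sits at 0
project_and_extend <- function(points, vertices) {
  proj <- project_to_curve(points, vertices, extend = TRUE)
  seg_vec <- diff(vertices)
  seg_len <- sqrt(rowSums(seg_vec^2))
  total_len <- sum(seg_len)
  lam <- proj$lambda
  lam_min <- min(lam, 0)
  lam_max <- max(lam, total_len)
  if (lam_min < 0) {
    u <- seg_vec[1, ] / seg_len[1]
    vertices <- rbind(vertices[1, ] + lam_min * u, vertices)
  }
  if (lam_max > total_len) {
    u <- seg_vec[nrow(seg_vec), ] / seg_len[length(seg_len)]
    vertices <- rbind(vertices, vertices[nrow(vertices), ] + (lam_max - total_len) * u)
  }
  rownames(vertices) <- NULL
  proj$lambda <- lam - lam_min
  list(vertices = vertices, proj = proj)
}

#' Fit a principal curve through a 3-D score cloud
#'
#' Iterative projection / smoothing fit of a one-dimensional curve
#' summarizing a point cloud: the curve is initialized as the oriented
#' segment from `start_a` through `start_b` (extended to span the data); each
#' iteration projects the points onto the current polyline to get arc-length
#' positions `lambda`, smooths each coordinate as a cubic smoothing-spline
#' function of `lambda`, rebuilds the polyline from the smoothed coordinates
#' and reparameterizes `lambda` by cumulative arc length. Iterations are
#' accepted only while the total squared projection residual does not
#' increase, so the residual trajectory is monotone; the fit stops when the
#' relative residual change drops below `tol` or after `max_iter`
#' iterations. The curve end nearer `start_a` is anchored at `lambda = 0`
#' throughout.
#'
#' @param scores Numeric matrix (or data frame) of sample scores, one row per
#'   sample; typically the first three principal components.
#' @param start_a,start_b Numeric vectors defining the initial oriented
#'   segment; `start_a` marks the origin of the arc-length scale (in the RA
#'   study: the centroid of the 0 h Control samples, versus the centroid of
#'   the remaining samples).
#' @param smoother_df Degrees of freedom of the per-coordinate smoothing
#'   spline, default 5.
#' @param tol Relative residual-change convergence tolerance, default 1e-4.
#' @param max_iter Maximum number of smoothing iterations, default 50.
#' @return An `ra_curve` object: `vertices`, `lambda`, `sq_residual`, `feet`,
#'   `rss` (accepted residual trajectory), `n_iter`, `converged`,
#'   `sample_ids`.
#' @export
fit_principal_curve <- function(scores, start_a, start_b, smoother_df = 5,
                                tol = 1e-4, max_iter = 50) {
  x <- as.matrix(scores)
  if (nrow(x) < 4) abort("need at least 4 samples to fit a principal curve")
  if (max(apply(x, 2, function(col) diff(range(col)))) == 0) {
    abort("degenerate input: all samples identical")
  }
  start_a <- as.numeric(start_a)
  start_b <- as.numeric(start_b)
  if (isTRUE(all.equal(start_a, start_b))) abort("start_a and start_b coincide")

  state <- project_and_extend(x, rbind(start_a, start_b))
  rss <- sum(state$proj$sq_residual)
  rss_path <- rss
  converged <- rss <= .Machine$double.eps^0.25
  iter <- 0

  while (!converged && iter < max_iter) {
    iter <- iter + 1
    lam <- state$proj$lambda
    n_unique <- length(unique(lam))
    if (n_unique < 4) break              # too few distinct positions to smooth
    df_use <- min(smoother_df, n_unique - 1)
    smoothed <- vapply(seq_len(ncol(x)), function(j) {
      fit <- smooth.spline(lam, x[, j], df = df_use)
      predict(fit, lam)$y
    }, numeric(nrow(x)))
    ord <- order(lam)
    new_vertices <- smoothed[ord, , drop = FALSE]
    dup <- c(FALSE, rowSums(abs(diff(new_vertices))) == 0)
    new_vertices <- new_vertices[!dup, , drop = FALSE]
    if (nrow(new_vertices) < 2) break
    # keep the start_a side at lambda = 0
    d_first <- sum((new_vertices[1, ] - start_a)^2)
    d_last <- sum((new_vertices[nrow(new_vertices), ] - start_a)^2)
    if (d_last < d_first) {
      new_vertices <- new_vertices[rev(seq_len(nrow(new_vertices))), , drop = FALSE]
    }

    new_state <- project_and_extend(x, new_vertices)
    new_rss <- sum(new_state$proj$sq_residual)
    if (new_rss > rss + .Machine$double.eps^0.5 * max(1, rss)) break  # reject
    state <- new_state
    rss_path <- c(rss_path, new_rss)
    rel_change <- if (rss > 0) (rss - new_rss) / rss else 0
    rss <- new_rss
    if (rel_change < tol) converged <- TRUE
  }
  if (rss <= .Machine$double.eps^0.25) converged <- TRUE

  structure(
    list(vertices = state$vertices, lambda = state$proj$lambda,
         sq_residual = state$proj$sq_residual,
         feet = attr(state$proj, "feet"),
         rss = rss_path, n_iter = iter, converged = converged,
         sample_ids = rownames(x)),
    class = "ra_curve")
}

#' @export
print.ra_curve <- function(x, ...) {
  cat(sprintf(
    "Principal curve: %d vertices, %d samples, RSS %.4g, %d iteration(s)%s\n",
    nrow(x$vertices), length(x$lambda), x$rss[length(x$rss)], x$n_iter,
    if (x$converged) " (converged)" else " (not converged)"))
  invisible(x)
}
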