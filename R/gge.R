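#' Fit a GGE model (genotype main effect + genotype-by-environment interaction)
#'
#' Centers the two-way table of cell means by environment only, so the
#' genotype main effect G and the interaction GE are retained together:
#'
#' \deqn{y_{ge} - \mu - \psi_e = \theta_1 \xi_{g1}\eta_{e1} +
#'   \theta_2 \xi_{g2}\eta_{e2} + \varepsilon_{ge}}
#'
#' The centered matrix is decomposed by SVD and the top two axes form the
#' biplot.  The singular values are partitioned between the genotype and
#' environment markers by the scaling exponent `f`: genotype coordinates
#' are \eqn{\theta_n^{f}\xi_{gn}} and environment coordinates
#' \eqn{\theta_n^{1-f}\eta_{en}}, so the inner product of a genotype and
#' an environment marker always reconstructs the rank-2 approximation of
#' the centered value, whatever `f`.  No scaling by environment standard
#' deviation is applied.
#'
#' Axis signs are fixed by orienting each axis so its largest-magnitude
#' environment score is positive.
#'
#' @param matrix a `cell_means` object or plain numeric `g x e` matrix
#'   (genotype rows, environment columns).
#' @param scaling_f singular-value partitioning exponent in `[0, 1]`:
#'   0.5 (default) is symmetric, 1 genotype-focused, 0
#'   environment-focused.
#' @return An object of class `gge_model`: a list with `centered`,
#'   `theta` (all singular values), `theta1`, `theta2`,
#'   `genotype_coords` (`g x 2`), `environment_coords` (`e x 2`),
#'   `scaling_f`, and `var_explained` (fractions of total squared
#'   singular values, all axes).
#' @examples
#' m <- matrix(c(1, 0, 0, 1), nrow = 2,
#'             dimnames = list(c("A", "B"), c("E1", "E2")))
#' fit_gge(m)$var_explained
#' @export
fit_gge <- function(matrix, scaling_f = 0.5) {
  m <- if (inherits(matrix, "cell_means")) matrix$means else as.matrix(matrix)
  if (!is.numeric(m)) stop("cell means must be numeric")
  if (!is.numeric(scaling_f) || scaling_f < 0 || scaling_f > 1)
    stop("scaling_f must lie in [0, 1]")
  g <- nrow(m); e <- ncol(m)
  if (g < 2L || e < 2L) stop("need at least 2 genotypes and 2 environments")
  gn <- rownames(m); if (is.null(gn)) gn <- paste0("G", seq_len(g))
  en <- colnames(m); if (is.null(en)) en <- paste0("E", seq_len(e))

  centered <- sweep(m, 2L, colMeans(m))
  dimnames(centered) <- list(gn, en)
  sv <- svd(centered)
  theta <- sv$d
  u <- sv$u; v <- sv$v
  for (j in seq_along(theta)) {
    if (theta[j] == 0) next
    i <- which.max(abs(v[, j]))
    if (v[i, j] < 0) { v[, j] <- -v[, j]; u[, j] <- -u[, j] }
  }
  tot <- sum(theta^2)
  var_explained <- if (tot > 0) theta^2 / tot else rep(0, length(theta))

  # theta^f with the convention 0^f = 0 even when f = 0 (a null axis
  # contributes nothing to the biplot)
  pw <- function(d, ex) ifelse(d > 0, d^ex, 0)
  d2 <- theta[seq_len(min(2L, length(theta)))]
  d2 <- c(d2, rep(0, 2L - length(d2)))
  gc <- u[, 1:2, drop = FALSE] %*% diag(pw(d2, scaling_f), 2L)
  ec <- v[, 1:2, drop = FALSE] %*% diag(pw(d2, 1 - scaling_f), 2L)
  dimnames(gc) <- list(gn, c("PC1", "PC2"))
  dimnames(ec) <- list(en, c("PC1", "PC2"))

  structure(list(centered = centered, theta = theta,
                 theta1 = d2[1], theta2 = d2[2],
                 genotype_coords = gc, environment_coords = ec,
                 scaling_f = scaling_f, var_explained = var_explained),
            class = "gge_model")
}

#' @export
print.gge_model <- function(x, ...) {
  cat(sprintf("GGE model: %d genotypes x %d environments (scaling f = %g)\n",
              nrow(x$genotype_coords), nrow(x$environment_coords), x$scaling_f))
  cat(sprintf("PC1 %.1f%%, PC2 %.1f%% of G+GE variation\n",
              100 * x$var_explained[1], 100 * x$var_explained[2]))
  invisible(x)
}

#' Environment-relationship view: angles and vector lengths
#'
#' The cosine of the angle between two environment vectors approximates
#' the correlation between the two environments' centered activity
#' profiles, so small angles mean near-identical genotype rankings;
#' longer environment vectors discriminate genotypes better.  The
#' approximation is exact when two axes capture all variation *and* the
#' model uses environment-focused scaling (`scaling_f = 0`, so
#' environment coordinates carry the full singular values); under
#' symmetric scaling the axis weights are \eqn{\sqrt{\theta_n}} and the
#' cosines are close but not identical.
#'
#' @param model a [fit_gge()] model.
#' @return A list with `env_angles` (symmetric `e x e` matrix of angles
#'   in radians, zero diagonal, NA for zero-length vectors) and
#'   `env_vector_lengths` (named vector of Euclidean norms).
#' @export
env_relationship <- function(model) {
  stopifnot(inherits(model, "gge_model"))
  ec <- model$environment_coords
  len <- sqrt(rowSums(ec^2))
  e <- nrow(ec)
  ang <- matrix(NA_real_, e, e, dimnames = list(rownames(ec), rownames(ec)))
  for (i in seq_len(e)) for (j in seq_len(e)) {
    if (len[i] == 0 || len[j] == 0) next
    cosij <- sum(ec[i, ] * ec[j, ]) / (len[i] * len[j])
    ang[i, j] <- acos(pmin(pmax(cosij, -1), 1))
  }
  diag(ang)[len > 0] <- 0
  list(env_angles = ang, env_vector_lengths = len)
}

#' Which-won-where view: convex hull, sectors and sector winners
#'
#' Computes the convex hull of the genotype markers in the biplot plane;
#' rays from the origin perpendicular to the hull edges partition the
#' plane into sectors, and every environment falling in a sector is
#' "won" by the sector's vertex genotype — the genotype maximizing the
#' inner product with that environment's vector, i.e. the rank-2
#' reconstruction of its centered activity.  Winners are therefore
#' independent of the singular-value scaling `f`.
#'
#' If the genotype markers are (numerically) collinear the hull geometry
#' degenerates; the function warns and still returns the inner-product
#' winner of each environment.
#'
#' @param model a [fit_gge()] model.
#' @param tol tie tolerance on inner products: genotypes within `tol` of
#'   the maximum are reported as joint winners.
#' @return A list with `hull_vertices` (genotype labels in hull order),
#'   `sectors` (named character vector: environment -> winning genotype;
#'   ties broken by genotype order), `ties` (list of all joint winners
#'   per environment), and `boundary_angles` (angles, in radians, of the
#'   sector-boundary rays; NULL when degenerate).
#' @export
which_won_where <- function(model, tol = 1e-9) {
  stopifnot(inherits(model, "gge_model"))
  gc <- model$genotype_coords; ec <- model$environment_coords
  gn <- rownames(gc)
  scores <- gc %*% t(ec)  # g x e inner products, scaling-invariant
  ties <- lapply(seq_len(ncol(scores)), function(j) {
    s <- scores[, j]
    gn[s >= max(s) - tol]
  })
  names(ties) <- rownames(ec)
  winners <- vapply(ties, `[`, character(1), 1L)

  degenerate <- nrow(gc) < 3L ||
    qr(sweep(gc, 2L, colMeans(gc)))$rank < 2L
  if (degenerate) {
    warning("genotype markers are collinear in the biplot plane; ",
            "sector geometry is degenerate, returning inner-product winners")
    return(list(hull_vertices = gn[!duplicated(gn)], sectors = winners,
                ties = ties, boundary_angles = NULL))
  }
  hull <- grDevices::chull(gc)  # clockwise order
  hv <- gn[hull]
  # perpendicular ray for each hull edge, oriented away from the origin side
  k <- length(hull)
  bang <- numeric(k)
  for (i in seq_len(k)) {
    a <- gc[hull[i], ]; b <- gc[hull[i %% k + 1L], ]
    d <- b - a
    nvec <- c(d[2], -d[1])
    if (sum(nvec * a) < 0) nvec <- -nvec
    bang[i] <- atan2(nvec[2], nvec[1])
  }
  list(hull_vertices = hv, sectors = winners, ties = ties,
       boundary_angles = sort(bang))
}

#' Mean-versus-stability view (average-environment coordination)
#'
#' The average-environment axis (AEC) is the unit vector from the origin
#' towards the mean of the environment markers.  A genotype's projection
#' onto the AEC is its mean-performance proxy (higher = more active on
#' average across environments); its orthogonal distance from the axis
#' is its instability proxy (larger = less stable ranking across
#' environments).
#'
#' @param model a [fit_gge()] model.
#' @return A list with `axis` (unit 2-vector), `aec_projection` and
#'   `aec_distance` (named g-vectors), and `ranking_activity`,
#'   `ranking_stability` (genotype labels, best first).
#' @export
mean_vs_stability <- function(model) {
  stopifnot(inherits(model, "gge_model"))
  me <- colMeans(model$environment_coords)
  len <- sqrt(sum(me^2))
  if (len < 1e-12)
    stop("average environment vector has zero length; AEC axis undefined")
  axis <- me / len
  gc <- model$genotype_coords
  proj <- drop(gc %*% axis)
  dist <- abs(drop(gc %*% c(-axis[2], axis[1])))
  list(axis = axis, aec_projection = proj, aec_distance = dist,
       ranking_activity = names(sort(proj, decreasing = TRUE)),
       ranking_stability = names(sort(dist)))
}

#' Ideal-entry (concentric circles) view
#'
#' The ideal entry sits on the positive average-environment axis at the
#' longest observed genotype projection: maximal mean performance with
#' zero instability.  Genotypes are ranked by Euclidean distance of
#' their biplot marker to this point; smaller is better on the combined
#' activity + stability criterion.
#'
#' @param model a [fit_gge()] model.
#' @return A list with `ideal_point` (2-vector), `ideal_distance` (named
#'   g-vector) and `ranking` (genotype labels, best first).
#' @export
ideal_entry <- function(model) {
  ms <- mean_vs_stability(model)
  ideal <- max(ms$aec_projection) * ms$axis
  gc <- model$genotype_coords
  d <- sqrt((gc[, 1] - ideal[1])^2 + (gc[, 2] - ideal[2])^2)
  list(ideal_point = ideal, ideal_distance = d, ranking = names(sort(d)))
}

#' All four GGE biplot views at once
#'
#' @param model a [fit_gge()] model.
#' @return A list with components `relationship`, `which_won_where`,
#'   `mean_vs_stability` and `ideal_entry`, as returned by the individual
#'   view functions.
#' @export
gge_views <- function(model) {
  list(relationship = env_relationship(model),
       which_won_where = which_won_where(model),
       mean_vs_stability = mean_vs_stability(model),
       ideal_entry = ideal_entry(model))
}

#' Plot a GGE biplot view
#'
#' Base-graphics rendering of the four standard panels: environment
#' vectors ("relationship"), convex hull with sector boundaries
#' ("which-won-where"), the average-environment axis with genotype
#' projections ("mean-stability"), and concentric circles around the
#' ideal entry ("ideal").
#'
#' @param x a [fit_gge()] model.
#' @param view one of `"relationship"`, `"which-won-where"`,
#'   `"mean-stability"`, `"ideal"`.
#' @param ... passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.gge_model <- function(x, view = c("relationship", "which-won-where",
                                       "mean-stability", "ideal"), ...) {
  view <- match.arg(view)
  gc <- x$genotype_coords; ec <- x$environment_coords
  lim <- range(c(gc, ec, 0)) * 1.2
  graphics::plot(NA, xlim = lim, ylim = lim, asp = 1,
                 xlab = sprintf("PC1 (%.1f%%)", 100 * x$var_explained[1]),
                 ylab = sprintf("PC2 (%.1f%%)", 100 * x$var_explained[2]),
                 main = view, ...)
  graphics::abline(h = 0, v = 0, col = "grey80")
  graphics::arrows(0, 0, ec[, 1], ec[, 2], length = 0.08, col = "steelblue")
  graphics::text(ec, labels = rownames(ec), pos = 3, col = "steelblue")
  graphics::points(gc, pch = 19)
  graphics::text(gc, labels = rownames(gc), pos = 1)
  if (view == "which-won-where") {
    ww <- which_won_where(x)
    idx <- match(ww$hull_vertices, rownames(gc))
    graphics::polygon(gc[idx, 1], gc[idx, 2], border = "tomato")
    if (!is.null(ww$boundary_angles)) {
      rr <- max(abs(lim))
      for (a in ww$boundary_angles)
        graphics::segments(0, 0, rr * cos(a), rr * sin(a),
                           lty = 2, col = "tomato")
    }
  } else if (view %in% c("mean-stability", "ideal")) {
    ms <- mean_vs_stability(x)
    rr <- max(abs(lim))
    graphics::segments(-rr * ms$axis[1], -rr * ms$axis[2],
                       rr * ms$axis[1], rr * ms$axis[2], col = "darkgreen")
    if (view == "ideal") {
      ie <- ideal_entry(x)
      radii <- sort(unique(signif(ie$ideal_distance, 3)))
      tt <- seq(0, 2 * pi, length.out = 181)
      for (rad in radii)
        graphics::lines(ie$ideal_point[1] + rad * cos(tt),
                        ie$ideal_point[2] + rad * sin(tt),
                        col = "grey60", lty = 3)
      graphics::points(ie$ideal_point[1], ie$ideal_point[2],
                       pch = 8, col = "darkgreen")
    } else {
      for (i in seq_len(nrow(gc))) {
        pr <- sum(gc[i, ] * ms$axis) * ms$axis
        graphics::segments(gc[i, 1], gc[i, 2], pr[1], pr[2],
                           lty = 3, col = "grey50")
      }
    }
  }
  invisible(x)
}
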