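#' Gollob degrees of freedom for an interaction principal component axis
#'
#' The n-th axis of the SVD of a double-centered `g x e` interaction
#' matrix is conventionally attributed `g + e - 1 - 2n` degrees of
#' freedom (Gollob's rule).  Summed over all `min(g-1, e-1)` axes the
#' rule closes the interaction budget `(g-1)(e-1)` exactly.
#'
#' @param g,e numbers of genotypes and environments (integers >= 2).
#' @param n axis index, `1 <= n <= min(g-1, e-1)`.
#' @return Integer degrees of freedom.
#' @examples
#' gollob_df(4, 5, 1) # 6
#' gollob_df(6, 5, 1) # 8
#' @export
gollob_df <- function(g, e, n) {
  g <- as.integer(g); e <- as.integer(e); n <- as.integer(n)
  if (any(is.na(c(g, e, n))) || g < 2L || e < 2L)
    stop("g and e must be integers >= 2")
  if (n < 1L || n > min(g - 1L, e - 1L))
    stop(sprintf("axis index n = %d out of range 1..%d", n, min(g - 1L, e - 1L)))
  g + e - 1L - 2L * n
}

#' Fit the AMMI model (additive main effects and multiplicative interaction)
#'
#' Works on the genotype-by-environment table of cell means: the additive
#' part is the two-way ANOVA decomposition into grand mean, genotype
#' deviations \eqn{\rho_g} and environment deviations \eqn{\psi_e}; the
#' multiplicative part is the singular value decomposition of the
#' double-centered interaction residuals,
#'
#' \deqn{y_{ge} = \mu + \rho_g + \psi_e +
#'   \sum_{n=1}^{M} \theta_n \xi_{gn} \eta_{en} + \varepsilon_{ge}}
#'
#' where \eqn{\theta_n} is the n-th singular value and \eqn{\xi_{gn}},
#' \eqn{\eta_{en}} are unit-norm genotype and environment scores.  On the
#' raw-data scale each interaction principal component axis (IPCA)
#' carries a sum of squares \eqn{r\,\theta_n^2}, with Gollob degrees of
#' freedom, so that the retained axes plus the residual reproduce the
#' interaction SS exactly.
#'
#' The ANOVA table pools blocks and both split-plot error strata into a
#' single error line: error SS is the total SS minus the treatment SS
#' (all between-cell variation), with `g*e*r - 1 - (g*e - 1)` degrees of
#' freedom.  Treatment, genotype, environment, interaction and every
#' IPCA axis are F-tested against this pooled error mean square.
#'
#' Axis signs are arbitrary in an SVD; for reproducibility each axis is
#' oriented so that its environment score of largest magnitude is
#' positive.
#'
#' @param table an [activity_table()] (balanced, `r >= 2`).
#' @param n_axes number of IPCA axes retained in the ANOVA table (default
#'   2, matching the usual IPCA1/IPCA2/Residual presentation); capped at
#'   `min(g-1, e-1)`.  Remaining interaction SS goes to the residual row.
#' @return An object of class `ammi_fit`: a list with `mu`, `rho`, `psi`,
#'   `theta` (all `min(g-1, e-1)` singular values, non-increasing), score
#'   matrices `xi` (`g x K`) and `eta` (`e x K`), `axis_ss` (`r*theta^2`),
#'   `axis_df` (Gollob), `M` (retained axes), `residual_ss`,
#'   `residual_df`, `interaction_ss`, `r`, and `anova` (a data frame with
#'   sources `total`, `treatment`, genotype, environment, `interaction`,
#'   `IPCA1..M`, `residual`, `error` and columns `df`, `ss`, `ms`, `f`,
#'   `p`, `pct_total`).
#' @examples
#' spec <- sim_spec(g = 4, e = 5, r = 6)
#' fit <- fit_ammi(simulate_activity(spec, seed = 1))
#' fit$anova
#' @export
fit_ammi <- function(table, n_axes = 2L) {
  if (!inherits(table, "activity_table")) table <- as_activity_table(table)
  cm <- aggregate_cell_means(table)
  g <- nrow(cm$means); e <- ncol(cm$means); r <- cm$r
  if (r < 2L) stop("AMMI needs r >= 2 blocks to estimate an error stratum")
  if (g < 2L || e < 2L) stop("AMMI needs at least 2 genotypes and 2 environments")
  dec <- grand_decomposition(cm)

  K <- min(g - 1L, e - 1L)
  sv <- svd(dec$interaction_residuals, nu = K, nv = K)
  theta <- sv$d[seq_len(K)]
  xi <- sv$u; eta <- sv$v
  for (j in seq_len(K)) {
    if (theta[j] == 0) next
    i <- which.max(abs(eta[, j]))
    if (eta[i, j] < 0) { eta[, j] <- -eta[, j]; xi[, j] <- -xi[, j] }
  }
  rownames(xi) <- cm$genotype_order; rownames(eta) <- cm$environment_order
  colnames(xi) <- colnames(eta) <- paste0("IPCA", seq_len(K))

  y <- table$value
  grand <- mean(y)
  ss_total <- sum((y - grand)^2)
  ss_treat <- r * sum((cm$means - dec$mu)^2)
  ss_gen <- e * r * sum(dec$genotype_effects^2)
  ss_env <- g * r * sum(dec$environment_effects^2)
  ss_int <- r * sum(dec$interaction_residuals^2)
  ss_err <- max(ss_total - ss_treat, 0)

  axis_ss <- r * theta^2
  axis_df <- vapply(seq_len(K), function(n) gollob_df(g, e, n), integer(1))
  M <- max(0L, min(as.integer(n_axes), K))
  keep <- seq_len(M)
  residual_ss <- max(ss_int - sum(axis_ss[keep]), 0)
  residual_df <- (g - 1L) * (e - 1L) - sum(axis_df[keep])

  gname <- "genotype"; ename <- "environment"
  df_total <- g * e * r - 1L
  df_treat <- g * e - 1L
  df_err <- df_total - df_treat
  sources <- c("total", "treatment", gname, ename, "interaction",
               paste0("IPCA", keep), "residual", "error")
  dfs <- c(df_total, df_treat, g - 1L, e - 1L, (g - 1L) * (e - 1L),
           axis_df[keep], residual_df, df_err)
  sss <- c(ss_total, ss_treat, ss_gen, ss_env, ss_int,
           axis_ss[keep], residual_ss, ss_err)
  ms <- ifelse(dfs > 0L, sss / dfs, NA_real_)
  ms_err <- ss_err / df_err
  tested <- c(FALSE, TRUE, TRUE, TRUE, TRUE, rep(TRUE, M), FALSE, FALSE)
  f <- rep(NA_real_, length(sources)); p <- rep(NA_real_, length(sources))
  for (i in which(tested)) {
    if (!is.finite(ms[i]) || !is.finite(ms_err)) next
    if (ms_err <= 0) { f[i] <- if (ms[i] == 0) 0 else NA_real_; p[i] <- if (ms[i] == 0) 1 else NA_real_; next }
    f[i] <- ms[i] / ms_err
    p[i] <- stats::pf(f[i], dfs[i], df_err, lower.tail = FALSE)
  }
  anova <- data.frame(source = sources, df = dfs, ss = sss, ms = ms,
                      f = f, p = p, stringsAsFactors = FALSE)
  anova <- pct_of_total(anova)

  structure(list(mu = dec$mu, rho = dec$genotype_effects,
                 psi = dec$environment_effects,
                 interaction_residuals = dec$interaction_residuals,
                 theta = theta, xi = xi, eta = eta,
                 axis_ss = axis_ss, axis_df = axis_df, M = M,
                 residual_ss = residual_ss, residual_df = residual_df,
                 interaction_ss = ss_int, r = r,
                 genotype_order = cm$genotype_order,
                 environment_order = cm$environment_order,
                 anova = anova),
            class = "ammi_fit")
}

#' Fill the percent-of-SS column of an AMMI ANOVA table
#'
#' Follows the dual convention of the standard AMMI presentation: the
#' genotype, environment and interaction rows are expressed as a
#' percentage of the *total* SS, while each IPCA row is expressed as a
#' percentage of the *interaction* SS.  Other rows are left blank.
#' Percentages are undefined (NA) when their reference SS is zero.
#'
#' @param table an AMMI ANOVA data frame with columns `source`, `ss`
#'   (as produced by [fit_ammi()], or assembled from a published table).
#' @return The table with a `pct_total` column filled.
#' @export
pct_of_total <- function(table) {
  table <- as.data.frame(table)
  if (!all(c("source", "ss") %in% names(table)))
    stop("table must have columns source and ss")
  ss_tot <- table$ss[match("total", table$source)]
  ss_int <- table$ss[match("interaction", table$source)]
  pct <- rep(NA_real_, nrow(table))
  of_total <- !(table$source %in% c("total", "treatment", "residual", "error")) &
    !grepl("^IPCA", table$source)
  if (length(ss_tot) == 1L && !is.na(ss_tot) && ss_tot > 0)
    pct[of_total] <- 100 * table$ss[of_total] / ss_tot
  ipca <- grepl("^IPCA", table$source)
  if (length(ss_int) == 1L && !is.na(ss_int) && ss_int > 0)
    pct[ipca] <- 100 * table$ss[ipca] / ss_int
  table$pct_total <- pct
  table
}

#' @export
print.ammi_fit <- function(x, ...) {
  K <- length(x$theta)
  cat(sprintf("AMMI fit: %d genotypes x %d environments, %d blocks; %d of %d IPCA axes retained\n\n",
              nrow(x$xi), nrow(x$eta), x$r, x$M, K))
  print(format_anova(x$anova))
  if (x$interaction_ss > 0) {
    cat("\nIPCA share of interaction SS:",
        paste(sprintf("IPCA%d %.2f%%", seq_len(K),
                      100 * x$axis_ss / x$interaction_ss), collapse = ", "), "\n")
  }
  invisible(x)
}
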