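#' Balanced long-format activity table
#'
#' The common input container of the package: one row per measured
#' observation, identified by a genotype label (in enzyme-activity trials
#' the assayed enzyme or antioxidant factor plays the "genotype" role),
#' an environment label (for example a water temperature), and a complete
#' block (replicate) label.  The design must be fully balanced: every
#' (genotype, environment, block) combination occurs exactly once, so a
#' table with `g` genotypes, `e` environments and `r` blocks holds
#' `g * e * r` records.
#'
#' Labels are treated as opaque: numeric-looking environment labels such
#' as temperatures are never interpreted ordinally by any analysis; the
#' factor level orderings are used for display only.
#'
#' @param genotype,environment,block vectors of labels (coerced to
#'   character); must be non-empty strings.
#' @param value numeric vector of activity measurements; must be finite.
#' @param units unit string attached to the table (e.g. `"U/mg"`); purely
#'   descriptive.
#' @param genotype_order,environment_order,block_order optional explicit
#'   level orderings; default is order of first appearance.
#'
#' @return An object of class `activity_table`: a `data.frame` with factor
#'   columns `genotype`, `environment`, `block` and numeric column
#'   `value`, plus a `units` attribute.
#' @examples
#' tab <- activity_table(
#'   genotype    = rep(c("SOD", "CAT"), each = 4),
#'   environment = rep(rep(c("20C", "8C"), each = 2), 2),
#'   block       = rep(c("B1", "B2"), 4),
#'   value       = c(1, 3, 2, 4, 5, 7, 6, 8)
#' )
#' aggregate_cell_means(tab)
#' @export
activity_table <- function(genotype, environment, block, value, units = "",
                           genotype_order = NULL, environment_order = NULL,
                           block_order = NULL) {
  genotype <- as.character(genotype)
  environment <- as.character(environment)
  block <- as.character(block)
  n <- length(value)
  if (length(genotype) != n || length(environment) != n || length(block) != n)
    stop("genotype, environment, block and value must have equal length")
  if (!is.numeric(value) || any(!is.finite(value)))
    stop("activity values must be finite numbers")
  for (nm in c("genotype", "environment", "block")) {
    v <- get(nm)
    if (any(is.na(v) | !nzchar(v)))
      stop(sprintf("%s labels must be non-empty", nm))
  }
  first_seen <- function(x) x[!duplicated(x)]
  lv <- function(x, ord, nm) {
    if (is.null(ord)) ord <- first_seen(x)
    if (!setequal(ord, unique(x)))
      stop(sprintf("%s_order must list exactly the observed %s labels", nm, nm))
    factor(x, levels = ord)
  }
  out <- data.frame(
    genotype    = lv(genotype, genotype_order, "genotype"),
    environment = lv(environment, environment_order, "environment"),
    block       = lv(block, block_order, "block"),
    value       = as.numeric(value)
  )
  attr(out, "units") <- units
  class(out) <- c("activity_table", "data.frame")
  check_balance(out)
  out
}

#' Coerce a data frame to an activity table
#'
#' @param x a `data.frame` holding long-format observations.
#' @param genotype,environment,block,value names of the columns carrying
#'   each role (defaults match [read_activity_csv()]'s required header).
#' @inheritParams activity_table
#' @return An `activity_table`.
#' @export
as_activity_table <- function(x, genotype = "genotype",
                              environment = "environment", block = "block",
                              value = "value", units = "") {
  x <- as.data.frame(x)
  missing_cols <- setdiff(c(genotype, environment, block, value), names(x))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  activity_table(x[[genotype]], x[[environment]], x[[block]], x[[value]],
                 units = units)
}

# Hard check that every (genotype, environment, block) cell occurs exactly
# once; names the first offending combinations in the error message.
check_balance <- function(tab) {
  counts <- table(tab$genotype, tab$environment, tab$block)
  bad <- which(counts != 1, arr.ind = TRUE)
  if (nrow(bad) == 0L) return(invisible(tab))
  dn <- dimnames(counts)
  msgs <- apply(bad[seq_len(min(nrow(bad), 5L)), , drop = FALSE], 1L, function(i) {
    k <- counts[i[1], i[2], i[3]]
    sprintf("(genotype=%s, environment=%s, block=%s) appears %d times%s",
            dn[[1]][i[1]], dn[[2]][i[2]], dn[[3]][i[3]], k,
            if (k == 0L) " (missing)" else " (duplicated)")
  })
  stop("design is not balanced: ", paste(msgs, collapse = "; "),
       if (nrow(bad) > 5L) sprintf("; and %d more", nrow(bad) - 5L) else "")
}

#' @export
print.activity_table <- function(x, ...) {
  g <- nlevels(x$genotype); e <- nlevels(x$environment); r <- nlevels(x$block)
  cat(sprintf("Balanced activity table: %d genotypes x %d environments x %d blocks (%d records)\n",
              g, e, r, nrow(x)))
  u <- attr(x, "units")
  if (nzchar(u)) cat("Units:", u, "\n")
  print.data.frame(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat(sprintf("... %d more rows\n", nrow(x) - 10L))
  invisible(x)
}

#' Aggregate replicate observations into a genotype-by-environment table
#'
#' Averages the `r` block replicates of each (genotype, environment) cell,
#' producing the two-way table of cell means on which the AMMI and GGE
#' models operate.
#'
#' @param table an [activity_table()].
#' @return An object of class `cell_means`: a list with `means` (a
#'   `g x e` numeric matrix with genotype rows and environment columns),
#'   `r` (the block count), the level orderings, and the units string.
#' @export
aggregate_cell_means <- function(table) {
  if (!inherits(table, "activity_table"))
    table <- as_activity_table(table)
  means <- tapply(table$value, list(table$genotype, table$environment), mean)
  means <- matrix(as.numeric(means), nrow = nlevels(table$genotype),
                  dimnames = dimnames(means))
  structure(list(means = means,
                 r = nlevels(table$block),
                 genotype_order = levels(table$genotype),
                 environment_order = levels(table$environment),
                 units = attr(table, "units")),
            class = "cell_means")
}

#' @export
print.cell_means <- function(x, ...) {
  cat(sprintf("Cell means over %d blocks:\n", x$r))
  print(x$means)
  invisible(x)
}

#' Additive decomposition of a two-way table of cell means
#'
#' Splits a genotype-by-environment table into the grand mean, zero-sum
#' genotype deviations, zero-sum environment deviations, and the
#' double-centered interaction residual matrix whose row and column sums
#' are all zero.  This is the additive part shared by the AMMI model (the
#' residuals are what its SVD decomposes).
#'
#' @param matrix a `cell_means` object or a plain numeric matrix with
#'   genotype rows and environment columns.
#' @return A list with components `mu` (grand mean), `genotype_effects`,
#'   `environment_effects`, and `interaction_residuals` (`g x e` matrix).
#' @examples
#' grand_decomposition(matrix(c(2, 6, 3, 7), nrow = 2))
#' @export
grand_decomposition <- function(matrix) {
  m <- if (inherits(matrix, "cell_means")) matrix$means else as.matrix(matrix)
  if (!is.numeric(m)) stop("cell means must be numeric")
  mu <- mean(m)
  rho <- rowMeans(m) - mu
  psi <- colMeans(m) - mu
  resid <- sweep(sweep(m, 1L, rho + mu), 2L, psi)
  list(mu = mu, genotype_effects = rho, environment_effects = psi,
       interaction_residuals = resid)
}
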