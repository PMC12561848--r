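#' Split-plot analysis of variance with two error strata
#'
#' Fits the classical balanced split-plot ANOVA in which the main-plot
#' factor (here, water temperature) is randomized to whole plots within
#' complete blocks, and the sub-plot factor (the assayed enzyme or
#' antioxidant factor) is randomized within each main plot.  The model is
#'
#' \deqn{y_{mnp} = \mu + a_p + g_{mn} + h_{mp} + \varepsilon_{mnp}}
#'
#' with block effects \eqn{a_p}, treatment effects \eqn{g_{mn}}
#' (main factor, sub factor and their interaction), a main-plot error
#' \eqn{h_{mp}} with variance \eqn{\sigma_h^2} shared by all sub-plot
#' observations of a (main level, block) pair, and an independent
#' sub-plot error with variance \eqn{\sigma^2}.  The two error strata
#' give two F-test denominators: the main factor is tested against the
#' main-plot error mean square, while the sub factor and the interaction
#' are tested against the sub-plot error mean square.  No F is reported
#' for blocks.
#'
#' Sums of squares use the standard balanced decomposition from marginal
#' and cell means; they add exactly to the total sum of squares.
#'
#' @param table an [activity_table()] (or coercible data frame).
#' @param main_factor,sub_factor names of the table columns playing the
#'   main-plot and sub-plot roles; defaults assign `environment` to the
#'   main plots and `genotype` to the sub plots.
#' @return An object of class `splitplot_anova`: a list with `table` (a
#'   data frame of rows `blocks`, main factor, `main_plot_error`,
#'   sub factor, `interaction`, `sub_plot_error`, `total`, with columns
#'   `source`, `df`, `ss`, `ms`, `f`, `p`), and the design sizes `g`,
#'   `e`, `r`.  F statistics are `NA` when their denominator mean square
#'   is zero or undefined.
#' @examples
#' spec <- sim_spec(g = 4, e = 5, r = 6)
#' fit_split_plot(simulate_activity(spec, seed = 1))
#' @export
fit_split_plot <- function(table, main_factor = "environment",
                           sub_factor = "genotype") {
  if (!inherits(table, "activity_table")) table <- as_activity_table(table)
  roles <- c(main_factor, sub_factor)
  if (!all(roles %in% c("genotype", "environment")) || main_factor == sub_factor)
    stop("main_factor and sub_factor must name the two distinct treatment columns")
  main <- table[[main_factor]]
  sub <- table[[sub_factor]]
  blk <- table$block
  y <- table$value
  e <- nlevels(main); g <- nlevels(sub); r <- nlevels(blk)
  if (r < 2L)
    stop("split-plot analysis needs at least 2 blocks (error strata have 0 df with r = 1)")

  grand <- mean(y)
  m_b <- tapply(y, blk, mean)
  m_e <- tapply(y, main, mean)
  m_g <- tapply(y, sub, mean)
  m_eb <- tapply(y, list(main, blk), mean)
  m_ge <- tapply(y, list(sub, main), mean)

  ss_blocks <- g * e * sum((m_b - grand)^2)
  ss_main <- g * r * sum((m_e - grand)^2)
  ss_mpe <- g * sum((sweep(sweep(m_eb, 1L, m_e), 2L, m_b) + grand)^2)
  ss_sub <- e * r * sum((m_g - grand)^2)
  ss_int <- r * sum((sweep(sweep(m_ge, 1L, m_g), 2L, m_e) + grand)^2)
  ss_total <- sum((y - grand)^2)
  ss_spe <- ss_total - ss_blocks - ss_main - ss_mpe - ss_sub - ss_int
  ss_spe <- max(ss_spe, 0)

  df <- c(blocks = r - 1L,
          main = e - 1L,
          mpe = (e - 1L) * (r - 1L),
          sub = g - 1L,
          int = (e - 1L) * (g - 1L),
          spe = e * (r - 1L) * (g - 1L),
          total = g * e * r - 1L)
  ss <- c(ss_blocks, ss_main, ss_mpe, ss_sub, ss_int, ss_spe, ss_total)
  ms <- ifelse(df > 0L, ss / df, NA_real_)

  f <- rep(NA_real_, 7L); p <- rep(NA_real_, 7L)
  safe_f <- function(num, den, df1, df2) {
    if (!is.finite(ms[den]) || ms[den] <= 0) return(c(NA_real_, NA_real_))
    fv <- ms[num] / ms[den]
    c(fv, stats::pf(fv, df1, df2, lower.tail = FALSE))
  }
  fp <- safe_f(2L, 3L, df["main"], df["mpe"]); f[2] <- fp[1]; p[2] <- fp[2]
  fp <- safe_f(4L, 6L, df["sub"], df["spe"]); f[4] <- fp[1]; p[4] <- fp[2]
  fp <- safe_f(5L, 6L, df["int"], df["spe"]); f[5] <- fp[1]; p[5] <- fp[2]

  sources <- c("blocks", main_factor, "main_plot_error", sub_factor,
               "interaction", "sub_plot_error", "total")
  out <- list(table = data.frame(source = sources, df = unname(df),
                                 ss = unname(ss), ms = unname(ms),
                                 f = f, p = p, stringsAsFactors = FALSE),
              g = g, e = e, r = r,
              main_factor = main_factor, sub_factor = sub_factor)
  class(out) <- "splitplot_anova"
  out
}

#' Rebuild mean squares, F and p from sums of squares alone
#'
#' Given ANOVA rows as (source, ss, df) and a map declaring which source
#' is the F-test denominator of which, recomputes `ms = ss/df`,
#' `F = ms_num/ms_den`, and the upper-tail p-value from the F
#' distribution.  This is the arithmetic core of the published-table
#' validation harness: printed ANOVA tables carry SS and df at full
#' printed precision, and everything else is derivable.
#'
#' Rows with `df = 0` get an undefined (NA) mean square; a row whose
#' numerator mean square is zero gets `F = 0` (and p = 1).  Negative
#' sums of squares are an error.
#'
#' @param rows a data frame with columns `source`, `ss`, `df`.
#' @param denominator_map named character vector mapping numerator source
#'   names to denominator source names; sources not named get no F test.
#' @return A data frame with columns `source`, `df`, `ss`, `ms`, `f`, `p`.
#' @examples
#' rows <- data.frame(source = c("temperature", "main_plot_error"),
#'                    ss = c(215.4319, 687.4302), df = c(4, 20))
#' ms_f_from_ss(rows, c(temperature = "main_plot_error"))
#' @export
ms_f_from_ss <- function(rows, denominator_map) {
  rows <- as.data.frame(rows)
  if (!all(c("source", "ss", "df") %in% names(rows)))
    stop("rows must have columns source, ss, df")
  if (any(rows$ss < 0)) stop("negative sum of squares")
  missing_den <- setdiff(unname(denominator_map), rows$source)
  if (length(missing_den))
    stop("denominator source(s) not present: ", paste(missing_den, collapse = ", "))
  ms <- ifelse(rows$df > 0, rows$ss / rows$df, NA_real_)
  f <- rep(NA_real_, nrow(rows)); p <- rep(NA_real_, nrow(rows))
  for (num in intersect(names(denominator_map), rows$source)) {
    i <- match(num, rows$source)
    j <- match(denominator_map[[num]], rows$source)
    if (!is.finite(ms[i]) || !is.finite(ms[j])) next
    if (ms[i] == 0) { f[i] <- 0; p[i] <- 1; next }
    if (ms[j] <= 0) next
    f[i] <- ms[i] / ms[j]
    p[i] <- stats::pf(f[i], rows$df[i], rows$df[j], lower.tail = FALSE)
  }
  data.frame(source = rows$source, df = rows$df, ss = rows$ss,
             ms = ms, f = f, p = p, stringsAsFactors = FALSE)
}

#' @export
print.splitplot_anova <- function(x, ...) {
  cat(sprintf("Split-plot ANOVA (main plots: %s, sub plots: %s; %d x %d x %d design)\n\n",
              x$main_factor, x$sub_factor, x$g, x$e, x$r))
  print(format_anova(x$table))
  invisible(x)
}

#' Round an ANOVA data frame the way the field's tables print it
#'
#' SS and MS to 4 decimals, F to 3, and p-values below 0.001 rendered as
#' `"<0.001"`.  Used by the print methods; all stored numbers remain at
#' full precision.
#'
#' @param tab a data frame with (some of) columns `ss`, `ms`, `f`, `p`,
#'   `pct_total`.
#' @return A character data frame ready for printing.
#' @export
format_anova <- function(tab) {
  out <- tab
  num <- function(v, d) ifelse(is.na(v), "", formatC(v, format = "f", digits = d))
  for (col in intersect(c("ss", "ms"), names(out))) out[[col]] <- num(tab[[col]], 4L)
  if ("f" %in% names(out)) out$f <- num(tab$f, 3L)
  if ("pct_total" %in% names(out)) out$pct_total <- num(tab$pct_total, 4L)
  if ("p" %in% names(out))
    out$p <- ifelse(is.na(tab$p), "",
                    ifelse(tab$p < 0.001, "<0.001",
                           formatC(tab$p, format = "f", digits = 4L)))
  out
}
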