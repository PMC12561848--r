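#' Bundled reference ANOVA tables
#'
#' The package ships six published split-plot and AMMI ANOVA tables from
#' a multi-environment enzyme-activity study of large yellow croaker
#' under natural winter water cooling (antioxidant factors in liver and
#' muscle, and serum enzymes, each measured at five temperatures in six
#' blocks).  Each fixture stores the printed cells as character strings
#' — sources, degrees of freedom, sums of squares, mean squares, F,
#' p-values and percent-of-SS — so the printed number of decimals is
#' preserved.
#'
#' @param name optional fixture name (without extension); with no
#'   argument, all six are returned.
#' @return A named list of character data frames (or a single data frame
#'   when `name` is given).
#' @export
reference_tables <- function(name = NULL) {
  dir <- system.file("extdata", "reference_tables", package = "gxetools")
  files <- list.files(dir, pattern = "[.]csv$", full.names = TRUE)
  tabs <- lapply(files, utils::read.csv, colClasses = "character")
  names(tabs) <- sub("[.]csv$", "", basename(files))
  if (!is.null(name)) {
    if (!name %in% names(tabs))
      stop("unknown reference table: ", name, " (available: ",
           paste(names(tabs), collapse = ", "), ")")
    return(tabs[[name]])
  }
  tabs
}

# decimals printed after the point in a number string
printed_decimals <- function(s) nchar(sub("^[^.]*[.]?", "", s))

# Agreement "at printed precision": the printed SS are themselves rounded,
# so a value recomputed from them can differ from the printed one by up to
# about one unit in the last printed digit even when both derive from the
# same full-precision table.  Match is therefore |computed - printed| <=
# one unit of the last printed decimal place.
agree_printed <- function(computed, printed) {
  if (is.na(printed) || !nzchar(printed)) return(NA)
  if (printed == "<0.001") return(is.finite(computed) && computed < 0.001)
  p <- suppressWarnings(as.numeric(printed))
  if (is.na(p)) return(NA)
  if (!is.finite(computed)) return(FALSE)
  if (p == 0 && printed_decimals(printed) == 0L) return(computed < 5e-5)
  abs(computed - p) <= 10^(-printed_decimals(printed)) + 1e-12
}

#' Replay the bundled published ANOVA tables from SS and df alone
#'
#' For every bundled reference table (see [reference_tables()]) the
#' harness takes only the printed sums of squares and degrees of freedom
#' and recomputes all derivable cells: mean squares, F statistics with
#' the correct denominator stratum (main-plot error for the main factor
#' and sub-plot error for sub factor and interaction in the split-plot
#' tables; the pooled error line for everything in the AMMI tables),
#' upper-tail F p-values, and both percent-of-SS conventions (main rows
#' as a share of total SS, IPCA rows as a share of interaction SS).
#' Each recomputed cell is compared with the printed one at printed
#' precision (within one unit of the last printed decimal; printed
#' `"<0.001"` and `"0"` p-cells are treated as upper bounds).
#'
#' @return An object of class `printed_table_report`: a data frame with
#'   columns `table`, `source`, `quantity`, `printed`, `computed`,
#'   `agree`.  The print method summarizes the mismatch count.
#' @examples
#' rep <- validate_printed_tables()
#' all(rep$agree)
#' @export
validate_printed_tables <- function() {
  tabs <- reference_tables()
  rows <- list()
  add <- function(tab_name, source, quantity, printed, computed) {
    if (is.na(printed) || !nzchar(printed)) return()
    rows[[length(rows) + 1L]] <<- data.frame(
      table = tab_name, source = source, quantity = quantity,
      printed = printed, computed = computed,
      agree = isTRUE(agree_printed(computed, printed)),
      stringsAsFactors = FALSE)
  }
  for (tab_name in names(tabs)) {
    tab <- tabs[[tab_name]]
    ss <- as.numeric(tab$ss); df <- as.numeric(tab$df)
    kind <- if (grepl("^splitplot", tab_name)) "splitplot" else "ammi"
    if (kind == "splitplot") {
      den_map <- c(environment = "main_plot_error",
                   genotype = "sub_plot_error",
                   interaction = "sub_plot_error")
    } else {
      err_sources <- setdiff(tab$source, c("total", "residual", "error"))
      den_map <- stats::setNames(rep("error", length(err_sources)), err_sources)
    }
    comp <- ms_f_from_ss(data.frame(source = tab$source, ss = ss, df = df),
                         den_map)
    for (i in seq_len(nrow(tab))) {
      add(tab_name, tab$source[i], "ms", tab$ms[i], comp$ms[i])
      add(tab_name, tab$source[i], "f", tab$f[i], comp$f[i])
      add(tab_name, tab$source[i], "p", tab$p[i], comp$p[i])
    }
    if (kind == "ammi" && "pct" %in% names(tab)) {
      pcts <- pct_of_total(data.frame(source = tab$source, ss = ss))
      for (i in seq_len(nrow(tab)))
        add(tab_name, tab$source[i], "pct", tab$pct[i], pcts$pct_total[i])
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("printed_table_report", "data.frame")
  out
}

#' @export
print.printed_table_report <- function(x, ...) {
  n_bad <- sum(!x$agree)
  cat(sprintf("Replayed %d printed cells across %d tables: %d mismatch(es)\n",
              nrow(x), length(unique(x$table)), n_bad))
  if (n_bad > 0) print.data.frame(x[!x$agree, ])
  invisible(x)
}
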