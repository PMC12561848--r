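#' Read a long-format activity CSV
#'
#' Expects a UTF-8 CSV with header columns `genotype`, `environment`,
#' `block`, `value` (extra columns are ignored, decimal point notation).
#' The table is validated and balance-checked; errors name the offending
#' rows or design cells.
#'
#' @param path path to the CSV file.
#' @param units unit string to attach (purely descriptive).
#' @return An [activity_table()].
#' @export
read_activity_csv <- function(path, units = "") {
  if (!file.exists(path)) stop("input file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("genotype", "environment", "block", "value")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("missing required column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "))
  v <- suppressWarnings(as.numeric(df$value))
  bad <- which(is.na(v) & !is.na(df$value))
  if (length(bad))
    stop("non-numeric value(s) in column 'value' at data row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  if (anyNA(v)) stop("missing value(s) in column 'value' at data row(s): ",
                     paste(utils::head(which(is.na(v)), 5L), collapse = ", "))
  activity_table(df$genotype, df$environment, df$block, v, units = units)
}

#' Write an activity table to CSV
#'
#' Full-precision (15 significant digits) long-format output that
#' round-trips through [read_activity_csv()].
#'
#' @param table an [activity_table()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_activity_csv <- function(table, path) {
  stopifnot(inherits(table, "activity_table"))
  df <- data.frame(genotype = as.character(table$genotype),
                   environment = as.character(table$environment),
                   block = as.character(table$block),
                   value = sprintf("%.15g", table$value))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an ANOVA table to CSV at full precision
#'
#' Accepts a fitted [fit_split_plot()] / [fit_ammi()] object or a plain
#' ANOVA data frame; numeric columns are written with 15 significant
#' digits (human-readable rounding is the job of [format_anova()]).
#'
#' @param x a `splitplot_anova`, `ammi_fit`, or ANOVA data frame.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_anova_csv <- function(x, path) {
  tab <- if (inherits(x, "splitplot_anova")) x$table
         else if (inherits(x, "ammi_fit")) x$anova
         else as.data.frame(x)
  out <- tab
  for (col in names(out))
    if (is.numeric(out[[col]]))
      out[[col]] <- ifelse(is.na(out[[col]]), "",
                           sprintf("%.15g", out[[col]]))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
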