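#' Dice similarity coefficient of two binary masks
#'
#' `DSC = 2 |A intersect B| / (|A| + |B|)`: 0 means no spatial overlap, 1
#' perfect alignment; values of 0.7 and above are conventionally read as good
#' agreement between two delineations. When both masks are empty the
#' coefficient is defined as 1 (perfect agreement on absence) with a
#' warning, since the ratio is otherwise 0/0.
#'
#' @param seg,ref [wmh_mask]s on a common grid.
#' @return Scalar in [0, 1].
#' @examples
#' a <- wmh_mask(array(c(1, 1, 0, 0, 0, 0, 0, 0), dim = c(2, 2, 2)))
#' dice(a, a)
#' @export
dice <- function(seg, ref) {
  stopifnot(inherits(seg, "wmh_mask"), inherits(ref, "wmh_mask"))
  check_same_grid(seg, ref)
  a <- sum(seg$data)
  b <- sum(ref$data)
  if (a + b == 0) {
    warning("both masks are empty; defining DSC = 1 (agreement on absence)",
            call. = FALSE)
    return(1)
  }
  2 * sum(seg$data * ref$data) / (a + b)
}

#' Paired two-tailed Student's t-test
#'
#' Tests a zero mean difference across matched pairs: `t = mean(a - b) /
#' (sd(a - b) / sqrt(n))` with `n - 1` degrees of freedom.
#'
#' @param a,b Equal-length numeric vectors of paired measurements.
#' @return List with `t`, `df`, `p`.
#' @export
paired_t <- function(a, b) {
  check_paired(a, b)
  d <- a - b
  if (stats::var(d) < .Machine$double.eps)
    stop("degenerate input: paired differences have zero variance",
         call. = FALSE)
  ht <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Pearson correlation (with r squared)
#'
#' @param a,b Equal-length numeric vectors, n >= 3, non-constant.
#' @return List with `r` and `r_squared`.
#' @export
pearson <- function(a, b) {
  check_paired(a, b, min_n = 3L)
  r <- stats::cor(a, b)
  list(r = r, r_squared = r^2)
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (ties averaged).
#'
#' @param a,b Equal-length numeric vectors, n >= 3, non-constant.
#' @return Scalar rho.
#' @export
spearman <- function(a, b) {
  check_paired(a, b, min_n = 3L)
  stats::cor(a, b, method = "spearman")
}

#' Ordinary least-squares regression of y on x
#'
#' @param x,y Equal-length numeric vectors, n >= 3; `x` non-constant.
#' @return List with `slope`, `intercept`, `F`, `df1`, `df2`, `r_squared`.
#' @export
linear_regression <- function(x, y) {
  check_paired(x, y, min_n = 3L)
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  fs <- sm$fstatistic
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       F = unname(fs[1]), df1 = unname(fs[2]), df2 = unname(fs[3]),
       r_squared = sm$r.squared)
}

check_paired <- function(a, b, min_n = 2L) {
  if (!is.numeric(a) || !is.numeric(b) || length(a) != length(b))
    stop("inputs must be numeric vectors of equal length", call. = FALSE)
  if (length(a) < min_n)
    stop("need at least ", min_n, " pairs", call. = FALSE)
  if (min_n >= 3L && (stats::var(a) == 0 || stats::var(b) == 0))
    stop("degenerate input: constant vector", call. = FALSE)
  invisible(TRUE)
}

#' Per-subject lesion-volume table
#'
#' A data frame of per-subject volumes (cm^3) in named columns, e.g.
#' `rater1`, `rater2`, `semi_automated`. Subject labels need not be unique;
#' positional pairing is what matters.
#'
#' @param subject Character vector of subject labels.
#' @param ... Named numeric columns of equal length (>= 2), all values >= 0.
#' @return A data frame of class `wmh_volume_table`.
#' @export
volume_table <- function(subject, ...) {
  cols <- list(...)
  if (length(cols) == 0 || is.null(names(cols)) || any(names(cols) == ""))
    stop("volume columns must be named", call. = FALSE)
  n <- length(subject)
  if (n < 2L) stop("need at least 2 subjects", call. = FALSE)
  for (nm in names(cols)) {
    if (length(cols[[nm]]) != n)
      stop("column ", nm, " has length ", length(cols[[nm]]),
           ", expected ", n, call. = FALSE)
    if (any(cols[[nm]] < 0))
      stop("column ", nm, " contains negative volumes", call. = FALSE)
  }
  out <- data.frame(subject = as.character(subject), cols,
                    stringsAsFactors = FALSE)
  class(out) <- c("wmh_volume_table", "data.frame")
  out
}

#' Read a volume or DSC table from CSV
#'
#' Expects a header row with a `subject` column followed by numeric columns.
#'
#' @param path CSV file path.
#' @return A `wmh_volume_table` data frame.
#' @export
read_volume_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"subject" %in% names(df))
    stop("CSV must contain a 'subject' column", call. = FALSE)
  do.call(volume_table,
          c(list(subject = df$subject),
            as.list(df[setdiff(names(df), "subject")])))
}

#' Agreement battery between segmentation methods
#'
#' For each requested pair of volume columns, computes per-column means and
#' SDs, the paired t-test, Pearson r and r squared, Spearman rho, and the
#' ordinary least-squares regression of the second column on the first. DSC
#' columns, when given, are summarised by mean and SD.
#'
#' @param table A [volume_table] (or the result of [read_volume_table()]).
#' @param dsc Optional named list (or `wmh_volume_table`) of per-subject DSC
#'   values aligned to the table's rows.
#' @param comparisons List of character pairs `c(x_column, y_column)`; by
#'   default all unordered pairs of volume columns.
#' @return An object of class `wmh_agreement` with elements
#'   `column_summary`, `comparisons` (one entry per pair holding `paired_t`,
#'   `pearson`, `spearman_rho`, `regression`) and `dsc_summary`.
#' @export
agreement_report <- function(table, dsc = NULL, comparisons = NULL) {
  stopifnot(inherits(table, "data.frame"))
  vol_cols <- setdiff(names(table), "subject")
  if (is.null(comparisons))
    comparisons <- utils::combn(vol_cols, 2, simplify = FALSE)
  column_summary <- data.frame(
    column = vol_cols,
    mean = vapply(table[vol_cols], mean, 0),
    sd = vapply(table[vol_cols], stats::sd, 0),
    row.names = NULL)

  cmp <- list()
  for (pair in comparisons) {
    x <- table[[pair[1]]]
    y <- table[[pair[2]]]
    key <- paste(pair, collapse = "_vs_")
    entry <- list(x = pair[1], y = pair[2], paired_t = paired_t(x, y))
    if (length(x) >= 3L) {
      entry$pearson <- pearson(x, y)
      entry$spearman_rho <- spearman(x, y)
      entry$regression <- linear_regression(x, y)
    }
    cmp[[key]] <- entry
  }

  dsc_summary <- NULL
  if (!is.null(dsc)) {
    if (inherits(dsc, "data.frame"))
      dsc <- as.list(dsc[setdiff(names(dsc), "subject")])
    dsc_summary <- data.frame(
      comparison = names(dsc),
      mean = vapply(dsc, mean, 0),
      sd = vapply(dsc, stats::sd, 0),
      row.names = NULL)
  }

  structure(list(column_summary = column_summary, comparisons = cmp,
                 dsc_summary = dsc_summary, n = nrow(table)),
            class = "wmh_agreement")
}

#' @export
print.wmh_agreement <- function(x, ...) {
  cat(sprintf("<wmh_agreement> n = %d subjects\n\n", x$n))
  cat("Lesion volumes (cm^3):\n")
  cs <- x$column_summary
  for (i in seq_len(nrow(cs)))
    cat(sprintf("  %-16s mean %6.2f  SD %6.2f\n",
                cs$column[i], cs$mean[i], cs$sd[i]))
  for (key in names(x$comparisons)) {
    c_ <- x$comparisons[[key]]
    cat(sprintf("\n%s vs %s:\n", c_$x, c_$y))
    cat(sprintf("  paired t = %.3f (df %d, p = %.4f)\n",
                c_$paired_t$t, c_$paired_t$df, c_$paired_t$p))
    if (!is.null(c_$pearson)) {
      cat(sprintf("  Pearson r = %.3f (r^2 = %.3f), Spearman rho = %.3f\n",
                  c_$pearson$r, c_$pearson$r_squared, c_$spearman_rho))
      cat(sprintf("  OLS: slope %.3f, intercept %.3f, F(%d,%d) = %.3f\n",
                  c_$regression$slope, c_$regression$intercept,
                  c_$regression$df1, c_$regression$df2, c_$regression$F))
    }
  }
  if (!is.null(x$dsc_summary)) {
    cat("\nDice similarity coefficients:\n")
    ds <- x$dsc_summary
    for (i in seq_len(nrow(ds)))
      cat(sprintf("  %-32s mean %4.2f  SD %4.2f\n",
                  ds$comparison[i], ds$mean[i], ds$sd[i]))
  }
  invisible(x)
}

#' Serialise an agreement report to JSON
#'
#' @param report A `wmh_agreement`.
#' @param path Optional output file.
#' @return JSON string (invisibly when written to file).
#' @export
agreement_report_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "wmh_agreement"))
  js <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Paths to the bundled example volume and DSC tables
#'
#' Per-subject lesion volumes from two manual raters and the semi-automated
#' pipeline (`table1.csv`), and pairwise Dice coefficients between the three
#' segmentations (`table2.csv`), for 30 subjects.
#'
#' @param which `"table1"` (volumes) or `"table2"` (DSC).
#' @return File path to the CSV.
#' @export
wmh_example_table <- function(which = c("table1", "table2")) {
  which <- match.arg(which)
  system.file("extdata", paste0(which, ".csv"), package = "wmhseg",
              mustWork = TRUE)
}
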