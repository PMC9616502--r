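#' Classify repeat copies by factor binding
#'
#' A copy is labelled bound when it shares at least `min_overlap` bases
#' with the merged peak set (half-open semantics: abutting peak and copy
#' share no base and do not bind). The default of 1 bp is the loosest
#' reproducible criterion; tighten via `min_overlap` if peak calls are
#' noisy. Always `n_bound + n_unbound = length(copies)`.
#'
#' @param copies a `GRanges` of repeat copies.
#' @param peaks a `GRanges` of peaks (any condition/replicate union).
#' @param min_overlap minimum shared bases (default 1).
#' @return `copies` with a logical metadata column `bound` added.
#' @export
classify_copies <- function(copies, peaks, min_overlap = 1L) {
  min_overlap <- .check_min_overlap(min_overlap)
  mcols(copies)$bound <- shared_bases(copies, peaks) >= min_overlap
  copies
}

#' Two-sample t-test (pooled or Welch)
#'
#' Classical unpaired Student's t-test with pooled variance
#' (`df = nx + ny - 2`) by default; set `var_equal = FALSE` for the Welch
#' form. Two-sided p-value from the t distribution. When both groups are
#' constant and equal, `t = 0, p = 1` by convention; when constant but
#' different, `t` is infinite and `p = 0`.
#'
#' @param x,y numeric vectors, each of length >= 2.
#' @param var_equal pooled-variance Student form (default `TRUE`).
#' @return A `t_test_result`: list with `t`, `df`, `p` (two-sided) and
#'   `method`.
#' @export
two_sample_t_test <- function(x, y, var_equal = TRUE) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2)
    stop("each group needs at least 2 non-missing values")
  nx <- length(x); ny <- length(y)
  vx <- stats::var(x); vy <- stats::var(y)
  delta <- mean(x) - mean(y)
  if (var_equal) {
    df <- nx + ny - 2
    sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / df
    se <- sqrt(sp2 * (1 / nx + 1 / ny))
    method <- "Student (pooled variance)"
  } else {
    se <- sqrt(vx / nx + vy / ny)
    df <- if (se > 0)
      (vx / nx + vy / ny)^2 /
        ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
    else nx + ny - 2
    method <- "Welch"
  }
  if (se == 0) {
    t <- if (delta == 0) 0 else sign(delta) * Inf
  } else {
    t <- delta / se
  }
  p <- 2 * pt(-abs(t), df)
  structure(list(t = t, df = df, p = p, method = method),
            class = "t_test_result")
}

#' @export
print.t_test_result <- function(x, ...) {
  cat("<t_test_result> ", x$method, ": t = ", format(x$t, digits = 4),
      ", df = ", format(x$df, digits = 4), ", p = ",
      format(x$p, digits = 3), " (two-sided)\n", sep = "")
  invisible(x)
}

#' Bound-vs-unbound group summary
#'
#' Summarizes length and percent divergence of labelled repeat copies:
#' per-group n, mean and SD, histogram counts at configurable bin widths,
#' and the two-sided t-test comparing groups on each metric.
#'
#' @param copies a `GRanges` with logical `bound` and numeric `divergence`
#'   metadata columns (see [classify_copies()], [copy_divergence()]).
#' @param length_bin histogram bin width for lengths in bp (default 100).
#' @param divergence_bin histogram bin width for percent divergence
#'   (default 1).
#' @param var_equal passed to [two_sample_t_test()].
#' @return A `group_summary`: list with `stats` (data.frame of per-group
#'   n/mean/sd for both metrics), `length_hist` and `divergence_hist`
#'   (data.frames of per-bin counts), and `t_length`, `t_divergence`.
#' @export
group_summary <- function(copies, length_bin = 100, divergence_bin = 1,
                          var_equal = TRUE) {
  bound <- mcols(copies)$bound
  d <- mcols(copies)$divergence
  if (is.null(bound) || is.null(d))
    stop("copies need 'bound' and 'divergence' metadata columns")
  if (!any(bound) || !any(!bound))
    stop("a group is empty; inspect the peak set and classification ",
         "min_overlap before summarizing")
  L <- width(copies)
  grp <- function(v) data.frame(
    group = c("bound", "unbound"),
    n = c(sum(bound), sum(!bound)),
    mean = c(mean(v[bound]), mean(v[!bound])),
    sd = c(stats::sd(v[bound]), stats::sd(v[!bound])))
  st_L <- grp(L); names(st_L)[3:4] <- c("mean_length", "sd_length")
  st_d <- grp(d); names(st_d)[3:4] <- c("mean_divergence", "sd_divergence")
  stats_df <- cbind(st_L, st_d[3:4])

  histogram <- function(v, bw) {
    breaks <- seq(floor(min(v) / bw) * bw, ceiling(max(v) / bw) * bw + bw,
                  by = bw)
    data.frame(
      bin_start = head(breaks, -1L),
      bound = as.integer(table(cut(v[bound], breaks, right = FALSE))),
      unbound = as.integer(table(cut(v[!bound], breaks, right = FALSE))))
  }
  structure(list(
    stats = stats_df,
    length_hist = histogram(L, length_bin),
    divergence_hist = histogram(d, divergence_bin),
    t_length = two_sample_t_test(L[bound], L[!bound], var_equal),
    t_divergence = two_sample_t_test(d[bound], d[!bound], var_equal)),
    class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  print(x$stats, row.names = FALSE)
  cat("length:     t = ", format(x$t_length$t, digits = 4), ", p = ",
      format(x$t_length$p, digits = 3), "\n", sep = "")
  cat("divergence: t = ", format(x$t_divergence$t, digits = 4), ", p = ",
      format(x$t_divergence$p, digits = 3), "\n", sep = "")
  invisible(x)
}
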