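#' Paired Student's t-test with star annotation
#'
#' Standard paired t on per-cell value pairs (wraps [stats::t.test()]),
#' reporting the raw p value alongside the conventional star annotation at
#' thresholds 0.05 / 0.01 / 0.001. No multiplicity adjustment is applied.
#' Constant nonzero differences (zero variance) are reported as `t = Inf`,
#' `p = 0` with a `degenerate` flag; identical pairs are an error.
#'
#' @param x,y Paired numeric vectors (one value per cell), no missing
#'   halves, >= 2 pairs.
#' @param tail `"two_sided"`, `"one_sided_greater"` (mean of `x - y` > 0) or
#'   `"one_sided_less"`.
#' @return An object of class `test_result`: `statistic`, `p_value`, `n`,
#'   `df`, `tail`, `paired`, `stars`, `degenerate`.
#' @export
paired_t <- function(x, y, tail = c("two_sided", "one_sided_greater",
                                    "one_sided_less")) {
  tail <- match.arg(tail)
  if (length(x) != length(y)) stop("x and y must be paired")
  if (anyNA(x) || anyNA(y)) stop("missing halves are not allowed")
  if (length(x) < 2) stop("need >= 2 pairs")
  d <- x - y
  if (stats::sd(d) == 0) {
    if (all(d == 0)) stop("degenerate test: all pairs identical")
    stat <- sign(mean(d)) * Inf
    p <- switch(tail, two_sided = 0,
                one_sided_greater = if (mean(d) > 0) 0 else 1,
                one_sided_less = if (mean(d) < 0) 0 else 1)
    return(new_test_result(stat, p, length(x), length(x) - 1, tail,
                           paired = TRUE, degenerate = TRUE))
  }
  ht <- stats::t.test(x, y, paired = TRUE, alternative = .alt(tail))
  new_test_result(unname(ht$statistic), ht$p.value, length(x),
                  unname(ht$parameter), tail, paired = TRUE)
}

#' Two-sample (unpaired) t-test with star annotation
#'
#' @param g1,g2 Numeric vectors (each n >= 2).
#' @param tail As in [paired_t()]; `"one_sided_greater"` tests mean(g1) >
#'   mean(g2).
#' @param var_equal Pooled-variance t by default; `FALSE` for Welch.
#' @return A `test_result`.
#' @export
unpaired_t <- function(g1, g2, tail = c("two_sided", "one_sided_greater",
                                        "one_sided_less"), var_equal = TRUE) {
  tail <- match.arg(tail)
  if (length(g1) < 2 || length(g2) < 2) stop("each group needs n >= 2")
  if (stats::sd(g1) == 0 && stats::sd(g2) == 0) {
    if (mean(g1) == mean(g2)) stop("degenerate test: no variance, equal means")
    stat <- sign(mean(g1) - mean(g2)) * Inf
    p <- switch(tail, two_sided = 0,
                one_sided_greater = if (mean(g1) > mean(g2)) 0 else 1,
                one_sided_less = if (mean(g1) < mean(g2)) 0 else 1)
    return(new_test_result(stat, p, length(g1) + length(g2),
                           length(g1) + length(g2) - 2, tail,
                           paired = FALSE, degenerate = TRUE))
  }
  ht <- stats::t.test(g1, g2, var.equal = var_equal, alternative = .alt(tail))
  new_test_result(unname(ht$statistic), ht$p.value, length(g1) + length(g2),
                  unname(ht$parameter), tail, paired = FALSE)
}

.alt <- function(tail) switch(tail, two_sided = "two.sided",
                              one_sided_greater = "greater",
                              one_sided_less = "less")

new_test_result <- function(statistic, p_value, n, df, tail, paired,
                            degenerate = FALSE) {
  structure(list(statistic = statistic, p_value = p_value, n = n, df = df,
                 tail = tail, paired = paired, stars = p_stars(p_value),
                 degenerate = degenerate),
            class = "test_result")
}

#' Star annotation for a p value
#'
#' `"***"` for p < 0.001, `"**"` for p < 0.01, `"*"` for p < 0.05, `""`
#' otherwise. Reports always carry the raw p value alongside.
#' @param p p value(s).
#' @return Character vector of stars.
#' @export
p_stars <- function(p) {
  vapply(p, function(pp) {
    if (is.na(pp)) NA_character_
    else if (pp < 0.001) "***"
    else if (pp < 0.01) "**"
    else if (pp < 0.05) "*"
    else ""
  }, "")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<test_result> %s %s t = %.3g, df = %.3g, n = %d, p = %.3g %s%s\n",
              if (x$paired) "paired" else "unpaired", x$tail,
              x$statistic, x$df, x$n, x$p_value, x$stars,
              if (x$degenerate) " [degenerate: zero-variance guard]" else ""))
  invisible(x)
}
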