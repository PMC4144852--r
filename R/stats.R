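#' Two-sample Student's t-test
#'
#' Classic pooled-variance two-sided test (Welch available behind
#' `var_equal = FALSE`).  Implemented from the closed form so that the
#' degenerate zero-variance case can follow the fixed convention: equal
#' means give t = 0, p = 1; unequal means with zero pooled variance are an
#' error.
#'
#' @param group_a,group_b numeric vectors, each of length >= 2.
#' @param labels group labels for reporting.
#' @param var_equal pooled-variance Student test (default) or Welch.
#' @param alpha significance level for the `significant` flag.
#' @return object of class `group_comparison`: labels, n, means, sd, se,
#'   `t`, `df`, `p`, `significant`.
#' @examples
#' students_t_test(c(1, 2, 3), c(1, 2, 3))$p   # 1
#' @export
students_t_test <- function(group_a, group_b, labels = c("A", "B"),
                            var_equal = TRUE, alpha = 0.05) {
  stopifnot(length(group_a) >= 2L, length(group_b) >= 2L)
  n1 <- length(group_a)
  n2 <- length(group_b)
  m1 <- mean(group_a)
  m2 <- mean(group_b)
  v1 <- stats::var(group_a)
  v2 <- stats::var(group_b)
  if (var_equal) {
    df <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
    if (sp2 == 0) {
      if (m1 == m2) {
        tt <- 0
        p <- 1
      } else stop("degenerate test: zero pooled variance with unequal means")
    } else {
      tt <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
      p <- 2 * stats::pt(-abs(tt), df)
    }
  } else {
    se2 <- v1 / n1 + v2 / n2
    if (se2 == 0) {
      if (m1 == m2) {
        tt <- 0
        p <- 1
        df <- n1 + n2 - 2
      } else stop("degenerate test: zero variance with unequal means")
    } else {
      tt <- (m1 - m2) / sqrt(se2)
      df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
      p <- 2 * stats::pt(-abs(tt), df)
    }
  }
  structure(list(labels = labels, n = c(n1, n2), means = c(m1, m2),
                 sd = c(sqrt(v1), sqrt(v2)),
                 se = c(sqrt(v1 / n1), sqrt(v2 / n2)),
                 t = tt, df = df, p = p, alpha = alpha,
                 significant = p < alpha),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s (n=%d, mean %.4g) vs %s (n=%d, mean %.4g): t=%.4g, df=%.4g, p=%.4g%s\n",
              x$labels[1], x$n[1], x$means[1], x$labels[2], x$n[2],
              x$means[2], x$t, x$df, x$p,
              if (x$significant) " *" else ""))
  invisible(x)
}
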