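#' Hoeffding's D statistic of bivariate dependence
#'
#' Nonparametric measure of the distance between the joint rank distribution
#' of `(x, y)` and what independence would predict. This is the classical
#' estimator built from the joint ranks,
#' `D = 30 * ((n-2)(n-3) D1 + D2 - 2(n-2) D3) / (n(n-1)(n-2)(n-3)(n-4))`,
#' where `Q_i` counts points concordantly below point i (with half weights for
#' ties), `R_i`, `S_i` are midranks, `D1 = sum (Q-1)(Q-2)`,
#' `D2 = sum (R-1)(R-2)(S-1)(S-2)`, `D3 = sum (R-2)(S-2)(Q-1)`. On the
#' 30-scaled convention used here D lies in about \[-0.5, 1\], reaching 1 for
#' a monotone association of distinct values and ~0 under independence.
#'
#' @param x,y Paired numeric vectors, length >= 5; neither may be constant
#'   (degenerate ranks).
#' @return The scaled D statistic (length 1).
#' @examples
#' hoeffding_d(1:10, (1:10)^2) # 1: monotone dependence
#' @export
hoeffding_d <- function(x, y) {
  if (length(x) != length(y)) {
    stop_domain("`x` and `y` must have equal length.")
  }
  n <- length(x)
  if (n < 5) {
    stop_domain("Hoeffding's D requires at least 5 paired observations.")
  }
  check_number(x, "x")
  check_number(y, "y")
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    stop_domain("Hoeffding's D is undefined for a constant vector.")
  }
  R <- rank(x) # midranks
  S <- rank(y)
  Q <- hoeffding_q(x, y)
  D1 <- sum((Q - 1) * (Q - 2))
  D2 <- sum((R - 1) * (R - 2) * (S - 1) * (S - 2))
  D3 <- sum((R - 2) * (S - 2) * (Q - 1))
  30 * ((n - 2) * (n - 3) * D1 + D2 - 2 * (n - 2) * D3) /
    (n * (n - 1) * (n - 2) * (n - 3) * (n - 4))
}

# Q_i: 1 + #{x_j < x_i & y_j < y_i} with half weight for single ties and
# quarter weight for double ties (j != i); chunked O(n^2) to bound memory
hoeffding_q <- function(x, y, chunk = 512L) {
  n <- length(x)
  Q <- numeric(n)
  for (start in seq.int(1L, n, by = chunk)) {
    i <- start:min(start + chunk - 1L, n)
    lx <- outer(x, x[i], "<")
    ly <- outer(y, y[i], "<")
    ex <- outer(x, x[i], "==")
    ey <- outer(y, y[i], "==")
    Q[i] <- 1 + colSums(lx & ly) +
      0.5 * colSums(ex & ly) +
      0.5 * colSums(lx & ey) +
      0.25 * (colSums(ex & ey) - 1)
  }
  Q
}
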