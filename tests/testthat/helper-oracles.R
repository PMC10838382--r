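# Independent oracles used across the suite.

# Hoeffding's D as an order-5 U-statistic: average over all ordered 5-tuples
# of distinct indices of (1/4) psi(i; j, k) psi(i; l, m) with
# psi(1; 2, 3) = [I(x2 <= x1) - I(x3 <= x1)] [I(y2 <= y1) - I(y3 <= y1)].
# Its expectation is the population D = integral of (F12 - F1 F2)^2 dF12;
# the package reports the 30-scaled convention, so impl == 30 * oracle.
hoeffding_tuples <- function(n) {
  idx <- as.matrix(expand.grid(i = 1:n, j = 1:n, k = 1:n, l = 1:n, m = 1:n))
  keep <- apply(idx, 1, function(r) length(unique(r)) == 5L)
  idx[keep, , drop = FALSE]
}

hoeffding_oracle <- function(x, y, tuples = hoeffding_tuples(length(x))) {
  ps1 <- (x[tuples[, "j"]] <= x[tuples[, "i"]]) - (x[tuples[, "k"]] <= x[tuples[, "i"]])
  ps2 <- (y[tuples[, "j"]] <= y[tuples[, "i"]]) - (y[tuples[, "k"]] <= y[tuples[, "i"]])
  ps3 <- (x[tuples[, "l"]] <= x[tuples[, "i"]]) - (x[tuples[, "m"]] <= x[tuples[, "i"]])
  ps4 <- (y[tuples[, "l"]] <= y[tuples[, "i"]]) - (y[tuples[, "m"]] <= y[tuples[, "i"]])
  mean(0.25 * ps1 * ps2 * ps3 * ps4)
}

# default concentration grids of the checkerboard design: taxane 1-100 nM,
# inhibitor 0.3-30 uM
doc_grid_m <- c(1, 3.16, 10, 31.6, 100) * 1e-9
rit_grid_m <- c(0.3, 0.949, 3, 9.49, 30) * 1e-6

# all permutations of 1..n, one per row
perms_of <- function(n) {
  if (n == 1) {
    return(matrix(1L, 1, 1))
  }
  sub <- perms_of(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

ref_path <- function(file) {
  system.file("extdata", file, package = "effluxr", mustWork = TRUE)
}
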