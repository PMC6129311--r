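# Shared fixtures and the independent t-test oracle.

# Closed-form log tail probability of the t distribution via the regularized
# incomplete beta function: for t >= 0, P(T > t) = I_x(df/2, 1/2) / 2 with
# x = df / (df + t^2); mirrored for t < 0. Deliberately avoids pt() so it is
# an independent route to the same quantity.
oracle_log_tail <- function(t, df) {
  x <- df / (df + t^2)
  if (t >= 0) {
    log(0.5) + stats::pbeta(x, df / 2, 0.5, log.p = TRUE)
  } else {
    log1p(-0.5 * stats::pbeta(x, df / 2, 0.5))
  }
}

# Closed-form one-sided two-sample t-test, computed from first principles.
oracle_set_log_p <- function(member, complement, var_equal = FALSE) {
  n1 <- length(member)
  n2 <- length(complement)
  v1 <- stats::var(member)
  v2 <- stats::var(complement)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  oracle_log_tail((mean(member) - mean(complement)) / se, df)
}

# Direct step-up BH oracle: q_(i) = min over j >= i of p_(j) * n / j.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(p[o] * n / seq_len(n))))
  pmin(1, q_sorted)[order(o)]
}

# Tiny expression table: 2 genes x 3 tissues, fully observed.
tiny_expr <- function() {
  expression_table(tibble::tibble(
    gene = rep(c("G1", "G2"), each = 3),
    tissue = rep(c("liver", "lung", "skin"), 2),
    value = c(10, 2, 0, 4, 4, 4)
  ))
}

# Tiny IHC table exercising all three evidence states for G1 (G2's skin
# record keeps "skin" inside the tissue intersection while G1 stays
# unrecorded there).
tiny_ihc <- function() {
  ihc_table(tibble::tibble(
    gene = c("G1", "G1", "G2", "G2"),
    tissue = c("liver", "lung", "liver", "skin"),
    level = c("High", "Not detected", "Low", "Low")
  ))
}

write_lines_tmp <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
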