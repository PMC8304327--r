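# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a deterministic sub-seed from a master seed
#'
#' Each simulator consumes one RNG stream seeded from its config; when a
#' simulator writes several tables it derives one sub-seed per table from the
#' master seed so that tables are individually reproducible.  Sub-seeds stay
#' below 2^31 - 1 (R integers are 32-bit).
#'
#' @param seed master integer seed.
#' @param offset table index (small non-negative integer).
#' @return an integer seed.
#' @keywords internal
sub_seed <- function(seed, offset = 0L) {
  as.integer((as.numeric(seed) * 1000003 + offset * 7919) %% (2^31 - 1))
}

#' Vectorised two-sample Student t-test across rows
#'
#' Equal-variance (pooled) two-sided t-test computed row-wise on two matrices,
#' the workhorse behind interactor calling where thousands of protein groups
#' are tested at once.  Rows with fewer than 2 finite values in either matrix
#' get NA.
#'
#' @param x,y numeric matrices with one row per feature.
#' @param var_equal pooled (Student, default) or Welch variance.
#' @return tibble with columns `mean_diff` (rowMeans(x) - rowMeans(y)), `t`,
#'   `df`, `p`.
#' @keywords internal
row_t_test <- function(x, y, var_equal = TRUE) {
  x <- as.matrix(x); y <- as.matrix(y)
  nx <- rowSums(is.finite(x)); ny <- rowSums(is.finite(y))
  mx <- rowMeans(x, na.rm = TRUE); my <- rowMeans(y, na.rm = TRUE)
  vx <- rowSums((x - mx)^2, na.rm = TRUE) / pmax(nx - 1, 1)
  vy <- rowSums((y - my)^2, na.rm = TRUE) / pmax(ny - 1, 1)
  if (var_equal) {
    sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
    se <- sqrt(sp2 * (1 / nx + 1 / ny))
    df <- nx + ny - 2
  } else {
    se <- sqrt(vx / nx + vy / ny)
    df <- (vx / nx + vy / ny)^2 /
      ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  }
  tt <- (mx - my) / se
  p <- 2 * stats::pt(abs(tt), df, lower.tail = FALSE)
  # degenerate groups: zero pooled variance -> p = 1 when means equal
  zero_se <- is.finite(se) & se == 0
  p[zero_se & (mx == my)] <- 1
  bad <- nx < 2 | ny < 2
  p[bad] <- NA_real_; tt[bad] <- NA_real_
  tibble::tibble(mean_diff = unname(mx - my), t = unname(tt),
                 df = unname(df), p = unname(p))
}

#' Vectorised one-sample Student t-test across rows
#'
#' Two-sided test of row means against `mu`; used for SILAC ratios where each
#' replicate carries both conditions in a single H/L ratio.
#'
#' @param x numeric matrix.
#' @param mu null value (default 0).
#' @return tibble with columns `mean`, `t`, `df`, `p`.
#' @keywords internal
row_t_test_one <- function(x, mu = 0) {
  x <- as.matrix(x)
  n <- rowSums(is.finite(x))
  m <- rowMeans(x, na.rm = TRUE)
  v <- rowSums((x - m)^2, na.rm = TRUE) / pmax(n - 1, 1)
  se <- sqrt(v / n)
  tt <- (m - mu) / se
  p <- 2 * stats::pt(abs(tt), n - 1, lower.tail = FALSE)
  p[is.finite(se) & se == 0 & m == mu] <- 1
  p[n < 2] <- NA_real_; tt[n < 2] <- NA_real_
  tibble::tibble(mean = unname(m), t = unname(tt), df = unname(n - 1),
                 p = unname(p))
}
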