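#' Column-wise pooled-variance two-sample t-test
#'
#' Student's t with pooled variance for every column of two matrices.
#' Sign convention: positive t means the first group has the larger
#' mean. Columns with zero pooled variance get t = 0, p = 1 and are
#' flagged degenerate.
#'
#' @param x,y numeric matrices (subjects x features) for the two groups.
#' @return list with numeric vectors `t`, `p`, scalar `df`, and logical
#'   `degenerate`.
#' @export
col_ttest_pooled <- function(x, y) {
  x <- as.matrix(x); y <- as.matrix(y)
  stopifnot(ncol(x) == ncol(y))
  n1 <- nrow(x); n2 <- nrow(y)
  if (n1 < 2L || n2 < 2L) stop("each group needs at least 2 subjects")
  m1 <- colMeans(x); m2 <- colMeans(y)
  v1 <- colVars(x); v2 <- colVars(y)
  df <- n1 + n2 - 2L
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  degen <- se <= 0 | !is.finite(se)
  tt <- (m1 - m2) / se
  tt[degen] <- 0
  p <- 2 * pt(-abs(tt), df)
  p[degen] <- 1
  list(t = tt, p = p, df = df, degenerate = degen)
}

#' Column-wise one-way fixed-effects ANOVA
#'
#' @param values numeric matrix, subjects x features.
#' @param groups factor or vector of group labels, length `nrow(values)`.
#' @return list with vectors `F`, `p` and scalar dfs `df1`, `df2`.
#' @export
col_anova_oneway <- function(values, groups) {
  values <- as.matrix(values)
  g <- factor(groups)
  k <- nlevels(g)
  if (k < 2L) stop("need at least 2 groups")
  n <- nrow(values)
  counts <- tabulate(g, nbins = k)
  if (any(counts < 2L)) stop("every group needs at least 2 subjects")
  grand <- colMeans(values)
  ssb <- numeric(ncol(values))
  ssw <- numeric(ncol(values))
  for (lev in seq_len(k)) {
    sub <- values[as.integer(g) == lev, , drop = FALSE]
    mg <- colMeans(sub)
    ssb <- ssb + nrow(sub) * (mg - grand)^2
    ssw <- ssw + (nrow(sub) - 1) * colVars(sub)
  }
  df1 <- k - 1L
  df2 <- n - k
  Fv <- (ssb / df1) / (ssw / df2)
  degen <- ssw <= 0 | !is.finite(Fv)
  Fv[degen] <- 0
  p <- pf(Fv, df1, df2, lower.tail = FALSE)
  p[degen] <- 1
  list(F = Fv, p = p, df1 = df1, df2 = df2)
}

# column variances without apply() overhead
colVars <- function(x) {
  n <- nrow(x)
  if (n < 2L) return(rep(NA_real_, ncol(x)))
  m <- colMeans(x)
  colSums((x - rep(m, each = n))^2) / (n - 1)
}

# Fisher z with clipping of |r| ~ 1; returns list(z, flagged)
fisher_z <- function(r, clip = 0.999999) {
  flagged <- is.finite(r) & abs(r) >= clip
  rc <- pmin(pmax(r, -clip), clip)
  list(z = atanh(rc), flagged = flagged)
}
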