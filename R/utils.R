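#' @importFrom stats median quantile rbinom rnbinom rnorm rpois runif rbeta
#'   pnorm pt cor sd setNames complete.cases
#' @importFrom utils head
NULL

#' Round half away from zero
#'
#' Printed percentages follow the half-up convention (89.45 -> 89.5), unlike
#' base R's banker's rounding.
#'
#' @param x numeric vector
#' @param digits decimal places
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 1) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment: sorted p * m / rank with a running minimum,
#' capped at 1. NA p-values stay NA and do not count toward m.
#'
#' @param p numeric vector of p-values
#' @return adjusted p-values, same order as input
#' @export
bh_adjust <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  m <- length(ok)
  if (m == 0L) return(out)
  pp <- p[ok]
  o <- order(pp, decreasing = TRUE)
  padj <- pmin(1, cummin(m / seq.int(m, 1L) * pp[o]))
  out[ok[o]] <- padj
  out
}

#' Derive a named RNG substream seed
#'
#' Each pipeline stage / generator draws from its own deterministic substream
#' of the global seed so stages are individually reproducible.
#'
#' @param seed integer global seed
#' @param stream character stream name
#' @return integer seed < 2^31
#' @export
substream_seed <- function(seed, stream) {
  v <- utf8ToInt(stream)
  h <- sum(v * seq_along(v)) %% 99991L
  as.integer((as.numeric(seed) %% 1048573) * 2017 + h * 7919) %% 2147483629L
}

# Vectorised Welch t-test over rows of x (groupB minus groupA).
# Returns data.frame(diff, t, df, p). Degenerate rows (zero pooled
# variance): p = 1 when means agree, p = 0 otherwise.
welch_t_rows <- function(x, ia, ib) {
  n1 <- length(ia); n2 <- length(ib)
  stopifnot(n1 >= 2L, n2 >= 2L)
  xa <- x[, ia, drop = FALSE]; xb <- x[, ib, drop = FALSE]
  m1 <- rowMeans(xa); m2 <- rowMeans(xb)
  v1 <- matrixStats::rowVars(xa); v2 <- matrixStats::rowVars(xb)
  se2 <- v1 / n1 + v2 / n2
  d <- m2 - m1
  tt <- d / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(-abs(tt), df)
  zero <- se2 <= 0 | !is.finite(tt)
  p[zero] <- ifelse(abs(d[zero]) < 1e-12, 1, 0)
  tt[zero] <- ifelse(abs(d[zero]) < 1e-12, 0, Inf * sign(d[zero]))
  data.frame(diff = d, t = tt, df = df, p = p)
}

# Vectorised two-sided Wilcoxon rank-sum over rows; group = column indices of
# group 1. Normal approximation with tie correction and continuity
# correction (the convention of wilcox.test(exact = FALSE, correct = TRUE)).
# Returns data.frame(U, p).
ranksum_rows <- function(x, group) {
  n1 <- length(group)
  n2 <- ncol(x) - n1
  stopifnot(n1 >= 1L, n2 >= 1L)
  r <- t(apply(x, 1L, rank))
  U <- rowSums(r[, group, drop = FALSE]) - n1 * (n1 + 1) / 2
  ties <- apply(x, 1L, function(v) {
    tb <- table(v)
    sum(tb^3 - tb)
  })
  n <- n1 + n2
  sigma2 <- n1 * n2 / 12 * ((n + 1) - ties / (n * (n - 1)))
  mu <- n1 * n2 / 2
  z <- U - mu
  cc <- pmin(abs(z), 0.5) * sign(z)
  z <- (z - cc) / sqrt(sigma2)
  p <- 2 * pnorm(-abs(z))
  p[sigma2 <= 0] <- 1
  p <- pmin(p, 1)
  data.frame(U = U, p = p)
}

# Adjusted Rand index between two label vectors.
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  choose2 <- function(v) sum(v * (v - 1) / 2)
  sij <- choose2(as.vector(tab))
  si <- choose2(rowSums(tab))
  sj <- choose2(colSums(tab))
  n <- length(a)
  tot <- n * (n - 1) / 2
  expected <- si * sj / tot
  den <- (si + sj) / 2 - expected
  if (den == 0) return(1)
  (sij - expected) / den
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_nb <- function(...) stop(sprintf(...), call. = FALSE)
warn_nb <- function(...) warning(sprintf(...), call. = FALSE)
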