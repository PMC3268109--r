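# First-principles implementations of the study's statistical comparisons:
# paired t, two-way repeated-measures ANOVA, OLS R^2, inter-observer CoV.

#' Paired t test
#'
#' \code{t = mean(d) / (sd(d) / sqrt(n))} on the paired differences, with a
#' two-sided p from the t distribution on n - 1 df.  All-zero differences
#' give t = 0, p = 1; zero-variance differences with non-zero mean give an
#' infinite t and p = 0.
#'
#' @param x,y paired samples (same subject order), length >= 2
#' @return list: \code{t}, \code{df}, \code{p}, \code{mean_diff}
#' @export
paired_t <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  d <- x - y
  n <- length(d)
  m <- mean(d); s <- stats::sd(d)
  if (s == 0) {
    t <- if (m == 0) 0 else sign(m) * Inf
  } else {
    t <- m / (s / sqrt(n))
  }
  p <- if (is.infinite(t)) 0 else 2 * stats::pt(-abs(t), df = n - 1)
  list(t = as.numeric(t), df = n - 1L, p = as.numeric(p), mean_diff = m)
}

#' Two-way repeated-measures ANOVA (within-subject factors)
#'
#' Classical within-subject decomposition for a complete balanced design
#' (every subject observed at every factor-level combination): each
#' factor's sum of squares is tested against its subject-interaction error
#' term (A vs A:S, B vs B:S, A:B vs A:B:S).  No sphericity correction is
#' applied.
#'
#' @param value response vector
#' @param subject,f1,f2 subject and factor codings (coerced to factor)
#' @return data.frame: \code{effect}, \code{df1}, \code{df2}, \code{F},
#'   \code{p}
#' @export
rm_anova <- function(value, subject, f1, f2) {
  subject <- factor(subject); f1 <- factor(f1); f2 <- factor(f2)
  ns <- nlevels(subject); na <- nlevels(f1); nb <- nlevels(f2)
  if (na < 2 || nb < 2) stop("each factor needs at least 2 levels")
  tab <- table(subject, f1, f2)
  if (any(tab != 1))
    stop("unbalanced or incomplete design: drop incomplete subjects first")
  if (stats::var(value) == 0)
    stop("constant response: F statistics undefined")
  gm <- mean(value)
  mean_by <- function(...) tapply(value, list(...), mean)
  mS <- mean_by(subject); mA <- mean_by(f1); mB <- mean_by(f2)
  mAS <- mean_by(subject, f1); mBS <- mean_by(subject, f2)
  mAB <- mean_by(f1, f2)
  ssA <- ns * nb * sum((mA - gm)^2)
  ssB <- ns * na * sum((mB - gm)^2)
  ssAB <- ns * sum((mAB - gm)^2) - ssA - ssB
  ssAS <- nb * sum(sweep(sweep(mAS, 1, mS - gm), 2, mA)^2)
  ssBS <- na * sum(sweep(sweep(mBS, 1, mS - gm), 2, mB)^2)
  ssT <- sum((value - gm)^2)
  ssS <- na * nb * sum((mS - gm)^2)
  ssABS <- ssT - ssS - ssA - ssB - ssAB - ssAS - ssBS
  dfA <- na - 1; dfB <- nb - 1; dfAB <- dfA * dfB
  dfAS <- dfA * (ns - 1); dfBS <- dfB * (ns - 1); dfABS <- dfAB * (ns - 1)
  Fa <- (ssA / dfA) / (ssAS / dfAS)
  Fb <- (ssB / dfB) / (ssBS / dfBS)
  Fab <- (ssAB / dfAB) / (ssABS / dfABS)
  data.frame(
    effect = c("f1", "f2", "f1:f2"),
    df1 = c(dfA, dfB, dfAB),
    df2 = c(dfAS, dfBS, dfABS),
    F = c(Fa, Fb, Fab),
    p = stats::pf(c(Fa, Fb, Fab), c(dfA, dfB, dfAB),
                  c(dfAS, dfBS, dfABS), lower.tail = FALSE))
}

#' Ordinary least-squares R-squared and slope p value
#'
#' \code{R^2 = 1 - SS_res / SS_tot}; the slope p value comes from the usual
#' t test on n - 2 df.
#'
#' @param x,y numeric vectors, n >= 3
#' @return list: \code{r2}, \code{slope}, \code{p}
#' @export
linreg_r2 <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::var(x) == 0) stop("zero-variance predictor")
  n <- length(x)
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a <- mean(y) - b * mean(x)
  resid <- y - a - b * x
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst == 0) 1 else 1 - sum(resid^2) / sst
  se <- sqrt(sum(resid^2) / (n - 2) / sum((x - mean(x))^2))
  tt <- if (se == 0) sign(b) * Inf else b / se
  p <- if (is.infinite(tt)) 0 else 2 * stats::pt(-abs(tt), df = n - 2)
  list(r2 = r2, slope = b, p = as.numeric(p))
}

#' Inter-observer agreement: mean difference and coefficient of variation
#'
#' Mean difference = \code{mean(a - b)}; CoV = SD of the paired differences
#' divided by the grand mean of both observers, in percent.  (Other CoV
#' definitions exist; this one is used consistently and documented.)
#'
#' @param a,b paired measurements from two observers
#' @return list: \code{mean_diff}, \code{cov_pct}
#' @export
interobserver_cov <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  gm <- mean(c(a, b))
  if (gm == 0) stop("grand mean is zero: CoV undefined")
  list(mean_diff = mean(a - b),
       cov_pct = 100 * stats::sd(a - b) / gm)
}
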