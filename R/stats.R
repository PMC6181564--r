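# Nonparametric population statistics: Wilcoxon signed-rank for paired
# measures (exact by enumeration for small samples, including ties) and
# Kruskal-Wallis for unpaired groups.

# Exact null distribution of twice the signed-rank statistic, conditional on
# the observed absolute-value ranks (midranks double to integers), as a
# generating polynomial over all 2^n equally likely sign assignments.
signed_rank_poly <- function(ranks2) {
  total <- sum(ranks2)
  poly <- numeric(total + 1L)
  poly[1L] <- 1
  for (r in ranks2) {
    shifted <- c(numeric(r), poly[seq_len(total + 1L - r)])
    poly <- poly + shifted
  }
  poly
}

#' Wilcoxon signed-rank test for paired measures
#'
#' Tests whether paired differences are symmetric about zero.  Zero
#' differences are dropped; absolute differences are midranked (ties
#' allowed).  For `n <= exact_limit` non-zero differences the two-sided
#' p-value comes from full enumeration of the 2^n sign assignments
#' (conditional on the observed ranks, so ties are handled exactly); above
#' that, a normal approximation with tie correction and continuity
#' correction is used.
#'
#' @param before,after paired measurements (equal length); differences are
#'   `after - before`.  Alternatively pass the differences as `before` and
#'   leave `after = NULL`.
#' @param exact_limit largest n for exact enumeration (default 25).
#' @return a list with `statistic` (V, the positive-rank sum), `p_value`,
#'   `n` (non-zero differences), and `method`.
#' @examples
#' wilcoxon_signed_rank(c(0, 0, 0), c(1, 2, 3))$p_value  # exact 0.25
#' @export
wilcoxon_signed_rank <- function(before, after = NULL, exact_limit = 25) {
  d <- if (is.null(after)) as.numeric(before) else {
    stopifnot(length(before) == length(after))
    as.numeric(after) - as.numeric(before)
  }
  d <- d[is.finite(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    stop("all paired differences are zero: signed-rank test undefined",
         call. = FALSE)
  }
  if (n < 3) {
    stop("need at least 3 non-zero paired differences", call. = FALSE)
  }
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (n <= exact_limit) {
    ranks2 <- as.integer(round(2 * r))
    poly <- signed_rank_poly(ranks2)
    w2 <- as.integer(round(2 * v))
    p_le <- sum(poly[seq_len(w2 + 1L)]) / 2^n
    p_ge <- sum(poly[seq(w2 + 1L, length(poly))]) / 2^n
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact enumeration"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(ties^3 - ties) / 48
    z <- (v - mu - 0.5 * sign(v - mu)) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal approximation with continuity correction"
  }
  list(statistic = v, p_value = p, n = n, method = method)
}

#' Kruskal-Wallis rank test for unpaired groups
#'
#' Wraps [stats::kruskal.test()] (average ranks for ties, tie-corrected H,
#' chi-squared p-value with k - 1 degrees of freedom).
#'
#' @param groups a list of numeric vectors, one per group (>= 2 non-empty
#'   groups).
#' @return a list with `statistic` (H), `p_value`, `df`.
#' @examples
#' kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))$statistic  # ~3.857
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) {
    stop("need at least 2 groups", call. = FALSE)
  }
  if (any(vapply(groups, length, integer(1)) == 0)) {
    stop("all groups must be non-empty", call. = FALSE)
  }
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  kt <- stats::kruskal.test(values, g)
  list(statistic = unname(kt$statistic), p_value = kt$p.value,
       df = unname(kt$parameter))
}
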