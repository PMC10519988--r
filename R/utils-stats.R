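# Shared statistical primitives: rank-sum test, BH step-up, seeded evaluation.

#' Evaluate an expression under a fixed RNG seed
#'
#' Runs `code` with the RNG seeded to `seed` and restores the caller's RNG
#' state afterwards, so seeded simulation helpers do not perturb the global
#' random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Computes the Mann-Whitney U statistic on midranks. When the number of
#' distinct assignments `choose(n1 + n2, n1)` does not exceed `exact_max`,
#' the two-sided p-value is obtained by exhaustive enumeration of all group
#' assignments of the observed (possibly tied) values; otherwise a normal
#' approximation with tie correction and continuity correction is used.
#' Exhaustive enumeration is exact in the presence of ties, unlike the
#' classical no-tie null distribution.
#'
#' @param x,y Numeric vectors for the two groups.
#' @param exact_max Maximum number of combinations for the exact branch
#'   (default `1e5`; covers all group sizes up to 8 and well beyond).
#' @return A list with elements `statistic` (U for the `x` group), `p.value`
#'   and `method` (`"exact"` or `"normal"`).
#' @export
#' @examples
#' rank_sum_test(c(1, 2, 3), c(4, 5, 6))$p.value
rank_sum_test <- function(x, y, exact_max = 1e5) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (anyNA(x) || anyNA(y)) stop("rank_sum_test: NA values in input", call. = FALSE)
  n1 <- length(x)
  n2 <- length(y)
  if (n1 == 0L || n2 == 0L) stop("rank_sum_test: both groups must be non-empty", call. = FALSE)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2

  n <- n1 + n2
  ncomb <- choose(n, min(n1, n2))
  if (ncomb <= exact_max) {
    # enumerate all assignments of n1 pooled values to group 1
    idx <- utils::combn(n, n1)
    rsums <- colSums(matrix(r[idx], nrow = n1))
    u_all <- rsums - n1 * (n1 + 1) / 2
    p <- mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
    return(list(statistic = u_obs, p.value = p, method = "exact"))
  }

  # normal approximation with tie correction
  tie_tab <- table(pooled)
  tie_corr <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_corr)
  if (sigma2 <= 0) {
    # all values tied: the statistic is degenerate at its mean
    return(list(statistic = u_obs, p.value = 1, method = "normal"))
  }
  z <- (abs(u_obs - mu) - 0.5) / sqrt(sigma2)
  z <- max(z, 0)
  p <- min(1, 2 * stats::pnorm(z, lower.tail = FALSE))
  list(statistic = u_obs, p.value = p, method = "normal")
}

#' Benjamini-Hochberg step-up adjustment
#'
#' False-discovery-rate adjusted p-values: with ordered p-values p_(1) <=
#' ... <= p_(m), the adjusted value is `min_{j >= i} ( m * p_(j) / j )`,
#' capped at 1. Rejecting adjusted p <= alpha reproduces the step-up rule
#' (largest i with p_(i) <= i * alpha / m).
#'
#' @param p Numeric vector of p-values (NA allowed, returned as NA).
#' @return Adjusted p-values in the original order.
#' @export
bh_adjust <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  pv <- p[ok]
  m <- length(pv)
  if (m == 0L) return(out)
  o <- order(pv, decreasing = TRUE)
  ro <- order(o)
  adj <- pmin(1, cummin(m / (m:1) * pv[o]))[ro]
  out[ok] <- adj
  out
}

#' Compare ratio (or expression) values between groups against a reference
#'
#' For each non-reference group, performs a two-sided Wilcoxon rank-sum test
#' of that group's values against the reference group's, then applies
#' Benjamini-Hochberg adjustment across the family of comparisons. Used both
#' for bulk domain-ratio cohort comparisons and for single-nucleus ratio
#' comparisons.
#'
#' @param values Numeric vector of per-unit values.
#' @param group Group label per value.
#' @param reference Label of the reference group (default: first level).
#' @param extra_p Optional named numeric vector of additional raw p-values to
#'   include in the same BH family (e.g. a companion expression test).
#' @return A data.frame with one row per comparison: `group`, `n`, `n_ref`,
#'   `statistic`, `p`, `p_adj`, `median`, `median_ref`.
#' @export
compare_ratio_groups <- function(values, group, reference = NULL, extra_p = NULL) {
  group <- as.character(group)
  stopifnot(length(values) == length(group))
  keep <- !is.na(values) & !is.na(group)
  values <- values[keep]
  group <- group[keep]
  groups <- unique(group)
  if (length(groups) < 2L) stop("compare_ratio_groups: need at least 2 groups", call. = FALSE)
  if (is.null(reference)) reference <- groups[1L]
  if (!reference %in% groups) stop("reference group '", reference, "' not present", call. = FALSE)
  ref_vals <- values[group == reference]
  others <- setdiff(groups, reference)
  rows <- lapply(others, function(g) {
    gv <- values[group == g]
    if (length(gv) == 0L || length(ref_vals) == 0L) {
      stop("compare_ratio_groups: empty group '", g, "' or reference", call. = FALSE)
    }
    ts <- rank_sum_test(gv, ref_vals)
    data.frame(
      group = g, n = length(gv), n_ref = length(ref_vals),
      statistic = ts$statistic, p = ts$p.value,
      median = stats::median(gv), median_ref = stats::median(ref_vals),
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, rows)
  fam <- res$p
  if (!is.null(extra_p)) fam <- c(fam, unname(extra_p))
  adj <- bh_adjust(fam)
  res$p_adj <- adj[seq_len(nrow(res))]
  if (!is.null(extra_p)) {
    attr(res, "extra_p_adj") <- stats::setNames(adj[-seq_len(nrow(res))], names(extra_p))
  }
  res[, c("group", "n", "n_ref", "statistic", "p", "p_adj", "median", "median_ref")]
}
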