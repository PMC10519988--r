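rand_counts <- function(seed, ng = 1500, ns = 6) {
  set.seed(seed)
  cnt <- matrix(rnbinom(ng * ns, mu = exp(runif(ng, 2, 6)), size = 5), ng, ns)
  dimnames(cnt) <- list(sprintf("G%04d", seq_len(ng)), paste0("S", seq_len(ns)))
  cnt
}

test_that("TMM factors: identity, scaling and gene-order invariance", {
  cnt <- rand_counts(1)
  ident <- cnt[, c(1, 1, 1, 1)]
  colnames(ident) <- paste0("R", 1:4)
  expect_equal(unname(tmm_factors(ident)), rep(1, 4))
  # a uniformly 2x-scaled copy of the reference has factor ~1
  two <- cbind(a = cnt[, 1], b = 2 * cnt[, 1], c = cnt[, 1])
  expect_equal(unname(tmm_factors(two)), rep(1, 3), tolerance = 1e-6)
  f <- tmm_factors(cnt)
  expect_equal(tmm_factors(cnt * 5), f)            # global scaling
  perm <- sample(nrow(cnt))
  expect_equal(tmm_factors(cnt[perm, ]), f)        # gene order
  expect_equal(exp(mean(log(f))), 1)               # centred in log space
  bad <- cnt; bad[, 2] <- 0
  expect_error(tmm_factors(bad), "all-zero")
})

test_that("TMM matches the reference implementation", {
  skip_if_not_installed("edgeR")
  for (s in 1:3) {
    cnt <- rand_counts(s)
    expect_equal(unname(tmm_factors(cnt)),
                 unname(edgeR::calcNormFactors(cnt)), tolerance = 1e-10)
  }
})

test_that("trimming excludes a planted shifted tail (brute-force check)", {
  # 10% of genes 8-fold up in sample 2; with 30% M-trimming those genes are
  # excluded, so the factor reflects only the unshifted majority
  set.seed(4)
  ref <- rnbinom(2000, mu = 200, size = 20)
  obs <- ref
  up <- sample(2000, 200)
  obs[up] <- obs[up] * 8
  cnt <- cbind(ref = ref, obs = obs)
  f <- tmm_factors(cnt, reference = "ref")
  # brute-force trimmed weighted mean on the constructed M/A vectors
  keep <- ref > 0 & obs > 0
  m <- log2((obs / sum(obs)) / (ref / sum(ref)))[keep]
  a <- (0.5 * log2((obs / sum(obs)) * (ref / sum(ref))))[keep]
  v <- ((sum(obs) - obs) / (sum(obs) * obs) + (sum(ref) - ref) / (sum(ref) * ref))[keep]
  n <- length(m)
  sel <- rank(m) >= floor(n * .3) + 1 & rank(m) <= n - floor(n * .3) &
    rank(a) >= floor(n * .05) + 1 & rank(a) <= n - floor(n * .05)
  brute <- 2^(sum(m[sel] / v[sel]) / sum(1 / v[sel]))
  brute <- c(1, brute); brute <- brute / exp(mean(log(brute)))
  expect_equal(unname(f), brute, tolerance = 1e-10)
  # shifted genes did not drag the factor to the 8-fold tail
  expect_lt(abs(log2(f[["obs"]] / brute[2])), 0.01)
})

test_that("log-CPM arithmetic, joint-scaling invariance and monotonicity", {
  cnt <- matrix(c(0, 10), 2, 1, dimnames = list(c("a", "b"), "s"))
  cnt2 <- rbind(cnt, pad = 1e6 - 10)
  lc <- log_cpm(cnt2, factors = 1)
  expect_equal(lc["a", 1], log2(0.5 / (1e6 + 1) * 1e6), tolerance = 1e-9)
  cntr <- rand_counts(2)
  f <- tmm_factors(cntr)
  l1 <- log_cpm(cntr, f)
  # within a sample, larger count -> larger log-CPM
  expect_true(all(diff(l1[order(cntr[, 1]), 1]) >= 0))
  expect_error(log_cpm(cntr, factors = rep(-1, 6)), "positive")
})

test_that("cohort comparison flags a planted excess and respects BH m=1", {
  set.seed(6)
  ns <- c(renin = 4, cmn = 20, wilms = 20, normal = 20)
  cohorts <- rep(names(ns), ns)
  cnt <- matrix(rnbinom(500 * sum(ns), mu = 100, size = 10), 500,
                dimnames = list(sprintf("G%03d", 1:500), NULL))
  cnt["G001", cohorts == "renin"] <- rnbinom(4, mu = 400, size = 10)
  lc <- log_cpm(cnt)
  res <- cohort_compare(lc, "G001", cohorts, "renin")
  expect_true(all(res$p_adj < 0.05))
  # identical cohorts: nonsignificant
  res0 <- cohort_compare(lc, "G200", cohorts, "renin")
  expect_true(all(res0$p_adj > 0.05))
  # single pair: adjusted equals raw
  res1 <- cohort_compare(lc[, cohorts %in% c("renin", "cmn")], "G001",
                         cohorts[cohorts %in% c("renin", "cmn")], "renin")
  expect_equal(res1$p_adj, res1$p)
  expect_error(cohort_compare(lc, "G001", cohorts, "missing"), "missing cohort")
  expect_error(cohort_compare(lc, "NOPE", cohorts, "renin"), "NOPE")
})

test_that("DE intersection recovers genes planted in both sets only", {
  sim <- simulate_bulk_sets(seed = 11)
  de <- de_and_intersect(sim$counts_a, sim$design_a, sim$counts_b, sim$design_b)
  expect_setequal(de$shared, sim$truth_both)
  expect_false(any(sim$truth_a_only %in% de$shared))
  expect_true(all(sim$truth_a_only %in% de$set_a$gene[de$set_a$de]))
  # adjusted p >= p and direction consistent with the fold sign
  expect_true(all(de$set_a$p_adj >= de$set_a$p))
  expect_true(all(de$set_a$direction[de$set_a$gene %in% sim$truth_both] == "up"))
  # symmetric in its two data sets
  de2 <- de_and_intersect(sim$counts_b, sim$design_b, sim$counts_a, sim$design_a)
  expect_setequal(de2$shared, de$shared)
  expect_error(de_and_intersect(sim$counts_a, rep("tumour", 16),
                                sim$counts_b, sim$design_b), "normal")
})
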