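test_that("threshold grid has 141 points, type-7 quantiles, tie collapsing", {
  g <- threshold_grid(seq_len(200))
  expect_equal(nrow(g), 141)
  expect_equal(g$percentile, seq(15, 85, 0.5))
  g100 <- threshold_grid(as.numeric(1:100))
  expect_equal(g100$value[g100$percentile == 50], 50.5)
  # constant expression: empty grid
  expect_equal(nrow(threshold_grid(rep(2, 50))), 0)
  expect_error(threshold_grid(1:5), ">= 10")
  # heavy ties collapse, keeping the lowest percentile per value
  gt <- threshold_grid(rep(c(0, 10), c(50, 50)))
  expect_false(any(duplicated(gt$value)))
  full <- stats::quantile(rep(c(0, 10), c(50, 50)), seq(15, 85, 0.5) / 100,
                          type = 7, names = FALSE)
  expect_equal(gt$percentile,
               vapply(unique(full), function(v)
                 seq(15, 85, 0.5)[which(full == v)[1]], numeric(1)))
})

test_that("cv partitions are disjoint, covering, reproducible", {
  parts <- cv_partitions(90, seed = 4)
  expect_length(parts, 15)
  # held-in subsets have 2/3 of the samples
  expect_true(all(vapply(parts, length, integer(1)) == 60))
  held_out <- cv_partitions(90, seed = 4, evaluate = "held_out")
  for (r in 0:4) {
    folds <- held_out[r * 3 + 1:3]
    expect_equal(sort(unlist(folds)), 1:90)           # union = all samples
    expect_equal(anyDuplicated(unlist(folds)), 0L)    # disjoint
  }
  expect_identical(parts, cv_partitions(90, seed = 4))
  expect_false(identical(parts, cv_partitions(90, seed = 5)))
  expect_error(cv_partitions(8, seed = 1), "at least 9")
})

test_that("propagation round-trips and is shift-equivariant", {
  set.seed(11)
  v <- rnorm(300)
  g <- threshold_grid(v)
  i <- 57
  expect_equal(propagate_threshold(g$percentile[i], v), g$value[i])
  expect_equal(propagate_threshold(40, v + 1.5),
               propagate_threshold(40, v) + 1.5)
  # synthetic cohort shift: ON frequency preserved after propagation
  src <- c(rnorm(210, 0), rnorm(90, 4))
  tgt <- c(rnorm(210, 0), rnorm(90, 4)) + 1.5
  thr_src <- propagate_threshold(70, src)
  thr_tgt <- propagate_threshold(70, tgt)
  expect_lt(abs(mean(src > thr_src) - mean(tgt > thr_tgt)), 0.05)
})

test_that("reference-threshold selection applies gates and tie rules", {
  rec <- data.frame(percentile = c(20, 30, 40, 50),
                    threshold = 1:4, n_on = 50,
                    logrank_p = c(0.01, 0.001, 0.20, 0.001),
                    hazard_ratio = c(2, 2, 2, 0.5),
                    stability = c(0.4, 0.8, 1.0, 1.0),
                    fdr = c(0.1, 0.1, 0.5, 0.1))
  # row 3 fails p/fdr, row 4 fails HR > 1; row 2 beats row 1 on stability
  sel <- select_reference_threshold(rec)
  expect_equal(sel$percentile, 30)
  # stability tie broken by lower p, then lower percentile
  rec2 <- data.frame(percentile = c(20, 30, 40), threshold = 1:3, n_on = 50,
                     logrank_p = c(0.01, 0.001, 0.001), hazard_ratio = 2,
                     stability = 0.8, fdr = 0.05)
  expect_equal(select_reference_threshold(rec2)$percentile, 30)
  rec2$logrank_p <- 0.001
  expect_equal(select_reference_threshold(rec2)$percentile, 20)
  rec2$fdr <- 0.5
  expect_null(select_reference_threshold(rec2))
})

test_that("scan skips undersized arms and collapses duplicate thresholds", {
  set.seed(21)
  n <- 120
  v <- rnorm(n)
  tm <- rexp(n); ev <- rbinom(n, 1, 0.7)
  subsets <- cv_partitions(n, seed = 1)
  grid <- threshold_grid(v)
  rec <- scan_gene(v, tm, ev, grid, subsets)
  expect_false(any(duplicated(rec$threshold)))
  expect_true(all(rec$n_on >= ceiling(0.15 * n)))
  expect_true(all(n - rec$n_on >= ceiling(0.15 * n)))
  expect_true(all(rec$stability >= 0 & rec$stability <= 1))
  # constant gene: unscorable
  expect_equal(nrow(scan_gene(rep(1, n), tm, ev, threshold_grid(rep(1, n)),
                              subsets)), 0)
})

test_that("null genes are rarely selected after FDR and stability gating", {
  # survival-independent genes screened with the pooled BH family (the
  # family the screen itself uses): per-gene selection rate stays low
  n <- 120; n_genes <- 10
  picked <- vapply(1:20, function(s) {
    set.seed(s)
    expr <- matrix(rnorm(n_genes * n), n_genes, n,
                   dimnames = list(sprintf("g%02d", 1:n_genes),
                                   sprintf("s%03d", 1:n)))
    tm <- rexp(n, 0.3); cs <- rexp(n, 0.15)
    ev <- as.integer(tm <= cs); tm <- pmin(tm, cs)
    res <- screen_genes(expr, tm, ev, seed = s, grid_step = 2.5)
    if (is.null(res$candidates)) 0 else nrow(res$candidates) / n_genes
  }, numeric(1))
  expect_lte(mean(picked), 0.10)
})

test_that("a planted prognostic gene is found near its activation boundary", {
  found <- vapply(1:20, function(s) {
    set.seed(s)
    n <- 600
    act <- rbinom(n, 1, 0.3)
    v <- rnorm(n) + 4 * act
    tm <- rexp(n, 0.05 * exp(log(2.5) * act))
    cs <- pmin(rexp(n, 0.03), 15)
    ev <- as.integer(tm <= cs); tm <- pmin(tm, cs)
    subsets <- cv_partitions(n, seed = s)
    rec <- scan_gene(v, tm, ev, threshold_grid(v), subsets)
    rec$fdr <- bh_adjust(rec$logrank_p)
    sel <- select_reference_threshold(rec)
    !is.null(sel) && sel$logrank_p < 0.05 && sel$hazard_ratio > 1
  }, logical(1))
  expect_gte(mean(found), 0.9)
})

test_that("validation decision implements the 2-of-3 plus lenient-third rule", {
  hr <- c(2, 2, 2)
  expect_true(validation_decision(c(0.01, 0.02, 0.03), hr))
  expect_true(validation_decision(c(0.01, 0.04, 0.09), hr))
  expect_false(validation_decision(c(0.01, 0.04, 0.11), hr))
  expect_false(validation_decision(c(0.01, 0.02, 0.5), hr))
  expect_false(validation_decision(c(0.01, 0.2, 0.09), hr))
  # significance requires HR > 1
  expect_false(validation_decision(c(0.01, 0.01, 0.09), c(2, 0.5, 2)))
  expect_true(validation_decision(c(0.01, 0.01, 0.09), c(2, 2, 0.5)))
  # generalized m = 4: need ceiling(8/3) = 3 significant
  expect_true(validation_decision(c(0.01, 0.01, 0.01, 0.09), rep(2, 4)))
  expect_false(validation_decision(c(0.01, 0.01, 0.09, 0.09), rep(2, 4)))
  # missing cohort p-value blocks validation
  expect_false(validation_decision(c(0.01, 0.01, NA), hr))
})

test_that("screen + validation recover planted biomarkers end to end", {
  study <- simulate_study(recovery_config(101), panel = FALSE)
  res <- run_pipeline(study, seed = 101)
  truth <- study$truth$gene[study$truth$prognostic]
  validated <- res$validation$gene[res$validation$validated]
  expect_gte(length(intersect(validated, truth)), 4)
  expect_lte(length(setdiff(validated, truth)), 2)
  # all candidates satisfy the construction gates
  cand <- res$screen$candidates
  expect_true(all(cand$logrank_p < 0.05 & cand$fdr < 0.2 &
                    cand$hazard_ratio > 1))
})
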