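make_gec <- function(counts, K = 5) {
  out <- data.frame(sample_id = sprintf("s%03d", seq_along(counts)),
                    activated_count = as.integer(counts),
                    group = ifelse(counts <= 1, "low", "high"),
                    extreme = ifelse(counts == 0, "GEC-",
                                     ifelse(counts >= K - 1, "GEC+",
                                            "intermediate")))
  attr(out, "panel_size") <- K
  class(out) <- c("gec_result", "data.frame")
  out
}

test_that("GEC counts, groups and extremes follow the exact boundaries", {
  thr <- setNames(rep(1, 5), paste0("g", 1:5))
  # sample k activates exactly k genes, k = 0..5
  expr <- sapply(0:5, function(k) c(rep(2, k), rep(0, 5 - k)))
  rownames(expr) <- names(thr); colnames(expr) <- paste0("s", 0:5)
  sc <- gec_score(expr, thr)
  expect_equal(sc$activated_count, 0:5)
  expect_equal(sc$group, c("low", "low", "high", "high", "high", "high"))
  expect_equal(sc$extreme, c("GEC-", "intermediate", "intermediate",
                             "intermediate", "GEC+", "GEC+"))
  # boundary value is OFF; missing values contribute OFF
  expr2 <- expr; expr2["g1", "s5"] <- 1; expr2["g2", "s5"] <- NA
  sc2 <- suppressMessages(gec_score(expr2, thr))
  expect_equal(sc2$activated_count[sc2$sample_id == "s5"], 3L)
  expect_error(gec_score(expr, c(thr, zz = 1)), "absent")
})

test_that("gec_score is monotone in expression", {
  set.seed(8)
  thr <- setNames(rnorm(5), paste0("g", 1:5))
  expr <- matrix(rnorm(5 * 40), 5, 40,
                 dimnames = list(names(thr), sprintf("s%02d", 1:40)))
  base <- gec_score(expr, thr)$activated_count
  for (i in 1:5) {
    up <- expr; up[i, ] <- up[i, ] + abs(rnorm(40))
    expect_true(all(gec_score(up, thr)$activated_count >= base))
  }
})

test_that("evaluate_gec recovers the planted per-activation hazard ratio", {
  cfg <- sim_config(seed = 55, n_cohorts = 1, n_tumour = 1000,
                    n_nontumour = 60, cohort_roles = "test",
                    log_hazard_per_activation = 0.2)
  co <- generate_cohort(cfg, 1)
  prog <- co$truth$gene[co$truth$prognostic]
  counts <- rowSums(co$activation[, prog, drop = FALSE])
  gec <- make_gec(counts)
  gec$sample_id <- co$clinical$sample_id[co$clinical$sample_type == "tumour"]
  ev <- evaluate_gec(gec, co$clinical)
  expect_true(ev$evaluable)
  expect_lt(abs(ev$cox_hr - exp(0.2)), 0.1)
  expect_lt(ev$logrank_p, 0.05)
  # degenerate grouping flagged, not an error
  gec0 <- gec; gec0$group <- "low"
  expect_false(evaluate_gec(gec0, co$clinical)$evaluable)
})

test_that("evaluate_gec is calibrated under the null", {
  ps <- vapply(1:40, function(s) {
    set.seed(s)
    n <- 150
    counts <- rbinom(n, 5, 0.3)
    cl <- data.frame(sample_id = sprintf("s%03d", 1:n),
                     time = rexp(n, 0.2), event = rbinom(n, 1, 0.7))
    evaluate_gec(make_gec(counts), cl)$logrank_p
  }, numeric(1))
  expect_lt(mean(ps < 0.05), 0.15)
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("multivariate Cox keeps the GEC effect and handles covariates", {
  cfg <- sim_config(seed = 77, n_cohorts = 1, n_tumour = 800,
                    n_nontumour = 60, cohort_roles = "test",
                    log_hazard_per_activation = 0.3)
  co <- generate_cohort(cfg, 1)
  prog <- co$truth$gene[co$truth$prognostic]
  counts <- rowSums(co$activation[, prog, drop = FALSE])
  cl <- co$clinical[co$clinical$sample_type == "tumour", ]
  gec <- make_gec(counts); gec$sample_id <- cl$sample_id
  fit <- multivariate_cox(gec, cl)
  expect_setequal(fit$term, c("GEC", "age", "subtype", "stage"))
  expect_lt(fit$p[fit$term == "GEC"], 0.01)
  expect_gt(min(fit$p[fit$term != "GEC"]), 0.001)  # noise covariates
  # dummy coding expands the subtype term
  fit_d <- multivariate_cox(gec, cl, subtype_coding = "dummy")
  expect_true(sum(grepl("^subtype_", fit_d$term)) == 3)
  # no covariates available: reduces to the univariate count model
  fit0 <- multivariate_cox(gec, cl[, c("sample_id", "time", "event")])
  uni <- evaluate_gec(gec, cl)
  expect_equal(fit0$hr[fit0$term == "GEC"], uni$cox_hr, tolerance = 1e-8)
  # entirely missing covariate dropped with a warning
  cl2 <- cl; cl2$stage <- NA
  expect_warning(multivariate_cox(gec, cl2), "stage")
})

test_that("confounder adjustment moves the GEC HR toward the direct effect", {
  # subtype correlated with activation; subtype carries its own hazard
  devs <- vapply(1:20, function(s) {
    set.seed(s)
    n <- 800
    sub <- rbinom(n, 1, 0.4)                      # aggressive subtype
    counts <- rbinom(n, 5, ifelse(sub == 1, 0.45, 0.15))
    tm <- rexp(n, 0.05 * exp(0.25 * counts + 0.8 * sub))
    cs <- pmin(rexp(n, 0.05), 15)
    cl <- data.frame(sample_id = sprintf("s%03d", 1:n),
                     time = pmin(tm, cs), event = as.integer(tm <= cs),
                     subtype = ifelse(sub == 1, "basal", "luminal_A"))
    gec <- make_gec(counts); gec$sample_id <- cl$sample_id
    adj <- multivariate_cox(gec, cl, covariates = "subtype")
    una <- evaluate_gec(gec, cl)
    c(adj = adj$coef[adj$term == "GEC"], una = log(una$cox_hr))
  }, numeric(2))
  expect_lt(abs(mean(devs["adj", ]) - 0.25), abs(mean(devs["una", ]) - 0.25))
})

test_that("subtype-stratified evaluation reports proper distributions and flags", {
  set.seed(12)
  n <- 600
  subtype <- sample(c("luminal_A", "luminal_B", "basal"), n, TRUE,
                    prob = c(0.6, 0.25, 0.15))
  counts <- rbinom(n, 5, ifelse(subtype == "luminal_A", 0.08, 0.35))
  haz <- 0.05 * exp(0.4 * counts)
  tm <- rexp(n, haz); cs <- pmin(rexp(n, 0.03), 15)
  cl <- data.frame(sample_id = sprintf("s%03d", 1:n),
                   time = pmin(tm, cs), event = as.integer(tm <= cs),
                   subtype = subtype)
  res <- subtype_stratified_evaluation(make_gec(counts), cl)
  sums <- tapply(res$distribution$fraction, res$distribution$subtype, sum)
  expect_equal(as.vector(sums), rep(1, 3), tolerance = 1e-12)
  # low-activation stratum is dominated by count 0
  la <- res$distribution[res$distribution$subtype == "luminal_A", ]
  expect_gt(la$fraction[la$count == 0], 0.5)
  # planted hazard shows up in the high-frequency strata
  expect_lt(res$tests$basal$logrank_p, 0.05)
  # a stratum with a degenerate group is flagged non-evaluable
  cl2 <- cl; counts2 <- counts
  counts2[subtype == "luminal_B"] <- 0
  res2 <- subtype_stratified_evaluation(make_gec(counts2), cl2)
  expect_false(res2$tests$luminal_B$evaluable)
})

test_that("extreme-group DE applies the Mann-Whitney and ratio gates", {
  set.seed(33)
  n_pos <- 50; n_neg <- 50
  gec <- make_gec(c(rep(5, n_pos), rep(0, n_neg), rep(2, 20)))
  samples <- gec$sample_id
  n_genes <- 140
  expr <- matrix(rnorm(n_genes * length(samples), 3, 0.5), n_genes,
                 dimnames = list(sprintf("d%03d", 1:n_genes), samples))
  planted_up <- 1:20        # ~2-fold linear shift in GEC+
  planted_small <- 21:40    # sub-threshold shift, large n => small p
  expr[planted_up, 1:n_pos] <- expr[planted_up, 1:n_pos] + 1
  expr[planted_small, 1:n_pos] <- expr[planted_small, 1:n_pos] + 0.35
  de <- de_extreme_groups(expr, gec)
  up <- de$gene[de$selected & de$direction == "up"]
  expect_gte(mean(sprintf("d%03d", planted_up) %in% up), 0.95)
  # small-shift genes are significant but fail the 1.5x ratio gate
  small <- de[match(sprintf("d%03d", planted_small), de$gene), ]
  expect_true(all(!small$selected[small$p_adj < 0.05 &
                                    small$ratio <= 1.5]))
  expect_gt(sum(small$p_adj < 0.05), 10)
  # null genes essentially never selected
  null_sel <- de$selected[-(1:40)]
  expect_lte(mean(null_sel), 0.05)
  expect_error(de_extreme_groups(expr, make_gec(rep(2, 120))), "empty")
})
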