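#' Score samples with the Gene Expression Classifier (GEC)
#'
#' Counts, per sample, how many panel genes are ON (expression strictly
#' above the gene's cohort-calibrated threshold). Samples with 0 or 1
#' activated genes form the favourable `low` group, samples with 2 or more
#' the unfavourable `high` group; counts of 0 and >= K-1 (K = panel size)
#' mark the extreme `GEC-` / `GEC+` groups used for differential
#' expression. Missing expression values contribute OFF.
#'
#' @param expr genes x samples log2 matrix containing the panel genes.
#' @param thresholds named numeric vector of per-gene thresholds (names =
#'   panel genes), typically obtained via [propagate_threshold()] in each
#'   cohort.
#' @return data.frame of class `gec_result` with `sample_id`,
#'   `activated_count`, `group` (`low`/`high`) and `extreme`
#'   (`GEC-`/`intermediate`/`GEC+`); attribute `panel_size`.
#' @examples
#' expr <- rbind(a = c(0, 5), b = c(0, 5))
#' gec_score(expr, c(a = 1, b = 1))$activated_count  # 0 2
#' @export
gec_score <- function(expr, thresholds) {
  stopifnot(is.matrix(expr), is.numeric(thresholds), !is.null(names(thresholds)))
  missing_genes <- setdiff(names(thresholds), rownames(expr))
  if (length(missing_genes))
    stop("panel gene(s) absent from expression matrix: ",
         paste(missing_genes, collapse = ", "))
  K <- length(thresholds)
  on <- expr[names(thresholds), , drop = FALSE] > thresholds
  if (anyNA(on)) {
    message(sum(is.na(on)), " missing panel value(s) treated as OFF")
    on[is.na(on)] <- FALSE
  }
  count <- colSums(on)
  out <- data.frame(sample_id = colnames(expr),
                    activated_count = as.integer(count),
                    group = ifelse(count <= 1, "low", "high"),
                    extreme = ifelse(count == 0, "GEC-",
                                     ifelse(count >= K - 1, "GEC+",
                                            "intermediate")),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "panel_size") <- K
  class(out) <- c("gec_result", "data.frame")
  out
}

#' Evaluate the GEC in one cohort
#'
#' Logrank test between the low (0-1 activated genes) and high (>= 2)
#' groups, and a univariate Cox model with the activated-gene count as a
#' numeric covariate.
#'
#' @param gec a [gec_score()] result.
#' @param clinical data.frame with `sample_id`, `time`, `event` (tumour
#'   samples; others ignored).
#' @return list with `logrank_p`, `logrank_hr` (high vs low, Pike
#'   estimate), `cox_p`, `cox_hr` (per activated gene), `n`, `n_high`;
#'   or a list with `evaluable = FALSE` and a `reason` when a group is
#'   empty or event-free.
#' @export
evaluate_gec <- function(gec, clinical) {
  d <- merge(gec, clinical[, c("sample_id", "time", "event")], by = "sample_id")
  d <- d[!is.na(d$time) & !is.na(d$event), , drop = FALSE]
  hi <- d$group == "high"
  if (!any(hi) || all(hi))
    return(list(evaluable = FALSE, reason = "degenerate grouping"))
  if (sum(d$event) < 1)
    return(list(evaluable = FALSE, reason = "no events"))
  lr <- logrank_test(d$time, d$event, hi)
  cx <- cox_fit(d$time, d$event, data.frame(gec_count = d$activated_count))
  list(evaluable = TRUE, logrank_p = lr$p, logrank_hr = lr$hr_pike,
       cox_p = cx$p[1L], cox_hr = cx$hr[1L],
       n = nrow(d), n_high = sum(hi))
}

#' Multivariate Cox model with the GEC and clinical risk factors
#'
#' Joint Cox fit of the activated-gene count with any of age, molecular
#' subtype and tumour stage. Subtype enters as a single ordered numeric
#' covariate by default (`luminal_A < luminal_B < HER2 < basal`), or as
#' dummy variables with `subtype_coding = "dummy"`; stage is ordinal.
#' Covariates absent (all `NA`) or constant in the cohort are dropped with
#' a warning.
#'
#' @param gec a [gec_score()] result.
#' @param clinical data.frame with `sample_id`, `time`, `event` and any of
#'   `age`, `subtype`, `stage`.
#' @param covariates covariates to include besides `gec_count`.
#' @param subtype_coding `"ordinal"` (default) or `"dummy"`.
#' @param subtype_order level order used for the ordinal coding.
#' @return a [cox_fit()] data.frame (term, coef, hr, se, p).
#' @export
multivariate_cox <- function(gec, clinical,
                             covariates = c("age", "subtype", "stage"),
                             subtype_coding = c("ordinal", "dummy"),
                             subtype_order = c("luminal_A", "luminal_B",
                                               "HER2", "basal")) {
  subtype_coding <- match.arg(subtype_coding)
  d <- merge(gec, clinical, by = "sample_id")
  d <- d[!is.na(d$time) & !is.na(d$event), , drop = FALSE]
  X <- data.frame(GEC = d$activated_count)
  for (cv in intersect(covariates, names(d))) {
    v <- d[[cv]]
    if (all(is.na(v))) {
      warning("covariate '", cv, "' entirely missing; excluded")
      next
    }
    if (cv == "subtype") {
      if (subtype_coding == "ordinal") {
        X$subtype <- as.numeric(factor(v, levels = subtype_order))
      } else {
        f <- factor(v, levels = subtype_order)
        mm <- stats::model.matrix(~f)[, -1, drop = FALSE]
        colnames(mm) <- paste0("subtype_", levels(f)[-1])
        # model.matrix drops NA rows; rebuild aligned
        mm_full <- matrix(NA_real_, nrow(d), ncol(mm),
                          dimnames = list(NULL, colnames(mm)))
        mm_full[!is.na(v), ] <- mm
        X <- cbind(X, as.data.frame(mm_full))
      }
    } else {
      X[[cv]] <- as.numeric(v)
    }
  }
  cox_fit(d$time, d$event, X)
}

#' Subtype-stratified GEC evaluation
#'
#' Pools already-scored cohorts (counts are cohort-calibrated before
#' pooling) and, within each molecular subtype, reports the distribution of
#' activated-gene counts and the low-vs-high survival comparison. Subtypes
#' in which a group is empty or event-free are flagged non-evaluable.
#'
#' @param gec a (pooled) [gec_score()] result.
#' @param clinical pooled clinical data.frame with `sample_id`, `time`,
#'   `event`, `subtype`.
#' @return list with `distribution` (data.frame of per-subtype count
#'   fractions, summing to 1 within subtype) and `tests` (per-subtype
#'   [evaluate_gec()] results).
#' @export
subtype_stratified_evaluation <- function(gec, clinical) {
  stopifnot("subtype" %in% names(clinical))
  d <- merge(gec, clinical, by = "sample_id")
  d <- d[!is.na(d$subtype), , drop = FALSE]
  K <- attr(gec, "panel_size")
  if (is.null(K)) K <- max(d$activated_count)
  dist <- do.call(rbind, lapply(split(d, d$subtype), function(s) {
    tab <- tabulate(s$activated_count + 1L, nbins = K + 1L)
    data.frame(subtype = s$subtype[1L], count = 0:K,
               fraction = tab / nrow(s), n = nrow(s))
  }))
  rownames(dist) <- NULL
  tests <- lapply(split(d, d$subtype), function(s)
    evaluate_gec(s[, c("sample_id", "activated_count", "group", "extreme")],
                 s[, c("sample_id", "time", "event")]))
  list(distribution = dist, tests = tests)
}

#' Differential expression between extreme GEC groups
#'
#' Compares every gene between the GEC+ samples (>= K-1 activated panel
#' genes) and the GEC- samples (0 activated), excluding the intermediate
#' group: two-sided Mann-Whitney (Wilcoxon rank-sum) p-values,
#' BH-adjusted over all tested genes, and the linear-scale fold ratio of
#' group means (values back-transformed as `2^x - 1`). A gene is selected
#' when its adjusted p < `alpha` and the ratio exceeds `min_ratio` in
#' either direction.
#'
#' @param expr genes x samples log2 matrix.
#' @param gec a [gec_score()] result for the same samples.
#' @param alpha adjusted-p cutoff (default 0.05).
#' @param min_ratio linear fold-ratio cutoff (default 1.5).
#' @return data.frame per gene: `gene`, `p`, `p_adj`, `ratio` (GEC+ over
#'   GEC-), `direction` (`up`/`down` in GEC+), `selected`.
#' @export
de_extreme_groups <- function(expr, gec, alpha = 0.05, min_ratio = 1.5) {
  pos <- gec$sample_id[gec$extreme == "GEC+"]
  neg <- gec$sample_id[gec$extreme == "GEC-"]
  if (!length(pos) || !length(neg))
    stop("an extreme GEC group is empty; differential analysis impossible")
  if (length(pos) < 3 || length(neg) < 3)
    stop("need >= 3 samples per extreme GEC group")
  ep <- expr[, intersect(colnames(expr), pos), drop = FALSE]
  en <- expr[, intersect(colnames(expr), neg), drop = FALSE]
  lin <- function(x) 2^x - 1
  p <- vapply(seq_len(nrow(expr)), function(i)
    suppressWarnings(stats::wilcox.test(ep[i, ], en[i, ])$p.value),
    numeric(1))
  mp <- rowMeans(lin(ep)); mn <- rowMeans(lin(en))
  ratio <- mp / pmax(mn, .Machine$double.eps)
  p_adj <- bh_adjust(p)
  data.frame(gene = rownames(expr), p = p, p_adj = p_adj, ratio = ratio,
             direction = ifelse(ratio >= 1, "up", "down"),
             selected = !is.na(p_adj) & p_adj < alpha &
               (ratio > min_ratio | ratio < 1 / min_ratio),
             stringsAsFactors = FALSE, row.names = NULL)
}
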