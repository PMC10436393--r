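#' Percentile grid of candidate activation thresholds
#'
#' Candidate thresholds for one gene: the tumour-expression quantiles from
#' the 15th to the 85th percentile in steps of half a percentile (141 points
#' before tie-collapsing). Quantiles use linear interpolation between order
#' statistics (type 7), the same convention as [propagate_threshold()], so
#' propagating a selected percentile back into the defining cohort recovers
#' the threshold value. Duplicate threshold values are collapsed keeping the
#' lowest percentile.
#'
#' @param values tumour log2 expression of the gene (>= 10 samples).
#' @param lower,upper,step percentile range and step (defaults 15, 85, 0.5).
#' @return data.frame with `percentile` and `value`; zero rows when the
#'   expression is constant.
#' @examples
#' nrow(threshold_grid(rnorm(100)))  # <= 141
#' @export
threshold_grid <- function(values, lower = 15, upper = 85, step = 0.5) {
  values <- values[!is.na(values)]
  if (length(values) < 10) stop("need >= 10 tumour samples for the grid")
  if (max(values) == min(values))
    return(data.frame(percentile = numeric(0), value = numeric(0)))
  pct <- seq(lower, upper, by = step)
  val <- stats::quantile(values, probs = pct / 100, type = 7, names = FALSE)
  keep <- !duplicated(val)
  data.frame(percentile = pct[keep], value = val[keep])
}

#' Repeated k-fold cross-validation sample subsets
#'
#' Generates `repeats` independent random k-fold partitions of the samples
#' and returns the evaluation subsets: by default the held-in portions (the
#' (k-1)/k complements of each fold), i.e. 15 subsets of 2/3 of the samples
#' for k = 3 and 5 repeats. The held-out 1/3 folds are available via
#' `evaluate = "held_out"`.
#'
#' @param n_samples number of samples (>= 3k).
#' @param k folds per repeat (default 3).
#' @param repeats number of repeats (default 5).
#' @param seed integer seed; the partitioning is deterministic given it.
#' @param evaluate `"held_in"` (default) or `"held_out"`.
#' @return list of `k * repeats` integer index vectors.
#' @export
cv_partitions <- function(n_samples, k = 3, repeats = 5, seed,
                          evaluate = c("held_in", "held_out")) {
  evaluate <- match.arg(evaluate)
  if (n_samples < 3 * k)
    stop("need at least ", 3 * k, " samples for ", k, "-fold partitions")
  if (missing(seed)) stop("`seed` is required")
  set.seed(.derive_seed(seed, 17L))
  out <- vector("list", k * repeats)
  idx <- 1L
  for (r in seq_len(repeats)) {
    fold <- sample(rep_len(seq_len(k), n_samples))
    for (f in seq_len(k)) {
      out[[idx]] <- if (evaluate == "held_in")
        which(fold != f) else which(fold == f)
      idx <- idx + 1L
    }
  }
  out
}

#' Scan one gene's threshold grid for survival association
#'
#' For each candidate threshold, splits tumour samples into ON (expression
#' strictly above) and OFF, and computes the full-cohort logrank p-value and
#' ON-vs-OFF hazard ratio, the per-CV-subset logrank p-values, and the
#' stability score (fraction of CV subsets with p < 0.05). Thresholds
#' leaving either arm below `min_group_frac` of the cohort are skipped. The
#' per-threshold hazard ratio is the Pike O/E-ratio estimate from the
#' logrank quantities; the partial-likelihood Cox hazard ratio is attached
#' to the selected reference threshold downstream (see
#' [select_reference_threshold()]).
#'
#' @param values tumour log2 expression of the gene, aligned with `time`.
#' @param time,event disease-free survival data of the tumour samples.
#' @param grid a [threshold_grid()] data.frame.
#' @param subsets list of index vectors from [cv_partitions()].
#' @param min_group_frac minimum fraction of samples per arm (default 0.15,
#'   the grid's own percentile bounds).
#' @param alpha_stability per-subset significance level entering the
#'   stability score (default 0.05).
#' @return data.frame with one row per evaluated threshold: `percentile`,
#'   `threshold`, `n_on`, `logrank_p`, `hazard_ratio`, `stability`; zero
#'   rows if every threshold was skipped.
#' @export
scan_gene <- function(values, time, event, grid, subsets,
                      min_group_frac = 0.15, alpha_stability = 0.05) {
  stopifnot(length(values) == length(time), length(time) == length(event))
  if (!nrow(grid)) return(.empty_scan())
  n <- length(values)
  on <- outer(values, grid$value, ">")
  n_on <- colSums(on)
  m <- ceiling(min_group_frac * n)
  ok <- n_on >= m & (n - n_on) >= m
  if (!any(ok)) return(.empty_scan())
  on <- on[, ok, drop = FALSE]
  full <- .logrank_core(time, event, on)
  stab_hits <- matrix(0, nrow = sum(ok), ncol = length(subsets))
  for (j in seq_along(subsets)) {
    s <- subsets[[j]]
    sub <- .logrank_core(time[s], event[s], on[s, , drop = FALSE])
    stab_hits[, j] <- !is.na(sub$p) & sub$p < alpha_stability
  }
  data.frame(percentile = grid$percentile[ok],
             threshold = grid$value[ok],
             n_on = n_on[ok],
             logrank_p = full$p,
             hazard_ratio = full$hr_pike,
             stability = rowMeans(stab_hits))
}

.empty_scan <- function() {
  data.frame(percentile = numeric(0), threshold = numeric(0),
             n_on = integer(0), logrank_p = numeric(0),
             hazard_ratio = numeric(0), stability = numeric(0))
}

#' Select the reference threshold for a gene
#'
#' Among the thresholds passing all three gates (logrank p < `alpha`,
#' BH-adjusted FDR < `max_fdr`, hazard ratio > 1), picks the one with the
#' maximal cross-validation stability; ties are broken by the lower
#' full-cohort p-value, then by the lower percentile.
#'
#' @param records a [scan_gene()] data.frame with an `fdr` column (adjusted
#'   over the screen-wide family, see [screen_genes()]).
#' @param alpha,max_fdr significance gates (defaults 0.05 and 0.2).
#' @return The selected record (one-row data.frame) or `NULL` when no
#'   threshold is significant.
#' @export
select_reference_threshold <- function(records, alpha = 0.05, max_fdr = 0.2) {
  stopifnot("fdr" %in% names(records))
  sig <- records[!is.na(records$logrank_p) & records$logrank_p < alpha &
                   records$fdr < max_fdr & records$hazard_ratio > 1, ,
                 drop = FALSE]
  if (!nrow(sig)) return(NULL)
  ord <- order(-sig$stability, sig$logrank_p, sig$percentile)
  sig[ord[1L], , drop = FALSE]
}

#' Propagate a threshold across cohorts by percentile rank
#'
#' Converts a reference percentile (defined in the training cohort) into a
#' threshold value in a target cohort: the target tumour-expression quantile
#' at that percentile, with the same linear-interpolation convention as
#' [threshold_grid()]. Propagation absorbs additive cross-cohort shifts.
#'
#' @param percentile reference percentile in `[0, 100]`.
#' @param target_values tumour log2 expression of the gene in the target
#'   cohort.
#' @return The propagated threshold value.
#' @export
propagate_threshold <- function(percentile, target_values) {
  stopifnot(is.numeric(percentile), percentile >= 0, percentile <= 100)
  target_values <- target_values[!is.na(target_values)]
  if (!length(target_values)) stop("target cohort has no tumour samples")
  stats::quantile(target_values, probs = percentile / 100, type = 7,
                  names = FALSE)
}

#' Training-cohort threshold screen over many genes
#'
#' Runs [scan_gene()] for each gene of the training cohort, adjusts all
#' full-cohort logrank p-values by Benjamini-Hochberg in one pooled
#' gene-by-threshold family, and selects each gene's reference threshold.
#' For every selected candidate the ON-vs-OFF hazard ratio is re-estimated
#' by a univariate Cox fit at the reference threshold.
#'
#' @param expr genes x tumour-samples log2 matrix (training cohort).
#' @param time,event disease-free survival of the tumour samples (aligned
#'   with columns of `expr`).
#' @param genes character vector of genes to screen (default all rows).
#' @param seed integer seed driving the cross-validation partitions.
#' @param k,repeats cross-validation shape (default 3-fold x 5).
#' @param grid_step percentile step of the threshold grid (default 0.5).
#' @param alpha,max_fdr significance gates for candidate selection.
#' @param cv_evaluate which CV portions to evaluate (see
#'   [cv_partitions()]).
#' @return list with `scan` (all evaluated thresholds, with `gene` and
#'   `fdr` columns) and `candidates` (one row per selected gene: reference
#'   percentile/threshold, training p, fdr, stability, Cox `hazard_ratio`).
#' @export
screen_genes <- function(expr, time, event, genes = rownames(expr), seed,
                         k = 3, repeats = 5, grid_step = 0.5,
                         alpha = 0.05, max_fdr = 0.2,
                         cv_evaluate = c("held_in", "held_out")) {
  cv_evaluate <- match.arg(cv_evaluate)
  stopifnot(is.matrix(expr), ncol(expr) == length(time))
  if (missing(seed)) stop("`seed` is required")
  subsets <- cv_partitions(ncol(expr), k = k, repeats = repeats, seed = seed,
                           evaluate = cv_evaluate)
  scans <- lapply(genes, function(g) {
    grid <- threshold_grid(expr[g, ], step = grid_step)
    rec <- scan_gene(expr[g, ], time, event, grid, subsets)
    if (nrow(rec)) rec$gene <- g
    rec
  })
  scan <- do.call(rbind, scans[vapply(scans, nrow, integer(1)) > 0])
  if (is.null(scan) || !nrow(scan))
    return(list(scan = .empty_scan(), candidates = NULL))
  scan$fdr <- bh_adjust(scan$logrank_p)
  scan <- scan[, c("gene", setdiff(names(scan), "gene"))]

  cand <- lapply(split(scan, scan$gene), select_reference_threshold,
                 alpha = alpha, max_fdr = max_fdr)
  cand <- do.call(rbind, cand[!vapply(cand, is.null, logical(1))])
  if (!is.null(cand) && nrow(cand)) {
    cand$hazard_ratio <- vapply(seq_len(nrow(cand)), function(i) {
      on <- expr[cand$gene[i], ] > cand$threshold[i]
      fit <- cox_fit(time, event, data.frame(on = as.numeric(on)))
      fit$hr[1L]
    }, numeric(1))
    cand <- cand[order(cand$logrank_p), , drop = FALSE]
    rownames(cand) <- NULL
  }
  list(scan = scan, candidates = cand)
}

#' Validation decision rule for a candidate biomarker
#'
#' A candidate is validated when it is significant (p < `alpha` with hazard
#' ratio > 1) in at least `ceiling(2m/3)` of the m validation cohorts and
#' its p-value stays below `lenient` in every remaining cohort (the
#' 2-of-3-plus-p<0.1 rule for m = 3).
#'
#' @param p per-cohort logrank p-values.
#' @param hr per-cohort ON-vs-OFF hazard ratios.
#' @param alpha,lenient the strict and lenient significance levels
#'   (defaults 0.05 and 0.1).
#' @return logical.
#' @examples
#' validation_decision(c(0.01, 0.04, 0.09), c(2, 1.8, 1.5))  # TRUE
#' validation_decision(c(0.01, 0.02, 0.5), c(2, 1.8, 1.5))   # FALSE
#' @export
validation_decision <- function(p, hr, alpha = 0.05, lenient = 0.1) {
  stopifnot(length(p) == length(hr), length(p) >= 1)
  ok <- !is.na(p)
  sig <- ok & p < alpha & !is.na(hr) & hr > 1
  m <- length(p)
  sum(sig) >= ceiling(2 * m / 3) && all(p[ok & !sig] < lenient) && all(ok)
}

#' Validate candidate biomarkers in independent cohorts
#'
#' Propagates each candidate's reference percentile into every validation
#' cohort, performs the ON-vs-OFF logrank test there, and applies
#' [validation_decision()]. Cohorts without events are excluded with a
#' warning.
#'
#' @param candidates the `candidates` table from [screen_genes()].
#' @param cohorts named list of validation cohorts, each a list with `expr`
#'   (genes x tumour samples) and `time`, `event` vectors.
#' @param alpha,lenient decision-rule levels.
#' @return `candidates` extended with per-cohort `p_<cohort>` / `hr_<cohort>`
#'   columns and a logical `validated` column.
#' @export
validate_genes <- function(candidates, cohorts, alpha = 0.05, lenient = 0.1) {
  if (is.null(candidates) || !nrow(candidates)) return(candidates)
  usable <- vapply(cohorts, function(co) sum(co$event, na.rm = TRUE) > 0,
                   logical(1))
  if (!all(usable)) {
    warning("excluding validation cohort(s) with zero events: ",
            paste(names(cohorts)[!usable], collapse = ", "))
    cohorts <- cohorts[usable]
  }
  if (!length(cohorts)) stop("no usable validation cohorts")
  pmat <- hmat <- matrix(NA_real_, nrow(candidates), length(cohorts),
                         dimnames = list(NULL, names(cohorts)))
  for (ci in seq_along(cohorts)) {
    co <- cohorts[[ci]]
    for (i in seq_len(nrow(candidates))) {
      g <- candidates$gene[i]
      if (!g %in% rownames(co$expr)) next
      thr <- propagate_threshold(candidates$percentile[i], co$expr[g, ])
      on <- co$expr[g, ] > thr
      if (!any(on) || all(on)) next
      lr <- logrank_test(co$time, co$event, on)
      pmat[i, ci] <- lr$p
      hmat[i, ci] <- lr$hr_pike
    }
  }
  out <- candidates
  for (ci in seq_along(cohorts)) {
    out[[paste0("p_", names(cohorts)[ci])]] <- pmat[, ci]
    out[[paste0("hr_", names(cohorts)[ci])]] <- hmat[, ci]
  }
  out$validated <- vapply(seq_len(nrow(out)), function(i)
    validation_decision(pmat[i, ], hmat[i, ], alpha, lenient), logical(1))
  out
}
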