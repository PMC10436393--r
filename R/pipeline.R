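#' Run the full biomarker-discovery pipeline
#'
#' Executes the training -> validation -> test flow on an in-memory study:
#' optional tissue-specificity candidate selection on a normal panel, then
#' activation-threshold fitting and the >10% frequent-activation filter on
#' the training cohort, the cross-validated threshold screen, validation of
#' candidates in the validation cohorts via percentile propagation, GEC
#' scoring and evaluation in every cohort (plus pooled subtype-stratified
#' analysis and a multivariate Cox where covariates exist), and the
#' extreme-group differential expression in the training cohort.
#'
#' @param study list with `cohorts` (named list as produced by
#'   [generate_cohort()]: each with `expr`, `clinical`, `role`) and
#'   optionally `panel` (as from [generate_normal_panel()]).
#' @param seed integer seed driving all pipeline randomness (the CV
#'   partitions).
#' @param out_dir optional directory; when given, all stage tables are
#'   written as TSV/CSV plus a JSON run log.
#' @param min_frequency frequent-activation cutoff (default 0.10).
#' @param max_panel maximum GEC panel size (default 5); validated genes are
#'   ranked by training logrank p.
#' @param grid_step percentile step of the screen grid (default 0.5).
#' @param ... further arguments passed to [screen_genes()].
#' @return list with `candidate_genes`, `activation_models`,
#'   `frequent_genes`, `screen` (scan + candidates), `validation`,
#'   `panel_genes`, `gec` (per-cohort scores and evaluations),
#'   `subtype` (pooled subtype analysis), `multivariate` (per-cohort Cox
#'   tables), `de` (training-cohort differential table), `log`.
#' @export
run_pipeline <- function(study, seed, out_dir = NULL, min_frequency = 0.10,
                         max_panel = 5, grid_step = 0.5, ...) {
  if (missing(seed)) stop("`seed` is required")
  roles <- vapply(study$cohorts, `[[`, character(1), "role")
  if (sum(roles == "training") != 1L)
    stop("exactly one training cohort required (found ",
         sum(roles == "training"), ")")
  if (!any(roles == "validation"))
    stop("at least one validation cohort required for the screen")
  log <- list(seed = seed, n_cohorts = length(study$cohorts),
              roles = as.list(table(roles)))

  # -- tissue specificity (optional; needs a normal panel) ------------------
  candidate_genes <- NULL
  if (!is.null(study$panel)) {
    pd <- compute_tissue_means(study$panel$expr, study$panel$tissues, "detailed")
    pg <- compute_tissue_means(study$panel$expr, study$panel$tissues, "grouped")
    cand <- select_candidate_genes(call_predominance(pd), call_predominance(pg),
                                   pd, pg)
    candidate_genes <- unique(cand$gene)
    log$n_candidate_genes <- length(candidate_genes)
  }

  # -- activation thresholds + frequency filter (training cohort) ----------
  train <- study$cohorts[[which(roles == "training")]]
  models <- build_activation_models(train$expr, train$clinical)
  freqs <- stats::setNames(models$frequency, models$gene)
  frequent <- filter_frequent(freqs, min_frequency)
  if (!is.null(candidate_genes)) frequent <- intersect(frequent, candidate_genes)
  log$n_frequent_genes <- length(frequent)
  if (!length(frequent)) stop("no frequently activated genes to screen")

  # -- training screen ------------------------------------------------------
  tt <- .tumour_view(train)
  screen <- screen_genes(tt$expr, tt$time, tt$event, genes = frequent,
                         seed = seed, grid_step = grid_step, ...)
  log$n_training_candidates <- if (is.null(screen$candidates)) 0L
    else nrow(screen$candidates)

  # -- validation -----------------------------------------------------------
  vcoh <- lapply(study$cohorts[roles == "validation"], .tumour_view)
  validation <- validate_genes(screen$candidates, vcoh)
  validated <- if (is.null(validation)) character(0)
    else validation$gene[validation$validated]
  log$n_validated <- length(validated)

  # -- GEC ------------------------------------------------------------------
  gec <- subtype <- multivariate <- de <- NULL
  panel_genes <- utils::head(validated, max_panel)
  if (length(panel_genes)) {
    ref_pct <- stats::setNames(
      validation$percentile[match(panel_genes, validation$gene)], panel_genes)
    gec <- lapply(study$cohorts, function(co) {
      tv <- .tumour_view(co)
      thr <- vapply(panel_genes, function(g)
        propagate_threshold(ref_pct[[g]], tv$expr[g, ]), numeric(1))
      sc <- gec_score(tv$expr, thr)
      list(role = co$role, scores = sc, thresholds = thr,
           evaluation = evaluate_gec(sc, tv$clinical))
    })
    # pooled subtype analysis over cohorts with subtype labels
    pooled_sc <- do.call(rbind, lapply(gec, `[[`, "scores"))
    K <- length(panel_genes)
    attr(pooled_sc, "panel_size") <- K
    pooled_cl <- do.call(rbind, lapply(study$cohorts, function(co)
      co$clinical[co$clinical$sample_type == "tumour",
                  intersect(c("sample_id", "time", "event", "subtype"),
                            names(co$clinical))]))
    if ("subtype" %in% names(pooled_cl))
      subtype <- subtype_stratified_evaluation(pooled_sc, pooled_cl)
    multivariate <- lapply(gec, function(g) NULL)
    for (nm in names(gec)) {
      co <- study$cohorts[[nm]]
      cov_av <- intersect(c("age", "subtype", "stage"), names(co$clinical))
      multivariate[[nm]] <- tryCatch(
        multivariate_cox(gec[[nm]]$scores,
                         co$clinical[co$clinical$sample_type == "tumour", ],
                         covariates = cov_av),
        error = function(e) NULL)
    }
    # differential expression between extreme groups, training cohort
    tr_name <- names(study$cohorts)[roles == "training"]
    de <- tryCatch(
      de_extreme_groups(.tumour_view(train)$expr, gec[[tr_name]]$scores),
      error = function(e) { warning(conditionMessage(e)); NULL })
  }

  result <- list(candidate_genes = candidate_genes,
                 activation_models = models, frequent_genes = frequent,
                 screen = screen, validation = validation,
                 panel_genes = panel_genes, gec = gec, subtype = subtype,
                 multivariate = multivariate, de = de, log = log)
  if (!is.null(out_dir)) .write_pipeline_outputs(result, study, out_dir)
  result
}

# tumour-only view of a cohort: expr restricted to tumour samples plus
# aligned survival vectors
.tumour_view <- function(cohort) {
  cl <- cohort$clinical
  tum <- cl$sample_id[cl$sample_type == "tumour"]
  expr <- cohort$expr[, tum, drop = FALSE]
  cl <- cl[match(tum, cl$sample_id), , drop = FALSE]
  list(expr = expr, time = cl$time, event = cl$event, clinical = cl)
}

.write_pipeline_outputs <- function(result, study, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) if (!is.null(df) && nrow(df))
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  w(result$activation_models, "activation_models.tsv")
  w(result$screen$scan, "threshold_scan.tsv")
  w(result$screen$candidates, "training_candidates.tsv")
  w(result$validation, "validated_biomarkers.tsv")
  if (!is.null(result$gec)) {
    all_scores <- do.call(rbind, lapply(names(result$gec), function(nm)
      cbind(cohort = nm, result$gec[[nm]]$scores)))
    w(all_scores, "gec_scores.tsv")
  }
  if (!is.null(result$subtype)) w(result$subtype$distribution,
                                  "subtype_distribution.tsv")
  w(result$de, "de_extreme_groups.tsv")
  jsonlite::write_json(result$log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}
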