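#' Fit per-gene activation thresholds from non-tumour samples
#'
#' The activation threshold of a gene is the mean + 2 standard deviations
#' (sample SD, n-1 denominator) of its log2 expression in the non-tumour
#' reference samples; tumour samples strictly above it are called ON.
#'
#' @param expr_nontumour genes x non-tumour-samples log2 matrix (or a single
#'   gene's numeric vector).
#' @param expr_tumour optional genes x tumour-samples matrix; when given, the
#'   threshold's percentile rank in the tumour distribution (fraction of
#'   tumour samples at or below the threshold) and the activation frequency
#'   are attached.
#' @return data.frame of class `activation_model` with columns `gene`,
#'   `threshold`, `source`, and (if `expr_tumour` given) `percentile_rank`
#'   and `frequency`.
#' @examples
#' fit_activation_threshold(rbind(g1 = c(0, 2)))$threshold  # 1 + 2*sqrt(2)
#' @export
fit_activation_threshold <- function(expr_nontumour, expr_tumour = NULL) {
  if (!is.matrix(expr_nontumour))
    expr_nontumour <- matrix(expr_nontumour, nrow = 1,
                             dimnames = list("gene", NULL))
  if (ncol(expr_nontumour) < 2)
    stop("need >= 2 non-tumour samples to fit activation thresholds")
  mu <- rowMeans(expr_nontumour)
  sd <- apply(expr_nontumour, 1L, stats::sd)
  out <- data.frame(gene = rownames(expr_nontumour),
                    threshold = mu + 2 * sd,
                    source = "nontumour_mean2sd",
                    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(expr_tumour)) {
    stopifnot(identical(rownames(expr_tumour), rownames(expr_nontumour)))
    out$percentile_rank <- vapply(seq_len(nrow(out)), function(i)
      mean(expr_tumour[i, ] <= out$threshold[i]), numeric(1))
    out$frequency <- vapply(seq_len(nrow(out)), function(i)
      activation_frequency(expr_tumour[i, ], out$threshold[i]), numeric(1))
  }
  class(out) <- c("activation_model", "data.frame")
  out
}

#' Call ON/OFF activation status
#'
#' A sample is ON for a gene iff its expression is strictly greater than the
#' gene's activation threshold; values equal to the threshold, and missing
#' values, are OFF (missing values are counted and reported via a message).
#'
#' @param values numeric log2 expression values.
#' @param threshold scalar activation threshold.
#' @return logical vector, `TRUE` = ON.
#' @export
call_activation <- function(values, threshold) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L)
  n_missing <- sum(is.na(values))
  if (n_missing)
    message(n_missing, " missing expression value(s) treated as OFF")
  on <- values > threshold
  on[is.na(on)] <- FALSE
  on
}

#' Ectopic activation frequency in tumour samples
#'
#' Fraction of tumour samples (with non-missing values) whose expression lies
#' strictly above the activation threshold.
#'
#' @param tumour_values numeric log2 expression of the gene in tumours.
#' @param threshold activation threshold.
#' @return Fraction in `[0, 1]`; `NA` (with a warning) if no usable sample.
#' @export
activation_frequency <- function(tumour_values, threshold) {
  usable <- !is.na(tumour_values)
  if (!any(usable)) {
    warning("no usable tumour samples; activation frequency undefined")
    return(NA_real_)
  }
  mean(tumour_values[usable] > threshold)
}

#' Filter genes by minimum activation frequency
#'
#' Keeps genes activated in strictly more than `min_frequency` of tumour
#' samples (the "frequently activated" convention: more than 10%).
#'
#' @param frequencies named numeric vector of per-gene activation
#'   frequencies.
#' @param min_frequency exclusive lower bound (default 0.10).
#' @return Character vector of gene names passing the filter.
#' @export
filter_frequent <- function(frequencies, min_frequency = 0.10) {
  stopifnot(is.numeric(frequencies), !is.null(names(frequencies)))
  names(frequencies)[!is.na(frequencies) & frequencies > min_frequency]
}

#' Build activation models for a cohort
#'
#' Convenience wrapper: splits a cohort into tumour / non-tumour samples via
#' the clinical table, fits mean + 2 SD thresholds on the non-tumour side and
#' attaches tumour percentile ranks and activation frequencies.
#'
#' @param expr genes x samples log2 matrix.
#' @param clinical data.frame with `sample_id` and `sample_type`
#'   (`"tumour"` / `"non-tumour"`).
#' @return An `activation_model` data.frame (see
#'   [fit_activation_threshold()]).
#' @export
build_activation_models <- function(expr, clinical) {
  stopifnot(all(c("sample_id", "sample_type") %in% names(clinical)))
  ann <- clinical[match(colnames(expr), clinical$sample_id), , drop = FALSE]
  if (anyNA(ann$sample_type))
    stop("samples without clinical annotation: ",
         paste(utils::head(colnames(expr)[is.na(ann$sample_type)], 5),
               collapse = ", "))
  non <- expr[, ann$sample_type == "non-tumour", drop = FALSE]
  tum <- expr[, ann$sample_type == "tumour", drop = FALSE]
  fit_activation_threshold(non, tum)
}
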