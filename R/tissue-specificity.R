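#' Per-gene per-tissue mean expression panel
#'
#' Averages log2 expression within each tissue (detailed granularity) or
#' within each tissue group (grouped granularity, pooling all samples of the
#' group so tissues are weighted by sample count).
#'
#' @param expr genes x samples log2 expression matrix.
#' @param tissues data.frame with columns `sample_id`, `tissue`,
#'   `tissue_group`, `is_foetal`, one row per sample (all columns of `expr`).
#' @param granularity `"detailed"` (per tissue) or `"grouped"` (per tissue
#'   group).
#' @return An object of class `tissue_panel`: list with `means` (genes x
#'   tissues matrix of mean log2 expression), `is_foetal` (per tissue),
#'   `N` (number of non-foetal tissues, the N of the Z-score threshold) and
#'   `granularity`.
#' @examples
#' p <- generate_normal_panel(sim_config(seed = 1))
#' tp <- compute_tissue_means(p$expr, p$tissues)
#' tp$N
#' @export
compute_tissue_means <- function(expr, tissues,
                                 granularity = c("detailed", "grouped")) {
  granularity <- match.arg(granularity)
  stopifnot(is.matrix(expr), is.data.frame(tissues))
  missing_cols <- setdiff(c("sample_id", "tissue", "tissue_group", "is_foetal"),
                          names(tissues))
  if (length(missing_cols))
    stop("tissue annotation lacks columns: ", paste(missing_cols, collapse = ", "))
  unlabelled <- setdiff(colnames(expr), tissues$sample_id)
  if (length(unlabelled))
    stop("unlabelled samples in expression matrix: ",
         paste(utils::head(unlabelled, 5), collapse = ", "))
  ann <- tissues[match(colnames(expr), tissues$sample_id), , drop = FALSE]
  key <- if (granularity == "detailed") ann$tissue else ann$tissue_group
  groups <- unique(key)
  means <- vapply(groups,
                  function(g) rowMeans(expr[, key == g, drop = FALSE]),
                  numeric(nrow(expr)))
  dimnames(means) <- list(rownames(expr), groups)
  foetal <- vapply(groups, function(g) any(ann$is_foetal[key == g]), logical(1))
  structure(list(means = means, is_foetal = foetal,
                 N = sum(!foetal), granularity = granularity),
            class = "tissue_panel")
}

#' Z-score expression profile across non-foetal tissues
#'
#' For each gene, standardizes the per-tissue mean expression over the
#' non-foetal tissues: `z = (x - mean) / sd`, where the mean and the
#' population standard deviation (divide by N) are taken over the non-foetal
#' tissue means. Foetal tissues receive no score. With the population-SD
#' convention the maximum attainable Z is exactly `(N - 1) / sqrt(N)`, the
#' quantity the predominance threshold scales by 0.6.
#'
#' @param panel a [compute_tissue_means()] result.
#' @param genes optional character vector restricting the genes scored.
#' @return Numeric matrix genes x non-foetal tissues of Z-scores; rows of
#'   zero-variance (non-scorable) genes are `NA`.
#' @export
zscore_profile <- function(panel, genes = NULL) {
  stopifnot(inherits(panel, "tissue_panel"))
  m <- panel$means[, !panel$is_foetal, drop = FALSE]
  if (!is.null(genes)) m <- m[genes, , drop = FALSE]
  if (panel$N < 3) stop("need >= 3 non-foetal tissues to score")
  mu <- rowMeans(m)
  sd_pop <- sqrt(rowMeans((m - mu)^2))
  z <- (m - mu) / sd_pop
  z[sd_pop == 0, ] <- NA_real_
  z
}

#' Z-score threshold for calling tissue predominance
#'
#' The predominance cutoff is 60% of the maximum Z-score attainable over N
#' tissues under the population-SD convention: `0.6 * (N - 1) / sqrt(N)`.
#' At N = 40 (detailed tissue list) this is 3.7 and at N = 19 (tissue
#' groups) 2.5, to one decimal.
#'
#' @param N number of (non-foetal) tissues entering the Z computation; >= 2.
#' @return The dimensionless threshold.
#' @examples
#' round(zscore_threshold(40), 1)  # 3.7
#' round(zscore_threshold(19), 1)  # 2.5
#' @export
zscore_threshold <- function(N) {
  if (!is.numeric(N) || any(N < 2))
    stop("invalid `N`: need N >= 2 tissues")
  0.6 * (N - 1) / sqrt(N)
}

#' Call the predominant tissue for each gene
#'
#' Reports, per gene, the non-foetal tissue with the maximal Z-score and
#' whether that Z exceeds the [zscore_threshold()] for the panel's N. Genes
#' with zero variance across tissues are non-scorable and never pass.
#'
#' @param panel a [compute_tissue_means()] result.
#' @return data.frame with columns `gene`, `granularity`, `predominant_tissue`,
#'   `z_score`, `threshold`, `passed`, `scorable`.
#' @export
call_predominance <- function(panel) {
  stopifnot(inherits(panel, "tissue_panel"))
  z <- zscore_profile(panel)
  scorable <- !is.na(z[, 1])
  thr <- zscore_threshold(panel$N)
  top <- apply(z, 1L, function(r) if (all(is.na(r))) NA_integer_ else which.max(r))
  tiss <- colnames(z)[top]
  zmax <- z[cbind(seq_len(nrow(z)), ifelse(is.na(top), 1L, top))]
  zmax[!scorable] <- NA_real_
  n_drop <- sum(!scorable)
  if (n_drop)
    message(n_drop, " gene(s) non-scorable (zero variance across tissues)")
  data.frame(gene = rownames(z),
             granularity = panel$granularity,
             predominant_tissue = ifelse(scorable, tiss, NA),
             z_score = zmax,
             threshold = thr,
             passed = !is.na(zmax) & zmax > thr,
             scorable = scorable,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Select candidate tissue-specific genes not expressed in breast
#'
#' A gene is a candidate if it is called predominant (Z above threshold) in
#' one of the target tissues at either granularity, and its breast
#' expression is more than 10-fold lower than in the predominant tissue.
#' The 10x rule is evaluated on the linear scale: per-tissue means are
#' back-transformed as `2^x - 1` and the gene is kept only when
#' `linear(breast) < linear(predominant) / 10` (strict).
#'
#' @param calls_detailed,calls_grouped [call_predominance()] results at the
#'   two granularities.
#' @param panel_detailed,panel_grouped the matching [compute_tissue_means()]
#'   panels (used for the breast / predominant linear means).
#' @param target_tissues detailed-granularity target tissues
#'   (default `c("testis","placenta","esc")`).
#' @param target_groups grouped-granularity analogues
#'   (default `c("male_germinal","placenta","es_cells")`).
#' @param breast name of the breast tissue/group (must exist in both panels).
#' @return data.frame of selected genes with the granularity that selected
#'   them, predominant tissue, Z, threshold and the linear breast ratio.
#' @export
select_candidate_genes <- function(calls_detailed, calls_grouped,
                                   panel_detailed, panel_grouped,
                                   target_tissues = c("testis", "placenta", "esc"),
                                   target_groups = c("male_germinal", "placenta", "es_cells"),
                                   breast = "breast") {
  pick <- function(calls, panel, targets) {
    if (!breast %in% colnames(panel$means))
      stop("breast tissue '", breast, "' absent from the panel")
    hits <- calls[calls$passed & calls$predominant_tissue %in% targets, , drop = FALSE]
    if (!nrow(hits)) {
      hits <- hits[, c("gene", "granularity", "predominant_tissue",
                       "z_score", "threshold")]
      hits$breast_ratio <- numeric(0)
      return(hits)
    }
    lin <- function(x) 2^x - 1
    b <- lin(panel$means[hits$gene, breast])
    p <- lin(panel$means[cbind(match(hits$gene, rownames(panel$means)),
                               match(hits$predominant_tissue, colnames(panel$means)))])
    keep <- b < p / 10
    hits <- hits[keep, , drop = FALSE]
    hits$breast_ratio <- (p / pmax(b, .Machine$double.eps))[keep]
    hits[, c("gene", "granularity", "predominant_tissue", "z_score",
             "threshold", "breast_ratio")]
  }
  out <- rbind(pick(calls_detailed, panel_detailed, target_tissues),
               pick(calls_grouped, panel_grouped, target_groups))
  rownames(out) <- NULL
  out
}
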