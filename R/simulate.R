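#' Generate a synthetic normal-tissue expression panel
#'
#' Simulates a genes-by-samples log2 expression matrix over the detailed
#' tissue list of `config`, with the planted tissue-predominant genes elevated
#' by `predominance_shift` in their designated tissue only (baseline in
#' breast and everywhere else) and ubiquitous genes at a shared baseline.
#'
#' @param config a [sim_config()] object.
#' @return A list with components:
#'   \describe{
#'     \item{expr}{numeric matrix, genes x samples, log2 scale.}
#'     \item{tissues}{data.frame with `sample_id`, `tissue`, `tissue_group`,
#'       `is_foetal` for every sample.}
#'     \item{truth}{planted-truth manifest: per gene its class,
#'       predominant tissue, activatable/prognostic flags, planted
#'       activation frequency and log hazard.}
#'   }
#' @examples
#' panel <- generate_normal_panel(sim_config(seed = 7))
#' dim(panel$expr)
#' @export
generate_normal_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  genes <- .sim_genes(config)
  tissues <- .sim_tissues(config)
  set.seed(.derive_seed(config$seed, 1L))

  spt <- config$samples_per_tissue
  ann <- data.frame(
    sample_id = paste0("N_", rep(tissues$tissue, each = spt), "_",
                       rep(seq_len(spt), times = nrow(tissues))),
    tissue = rep(tissues$tissue, each = spt),
    tissue_group = rep(tissues$tissue_group, each = spt),
    is_foetal = rep(tissues$is_foetal, each = spt),
    stringsAsFactors = FALSE
  )
  n_samp <- nrow(ann)
  expr <- matrix(stats::rnorm(config$n_genes * n_samp,
                              mean = config$baseline_mean,
                              sd = config$baseline_sd),
                 nrow = config$n_genes, ncol = n_samp,
                 dimnames = list(genes$gene, ann$sample_id))
  planted <- which(!is.na(genes$predominant_tissue))
  for (g in planted) {
    in_target <- ann$tissue == genes$predominant_tissue[g]
    expr[g, in_target] <- expr[g, in_target] + config$predominance_shift
  }
  list(expr = expr, tissues = ann, truth = genes)
}

#' Generate one synthetic tumour cohort
#'
#' Simulates a tumour cohort with non-tumour reference samples, planted
#' ectopic activations and proportional-hazards disease-free survival. Every
#' activatable gene is silent (baseline) in non-tumour samples; each tumour
#' sample activates each activatable gene independently with its planted
#' frequency, adding `activation_shift` log2 units. The event time is
#' exponential with hazard
#' `baseline_hazard * exp(sum(log_hazard * activated prognostic genes))`,
#' censored by an independent exponential and by the administrative
#' follow-up cap. A cohort-level offset (SD `cohort_shift_sd`) is added to
#' all expression values to emulate platform heterogeneity.
#'
#' @param config a [sim_config()] object.
#' @param cohort_index integer in `1..config$n_cohorts`.
#' @return A list with components:
#'   \describe{
#'     \item{expr}{log2 expression matrix, genes x (tumour + non-tumour)
#'       samples.}
#'     \item{clinical}{data.frame: `sample_id`, `sample_type`
#'       (tumour/non-tumour), `time`, `event`, `age`, `subtype`, `stage`
#'       (survival fields `NA` for non-tumour samples).}
#'     \item{activation}{planted-truth 0/1 matrix, tumour samples x
#'       activatable genes.}
#'     \item{truth}{gene manifest as in [generate_normal_panel()].}
#'     \item{role}{cohort role (training/validation/test).}
#'     \item{cohort_shift}{the additive log2 offset applied.}
#'   }
#' @examples
#' co <- generate_cohort(sim_config(seed = 7), 1)
#' table(co$clinical$sample_type)
#' @export
generate_cohort <- function(config, cohort_index) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.numeric(cohort_index) || length(cohort_index) != 1L ||
      cohort_index < 1 || cohort_index > config$n_cohorts)
    stop("invalid `cohort_index`: must be in 1..", config$n_cohorts, call. = FALSE)
  cohort_index <- as.integer(cohort_index)
  genes <- .sim_genes(config)
  set.seed(.derive_seed(config$seed, 100L + cohort_index))

  nt <- config$n_tumour[cohort_index]
  nn <- config$n_nontumour[cohort_index]
  cid <- sprintf("C%d", cohort_index)
  tum_id <- sprintf("%s_T%04d", cid, seq_len(nt))
  non_id <- sprintf("%s_N%04d", cid, seq_len(nn))

  cohort_shift <- stats::rnorm(1L, 0, config$cohort_shift_sd)

  expr <- matrix(stats::rnorm(config$n_genes * (nt + nn),
                              mean = config$baseline_mean,
                              sd = config$baseline_sd),
                 nrow = config$n_genes, ncol = nt + nn,
                 dimnames = list(genes$gene, c(tum_id, non_id)))

  act_idx <- which(genes$activatable)
  n_act <- length(act_idx)
  A <- matrix(stats::rbinom(nt * n_act, 1L,
                            rep(config$activation_frequency, each = nt)),
              nrow = nt, ncol = n_act,
              dimnames = list(tum_id, genes$gene[act_idx]))
  expr[act_idx, seq_len(nt)] <- expr[act_idx, seq_len(nt)] +
    config$activation_shift * t(A)

  # proportional-hazards event times from activated prognostic genes
  loghr <- genes$log_hazard[act_idx]
  lp <- as.vector(A %*% loghr)
  hazard <- config$baseline_hazard * exp(lp)
  t_event <- stats::rexp(nt, rate = hazard)
  t_cens <- if (config$censoring_rate > 0)
    stats::rexp(nt, rate = config$censoring_rate) else rep(Inf, nt)
  t_cens <- pmin(t_cens, config$follow_up_cap)
  time <- pmin(t_event, t_cens)
  event <- as.integer(t_event <= t_cens)

  age <- round(stats::runif(nt + nn, 30, 85), 1)
  subtype <- sample(c("luminal_A", "luminal_B", "HER2", "basal"), nt,
                    replace = TRUE, prob = c(0.534, 0.198, 0.080, 0.188))
  stage <- sample(1:4, nt, replace = TRUE, prob = c(0.25, 0.40, 0.25, 0.10))

  clinical <- data.frame(
    sample_id = c(tum_id, non_id),
    sample_type = rep(c("tumour", "non-tumour"), c(nt, nn)),
    time = c(time, rep(NA_real_, nn)),
    event = c(event, rep(NA_integer_, nn)),
    age = age,
    subtype = c(subtype, rep(NA_character_, nn)),
    stage = c(stage, rep(NA_integer_, nn)),
    stringsAsFactors = FALSE
  )

  expr <- expr + cohort_shift
  list(expr = expr, clinical = clinical, activation = A, truth = genes,
       role = config$cohort_roles[cohort_index], cohort_shift = cohort_shift)
}

#' Generate a complete synthetic study
#'
#' Convenience wrapper producing the normal panel and all cohorts of a
#' configuration, in the shape [run_pipeline()] consumes.
#'
#' @param config a [sim_config()] object.
#' @param panel generate the normal-tissue panel too? (default `TRUE`).
#' @return A list with `config`, `truth`, optional `panel`, and `cohorts`
#'   (one [generate_cohort()] result per cohort, named `C1`, `C2`, ...).
#' @examples
#' study <- simulate_study(sim_config(seed = 3, n_cohorts = 2,
#'                                    n_tumour = c(80, 60),
#'                                    cohort_roles = c("training", "validation")))
#' names(study$cohorts)
#' @export
simulate_study <- function(config, panel = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  cohorts <- lapply(seq_len(config$n_cohorts),
                    function(i) generate_cohort(config, i))
  names(cohorts) <- sprintf("C%d", seq_len(config$n_cohorts))
  out <- list(config = config, truth = .sim_genes(config), cohorts = cohorts)
  if (panel) out$panel <- generate_normal_panel(config)
  out
}
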