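#' Simulation configuration for synthetic study data
#'
#' Builds and validates the configuration object consumed by
#' [generate_normal_panel()] and [generate_cohort()]. The defaults describe a
#' synthetic multi-cohort breast-cancer-like study: a normal-tissue panel with
#' genes predominantly expressed in testis, placenta or embryonic stem cells
#' (ESC) and silent in breast, plus one training, three validation and four
#' test tumour cohorts carrying planted ectopic activations and
#' proportional-hazards disease-free survival.
#'
#' Expression is simulated on the log2 scale with Gaussian noise. Activatable
#' genes (the planted tissue-predominant genes) are silent at baseline in
#' non-tumour samples and gain `activation_shift` log2 units in each tumour
#' sample independently with probability `activation_frequency`. Event times
#' are exponential with hazard
#' `baseline_hazard * exp(sum(log_hazard_per_activation * activated))` over
#' the prognostic genes; censoring is an independent exponential capped at
#' `follow_up_cap`.
#'
#' @param seed integer seed; all randomness in the generators derives from it.
#' @param n_tissues number of detailed tissues in the normal panel (>= 8);
#'   always includes `testis`, `placenta`, `esc`, `breast` and two foetal
#'   tissues, the remainder are generic somatic tissues.
#' @param samples_per_tissue normal samples simulated per tissue.
#' @param n_genes total number of genes.
#' @param n_predominant named integer vector `c(testis=, placenta=, esc=)`:
#'   planted tissue-predominant (hence tumour-activatable) genes per target
#'   tissue class. Remaining genes are ubiquitous.
#' @param baseline_mean,baseline_sd baseline log2 expression mean and SD.
#' @param predominance_shift log2 units added in the designated tissue of a
#'   planted predominant gene.
#' @param n_cohorts number of tumour cohorts.
#' @param n_tumour,n_nontumour per-cohort tumour / non-tumour sample counts
#'   (recycled to `n_cohorts`).
#' @param cohort_roles character vector of roles in
#'   `c("training","validation","test")`, recycled to `n_cohorts`.
#' @param activation_frequency per-activatable-gene activation probability in
#'   tumours (recycled). Default: 0.30 for non-prognostic activatable genes
#'   and an even spread over 0.25--0.35 for the prognostic genes.
#' @param activation_shift log2 units added upon activation.
#' @param prognostic_genes integer indices (into the activatable genes) of the
#'   genes whose activation carries a hazard effect; may be empty.
#' @param log_hazard_per_activation log hazard ratio per activated prognostic
#'   gene; scalar or one value per prognostic gene. Default spreads over
#'   `log(2.5)`..`log(3)`.
#' @param baseline_hazard baseline event hazard (events per time unit).
#' @param censoring_rate rate of the independent exponential censoring process.
#' @param cohort_shift_sd SD of the per-cohort additive log2 offset
#'   (inter-cohort heterogeneity, e.g. platform shifts).
#' @param follow_up_cap administrative censoring time.
#'
#' @return An object of class `sim_config` (a validated list of the above).
#' @examples
#' cfg <- sim_config(seed = 1)
#' cfg$n_tumour
#' @export
sim_config <- function(seed = 1L,
                       n_tissues = 20L,
                       samples_per_tissue = 5L,
                       n_genes = 125L,
                       n_predominant = c(testis = 9L, placenta = 8L, esc = 8L),
                       baseline_mean = 1,
                       baseline_sd = 0.5,
                       predominance_shift = 6,
                       n_cohorts = 8L,
                       n_tumour = c(600L, 250L, 250L, 250L, 1500L, 1500L, 1500L, 1500L),
                       n_nontumour = c(100L, rep(60L, 7L)),
                       cohort_roles = c("training", rep("validation", 3), rep("test", 4)),
                       activation_frequency = NULL,
                       activation_shift = 4,
                       prognostic_genes = 1:5,
                       log_hazard_per_activation = NULL,
                       baseline_hazard = 0.05,
                       censoring_rate = 0.03,
                       cohort_shift_sd = 0.5,
                       follow_up_cap = 15) {
  chk_count <- function(x, name, min = 1L) {
    if (!is.numeric(x) || any(is.na(x)) || any(x < min) || any(x != floor(x)))
      stop("invalid `", name, "`: must be integer(s) >= ", min, call. = FALSE)
    as.integer(x)
  }
  chk_pos <- function(x, name) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0)
      stop("invalid `", name, "`: must be a positive number", call. = FALSE)
    as.numeric(x)
  }
  seed <- chk_count(seed, "seed", min = 0L)
  if (length(seed) != 1L) stop("invalid `seed`: must be a single integer", call. = FALSE)
  n_tissues <- chk_count(n_tissues, "n_tissues", min = 8L)
  samples_per_tissue <- chk_count(samples_per_tissue, "samples_per_tissue")
  n_genes <- chk_count(n_genes, "n_genes")
  if (!all(c("testis", "placenta", "esc") %in% names(n_predominant)))
    stop("invalid `n_predominant`: needs named entries testis, placenta, esc", call. = FALSE)
  n_predominant <- chk_count(n_predominant, "n_predominant", min = 0L)
  names(n_predominant) <- c("testis", "placenta", "esc")
  n_act <- sum(n_predominant)
  if (n_act < 1L || n_act > n_genes)
    stop("invalid `n_predominant`: total planted genes must be in [1, n_genes]", call. = FALSE)
  if (!is.numeric(baseline_sd) || baseline_sd <= 0)
    stop("invalid `baseline_sd`: must be > 0", call. = FALSE)
  n_cohorts <- chk_count(n_cohorts, "n_cohorts")
  n_tumour <- rep_len(chk_count(n_tumour, "n_tumour"), n_cohorts)
  n_nontumour <- rep_len(chk_count(n_nontumour, "n_nontumour", min = 2L), n_cohorts)
  cohort_roles <- rep_len(as.character(cohort_roles), n_cohorts)
  if (!all(cohort_roles %in% c("training", "validation", "test")))
    stop("invalid `cohort_roles`: must be training/validation/test", call. = FALSE)

  prognostic_genes <- if (length(prognostic_genes)) chk_count(prognostic_genes, "prognostic_genes") else integer(0)
  if (any(prognostic_genes > n_act))
    stop("invalid `prognostic_genes`: indices must refer to activatable genes (1..",
         n_act, ")", call. = FALSE)
  n_prog <- length(prognostic_genes)

  if (is.null(activation_frequency)) {
    activation_frequency <- rep(0.30, n_act)
    if (n_prog)
      activation_frequency[prognostic_genes] <-
        seq(0.25, 0.35, length.out = n_prog)
  }
  activation_frequency <- rep_len(as.numeric(activation_frequency), n_act)
  if (any(is.na(activation_frequency)) || any(activation_frequency < 0) ||
      any(activation_frequency > 1))
    stop("invalid `activation_frequency`: fractions must lie in [0, 1]", call. = FALSE)

  if (is.null(log_hazard_per_activation)) {
    log_hazard_per_activation <- if (n_prog)
      seq(log(2.5), log(3), length.out = n_prog) else numeric(0)
  }
  log_hazard_per_activation <- rep_len(as.numeric(log_hazard_per_activation),
                                       max(n_prog, 1L))[seq_len(n_prog)]

  baseline_hazard <- chk_pos(baseline_hazard, "baseline_hazard")
  if (!is.numeric(censoring_rate) || censoring_rate < 0)
    stop("invalid `censoring_rate`: must be >= 0", call. = FALSE)
  if (!is.numeric(cohort_shift_sd) || cohort_shift_sd < 0)
    stop("invalid `cohort_shift_sd`: must be >= 0", call. = FALSE)
  follow_up_cap <- chk_pos(follow_up_cap, "follow_up_cap")

  structure(list(
    seed = seed, n_tissues = n_tissues, samples_per_tissue = samples_per_tissue,
    n_genes = n_genes, n_predominant = n_predominant,
    baseline_mean = as.numeric(baseline_mean), baseline_sd = as.numeric(baseline_sd),
    predominance_shift = as.numeric(predominance_shift),
    n_cohorts = n_cohorts, n_tumour = n_tumour, n_nontumour = n_nontumour,
    cohort_roles = cohort_roles,
    activation_frequency = activation_frequency,
    activation_shift = as.numeric(activation_shift),
    prognostic_genes = prognostic_genes,
    log_hazard_per_activation = log_hazard_per_activation,
    baseline_hazard = baseline_hazard, censoring_rate = as.numeric(censoring_rate),
    cohort_shift_sd = as.numeric(cohort_shift_sd), follow_up_cap = follow_up_cap
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_genes, "genes (", sum(x$n_predominant),
      "activatable,", length(x$prognostic_genes), "prognostic ),",
      x$n_tissues, "tissues,", x$n_cohorts, "cohorts [",
      paste(x$cohort_roles, collapse = ", "), "]\n")
  invisible(x)
}

# deterministic per-component seed derivation, kept inside 32-bit range
.derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) + 7919 * as.double(offset)) %% 2147483647)
}

# gene identifiers and planted-truth manifest implied by a config
.sim_genes <- function(config) {
  n_act <- sum(config$n_predominant)
  cls <- rep(c(names(config$n_predominant), "ubiquitous"),
             c(config$n_predominant, config$n_genes - n_act))
  gene <- character(config$n_genes)
  gene[cls != "ubiquitous"] <- sprintf("TSG%03d", seq_len(n_act))
  gene[cls == "ubiquitous"] <- sprintf("UBQ%03d", seq_len(config$n_genes - n_act))
  activatable <- cls != "ubiquitous"
  prognostic <- rep(FALSE, config$n_genes)
  prognostic[which(activatable)[config$prognostic_genes]] <- TRUE
  freq <- rep(NA_real_, config$n_genes)
  freq[activatable] <- config$activation_frequency
  loghr <- rep(0, config$n_genes)
  loghr[which(activatable)[config$prognostic_genes]] <- config$log_hazard_per_activation
  data.frame(gene = gene, class = cls,
             predominant_tissue = ifelse(cls %in% c("testis", "placenta", "esc"), cls, NA),
             activatable = activatable, prognostic = prognostic,
             activation_frequency = freq, log_hazard = loghr,
             stringsAsFactors = FALSE)
}

# detailed tissue list with foetal flags and coarse group mapping
.sim_tissues <- function(config) {
  generic <- c("brain", "liver", "lung", "kidney", "heart", "muscle", "skin",
               "colon", "stomach", "pancreas", "spleen", "thyroid", "ovary",
               "prostate", "bladder", "adipose", "nerve", "pituitary",
               "adrenal", "oesophagus", "salivary", "artery")
  n_generic <- config$n_tissues - 6L
  if (n_generic > length(generic))
    generic <- c(generic, sprintf("tissue%02d", seq_len(n_generic - length(generic))))
  tissue <- c("testis", "placenta", "esc", "breast",
              "foetal_brain", "foetal_liver", generic[seq_len(n_generic)])
  group <- c("male_germinal", "placenta", "es_cells", "breast",
             "foetal", "foetal",
             sprintf("group%02d", ceiling(seq_len(n_generic) / 2)))
  data.frame(tissue = tissue, tissue_group = group,
             is_foetal = grepl("^foetal", tissue), stringsAsFactors = FALSE)
}
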