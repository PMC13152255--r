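# Multifactorial likelihood analysis: combined likelihood ratio, Bayes
# posterior probability of pathogenicity, and IARC five-class assignment.

#' Combine likelihood-ratio components
#'
#' The combined likelihood ratio (LR) is the product of independent
#' component LRs (personal/family cancer history, pathology profile,
#' co-occurrence with pathogenic variants, ...). An empty component list is
#' the neutral LR 1.
#'
#' @param components Numeric vector of non-negative component LRs.
#' @return The product of the components.
#' @export
combine_lr <- function(components) {
  components <- as.numeric(components)
  if (anyNA(components) || any(components < 0)) {
    stop("likelihood-ratio components must be non-negative and non-missing",
         call. = FALSE)
  }
  prod(components)
}

#' Bayes posterior probability of pathogenicity
#'
#' Converts a prior probability and a combined likelihood ratio to a
#' posterior via Bayes' theorem on the odds scale:
#' posterior = prior * LR / (prior * LR + (1 - prior)).
#'
#' @param prior Prior probability of pathogenicity in \[0, 1\].
#' @param combined_lr Non-negative combined likelihood ratio.
#' @return Posterior probability in \[0, 1\].
#' @examples
#' posterior_probability(0.5, 1)       # 0.5: uninformative LR
#' posterior_probability(0.02, 0.024)  # ~0.00049
#' @export
posterior_probability <- function(prior, combined_lr) {
  stopifnot(length(prior) == length(combined_lr))
  if (anyNA(prior) || any(prior < 0 | prior > 1)) {
    stop("prior must be a probability in [0, 1]", call. = FALSE)
  }
  if (anyNA(combined_lr) || any(combined_lr < 0)) {
    stop("combined_lr must be non-negative", call. = FALSE)
  }
  if (any(prior == 1 & combined_lr == 0)) {
    stop("indeterminate posterior: prior = 1 with combined LR = 0",
         call. = FALSE)
  }
  num <- prior * combined_lr
  num / (num + (1 - prior))
}

#' IARC five-class assignment from posterior probability
#'
#' Classes on the posterior probability of pathogenicity: class 5
#' (pathogenic) above 0.99; class 4 (likely pathogenic) 0.95 to 0.99; class
#' 3 (uncertain) 0.05 to below 0.95; class 2 (likely neutral) above 0.001
#' and below 0.05; class 1 (neutral) at or below 0.001. Posteriors are
#' conventionally reported at three decimals, so the class-1 boundary value
#' 0.001 itself maps to class 1 (a full-precision posterior printed as 0.001
#' may lie below it). A variant whose combined LR falls in
#' the informativeness exclusion window (0.5 to 2 inclusive by default) is
#' not assigned a class: such an LR is too close to neutral for the
#' posterior to mean more than its prior.
#'
#' @param posterior Posterior probabilities in \[0, 1\].
#' @param combined_lr Combined likelihood ratios (same length).
#' @param exclusion_window Length-2 numeric, inclusive LR bounds within which
#'   no class is assigned.
#' @return Character vector with values `"1"` to `"5"` or `"not_assigned"`.
#' @examples
#' iarc_class(0.999, 29.348) # "5"
#' iarc_class(0.296, 1.030)  # "not_assigned": LR within [0.5, 2]
#' @export
iarc_class <- function(posterior, combined_lr,
                       exclusion_window = c(0.5, 2)) {
  stopifnot(length(posterior) == length(combined_lr),
            length(exclusion_window) == 2L,
            exclusion_window[1] <= exclusion_window[2])
  if (anyNA(posterior) || any(posterior < 0 | posterior > 1)) {
    stop("posterior must be a probability in [0, 1]", call. = FALSE)
  }
  excluded <- combined_lr >= exclusion_window[1] &
    combined_lr <= exclusion_window[2]
  cls <- ifelse(posterior <= 0.001, "1",
    ifelse(posterior < 0.05, "2",
      ifelse(posterior < 0.95, "3",
        ifelse(posterior <= 0.99, "4", "5"))))
  ifelse(excluded, "not_assigned", cls)
}

#' Load the pipeline configuration
#'
#' Reads the YAML configuration holding the prior-probability table (keyed
#' by Align-GVGD grade and by variant type) and the LR exclusion-window
#' bounds. The shipped defaults use the published Align-GVGD prior
#' conventions for BRCA2; the table is configuration, not a fixed constant,
#' because priors are maintained in external curation databases.
#'
#' @param path Path to a YAML file; defaults to the configuration shipped
#'   with the package.
#' @return A list with elements `priors` (a list with `align_gvgd_grade` and
#'   `variant_type` maps) and `exclusion_window` (length-2 numeric).
#' @export
load_config <- function(path = system.file("extdata", "config.yaml",
                                           package = "sgecurate")) {
  cfg <- yaml::read_yaml(path)
  stopifnot(is.list(cfg$priors), length(cfg$exclusion_window) == 2L)
  cfg$exclusion_window <- as.numeric(cfg$exclusion_window)
  cfg
}

#' Look up a prior probability of pathogenicity
#'
#' An Align-GVGD grade takes precedence; the variant type (nonsense,
#' synonymous, intronic, ...) is the fallback for variants without a grade.
#'
#' @param gvgd_grade Align-GVGD grade token (e.g. `"C0"`, `"C65"`) or `NA`.
#' @param variant_type Variant-type token (e.g. `"synonymous"`) or `NA`.
#' @param config Configuration list from [load_config()].
#' @return Prior probability, or `NA` when neither key resolves.
#' @export
lookup_prior <- function(gvgd_grade = NA, variant_type = NA,
                         config = load_config()) {
  pick <- function(map, key) {
    if (is.na(key) || !nzchar(key)) return(NA_real_)
    val <- map[[as.character(key)]]
    if (is.null(val)) NA_real_ else as.numeric(val)
  }
  p <- pick(config$priors$align_gvgd_grade, gvgd_grade)
  if (is.na(p)) p <- pick(config$priors$variant_type, variant_type)
  if (!is.na(p) && (p < 0 || p > 1)) {
    stop("configured prior out of [0, 1]: ", p, call. = FALSE)
  }
  p
}
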