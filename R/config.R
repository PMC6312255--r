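#' Analysis configuration
#'
#' Collects the tunable settings of the pipeline with their defaults.
#' Any subset can be overridden by name; unknown names are an error.
#'
#' @param fdr_level Storey q-value threshold used to select differential
#'   proteins (default 0.05).
#' @param posthoc_alpha significance level of the Dunnett many-to-one
#'   post-hoc comparisons (default 0.05).
#' @param min_total_counts transcripts with a total mapped count below this
#'   value are discarded before differential expression (default 15).
#' @param storey_lambda fixed lambda of the Storey pi0 estimator
#'   (default 0.5).
#' @param dose_boundaries the two dose-group boundaries in mGy
#'   (default c(100, 500)); doses equal to a boundary fall in the medium
#'   group, matching the interval notation control / <100 / 100-500 / >500.
#' @param coef_alpha significance level applied to coefficients of the
#'   final stepwise model when classifying dose/age dependency
#'   (default 0.05).
#' @param enrich_alpha BH-adjusted significance threshold for gene-set
#'   over-representation (default 0.05).
#' @param integration_protein_test which proteomics p-value feeds Fisher's
#'   combination: \code{"mann-whitney"} (dedicated two-group rank test of
#'   high vs control, the default) or \code{"dunnett"} (the high-group
#'   adjusted p from the post-hoc stage).
#' @param remove_outliers drop Dixon-flagged values instead of merely
#'   reporting them (default FALSE).
#' @param dixon_alpha level of the Dixon outlier screen, one of
#'   0.01, 0.05, 0.10 (default 0.05).
#' @param seed integer seed used by stochastic stages (Dunnett integration,
#'   simulation); per-stage child seeds are derived from it.
#' @return A named list of settings with class \code{"radConfig"}.
#' @examples
#' cfg <- radConfig(fdr_level = 0.1)
#' cfg$fdr_level
#' @export
radConfig <- function(fdr_level = 0.05, posthoc_alpha = 0.05,
                      min_total_counts = 15, storey_lambda = 0.5,
                      dose_boundaries = c(100, 500), coef_alpha = 0.05,
                      enrich_alpha = 0.05,
                      integration_protein_test = c("mann-whitney", "dunnett"),
                      remove_outliers = FALSE, dixon_alpha = 0.05,
                      seed = 1L) {
    stopifnot(fdr_level > 0, fdr_level < 1,
              posthoc_alpha > 0, posthoc_alpha < 1,
              min_total_counts >= 0,
              storey_lambda > 0, storey_lambda < 1,
              length(dose_boundaries) == 2L,
              dose_boundaries[1L] < dose_boundaries[2L],
              dose_boundaries[1L] > 0)
    integration_protein_test <- match.arg(integration_protein_test)
    structure(list(
        fdr_level = fdr_level,
        posthoc_alpha = posthoc_alpha,
        min_total_counts = min_total_counts,
        storey_lambda = storey_lambda,
        dose_boundaries = as.numeric(dose_boundaries),
        coef_alpha = coef_alpha,
        enrich_alpha = enrich_alpha,
        integration_protein_test = integration_protein_test,
        remove_outliers = isTRUE(remove_outliers),
        dixon_alpha = dixon_alpha,
        seed = as.integer(seed)), class = "radConfig")
}

#' Read a configuration from a YAML file
#'
#' Fields absent from the file keep their \code{\link{radConfig}} defaults.
#'
#' @param path path to a YAML file whose top-level keys are radConfig
#'   argument names.
#' @return A \code{radConfig} list.
#' @export
readConfig <- function(path) {
    vals <- yaml::read_yaml(path)
    known <- names(formals(radConfig))
    unknown <- setdiff(names(vals), known)
    if (length(unknown))
        stop("unknown config field(s): ", paste(unknown, collapse = ", "))
    do.call(radConfig, vals)
}
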