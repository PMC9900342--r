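#' Default run configuration
#'
#' Every numeric threshold used anywhere in the pipeline, with defaults equal
#' to the published analysis parameters: Cutadapt-style trimming (`-m 25 -q
#' 20`, reads of length <= 24 discarded), ncRNA decontamination (identity 80,
#' mismatches <= 1, query coverage >= 90), zero-mismatch reference matching,
#' genome alignment cap of 100 placements, full-containment (`-f 1`) cluster
#' intersection, differential-expression thresholds (adjusted p <= 0.05,
#' |log2FC| >= 1), a +/-200 nt 5'-5' distance window with LOWESS span 0.1, the
#' 3-scaled-MAD outlier rule with a minimum of 4 retained samples, and ANOVA
#' alpha 0.05.
#'
#' @return Named list of configuration values.
#' @export
default_config <- function() {
  list(
    seed              = 1L,
    # preprocess
    adapter           = "TGGAATTCTCGGGTGCCAAGG",
    min_quality       = 20L,
    min_length        = 25L,
    adapter_error_rate = 0.10,
    adapter_min_overlap = 3L,
    # ncRNA decontamination / target matching
    min_identity      = 80,
    max_mismatches    = 1L,
    min_query_coverage = 90,
    max_hits_reported = 1L,
    orientations      = c("sense", "antisense"),
    # discovery
    alignment_cap     = 100L,
    intersect_fraction = 1.0,
    # characterization
    distance_window   = 200L,
    lowess_span       = 0.1,
    # expression
    padj_threshold    = 0.05,
    lfc_threshold     = 1,
    mad_multiplier    = 3,
    mad_min_values    = 4L,
    anova_alpha       = 0.05,
    # output
    outdir            = "pirnakit_out",
    simulate          = TRUE
  )
}

#' Read a JSON run configuration
#'
#' Unknown keys are rejected; values present in the file override the
#' defaults from [default_config()].
#'
#' @param path Path to a JSON configuration file.
#' @return Named list of configuration values.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  user <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  defaults <- default_config()
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stopf("unknown configuration key(s): %s", paste(unknown, collapse = ", "))
  utils::modifyList(defaults, user)
}

#' Write a run configuration to JSON
#'
#' @param config Named configuration list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
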