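#' Filtering policy for IP-MS identification evidence
#'
#' Bundles every tunable threshold of the candidate-filtering cascade:
#' per-experiment identification thresholds, the number of supporting
#' experiments required per species, and the name patterns used for
#' contaminant and "sticky"-category removal.
#'
#' The defaults encode the conventional acceptance rule for spectral-count
#' AP-MS screens: a protein is identified in an experiment only with at
#' least three spectral counts, for human data additionally from at least
#' two unique peptides, and must be identified in at least two human
#' experiments or one fly experiment. Contaminant patterns cover the
#' classic sample-handling contaminants (keratins, dermcidin, caseins,
#' trypsin, serum albumin); sticky patterns cover prey categories that bind
#' nonspecifically in pull-downs (ribosomal proteins, heat-shock proteins,
#' actin, tubulin).
#'
#' Pattern matching is case-insensitive fixed-substring matching on the
#' protein description. `sticky_exempt_patterns` rescues descriptions that
#' contain a category word without belonging to the category; the default
#' keeps co-chaperones such as "Activator of 90 kDa heat shock protein
#' ATPase homolog 1", which mention "heat shock" but are not heat-shock
#' proteins themselves.
#'
#' @param min_counts_per_experiment Minimum spectral counts a protein needs
#'   in a single experiment to count as identified there (default 3).
#' @param min_unique_peptides Minimum unique peptides per supporting
#'   experiment; applied to human evidence (default 2).
#' @param min_supporting_experiments_human Number of human
#'   experiment-condition units that must individually support a protein
#'   (default 2).
#' @param min_supporting_experiments_fly Same for fly (default 1).
#' @param contaminant_accessions Character vector of accessions removed
#'   outright.
#' @param contaminant_name_patterns Case-insensitive substrings flagging
#'   contaminant descriptions.
#' @param sticky_name_patterns Case-insensitive substrings flagging sticky
#'   prey categories.
#' @param sticky_exempt_patterns Substrings that exempt a description from
#'   sticky removal even if a sticky pattern matches.
#' @return A list of class `filter_policy`.
#' @examples
#' pol <- filter_policy()
#' pol$min_counts_per_experiment
#' @export
filter_policy <- function(min_counts_per_experiment = 3,
                          min_unique_peptides = 2,
                          min_supporting_experiments_human = 2,
                          min_supporting_experiments_fly = 1,
                          contaminant_accessions = character(),
                          contaminant_name_patterns = c(
                            "keratin", "dermcidin", "dermicidin",
                            "casein", "trypsin", "serum albumin"
                          ),
                          sticky_name_patterns = c(
                            "ribosomal protein", "heat shock",
                            "actin", "tubulin"
                          ),
                          sticky_exempt_patterns = c(
                            "heat shock protein ATPase"
                          )) {
  pol <- list(
    min_counts_per_experiment =
      check_count_int(min_counts_per_experiment, "min_counts_per_experiment"),
    min_unique_peptides =
      check_count_int(min_unique_peptides, "min_unique_peptides"),
    min_supporting_experiments_human =
      check_count_int(min_supporting_experiments_human,
                      "min_supporting_experiments_human"),
    min_supporting_experiments_fly =
      check_count_int(min_supporting_experiments_fly,
                      "min_supporting_experiments_fly"),
    contaminant_accessions = as.character(contaminant_accessions %||% character()),
    contaminant_name_patterns = as.character(contaminant_name_patterns %||% character()),
    sticky_name_patterns = as.character(sticky_name_patterns %||% character()),
    sticky_exempt_patterns = as.character(sticky_exempt_patterns %||% character())
  )
  structure(pol, class = c("filter_policy", "list"))
}

#' Orthology-mapping policy
#'
#' Controls the reciprocal best-k-hits mapping: the E-value cutoff applied
#' to every sequence-search hit, how many top hits per query are considered
#' reciprocal candidates, and the deterministic tie-break order among hits.
#'
#' @param evalue_cutoff Hits with E-value at or above this are discarded
#'   (default 1e-60, the conventional stringency for calling cross-phylum
#'   protein orthologs by sequence alone).
#' @param top_k Reciprocal window: (a, b) is a candidate pair when each is
#'   within the other's `top_k` best hits (default 3, admitting close
#'   paralogs/splice variants such as the p55/p85 regulatory subunits).
#' @param tie_breaker Comparator among hits of one query; only
#'   `"evalue_bitscore_subject"` is defined: ascending E-value, then
#'   descending bitscore, then lexicographic subject accession.
#' @return A list of class `orthology_policy`.
#' @export
orthology_policy <- function(evalue_cutoff = 1e-60,
                             top_k = 3,
                             tie_breaker = "evalue_bitscore_subject") {
  if (!is.numeric(evalue_cutoff) || length(evalue_cutoff) != 1 ||
      is.na(evalue_cutoff) || evalue_cutoff <= 0) {
    validation_error("evalue_cutoff must be a single positive number")
  }
  top_k <- check_count_int(top_k, "top_k")
  if (top_k < 1) validation_error("top_k must be >= 1")
  tie_breaker <- match.arg(tie_breaker, "evalue_bitscore_subject")
  structure(
    list(
      evalue_cutoff = as.numeric(evalue_cutoff),
      top_k = top_k,
      tie_breaker = tie_breaker
    ),
    class = c("orthology_policy", "list")
  )
}

#' Quantification and network policy
#'
#' Parameters for replicate-averaged spectral-count quantification and
#' network export: the pseudocount protecting ratios against zero means,
#' the minimum average spectral count an edge must reach, and the mapping
#' from condition labels to edge colors (black/green/orange for 0, 10 and
#' 30 minutes of insulin stimulation).
#'
#' @param pseudocount Added to both numerator and denominator means in
#'   fold-change and preference ratios; must be > 0 (default 1).
#' @param min_average_counts Minimum replicate-averaged spectral count for
#'   a bait-prey edge to be reported (default 3).
#' @param log_base Base of the logarithm used for subunit-preference
#'   scores (default 2).
#' @param condition_colors Named character vector mapping condition labels
#'   to edge colors.
#' @return A list of class `quant_policy`.
#' @export
quant_policy <- function(pseudocount = 1.0,
                         min_average_counts = 3.0,
                         log_base = 2,
                         condition_colors = c(
                           basal = "black",
                           insulin_10 = "green",
                           insulin_30 = "orange"
                         )) {
  if (!is.numeric(pseudocount) || length(pseudocount) != 1 ||
      is.na(pseudocount) || pseudocount <= 0) {
    validation_error("pseudocount must be a single positive number")
  }
  if (!is.numeric(min_average_counts) || length(min_average_counts) != 1 ||
      is.na(min_average_counts) || min_average_counts < 0) {
    validation_error("min_average_counts must be >= 0")
  }
  structure(
    list(
      pseudocount = as.numeric(pseudocount),
      min_average_counts = as.numeric(min_average_counts),
      log_base = as.numeric(log_base),
      condition_colors = condition_colors
    ),
    class = c("quant_policy", "list")
  )
}

#' Read a policy configuration file
#'
#' Loads a flat YAML document and builds the corresponding policy objects.
#' Recognised top-level sections are `filter`, `orthology` and `quant`;
#' each may set any argument of [filter_policy()], [orthology_policy()] or
#' [quant_policy()]. Missing sections fall back to defaults.
#'
#' @param path Path to a YAML file.
#' @return A list with elements `filter`, `orthology`, `quant`.
#' @export
read_policy_file <- function(path) {
  if (!file.exists(path)) format_error(sprintf("file does not exist: %s", path))
  raw <- yaml::read_yaml(path)
  build <- function(ctor, section) {
    args <- raw[[section]] %||% list()
    if (section == "quant" && !is.null(args$condition_colors)) {
      args$condition_colors <- unlist(args$condition_colors)
    }
    do.call(ctor, args)
  }
  list(
    filter = build(filter_policy, "filter"),
    orthology = build(orthology_policy, "orthology"),
    quant = build(quant_policy, "quant")
  )
}
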