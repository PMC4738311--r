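#' Conserved-interactor (interolog) calling
#'
#' Overlaps the two species' accepted interactor sets through the ortholog
#' map: a conserved-interactor record is emitted for every ortholog pair
#' whose fly accession passed the fly filtering cascade and whose human
#' accession passed the human cascade. Each record carries the supporting
#' experiments — the runs in which the accession individually met the
#' per-experiment identification thresholds.
#'
#' Many-to-many ortholog pairs each yield their own record; use
#' [collapse_by_human()] for a one-row-per-human-protein view.
#'
#' @param accepted_fly,accepted_human Accepted accession vectors from
#'   [filter_cascade()] / [apply_identification_policy()].
#' @param pairs Ortholog pair tibble ([merge_orthology()]).
#' @param evidence Evidence tibble (post contaminant/control subtraction).
#' @param experiments Experiments tibble.
#' @param policy The [filter_policy()] defining per-experiment support.
#' @return A tibble sorted by human then fly accession with columns
#'   `fly_accession`, `human_accession`, `source`,
#'   `supporting_fly_experiments`, `supporting_human_experiments`
#'   (list-columns of experiment ids) and the corresponding
#'   `n_fly_experiments`, `n_human_experiments`.
#' @export
compute_interlogs <- function(accepted_fly, accepted_human, pairs,
                              evidence, experiments,
                              policy = filter_policy()) {
  empty <- tibble(
    fly_accession = character(), human_accession = character(),
    source = character(),
    supporting_fly_experiments = list(),
    supporting_human_experiments = list(),
    n_fly_experiments = integer(), n_human_experiments = integer()
  )
  if (is.null(pairs) || nrow(pairs) == 0) return(empty)
  hit <- pairs$fly_accession %in% accepted_fly &
    pairs$human_accession %in% accepted_human
  pairs <- pairs[hit, , drop = FALSE]
  if (nrow(pairs) == 0) return(empty)

  sup <- supporting_runs(evidence, experiments, policy)
  support_of <- function(acc, sp) {
    sort(unique(sup$experiment_id[sup$accession == acc & sup$species == sp]))
  }
  fly_sup <- lapply(pairs$fly_accession, support_of, sp = "fly")
  hum_sup <- lapply(pairs$human_accession, support_of, sp = "human")
  out <- tibble(
    fly_accession = pairs$fly_accession,
    human_accession = pairs$human_accession,
    source = pairs$source,
    supporting_fly_experiments = fly_sup,
    supporting_human_experiments = hum_sup,
    n_fly_experiments = lengths(fly_sup),
    n_human_experiments = lengths(hum_sup)
  )
  out[order(out$human_accession, out$fly_accession), ]
}

#' Collapse conserved-interactor records by human protein
#'
#' Reduces a many-to-many conserved-interactor table to one row per human
#' accession, concatenating the fly accessions that map to it and pooling
#' their supporting experiments.
#'
#' @param records Output of [compute_interlogs()].
#' @return A tibble with one row per `human_accession`.
#' @export
collapse_by_human <- function(records) {
  if (nrow(records) == 0) {
    return(tibble(
      human_accession = character(), fly_accessions = character(),
      n_fly_experiments = integer(), n_human_experiments = integer()
    ))
  }
  records |>
    dplyr::group_by(.data$human_accession) |>
    dplyr::summarise(
      fly_accessions = paste(sort(unique(.data$fly_accession)),
                             collapse = ";"),
      n_fly_experiments =
        length(unique(unlist(.data$supporting_fly_experiments))),
      n_human_experiments =
        length(unique(unlist(.data$supporting_human_experiments))),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$human_accession)
}

#' Write / read the conserved-interactor table
#'
#' Serialises conserved-interactor records as a TSV with one row per
#' ortholog pair; supporting-experiment lists are joined with `;`.
#' `read_conserved_table()` inverts the serialisation, so write-then-read
#' is the identity.
#'
#' @param records Output of [compute_interlogs()].
#' @param path TSV path.
#' @return `path` invisibly (write); a records tibble (read).
#' @export
write_conserved_table <- function(records, path) {
  flat <- tibble(
    fly_accession = records$fly_accession,
    human_accession = records$human_accession,
    source = records$source,
    n_fly_experiments = as.integer(records$n_fly_experiments),
    n_human_experiments = as.integer(records$n_human_experiments),
    supporting_fly_experiments =
      vapply(records$supporting_fly_experiments, paste,
             character(1), collapse = ";"),
    supporting_human_experiments =
      vapply(records$supporting_human_experiments, paste,
             character(1), collapse = ";")
  )
  write_tsv_plain(flat, path)
}

#' @rdname write_conserved_table
#' @export
read_conserved_table <- function(path) {
  flat <- read_tsv_strict(path, c(
    "fly_accession", "human_accession", "source",
    "n_fly_experiments", "n_human_experiments",
    "supporting_fly_experiments", "supporting_human_experiments"
  ))
  split_ids <- function(x) {
    lapply(as.character(x), function(s) {
      if (is.na(s) || s == "") character() else strsplit(s, ";", fixed = TRUE)[[1]]
    })
  }
  tibble(
    fly_accession = as.character(flat$fly_accession),
    human_accession = as.character(flat$human_accession),
    source = as.character(flat$source),
    supporting_fly_experiments = split_ids(flat$supporting_fly_experiments),
    supporting_human_experiments = split_ids(flat$supporting_human_experiments),
    n_fly_experiments = as.integer(flat$n_fly_experiments),
    n_human_experiments = as.integer(flat$n_human_experiments)
  )
}

#' Reference list of conserved PI3K-interacting protein pairs
#'
#' Loads the packaged reference table of 49 fly-human ortholog pairs found
#' to interact with PI3K in both Drosophila and human cells by
#' cross-species IP-MS — the canonical conserved-interactor set this
#' pipeline reproduces the shape of. Columns give the fly (FlyBase
#' polypeptide) accession, any additional isoform count reported with it,
#' both molecular weights, the human protein name and the human accession
#' token as published (dual tokens such as `P55G/P85A` for the bait's two
#' regulatory-subunit variants are kept verbatim).
#'
#' @return A tibble with one row per conserved fly-human pair.
#' @examples
#' nrow(conserved_reference_pairs())
#' @export
conserved_reference_pairs <- function() {
  path <- system.file("extdata", "pi3k_conserved_pairs.tsv",
                      package = "interologr", mustWork = TRUE)
  read_tsv_strict(path, c(
    "fly_accession", "fly_extra_isoforms", "fly_mw_kda",
    "human_protein_name", "human_accession", "human_mw_kda"
  ))
}
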