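#' Read IP-MS identification evidence and experiment design tables
#'
#' Loads a protein-report export (one row per protein per experiment, with
#' unique-peptide and spectral-count evidence) together with the
#' experiment design table describing each immunoprecipitation run
#' (species, bait, condition, replicate, control flag).
#'
#' Both files are tab-separated UTF-8 with a header row. Evidence rows
#' that reference an experiment absent from the design table are dropped
#' with a warning. Structural problems (missing columns) raise a format
#' error; value problems (negative counts, spectral counts below unique
#' peptides, duplicated experiment/accession keys) raise a validation
#' error naming the offending row.
#'
#' @param path Path to the evidence TSV with columns `experiment_id`,
#'   `accession`, `unique_peptides`, `spectral_counts`, `description`.
#' @param experiment_table Path to the design TSV with columns
#'   `experiment_id`, `species`, `bait`, `condition`, `replicate`,
#'   `is_control`.
#' @return A list with tibbles `experiments` and `evidence`.
#' @seealso [write_evidence()] for the inverse operation.
#' @export
read_evidence <- function(path, experiment_table) {
  experiments <- read_experiment_table(experiment_table)
  ev <- read_tsv_strict(path, c(
    "experiment_id", "accession", "unique_peptides",
    "spectral_counts", "description"
  ))
  ev <- as_tibble(ev)
  ev$experiment_id <- as.character(ev$experiment_id)
  ev$accession <- as.character(ev$accession)
  ev$description <- as.character(ev$description)
  ev$description[is.na(ev$description)] <- ""
  for (col in c("unique_peptides", "spectral_counts")) {
    ev[[col]] <- suppressWarnings(as.numeric(ev[[col]]))
  }
  validate_evidence(ev)
  ev$unique_peptides <- as.integer(ev$unique_peptides)
  ev$spectral_counts <- as.integer(ev$spectral_counts)
  unknown <- !(ev$experiment_id %in% experiments$experiment_id)
  if (any(unknown)) {
    warn(sprintf(
      "dropping %d evidence row(s) referencing unknown experiment_id(s): %s",
      sum(unknown),
      paste(unique(ev$experiment_id[unknown]), collapse = ", ")
    ))
    ev <- ev[!unknown, , drop = FALSE]
  }
  list(experiments = experiments, evidence = ev)
}

read_experiment_table <- function(path) {
  ex <- read_tsv_strict(path, c(
    "experiment_id", "species", "bait", "condition", "replicate", "is_control"
  ))
  ex <- as_tibble(ex)
  ex$experiment_id <- as.character(ex$experiment_id)
  ex$species <- as.character(ex$species)
  ex$bait <- as.character(ex$bait)
  ex$condition <- as.character(ex$condition)
  ex$is_control <- as.logical(ex$is_control)
  validate_experiments(ex)
  ex
}

validate_experiments <- function(ex) {
  if (anyDuplicated(ex$experiment_id)) {
    validation_error(sprintf(
      "duplicated experiment_id: %s",
      paste(unique(ex$experiment_id[duplicated(ex$experiment_id)]),
            collapse = ", ")
    ))
  }
  bad_sp <- !(ex$species %in% c("fly", "human"))
  if (any(bad_sp)) {
    validation_error(sprintf(
      "species must be 'fly' or 'human'; offending row(s): %s",
      paste(which(bad_sp), collapse = ", ")
    ))
  }
  bad_rep <- !is.finite(ex$replicate) | ex$replicate < 1 |
    ex$replicate != floor(ex$replicate)
  if (any(bad_rep)) {
    validation_error(sprintf(
      "replicate must be a positive integer; offending row(s): %s",
      paste(which(bad_rep), collapse = ", ")
    ))
  }
  bad_ctl <- ex$is_control & ex$bait != "control"
  if (any(bad_ctl)) {
    validation_error(sprintf(
      "control experiments must have bait 'control'; offending row(s): %s",
      paste(which(bad_ctl), collapse = ", ")
    ))
  }
  invisible(ex)
}

validate_evidence <- function(ev) {
  for (col in c("unique_peptides", "spectral_counts")) {
    bad <- !is.finite(ev[[col]]) | ev[[col]] < 0 | ev[[col]] != floor(ev[[col]])
    if (any(bad)) {
      validation_error(sprintf(
        "%s must be a non-negative integer; offending row(s): %s",
        col, paste(which(bad), collapse = ", ")
      ))
    }
  }
  incoherent <- ev$unique_peptides > 0 & ev$spectral_counts < ev$unique_peptides
  if (any(incoherent)) {
    validation_error(sprintf(
      "spectral_counts below unique_peptides; offending row(s): %s",
      paste(which(incoherent), collapse = ", ")
    ))
  }
  key <- paste(ev$experiment_id, ev$accession, sep = "\r")
  if (anyDuplicated(key)) {
    validation_error(sprintf(
      "duplicated (experiment_id, accession); offending row(s): %s",
      paste(which(duplicated(key)), collapse = ", ")
    ))
  }
  invisible(ev)
}

#' Write evidence and experiment design tables
#'
#' Serialises the tibbles produced by [read_evidence()] (or by
#' [simulate_ipms()]) back to the tab-separated dialect, so that
#' write-then-read is the identity up to row order.
#'
#' @param evidence Evidence tibble.
#' @param path Output path for the evidence TSV.
#' @param experiments Optional experiments tibble.
#' @param experiment_path Output path for the design TSV (required when
#'   `experiments` is given).
#' @return `path`, invisibly.
#' @export
write_evidence <- function(evidence, path,
                           experiments = NULL, experiment_path = NULL) {
  cols <- c("experiment_id", "accession", "unique_peptides",
            "spectral_counts", "description")
  write_tsv_plain(evidence[, cols], path)
  if (!is.null(experiments)) {
    if (is.null(experiment_path)) {
      validation_error("experiment_path is required when experiments is given")
    }
    ecols <- c("experiment_id", "species", "bait", "condition",
               "replicate", "is_control")
    write_tsv_plain(experiments[, ecols], experiment_path)
  }
  invisible(path)
}

#' Remove common contaminant proteins
#'
#' Drops every evidence record whose accession is on the policy's
#' contaminant blocklist or whose description matches a contaminant name
#' pattern (case-insensitive substring; defaults cover keratins,
#' dermcidin, caseins, trypsin and serum albumin). All other records pass
#' through unchanged.
#'
#' @param evidence Evidence tibble.
#' @param policy A [filter_policy()].
#' @return The surviving evidence tibble, with the removed records
#'   attached as attribute `"removed"`.
#' @export
remove_contaminants <- function(evidence, policy = filter_policy()) {
  hit <- evidence$accession %in% policy$contaminant_accessions |
    matches_any_pattern(evidence$description, policy$contaminant_name_patterns)
  out <- evidence[!hit, , drop = FALSE]
  attr(out, "removed") <- evidence[hit, , drop = FALSE]
  out
}

#' Subtract control-IP observations
#'
#' Removes, per species, every accession observed (at least one spectral
#' count) in any control immunoprecipitation (empty-TAP or IgG) from all
#' non-control evidence of that species, and drops the control
#' experiments' own records from the output. The operation is a pure set
#' subtraction and therefore idempotent.
#'
#' `mode = "accession"` (default) subtracts exact accessions;
#' `mode = "description"` additionally removes records whose description
#' equals a description observed in a control of the same species, for
#' screens where control and sample searches used different database
#' versions.
#'
#' @param evidence Evidence tibble.
#' @param experiments Experiments tibble.
#' @param mode Subtraction mode, `"accession"` or `"description"`.
#' @return The surviving non-control evidence tibble.
#' @export
subtract_controls <- function(evidence, experiments,
                              mode = c("accession", "description")) {
  mode <- match.arg(mode)
  ex <- experiments[, c("experiment_id", "species", "is_control")]
  ev <- dplyr::left_join(evidence, ex, by = "experiment_id")
  ctl <- ev[ev$is_control %in% TRUE & ev$spectral_counts >= 1, , drop = FALSE]
  keep <- !(ev$is_control %in% TRUE)
  for (sp in unique(ctl$species)) {
    seen_acc <- unique(ctl$accession[ctl$species == sp])
    drop <- ev$species %in% sp & ev$accession %in% seen_acc
    if (mode == "description") {
      seen_desc <- unique(ctl$description[ctl$species == sp])
      seen_desc <- seen_desc[seen_desc != ""]
      drop <- drop | (ev$species %in% sp & ev$description %in% seen_desc)
    }
    keep <- keep & !drop
  }
  out <- ev[keep, , drop = FALSE]
  out$species <- NULL
  out$is_control <- NULL
  out
}

# species-specific per-run identification test; human additionally needs
# the unique-peptide minimum
run_meets_threshold <- function(counts, peptides, species, policy) {
  ok <- counts >= policy$min_counts_per_experiment
  ok & ifelse(species == "human", peptides >= policy$min_unique_peptides, TRUE)
}

# evidence rows (joined with experiment metadata) that individually pass
# the per-run identification thresholds; control runs excluded
supporting_runs <- function(evidence, experiments, policy = filter_policy()) {
  ex <- experiments[, c("experiment_id", "species", "bait", "condition",
                        "is_control")]
  ev <- dplyr::inner_join(evidence, ex, by = "experiment_id")
  ev <- ev[!(ev$is_control %in% TRUE), , drop = FALSE]
  ok <- run_meets_threshold(ev$spectral_counts, ev$unique_peptides,
                            ev$species, policy)
  ev[ok, , drop = FALSE]
}

#' Apply the per-species identification policy
#'
#' A human accession is accepted when it is identified — at least
#' `min_counts_per_experiment` spectral counts from at least
#' `min_unique_peptides` unique peptides in a single run — in at least
#' `min_supporting_experiments_human` distinct experiment-condition units.
#' A fly accession is accepted when it reaches the spectral-count minimum
#' in at least `min_supporting_experiments_fly` units. An
#' experiment-condition unit is a (species, bait, condition) combination;
#' replicate runs of the same unit count once, through their best run.
#'
#' @param evidence Evidence tibble (normally already contaminant- and
#'   control-subtracted; the order is documented, not enforced).
#' @param experiments Experiments tibble.
#' @param policy A [filter_policy()].
#' @return A list with sorted character vectors `fly` and `human` of
#'   accepted accessions.
#' @export
apply_identification_policy <- function(evidence, experiments,
                                        policy = filter_policy()) {
  out <- list(fly = character(), human = character())
  non_ctl <- experiments[!(experiments$is_control %in% TRUE), , drop = FALSE]
  sup <- supporting_runs(evidence, experiments, policy)
  for (sp in c("fly", "human")) {
    need <- if (sp == "human") {
      policy$min_supporting_experiments_human
    } else {
      policy$min_supporting_experiments_fly
    }
    if (!any(non_ctl$species == sp)) {
      if (nrow(evidence) > 0) {
        inform(sprintf("no non-control %s experiments; %s accepted set is empty",
                       sp, sp))
      }
      next
    }
    s <- sup[sup$species == sp, , drop = FALSE]
    if (nrow(s) == 0) next
    units <- dplyr::distinct(s[, c("accession", "bait", "condition")])
    tallies <- dplyr::count(units, .data$accession, name = "n_units")
    out[[sp]] <- sort(tallies$accession[tallies$n_units >= need])
  }
  out
}

#' Remove sticky prey categories from an accepted set
#'
#' Drops accessions whose description (looked up in the evidence table)
#' matches a sticky-category name pattern — ribosomal proteins, heat-shock
#' proteins, actin, tubulin by default — unless an exemption pattern also
#' matches. These categories bind nonspecifically in pull-downs and are
#' excluded from core-complex analysis.
#'
#' @param accepted Character vector of accepted accessions.
#' @param evidence Evidence tibble supplying descriptions.
#' @param policy A [filter_policy()].
#' @return The surviving accession vector, sorted.
#' @export
remove_sticky <- function(accepted, evidence, policy = filter_policy()) {
  if (length(accepted) == 0) return(character())
  desc <- evidence$description[match(accepted, evidence$accession)]
  desc[is.na(desc)] <- ""
  sticky <- matches_any_pattern(desc, policy$sticky_name_patterns) &
    !matches_any_pattern(desc, policy$sticky_exempt_patterns)
  sort(accepted[!sticky])
}

#' Run the full evidence-filtering cascade
#'
#' Applies, in order: contaminant removal, control-IP subtraction, the
#' per-species identification policy, and sticky-category removal —
#' recording candidate counts at every checkpoint and the reason each
#' accession was removed. Contaminant and control subtraction are both
#' pure set subtractions, so their relative order does not change the
#' final sets.
#'
#' @param evidence Evidence tibble.
#' @param experiments Experiments tibble.
#' @param policy A [filter_policy()].
#' @param control_mode Passed to [subtract_controls()].
#' @return A list with
#'   * `accepted`: list of sorted accession vectors `fly`, `human`
#'     (post-sticky);
#'   * `candidates`: the same sets before sticky removal;
#'   * `checkpoints`: tibble of per-species accession counts at each step;
#'   * `removals`: tibble (`species`, `accession`, `step`, `reason`)
#'     auditing every removed accession;
#'   * `evidence`: the contaminant- and control-subtracted evidence.
#' @export
filter_cascade <- function(evidence, experiments, policy = filter_policy(),
                           control_mode = "accession") {
  species_of <- function(ev) {
    ex <- experiments[, c("experiment_id", "species")]
    j <- dplyr::left_join(ev, ex, by = "experiment_id")
    dplyr::distinct(j[, c("species", "accession")])
  }
  count_by_species <- function(acc_tab) {
    vapply(c("fly", "human"),
           function(sp) sum(acc_tab$species == sp, na.rm = TRUE),
           integer(1))
  }
  removals <- list()
  note_removed <- function(before_tab, after_tab, step, reason) {
    gone <- dplyr::anti_join(before_tab, after_tab,
                             by = c("species", "accession"))
    if (nrow(gone) > 0) {
      gone$step <- step
      gone$reason <- reason
      removals[[length(removals) + 1]] <<- gone
    }
  }

  chk <- list()
  tab0 <- species_of(evidence)
  chk$input <- count_by_species(tab0)

  ev1 <- remove_contaminants(evidence, policy)
  tab1 <- species_of(ev1)
  chk$post_contaminant <- count_by_species(tab1)
  note_removed(tab0, tab1, "contaminant", "contaminant accession/pattern")

  ev2 <- subtract_controls(ev1, experiments, mode = control_mode)
  tab2 <- species_of(ev2)
  chk$post_control <- count_by_species(tab2)
  note_removed(tab1, tab2, "control", "observed in control IP")

  accepted <- apply_identification_policy(ev2, experiments, policy)
  tab3 <- tibble(
    species = rep(c("fly", "human"),
                  c(length(accepted$fly), length(accepted$human))),
    accession = c(accepted$fly, accepted$human)
  )
  chk$post_policy <- count_by_species(tab3)
  note_removed(tab2, tab3, "identification_policy",
               "below identification thresholds")

  final <- list(
    fly = remove_sticky(accepted$fly, ev2, policy),
    human = remove_sticky(accepted$human, ev2, policy)
  )
  tab4 <- tibble(
    species = rep(c("fly", "human"),
                  c(length(final$fly), length(final$human))),
    accession = c(final$fly, final$human)
  )
  chk$post_sticky <- count_by_species(tab4)
  note_removed(tab3, tab4, "sticky", "sticky prey category")

  checkpoints <- tibble(
    step = rep(names(chk), each = 2),
    species = rep(c("fly", "human"), times = length(chk)),
    n_accessions = as.integer(unlist(chk, use.names = FALSE))
  )
  removals <- if (length(removals)) dplyr::bind_rows(removals) else
    tibble(species = character(), accession = character(),
           step = character(), reason = character())

  list(
    accepted = final,
    candidates = accepted,
    checkpoints = checkpoints,
    removals = removals[, c("species", "accession", "step", "reason")],
    evidence = ev2
  )
}
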