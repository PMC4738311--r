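#' Pipeline configuration
#'
#' Bundles the file layout and the stage policies of a full run. All
#' artifacts live under `dir`; input paths can be overridden to point at
#' real data (evidence/design tables, proteome FASTAs, a curated ortholog
#' pair table, or a precomputed 12-column hit table that bypasses the
#' internal aligner).
#'
#' @param dir Working directory for all pipeline artifacts.
#' @param seed Integer seed forwarded to the simulation stage.
#' @param filter,orthology,quant Policy objects (defaults used if `NULL`).
#' @param simulation A [simulation_config()]; defaults to
#'   `simulation_config(seed = seed)`.
#' @param curated_orthology Optional path to a curated two-column ortholog
#'   pair TSV.
#' @param blast_tabular Optional named list with paths `fly_to_human` and
#'   `human_to_fly` of precomputed tabular hit files; when given, the
#'   orthology stage skips the internal aligner.
#' @param network_species Species whose averaged counts feed the network
#'   export (default `"fly"`, the insulin time-course arm whose condition
#'   labels carry the edge-color map).
#' @param log_level `"info"` (stage messages) or `"quiet"`.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(dir,
                            seed = 1,
                            filter = NULL,
                            orthology = NULL,
                            quant = NULL,
                            simulation = NULL,
                            curated_orthology = NULL,
                            blast_tabular = NULL,
                            network_species = "fly",
                            log_level = c("info", "quiet")) {
  log_level <- match.arg(log_level)
  seed <- check_count_int(seed, "seed")
  cfg <- list(
    dir = dir,
    seed = seed,
    filter = filter %||% filter_policy(),
    orthology = orthology %||% orthology_policy(),
    quant = quant %||% quant_policy(),
    simulation = simulation %||% simulation_config(seed = seed),
    curated_orthology = curated_orthology,
    blast_tabular = blast_tabular,
    network_species = network_species,
    log_level = log_level
  )
  cfg$paths <- lapply(list(
    proteome_fly = "proteome_fly.fasta",
    proteome_human = "proteome_human.fasta",
    truth = "truth.tsv",
    experiments = "experiments.tsv",
    evidence = "evidence.tsv",
    accepted_fly = "accepted_fly.txt",
    accepted_human = "accepted_human.txt",
    checkpoints = "checkpoints.tsv",
    removals = "removed_accessions.tsv",
    filtered_evidence = "filtered_evidence.tsv",
    ortholog_pairs = "ortholog_pairs.tsv",
    conserved = "conserved_interactors.tsv",
    averages = "average_counts.tsv",
    fold_changes = "fold_changes.tsv",
    preferences = "subunit_preferences.tsv",
    network_tsv = "network_edges.tsv",
    network_sif = "network.sif",
    network_graphml = "network.graphml",
    summary = "run_summary.json"
  ), function(f) file.path(dir, f))
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Load a pipeline configuration from YAML
#'
#' Reads a YAML document with optional sections `dir`, `seed`,
#' `filter`, `orthology`, `quant`, `simulation`, `curated_orthology`,
#' `blast_tabular`, `network_species`; each policy section accepts the
#' arguments of its constructor.
#'
#' @param path YAML path.
#' @param dir Override for the working directory.
#' @return A [pipeline_config()].
#' @export
load_pipeline_config <- function(path, dir = NULL) {
  if (!file.exists(path)) format_error(sprintf("file does not exist: %s", path))
  raw <- yaml::read_yaml(path)
  mk <- function(ctor, section) {
    if (is.null(raw[[section]])) return(NULL)
    args <- raw[[section]]
    if (section == "quant" && !is.null(args$condition_colors)) {
      args$condition_colors <- unlist(args$condition_colors)
    }
    do.call(ctor, args)
  }
  pipeline_config(
    dir = dir %||% raw$dir %||% ".",
    seed = raw$seed %||% 1,
    filter = mk(filter_policy, "filter"),
    orthology = mk(orthology_policy, "orthology"),
    quant = mk(quant_policy, "quant"),
    simulation = mk(simulation_config, "simulation"),
    curated_orthology = raw$curated_orthology,
    blast_tabular = raw$blast_tabular,
    network_species = raw$network_species %||% "fly",
    log_level = raw$log_level %||% "info"
  )
}

say <- function(config, fmt, ...) {
  if (identical(config$log_level, "info")) inform(sprintf(fmt, ...))
}

need_artifact <- function(config, key, produced_by) {
  path <- config$paths[[key]]
  if (!file.exists(path)) {
    abort(
      sprintf("missing artifact '%s'; run stage '%s' first",
              basename(path), produced_by),
      class = "interologr_stage_error"
    )
  }
  path
}

read_summary <- function(config) {
  if (file.exists(config$paths$summary)) {
    jsonlite::read_json(config$paths$summary, simplifyVector = TRUE)
  } else {
    list()
  }
}

update_summary <- function(config, stage, values) {
  s <- read_summary(config)
  s[[stage]] <- values
  jsonlite::write_json(s, config$paths$summary, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  s
}

#' Run one pipeline stage (or all of them)
#'
#' Orchestrates the analysis as resumable stages over a shared artifact
#' directory, mirroring the study workflow: simulate (or supply) evidence,
#' filter it through the acceptance cascade, map orthologs, call
#' conserved interactors, quantify, and export the network. Each stage
#' writes its tabular outputs plus an entry in the machine-readable run
#' summary (`run_summary.json`), including the per-species candidate
#' counts at every filtering checkpoint. A stage whose upstream artifacts
#' are missing fails with an error naming the stage to run first.
#'
#' Stages:
#' * `simulate` — synthetic proteomes, truth, design and evidence tables;
#' * `filter` — [filter_cascade()]: accepted accessions per species,
#'   checkpoint counts, per-accession removal log;
#' * `orthology` — curated pairs and/or reciprocal best-k hits from the
#'   internal aligner or a precomputed hit table, merged;
#' * `interlog` — conserved-interactor table;
#' * `quantify` — replicate-averaged counts, insulin fold changes and
#'   bait-subunit preference scores for the fly arm;
#' * `network` — thresholded condition-colored edges in TSV/SIF/GraphML;
#' * `all` — every stage in order, plus precision/recall against the
#'   planted truth when a truth table is present.
#'
#' @param stage One of `"simulate"`, `"filter"`, `"orthology"`,
#'   `"interlog"`, `"quantify"`, `"network"`, `"all"`.
#' @param config A [pipeline_config()].
#' @return The updated run summary (a named list), invisibly.
#' @export
run_stage <- function(stage = c("simulate", "filter", "orthology",
                                "interlog", "quantify", "network", "all"),
                      config) {
  stage <- match.arg(stage)
  if (!dir.exists(config$dir)) dir.create(config$dir, recursive = TRUE)
  summary <- switch(
    stage,
    simulate = stage_simulate(config),
    filter = stage_filter(config),
    orthology = stage_orthology(config),
    interlog = stage_interlog(config),
    quantify = stage_quantify(config),
    network = stage_network(config),
    all = {
      for (st in c("simulate", "filter", "orthology", "interlog",
                   "quantify", "network")) {
        run_stage(st, config)
      }
      stage_score(config)
    }
  )
  invisible(summary)
}

#' @rdname run_stage
#' @export
run_pipeline <- function(config) run_stage("all", config)

stage_simulate <- function(config) {
  say(config, "simulate: generating proteomes and IP-MS evidence (seed %d)",
      config$simulation$seed)
  prot <- generate_proteomes(config$simulation)
  Biostrings::writeXStringSet(prot$fly, config$paths$proteome_fly)
  Biostrings::writeXStringSet(prot$human, config$paths$proteome_human)
  write_truth(prot$truth, config$paths$truth)
  sim <- simulate_ipms(config$simulation, prot$truth)
  write_evidence(sim$evidence, config$paths$evidence,
                 sim$experiments, config$paths$experiments)
  update_summary(config, "simulate", list(
    seed = config$simulation$seed,
    n_fly_proteins = length(prot$fly),
    n_human_proteins = length(prot$human),
    n_experiments = nrow(sim$experiments),
    n_evidence_rows = nrow(sim$evidence),
    n_planted_conserved = nrow(prot$truth$conserved)
  ))
}

stage_filter <- function(config) {
  need_artifact(config, "evidence", "simulate")
  need_artifact(config, "experiments", "simulate")
  dat <- read_evidence(config$paths$evidence, config$paths$experiments)
  res <- filter_cascade(dat$evidence, dat$experiments, config$filter)
  writeLines(res$accepted$fly, config$paths$accepted_fly)
  writeLines(res$accepted$human, config$paths$accepted_human)
  write_tsv_plain(res$checkpoints, config$paths$checkpoints)
  write_tsv_plain(res$removals, config$paths$removals)
  write_evidence(res$evidence, config$paths$filtered_evidence)
  chk <- res$checkpoints
  as_list <- function(step) {
    v <- chk$n_accessions[chk$step == step]
    names(v) <- chk$species[chk$step == step]
    as.list(v)
  }
  say(config,
      "filter: %d fly / %d human candidates post-control; %d / %d accepted",
      as_list("post_control")$fly, as_list("post_control")$human,
      length(res$accepted$fly), length(res$accepted$human))
  update_summary(config, "filter", list(
    input = as_list("input"),
    post_contaminant = as_list("post_contaminant"),
    post_control = as_list("post_control"),
    post_policy = as_list("post_policy"),
    post_sticky = as_list("post_sticky"),
    n_removed_accessions = nrow(res$removals)
  ))
}

stage_orthology <- function(config) {
  curated <- if (!is.null(config$curated_orthology)) {
    read_ortholog_pairs(config$curated_orthology)
  } else {
    NULL
  }
  rbh <- if (!is.null(config$blast_tabular)) {
    say(config, "orthology: ranking precomputed hit tables")
    reciprocal_best_k(
      read_blast_tabular(config$blast_tabular$fly_to_human,
                         config$orthology),
      read_blast_tabular(config$blast_tabular$human_to_fly,
                         config$orthology),
      config$orthology
    )
  } else {
    need_artifact(config, "proteome_fly", "simulate")
    need_artifact(config, "proteome_human", "simulate")
    say(config, "orthology: all-vs-all alignment of the two proteomes")
    hits <- align_proteomes(config$paths$proteome_fly,
                            config$paths$proteome_human,
                            config$orthology)
    reciprocal_best_k(hits$a_to_b, hits$b_to_a, config$orthology)
  }
  pairs <- merge_orthology(curated, rbh)
  write_ortholog_pairs(pairs, config$paths$ortholog_pairs)
  update_summary(config, "orthology", list(
    n_pairs = nrow(pairs),
    n_curated = sum(pairs$source == "curated"),
    n_rbh = sum(pairs$source == "rbh")
  ))
}

stage_interlog <- function(config) {
  need_artifact(config, "accepted_fly", "filter")
  need_artifact(config, "ortholog_pairs", "orthology")
  need_artifact(config, "filtered_evidence", "filter")
  accepted_fly <- readLines(config$paths$accepted_fly)
  accepted_human <- readLines(config$paths$accepted_human)
  pairs <- read_tsv_strict(config$paths$ortholog_pairs,
                           c("fly_accession", "human_accession", "source"))
  dat <- read_evidence(config$paths$filtered_evidence,
                       config$paths$experiments)
  records <- compute_interlogs(accepted_fly, accepted_human, pairs,
                               dat$evidence, dat$experiments, config$filter)
  write_conserved_table(records, config$paths$conserved)
  say(config, "interlog: %d conserved interactor pair(s)", nrow(records))
  update_summary(config, "interlog", list(
    n_conserved_pairs = nrow(records),
    n_conserved_human_proteins = length(unique(records$human_accession))
  ))
}

stage_quantify <- function(config) {
  need_artifact(config, "filtered_evidence", "filter")
  dat <- read_evidence(config$paths$filtered_evidence,
                       config$paths$experiments)
  avg <- average_counts(dat$evidence, dat$experiments)
  write_tsv_plain(avg, config$paths$averages)

  fly_avg <- avg[avg$species == "fly", , drop = FALSE]
  fly_baits <- sort(unique(fly_avg$bait))
  fc <- list()
  for (stim in intersect(c("insulin_10", "insulin_30"),
                         unique(fly_avg$condition))) {
    if (!"basal" %in% fly_avg$condition) break
    tab <- fold_change_table(fly_avg, fly_baits, stim, "basal",
                             config$quant)
    if (nrow(tab) > 0) tab$stimulated_condition <- stim
    fc[[stim]] <- tab
  }
  fc <- if (length(fc)) dplyr::bind_rows(fc) else
    tibble(bait = character(), prey = character(),
           mean_basal = numeric(), mean_stimulated = numeric(),
           fold_change = numeric(), stimulated_condition = character())
  write_tsv_plain(fc, config$paths$fold_changes)

  prefs <- tibble(prey = character(), preference = numeric())
  if (length(fly_baits) == 2) {
    preys <- sort(unique(fly_avg$prey))
    preys <- setdiff(preys, fly_baits)
    vals <- vapply(preys, function(p) {
      subunit_preference(fly_avg, p,
                         regulatory_bait = fly_baits[grepl("21B", fly_baits)][1],
                         catalytic_bait = fly_baits[!grepl("21B", fly_baits)][1],
                         condition = NULL, policy = config$quant)
    }, numeric(1))
    prefs <- tibble(prey = preys, preference = vals)
    prefs <- prefs[order(-prefs$preference), ]
  }
  write_tsv_plain(prefs, config$paths$preferences)
  update_summary(config, "quantify", list(
    n_quantified_groups = nrow(avg),
    n_fold_changes = nrow(fc),
    n_preference_scores = nrow(prefs)
  ))
}

stage_network <- function(config) {
  need_artifact(config, "averages", "quantify")
  avg <- read_tsv_strict(config$paths$averages, c(
    "species", "bait", "condition", "prey", "mean_counts", "n_replicates"
  ))
  avg <- avg[avg$species %in% config$network_species, , drop = FALSE]
  edges <- build_network(avg, config$quant)
  export_network(edges, config$paths$network_tsv, "tsv")
  export_network(edges, config$paths$network_sif, "sif")
  export_network(edges, config$paths$network_graphml, "graphml")
  say(config, "network: %d edge(s) exported", nrow(edges))
  update_summary(config, "network", list(
    n_edges = nrow(edges),
    n_baits = length(unique(edges$bait)),
    n_preys = length(unique(edges$prey))
  ))
}

stage_score <- function(config) {
  if (!file.exists(config$paths$truth)) {
    return(invisible(read_summary(config)))
  }
  truth <- read_truth(config$paths$truth)
  records <- read_conserved_table(config$paths$conserved)
  sc <- score_recovery(records, truth)
  say(config, "score: precision %.3f, recall %.3f (n=%d planted pairs)",
      sc$precision, sc$recall, sc$n_truth)
  update_summary(config, "score", sc)
}
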