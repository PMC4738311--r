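# run code under a fixed RNG seed without disturbing the caller's stream
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Configuration of the synthetic two-species IP-MS study
#'
#' Describes the simulated study the generator emulates: a fly arm with
#' two TAP-tagged PI3K bait subunits (regulatory and catalytic) sampled at
#' basal, 10-minute and 30-minute insulin stimulation in three biological
#' replicates plus an empty-TAP control, and a human arm with sixteen
#' p85-antibody IP experiment-condition units across cell lines and
#' treatments in two biological replicates plus an IgG control.
#'
#' Planted protein categories: conserved preys (ortholog-paired, present
#' in both arms; the first two mimic the regulatory-subunit-preferring,
#' insulin-responsive SHP2/Csw pattern and the catalytic-preferring
#' IRS1/Chico pattern), species-specific preys (no ortholog), sticky
#' background proteins (ortholog-paired ribosomal/heat-shock/actin/tubulin
#' lookalikes present in every IP including controls), and named
#' contaminants (keratin/dermcidin/casein/trypsin/albumin lookalikes,
#' likewise ubiquitous). The two bait subunits are themselves
#' ortholog-paired and observed in the IPs, so the planted conserved truth
#' is `n_conserved_preys + 2` pairs.
#'
#' @param seed Integer seed; fixing it makes every generator output
#'   byte-identical.
#' @param n_conserved_preys Number of conserved preys (>= 2; the first two
#'   are the named analogues).
#' @param n_species_specific_preys Species-specific preys per species.
#' @param n_sticky Sticky background proteins per species.
#' @param n_contaminants Named contaminants per species.
#' @param ortholog_identity Expected per-site identity of planted ortholog
#'   sequence pairs, in (0, 1].
#' @param baseline_abundance Mean spectral count of a true prey in an IP
#'   of its bait.
#' @param background_rate Mean spectral count of sticky/contaminant
#'   carryover in every IP, controls included.
#' @param preference_factor Fold depletion of a bait-preferring prey in
#'   the non-preferred bait's IPs.
#' @param stimulation_effects Named numeric vector of per-prey
#'   multiplicative folds applied under insulin conditions; `NULL` plants
#'   fold 3 on the two named analogue preys.
#' @param count_model `"poisson"` or `"negative_binomial"` (real spectral
#'   counts are overdispersed; Poisson is the default for simple
#'   oracles).
#' @param dispersion Negative-binomial size parameter.
#' @param length_range Sequence length range (amino acids).
#' @param n_human_units Number of human experiment-condition units.
#' @param fly_replicates,human_replicates Biological replicates per unit.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1,
                              n_conserved_preys = 12,
                              n_species_specific_preys = 30,
                              n_sticky = 20,
                              n_contaminants = 15,
                              ortholog_identity = 0.85,
                              baseline_abundance = 30,
                              background_rate = 8,
                              preference_factor = 8,
                              stimulation_effects = NULL,
                              count_model = c("poisson", "negative_binomial"),
                              dispersion = 5,
                              length_range = c(150, 600),
                              n_human_units = 16,
                              fly_replicates = 3,
                              human_replicates = 2) {
  count_model <- match.arg(count_model)
  cfg <- list(
    seed = check_count_int(seed, "seed"),
    n_conserved_preys = check_count_int(n_conserved_preys,
                                        "n_conserved_preys"),
    n_species_specific_preys =
      check_count_int(n_species_specific_preys, "n_species_specific_preys"),
    n_sticky = check_count_int(n_sticky, "n_sticky"),
    n_contaminants = check_count_int(n_contaminants, "n_contaminants"),
    ortholog_identity = check_fraction(ortholog_identity,
                                       "ortholog_identity"),
    baseline_abundance = as.numeric(baseline_abundance),
    background_rate = as.numeric(background_rate),
    preference_factor = as.numeric(preference_factor),
    stimulation_effects = stimulation_effects,
    count_model = count_model,
    dispersion = as.numeric(dispersion),
    length_range = as.integer(length_range),
    n_human_units = check_count_int(n_human_units, "n_human_units"),
    fly_replicates = check_count_int(fly_replicates, "fly_replicates"),
    human_replicates = check_count_int(human_replicates, "human_replicates")
  )
  if (cfg$n_conserved_preys < 2) {
    validation_error("n_conserved_preys must be >= 2 (the two named analogues)")
  }
  if (cfg$baseline_abundance < 0 || cfg$background_rate < 0) {
    validation_error("abundance parameters must be >= 0")
  }
  if (!is.null(cfg$stimulation_effects) &&
      (is.null(names(cfg$stimulation_effects)) ||
         any(cfg$stimulation_effects <= 0))) {
    validation_error("stimulation_effects must be a named vector of folds > 0")
  }
  structure(cfg, class = c("simulation_config", "list"))
}

# deterministic naming and per-protein parameters of the planted universe
synthetic_roster <- function(config) {
  sticky_desc <- c(
    "60S ribosomal protein L%d, synthetic",
    "heat shock protein HSP%d, synthetic",
    "actin-related protein %d, synthetic",
    "tubulin beta-%d chain, synthetic"
  )
  contam_desc <- c(
    "Keratin, type II cytoskeletal %d, synthetic",
    "Dermcidin isoform %d, synthetic",
    "Casein kappa %d, synthetic",
    "Trypsin precursor %d, synthetic",
    "Bovine serum albumin fragment %d, synthetic"
  )
  cyc <- function(templates, n) {
    vapply(seq_len(n),
           function(i) sprintf(templates[(i - 1) %% length(templates) + 1], i),
           character(1))
  }
  n_cons <- config$n_conserved_preys
  cons_fly <- c("FLY_CSW", "FLY_CHICO",
                sprintf("FLY_CONS%02d", seq_len(n_cons))[-(1:2)])
  cons_hum <- c("HUM_SHP2", "HUM_IRS1",
                sprintf("HUM_CONS%02d", seq_len(n_cons))[-(1:2)])
  cons_desc <- c(
    "tyrosine-protein phosphatase corkscrew homolog, synthetic",
    "insulin receptor substrate homolog, synthetic",
    sprintf("conserved prey protein %d, synthetic",
            seq_len(n_cons))[-(1:2)]
  )
  pref <- c("regulatory", "catalytic", rep("both", n_cons - 2))
  stim <- if (is.null(config$stimulation_effects)) {
    c(3, 3, rep(1, n_cons - 2))
  } else {
    rep(1, n_cons)
  }

  one_species <- function(sp) {
    tag <- if (sp == "fly") "FLY" else "HUM"
    baits <- tibble(
      accession = if (sp == "fly") c("FLY_PI3K21B", "FLY_PI3K92E")
                  else c("HUM_P85A", "HUM_P110"),
      category = "bait",
      description = paste0(
        c("phosphatidylinositol 3-kinase regulatory subunit homolog",
          "phosphatidylinositol 3-kinase catalytic subunit homolog"),
        ", synthetic"
      ),
      preferred_bait = c("regulatory", "catalytic"),
      stimulation_fold = 1
    )
    conserved <- tibble(
      accession = if (sp == "fly") cons_fly else cons_hum,
      category = "conserved",
      description = cons_desc,
      preferred_bait = pref,
      stimulation_fold = stim
    )
    specific <- tibble(
      accession = sprintf("%s_SPEC%02d", tag,
                          seq_len(config$n_species_specific_preys)),
      category = "specific",
      description = sprintf("species-restricted prey protein %d, synthetic",
                            seq_len(config$n_species_specific_preys)),
      preferred_bait = "both",
      stimulation_fold = 1
    )
    sticky <- tibble(
      accession = sprintf("%s_STKY%02d", tag, seq_len(config$n_sticky)),
      category = "sticky",
      description = cyc(sticky_desc, config$n_sticky),
      preferred_bait = "both",
      stimulation_fold = 1
    )
    contam <- tibble(
      accession = sprintf("%s_CONT%02d", tag, seq_len(config$n_contaminants)),
      category = "contaminant",
      description = cyc(contam_desc, config$n_contaminants),
      preferred_bait = "both",
      stimulation_fold = 1
    )
    dplyr::bind_rows(baits, conserved, specific, sticky, contam)
  }
  fly <- one_species("fly")
  human <- one_species("human")
  if (!is.null(config$stimulation_effects)) {
    se <- config$stimulation_effects
    for (nm in names(se)) {
      fly$stimulation_fold[fly$accession == nm] <- se[[nm]]
      human$stimulation_fold[human$accession == nm] <- se[[nm]]
    }
  }
  list(fly = fly, human = human)
}

random_protein <- function(len) {
  paste(sample(Biostrings::AA_STANDARD, len, replace = TRUE), collapse = "")
}

mutate_protein <- function(seq, identity) {
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  flip <- stats::runif(length(v)) > identity
  if (any(flip)) {
    v[flip] <- vapply(v[flip], function(res) {
      sample(setdiff(Biostrings::AA_STANDARD, res), 1)
    }, character(1))
  }
  paste(v, collapse = "")
}

#' Generate the two synthetic proteomes and the planted truth
#'
#' Fly sequences are random amino-acid strings; each ortholog-paired
#' protein (baits, conserved preys, sticky proteins) gets a human
#' counterpart produced by per-site mutation at the configured identity
#' (each site independently kept with probability `ortholog_identity`,
#' otherwise replaced by a different residue). Species-specific preys,
#' contaminants and all other human sequences are independent random
#' decoys. Fully deterministic under the configuration seed.
#'
#' @param config A [simulation_config()].
#' @return A list with `fly` and `human` (`AAStringSet`, names =
#'   accessions) and `truth` (see [write_truth()]): the planted ortholog
#'   pairs, the planted conserved-interactor set, and per-prey preference
#'   and stimulation parameters.
#' @export
generate_proteomes <- function(config = simulation_config()) {
  roster <- synthetic_roster(config)
  with_seed(config$seed, {
    lo <- config$length_range[1]
    hi <- config$length_range[2]
    fly_tab <- roster$fly
    hum_tab <- roster$human
    fly_seqs <- vapply(seq_len(nrow(fly_tab)), function(i) {
      random_protein(sample(lo:hi, 1))
    }, character(1))
    names(fly_seqs) <- fly_tab$accession
    paired <- fly_tab$category %in% c("bait", "conserved", "sticky")
    hum_seqs <- character(nrow(hum_tab))
    names(hum_seqs) <- hum_tab$accession
    for (i in seq_len(nrow(hum_tab))) {
      if (paired[i]) {
        hum_seqs[i] <- mutate_protein(fly_seqs[i], config$ortholog_identity)
      } else {
        hum_seqs[i] <- random_protein(sample(lo:hi, 1))
      }
    }
    pairs <- tibble(
      fly_accession = fly_tab$accession[paired],
      human_accession = hum_tab$accession[paired],
      category = fly_tab$category[paired]
    )
    conserved <- pairs[pairs$category %in% c("bait", "conserved"),
                       c("fly_accession", "human_accession")]
    truth <- list(
      ortholog_pairs = pairs,
      conserved = conserved,
      prey_params = tibble(
        fly_accession = fly_tab$accession,
        human_accession = ifelse(paired, hum_tab$accession, NA_character_),
        category = fly_tab$category,
        preferred_bait = fly_tab$preferred_bait,
        preference_factor = ifelse(
          fly_tab$preferred_bait %in% c("regulatory", "catalytic"),
          config$preference_factor, 1
        ),
        stimulation_fold = fly_tab$stimulation_fold
      )
    )
    list(
      fly = Biostrings::AAStringSet(fly_seqs),
      human = Biostrings::AAStringSet(hum_seqs),
      truth = truth
    )
  })
}

human_unit_conditions <- function(n) {
  base <- c(
    "serum_H1703", "imatinib_H1703", "starved_H929", "serum_H929",
    "insulin_10_H929", "insulin_30_H929", "serum_A549", "serum_8226",
    "starved_8226", "bortezomib_8226", "serum_HCC827", "gefitinib_HCC827",
    "gefitinib_HGF_HCC827", "serum_H1993", "PHA665752_H1993", "serum_EBC1"
  )
  if (n <= length(base)) base[seq_len(n)]
  else c(base, sprintf("serum_extra%02d", seq_len(n - length(base))))
}

draw_counts <- function(n, mu, config) {
  if (mu <= 0) return(rep(0L, n))
  if (config$count_model == "poisson") {
    stats::rpois(n, mu)
  } else {
    stats::rnbinom(n, size = config$dispersion, mu = mu)
  }
}

#' Simulate the IP-MS evidence tables
#'
#' Draws spectral counts for every planted protein in every
#' immunoprecipitation run of the study design. True preys draw from the
#' count model at `baseline_abundance` scaled by the condition's
#' stimulation fold (insulin conditions only) and the prey's bait
#' preference (non-preferred bait divided by `preference_factor`); each
#' bait IP also contains the bait itself (3x baseline) and its partner
#' subunit (baseline). Sticky proteins and contaminants draw background
#' counts in every IP, controls included; controls contain nothing else.
#' Unique peptides are drawn as `min(counts, 1 + Binomial(counts, 0.25))`.
#' Zero draws produce no record. Deterministic under the configuration
#' seed.
#'
#' @param config A [simulation_config()].
#' @param truth The truth object from [generate_proteomes()].
#' @return A list with tibbles `experiments` and `evidence` in the
#'   package's standard dialects.
#' @export
simulate_ipms <- function(config = simulation_config(), truth) {
  roster <- synthetic_roster(config)
  with_seed(config$seed + 1L, {
    fly_baits <- c(regulatory = "FLY_PI3K21B", catalytic = "FLY_PI3K92E")
    hum_baits <- c(regulatory = "HUM_P85A", catalytic = "HUM_P110")
    fly_conditions <- c("basal", "insulin_10", "insulin_30")

    experiments <- list()
    add_exp <- function(id, species, bait, condition, replicate, is_control) {
      experiments[[length(experiments) + 1]] <<- tibble(
        experiment_id = id, species = species, bait = bait,
        condition = condition, replicate = as.integer(replicate),
        is_control = is_control
      )
    }
    for (b in names(fly_baits)) {
      for (cd in fly_conditions) {
        for (r in seq_len(config$fly_replicates)) {
          add_exp(sprintf("fly_%s_%s_r%d", tolower(fly_baits[[b]]), cd, r),
                  "fly", fly_baits[[b]], cd, r, FALSE)
        }
      }
    }
    for (r in seq_len(config$fly_replicates)) {
      add_exp(sprintf("fly_emptyTAP_r%d", r), "fly", "control", "basal", r,
              TRUE)
    }
    for (cd in human_unit_conditions(config$n_human_units)) {
      for (r in seq_len(config$human_replicates)) {
        add_exp(sprintf("human_p85_%s_r%d", cd, r), "human",
                hum_baits[["regulatory"]], cd, r, FALSE)
      }
    }
    for (r in seq_len(config$human_replicates)) {
      add_exp(sprintf("human_IgG_r%d", r), "human", "control", "serum_H929",
              r, TRUE)
    }
    experiments <- dplyr::bind_rows(experiments)

    is_insulin <- function(cond) grepl("insulin", cond, fixed = TRUE)

    expected_rate <- function(tab, i, species, bait, condition, is_control) {
      cat <- tab$category[i]
      if (cat %in% c("sticky", "contaminant")) return(config$background_rate)
      if (is_control) return(0)
      baits <- if (species == "fly") fly_baits else hum_baits
      role <- names(baits)[match(bait, baits)]
      mu <- config$baseline_abundance
      if (cat == "bait") {
        own_role <- tab$preferred_bait[i]
        return(if (identical(own_role, role)) 3 * mu else mu)
      }
      pref <- tab$preferred_bait[i]
      if (pref != "both" && !identical(pref, role)) {
        mu <- mu / config$preference_factor
      }
      if (is_insulin(condition)) mu <- mu * tab$stimulation_fold[i]
      mu
    }

    rows <- list()
    for (e in seq_len(nrow(experiments))) {
      sp <- experiments$species[e]
      tab <- roster[[sp]]
      for (i in seq_len(nrow(tab))) {
        mu <- expected_rate(tab, i, sp, experiments$bait[e],
                            experiments$condition[e],
                            experiments$is_control[e])
        cts <- draw_counts(1, mu, config)
        if (cts > 0) {
          up <- min(cts, 1L + stats::rbinom(1, cts, 0.25))
          rows[[length(rows) + 1]] <- tibble(
            experiment_id = experiments$experiment_id[e],
            accession = tab$accession[i],
            unique_peptides = as.integer(up),
            spectral_counts = as.integer(cts),
            description = tab$description[i]
          )
        }
      }
    }
    evidence <- if (length(rows)) dplyr::bind_rows(rows) else tibble(
      experiment_id = character(), accession = character(),
      unique_peptides = integer(), spectral_counts = integer(),
      description = character()
    )
    list(experiments = experiments, evidence = evidence)
  })
}

#' Write / read the planted ground truth
#'
#' Serialises the truth object of [generate_proteomes()] as a single TSV:
#' one row per planted protein (fly side), with its human ortholog where
#' one was planted, its category, whether the pair belongs to the planted
#' conserved set, and its bait-preference and stimulation parameters.
#'
#' @param truth Truth object.
#' @param path TSV path.
#' @return `path` invisibly (write); a truth object (read).
#' @export
write_truth <- function(truth, path) {
  tab <- truth$prey_params
  tab$conserved <- paste(tab$fly_accession, tab$human_accession) %in%
    paste(truth$conserved$fly_accession, truth$conserved$human_accession)
  write_tsv_plain(tab, path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  tab <- read_tsv_strict(path, c(
    "fly_accession", "human_accession", "category", "preferred_bait",
    "preference_factor", "stimulation_fold", "conserved"
  ))
  tab <- as_tibble(tab)
  paired <- !is.na(tab$human_accession)
  list(
    ortholog_pairs = tab[paired, c("fly_accession", "human_accession",
                                   "category")],
    conserved = tab[tab$conserved %in% TRUE,
                    c("fly_accession", "human_accession")],
    prey_params = tab[, c("fly_accession", "human_accession", "category",
                          "preferred_bait", "preference_factor",
                          "stimulation_fold")]
  )
}

#' Score recovery of the planted conserved set
#'
#' Exact set arithmetic between the conserved-interactor pairs produced by
#' the pipeline and the planted conserved pairs: precision is the fraction
#' of reported pairs that are planted, recall the fraction of planted
#' pairs that are reported. `NA` when the respective denominator is
#' empty.
#'
#' @param records Conserved-interactor tibble ([compute_interlogs()]) or
#'   any tibble with `fly_accession` and `human_accession`.
#' @param truth Truth object.
#' @return A list with `precision`, `recall`, `n_predicted`, `n_truth`,
#'   `n_true_positive`.
#' @export
score_recovery <- function(records, truth) {
  pred <- unique(paste(records$fly_accession, records$human_accession,
                       sep = "\r"))
  want <- unique(paste(truth$conserved$fly_accession,
                       truth$conserved$human_accession, sep = "\r"))
  tp <- length(intersect(pred, want))
  list(
    precision = if (length(pred) == 0) NA_real_ else tp / length(pred),
    recall = if (length(want) == 0) NA_real_ else tp / length(want),
    n_predicted = length(pred),
    n_truth = length(want),
    n_true_positive = tp
  )
}
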