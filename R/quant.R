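#' Replicate-averaged spectral counts
#'
#' Averages spectral counts over the replicate runs of each
#' experiment-condition unit — a (species, bait, condition) combination of
#' non-control experiments. A prey absent from a replicate contributes a
#' zero, so the mean is the arithmetic mean over *all* replicates of the
#' unit, not only those where the prey was seen.
#'
#' @param evidence Evidence tibble.
#' @param experiments Experiments tibble.
#' @return A tibble keyed by (`species`, `bait`, `condition`, `prey`) with
#'   `mean_counts` and `n_replicates`.
#' @export
average_counts <- function(evidence, experiments) {
  ex <- experiments[!(experiments$is_control %in% TRUE),
                    c("experiment_id", "species", "bait", "condition")]
  if (nrow(ex) == 0) {
    return(tibble(
      species = character(), bait = character(), condition = character(),
      prey = character(), mean_counts = numeric(), n_replicates = integer()
    ))
  }
  sizes <- dplyr::count(ex, .data$species, .data$bait, .data$condition,
                        name = "n_replicates")
  ev <- dplyr::inner_join(evidence, ex, by = "experiment_id")
  sums <- ev |>
    dplyr::group_by(.data$species, .data$bait, .data$condition,
                    prey = .data$accession) |>
    dplyr::summarise(total = sum(.data$spectral_counts), .groups = "drop")
  out <- dplyr::inner_join(sums, sizes,
                           by = c("species", "bait", "condition"))
  out$mean_counts <- out$total / out$n_replicates
  out$total <- NULL
  out <- out[order(out$species, out$bait, out$condition, out$prey), ]
  as_tibble(out[, c("species", "bait", "condition", "prey",
                    "mean_counts", "n_replicates")])
}

lookup_mean <- function(avg, bait, prey, condition) {
  grp <- avg$bait == bait & avg$condition == condition
  if (!any(grp)) return(NULL) # the unit itself does not exist
  hit <- grp & avg$prey == prey
  if (any(hit)) avg$mean_counts[which(hit)[1]] else 0
}

#' Stimulation fold change of a bait-prey association
#'
#' Ratio of pseudocount-shifted replicate-averaged spectral counts between
#' a stimulated and a basal condition of the same bait:
#' `(mean_stim + pc) / (mean_basal + pc)`. The pseudocount keeps the ratio
#' defined when the basal mean is zero. A prey never observed with the
#' bait in either condition has no defined fold change and is reported as
#' `NA` rather than 1.
#'
#' @param avg Averaged-count table from [average_counts()].
#' @param bait Bait accession.
#' @param prey Prey accession.
#' @param stimulated_condition,basal_condition Condition labels; both
#'   units must exist for the bait.
#' @param policy A [quant_policy()].
#' @return A single number (or `NA_real_` when undefined).
#' @export
fold_change <- function(avg, bait, prey, stimulated_condition,
                        basal_condition, policy = quant_policy()) {
  m_stim <- lookup_mean(avg, bait, prey, stimulated_condition)
  m_bas <- lookup_mean(avg, bait, prey, basal_condition)
  if (is.null(m_stim) || is.null(m_bas)) {
    validation_error(sprintf(
      "bait '%s' lacks condition '%s'", bait,
      if (is.null(m_stim)) stimulated_condition else basal_condition
    ))
  }
  if (m_stim == 0 && m_bas == 0) return(NA_real_)
  (m_stim + policy$pseudocount) / (m_bas + policy$pseudocount)
}

#' Bait-subunit preference score
#'
#' Log-ratio of a prey's pseudocount-shifted average spectral counts
#' between the regulatory and catalytic bait subunits:
#' `log2((mean_reg + pc) / (mean_cat + pc))` (base from the policy).
#' Positive scores mean preferential association with the regulatory
#' subunit (the free-p85 binding pattern of SHP2/Csw); negative scores
#' mean catalytic-subunit preference (the active-heterodimer pattern of
#' IRS1/Chico). `NA` when the prey was observed with neither bait.
#'
#' @param avg Averaged-count table from [average_counts()].
#' @param prey Prey accession.
#' @param regulatory_bait,catalytic_bait Bait accessions.
#' @param condition Condition label to compare within; `NULL` pools every
#'   condition shared by both baits by averaging their per-condition
#'   means.
#' @param policy A [quant_policy()].
#' @return A single number (or `NA_real_` when undefined).
#' @export
subunit_preference <- function(avg, prey, regulatory_bait, catalytic_bait,
                               condition = NULL, policy = quant_policy()) {
  mean_for <- function(bait) {
    conds <- if (is.null(condition)) {
      intersect(unique(avg$condition[avg$bait == regulatory_bait]),
                unique(avg$condition[avg$bait == catalytic_bait]))
    } else {
      condition
    }
    ms <- vapply(conds, function(cd) {
      m <- lookup_mean(avg, bait, prey, cd)
      if (is.null(m)) {
        validation_error(sprintf("bait '%s' lacks condition '%s'", bait, cd))
      }
      m
    }, numeric(1))
    if (length(ms) == 0) {
      validation_error("baits share no conditions to compare within")
    }
    mean(ms)
  }
  m_reg <- mean_for(regulatory_bait)
  m_cat <- mean_for(catalytic_bait)
  if (m_reg == 0 && m_cat == 0) return(NA_real_)
  log((m_reg + policy$pseudocount) / (m_cat + policy$pseudocount),
      base = policy$log_base)
}

#' Fold-change table for every bait-prey pair
#'
#' Convenience wrapper computing [fold_change()] for every prey of each
#' given bait between a stimulated and a basal condition, returned ranked
#' by descending fold change.
#'
#' @param avg Averaged-count table.
#' @param baits Character vector of bait accessions.
#' @param stimulated_condition,basal_condition Condition labels.
#' @param policy A [quant_policy()].
#' @return A tibble (`bait`, `prey`, `mean_basal`, `mean_stimulated`,
#'   `fold_change`) sorted by descending fold change.
#' @export
fold_change_table <- function(avg, baits, stimulated_condition,
                              basal_condition, policy = quant_policy()) {
  rows <- list()
  for (b in baits) {
    preys <- sort(unique(avg$prey[avg$bait == b &
                                    avg$condition %in% c(stimulated_condition,
                                                         basal_condition)]))
    for (p in preys) {
      fc <- fold_change(avg, b, p, stimulated_condition, basal_condition,
                        policy)
      rows[[length(rows) + 1]] <- tibble(
        bait = b, prey = p,
        mean_basal = lookup_mean(avg, b, p, basal_condition),
        mean_stimulated = lookup_mean(avg, b, p, stimulated_condition),
        fold_change = fc
      )
    }
  }
  if (length(rows) == 0) {
    return(tibble(bait = character(), prey = character(),
                  mean_basal = numeric(), mean_stimulated = numeric(),
                  fold_change = numeric()))
  }
  out <- dplyr::bind_rows(rows)
  out[order(-out$fold_change, out$bait, out$prey), ]
}
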