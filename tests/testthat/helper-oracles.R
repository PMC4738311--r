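# Independent brute-force reimplementations of each operation, used as
# oracles. They share no code with the package internals: plain loops,
# explicit comparators, no dplyr.

tb <- tibble::tibble

make_experiments <- function(ids, species, bait, condition,
                             replicate = 1L, is_control = FALSE) {
  tb(
    experiment_id = ids, species = species, bait = bait,
    condition = condition,
    replicate = as.integer(rep_len(replicate, length(ids))),
    is_control = rep_len(is_control, length(ids))
  )
}

make_evidence <- function(experiment_id, accession, spectral_counts,
                          unique_peptides = pmax(1L, pmin(spectral_counts, 2L)),
                          description = "") {
  tb(
    experiment_id = experiment_id, accession = accession,
    unique_peptides = as.integer(unique_peptides),
    spectral_counts = as.integer(spectral_counts),
    description = rep_len(description, length(accession))
  )
}

desc_matches <- function(desc, patterns) {
  any(vapply(patterns, function(p) grepl(tolower(p), tolower(desc),
                                         fixed = TRUE), logical(1)))
}

oracle_contaminants <- function(ev, policy) {
  keep <- logical(nrow(ev))
  for (i in seq_len(nrow(ev))) {
    bad <- ev$accession[i] %in% policy$contaminant_accessions ||
      desc_matches(ev$description[i], policy$contaminant_name_patterns)
    keep[i] <- !bad
  }
  ev[keep, , drop = FALSE]
}

oracle_controls <- function(ev, ex) {
  sp_of <- function(id) ex$species[match(id, ex$experiment_id)]
  ctl_of <- function(id) isTRUE(ex$is_control[match(id, ex$experiment_id)])
  seen <- list(fly = character(), human = character())
  for (i in seq_len(nrow(ev))) {
    if (ctl_of(ev$experiment_id[i]) && ev$spectral_counts[i] >= 1) {
      sp <- sp_of(ev$experiment_id[i])
      seen[[sp]] <- union(seen[[sp]], ev$accession[i])
    }
  }
  keep <- logical(nrow(ev))
  for (i in seq_len(nrow(ev))) {
    sp <- sp_of(ev$experiment_id[i])
    keep[i] <- !ctl_of(ev$experiment_id[i]) &&
      (is.na(sp) || !(ev$accession[i] %in% seen[[sp]]))
  }
  ev[keep, , drop = FALSE]
}

oracle_policy <- function(ev, ex, policy) {
  out <- list(fly = character(), human = character())
  for (sp in c("fly", "human")) {
    need <- if (sp == "human") policy$min_supporting_experiments_human
            else policy$min_supporting_experiments_fly
    exs <- ex[ex$species == sp & !ex$is_control, , drop = FALSE]
    if (nrow(exs) == 0) next
    units <- unique(paste(exs$bait, exs$condition, sep = "\r"))
    for (acc in unique(ev$accession)) {
      n_units <- 0L
      for (u in units) {
        ids <- exs$experiment_id[paste(exs$bait, exs$condition,
                                       sep = "\r") == u]
        hit <- FALSE
        for (id in ids) {
          row <- which(ev$experiment_id == id & ev$accession == acc)
          for (r in row) {
            ok <- ev$spectral_counts[r] >= policy$min_counts_per_experiment
            if (sp == "human") {
              ok <- ok && ev$unique_peptides[r] >= policy$min_unique_peptides
            }
            if (ok) hit <- TRUE
          }
        }
        if (hit) n_units <- n_units + 1L
      }
      if (n_units >= need) out[[sp]] <- c(out[[sp]], acc)
    }
  }
  lapply(out, sort)
}

oracle_sticky <- function(accepted, ev, policy) {
  keep <- character()
  for (acc in accepted) {
    d <- ev$description[match(acc, ev$accession)]
    if (is.na(d)) d <- ""
    sticky <- desc_matches(d, policy$sticky_name_patterns) &&
      !desc_matches(d, policy$sticky_exempt_patterns)
    if (!sticky) keep <- c(keep, acc)
  }
  sort(keep)
}

# selection-sort ranking with an explicit pairwise comparator
oracle_rank <- function(hits, policy) {
  hits <- hits[hits$evalue < policy$evalue_cutoff, , drop = FALSE]
  better <- function(i, j) {
    if (hits$evalue[i] != hits$evalue[j]) return(hits$evalue[i] < hits$evalue[j])
    if (hits$bitscore[i] != hits$bitscore[j]) {
      return(hits$bitscore[i] > hits$bitscore[j])
    }
    hits$subject[i] < hits$subject[j]
  }
  out <- NULL
  for (q in sort(unique(hits$query))) {
    idx <- which(hits$query == q)
    ranked <- integer(0)
    while (length(idx) > 0) {
      best <- idx[1]
      for (i in idx) if (i != best && better(i, best)) best <- i
      ranked <- c(ranked, best)
      idx <- setdiff(idx, best)
    }
    part <- hits[ranked, , drop = FALSE]
    part$rank <- seq_along(ranked)
    out <- rbind(out, part)
  }
  if (is.null(out)) {
    out <- hits
    out$rank <- integer(0)
  }
  out
}

oracle_rbh <- function(hits_ab, hits_ba, policy) {
  k <- policy$top_k
  in_topk <- function(hits, q, s) {
    any(hits$query == q & hits$subject == s & hits$rank <= k &
          hits$evalue < policy$evalue_cutoff)
  }
  pairs <- NULL
  for (a in unique(hits_ab$query)) {
    for (b in unique(hits_ba$query)) {
      if (in_topk(hits_ab, a, b) && in_topk(hits_ba, b, a)) {
        pairs <- rbind(pairs, data.frame(fly_accession = a,
                                         human_accession = b))
      }
    }
  }
  if (is.null(pairs)) {
    return(data.frame(fly_accession = character(),
                      human_accession = character()))
  }
  pairs[order(pairs$fly_accession, pairs$human_accession), , drop = FALSE]
}

oracle_interlog <- function(accepted_fly, accepted_human, pairs) {
  keep <- logical(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    keep[i] <- pairs$fly_accession[i] %in% accepted_fly &&
      pairs$human_accession[i] %in% accepted_human
  }
  out <- pairs[keep, c("fly_accession", "human_accession"), drop = FALSE]
  out[order(out$human_accession, out$fly_accession), , drop = FALSE]
}

oracle_average <- function(ev, ex) {
  exs <- ex[!ex$is_control, , drop = FALSE]
  out <- NULL
  for (key in unique(paste(exs$species, exs$bait, exs$condition,
                           sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    ids <- exs$experiment_id[exs$species == parts[1] &
                               exs$bait == parts[2] &
                               exs$condition == parts[3]]
    sub <- ev[ev$experiment_id %in% ids, , drop = FALSE]
    for (acc in sort(unique(sub$accession))) {
      total <- sum(sub$spectral_counts[sub$accession == acc])
      out <- rbind(out, data.frame(
        species = parts[1], bait = parts[2], condition = parts[3],
        prey = acc, mean_counts = total / length(ids),
        n_replicates = length(ids)
      ))
    }
  }
  if (is.null(out)) {
    return(data.frame(species = character(), bait = character(),
                      condition = character(), prey = character(),
                      mean_counts = numeric(), n_replicates = integer()))
  }
  out[order(out$species, out$bait, out$condition, out$prey), , drop = FALSE]
}

# small randomized IP-MS dataset; descriptions sampled so that some match
# contaminant/sticky patterns
rand_dataset <- function(seed, n_exp = 6, n_acc = 12) {
  set.seed(seed)
  species <- sample(c("fly", "human"), n_exp, replace = TRUE)
  is_control <- stats::runif(n_exp) < 0.25
  ex <- make_experiments(
    ids = sprintf("e%02d", seq_len(n_exp)),
    species = species,
    bait = ifelse(is_control, "control",
                  sample(c("baitR", "baitC"), n_exp, replace = TRUE)),
    condition = sample(c("basal", "insulin_10", "insulin_30"), n_exp,
                       replace = TRUE),
    replicate = sample(1:3, n_exp, replace = TRUE),
    is_control = is_control
  )
  accs <- sprintf("P%03d", seq_len(n_acc))
  descs <- sample(c(
    "generic binding protein", "Keratin, type I cytoskeletal 9",
    "60S ribosomal protein L7", "heat shock protein beta-1",
    "Activator of 90 kDa heat shock protein ATPase homolog 1",
    "Trypsin-1 precursor", "tyrosine-protein phosphatase",
    "insulin receptor substrate homolog", "tubulin alpha chain",
    "serum albumin precursor"
  ), n_acc, replace = TRUE)
  rows <- expand.grid(e = seq_len(n_exp), a = seq_len(n_acc))
  keep <- stats::runif(nrow(rows)) < 0.6
  rows <- rows[keep, , drop = FALSE]
  counts <- stats::rpois(nrow(rows), 4)
  ev <- make_evidence(
    experiment_id = ex$experiment_id[rows$e],
    accession = accs[rows$a],
    spectral_counts = counts,
    unique_peptides = pmin(counts, 1L + stats::rpois(nrow(rows), 1)),
    description = descs[rows$a]
  )
  ev <- ev[ev$spectral_counts > 0, , drop = FALSE]
  list(experiments = ex, evidence = ev)
}

# random ranked hit tables for two small proteomes
rand_hits <- function(seed, n_a = 8, n_b = 8, policy = orthology_policy()) {
  set.seed(seed)
  a <- sprintf("A%02d", seq_len(n_a))
  b <- sprintf("B%02d", seq_len(n_b))
  grid <- expand.grid(q = a, s = b, stringsAsFactors = FALSE)
  keep <- stats::runif(nrow(grid)) < 0.5
  grid <- grid[keep, , drop = FALSE]
  score <- stats::runif(nrow(grid), 400, 900)
  ab <- tb(query = grid$q, subject = grid$s,
           bitscore = round(score, 1),
           evalue = 10^(-round(score / 10)))
  ba <- tb(query = grid$s, subject = grid$q,
           bitscore = ab$bitscore, evalue = ab$evalue)
  list(ab = rank_hits(ab, policy), ba = rank_hits(ba, policy))
}

random_aa <- function(n) {
  paste(sample(Biostrings::AA_STANDARD, n, replace = TRUE), collapse = "")
}
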