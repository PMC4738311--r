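small_sim <- function(seed = 11, ...) {
  simulation_config(
    seed = seed, n_conserved_preys = 3, n_species_specific_preys = 3,
    n_sticky = 2, n_contaminants = 2, length_range = c(150, 250),
    n_human_units = 4, ...
  )
}

test_that("generator outputs are byte-identical under a fixed seed", {
  cfg <- small_sim()
  p1 <- generate_proteomes(cfg)
  p2 <- generate_proteomes(cfg)
  expect_identical(as.character(p1$fly), as.character(p2$fly))
  expect_identical(as.character(p1$human), as.character(p2$human))
  expect_identical(p1$truth, p2$truth)
  s1 <- simulate_ipms(cfg, p1$truth)
  s2 <- simulate_ipms(cfg, p2$truth)
  expect_identical(s1, s2)
  # and a different seed changes the data
  p3 <- generate_proteomes(small_sim(seed = 12))
  expect_false(identical(as.character(p1$fly), as.character(p3$fly)))
})

test_that("ortholog identity 1.0 yields exact sequence copies", {
  prot <- generate_proteomes(small_sim(ortholog_identity = 1.0))
  pairs <- prot$truth$ortholog_pairs
  fly <- as.character(prot$fly)[pairs$fly_accession]
  hum <- as.character(prot$human)[pairs$human_accession]
  expect_identical(unname(fly), unname(hum))
})

test_that("empirical per-site identity matches the configured fraction", {
  cfg <- simulation_config(
    seed = 5, n_conserved_preys = 10, n_species_specific_preys = 0,
    n_sticky = 0, n_contaminants = 0, ortholog_identity = 0.8,
    length_range = c(600, 600)
  )
  prot <- generate_proteomes(cfg)
  pairs <- prot$truth$ortholog_pairs
  n_sites <- 0L
  n_same <- 0L
  for (i in seq_len(nrow(pairs))) {
    f <- strsplit(as.character(prot$fly[[pairs$fly_accession[i]]]), "")[[1]]
    h <- strsplit(as.character(prot$human[[pairs$human_accession[i]]]),
                  "")[[1]]
    n_sites <- n_sites + length(f)
    n_same <- n_same + sum(f == h)
  }
  se <- sqrt(0.8 * 0.2 / n_sites)
  expect_lt(abs(n_same / n_sites - 0.8), 3 * se)
})

test_that("zero background leaves the control IPs empty", {
  cfg <- small_sim(background_rate = 0)
  prot <- generate_proteomes(cfg)
  sim <- simulate_ipms(cfg, prot$truth)
  ctl_ids <- sim$experiments$experiment_id[sim$experiments$is_control]
  expect_true(length(ctl_ids) > 0)
  expect_equal(sum(sim$evidence$experiment_id %in% ctl_ids), 0)
})

test_that("simulated counts respect the configured mean (law of large numbers)", {
  cfg <- simulation_config(
    seed = 21, n_conserved_preys = 2, n_species_specific_preys = 0,
    n_sticky = 0, n_contaminants = 0, baseline_abundance = 30,
    fly_replicates = 200, n_human_units = 1, human_replicates = 1,
    length_range = c(150, 150)
  )
  prot <- generate_proteomes(cfg)
  sim <- simulate_ipms(cfg, prot$truth)
  ex <- sim$experiments
  # the regulatory-preferring analogue prey in its preferred bait, basal:
  # 200 replicate draws at mean 30
  ids <- ex$experiment_id[ex$species == "fly" & ex$bait == "FLY_PI3K21B" &
                            ex$condition == "basal"]
  counts <- sim$evidence$spectral_counts[
    sim$evidence$experiment_id %in% ids &
      sim$evidence$accession == "FLY_CSW"
  ]
  counts <- c(counts, rep(0, length(ids) - length(counts)))
  expect_lt(abs(mean(counts) - 30), 3 * sqrt(30 / length(ids)))
  # and the insulin conditions carry the planted 3-fold stimulation
  ids_ins <- ex$experiment_id[ex$species == "fly" &
                                ex$bait == "FLY_PI3K21B" &
                                ex$condition == "insulin_10"]
  counts_ins <- sim$evidence$spectral_counts[
    sim$evidence$experiment_id %in% ids_ins &
      sim$evidence$accession == "FLY_CSW"
  ]
  counts_ins <- c(counts_ins, rep(0, length(ids_ins) - length(counts_ins)))
  expect_lt(abs(mean(counts_ins) - 90), 3 * sqrt(90 / length(ids_ins)))
})

test_that("negative-binomial counts are overdispersed relative to Poisson", {
  cfg <- simulation_config(
    seed = 31, n_conserved_preys = 2, n_species_specific_preys = 0,
    n_sticky = 0, n_contaminants = 0, baseline_abundance = 30,
    fly_replicates = 200, n_human_units = 1, human_replicates = 1,
    length_range = c(150, 150),
    count_model = "negative_binomial", dispersion = 2
  )
  prot <- generate_proteomes(cfg)
  sim <- simulate_ipms(cfg, prot$truth)
  ex <- sim$experiments
  ids <- ex$experiment_id[ex$bait == "FLY_PI3K21B" & ex$condition == "basal"]
  counts <- sim$evidence$spectral_counts[
    sim$evidence$experiment_id %in% ids &
      sim$evidence$accession == "FLY_CSW"
  ]
  counts <- c(counts, rep(0, length(ids) - length(counts)))
  # NB variance mu + mu^2/size = 480 here vs 30 for Poisson
  expect_gt(stats::var(counts), 3 * mean(counts))
})

test_that("truth tables round-trip and recovery scoring is exact set arithmetic", {
  prot <- generate_proteomes(small_sim())
  p <- tempfile(fileext = ".tsv")
  write_truth(prot$truth, p)
  back <- read_truth(p)
  expect_equal(back$conserved, prot$truth$conserved)
  expect_equal(back$ortholog_pairs, prot$truth$ortholog_pairs)

  truth <- prot$truth
  perfect <- score_recovery(truth$conserved, truth)
  expect_equal(perfect$precision, 1.0)
  expect_equal(perfect$recall, 1.0)

  with_decoy <- dplyr::bind_rows(
    truth$conserved,
    tb(fly_accession = "FLY_DECOY", human_accession = "HUM_DECOY")
  )
  sc <- score_recovery(with_decoy, truth)
  n <- nrow(truth$conserved)
  expect_equal(sc$precision, n / (n + 1))
  expect_equal(sc$recall, 1.0)

  # randomized outputs match a confusion-matrix computed by hand
  set.seed(3)
  for (i in 1:10) {
    pred <- truth$conserved[stats::runif(nrow(truth$conserved)) < 0.5, ]
    extra <- tb(fly_accession = sprintf("FX%d", seq_len(i)),
                human_accession = sprintf("HX%d", seq_len(i)))
    pred <- dplyr::bind_rows(pred, extra)
    sc <- score_recovery(pred, truth)
    tp <- sum(paste(pred$fly_accession, pred$human_accession) %in%
                paste(truth$conserved$fly_accession,
                      truth$conserved$human_accession))
    expect_equal(sc$precision, tp / nrow(pred))
    expect_equal(sc$recall, tp / nrow(truth$conserved))
  }
})

test_that("planted orthologs are recovered exactly by reciprocal best-3", {
  prot <- generate_proteomes(small_sim(seed = 41))
  hits <- align_proteomes(prot$fly, prot$human)
  pairs <- reciprocal_best_k(hits$a_to_b, hits$b_to_a)
  expect_setequal(
    paste(pairs$fly_accession, pairs$human_accession),
    paste(prot$truth$ortholog_pairs$fly_accession,
          prot$truth$ortholog_pairs$human_accession)
  )
})

test_that("degrading ortholog identity lowers RBH recall monotonically", {
  recalls <- vapply(c(0.9, 0.5, 0.25), function(id) {
    prot <- generate_proteomes(small_sim(seed = 51, ortholog_identity = id))
    hits <- align_proteomes(prot$fly, prot$human)
    pairs <- reciprocal_best_k(hits$a_to_b, hits$b_to_a)
    want <- paste(prot$truth$ortholog_pairs$fly_accession,
                  prot$truth$ortholog_pairs$human_accession)
    mean(want %in% paste(pairs$fly_accession, pairs$human_accession))
  }, numeric(1))
  expect_equal(recalls[1], 1.0)
  expect_true(all(diff(recalls) <= 0))
  expect_lt(recalls[3], 1.0)
})
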