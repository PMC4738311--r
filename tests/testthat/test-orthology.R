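pol60 <- orthology_policy() # E < 1e-60, top 3

test_that("rank_hits orders by evalue, bitscore, then subject accession", {
  hits <- tb(
    query = c("q", "q"),
    subject = c("s1", "s2"),
    bitscore = c(300, 350),
    evalue = c(1e-70, 1e-90)
  )
  r <- rank_hits(hits, pol60)
  expect_equal(r$subject[r$rank == 1], "s2")
  expect_equal(r$subject[r$rank == 2], "s1")

  ties <- tb(
    query = "q", subject = c("zzz", "aaa"),
    bitscore = c(300, 300), evalue = c(1e-80, 1e-80)
  )
  r2 <- rank_hits(ties, pol60)
  expect_equal(r2$subject[r2$rank == 1], "aaa")

  # the cutoff is strict: E exactly at the cutoff is dropped
  at_cut <- tb(query = "q", subject = "s", bitscore = 1, evalue = 1e-60)
  expect_equal(nrow(rank_hits(at_cut, pol60)), 0)
})

test_that("rank_hits agrees with a comparator-based selection sort", {
  for (seed in 1:30) {
    set.seed(seed)
    n <- 25
    hits <- tb(
      query = sample(sprintf("q%d", 1:4), n, replace = TRUE),
      subject = sample(sprintf("s%d", 1:10), n, replace = TRUE),
      bitscore = sample(seq(200, 400, by = 50), n, replace = TRUE),
      evalue = 10^-sample(c(50, 65, 70, 80), n, replace = TRUE)
    )
    hits <- unique(hits)
    got <- rank_hits(hits, pol60)
    want <- oracle_rank(hits, pol60)
    expect_equal(
      got[order(got$query, got$rank), c("query", "subject", "rank")],
      tibble::as_tibble(
        want[order(want$query, want$rank),
             c("query", "subject", "rank")]
      )
    )
  }
})

test_that("tabular hit files parse, reject bad column counts, and are order-invariant", {
  lines <- c(
    "fly1\thumA\t80.0\t200\t40\t2\t1\t200\t1\t200\t1e-80\t350",
    "fly1\thumB\t60.0\t200\t80\t2\t1\t200\t1\t200\t1e-65\t250",
    "fly2\thumA\t90.0\t300\t30\t1\t1\t300\t1\t300\t1e-120\t500"
  )
  p <- tempfile(fileext = ".tsv")
  writeLines(lines, p)
  hits <- read_blast_tabular(p, pol60)
  expect_equal(nrow(hits), 3)
  expect_equal(hits$evalue[hits$query == "fly1" & hits$subject == "humB"],
               1e-65)
  expect_equal(hits$rank[hits$query == "fly1" & hits$subject == "humA"], 1)

  p2 <- tempfile(fileext = ".tsv")
  writeLines(lines[c(3, 1, 2)], p2)
  hits2 <- read_blast_tabular(p2, pol60)
  expect_equal(
    hits[order(hits$query, hits$rank), ],
    hits2[order(hits2$query, hits2$rank), ]
  )

  p3 <- tempfile(fileext = ".tsv")
  writeLines(c(lines[1], "fly9\thumZ\tbroken"), p3)
  expect_error(read_blast_tabular(p3, pol60), "line 2",
               class = "interologr_format_error")
})

test_that("reciprocal best-k admits close paralogs like the p55/p85 variants", {
  # regulatory-subunit situation: fly query's best hit is the short splice
  # variant, second best the long isoform; both reciprocate within top 3
  hits_ab <- rank_hits(tb(
    query = "Pi3k21B",
    subject = c("P55G", "P85A", "OTHER"),
    bitscore = c(500, 450, 400),
    evalue = c(1e-150, 1e-130, 1e-100)
  ), pol60)
  hits_ba <- rank_hits(tb(
    query = c("P55G", "P85A", "OTHER"),
    subject = "Pi3k21B",
    bitscore = c(500, 450, 80),
    evalue = c(1e-150, 1e-130, 1e-10)
  ), pol60)
  pairs <- reciprocal_best_k(hits_ab, hits_ba, pol60)
  expect_setequal(pairs$human_accession, c("P55G", "P85A"))
  expect_equal(
    pairs$best_rank_fly_to_human[pairs$human_accession == "P55G"], 1
  )
  expect_equal(
    pairs$best_rank_fly_to_human[pairs$human_accession == "P85A"], 2
  )
  # OTHER fails reciprocity (its back-hit misses the E-value cutoff)
  expect_false("OTHER" %in% pairs$human_accession)
})

test_that("reciprocity is required in both directions", {
  hits_ab <- rank_hits(tb(
    query = "a1", subject = "b1", bitscore = 500, evalue = 1e-150
  ), pol60)
  # b1's own top-3 excludes a1 entirely
  hits_ba <- rank_hits(tb(
    query = "b1", subject = c("a2", "a3", "a4", "a1"),
    bitscore = c(600, 590, 580, 100),
    evalue = c(1e-170, 1e-168, 1e-165, 1e-61)
  ), pol60)
  expect_equal(nrow(reciprocal_best_k(hits_ab, hits_ba, pol60)), 0)
})

test_that("RBH matches the double-loop oracle and its set properties hold", {
  pol1 <- orthology_policy(top_k = 1)
  for (seed in 1:25) {
    h <- rand_hits(seed)
    got <- reciprocal_best_k(h$ab, h$ba, pol60)
    want <- oracle_rbh(h$ab, h$ba, pol60)
    expect_equal(as.data.frame(got[, c("fly_accession", "human_accession")]),
                 want, ignore_attr = TRUE)
    # symmetry under species swap
    swapped <- reciprocal_best_k(h$ba, h$ab, pol60)
    expect_setequal(
      paste(got$fly_accession, got$human_accession),
      paste(swapped$human_accession, swapped$fly_accession)
    )
    # classic RBH is a subset of reciprocal best-3
    rb1 <- reciprocal_best_k(h$ab, h$ba, pol1)
    expect_true(all(
      paste(rb1$fly_accession, rb1$human_accession) %in%
        paste(got$fly_accession, got$human_accession)
    ))
    expect_true(all(got$min_evalue < pol60$evalue_cutoff))
  }
})

test_that("identical proteomes self-match at rank 1", {
  set.seed(42)
  seqs <- Biostrings::AAStringSet(
    vapply(1:6, function(i) random_aa(300), character(1))
  )
  names(seqs) <- sprintf("prot%d", 1:6)
  hits <- align_proteomes(seqs, seqs, orthology_policy())
  top <- hits$a_to_b[hits$a_to_b$rank == 1, ]
  expect_equal(top$subject[match(names(seqs), top$query)], names(seqs))
  # a substituted copy scores strictly below the self-alignment
  mutant <- seqs
  m <- as.character(seqs[[1]])
  substr(m, 10, 10) <- if (substr(m, 10, 10) == "A") "W" else "A"
  mutant[[1]] <- Biostrings::AAString(m)
  h2 <- align_proteomes(seqs[1], mutant[1], orthology_policy())
  self <- hits$a_to_b$bitscore[hits$a_to_b$query == "prot1" &
                                 hits$a_to_b$subject == "prot1"]
  expect_lt(h2$a_to_b$bitscore[1], self)
})

test_that("internal aligner ranking matches an exhaustive per-pair oracle", {
  set.seed(7)
  a <- Biostrings::AAStringSet(
    vapply(1:5, function(i) random_aa(sample(200:300, 1)), character(1))
  )
  names(a) <- sprintf("a%d", 1:5)
  b <- Biostrings::AAStringSet(c(
    vapply(1:3, function(i) random_aa(sample(200:300, 1)), character(1)),
    as.character(a[[2]]) # plant one true match
  ))
  names(b) <- sprintf("b%d", 1:4)
  lax <- orthology_policy(evalue_cutoff = 1e6)
  hits <- align_proteomes(a, b, lax)
  # oracle: score every pair independently, compute E the same way, rank
  # by explicit comparator
  rows <- NULL
  for (i in seq_along(a)) {
    for (j in seq_along(b)) {
      s <- Biostrings::pairwiseAlignment(
        a[[i]], b[[j]], type = "local", substitutionMatrix = "BLOSUM62",
        gapOpening = 11, gapExtension = 1, scoreOnly = TRUE
      )
      bits <- (0.267 * s - log(0.041)) / log(2)
      rows <- rbind(rows, data.frame(
        query = names(a)[i], subject = names(b)[j], bitscore = bits,
        evalue = Biostrings::width(a)[i] * sum(Biostrings::width(b)) *
          2^(-bits)
      ))
    }
  }
  want <- oracle_rank(rows, lax)
  got <- hits$a_to_b
  expect_equal(
    got[order(got$query, got$rank), c("query", "subject", "rank")],
    tibble::as_tibble(want[order(want$query, want$rank),
                           c("query", "subject", "rank")])
  )
  # the planted identical pair is the only one under the strict cutoff
  strict <- rank_hits(got, orthology_policy())
  expect_equal(strict[, c("query", "subject")],
               tb(query = "a2", subject = "b4"))
})

test_that("aligner input validation catches empty and non-protein input", {
  expect_error(
    align_proteomes(Biostrings::AAStringSet(), Biostrings::AAStringSet("ACDE")),
    "empty", class = "interologr_validation_error"
  )
  bad <- Biostrings::AAStringSet(c(ok = "ACDEFGHIKL", bad = "ACDEX*"))
  expect_error(
    align_proteomes(bad, Biostrings::AAStringSet(c(s = "ACDEFGHIKL"))),
    "bad", class = "interologr_validation_error"
  )
})

test_that("curated pairs take precedence in the orthology merge", {
  curated <- tb(fly_accession = "cswFB", human_accession = "PTN11")
  rbh <- tb(
    fly_accession = c("cswFB", "chico"),
    human_accession = c("PTPN6", "IRS1"),
    source = "rbh",
    best_rank_fly_to_human = 1L, best_rank_human_to_fly = 1L,
    min_evalue = 1e-100
  )
  merged <- merge_orthology(curated, rbh)
  expect_setequal(
    paste(merged$fly_accession, merged$human_accession),
    c("cswFB PTN11", "chico IRS1")
  )
  expect_equal(merged$source[merged$fly_accession == "cswFB"], "curated")
  # empty curated set: the merge is the rbh set
  expect_equal(
    merge_orthology(NULL, rbh)[, c("fly_accession", "human_accession")],
    rbh[order(rbh$fly_accession), c("fly_accession", "human_accession")]
  )
})

test_that("orthology merge equals a two-pass set construction on random mixtures", {
  for (seed in 1:15) {
    set.seed(seed)
    flys <- sprintf("f%d", 1:8)
    hums <- sprintf("h%d", 1:8)
    curated <- unique(tb(
      fly_accession = sample(flys, 5, replace = TRUE),
      human_accession = sample(hums, 5, replace = TRUE)
    ))
    rbh <- unique(tb(
      fly_accession = sample(flys, 6, replace = TRUE),
      human_accession = sample(hums, 6, replace = TRUE),
      source = "rbh",
      best_rank_fly_to_human = 1L, best_rank_human_to_fly = 1L,
      min_evalue = 1e-90
    ))
    got <- suppressMessages(merge_orthology(curated, rbh))
    want <- rbind(
      data.frame(fly = curated$fly_accession, hum = curated$human_accession),
      data.frame(
        fly = rbh$fly_accession, hum = rbh$human_accession
      )[!(rbh$fly_accession %in% curated$fly_accession), ]
    )
    want <- unique(want)
    expect_setequal(paste(got$fly_accession, got$human_accession),
                    paste(want$fly, want$hum))
  }
})
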