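# Karlin-Altschul parameters for gapped BLOSUM62 (gap open 11, extend 1),
# the standard values used by protein sequence-search tools.
KA_LAMBDA <- 0.267
KA_K <- 0.041

# raw local-alignment score -> bit score / E-value for a search of a query
# of length m against a database of total length n
ka_bitscore <- function(score) (KA_LAMBDA * score - log(KA_K)) / log(2)
ka_evalue <- function(score, m, n) m * n * 2^(-ka_bitscore(score))

load_proteome <- function(x, what) {
  if (inherits(x, "AAStringSet")) {
    seqs <- x
  } else {
    if (!file.exists(x)) format_error(sprintf("file does not exist: %s", x))
    seqs <- Biostrings::readAAStringSet(x)
  }
  if (length(seqs) == 0) {
    validation_error(sprintf("%s proteome is empty", what))
  }
  # keep the accession token only (FASTA headers may carry a description)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  freqs <- Biostrings::alphabetFrequency(seqs)
  standard <- colnames(freqs) %in% Biostrings::AA_STANDARD
  nonstd <- rowSums(freqs[, !standard, drop = FALSE])
  if (any(nonstd > 0)) {
    validation_error(sprintf(
      "non-standard amino-acid characters in %s proteome record(s): %s",
      what, paste(names(seqs)[nonstd > 0], collapse = ", ")
    ))
  }
  seqs
}

#' All-vs-all local alignment of two proteomes
#'
#' Scores every sequence of proteome A against every sequence of proteome
#' B by Smith-Waterman local alignment (BLOSUM62, affine gaps: open 11,
#' extend 1) and converts raw scores to bit scores and E-values by the
#' Karlin-Altschul extreme-value approximation, with the query length and
#' total database length as the search-space size. Hits at or above the
#' policy's E-value cutoff are discarded; survivors are ranked per query
#' by [rank_hits()].
#'
#' Intended for desk-scale proteomes (hundreds of sequences); for real
#' proteome-wide searches, import a precomputed hit table with
#' [read_blast_tabular()] instead.
#'
#' @param proteome_a,proteome_b FASTA paths or `AAStringSet` objects;
#'   `proteome_a` is the fly side and `proteome_b` the human side in the
#'   downstream pair naming.
#' @param policy An [orthology_policy()].
#' @return A list of two ranked hit tibbles, `a_to_b` and `b_to_a`, each
#'   with columns `query`, `subject`, `bitscore`, `evalue`, `rank`.
#' @export
align_proteomes <- function(proteome_a, proteome_b,
                            policy = orthology_policy()) {
  a <- load_proteome(proteome_a, "first")
  b <- load_proteome(proteome_b, "second")
  # raw Smith-Waterman scores are symmetric, so one score matrix serves
  # both search directions; only the E-values differ (search-space size)
  scores <- vapply(
    seq_along(a),
    function(i) {
      Biostrings::pairwiseAlignment(
        pattern = b, subject = a[[i]], type = "local",
        substitutionMatrix = "BLOSUM62",
        gapOpening = 11, gapExtension = 1, scoreOnly = TRUE
      )
    },
    numeric(length(b))
  ) # length(b) x length(a)
  len_a <- Biostrings::width(a)
  len_b <- Biostrings::width(b)
  grid <- expand.grid(bi = seq_along(b), ai = seq_along(a))
  s <- as.vector(scores)
  hits_ab <- tibble(
    query = names(a)[grid$ai],
    subject = names(b)[grid$bi],
    bitscore = ka_bitscore(s),
    evalue = ka_evalue(s, m = len_a[grid$ai], n = sum(len_b))
  )
  hits_ba <- tibble(
    query = names(b)[grid$bi],
    subject = names(a)[grid$ai],
    bitscore = ka_bitscore(s),
    evalue = ka_evalue(s, m = len_b[grid$bi], n = sum(len_a))
  )
  list(
    a_to_b = rank_hits(hits_ab, policy),
    b_to_a = rank_hits(hits_ba, policy)
  )
}

#' Read a 12-column tabular sequence-search hit file
#'
#' Parses the standard tab-separated hit-table dialect (query, subject,
#' percent identity, alignment length, mismatches, gap opens, query
#' start/end, subject start/end, E-value, bit score) as written by
#' `blastp -outfmt 6` and compatible tools, and ranks the hits per query
#' with [rank_hits()].
#'
#' @param path Path to the tabular hit file (no header row).
#' @param policy An [orthology_policy()]; its E-value cutoff is applied
#'   during ranking.
#' @return A ranked hit tibble with columns `query`, `subject`, `pident`,
#'   `length`, `mismatches`, `gapopens`, `qstart`, `qend`, `sstart`,
#'   `send`, `evalue`, `bitscore`, `rank`.
#' @export
read_blast_tabular <- function(path, policy = orthology_policy()) {
  if (!file.exists(path)) format_error(sprintf("file does not exist: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    hits <- tibble(
      query = character(), subject = character(), pident = numeric(),
      length = integer(), mismatches = integer(), gapopens = integer(),
      qstart = integer(), qend = integer(), sstart = integer(),
      send = integer(), evalue = numeric(), bitscore = numeric()
    )
    return(rank_hits(hits, policy))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf != 12)
  if (length(bad) > 0) {
    format_error(sprintf(
      "expected 12 tab-separated columns; line %d has %d",
      bad[1], nf[bad[1]]
    ))
  }
  m <- do.call(rbind, fields)
  hits <- tibble(
    query = m[, 1],
    subject = m[, 2],
    pident = as.numeric(m[, 3]),
    length = as.integer(m[, 4]),
    mismatches = as.integer(m[, 5]),
    gapopens = as.integer(m[, 6]),
    qstart = as.integer(m[, 7]),
    qend = as.integer(m[, 8]),
    sstart = as.integer(m[, 9]),
    send = as.integer(m[, 10]),
    evalue = as.numeric(m[, 11]),
    bitscore = as.numeric(m[, 12])
  )
  if (anyNA(hits$evalue) || anyNA(hits$bitscore)) {
    validation_error("non-numeric evalue or bitscore field in hit table")
  }
  rank_hits(hits, policy)
}

#' Rank sequence-search hits per query
#'
#' Drops hits whose E-value is at or above the policy cutoff, then sorts
#' the survivors within each query by ascending E-value, descending bit
#' score, and finally lexicographic subject accession (a deterministic
#' tie-break), assigning ranks 1..n per query.
#'
#' @param hits Hit tibble with at least `query`, `subject`, `evalue`,
#'   `bitscore`.
#' @param policy An [orthology_policy()].
#' @return The filtered hits with a `rank` column, ordered by query then
#'   rank.
#' @export
rank_hits <- function(hits, policy = orthology_policy()) {
  hits <- hits[hits$evalue < policy$evalue_cutoff, , drop = FALSE]
  ord <- order(hits$query, hits$evalue, -hits$bitscore, hits$subject,
               method = "radix")
  hits <- hits[ord, , drop = FALSE]
  hits$rank <- stats::ave(seq_len(nrow(hits)), hits$query,
                          FUN = seq_along)
  if (nrow(hits) == 0) hits$rank <- integer(0)
  as_tibble(hits)
}

#' Reciprocal best-k-hits ortholog pairing
#'
#' Calls (fly, human) a candidate ortholog pair when the human protein is
#' within the fly protein's `top_k` best hits *and* the fly protein is
#' within the human protein's `top_k` best hits, both under the E-value
#' cutoff. With `top_k > 1` the mapping is deliberately many-to-many, so
#' close paralogs and splice variants (e.g. the p55/p85 regulatory-subunit
#' variants) are all retained as candidates.
#'
#' @param hits_ab Ranked hits with fly queries and human subjects (the
#'   `a_to_b` element of [align_proteomes()]).
#' @param hits_ba Ranked hits with human queries and fly subjects.
#' @param policy An [orthology_policy()].
#' @return A pair tibble with columns `fly_accession`, `human_accession`,
#'   `source` (`"rbh"`), `best_rank_fly_to_human`, `best_rank_human_to_fly`
#'   and `min_evalue`, sorted by fly then human accession.
#' @export
reciprocal_best_k <- function(hits_ab, hits_ba,
                              policy = orthology_policy()) {
  k <- policy$top_k
  fwd <- hits_ab[hits_ab$rank <= k & hits_ab$evalue < policy$evalue_cutoff,
                 c("query", "subject", "rank", "evalue")]
  rev <- hits_ba[hits_ba$rank <= k & hits_ba$evalue < policy$evalue_cutoff,
                 c("query", "subject", "rank", "evalue")]
  names(fwd) <- c("fly_accession", "human_accession",
                  "best_rank_fly_to_human", "evalue_fwd")
  names(rev) <- c("human_accession", "fly_accession",
                  "best_rank_human_to_fly", "evalue_rev")
  pairs <- dplyr::inner_join(fwd, rev,
                             by = c("fly_accession", "human_accession"))
  pairs$min_evalue <- pmin(pairs$evalue_fwd, pairs$evalue_rev)
  pairs$source <- "rbh"
  pairs <- pairs[order(pairs$fly_accession, pairs$human_accession), ]
  as_tibble(pairs[, c("fly_accession", "human_accession", "source",
                      "best_rank_fly_to_human", "best_rank_human_to_fly",
                      "min_evalue")])
}

#' Merge curated and reciprocal-best-hit ortholog pairs
#'
#' Curated pairs always win: every curated pair is retained, and
#' sequence-derived (rbh) pairs are added only for fly accessions that do
#' not appear in any curated pair — sequence search fills the gaps the
#' curated databases leave, it never overrides them. Duplicate pairs
#' collapse to curated provenance.
#'
#' @param curated Pair tibble with `fly_accession`, `human_accession`
#'   (source forced to `"curated"`).
#' @param rbh Pair tibble as returned by [reciprocal_best_k()].
#' @return The merged pair tibble, sorted by fly then human accession.
#' @export
merge_orthology <- function(curated, rbh) {
  template <- tibble(
    fly_accession = character(), human_accession = character(),
    source = character(),
    best_rank_fly_to_human = integer(), best_rank_human_to_fly = integer(),
    min_evalue = numeric()
  )
  norm <- function(p, src) {
    if (is.null(p) || nrow(p) == 0) return(template)
    out <- tibble(
      fly_accession = as.character(p$fly_accession),
      human_accession = as.character(p$human_accession),
      source = if (is.null(src)) as.character(p$source) else src,
      best_rank_fly_to_human =
        if ("best_rank_fly_to_human" %in% names(p))
          as.integer(p$best_rank_fly_to_human) else NA_integer_,
      best_rank_human_to_fly =
        if ("best_rank_human_to_fly" %in% names(p))
          as.integer(p$best_rank_human_to_fly) else NA_integer_,
      min_evalue =
        if ("min_evalue" %in% names(p)) as.numeric(p$min_evalue) else NA_real_
    )
    dplyr::distinct(out, .data$fly_accession, .data$human_accession,
                    .keep_all = TRUE)
  }
  cur <- norm(curated, "curated")
  seq <- norm(rbh, NULL)
  drop <- seq$fly_accession %in% cur$fly_accession
  if (any(drop)) {
    contradictory <- dplyr::semi_join(
      seq[drop, ], cur, by = c("fly_accession", "human_accession")
    )
    if (nrow(contradictory) > 0) {
      inform(sprintf(
        "%d pair(s) present with both curated and rbh provenance; keeping curated",
        nrow(contradictory)
      ))
    }
  }
  out <- dplyr::bind_rows(cur, seq[!drop, , drop = FALSE])
  out[order(out$fly_accession, out$human_accession), ]
}

#' Read / write ortholog pair tables
#'
#' `read_ortholog_pairs()` consumes a curated two-column TSV
#' (`fly_accession`, `human_accession`; extra columns ignored) such as a
#' flattened HomoloGene/InParanoid export, tagging every pair as curated.
#' `write_ortholog_pairs()` serialises a merged pair table with its
#' provenance columns.
#'
#' @param path TSV path.
#' @param pairs Pair tibble as produced by [merge_orthology()].
#' @return A pair tibble (read); `path` invisibly (write).
#' @export
read_ortholog_pairs <- function(path) {
  tab <- read_tsv_strict(path, c("fly_accession", "human_accession"))
  merge_orthology(tab, NULL)
}

#' @rdname read_ortholog_pairs
#' @export
write_ortholog_pairs <- function(pairs, path) {
  write_tsv_plain(pairs, path)
}
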