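# Independent brute-force oracles and fixture builders shared by the tests.
# The oracles deliberately use plain position-by-position loops, not the
# package's vectorised code paths.

# minimal spliced-cdna object for in-memory sequences
make_cdna <- function(seq, morf_start, morf_end = NULL, id = "tx") {
  if (is.null(morf_end)) morf_end <- nchar(seq)
  structure(list(transcript_id = id, gene_id = id, seq = seq,
                 morf_start = as.integer(morf_start),
                 morf_end = as.integer(morf_end),
                 gmap = seq_len(nchar(seq)) - 1L,
                 inserted = rep(FALSE, nchar(seq)),
                 strand = "+", contig = id),
            class = "spliced_cdna")
}

# brute-force ORF scanner: walk every leader position, test start-codon
# membership, then translate codon by codon in a while loop
oracle_uorfs <- function(seq, morf_start, morf_end,
                         start_codons = "ATG") {
  stops <- c("TAA", "TAG", "TGA")
  n <- nchar(seq)
  out <- list()
  p <- 0L
  while (p < morf_start) {
    codon <- substr(seq, p + 1L, p + 3L)
    if (nchar(codon) == 3L && codon %in% start_codons) {
      q <- p
      stop_end <- NA_integer_
      while (q + 3L <= n) {
        c2 <- substr(seq, q + 1L, q + 3L)
        if (c2 %in% stops) { stop_end <- q + 3L; break }
        q <- q + 3L
      }
      type <- if (is.na(stop_end)) "unterminated"
        else if (stop_end <= morf_start) "Type1"
        else if ((morf_start - p) %% 3L == 0L && stop_end == morf_end) "Type3"
        else "Type2"
      out[[length(out) + 1L]] <-
        data.frame(start = p, stop_end = stop_end, type = type,
                   length_nt = if (is.na(stop_end)) n - p else stop_end - p,
                   stringsAsFactors = FALSE)
    }
    p <- p + 1L
  }
  if (!length(out))
    return(data.frame(start = integer(), stop_end = integer(),
                      type = character(), length_nt = integer()))
  do.call(rbind, out)
}

# random cDNA with a random in-bounds mORF frame
random_cdna <- function(max_len = 500L) {
  len <- sample(30:max_len, 1L)
  seq <- paste0(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                collapse = "")
  morf_start <- sample(3:(len - 9L), 1L)
  k <- sample.int((len - morf_start) %/% 3L, 1L)
  list(seq = seq, morf_start = morf_start, morf_end = morf_start + 3L * k)
}

# brute-force identifier oracle: repeatedly extract the minimal Level1 group
# under (anchor, length, origin rank), then number members by (n_snps,
# snp positions, sequence) via pairwise comparison
oracle_identifiers <- function(forms) {
  rank_of <- c("reference-identical" = 0, "SNP-only" = 0,
               "deletion-bearing" = 1, "insertion-bearing" = 2)
  key <- data.frame(anchor = forms$anchor, len = forms$length_nt,
                    rk = rank_of[forms$origin_class])
  groups <- unique(key)
  # selection sort of groups
  g_order <- integer()
  left <- seq_len(nrow(groups))
  while (length(left)) {
    best <- left[1L]
    for (j in left) {
      if (groups$anchor[j] < groups$anchor[best] ||
          (groups$anchor[j] == groups$anchor[best] &&
             (groups$len[j] < groups$len[best] ||
                (groups$len[j] == groups$len[best] &&
                   groups$rk[j] < groups$rk[best])))) best <- j
    }
    g_order <- c(g_order, best)
    left <- setdiff(left, best)
  }
  ids <- character(nrow(forms))
  for (gi in seq_along(g_order)) {
    gk <- groups[g_order[gi], ]
    member <- which(key$anchor == gk$anchor & key$len == gk$len &
                      key$rk == gk$rk)
    lt <- function(i, j) {
      if (forms$n_snps[i] != forms$n_snps[j])
        return(forms$n_snps[i] < forms$n_snps[j])
      if (forms$snp_positions[i] != forms$snp_positions[j])
        return(forms$snp_positions[i] < forms$snp_positions[j])
      forms$sequence[i] < forms$sequence[j]
    }
    remaining <- member
    l2 <- 1L
    while (length(remaining)) {
      m <- remaining[1L]
      for (j in remaining) if (lt(j, m)) m <- j
      ids[m] <- sprintf("%d.%d", gi, l2)
      remaining <- setdiff(remaining, m)
      l2 <- l2 + 1L
    }
  }
  ids
}

# one shared small fixture universe per test run
fixture_universe <- local({
  cache <- NULL
  function(n_genes = 10L, n_accessions = 20L, seed = 7L) {
    if (!is.null(cache)) return(cache)
    dir <- file.path(tempdir(), "uorfvar-fixture")
    truth <- generate_fixture(
      fixture_config(n_genes = n_genes, n_accessions = n_accessions,
                     seed = seed), dir)
    cache <<- list(dir = dir, truth = truth,
                   fasta = file.path(dir, "genome.fa"),
                   gff3 = file.path(dir, "annotation.gff3"),
                   vcf = file.path(dir, "variants.vcf"),
                   metadata = file.path(dir, "metadata.tsv"))
    cache
  }
})
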