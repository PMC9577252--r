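# shared fixtures and independent oracles for the test suite

# default-design bundle, generated once per session
.fixture_cache <- new.env(parent = emptyenv())
shared_sim <- function() {
  if (is.null(.fixture_cache$sim))
    .fixture_cache$sim <- simulate_bundle(sim_config(seed = 20240917))
  .fixture_cache$sim
}

# small, fast design for bookkeeping tests
small_config <- function(seed = 1, ...) {
  sim_config(
    seed = seed, n_coding_genes = 12,
    n_lnc_per_class = c(lincRNA = 2, antisense = 1, sense_overlapping = 1,
                        sense_intronic = 1),
    n_housekeeping = 2, n_single_exon_noise = 4, n_coding_like_decoys = 2,
    n_modules = 0, n_cultivars = 1,
    de_pattern_counts = c(up_down = 1, down_up = 1, single_transition = 1),
    n_below_floor = 0, n_coexpr_pairs = 2, chrom_length_bp = 1e6, ...)
}

# brute-force longest-ORF oracle: enumerate every (ATG, next in-frame stop)
orf_oracle <- function(s) {
  n <- nchar(s)
  best <- list(aa_length = 0L, frame = NA_integer_, start = NA_integer_)
  i <- 1L
  while (i + 5L <= n) {
    if (substr(s, i, i + 2) == "ATG") {
      j <- i + 3L
      while (j + 2L <= n) {
        cd <- substr(s, j, j + 2)
        if (cd %in% c("TAA", "TAG", "TGA")) {
          aa <- as.integer((j - i) / 3)
          if (aa > best$aa_length)
            best <- list(aa_length = aa, frame = (i - 1L) %% 3L, start = i)
          break
        }
        j <- j + 3L
      }
    }
    i <- i + 1L
  }
  best
}

random_seq <- function(n, alphabet = c("A", "C", "G", "T"))
  paste(sample(alphabet, n, replace = TRUE), collapse = "")

# build a transcript_set from a compact spec list:
# list(list(id, gene, strand, starts, ends, [seq]), ...)
make_ts <- function(spec, chrom = "chr1") {
  if (!length(spec)) {
    gr <- GenomicRanges::GRanges()
    gr$transcript_id <- character(0)
    gr$gene_id <- character(0)
    return(transcript_set(gr))
  }
  rows <- do.call(rbind, lapply(spec, function(x)
    data.frame(start = x$starts, end = x$ends, strand = x$strand,
               transcript_id = x$id,
               gene_id = if (is.null(x$gene)) paste0("g_", x$id) else x$gene,
               stringsAsFactors = FALSE)))
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(rows$start, rows$end),
                               strand = rows$strand)
  gr$transcript_id <- rows$transcript_id
  gr$gene_id <- rows$gene_id
  seqs <- Filter(Negate(is.null), lapply(spec, function(x) x$seq))
  names(seqs) <- vapply(Filter(function(x) !is.null(x$seq), spec),
                        function(x) x$id, character(1))
  transcript_set(gr, if (length(seqs))
    Biostrings::DNAStringSet(unlist(seqs)) else NULL)
}

# build a gene_annotation from list(list(id, biotype, strand,
# starts, ends), ...); gene span = exon hull
make_ann <- function(spec, chrom = "chr1") {
  g <- do.call(rbind, lapply(spec, function(x)
    data.frame(gene_id = x$id, biotype = x$biotype, strand = x$strand,
               start = min(x$starts), end = max(x$ends),
               stringsAsFactors = FALSE)))
  e <- do.call(rbind, lapply(spec, function(x)
    data.frame(gene_id = x$id, strand = x$strand,
               start = x$starts, end = x$ends, stringsAsFactors = FALSE)))
  gg <- GenomicRanges::GRanges(chrom, IRanges::IRanges(g$start, g$end),
                               strand = g$strand)
  gg$gene_id <- g$gene_id; gg$biotype <- g$biotype
  ee <- GenomicRanges::GRanges(chrom, IRanges::IRanges(e$start, e$end),
                               strand = e$strand)
  ee$gene_id <- e$gene_id
  ee$biotype <- g$biotype[match(e$gene_id, g$gene_id)]
  gene_annotation(gg, ee)
}

# brute-force positional classification of one lncRNA against plain tables
classify_oracle <- function(lnc_exons, lnc_strand, genes) {
  # genes: list of list(strand, starts, ends) (protein-coding only)
  anti <- FALSE; sens <- FALSE; within <- FALSE
  l_lo <- min(lnc_exons$start); l_hi <- max(lnc_exons$end)
  for (g in genes) {
    for (k in seq_along(g$starts)) {
      for (j in seq_len(nrow(lnc_exons))) {
        ov <- min(lnc_exons$end[j], g$ends[k]) >=
          max(lnc_exons$start[j], g$starts[k])
        if (ov) {
          if (g$strand == lnc_strand) sens <- TRUE else anti <- TRUE
        }
      }
    }
    if (l_lo >= min(g$starts) && l_hi <= max(g$ends)) within <- TRUE
  }
  if (anti) "antisense"
  else if (sens) "sense_overlapping"
  else if (within) "sense_intronic"
  else "lincRNA"
}

# double-loop TOM oracle
tom_oracle <- function(a) {
  n <- nrow(a)
  k <- rowSums(a)
  tom <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    l <- 0
    for (u in seq_len(n)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
    tom[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  tom
}

# clustering-recovery metric
ari <- function(x, y) mclust::adjustedRandIndex(x, y)
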