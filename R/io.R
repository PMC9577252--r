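#' Transcript set container
#'
#' Bundles a set of assembled transcript models: a per-transcript summary
#' table, the exon intervals as a [GenomicRanges::GRanges] (one row per exon,
#' carrying `transcript_id`/`gene_id`), and optionally the sense-strand
#' sequences as a [Biostrings::DNAStringSet] named by transcript id.
#'
#' Exons of one transcript must share chromosome and strand, must not overlap
#' one another, and are stored sorted by start. When sequences are supplied,
#' each sequence length must equal the transcript's summed exon width.
#'
#' @param exons `GRanges` of exons with metadata columns `transcript_id` and
#'   `gene_id`.
#' @param sequences optional named `DNAStringSet` (or named character vector)
#'   of sense-strand transcript sequences over the alphabet A/C/G/T/N.
#' @return An object of class `transcript_set` with elements `transcripts`
#'   (data.frame: transcript_id, gene_id, chrom, strand, start, end, n_exons,
#'   length), `exons` (`GRanges`) and `sequences` (`DNAStringSet` or `NULL`).
#' @export
transcript_set <- function(exons, sequences = NULL) {
  stopifnot(methods::is(exons, "GRanges"))
  if (!all(c("transcript_id", "gene_id") %in% names(S4Vectors::mcols(exons))))
    stop("exons must carry 'transcript_id' and 'gene_id' metadata columns")
  exons <- exons[order(exons$transcript_id, GenomicRanges::start(exons))]
  tid <- exons$transcript_id
  ex_chrom <- as.character(GenomicRanges::seqnames(exons))
  ex_strand <- as.character(GenomicRanges::strand(exons))
  ex_start <- GenomicRanges::start(exons)
  ex_end <- GenomicRanges::end(exons)
  ex_gene <- as.character(exons$gene_id)
  by_tx <- split(seq_along(exons), tid)

  chrom <- vapply(by_tx, function(i) {
    ch <- unique(ex_chrom[i])
    if (length(ch) != 1L) stop("transcript with exons on multiple chromosomes")
    ch
  }, character(1))
  strand <- vapply(by_tx, function(i) {
    st <- unique(ex_strand[i])
    if (length(st) != 1L)
      stop("validation error: transcript with exons on mixed strands: ",
           tid[i[1]])
    st
  }, character(1))
  start <- vapply(by_tx, function(i) min(ex_start[i]), numeric(1))
  end <- vapply(by_tx, function(i) max(ex_end[i]), numeric(1))
  len <- vapply(by_tx, function(i) sum(ex_end[i] - ex_start[i] + 1), numeric(1))
  n_ex <- vapply(by_tx, length, integer(1))
  gene <- vapply(by_tx, function(i) ex_gene[i[1]], character(1))

  for (i in by_tx) {
    if (length(i) > 1L) {
      s <- ex_start[i]; e <- ex_end[i]
      if (any(s[-1] <= e[-length(e)]))
        stop("validation error: overlapping exons within transcript ", tid[i[1]])
    }
  }

  tx <- data.frame(
    transcript_id = names(by_tx), gene_id = gene, chrom = chrom,
    strand = strand, start = start, end = end,
    n_exons = n_ex, length = len,
    stringsAsFactors = FALSE, row.names = NULL
  )

  if (!is.null(sequences)) {
    if (!methods::is(sequences, "DNAStringSet"))
      sequences <- Biostrings::DNAStringSet(toupper(sequences))
    if (is.null(names(sequences)) || anyDuplicated(names(sequences)))
      stop("sequences must be uniquely named by transcript id")
    common <- intersect(tx$transcript_id, names(sequences))
    bad <- common[Biostrings::width(sequences[common]) !=
                    tx$length[match(common, tx$transcript_id)]]
    if (length(bad))
      stop("sequence length != exon-union length for: ",
           paste(utils::head(bad, 5), collapse = ", "))
  }

  structure(list(transcripts = tx, exons = exons, sequences = sequences),
            class = "transcript_set")
}

#' @export
print.transcript_set <- function(x, ...) {
  cat("<transcript_set> ", nrow(x$transcripts), " transcripts, ",
      length(x$exons), " exons",
      if (!is.null(x$sequences)) paste0(", ", length(x$sequences), " sequences"),
      "\n", sep = "")
  invisible(x)
}

#' @export
length.transcript_set <- function(x) nrow(x$transcripts)

#' Subset a transcript set by transcript ids
#'
#' @param ts a `transcript_set`.
#' @param ids character vector of transcript ids to keep (order preserved
#'   as in `ts`).
#' @return A `transcript_set` restricted to `ids`.
#' @export
subset_transcripts <- function(ts, ids) {
  keep_tx <- ts$transcripts[ts$transcripts$transcript_id %in% ids, , drop = FALSE]
  ex <- ts$exons[ts$exons$transcript_id %in% ids]
  sq <- ts$sequences
  if (!is.null(sq)) sq <- sq[names(sq) %in% ids]
  structure(list(transcripts = keep_tx, exons = ex, sequences = sq),
            class = "transcript_set")
}

#' Transcript spans as a GRanges
#'
#' One range per transcript (the full genomic span from first to last exon),
#' named by transcript id.
#'
#' @param ts a `transcript_set`.
#' @return `GRanges` named by transcript id.
#' @export
transcript_spans <- function(ts) {
  tx <- ts$transcripts
  gr <- GenomicRanges::GRanges(
    seqnames = tx$chrom,
    ranges = IRanges::IRanges(start = tx$start, end = tx$end),
    strand = tx$strand
  )
  names(gr) <- tx$transcript_id
  gr$transcript_id <- tx$transcript_id
  gr$gene_id <- tx$gene_id
  gr
}

#' Gene annotation container
#'
#' Reference genes with a closed biotype vocabulary and their exon structure.
#' Biotypes outside the vocabulary are mapped to `"other"` (treated as
#' neither coding nor housekeeping downstream).
#'
#' @param genes `GRanges` with metadata columns `gene_id` and `biotype`.
#' @param exons `GRanges` with metadata columns `gene_id` and `biotype`;
#'   every exon must lie within its gene's interval.
#' @return An object of class `gene_annotation`.
#' @export
gene_annotation <- function(genes, exons) {
  stopifnot(methods::is(genes, "GRanges"), methods::is(exons, "GRanges"))
  vocab <- c("protein_coding", "rRNA", "tRNA", "snRNA", "snoRNA", "lncRNA", "other")
  genes$biotype <- ifelse(genes$biotype %in% vocab, genes$biotype, "other")
  exons$biotype <- genes$biotype[match(exons$gene_id, genes$gene_id)]
  m <- match(exons$gene_id, genes$gene_id)
  if (anyNA(m)) stop("exon with gene_id absent from gene table")
  inside <- GenomicRanges::start(exons) >= GenomicRanges::start(genes)[m] &
    GenomicRanges::end(exons) <= GenomicRanges::end(genes)[m]
  if (!all(inside)) stop("exon outside its gene interval")
  structure(list(genes = genes, exons = exons), class = "gene_annotation")
}

#' @export
print.gene_annotation <- function(x, ...) {
  cat("<gene_annotation> ", length(x$genes), " genes (",
      paste(names(table(x$genes$biotype)), table(x$genes$biotype),
            sep = ":", collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Read transcript models from a GTF file
#'
#' Parses exon features (GTF 2.2 dialect, `transcript_id`/`gene_id`
#' attributes) and assembles one [transcript_set]. Parsing is delegated to
#' [rtracklayer::import()]; coordinates stay in the 1-based closed convention
#' used throughout the package.
#'
#' @param path GTF file path.
#' @param sequences optional `DNAStringSet`/named character of transcript
#'   sequences to attach.
#' @return A `transcript_set`.
#' @export
read_transcripts_gtf <- function(path, sequences = NULL) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (length(gr) == 0L)
    return(transcript_set(GenomicRanges::GRanges(
      transcript_id = character(), gene_id = character()), sequences))
  if (is.null(gr$transcript_id) || anyNA(gr$transcript_id))
    stop("parse error: exon feature without transcript_id attribute in ", path)
  ex <- GenomicRanges::granges(gr)
  ex$transcript_id <- gr$transcript_id
  ex$gene_id <- if (!is.null(gr$gene_id)) gr$gene_id else gr$transcript_id
  transcript_set(ex, sequences)
}

#' Write transcript models to a GTF file
#'
#' Emits transcript and exon features; `read_transcripts_gtf()` on the result
#' reproduces the input structure exactly (coordinates, strands, exon
#' grouping).
#'
#' @param ts a `transcript_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_transcripts_gtf <- function(ts, path) {
  ex <- ts$exons
  ex$type <- "exon"
  tx <- transcript_spans(ts)
  tx$type <- "transcript"
  out <- c(tx, ex)
  out$source <- "lncscent"
  rtracklayer::export(out, path, format = "gtf")
  invisible(path)
}

#' Read transcript sequences from a FASTA file
#'
#' Sequences are upper-cased; ids must be unique; characters outside
#' A/C/G/T/N are rejected.
#'
#' @param path FASTA file path.
#' @return A named `DNAStringSet`.
#' @export
read_transcript_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs)))
    stop("duplicate sequence id in ", path)
  if (length(seqs)) {
    seqs <- Biostrings::DNAStringSet(toupper(as.character(seqs)))
    freqs <- Biostrings::alphabetFrequency(seqs)
    ok <- c("A", "C", "G", "T", "N")
    bad <- rowSums(freqs[, !(colnames(freqs) %in% ok), drop = FALSE]) > 0
    if (any(bad))
      stop("non-ACGTN characters in sequences: ",
           paste(utils::head(names(seqs)[bad], 5), collapse = ", "))
  }
  seqs
}

#' Read a gene annotation from a GFF3 file
#'
#' Expects `gene` features carrying `ID` (or `gene_id`) and `biotype`
#' attributes and `exon` features carrying `Parent`.
#'
#' @param path GFF3 file path.
#' @return A `gene_annotation`.
#' @export
read_annotation_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  genes <- gr[gr$type == "gene"]
  g <- GenomicRanges::granges(genes)
  g$gene_id <- if (!is.null(genes$gene_id) && !anyNA(genes$gene_id))
    genes$gene_id else as.character(genes$ID)
  g$biotype <- if (!is.null(genes$biotype)) as.character(genes$biotype) else "other"
  ex_raw <- gr[gr$type == "exon"]
  e <- GenomicRanges::granges(ex_raw)
  parent <- as.character(S4Vectors::unstrsplit(ex_raw$Parent, ","))
  e$gene_id <- parent
  e$biotype <- g$biotype[match(parent, g$gene_id)]
  gene_annotation(g, e)
}

#' Write a gene annotation to a GFF3 file
#'
#' @param ann a `gene_annotation`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotation_gff3 <- function(ann, path) {
  g <- ann$genes
  g$type <- "gene"
  g$ID <- g$gene_id
  e <- ann$exons
  e$type <- "exon"
  e$Parent <- e$gene_id
  out <- c(g, e)
  out$source <- "lncscent"
  rtracklayer::export(out, path, format = "gff3")
  invisible(path)
}

#' Read a protein-alignment hit table
#'
#' Tab-separated with columns `transcript_id`, `subject_id`, `identity_pct`,
#' `coverage_pct`, `p_value` (BLAST-style tabular order extended with an
#' explicit query-coverage column). One hit per line.
#'
#' @param path TSV path.
#' @return data.frame with those five columns.
#' @export
read_hit_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("transcript_id", "subject_id", "identity_pct", "coverage_pct", "p_value")
  if (!all(need %in% names(df)))
    stop("hit table must have columns: ", paste(need, collapse = ", "))
  df <- df[, need]
  if (nrow(df) && (any(df$identity_pct < 0) || any(df$coverage_pct < 0)))
    stop("validation error: negative identity or coverage in hit table")
  df
}

#' Read an expression matrix with sample metadata
#'
#' The matrix TSV has transcript ids in the first column and sample ids as
#' the header; the metadata TSV has columns `sample_id`, `cultivar`, `stage`,
#' `replicate`. Values must be non-negative (FPKM scale); stages are
#' restricted to the levels present in `stages`.
#'
#' @param expr_path expression TSV path.
#' @param meta_path sample-metadata TSV path.
#' @param stages allowed stage labels.
#' @return list with `values` (numeric matrix transcripts x samples) and
#'   `sample_meta` (data.frame).
#' @export
read_expression <- function(expr_path, meta_path,
                            stages = c("EF", "SF", "LF")) {
  df <- utils::read.table(expr_path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  ids <- df[[1]]
  if (anyDuplicated(ids)) stop("duplicate transcript ids in expression matrix")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- ids
  if (any(m < 0)) stop("negative expression values")
  meta <- utils::read.table(meta_path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  need <- c("sample_id", "cultivar", "stage", "replicate")
  if (!all(need %in% names(meta)))
    stop("sample metadata must have columns: ", paste(need, collapse = ", "))
  if (!all(colnames(m) %in% meta$sample_id))
    stop("sample without metadata: ",
         paste(setdiff(colnames(m), meta$sample_id), collapse = ", "))
  if (!all(meta$stage %in% stages))
    stop("unknown stage label in metadata")
  meta <- meta[match(colnames(m), meta$sample_id), , drop = FALSE]
  list(values = m, sample_meta = meta)
}

#' Read a GC-MS peak table
#'
#' Long format with columns `sample_id`, `compound`, `peak_area`,
#' `is_peak_area`, `is_concentration`, `is_volume`, `sample_mass`,
#' `extraction_time` (internal-standard fields: concentration in ug/uL,
#' volume in uL, mass in g, time in h).
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_gcms_peaks <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("sample_id", "compound", "peak_area", "is_peak_area",
            "is_concentration", "is_volume", "sample_mass", "extraction_time")
  if (!all(need %in% names(df)))
    stop("GC-MS peak table must have columns: ", paste(need, collapse = ", "))
  df
}

#' Read a compound-to-class map
#'
#' Columns `compound`, `class` with class in terpenoid /
#' phenylpropanoid_benzenoid / fatty_acid_derivative / non_scent.
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_compound_classes <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("compound", "class") %in% names(df)))
    stop("compound class table must have columns compound, class")
  ok <- c("terpenoid", "phenylpropanoid_benzenoid", "fatty_acid_derivative",
          "non_scent")
  if (!all(df$class %in% ok))
    stop("unknown compound class: ",
         paste(setdiff(df$class, ok), collapse = ", "))
  df
}

#' Filter criteria for the identification cascade
#'
#' Houses every constant of the five-filter cascade: the minimum transcript
#' length (kept if `length >= min_length_nt`), the ORF ceiling (kept if
#' longest ORF `< max_orf_aa`), the exon floor (kept if exons
#' `>= min_exons`), the protein-alignment exclusion thresholds (excluded if
#' a hit has `p < coding_hit_max_p` AND `identity > coding_hit_min_identity_pct`
#' AND `coverage > coding_hit_min_coverage_pct`, all strict), the Pfam
#' E-value ceiling (excluded if `E <= pfam_evalue_max`) and the
#' coding-potential ceiling (kept if `score < cpc_score_max`).
#'
#' @param min_length_nt minimum transcript length in nt.
#' @param max_orf_aa exclusive ORF-length bound in amino acids.
#' @param min_exons minimum exon count.
#' @param coding_hit_max_p alignment p-value bound (strict `<` to exclude).
#' @param coding_hit_min_identity_pct identity bound in percent (strict `>`).
#' @param coding_hit_min_coverage_pct coverage bound in percent (strict `>`).
#' @param pfam_evalue_max Pfam E-value ceiling (exclude at `<=`).
#' @param cpc_score_max coding-potential ceiling (keep at strict `<`).
#' @return list of class `filter_criteria`.
#' @export
filter_criteria <- function(min_length_nt = 200,
                            max_orf_aa = 100,
                            min_exons = 2,
                            coding_hit_max_p = 1.0e-10,
                            coding_hit_min_identity_pct = 90,
                            coding_hit_min_coverage_pct = 80,
                            pfam_evalue_max = 1e-5,
                            cpc_score_max = 0) {
  stopifnot(min_length_nt > 0, max_orf_aa > 0, min_exons >= 1,
            coding_hit_max_p > 0, pfam_evalue_max > 0)
  structure(list(
    min_length_nt = min_length_nt, max_orf_aa = max_orf_aa,
    min_exons = min_exons, coding_hit_max_p = coding_hit_max_p,
    coding_hit_min_identity_pct = coding_hit_min_identity_pct,
    coding_hit_min_coverage_pct = coding_hit_min_coverage_pct,
    pfam_evalue_max = pfam_evalue_max, cpc_score_max = cpc_score_max
  ), class = "filter_criteria")
}
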