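HOUSEKEEPING_BIOTYPES <- c("rRNA", "tRNA", "snRNA", "snoRNA")

#' Remove transcripts overlapping housekeeping ncRNA exons
#'
#' A transcript is removed if any of its exons overlaps (>= 1 bp, either
#' strand) an exon of an annotated rRNA, tRNA, snRNA or snoRNA gene.
#' Abutting intervals do not overlap.
#'
#' @param ts a `transcript_set`.
#' @param annotation a `gene_annotation`.
#' @return list with `kept` and `removed` (both `transcript_set`s) and
#'   `removed_ids`.
#' @export
filter_housekeeping <- function(ts, annotation) {
  hk <- annotation$exons[annotation$exons$biotype %in% HOUSEKEEPING_BIOTYPES]
  hits <- GenomicRanges::findOverlaps(ts$exons, hk, ignore.strand = TRUE)
  removed_ids <- unique(ts$exons$transcript_id[S4Vectors::queryHits(hits)])
  kept_ids <- setdiff(ts$transcripts$transcript_id, removed_ids)
  list(kept = subset_transcripts(ts, kept_ids),
       removed = subset_transcripts(ts, removed_ids),
       removed_ids = removed_ids)
}

#' Keep transcripts with at least `min_exons` exons
#'
#' Single-exon transcripts are filtered out at the default `min_exons = 2`
#' (low assembly reliability).
#'
#' @param ts a `transcript_set`.
#' @param min_exons exon floor (kept at `>=`).
#' @return list with `kept`, `removed`, `removed_ids`.
#' @export
filter_exon_count <- function(ts, min_exons = 2) {
  tx <- ts$transcripts
  removed_ids <- tx$transcript_id[tx$n_exons < min_exons]
  list(kept = subset_transcripts(ts, setdiff(tx$transcript_id, removed_ids)),
       removed = subset_transcripts(ts, removed_ids),
       removed_ids = removed_ids)
}

#' Remove transcripts with a qualifying protein alignment
#'
#' A transcript is excluded iff at least one hit satisfies all three strict
#' inequalities: `p < coding_hit_max_p`, `identity >
#' coding_hit_min_identity_pct` and `coverage > coding_hit_min_coverage_pct`.
#' A hit at identity exactly 90 (default) does not exclude.
#'
#' @param ts a `transcript_set`.
#' @param hits hit table as from [read_hit_table()].
#' @param criteria a [filter_criteria()].
#' @return list with `kept`, `removed`, `removed_ids`.
#' @export
filter_coding_hits <- function(ts, hits, criteria = filter_criteria()) {
  qualifying <- hits[hits$p_value < criteria$coding_hit_max_p &
                       hits$identity_pct > criteria$coding_hit_min_identity_pct &
                       hits$coverage_pct > criteria$coding_hit_min_coverage_pct, ]
  removed_ids <- intersect(ts$transcripts$transcript_id,
                           unique(qualifying$transcript_id))
  list(kept = subset_transcripts(
    ts, setdiff(ts$transcripts$transcript_id, removed_ids)),
    removed = subset_transcripts(ts, removed_ids),
    removed_ids = removed_ids)
}

#' Split off transcripts matching annotated lncRNA genes
#'
#' Transcripts with same-strand exonic overlap (>= 1 bp) with an exon of a
#' biotype-lncRNA gene are returned as `annotated` (they bypass the
#' remaining novel-lncRNA filters); the rest continue down the cascade.
#' Opposite-strand overlap does not count as a match.
#'
#' @param ts a `transcript_set`.
#' @param annotation a `gene_annotation` containing biotype-lncRNA genes.
#' @return list with `annotated` and `unannotated` (`transcript_set`s) and
#'   `annotated_ids`.
#' @export
split_annotated <- function(ts, annotation) {
  lnc_ex <- annotation$exons[annotation$exons$biotype == "lncRNA"]
  hits <- GenomicRanges::findOverlaps(ts$exons, lnc_ex, ignore.strand = FALSE)
  annotated_ids <- unique(ts$exons$transcript_id[S4Vectors::queryHits(hits)])
  list(annotated = subset_transcripts(ts, annotated_ids),
       unannotated = subset_transcripts(
         ts, setdiff(ts$transcripts$transcript_id, annotated_ids)),
       annotated_ids = annotated_ids)
}

#' Keep transcripts passing the length and ORF filters
#'
#' Kept iff transcript length `>= min_length_nt` (default 200 nt) AND the
#' longest forward-frame ORF is `< max_orf_aa` (default 100 aa, exclusive).
#' Candidates without a sequence are removed with reason `no_sequence`.
#'
#' @param ts a `transcript_set` with sequences attached.
#' @param criteria a [filter_criteria()].
#' @param six_frame scan six frames instead of the three forward frames.
#' @return list with `kept`, `removed`, `removed_ids` and a data.frame
#'   `reasons` (transcript_id, reason).
#' @export
filter_length_orf <- function(ts, criteria = filter_criteria(),
                              six_frame = FALSE) {
  ids <- ts$transcripts$transcript_id
  have_seq <- !is.null(ts$sequences) & ids %in% names(ts$sequences)
  reasons <- character(0); removed_ids <- character(0)
  if (any(!have_seq)) {
    removed_ids <- ids[!have_seq]
    reasons <- rep("no_sequence", length(removed_ids))
    warning("transcripts without sequence removed at length/ORF filter: ",
            length(removed_ids))
  }
  with_seq <- ids[have_seq]
  if (length(with_seq)) {
    seqs <- as.character(ts$sequences[with_seq])
    len <- nchar(seqs)
    aa <- vapply(seqs, function(s) longest_orf(s, six_frame)$aa_length,
                 integer(1))
    short <- with_seq[len < criteria$min_length_nt]
    longorf <- with_seq[len >= criteria$min_length_nt &
                          aa >= criteria$max_orf_aa]
    removed_ids <- c(removed_ids, short, longorf)
    reasons <- c(reasons, rep("too_short", length(short)),
                 rep("orf_too_long", length(longorf)))
  }
  list(kept = subset_transcripts(ts, setdiff(ids, removed_ids)),
       removed = subset_transcripts(ts, removed_ids),
       removed_ids = removed_ids,
       reasons = data.frame(transcript_id = removed_ids, reason = reasons,
                            stringsAsFactors = FALSE))
}

#' Protein-domain and coding-potential gate
#'
#' Removes transcripts with a Pfam-domain hit at `E <= pfam_evalue_max`
#' (regardless of score), then keeps, of the remainder, those with a
#' coding-potential score strictly below `cpc_score_max` (default 0).
#' External scores take precedence; transcripts absent from the external
#' table are scored by the built-in heuristic
#' ([coding_potential_score()]), which requires their sequences.
#'
#' @param ts a `transcript_set`.
#' @param external_scores optional data.frame (`transcript_id`, `score`).
#' @param pfam_hits optional data.frame (`transcript_id`, `evalue`).
#' @param criteria a [filter_criteria()].
#' @return list with `kept`, `removed`, `removed_ids` and `scores`
#'   (data.frame transcript_id, score, source).
#' @export
coding_potential_gate <- function(ts, external_scores = NULL,
                                  pfam_hits = NULL,
                                  criteria = filter_criteria()) {
  ids <- ts$transcripts$transcript_id
  pfam_removed <- character(0)
  if (!is.null(pfam_hits) && nrow(pfam_hits)) {
    qual <- pfam_hits$transcript_id[pfam_hits$evalue <= criteria$pfam_evalue_max]
    pfam_removed <- intersect(ids, unique(qual))
  }
  rest <- setdiff(ids, pfam_removed)

  scores <- data.frame(transcript_id = character(), score = numeric(),
                       source = character(), stringsAsFactors = FALSE)
  if (!is.null(external_scores) && nrow(external_scores)) {
    ext <- external_scores[external_scores$transcript_id %in% rest, ,
                           drop = FALSE]
    scores <- rbind(scores, data.frame(
      transcript_id = ext$transcript_id, score = ext$score,
      source = "external_table", stringsAsFactors = FALSE))
  }
  missing <- setdiff(rest, scores$transcript_id)
  if (length(missing)) {
    if (is.null(ts$sequences) || !all(missing %in% names(ts$sequences)))
      stop("transcripts lack both an external coding-potential score and a ",
           "sequence for the built-in heuristic: ",
           paste(utils::head(setdiff(missing, names(ts$sequences)), 5),
                 collapse = ", "))
    scores <- rbind(scores, coding_potential_score(ts$sequences[missing]))
  }
  scores <- scores[match(rest, scores$transcript_id), , drop = FALSE]
  keep <- rest[scores$score < criteria$cpc_score_max]
  removed_ids <- c(pfam_removed, setdiff(rest, keep))
  list(kept = subset_transcripts(ts, keep),
       removed = subset_transcripts(ts, removed_ids),
       removed_ids = removed_ids,
       scores = scores)
}

#' Run the five-filter lncRNA identification cascade
#'
#' Executes, in order: housekeeping-ncRNA removal, exon-count filter,
#' protein-alignment filter, annotated-lncRNA split (matching transcripts
#' bypass the remaining filters), length/ORF filter, and the protein-domain
#' plus coding-potential gate. The final lncRNA set is the union of the
#' annotated and novel branches.
#'
#' @param ts a `transcript_set` (sequences required for the length/ORF and,
#'   absent an external score table, the coding-potential stages).
#' @param annotation a `gene_annotation`.
#' @param hits protein-alignment hit table.
#' @param criteria a [filter_criteria()].
#' @param external_scores optional external coding-potential score table.
#' @param pfam_hits optional Pfam hit table.
#' @param six_frame scan six frames in the ORF filter.
#' @return An object of class `cascade_report`: list with `report`
#'   (data.frame stage, n_input, n_removed, n_surviving), `annotated_ids`,
#'   `novel_ids`, `lnc_ids` and `sets` (the per-stage `transcript_set`s).
#' @export
run_cascade <- function(ts, annotation, hits,
                        criteria = filter_criteria(),
                        external_scores = NULL, pfam_hits = NULL,
                        six_frame = FALSE) {
  stage <- function(name, n_in, n_rm)
    data.frame(stage = name, n_input = n_in, n_removed = n_rm,
               n_surviving = n_in - n_rm, stringsAsFactors = FALSE)

  n0 <- length(ts)
  s1 <- filter_housekeeping(ts, annotation)
  s2 <- filter_exon_count(s1$kept, criteria$min_exons)
  s3 <- filter_coding_hits(s2$kept, hits, criteria)
  sp <- split_annotated(s3$kept, annotation)
  s4 <- filter_length_orf(sp$unannotated, criteria, six_frame)
  s5 <- coding_potential_gate(s4$kept, external_scores, pfam_hits, criteria)

  report <- rbind(
    stage("housekeeping", n0, length(s1$removed_ids)),
    stage("exon_count", length(s1$kept), length(s2$removed_ids)),
    stage("coding_hits", length(s2$kept), length(s3$removed_ids)),
    stage("annotated_split", length(s3$kept), length(sp$annotated_ids)),
    stage("length_orf", length(sp$unannotated), length(s4$removed_ids)),
    stage("coding_potential", length(s4$kept), length(s5$removed_ids))
  )
  structure(list(
    report = report,
    annotated_ids = sp$annotated_ids,
    novel_ids = s5$kept$transcripts$transcript_id,
    lnc_ids = c(sp$annotated_ids, s5$kept$transcripts$transcript_id),
    sets = list(annotated = sp$annotated, novel = s5$kept),
    scores = s5$scores
  ), class = "cascade_report")
}

#' @export
print.cascade_report <- function(x, ...) {
  cat("<cascade_report>\n")
  print(x$report, row.names = FALSE)
  cat("annotated lncRNAs:", length(x$annotated_ids),
      " novel lncRNAs:", length(x$novel_ids), "\n")
  invisible(x)
}
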