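LNC_CLASSES <- c("lincRNA", "antisense", "sense_overlapping", "sense_intronic")

# pick the partner gene among candidate gene indices: the one whose span
# midpoint is closest to the lncRNA's span midpoint (ties -> first by index)
.pick_partner <- function(cand_idx, genes, lnc_mid) {
  if (!length(cand_idx)) return(NA_character_)
  mids <- (GenomicRanges::start(genes)[cand_idx] +
             GenomicRanges::end(genes)[cand_idx]) / 2
  genes$gene_id[cand_idx[which.min(abs(mids - lnc_mid))]]
}

#' Positional classification of lncRNAs against coding genes
#'
#' Assigns each lncRNA exactly one of four classes by decision order:
#' (1) `antisense` - >= 1 bp overlap between a lncRNA exon and a coding exon
#' on the opposite strand; (2) `sense_overlapping` - such overlap on the same
#' strand; (3) `sense_intronic` - the lncRNA span lies wholly inside a coding
#' gene span with no exonic overlap on either strand (containment, not
#' strand, drives this class); (4) `lincRNA` - everything else. The partner
#' gene is the gene providing the triggering overlap/containment, the one
#' with the closest span midpoint on ties; lincRNAs have no partner.
#'
#' @param lnc_ts `transcript_set` of lncRNAs.
#' @param annotation a `gene_annotation`; only `protein_coding` genes are
#'   used.
#' @return data.frame with columns `transcript_id`, `category`,
#'   `partner_gene_id`, `strand_label` (Watson for "+", Crick for "-",
#'   unstranded for ".").
#' @export
classify_lncRNAs <- function(lnc_ts, annotation) {
  genes <- annotation$genes[annotation$genes$biotype == "protein_coding"]
  cexons <- annotation$exons[annotation$exons$biotype == "protein_coding"]
  tx <- lnc_ts$transcripts
  if (!nrow(tx))
    return(data.frame(transcript_id = character(), category = character(),
                      partner_gene_id = character(), strand_label = character(),
                      stringsAsFactors = FALSE))
  spans <- transcript_spans(lnc_ts)

  ex_ov <- GenomicRanges::findOverlaps(lnc_ts$exons, cexons,
                                       ignore.strand = TRUE)
  ex_same <- as.character(GenomicRanges::strand(lnc_ts$exons))[
    S4Vectors::queryHits(ex_ov)] ==
    as.character(GenomicRanges::strand(cexons))[S4Vectors::subjectHits(ex_ov)]
  ov_tx <- lnc_ts$exons$transcript_id[S4Vectors::queryHits(ex_ov)]
  ov_gene_idx <- match(cexons$gene_id[S4Vectors::subjectHits(ex_ov)],
                       genes$gene_id)

  within_ov <- GenomicRanges::findOverlaps(spans, genes, type = "within",
                                           ignore.strand = TRUE)

  category <- character(nrow(tx))
  partner <- rep(NA_character_, nrow(tx))
  for (i in seq_len(nrow(tx))) {
    id <- tx$transcript_id[i]
    mid <- (tx$start[i] + tx$end[i]) / 2
    rows <- which(ov_tx == id)
    anti <- rows[!ex_same[rows]]
    sens <- rows[ex_same[rows]]
    if (length(anti)) {
      category[i] <- "antisense"
      partner[i] <- .pick_partner(unique(ov_gene_idx[anti]), genes, mid)
    } else if (length(sens)) {
      category[i] <- "sense_overlapping"
      partner[i] <- .pick_partner(unique(ov_gene_idx[sens]), genes, mid)
    } else {
      host <- S4Vectors::subjectHits(within_ov)[
        S4Vectors::queryHits(within_ov) == i]
      if (length(host)) {
        category[i] <- "sense_intronic"
        partner[i] <- .pick_partner(unique(host), genes, mid)
      } else {
        category[i] <- "lincRNA"
      }
    }
  }
  strand_label <- c("+" = "Watson", "-" = "Crick", "." = "unstranded")[tx$strand]
  if (any(tx$strand == "."))
    warning("unstranded lncRNAs counted under a separate 'unstranded' label")
  data.frame(transcript_id = tx$transcript_id, category = category,
             partner_gene_id = partner,
             strand_label = unname(strand_label),
             stringsAsFactors = FALSE)
}

#' Strand tallies per positional class
#'
#' @param classes data.frame from [classify_lncRNAs()].
#' @return data.frame with one row per category (plus `total`) and columns
#'   `Watson`, `Crick` and, when present, `unstranded`.
#' @export
strand_counts <- function(classes) {
  cats <- LNC_CLASSES
  labels <- c("Watson", "Crick",
              if (any(classes$strand_label == "unstranded")) "unstranded")
  out <- data.frame(category = c(cats, "total"), stringsAsFactors = FALSE)
  for (lab in labels) {
    n <- vapply(cats, function(cc)
      sum(classes$category == cc & classes$strand_label == lab), numeric(1))
    out[[lab]] <- c(n, sum(n))
  }
  out
}

# bin a numeric vector by left-closed right-open breaks with given labels
.bin_counts <- function(x, breaks, labels) {
  b <- cut(x, breaks = breaks, labels = labels, right = FALSE)
  as.vector(table(b))
}

#' Feature distributions of lncRNAs versus coding transcripts
#'
#' Computes binned histograms of transcript length (nine bins: <300,
#' 300-400, ..., 900-1000, >1000 nt), exon number (1..10, >10) and
#' longest-ORF length for both sets. Bins are left-closed, right-open;
#' values of 1000 nt and above fall in ">1000". Proportions sum to 1 within
#' each (set, feature).
#'
#' @param lnc_ts `transcript_set` of lncRNAs (sequences attached for ORFs).
#' @param coding_ts `transcript_set` of coding transcripts.
#' @return long data.frame (set, feature, bin, count, proportion).
#' @export
feature_distributions <- function(lnc_ts, coding_ts) {
  len_breaks <- c(0, seq(300, 1000, by = 100), Inf)
  len_labels <- c("<300", "300-400", "400-500", "500-600", "600-700",
                  "700-800", "800-900", "900-1000", ">1000")
  ex_breaks <- c(1:11, Inf)
  ex_labels <- c(as.character(1:10), ">10")
  orf_breaks <- c(0, seq(100, 1000, by = 100), Inf)
  orf_labels <- c("<100", "100-200", "200-300", "300-400", "400-500",
                  "500-600", "600-700", "700-800", "800-900", "900-1000",
                  ">=1000")

  one_set <- function(ts, set_name) {
    tx <- ts$transcripts
    aa <- if (!is.null(ts$sequences))
      longest_orf_lengths(ts$sequences[tx$transcript_id]) else numeric(0)
    rows <- list(
      data.frame(set = set_name, feature = "length", bin = len_labels,
                 count = .bin_counts(tx$length, len_breaks, len_labels)),
      data.frame(set = set_name, feature = "exons", bin = ex_labels,
                 count = .bin_counts(tx$n_exons, ex_breaks, ex_labels))
    )
    if (length(aa))
      rows <- c(rows, list(
        data.frame(set = set_name, feature = "orf_aa", bin = orf_labels,
                   count = .bin_counts(aa, orf_breaks, orf_labels))))
    do.call(rbind, rows)
  }
  out <- rbind(one_set(lnc_ts, "lncRNA"), one_set(coding_ts, "coding"))
  totals <- stats::ave(out$count, paste(out$set, out$feature), FUN = sum)
  out$proportion <- ifelse(totals > 0, out$count / totals, 0)
  rownames(out) <- NULL
  out
}
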