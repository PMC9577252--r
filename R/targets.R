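#' Parameters for target prediction
#'
#' @param window_bp co-location window in bp (pairing at gap `<=` window,
#'   inclusive; overlap counts as gap 0).
#' @param r_threshold co-expression Pearson threshold (pairing at `r >`
#'   threshold, signed unless `absolute`).
#' @param min_samples minimum shared sample count for co-expression (the
#'   "more than five samples" rule).
#' @param absolute pair on `|r|` instead of signed `r`.
#' @return list of class `target_params`.
#' @export
target_params <- function(window_bp = 100000, r_threshold = 0.95,
                          min_samples = 6, absolute = FALSE) {
  stopifnot(window_bp > 0, r_threshold > 0, r_threshold < 1, min_samples >= 3)
  structure(list(window_bp = window_bp, r_threshold = r_threshold,
                 min_samples = min_samples, absolute = absolute),
            class = "target_params")
}

#' Co-location target prediction
#'
#' Pairs each lncRNA with every protein-coding gene on the same chromosome
#' whose genomic gap to the lncRNA span is at most `window_bp` (default
#' 100 kb, boundary inclusive; overlapping intervals have gap 0). Strand is
#' ignored.
#'
#' @param lnc_ts `transcript_set` of lncRNAs.
#' @param annotation a `gene_annotation`; only `protein_coding` genes are
#'   considered.
#' @param params a [target_params()].
#' @return data.frame (lnc_id, gene_id, mechanism = "co_location",
#'   distance_bp).
#' @export
colocate_targets <- function(lnc_ts, annotation, params = target_params()) {
  genes <- annotation$genes[annotation$genes$biotype == "protein_coding"]
  spans <- transcript_spans(lnc_ts)
  hits <- GenomicRanges::findOverlaps(spans, genes,
                                      maxgap = params$window_bp,
                                      ignore.strand = TRUE)
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  d <- GenomicRanges::distance(spans[q], genes[s], ignore.strand = TRUE)
  keep <- !is.na(d) & d <= params$window_bp
  data.frame(lnc_id = names(spans)[q][keep],
             gene_id = genes$gene_id[s][keep],
             mechanism = "co_location",
             distance_bp = as.integer(d[keep]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Co-expression target prediction
#'
#' Pairs a lncRNA with a gene when the Pearson correlation of their
#' expression across shared samples exceeds `r_threshold` (signed by
#' default: perfectly anti-correlated pairs are not emitted). Requires more
#' than `min_samples - 1` shared samples. Constant expression vectors have
#' undefined correlation and yield no pairs (with a warning).
#'
#' @param lnc_expr numeric matrix, lncRNAs x samples.
#' @param gene_expr numeric matrix, genes x samples (same sample columns).
#' @param params a [target_params()].
#' @return data.frame (lnc_id, gene_id, mechanism = "co_expression",
#'   pearson_r).
#' @export
coexpress_targets <- function(lnc_expr, gene_expr, params = target_params()) {
  common <- intersect(colnames(lnc_expr), colnames(gene_expr))
  if (length(common) < params$min_samples)
    stop("co-expression prediction requires more than ",
         params$min_samples - 1, " shared samples (the >5-sample rule); got ",
         length(common))
  lm_ <- lnc_expr[, common, drop = FALSE]
  gm_ <- gene_expr[, common, drop = FALSE]
  const_l <- apply(lm_, 1, stats::sd) == 0
  const_g <- apply(gm_, 1, stats::sd) == 0
  if (any(const_l) || any(const_g))
    warning("constant expression vectors skipped: ",
            sum(const_l), " lncRNA(s), ", sum(const_g), " gene(s)")
  r <- suppressWarnings(stats::cor(t(lm_), t(gm_)))
  crit <- if (params$absolute) abs(r) else r
  idx <- which(!is.na(crit) & crit > params$r_threshold, arr.ind = TRUE)
  if (!nrow(idx))
    return(data.frame(lnc_id = character(), gene_id = character(),
                      mechanism = character(), pearson_r = numeric(),
                      stringsAsFactors = FALSE))
  data.frame(lnc_id = rownames(lm_)[idx[, 1]],
             gene_id = rownames(gm_)[idx[, 2]],
             mechanism = "co_expression",
             pearson_r = r[idx],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Annotate target pairs with curated gene lists
#'
#' Partitions predicted pairs by whether the gene appears in a curated
#' scent-pathway gene list or a transcription-factor homolog list; the
#' curation itself is an input, not a computation. Unknown ids in the lists
#' are warned about and ignored.
#'
#' @param pairs data.frame of target pairs (from [colocate_targets()] or
#'   [coexpress_targets()]).
#' @param scent_genes character vector of scent-pathway gene ids.
#' @param tf_homologs character vector of TF homolog gene ids.
#' @param known_genes optional character vector of all valid gene ids, used
#'   to warn on unknown list entries.
#' @return list with `pairs` (input plus a `link` column in
#'   scent / tf / other), and `per_lnc` summary counts.
#' @export
intersect_gene_lists <- function(pairs, scent_genes = character(),
                                 tf_homologs = character(),
                                 known_genes = NULL) {
  if (!is.null(known_genes)) {
    unk <- setdiff(c(scent_genes, tf_homologs), known_genes)
    if (length(unk))
      warning("unknown gene ids in curated lists ignored: ",
              paste(utils::head(unk, 5), collapse = ", "))
    scent_genes <- intersect(scent_genes, known_genes)
    tf_homologs <- intersect(tf_homologs, known_genes)
  }
  link <- rep("other", nrow(pairs))
  link[pairs$gene_id %in% tf_homologs] <- "tf"
  link[pairs$gene_id %in% scent_genes] <- "scent"
  pairs$link <- link
  per_lnc <- do.call(rbind, lapply(split(pairs, pairs$lnc_id), function(d)
    data.frame(lnc_id = d$lnc_id[1],
               n_scent = sum(d$link == "scent"),
               n_tf = sum(d$link == "tf"),
               n_other = sum(d$link == "other"),
               stringsAsFactors = FALSE)))
  rownames(per_lnc) <- NULL
  list(pairs = pairs, per_lnc = per_lnc)
}
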