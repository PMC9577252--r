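#' Differential expression between two developmental stages
#'
#' For each transcript, `log2fc = log2((mean_b + eps) / (mean_a + eps))`
#' over FPKM replicate means, with a per-transcript test on
#' `log2(value + eps)` across replicates and Benjamini-Hochberg adjustment
#' across all transcripts in the matrix. The default test is limma's
#' moderated t (empirical-Bayes variance shrinkage), the standard choice at
#' the three-replicate design this pipeline targets; `method = "welch"`
#' gives an unmoderated Welch two-sample t-test instead. Direction is `up`
#' iff `log2fc >= 1` and `p_adj < 0.05` (boundary inclusive), `down`
#' symmetrically, otherwise `ns`.
#'
#' @param expr numeric matrix, transcripts x samples (FPKM scale).
#' @param meta sample metadata (columns `sample_id`, `stage`, ...).
#' @param contrast length-2 character, `c(stage_a, stage_b)`; fold changes
#'   are b over a.
#' @param pseudocount eps added before logs (default 0.01).
#' @param lfc_min absolute log2 fold-change threshold (default 1).
#' @param alpha adjusted-p threshold (default 0.05).
#' @param method `"moderated"` (limma eBayes, default) or `"welch"`.
#' @return data.frame (transcript_id, contrast, log2fc, p, p_adj,
#'   direction).
#' @export
call_de <- function(expr, meta, contrast, pseudocount = 0.01,
                    lfc_min = 1, alpha = 0.05,
                    method = c("moderated", "welch")) {
  stopifnot(length(contrast) == 2)
  method <- match.arg(method)
  stage <- meta$stage[match(colnames(expr), meta$sample_id)]
  ia <- which(stage == contrast[1]); ib <- which(stage == contrast[2])
  if (length(ia) < 2 || length(ib) < 2)
    stop("stage missing or with fewer than 2 replicates: ",
         paste(contrast, collapse = ", "))
  a <- expr[, ia, drop = FALSE]; b <- expr[, ib, drop = FALSE]
  log2fc <- log2((rowMeans(b) + pseudocount) / (rowMeans(a) + pseudocount))

  la <- log2(a + pseudocount); lb <- log2(b + pseudocount)
  if (method == "moderated") {
    y <- cbind(la, lb)
    design <- cbind(intercept = 1,
                    b_vs_a = rep(c(0, 1), c(ncol(la), ncol(lb))))
    fit <- limma::eBayes(limma::lmFit(y, design))
    p <- fit$p.value[, "b_vs_a"]
    # rows with zero residual variance get NaN; treat like the degenerate
    # Welch case below
    mzero <- !is.finite(p)
    p[mzero] <- ifelse(rowMeans(lb)[mzero] == rowMeans(la)[mzero], 1, 0)
  } else {
    na <- ncol(la); nb <- ncol(lb)
    ma <- rowMeans(la); mb <- rowMeans(lb)
    va <- apply(la, 1, stats::var); vb <- apply(lb, 1, stats::var)
    se2 <- va / na + vb / nb
    tstat <- (mb - ma) / sqrt(se2)
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
    p <- 2 * stats::pt(-abs(tstat), df)
    # both groups constant: no evidence either way unless means differ
    degenerate <- se2 == 0
    p[degenerate] <- ifelse(mb[degenerate] == ma[degenerate], 1, 0)
  }
  p_adj <- stats::p.adjust(p, method = "BH")

  direction <- rep("ns", nrow(expr))
  direction[log2fc >= lfc_min & p_adj < alpha] <- "up"
  direction[log2fc <= -lfc_min & p_adj < alpha] <- "down"
  data.frame(transcript_id = rownames(expr),
             contrast = paste(contrast, collapse = "_vs_"),
             log2fc = log2fc, p = p, p_adj = p_adj, direction = direction,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Apply the minimum-expression floor
#'
#' Excludes a transcript iff its stage-mean expression is below `floor` in
#' every stage (AND semantics: one stage at or above the floor retains it).
#'
#' @param ids transcript ids to screen (e.g. DE lncRNAs).
#' @param expr expression matrix.
#' @param meta sample metadata.
#' @param floor expression floor (default 0.5 FPKM).
#' @param stages stage labels to consider (default the stages in `meta`).
#' @return list with `retained` and `excluded` id vectors.
#' @export
expression_floor <- function(ids, expr, meta, floor = 0.5, stages = NULL) {
  stage <- meta$stage[match(colnames(expr), meta$sample_id)]
  if (is.null(stages)) stages <- unique(stage)
  sub <- expr[rownames(expr) %in% ids, , drop = FALSE]
  stage_means <- vapply(stages, function(s)
    rowMeans(sub[, stage == s, drop = FALSE]), numeric(nrow(sub)))
  if (is.null(dim(stage_means)))
    stage_means <- matrix(stage_means, nrow = 1,
                          dimnames = list(rownames(sub), stages))
  below_all <- rowSums(stage_means < floor) == length(stages)
  list(retained = rownames(sub)[!below_all],
       excluded = rownames(sub)[below_all])
}

#' Core lncRNAs and their temporal patterns
#'
#' A transcript is core iff it is differentially expressed (direction not
#' `ns`) in both successive contrasts. Pattern `up_down` = up in the first
#' contrast and down in the second; `down_up` the reverse; any other DE/DE
#' combination is `other`.
#'
#' @param de_first DE results for the first contrast (e.g. EF vs SF).
#' @param de_second DE results for the second contrast (e.g. SF vs LF).
#' @return data.frame (transcript_id, pattern) for core transcripts only.
#' @export
core_lncRNAs <- function(de_first, de_second) {
  d1 <- de_first[de_first$direction != "ns", c("transcript_id", "direction")]
  d2 <- de_second[de_second$direction != "ns", c("transcript_id", "direction")]
  core <- merge(d1, d2, by = "transcript_id", suffixes = c("_1", "_2"))
  pattern <- rep("other", nrow(core))
  pattern[core$direction_1 == "up" & core$direction_2 == "down"] <- "up_down"
  pattern[core$direction_1 == "down" & core$direction_2 == "up"] <- "down_up"
  data.frame(transcript_id = core$transcript_id, pattern = pattern,
             stringsAsFactors = FALSE)
}

#' Relative quantification by the 2^-ddCt (Livak) method
#'
#' `RQ = 2^-ddCt` with `ddCt = (Ct_target_treat - Ct_ref_treat) -
#' (Ct_target_ctrl - Ct_ref_ctrl)`.
#'
#' @param ct_target_treat,ct_ref_treat target and reference-gene Ct in the
#'   treatment/condition of interest.
#' @param ct_target_ctrl,ct_ref_ctrl the same in the calibrator condition.
#' @return relative quantity (vectorized).
#' @export
ddct <- function(ct_target_treat, ct_ref_treat, ct_target_ctrl, ct_ref_ctrl) {
  stopifnot(all(is.finite(c(ct_target_treat, ct_ref_treat,
                            ct_target_ctrl, ct_ref_ctrl))))
  dd <- (ct_target_treat - ct_ref_treat) - (ct_target_ctrl - ct_ref_ctrl)
  2^(-dd)
}

#' Concordance of sequencing and qPCR fold changes
#'
#' Ordinary least squares of the qPCR fold changes on the sequencing fold
#' changes, as used to validate expression profiles.
#'
#' @param fc_seq numeric vector of sequencing-derived fold changes.
#' @param fc_qpcr numeric vector of qPCR-derived fold changes (same length,
#'   >= 3).
#' @return list with `slope`, `intercept`, `r_squared`.
#' @export
fc_concordance <- function(fc_seq, fc_qpcr) {
  stopifnot(length(fc_seq) == length(fc_qpcr), length(fc_seq) >= 3)
  if (stats::sd(fc_seq) == 0)
    stop("sequencing fold changes have zero variance; regression undefined")
  fit <- stats::lm(fc_qpcr ~ fc_seq)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = summary(fit)$r.squared)
}
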