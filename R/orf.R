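STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Longest open reading frame of a transcript sequence
#'
#' Scans the three forward frames of the sense-strand sequence. An ORF is an
#' ATG followed by in-frame codons up to (excluding) the first in-frame stop
#' (TAA/TAG/TGA); its length in amino acids counts the codons from the ATG
#' through the codon before the stop, so `"ATGAAATAA"` has a 2-aa ORF (M, K).
#' Open-ended ATG runs without a stop are not ORFs. Codons containing N never
#' match ATG or a stop. If no complete ORF exists the call has `aa_length 0`
#' and `NA` frame/start. Ties on length are broken by the smallest start
#' position, then the smallest frame.
#'
#' Only forward frames are scanned, matching strand-specific assembly; set
#' `six_frame = TRUE` to also scan the reverse complement (non-stranded
#' input), in which case frames 3-5 denote the reverse strand and `start`
#' positions refer to the reverse-complemented sequence.
#'
#' @param sequence a single character string over A/C/G/T/N (case
#'   insensitive).
#' @param six_frame also scan the reverse complement.
#' @return list with `aa_length` (integer), `frame` (0/1/2, or 3-5 for the
#'   reverse strand), `start` (1-based nt position of the ATG; `(start-1) %%
#'   3 == frame %% 3`).
#' @export
longest_orf <- function(sequence, six_frame = FALSE) {
  seq <- toupper(as.character(sequence))
  best <- list(aa_length = 0L, frame = NA_integer_, start = NA_integer_)
  strands <- seq
  if (six_frame)
    strands <- c(seq, as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(seq))))
  for (si in seq_along(strands)) {
    s <- strands[si]
    n <- nchar(s)
    if (n < 6) next   # shortest complete ORF (ATG + stop) needs 6 nt
    for (f in 0:2) {
      starts <- seq.int(f + 1L, n - 2L, by = 3L)
      if (length(starts) < 2L) next
      codons <- substring(s, starts, starts + 2L)
      atg <- which(codons == "ATG")
      stp <- which(codons %in% STOP_CODONS)
      if (!length(atg) || !length(stp)) next
      # index of first stop strictly after each ATG
      nxt <- stp[findInterval(atg, stp) + 1L]
      aa <- nxt - atg
      ok <- which(!is.na(aa))
      if (!length(ok)) next
      amax <- max(aa[ok])
      cand <- ok[aa[ok] == amax][1L]       # atg sorted => smallest start wins
      cand_start <- starts[atg[cand]]
      cand_frame <- (si - 1L) * 3L + f
      better <- amax > best$aa_length ||
        (amax == best$aa_length && amax > 0L &&
         (cand_start < best$start ||
          (cand_start == best$start && cand_frame < best$frame)))
      if (better)
        best <- list(aa_length = as.integer(amax),
                     frame = cand_frame,
                     start = as.integer(cand_start))
    }
  }
  best
}

#' Longest-ORF lengths for many sequences
#'
#' @param sequences character vector or `DNAStringSet`.
#' @return integer vector of amino-acid lengths, named like `sequences`.
#' @export
longest_orf_lengths <- function(sequences) {
  if (methods::is(sequences, "DNAStringSet")) {
    nm <- names(sequences)
    sequences <- as.character(sequences)
    names(sequences) <- nm
  }
  vapply(sequences, function(s) longest_orf(s)$aa_length, integer(1))
}

# Fickett TESTCODE lookup tables (position asymmetry and base composition,
# classic weighting). Values >= ~1.0 lean coding, < ~0.75 lean non-coding.
.fickett <- list(
  pos_param = c(1.9, 1.8, 1.7, 1.6, 1.5, 1.4, 1.3, 1.2, 1.1, 0),
  pos_prob = list(
    A = c(0.94, 0.68, 0.84, 0.93, 0.58, 0.68, 0.45, 0.34, 0.20, 0.22),
    C = c(0.80, 0.70, 0.70, 0.81, 0.66, 0.48, 0.51, 0.33, 0.30, 0.23),
    G = c(0.90, 0.88, 0.74, 0.64, 0.53, 0.48, 0.27, 0.16, 0.08, 0.08),
    T = c(0.97, 0.97, 0.91, 0.68, 0.69, 0.44, 0.54, 0.20, 0.09, 0.09)),
  pos_weight = c(A = 0.26, C = 0.18, G = 0.31, T = 0.33),
  cont_param = c(0.33, 0.31, 0.29, 0.27, 0.25, 0.23, 0.21, 0.17, 0),
  cont_prob = list(
    A = c(0.28, 0.49, 0.44, 0.55, 0.62, 0.49, 0.67, 0.65, 0.81, 0.21),
    C = c(0.82, 0.64, 0.51, 0.64, 0.59, 0.59, 0.43, 0.44, 0.39, 0.31),
    G = c(0.40, 0.54, 0.47, 0.64, 0.73, 0.41, 0.41, 0.47, 0.54, 0.33),
    T = c(0.28, 0.24, 0.39, 0.40, 0.55, 0.75, 0.56, 0.69, 0.51, 0.58)),
  cont_weight = c(A = 0.11, C = 0.12, G = 0.15, T = 0.14)
)

#' Fickett TESTCODE statistic
#'
#' The classic position/composition coding statistic: for each base, the
#' asymmetry of its counts across the three codon positions
#' (`max/(min + 1)`) and its overall frequency are mapped through lookup
#' tables to probabilities, which are combined by fixed weights. Higher
#' values indicate coding-like periodicity.
#'
#' @param sequence character string over A/C/G/T/N.
#' @return numeric TESTCODE value.
#' @export
fickett_testcode <- function(sequence) {
  s <- toupper(as.character(sequence))
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  chars <- chars[chars %in% c("A", "C", "G", "T")]
  n <- length(chars)
  if (n < 3) return(0)
  phase <- (seq_len(n) - 1L) %% 3L
  score <- 0
  for (b in c("A", "C", "G", "T")) {
    cnt <- vapply(0:2, function(p) sum(chars == b & phase == p), numeric(1))
    pos_val <- max(cnt) / (min(cnt) + 1)
    cont_val <- sum(cnt) / n
    pi <- which(pos_val >= .fickett$pos_param)[1]
    ci <- which(cont_val >= .fickett$cont_param)[1]
    score <- score +
      .fickett$pos_prob[[b]][pi] * .fickett$pos_weight[[b]] +
      .fickett$cont_prob[[b]][ci] * .fickett$cont_weight[[b]]
  }
  score
}

#' Built-in coding-potential score
#'
#' Heuristic stand-in score with the sign convention of coding-potential
#' classifiers (negative = non-coding): combines how much of the transcript
#' the longest ORF covers with the Fickett TESTCODE statistic,
#' `2 * (orf_coverage - 0.5) + (testcode - 0.95)` where `orf_coverage =
#' 3 * aa_length / length`. Used by the cascade only when no external score
#' table is supplied.
#'
#' @param sequences character vector or `DNAStringSet`.
#' @return data.frame with columns `transcript_id`, `score`, `source`.
#' @export
coding_potential_score <- function(sequences) {
  if (methods::is(sequences, "DNAStringSet")) {
    nm <- names(sequences)
    sequences <- as.character(sequences)
    names(sequences) <- nm
  }
  aa <- longest_orf_lengths(sequences)
  len <- nchar(sequences)
  cov <- ifelse(len > 0, 3 * aa / len, 0)
  fick <- vapply(sequences, fickett_testcode, numeric(1))
  data.frame(
    transcript_id = names(sequences),
    score = 2 * (cov - 0.5) + (fick - 0.95),
    source = "builtin_heuristic",
    stringsAsFactors = FALSE, row.names = NULL
  )
}
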