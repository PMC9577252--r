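#' Volatile emission rate from an internal-standard GC-MS peak
#'
#' Internal-standard quantification:
#' `rate = (peak_area / is_peak_area * is_concentration * is_volume) /
#' sample_mass / extraction_time`, in ug g^-1 h^-1 when the internal
#' standard concentration is in ug/uL, its volume in uL, the sample mass in
#' g and the extraction time in h. Exactly linear in `peak_area`.
#'
#' All arguments are vectorized and recycled.
#'
#' @param peak_area compound peak area (arbitrary units, >= 0).
#' @param is_peak_area internal-standard peak area (> 0).
#' @param is_concentration internal-standard concentration (ug/uL).
#' @param is_volume internal-standard volume (uL).
#' @param sample_mass sample mass (g, > 0).
#' @param extraction_time extraction time (h, > 0).
#' @return numeric emission rate(s), ug g^-1 h^-1.
#' @export
emission_rate <- function(peak_area, is_peak_area, is_concentration,
                          is_volume, sample_mass, extraction_time) {
  if (any(is_peak_area <= 0)) stop("internal-standard peak area must be > 0")
  if (any(sample_mass <= 0)) stop("sample mass must be > 0")
  if (any(extraction_time <= 0)) stop("extraction time must be > 0")
  if (any(peak_area < 0)) stop("negative peak area")
  (peak_area / is_peak_area * is_concentration * is_volume) /
    sample_mass / extraction_time
}

#' Emission-rate profile from a GC-MS peak table
#'
#' Applies [emission_rate()] row-wise and pivots to a compound x sample
#' matrix; attaches compound class labels.
#'
#' @param peaks data.frame as from [read_gcms_peaks()].
#' @param classes data.frame as from [read_compound_classes()]; every
#'   compound in `peaks` must be labelled.
#' @return list of class `volatile_profile` with `rates` (matrix compound x
#'   sample) and `compound_class` (named character vector).
#' @export
emission_profile <- function(peaks, classes) {
  rate <- emission_rate(peaks$peak_area, peaks$is_peak_area,
                        peaks$is_concentration, peaks$is_volume,
                        peaks$sample_mass, peaks$extraction_time)
  compounds <- unique(peaks$compound)
  samples <- unique(peaks$sample_id)
  m <- matrix(NA_real_, length(compounds), length(samples),
              dimnames = list(compounds, samples))
  m[cbind(match(peaks$compound, compounds),
          match(peaks$sample_id, samples))] <- rate
  missing_cls <- setdiff(compounds, classes$compound)
  if (length(missing_cls))
    stop("compounds without class label: ",
         paste(utils::head(missing_cls, 5), collapse = ", "))
  cls <- stats::setNames(classes$class, classes$compound)[compounds]
  structure(list(rates = m, compound_class = cls),
            class = "volatile_profile")
}

SCENT_CLASSES <- c("terpenoid", "phenylpropanoid_benzenoid",
                   "fatty_acid_derivative")

#' Per-stage emission totals and class shares
#'
#' Emission rates are computed per replicate sample, then summed over scent
#' compounds (class `non_scent` excluded) per sample; per-stage totals are
#' replicate means with SD. Class shares are each scent class's stage total
#' divided by the overall stage total, in percent; shares sum to 100 when
#' the stage total is positive. Stages with zero total are flagged
#' (`defined = FALSE`) rather than given shares.
#'
#' @param profile a `volatile_profile`.
#' @param meta sample metadata (columns `sample_id`, `stage`, ...).
#' @return list with `stage_totals` (stage, mean_total, sd_total,
#'   n_replicates) and `class_shares` (stage, class, total, share_pct,
#'   defined).
#' @export
aggregate_by_class <- function(profile, meta) {
  m <- profile$rates
  if (!all(colnames(m) %in% meta$sample_id))
    stop("profile contains samples without metadata")
  stage <- meta$stage[match(colnames(m), meta$sample_id)]
  scent <- profile$compound_class[rownames(m)] %in% SCENT_CLASSES
  per_sample_total <- colSums(m[scent, , drop = FALSE])

  stages <- unique(stage)
  stage_totals <- data.frame(
    stage = stages,
    mean_total = vapply(stages, function(s) mean(per_sample_total[stage == s]),
                        numeric(1)),
    sd_total = vapply(stages, function(s) stats::sd(per_sample_total[stage == s]),
                      numeric(1)),
    n_replicates = vapply(stages, function(s) sum(stage == s), numeric(1)),
    stringsAsFactors = FALSE
  )

  shares <- do.call(rbind, lapply(stages, function(s) {
    sub <- m[scent, stage == s, drop = FALSE]
    cls <- profile$compound_class[rownames(m)][scent]
    class_tot <- vapply(SCENT_CLASSES, function(k)
      sum(sub[cls == k, , drop = FALSE]), numeric(1))
    tot <- sum(class_tot)
    defined <- tot > 0
    if (!defined)
      warning("stage ", s, " has zero scent total; shares undefined")
    data.frame(stage = s, class = SCENT_CLASSES, total = class_tot,
               share_pct = if (defined) class_tot / tot * 100 else NA_real_,
               defined = defined, stringsAsFactors = FALSE)
  }))
  rownames(shares) <- NULL
  list(stage_totals = stage_totals, class_shares = shares)
}

#' Compare volatile emission between two stages
#'
#' Welch two-sample t-tests on replicate values: one test per compound and
#' one on the per-sample scent totals. Significance is flagged at
#' `p < alpha`.
#'
#' @param profile a `volatile_profile`.
#' @param meta sample metadata.
#' @param stage_a,stage_b stage labels to compare.
#' @param alpha significance level (default 0.05).
#' @return data.frame (compound, mean_a, mean_b, t, p, significant) with a
#'   final row `..total..` for the per-sample scent totals.
#' @export
stage_compare <- function(profile, meta, stage_a, stage_b, alpha = 0.05) {
  m <- profile$rates
  stage <- meta$stage[match(colnames(m), meta$sample_id)]
  ia <- which(stage == stage_a); ib <- which(stage == stage_b)
  if (length(ia) < 2 || length(ib) < 2)
    stop("need >= 2 replicates per stage for a t-test")
  scent <- profile$compound_class[rownames(m)] %in% SCENT_CLASSES
  tot_a <- colSums(m[scent, ia, drop = FALSE])
  tot_b <- colSums(m[scent, ib, drop = FALSE])

  welch <- function(x, y) {
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      if (isTRUE(all.equal(mean(x), mean(y))))
        return(c(t = 0, p = 1))
      return(c(t = Inf * sign(mean(y) - mean(x)), p = 0))
    }
    ht <- stats::t.test(y, x)
    c(t = unname(ht$statistic), p = ht$p.value)
  }

  rows <- lapply(rownames(m), function(cp) {
    w <- welch(m[cp, ia], m[cp, ib])
    data.frame(compound = cp, mean_a = mean(m[cp, ia]), mean_b = mean(m[cp, ib]),
               t = w[["t"]], p = w[["p"]], stringsAsFactors = FALSE)
  })
  w <- welch(tot_a, tot_b)
  rows <- c(rows, list(data.frame(
    compound = "..total..", mean_a = mean(tot_a), mean_b = mean(tot_b),
    t = w[["t"]], p = w[["p"]], stringsAsFactors = FALSE)))
  out <- do.call(rbind, rows)
  out$significant <- out$p < alpha
  out
}
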