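# module label palette: grey is reserved for unassigned transcripts, other
# colors are handed out in order of decreasing module size (WGCNA convention)
MODULE_COLORS <- c(
  "turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
  "magenta", "purple", "greenyellow", "tan", "salmon", "cyan", "midnightblue",
  "lightcyan", "grey60", "lightgreen", "lightyellow", "royalblue", "darkred",
  "darkgreen", "darkturquoise", "darkgrey", "orange", "darkorange", "white",
  "skyblue", "saddlebrown", "steelblue", "paleturquoise", "violet",
  "darkolivegreen", "darkmagenta")

#' Network parameters
#'
#' Defaults follow the standard unsigned WGCNA setup for a small lncRNA
#' network: soft-threshold power 6, minimum module size 6, deep split 4,
#' eigengene-dissimilarity merge threshold 0.15 and dendrogram cut height
#' 0.99. `merge_cut_height` is retained as an alias parameter and only
#' drives merging when `use_merge_cut_height = TRUE` (the eigengene
#' dissimilarity threshold governs by default).
#'
#' @param power soft-threshold exponent (>= 1).
#' @param min_module_size smallest module size; smaller clusters become grey.
#' @param deep_split 0-4; larger values cut sub-branches at progressively
#'   lower heights (`cut_height - 0.05 * deep_split`).
#' @param me_diss_thresh eigengene dissimilarity below which modules merge.
#' @param merge_cut_height alias merge threshold, ignored unless enabled.
#' @param cut_height static dendrogram cut height in (0,1).
#' @param use_merge_cut_height use `merge_cut_height` instead of
#'   `me_diss_thresh` for merging.
#' @param min_samples smallest sample count the network accepts.
#' @return list of class `network_params`.
#' @export
network_params <- function(power = 6, min_module_size = 6, deep_split = 4,
                           me_diss_thresh = 0.15, merge_cut_height = 0.1,
                           cut_height = 0.99, use_merge_cut_height = FALSE,
                           min_samples = 15) {
  stopifnot(power >= 1, deep_split %in% 0:4,
            me_diss_thresh > 0, me_diss_thresh < 1,
            merge_cut_height > 0, merge_cut_height < 1,
            cut_height > 0, cut_height < 1)
  structure(list(power = power, min_module_size = min_module_size,
                 deep_split = deep_split, me_diss_thresh = me_diss_thresh,
                 merge_cut_height = merge_cut_height, cut_height = cut_height,
                 use_merge_cut_height = use_merge_cut_height,
                 min_samples = min_samples, sign_mode = "unsigned"),
            class = "network_params")
}

#' Unsigned soft-threshold adjacency
#'
#' `a_ij = |cor(x_i, x_j)|^power` for `i != j`, zero diagonal (the diagonal
#' carries no information for network statistics). Rows with zero variance
#' get zero adjacency to everything, with a warning.
#'
#' @param expr numeric matrix, transcripts x samples.
#' @param power soft-threshold exponent.
#' @param min_samples required sample count (default 15, the usual floor
#'   for a stable correlation network).
#' @return symmetric adjacency matrix with zero diagonal.
#' @export
adjacency_matrix <- function(expr, power = 6, min_samples = 15) {
  if (ncol(expr) < min_samples)
    stop("network construction requires >= ", min_samples, " samples; got ",
         ncol(expr))
  const <- apply(expr, 1, stats::sd) == 0
  if (any(const))
    warning("constant expression rows get zero adjacency: ", sum(const))
  r <- suppressWarnings(stats::cor(t(expr)))
  r[is.na(r)] <- 0
  a <- abs(r)^power
  diag(a) <- 0
  a
}

#' Topological overlap matrix
#'
#' `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `l_ij = sum_u a_iu a_uj` over `u != i, j` and `k_i = sum_u a_iu`;
#' `TOM_ii = 1`. With only two nodes the TOM equals the adjacency.
#'
#' @param adj symmetric adjacency with zero diagonal and entries in [0,1].
#' @return symmetric TOM with unit diagonal.
#' @export
tom_similarity <- function(adj) {
  if (!isSymmetric(unname(adj))) stop("adjacency must be symmetric")
  if (any(diag(adj) != 0)) stop("adjacency must have a zero diagonal")
  if (any(adj < 0) || any(adj > 1)) stop("adjacency entries must be in [0,1]")
  # with zero diagonal, (adj %*% adj)_ij already excludes u = i and u = j
  l <- adj %*% adj
  k <- rowSums(adj)
  kmin <- outer(k, k, pmin)
  tom <- (l + adj) / (kmin + 1 - adj)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adj)
  tom
}

#' Module eigengene
#'
#' First principal component of the standardized member x sample matrix,
#' scaled to unit variance and sign-oriented so the mean correlation with
#' the members is positive (ties broken toward positive correlation with
#' the first member).
#'
#' @param expr numeric matrix, transcripts x samples.
#' @param members transcript ids of the module (>= 2).
#' @return numeric eigengene vector over samples.
#' @export
module_eigengene <- function(expr, members) {
  x <- expr[members, , drop = FALSE]
  if (nrow(x) < 2) stop("a module eigengene needs >= 2 members")
  xs <- t(scale(t(x)))
  xs[is.na(xs)] <- 0
  if (all(xs == 0)) stop("rank-0 module: all members constant")
  sv <- svd(xs)
  me <- sv$v[, 1]
  me <- me / stats::sd(me)
  cors <- suppressWarnings(stats::cor(me, t(x)))
  cors[is.na(cors)] <- 0
  s <- mean(cors)
  if (s < 0 || (s == 0 && cors[1] < 0)) me <- -me
  stats::setNames(me, colnames(expr))
}

# average-linkage tree on TOM dissimilarity, shared by detection
.tom_tree <- function(diss) stats::hclust(stats::as.dist(diss), method = "average")

#' Module detection by hierarchical clustering with branch recutting
#'
#' Average-linkage hierarchical clustering of the TOM dissimilarity; a
#' static cut at `cut_height` defines the main branches, and a simplified
#' dynamic-split step recuts within branches at
#' `cut_height - 0.05 * deep_split`. Clusters smaller than
#' `min_module_size` are labelled `grey`; remaining module labels are color
#' names assigned by decreasing module size.
#'
#' @param diss dissimilarity matrix (`1 - TOM`), row/col names = transcript
#'   ids.
#' @param params a [network_params()].
#' @return list of class `module_assignment` with `labels` (named character
#'   vector, `grey` = unassigned), `sizes` and `tree` (the `hclust`).
#' @export
detect_modules <- function(diss, params = network_params()) {
  ids <- rownames(diss)
  n <- length(ids)
  if (n < params$min_module_size) {
    warning("fewer transcripts than min_module_size; all grey")
    return(structure(list(labels = stats::setNames(rep("grey", n), ids),
                          sizes = integer(0), tree = NULL),
                     class = "module_assignment"))
  }
  tree <- .tom_tree(diss)
  coarse <- stats::cutree(tree, h = params$cut_height)
  h_deep <- max(params$cut_height - 0.05 * params$deep_split, 1e-6)
  fine <- stats::cutree(tree, h = h_deep)

  raw <- integer(n); nxt <- 1L
  for (b in unique(coarse)) {
    in_b <- which(coarse == b)
    sub <- fine[in_b]
    tab <- table(sub)
    big <- names(tab)[tab >= params$min_module_size]
    if (length(big)) {
      # accepted sub-branches become modules; small leftovers stay grey
      for (s in big) { raw[in_b[sub == s]] <- nxt; nxt <- nxt + 1L }
    } else if (length(in_b) >= params$min_module_size) {
      # no sub-branch stands alone: the whole branch is the module
      raw[in_b] <- nxt; nxt <- nxt + 1L
    }
  }
  labels <- .color_labels(raw, ids)
  structure(list(labels = labels,
                 sizes = .module_sizes(labels), tree = tree),
            class = "module_assignment")
}

# map integer cluster codes (0 = grey) to size-ordered color names
.color_labels <- function(raw, ids) {
  labels <- rep("grey", length(raw))
  mods <- setdiff(unique(raw), 0L)
  if (length(mods)) {
    sizes <- vapply(mods, function(m) sum(raw == m), numeric(1))
    mods <- mods[order(-sizes, mods)]
    if (length(mods) > length(MODULE_COLORS))
      stop("more modules than available color labels")
    for (i in seq_along(mods))
      labels[raw == mods[i]] <- MODULE_COLORS[i]
  }
  stats::setNames(labels, ids)
}

.module_sizes <- function(labels) {
  t <- table(labels[labels != "grey"])
  sizes <- as.integer(t)
  names(sizes) <- names(t)
  sort(sizes, decreasing = TRUE)
}

#' @export
print.module_assignment <- function(x, ...) {
  cat("<module_assignment> ", length(x$labels), " transcripts, ",
      length(x$sizes), " modules (grey: ",
      sum(x$labels == "grey"), ")\n", sep = "")
  invisible(x)
}

#' Merge modules with similar eigengenes
#'
#' Iteratively merges the module pair with the smallest eigengene
#' dissimilarity `1 - cor(ME_i, ME_j)` while it is below the threshold,
#' recomputing eigengenes after every merge. Labels are re-assigned by
#' decreasing size after merging; the module count never increases and
#' re-running on merged output is a fixed point.
#'
#' @param assignment a `module_assignment`.
#' @param expr the expression matrix modules were detected on.
#' @param params a [network_params()]; the threshold is `me_diss_thresh`
#'   unless `use_merge_cut_height`.
#' @return a `module_assignment` with an `eigengenes` element (matrix
#'   module x sample).
#' @export
merge_modules <- function(assignment, expr, params = network_params()) {
  thresh <- if (params$use_merge_cut_height) params$merge_cut_height
  else params$me_diss_thresh
  labels <- assignment$labels
  repeat {
    mods <- names(.module_sizes(labels))
    if (length(mods) < 2) break
    mes <- vapply(mods, function(m)
      module_eigengene(expr, names(labels)[labels == m]),
      numeric(ncol(expr)))
    diss <- 1 - stats::cor(mes)
    diag(diss) <- Inf
    if (min(diss) >= thresh) break
    idx <- which(diss == min(diss), arr.ind = TRUE)[1, ]
    keep <- mods[min(idx)]; drop <- mods[max(idx)]
    labels[labels == drop] <- keep
  }
  # refresh color order by size
  mods <- names(.module_sizes(labels))
  raw <- integer(length(labels))
  for (i in seq_along(mods)) raw[labels == mods[i]] <- i
  labels <- .color_labels(raw, names(labels))
  mods <- names(.module_sizes(labels))
  mes <- vapply(mods, function(m)
    module_eigengene(expr, names(labels)[labels == m]), numeric(ncol(expr)))
  structure(list(labels = labels, sizes = .module_sizes(labels),
                 tree = assignment$tree,
                 eigengenes = t(mes)),
            class = "module_assignment")
}

#' Module eigengenes for an assignment
#'
#' @param assignment a `module_assignment`.
#' @param expr expression matrix.
#' @return matrix module x sample of eigengenes (grey excluded).
#' @export
module_eigengenes <- function(assignment, expr) {
  mods <- names(.module_sizes(assignment$labels))
  t(vapply(mods, function(m)
    module_eigengene(expr, names(assignment$labels)[assignment$labels == m]),
    numeric(ncol(expr))))
}

#' Module-trait correlation and top-3 module selection
#'
#' Pearson correlation between every module eigengene and every compound's
#' emission vector over the shared samples; for each compound, modules are
#' ranked by `|r|` descending and the top three reported with their signed
#' r. Grey is never ranked; compounds constant across samples are skipped
#' with a warning.
#'
#' @param eigengenes matrix module x sample.
#' @param volatiles matrix compound x sample (emission rates).
#' @return list of class `module_trait_table` with `correlations` (matrix
#'   module x compound) and `top3` (data.frame compound, rank, module, r).
#' @export
module_trait_cor <- function(eigengenes, volatiles) {
  common <- intersect(colnames(eigengenes), colnames(volatiles))
  if (length(common) < 3) stop("eigengene and volatile samples do not align")
  e <- eigengenes[, common, drop = FALSE]
  v <- volatiles[, common, drop = FALSE]
  const <- apply(v, 1, stats::sd) == 0
  if (any(const)) {
    warning("constant compound vectors skipped: ",
            paste(rownames(v)[const], collapse = ", "))
    v <- v[!const, , drop = FALSE]
  }
  r <- stats::cor(t(e), t(v))   # module x compound
  top3 <- do.call(rbind, lapply(colnames(r), function(cp) {
    ord <- order(-abs(r[, cp]))
    k <- utils::head(ord, 3)
    data.frame(compound = cp, rank = seq_along(k),
               module = rownames(r)[k], r = r[k, cp],
               stringsAsFactors = FALSE)
  }))
  rownames(top3) <- NULL
  structure(list(correlations = r, top3 = top3),
            class = "module_trait_table")
}

#' End-to-end module detection from expression to merged modules
#'
#' Convenience wrapper: adjacency, TOM, dissimilarity, detection, merging.
#'
#' @param expr numeric matrix, transcripts x samples.
#' @param params a [network_params()].
#' @return merged `module_assignment` (with eigengenes).
#' @export
build_network <- function(expr, params = network_params()) {
  adj <- adjacency_matrix(expr, params$power, params$min_samples)
  tom <- tom_similarity(adj)
  assignment <- detect_modules(1 - tom, params)
  if (!length(assignment$sizes)) return(assignment)
  merge_modules(assignment, expr, params)
}
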