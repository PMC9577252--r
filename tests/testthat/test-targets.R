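test_that("co-location pairs at the 100 kb gap boundary, inclusively", {
  ann <- make_ann(list(
    list(id = "near", biotype = "protein_coding", strand = "+",
         starts = 1000, ends = 2000),
    # gap to the lncRNA is exactly 100,000 bp
    list(id = "edge", biotype = "protein_coding", strand = "-",
         starts = 300000, ends = 301000),
    # one bp beyond the window
    list(id = "far", biotype = "protein_coding", strand = "+",
         starts = 501102, ends = 502100),
    list(id = "overlapping", biotype = "protein_coding", strand = "+",
         starts = 400900, ends = 401050)
  ))
  lnc <- make_ts(list(
    list(id = "l1", strand = "+", starts = 401001, ends = 401000 + 100)
  ))
  pairs <- colocate_targets(lnc, ann, target_params(window_bp = 100000))
  expect_setequal(pairs$gene_id, c("edge", "overlapping"))
  expect_equal(pairs$distance_bp[pairs$gene_id == "edge"], 100000)
  expect_equal(pairs$distance_bp[pairs$gene_id == "overlapping"], 0)
})

test_that("co-location matches a brute-force all-pairs scan", {
  withr::local_seed(21)
  n_g <- 40; n_l <- 15
  g_start <- sort(sample(1:2e6, n_g)); g_end <- g_start + sample(500:5000, n_g, TRUE)
  l_start <- sort(sample(1:2e6, n_l)); l_end <- l_start + sample(200:2000, n_l, TRUE)
  ann <- make_ann(lapply(seq_len(n_g), function(i)
    list(id = paste0("g", i), biotype = "protein_coding",
         strand = sample(c("+", "-"), 1), starts = g_start[i], ends = g_end[i])))
  lnc <- make_ts(lapply(seq_len(n_l), function(i)
    list(id = paste0("l", i), strand = "+", starts = l_start[i],
         ends = l_end[i])))
  pairs <- colocate_targets(lnc, ann)
  # oracle: gap between closest edges, 0 on overlap
  expected <- list()
  for (i in seq_len(n_l)) for (j in seq_len(n_g)) {
    gap <- max(0, max(l_start[i], g_start[j]) - min(l_end[i], g_end[j]) - 1)
    if (gap <= 100000)
      expected[[length(expected) + 1]] <- c(paste0("l", i), paste0("g", j), gap)
  }
  expected <- do.call(rbind, expected)
  key <- function(a, b) paste(a, b)
  expect_setequal(key(pairs$lnc_id, pairs$gene_id),
                  key(expected[, 1], expected[, 2]))
  m <- match(key(pairs$lnc_id, pairs$gene_id), key(expected[, 1], expected[, 2]))
  expect_equal(pairs$distance_bp, as.integer(expected[m, 3]))
})

test_that("shrinking the window never adds pairs", {
  sim <- shared_sim()
  man <- sim$manifest$transcripts
  lnc <- subset_transcripts(sim$transcripts,
                            head(man$transcript_id[man$is_lnc], 30))
  big <- colocate_targets(lnc, sim$annotation, target_params(window_bp = 100000))
  small <- colocate_targets(lnc, sim$annotation, target_params(window_bp = 20000))
  key <- function(p) paste(p$lnc_id, p$gene_id)
  expect_true(all(key(small) %in% key(big)))
  expect_true(all(small$distance_bp <= 20000))
})

test_that("co-expression pairing follows the signed-r rule", {
  x <- matrix(c(1, 2, 3, 4, 5, 6, 7, 8), 1,
              dimnames = list("l1", paste0("s", 1:8)))
  same <- matrix(c(1, 2, 3, 4, 5, 6, 7, 8), 1,
                 dimnames = list("gsame", paste0("s", 1:8)))
  anti <- -same; rownames(anti) <- "ganti"
  genes <- rbind(same, anti)
  pairs <- coexpress_targets(x, genes)
  expect_equal(pairs$gene_id, "gsame")
  expect_equal(pairs$pearson_r, 1)
  # absolute mode admits the anti-correlated gene
  pairs_abs <- coexpress_targets(x, genes, target_params(absolute = TRUE))
  expect_setequal(pairs_abs$gene_id, c("gsame", "ganti"))
})

test_that("co-expression enforces the more-than-five-samples rule", {
  x <- matrix(1:5, 1, dimnames = list("l1", paste0("s", 1:5)))
  y <- matrix(1:5, 1, dimnames = list("g1", paste0("s", 1:5)))
  expect_error(coexpress_targets(x, y), "5")
})

test_that("constant vectors yield no pairs, with a warning", {
  x <- matrix(rep(2, 8), 1, dimnames = list("l1", paste0("s", 1:8)))
  y <- matrix(1:8, 1, dimnames = list("g1", paste0("s", 1:8)))
  expect_warning(pairs <- coexpress_targets(x, y), "constant")
  expect_equal(nrow(pairs), 0)
})

test_that("correlations match the covariance formula and ignore sample order", {
  withr::local_seed(12)
  lm_ <- matrix(rnorm(3 * 10), 3, dimnames = list(paste0("l", 1:3),
                                                  paste0("s", 1:10)))
  gm_ <- matrix(rnorm(4 * 10), 4, dimnames = list(paste0("g", 1:4),
                                                  paste0("s", 1:10)))
  p1 <- coexpress_targets(lm_, gm_, target_params(r_threshold = 0.01,
                                                  min_samples = 6))
  # direct covariance/variance oracle
  for (i in seq_len(nrow(p1))) {
    a <- lm_[p1$lnc_id[i], ]; b <- gm_[p1$gene_id[i], ]
    r_direct <- sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
    expect_equal(p1$pearson_r[i], r_direct, tolerance = 1e-12)
  }
  perm <- sample(colnames(lm_))
  p2 <- coexpress_targets(lm_[, perm], gm_[, perm],
                          target_params(r_threshold = 0.01, min_samples = 6))
  o <- order(p1$lnc_id, p1$gene_id)
  o2 <- order(p2$lnc_id, p2$gene_id)
  expect_equal(p1[o, ], p2[o2, ], ignore_attr = TRUE)
})

test_that("planted co-expression pairs are recovered on the fixture", {
  sim <- shared_sim()
  truth <- sim$manifest$coexpr_pairs
  man <- sim$manifest$transcripts
  lnc_expr <- sim$expr[unique(truth$lnc_id), , drop = FALSE]
  gene_expr <- sim$expr[man$transcript_id[man$category == "coding"], ,
                        drop = FALSE]
  pairs <- coexpress_targets(lnc_expr, gene_expr)
  key <- function(a, b) paste(a, b)
  recovered <- key(truth$lnc_id, truth$gene_tx) %in%
    key(pairs$lnc_id, pairs$gene_id)
  expect_gte(mean(recovered), 0.9)
})

test_that("curated-list intersection partitions pairs", {
  pairs <- data.frame(lnc_id = c("l1", "l1", "l2"),
                      gene_id = c("g1", "g2", "g3"),
                      mechanism = "co_expression", pearson_r = 0.99)
  res0 <- intersect_gene_lists(pairs)
  expect_true(all(res0$pairs$link == "other"))
  res1 <- intersect_gene_lists(pairs, scent_genes = c("g1", "g2", "g3"))
  expect_true(all(res1$pairs$link == "scent"))
  res2 <- intersect_gene_lists(pairs, scent_genes = "g1", tf_homologs = "g3")
  expect_equal(res2$pairs$link, c("scent", "other", "tf"))
  expect_equal(res2$per_lnc$n_scent[res2$per_lnc$lnc_id == "l1"], 1)
  expect_warning(
    intersect_gene_lists(pairs, scent_genes = "nope",
                         known_genes = c("g1", "g2", "g3")),
    "unknown")
})
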