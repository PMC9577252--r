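test_that("soft-threshold adjacency powers the absolute correlation", {
  s <- paste0("s", 1:16)
  x <- matrix(rnorm(16), 1)
  expr <- rbind(a = x[1, ], b = x[1, ], c = -0.0 + x[1, ] * -1)
  colnames(expr) <- s
  adj <- adjacency_matrix(expr, power = 6)
  expect_equal(adj["a", "b"], 1)
  expect_equal(adj["a", "c"], 1)  # unsigned: anti-correlation counts fully
  expect_equal(diag(adj), c(a = 0, b = 0, c = 0))
  # numeric value: |r| = 0.8 at power 6
  expect_equal(0.8^6, 0.262144)
})

test_that("too few samples or constant rows are handled explicitly", {
  expr <- matrix(rnorm(10 * 5), 10)
  colnames(expr) <- paste0("s", 1:5)
  expect_error(adjacency_matrix(expr), "15 samples")
  expr2 <- rbind(flat = rep(1, 16), live = rnorm(16))
  colnames(expr2) <- paste0("s", 1:16)
  expect_warning(adj <- adjacency_matrix(expr2), "constant")
  expect_equal(adj["flat", "live"], 0)
})

test_that("TOM closed forms hold", {
  # two nodes: TOM equals adjacency
  for (a in c(0.2, 0.5, 0.9)) {
    m <- matrix(c(0, a, a, 0), 2)
    expect_equal(tom_similarity(m)[1, 2], a)
  }
  # three nodes, all a = 0.5: (0.25 + 0.5) / (1 + 1 - 0.5) = 0.5
  m3 <- matrix(0.5, 3, 3); diag(m3) <- 0
  tom3 <- tom_similarity(m3)
  expect_true(all(abs(tom3[upper.tri(tom3)] - 0.5) < 1e-15))
  # empty network
  z <- matrix(0, 4, 4)
  tz <- tom_similarity(z)
  expect_true(all(tz[upper.tri(tz)] == 0))
  expect_equal(diag(tz), rep(1, 4))
  expect_error(tom_similarity(matrix(c(0, 1, 0.5, 0), 2)), "symmetric")
})

test_that("TOM matches the double-loop oracle on random networks", {
  withr::local_seed(41)
  for (i in 1:5) {
    a <- matrix(runif(64), 8); a <- (a + t(a)) / 2; diag(a) <- 0
    expect_lt(max(abs(tom_similarity(a) - tom_oracle(a))), 1e-12)
  }
})

test_that("module eigengene is the oriented first principal component", {
  s <- paste0("s", 1:16)
  v <- rnorm(16)
  expr <- rbind(a = v, b = v, c = v)
  colnames(expr) <- s
  me <- module_eigengene(expr, c("a", "b", "c"))
  expect_equal(abs(cor(me, v)), 1, tolerance = 1e-12)
  expect_gt(cor(me, v), 0)  # orientation: positive mean member correlation
  # two members x and -x: tie broken toward the first member
  expr2 <- rbind(a = v, b = -v); colnames(expr2) <- s
  me2 <- module_eigengene(expr2, c("a", "b"))
  expect_gte(cor(me2, v), 0)
  expect_error(module_eigengene(expr, "a"), ">= 2")
  flat <- rbind(a = rep(1, 16), b = rep(2, 16)); colnames(flat) <- s
  expect_error(module_eigengene(flat, c("a", "b")), "rank-0")
})

test_that("planted trajectory modules are detected exactly", {
  withr::local_seed(43)
  sim <- simulate_module_matrix(n_modules = 2, module_sizes = 10,
                                n_samples = 20, noise_sd = 0.2)
  asg <- build_network(sim$expr, network_params(min_samples = 15))
  expect_equal(length(asg$sizes), 2)
  expect_equal(ari(asg$labels, sim$labels), 1)
  # eigengenes track the planted trajectories
  for (m in names(asg$sizes)) {
    members <- names(asg$labels)[asg$labels == m]
    planted <- unique(sim$labels[members])
    expect_length(planted, 1)
    expect_gte(abs(cor(asg$eigengenes[m, ], sim$trajectories[, planted])),
               0.95)
  }
})

test_that("degenerate inputs collapse to one module or all grey", {
  s <- paste0("s", 1:16)
  v <- rnorm(16)
  same <- matrix(rep(v, each = 12), 12, dimnames = list(paste0("t", 1:12), s))
  same <- same + rnorm(12 * 16, 0, 1e-6)
  asg <- detect_modules(1 - tom_similarity(adjacency_matrix(same, 6)),
                        network_params())
  expect_equal(length(asg$sizes), 1)
  expect_true(all(asg$labels != "grey"))

  few <- matrix(rnorm(5 * 16), 5, dimnames = list(paste0("t", 1:5), s))
  expect_warning(
    asg2 <- detect_modules(1 - tom_similarity(adjacency_matrix(few, 6)),
                           network_params()),
    "grey")
  expect_true(all(asg2$labels == "grey"))
})

test_that("clusters below the size floor are grey; colors order by size", {
  withr::local_seed(44)
  sim <- simulate_module_matrix(n_modules = 3, module_sizes = c(10, 7, 3),
                                n_samples = 20, noise_sd = 0.2)
  asg <- build_network(sim$expr, network_params(min_module_size = 6,
                                                min_samples = 15))
  # the 3-member group cannot form a module
  expect_equal(sum(asg$labels == "grey"), 3)
  expect_equal(names(asg$sizes), c("turquoise", "blue"))
  expect_equal(unname(asg$sizes), c(10, 7))
})

test_that("eigengene merging is monotone and idempotent", {
  withr::local_seed(45)
  sim <- simulate_module_matrix(n_modules = 3, module_sizes = 8,
                                n_samples = 20, noise_sd = 0.2)
  # duplicate one trajectory: modules 2 and 3 share it
  expr <- sim$expr
  dup_ids <- names(sim$labels)[sim$labels == "planted03"]
  for (id in dup_ids)
    expr[id, ] <- pmax(10 + 3 * sim$trajectories[, 2] + rnorm(20, 0, 0.2),
                       0.01)
  asg <- detect_modules(1 - tom_similarity(adjacency_matrix(
    expr, 6, min_samples = 15)), network_params())
  merged <- merge_modules(asg, expr, network_params())
  expect_lte(length(merged$sizes), length(asg$sizes))
  truth <- ifelse(sim$labels == "planted03", "planted02", sim$labels)
  expect_equal(ari(merged$labels, truth), 1)
  again <- merge_modules(merged, expr, network_params())
  expect_equal(sort(names(again$sizes)), sort(names(merged$sizes)))
  expect_equal(ari(again$labels, merged$labels), 1)
})

test_that("module-trait correlation ranks the planted module first", {
  withr::local_seed(46)
  sim <- simulate_module_matrix(
    n_modules = 4, module_sizes = 8, n_samples = 24,
    compounds = data.frame(compound = c("geraniol", "noise_cpd"),
                           module_index = c(2, 3), r = c(0.98, 0.0)))
  asg <- build_network(sim$expr, network_params(min_samples = 15))
  mt <- module_trait_cor(asg$eigengenes, sim$volatiles)
  # the module holding planted02's members should rank first for geraniol
  members <- names(sim$labels)[sim$labels == "planted02"]
  det <- names(which.max(table(asg$labels[members])))
  top <- mt$top3[mt$top3$compound == "geraniol", ]
  expect_equal(top$module[1], det)
  expect_gte(abs(top$r[1]), 0.9)
  # an unlinked compound still yields three ranked modules
  expect_equal(nrow(mt$top3[mt$top3$compound == "noise_cpd", ]), 3)
  expect_false("grey" %in% mt$top3$module)
})

test_that("a compound equal to an eigengene correlates perfectly", {
  withr::local_seed(47)
  sim <- simulate_module_matrix(n_modules = 3, module_sizes = 8,
                                n_samples = 20, noise_sd = 0.2)
  asg <- build_network(sim$expr, network_params(min_samples = 15))
  vol <- asg$eigengenes["turquoise", , drop = FALSE]
  rownames(vol) <- "self"
  mt <- module_trait_cor(asg$eigengenes, vol)
  top <- mt$top3[mt$top3$compound == "self", ]
  expect_equal(top$module[1], "turquoise")
  expect_equal(top$r[1], 1, tolerance = 1e-12)
})
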