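test_that("GMT files round-trip", {
  sets <- list(A = c("g1", "g2", "g3"), B = sprintf("g%d", 1:12))
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, path, descriptions = c("first", "second"))
  back <- read_gmt(path)
  expect_equal(back$A, sets$A)
  expect_equal(back$B, sets$B)
  expect_equal(attr(back, "description"), c("first", "second"))
  writeLines("just_one_field", path)
  expect_error(read_gmt(path), "fewer than 3")
})

test_that("hypergeometric ORA matches exact enumeration on toy margins", {
  bg <- sprintf("g%02d", 1:20)
  coll <- list(S = bg[1:5], tiny = bg[1:3], huge = bg)
  res <- ora_hypergeometric(bg[1:5], bg, coll, set_size = c(5, 10))
  # all 5 hits inside the 5-gene set: the single most extreme configuration
  expect_equal(res$p[res$set == "S"], 1 / choose(20, 5), tolerance = 1e-12)
  # sets outside the size bounds are not tested
  expect_false(any(c("tiny", "huge") %in% res$set))
  # zero overlap with a small set: upper tail at 0 is 1
  res0 <- ora_hypergeometric(bg[6:10], bg, list(S = bg[1:5]), set_size = c(5, 10))
  expect_equal(res0$p, 1)
  expect_error(ora_hypergeometric(c(bg[1], "gX"), bg, coll), "gX")
})

test_that("random hit lists are almost never significant at q < 0.005", {
  set.seed(123)
  bg <- sprintf("g%04d", 1:800)
  coll <- simulate_gene_sets(bg, n_sets = 500, size_range = c(10, 80), seed = 5)
  n_disc <- vapply(1:100, function(i) {
    res <- ora_hypergeometric(sample(bg, 60), bg, coll)
    sum(res$q < 0.005, na.rm = TRUE)
  }, 0L)
  expect_gte(mean(n_disc == 0), 0.95)
})

test_that("the overlap test equals the exact hypergeometric tail and is symmetric", {
  U <- sprintf("g%03d", 1:100)
  A <- U[1:10]; B <- U[6:25]  # overlap 5
  got <- overlap_test(A, B, U)
  expect_equal(got$overlap, 5)
  exact <- sum(dhyper(5:10, 10, 90, 20))
  expect_equal(got$p, exact, tolerance = 1e-12)
  expect_equal(overlap_test(B, A, U)$p, got$p)
  # identical lists: the single most extreme table
  same <- overlap_test(A, A, U)
  expect_equal(same$p, dhyper(10, 10, 90, 10), tolerance = 1e-15)
  # disjoint lists covering the universe: p = 1
  expect_equal(overlap_test(U[1:40], U[41:100], U)$p, 1)
  expect_error(overlap_test(A, B, character()), "empty")
  expect_error(overlap_test(c(A, "zz"), B, U), "zz")
})

test_that("Wallenius at odds 1 collapses to the central hypergeometric", {
  for (m in list(c(5, 15, 6), c(12, 30, 10), c(40, 160, 50))) {
    pmf <- wallenius_pmf(m[1], m[2], m[3], omega = 1)
    expect_lt(max(abs(pmf - dhyper(0:min(m[3], m[1]), m[1], m[2], m[3]))), 1e-8)
  }
  # omega -> 1 limit is continuous
  pmf_near <- wallenius_pmf(12, 30, 10, omega = 1 + 1e-9)
  expect_lt(max(abs(pmf_near - dhyper(0:10, 12, 30, 10))), 1e-6)
})

test_that("the Wallenius tail is monotone in the overlap and in the odds", {
  tails <- vapply(0:8, wallenius_upper_tail, 0, m1 = 10, m2 = 40, n = 8,
                  omega = 2.5)
  expect_true(all(diff(tails) < 0))
  # larger bias odds make any given overlap less surprising
  p_low <- wallenius_upper_tail(6, 10, 40, 8, omega = 1)
  p_high <- wallenius_upper_tail(6, 10, 40, 8, omega = 3)
  expect_gt(p_high, p_low)
})

test_that("bias-adjusted ORA matches a weighted-sampling Monte-Carlo oracle", {
  # 50 genes; the 10 in-set genes carry 5 probes each, the 40 others 2 each,
  # so the biased-urn weights are exactly two-level with odds 5/2
  genes <- sprintf("G%02d", 1:50)
  counts <- c(rep(5, 10), rep(2, 40))
  ann <- tibble::tibble(
    feature = unlist(mapply(function(g, c) sprintf("%s_cg%d", g, seq_len(c)),
                            genes, counts)),
    gene = rep(genes, counts)
  )
  in_set <- genes %in% genes[1:10]
  n_draw <- 8; observed <- 4
  p_wall <- wallenius_upper_tail(observed, 10, 40, n_draw, omega = 5 / 2)
  mc <- oracle_biased_urn_tail(observed, in_set, counts, n_draw, n_mc = 1e5,
                               seed = 2)
  expect_lt(abs(p_wall - mc$p), 3 * mc$se)
  # and ora_methylation reproduces that p from raw CpG lists: pick hit CpGs
  # giving 4 in-set hit genes + 4 out-of-set hit genes
  hit_cpgs <- c(sprintf("G0%d_cg1", 1:4), sprintf("G%d_cg1", 11:14))
  res <- ora_methylation(hit_cpgs, ann$feature, ann,
                         list(S = genes[1:10]), set_size = c(10, 50))
  expect_equal(res$odds, 5 / 2)
  expect_equal(res$p, p_wall, tolerance = 1e-12)
})

test_that("probe-count bias breaks the plain test and the adjustment restores it", {
  set.seed(7)
  n_genes <- 500
  counts <- rnbinom(n_genes, size = 1.2, mu = 8) + 1
  genes <- sprintf("G%03d", seq_len(n_genes))
  ann <- tibble::tibble(feature = sprintf("cg%05d", seq_len(sum(counts))),
                        gene = rep(genes, counts))
  set_hi <- genes[order(-counts)][21:120]
  coll <- list(HI = set_hi)
  res <- replicate(150, {
    hits <- sample(ann$feature, 80)  # null: uniform over CpGs
    adj <- ora_methylation(hits, ann$feature, ann, coll)
    hit_genes <- unique(ann$gene[ann$feature %in% hits])
    un <- ora_hypergeometric(hit_genes, genes, coll)
    c(adj = adj$p, unadj = un$p)
  })
  expect_gt(mean(res["unadj", ] < 0.05), 0.5)    # badly anti-conservative
  rej_adj <- mean(res["adj", ] < 0.05)
  expect_gt(rej_adj, 0.01)
  expect_lt(rej_adj, 0.10)
})

test_that("gene-level hit status ignores duplicate probe rows", {
  genes <- sprintf("G%02d", 1:30)
  ann <- tibble::tibble(feature = sprintf("cg%03d", 1:60),
                        gene = rep(genes, each = 2))
  coll <- list(S = genes[1:15])
  hits <- c("cg001", "cg002")  # both probes of G01
  a <- ora_methylation(hits, ann$feature, ann, coll, set_size = c(10, 30))
  b <- ora_methylation("cg001", ann$feature, ann, coll, set_size = c(10, 30))
  expect_equal(a$overlap, b$overlap)
  # a multi-gene probe contributes a hit to every annotated gene
  ann2 <- dplyr::bind_rows(ann, tibble::tibble(feature = "cg001", gene = "G20"))
  cl <- musclemeta:::collapse_probes_to_genes("cg001", ann2$feature, ann2)
  expect_setequal(cl$hit_genes, c("G01", "G20"))
})

test_that("cell-type marker checks reuse the ORA machinery with size filtering", {
  set.seed(9)
  genes <- sprintf("G%03d", 1:300)
  markers <- list(
    endothelial = genes[1:20], typeI_fiber = genes[21:60],
    too_small = genes[1:4], too_big = genes
  )
  # expression side: hits seeded inside one marker set
  hits <- c(genes[21:35], sample(genes[61:300], 10))
  res <- celltype_confound_check(hits, genes, markers)
  expect_false("too_small" %in% res$set)   # below the 10-gene floor
  res_narrow <- celltype_confound_check(hits, genes, markers,
                                        set_size = c(10, 100))
  expect_setequal(res_narrow$set, c("endothelial", "typeI_fiber"))
  expect_equal(res$set[which.min(res$q)], "typeI_fiber")
  # disjoint markers: nothing significant
  res0 <- celltype_confound_check(genes[250:280], genes,
                                  markers[c("endothelial", "typeI_fiber")])
  expect_true(all(res0$p > 0.5))
  # methylation side delegates to the bias-adjusted test
  ann <- tibble::tibble(feature = sprintf("cg%04d", 1:600),
                        gene = rep(genes, each = 2))
  hit_cpgs <- ann$feature[ann$gene %in% hits]
  resm <- celltype_confound_check(hit_cpgs, ann$feature, markers,
                                  probe_gene_map = ann)
  expect_equal(resm$set[which.min(resm$q)], "typeI_fiber")
  expect_true(all(resm$odds > 0))
})
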