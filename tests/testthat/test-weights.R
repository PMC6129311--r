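test_that("fold-change is value over the all-tissue mean, with missing as zero", {
  # constant positive gene -> e = 1 everywhere
  et <- expression_table(tibble::tibble(
    gene = "G1", tissue = paste0("t", 1:4), value = 7
  ))
  e <- expression_fold_change(et)
  expect_equal(e$e, rep(1, 4))

  # {10, 0, 0, 0, 0}: mean 2, so e = {5, 0, 0, 0, 0}
  et <- expression_table(tibble::tibble(
    gene = "G1", tissue = paste0("t", 1:5), value = c(10, 0, 0, 0, 0)
  ))
  expect_equal(expression_fold_change(et)$e, c(5, 0, 0, 0, 0))

  # missing cell: e = 0 there, and it contributes 0 to the denominator
  et <- expression_table(
    tibble::tibble(gene = "G1", tissue = c("t1", "t3", "t4"), value = c(10, 5, 5)),
    tissues = paste0("t", 1:4)
  )
  e <- expression_fold_change(et)
  expect_equal(e$e[e$tissue == "t2"], 0)
  expect_equal(e$e[e$tissue == "t1"], 10 / 5) # mean = (10 + 0 + 5 + 5) / 4

  # all-zero (or all-missing) gene -> e = 0 everywhere
  et <- expression_table(
    tibble::tibble(gene = c("G1", "G2"), tissue = "t1", value = c(0, 1)),
    tissues = c("t1", "t2")
  )
  e <- expression_fold_change(et)
  expect_equal(e$e[e$gene == "G1"], c(0, 0))

  single <- expression_table(tibble::tibble(gene = "G1", tissue = "t1", value = 1))
  expect_error(expression_fold_change(single), "2 tissues")
})

test_that("IHC activity: detected >= Low is 1, Not detected is 0, no record is 1", {
  ihc <- tiny_ihc()
  a <- ihc_activity(ihc, c("G1", "G2"), c("liver", "lung", "skin"))
  get <- function(g, t) a$a[a$gene == g & a$tissue == t]
  expect_equal(get("G1", "liver"), 1) # High
  expect_equal(get("G1", "lung"), 0)  # Not detected
  expect_equal(get("G1", "skin"), 1)  # no record
  expect_equal(get("G2", "liver"), 1) # Low
})

test_that("IHC activity collapses cell types by maximum and can filter reliability", {
  ihc <- ihc_table(tibble::tibble(
    gene = "G1", tissue = "liver",
    cell_type = c("hepatocyte", "bile duct"),
    level = c("Not detected", "Medium"),
    reliability = c("Supported", "Uncertain")
  ))
  a <- ihc_activity(ihc, "G1", "liver")
  expect_equal(a$a, 1) # detected in at least one cell type
  a2 <- ihc_activity(ihc, "G1", "liver", drop_uncertain = TRUE)
  expect_equal(a2$a, 0) # only the Not detected record remains
})

test_that("gene weight is the product of fold-change and activity", {
  gw <- gene_weights(tiny_expr(), tiny_ihc())
  get <- function(g, t) gw[gw$gene == g & gw$tissue == t, ]
  # G1: values {10, 2, 0}, mean 4 -> e = {2.5, 0.5, 0}
  r <- get("G1", "liver")
  expect_equal(r$e, 2.5)
  expect_equal(r$weight, 2.5) # a = 1 (High)
  r <- get("G1", "lung")
  expect_equal(r$e, 0.5)
  expect_equal(r$weight, 0) # e > 0 but a = 0 (Not detected)
  r <- get("G1", "skin")
  expect_equal(r$weight, 0) # a = 1 (missing IHC) but e = 0
})

test_that("gene weights reconcile tissues by intersection and reject empty overlap", {
  expr <- tiny_expr()
  ihc <- ihc_table(tibble::tibble(
    gene = "G1", tissue = c("liver", "kidney"), level = c("Low", "High")
  ))
  expect_message(gw <- gene_weights(expr, ihc), "dropped")
  expect_setequal(unique(gw$tissue), "liver")

  far <- ihc_table(tibble::tibble(gene = "G1", tissue = "kidney", level = "Low"))
  expect_error(suppressMessages(gene_weights(expr, far)), "no tissues shared")

  # an IHC table with no records imposes no tissue restriction
  none <- ihc_table(tibble::tibble(gene = character(), tissue = character(),
                                   level = character()))
  gw2 <- gene_weights(expr, none)
  expect_setequal(unique(gw2$tissue), c("liver", "lung", "skin"))
  expect_true(all(gw2$a == 1))
})

test_that("gene weight invariants hold on random inputs", {
  sim <- simulate_hpa(n_genes = 300, tissues = paste0("t", 1:5),
                      planted = data.frame(size = 15, tissue = "t2", fold = 4),
                      n_decoys = 5, ihc_detect_prob = 0.6,
                      rna_missing_prob = 0.1, seed = 99)
  gw <- gene_weights(sim$expression, sim$ihc)
  expect_true(all(gw$weight >= 0))
  expect_true(all(gw$a %in% c(0, 1)))
  expect_true(all(gw$weight[gw$a == 0] == 0))
  expect_equal(gw$weight, gw$e * gw$a)
})

test_that("set weight matches the known symmetric case and the one-sided direction", {
  r <- set_weight(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$weight, -log(0.5), tolerance = 1e-12)
  up <- set_weight(c(5, 6, 7), c(1, 2, 3))
  expect_gt(up$weight, -log(0.5))
  down <- set_weight(c(1, 2, 3), c(5, 6, 7))
  expect_gte(down$weight, 0)
  expect_lt(down$weight, -log(0.5))
})

test_that("set weight agrees with the incomplete-beta oracle in both variance modes", {
  for (ve in c(FALSE, TRUE)) {
    r <- set_weight(c(5, 6, 7), c(1, 2, 3), var_equal = ve)
    expect_equal(r$log_p, oracle_set_log_p(c(5, 6, 7), c(1, 2, 3), var_equal = ve),
                 tolerance = 1e-12)
  }
  set.seed(202)
  for (i in 1:200) {
    m <- stats::rnorm(sample(2:30, 1), mean = stats::runif(1, 0, 2))
    cc <- stats::rnorm(sample(2:50, 1))
    ve <- i %% 2 == 0
    got <- set_weight(m, cc, var_equal = ve)$log_p
    want <- oracle_set_log_p(m, cc, var_equal = ve)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("set weight handles degenerate inputs and extreme separation", {
  expect_true(set_weight(1, c(1, 2))$degenerate)
  expect_true(set_weight(c(1, 2), 3)$degenerate)
  expect_true(set_weight(c(2, 2), c(2, 2))$degenerate)
  # one-group zero variance is still testable under Welch
  expect_false(set_weight(c(2, 2, 2), c(1, 2, 3))$degenerate)
  # log-space evaluation keeps huge separations finite
  big <- set_weight(stats::rnorm(50, 1e6), stats::rnorm(5000))
  expect_true(is.finite(big$weight))
  expect_gt(big$weight, 100)
})

test_that("set weight is monotone in member shift and invariant to common scaling", {
  set.seed(77)
  for (i in 1:25) {
    m <- stats::rnorm(10)
    cc <- stats::rnorm(40)
    w0 <- set_weight(m, cc)$weight
    expect_gte(set_weight(m + abs(stats::rnorm(1)), cc)$weight, w0)
    c_scale <- stats::runif(1, 0.1, 10)
    expect_equal(set_weight(m * c_scale, cc * c_scale)$weight, w0,
                 tolerance = 1e-9)
  }
})

test_that("log base rescales set weights as documented", {
  nat <- set_weight(c(5, 6, 7), c(1, 2, 3))
  ten <- set_weight(c(5, 6, 7), c(1, 2, 3), log_base = 10)
  expect_equal(ten$weight, nat$weight / log(10), tolerance = 1e-12)
})

test_that("collection weights: equal means give -log(0.5); small sets are flagged", {
  genes <- sprintf("G%03d", 1:100)
  gw <- tibble::tibble(gene = genes, tissue = "t1", weight = rep(c(1, 2), 50))
  # OTHER covers the rest of the genes so the collection universe is all 100
  gsc <- gene_set_collection(list(
    HALF = genes[1:50], # weights alternate 1,2 -> member and complement multisets match
    OTHER = genes[51:100],
    TINY = genes[1]
  ))
  sw <- collection_weights(gw, gsc)
  half <- sw[sw$set == "HALF", ]
  expect_equal(half$weight, -log(0.5), tolerance = 1e-12)
  expect_equal(half$n_used, 50L)
  tiny <- sw[sw$set == "TINY", ]
  expect_true(tiny$degenerate)
  expect_true(is.na(tiny$weight))
})

test_that("collection weights treat unmeasured universe genes as weight zero", {
  genes <- sprintf("G%03d", 1:40)
  measured <- genes[1:30]
  set.seed(5)
  gw <- tibble::tibble(gene = measured, tissue = "t1",
                       weight = stats::rexp(30))
  gsc <- gene_set_collection(list(A = genes[c(1:5, 31:35)], B = genes[6:15]))
  sw <- collection_weights(gw, gsc)
  # manual: universe = union of the set members; unmeasured members get 0
  universe <- gs_universe(gsc)
  w_all <- stats::setNames(rep(0, length(universe)), universe)
  w_all[intersect(measured, universe)] <-
    gw$weight[match(intersect(measured, universe), gw$gene)]
  m <- genes[c(1:5, 31:35)]
  want <- set_weight(w_all[m], w_all[setdiff(universe, m)])$weight
  expect_equal(sw$weight[sw$set == "A"], want, tolerance = 1e-12)

  # restricted universe drops the unmeasured genes instead
  swr <- collection_weights(gw, gsc, restrict_to_measured = TRUE)
  expect_equal(swr$n_used[swr$set == "A"], 5L)

  unrelated <- tibble::tibble(gene = "X1", tissue = "t1", weight = 1)
  expect_error(collection_weights(unrelated, gsc), "no overlap")
})

test_that("collection weights are invariant to gene-row permutation", {
  sim <- simulate_hpa(n_genes = 120, tissues = paste0("t", 1:3),
                      planted = data.frame(size = 10, tissue = "t1", fold = 3),
                      n_decoys = 6, seed = 3)
  gw <- gene_weights(sim$expression, sim$ihc)
  set.seed(1)
  perm <- gw[sample.int(nrow(gw)), ]
  a <- collection_weights(gw, sim$sets)
  b <- collection_weights(perm, sim$sets)
  b_ord <- b[match(paste(a$set, a$tissue), paste(b$set, b$tissue)), ]
  expect_equal(a$weight, b_ord$weight)
})

test_that("planted sets separate from decoys under the competitive test", {
  ranks <- vapply(1:20, function(s) {
    sim <- simulate_hpa(n_genes = 600, tissues = paste0("t", 1:5),
                        planted = data.frame(size = 20, tissue = "t1", fold = 5),
                        n_decoys = 30, seed = 1000 + s)
    gw <- gene_weights(sim$expression, sim$ihc)
    sw <- collection_weights(gw, sim$sets, tissues = "t1")
    ord <- order(-sw$weight, sw$set)
    which(sw$set[ord] == "PLANTED_T1_1")
  }, 1L)
  # planted set beats the median decoy always, and usually everything
  expect_true(all(ranks <= 15))
  expect_gte(mean(ranks == 1), 0.95)
})

test_that("multi-tissue weight takes the requested aggregate with exclusions", {
  sw <- tibble::tibble(
    set = rep(c("A", "B"), each = 4),
    tissue = rep(paste0("t", 1:4), 2),
    weight = c(3.7, 1.1, 5.0, 2.2, 1.0, NA, 2.0, 3.0)
  )
  mt <- suppressMessages(multi_tissue_weight(sw, paste0("t", 1:4)))
  expect_equal(mt$weight[mt$set == "A"], 1.1)
  expect_false("B" %in% mt$set)
  expect_equal(attr(mt, "excluded"), "B")

  one <- multi_tissue_weight(sw, "t1")
  expect_equal(one$weight[one$set == "A"], 3.7)
  expect_equal(one$weight[one$set == "B"], 1.0)

  mt_mean <- multi_tissue_weight(sw, c("t1", "t3"), aggregate = "mean")
  expect_equal(mt_mean$weight[mt_mean$set == "A"], mean(c(3.7, 5.0)))

  expect_error(multi_tissue_weight(sw, c("t1", "t9")), "t9")
})

test_that("minimum aggregation is bounded by components and monotone in tissue sets", {
  set.seed(42)
  for (i in 1:20) {
    n_t <- sample(2:6, 1)
    sw <- tibble::tibble(
      set = rep(sprintf("S%02d", 1:8), each = n_t),
      tissue = rep(paste0("t", 1:n_t), 8),
      weight = stats::rexp(8 * n_t)
    )
    all_t <- paste0("t", 1:n_t)
    sub_t <- all_t[1:sample(1:(n_t - 1), 1)]
    m_all <- multi_tissue_weight(sw, all_t)
    m_sub <- multi_tissue_weight(sw, sub_t)
    per_tissue <- tidyr::pivot_wider(sw, names_from = "tissue",
                                     values_from = "weight")
    for (s in m_all$set) {
      comp <- unlist(per_tissue[per_tissue$set == s, all_t])
      expect_lte(m_all$weight[m_all$set == s], min(comp) + 1e-12)
      expect_lte(m_all$weight[m_all$set == s], m_sub$weight[m_sub$set == s])
    }
  }
})
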