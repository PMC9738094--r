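toy_manifest <- function() {
  # panel TSSs: GENEA chr1:100000, GENEB chr1:500000
  data.frame(
    probe = paste0("cg", 1:6),
    chrom = c("1", "1", "1", "1", "1", "1"),
    pos = c(100000L, 110000L, 110001L, 90000L, 495000L, 503000L),
    stringsAsFactors = FALSE
  )
}

test_that("probe assignment is TSS +/- window, boundary inclusive", {
  panel <- toy_panel()
  pm <- suppressMessages(assign_promoter_probes(toy_manifest(), panel,
                                                window = 10000L))
  a <- pm$probe[pm$gene == "GENEA"]
  expect_true("cg1" %in% a)        # at the TSS
  expect_true("cg2" %in% a)        # TSS + 10000: inclusive
  expect_false("cg3" %in% a)       # TSS + 10001: out
  expect_true("cg4" %in% a)        # TSS - 10000
  expect_setequal(pm$probe[pm$gene == "GENEB"], c("cg5", "cg6"))
})

test_that("a probe between two close TSSs maps to both genes", {
  panel <- gene_panel(c("G1", "G2", "BRCA1", "BRCA2"),
                      c(FALSE, FALSE, TRUE, TRUE),
                      c("chr5", "chr5", "chr17", "chr13"),
                      c(100000L, 108000L, 1L, 1L))
  manifest <- data.frame(probe = "cgX", chrom = "chr5", pos = 104000L,
                         stringsAsFactors = FALSE)
  pm <- assign_promoter_probes(manifest, panel)
  expect_setequal(pm$gene, c("G1", "G2"))
  # shrinking the window never adds probes (monotone containment)
  for (w in c(10000L, 5000L, 3000L)) {
    inner <- assign_promoter_probes(manifest, panel, window = w)
    expect_true(all(paste(inner$probe, inner$gene) %in%
                      paste(pm$probe, pm$gene)))
  }
})

test_that("promoter means use window probes only, hypermethylation is strict >", {
  panel <- toy_panel()
  samples <- toy_samples(n_per_type = 2L, types = "TA")
  pm <- suppressMessages(assign_promoter_probes(toy_manifest(), panel))
  beta <- matrix(0.5, 6, 2, dimnames = list(paste0("cg", 1:6),
                                            samples$sample))
  beta[c("cg1", "cg2", "cg4"), ] <- c(0.2, 0.2, 0.4, 0.4, 0.3, 0.3)
  beta["cg3", ] <- 0.9   # outside the window: must be ignored
  prof <- promoter_means(list(beta = beta), pm, samples, panel)
  expect_equal(prof$mean["GENEA", "TA"], 0.3)
  expect_false(prof$hyper["GENEA", "TA"])          # exactly 0.3: not hyper
  beta[c("cg1", "cg2", "cg4"), ] <- 0.31
  prof2 <- promoter_means(list(beta = beta), pm, samples, panel)
  expect_equal(prof2$mean["GENEA", "TA"], 0.31)
  expect_true(prof2$hyper["GENEA", "TA"])
  # genes with no probes are missing, never zero
  expect_true(is.na(prof$mean["BRCA1", "TA"]))
  # permutation invariance to probe order
  prof3 <- promoter_means(list(beta = beta[6:1, ]), pm, samples, panel)
  expect_equal(prof3$mean, prof2$mean)
})

test_that("methylation load sums non-reference means and reports references", {
  panel <- load_default_panel()
  types <- c("TA", "TB")
  mean_mat <- matrix(0.5, nrow(panel), 2,
                     dimnames = list(panel$symbol, types))
  profile <- structure(list(mean = mean_mat, hyper = mean_mat > 0.3,
                            probe_count = setNames(rep(3L, 42), panel$symbol),
                            beta_threshold = 0.3),
                       class = "promoter_profile")
  load <- methylation_load(profile, panel)
  expect_equal(load$load, c(20, 20))                 # 40 genes x 0.5
  expect_equal(load$n_genes, c(40L, 40L))
  expect_equal(load$BRCA1, c(0.5, 0.5))
  # a missing gene cell is excluded and the included-gene count drops
  profile$mean[which(!panel$is_reference)[1], "TA"] <- NA
  load2 <- methylation_load(profile, panel)
  expect_equal(load2$load[1], 19.5)
  expect_equal(load2$n_genes[1], 39L)
})

test_that("constructed anti-correlation yields a silencing call", {
  panel <- toy_panel()
  samples <- toy_samples(n_per_type = 20L, types = "TA")
  pm <- suppressMessages(assign_promoter_probes(toy_manifest(), panel))
  set.seed(10)
  promoter <- runif(20, 0.2, 0.8)
  beta <- matrix(rep(promoter, each = 6), 6,
                 dimnames = list(paste0("cg", 1:6), samples$sample))
  expr <- matrix(8, 4, 20, dimnames = list(panel$symbol, samples$sample))
  expr["GENEA", ] <- 8 - promoter            # perfect anti-correlation
  expr["GENEB", ] <- 8 + 0.05 * promoter + rnorm(20, sd = 1)  # weak
  assoc <- methylation_expression_association(list(beta = beta), pm, expr,
                                              samples, panel)
  a <- assoc[assoc$gene == "GENEA", ]
  expect_equal(a$r, -1)
  expect_equal(a$call, "silencing")
  b <- assoc[assoc$gene == "GENEB", ]
  if (abs(b$r) < 0.5) expect_equal(b$call, "none")
  # enhancing direction
  expr["GENEA", ] <- 8 + promoter
  assoc2 <- methylation_expression_association(list(beta = beta), pm, expr,
                                               samples, panel)
  expect_equal(assoc2$call[assoc2$gene == "GENEA"], "enhancing")
})

test_that("planted silenced genes are recovered on a synthetic cohort", {
  gen <- generate_cohort(brcaness_design(seed = 21L, n_tumor = 50L,
                                         n_normal = 5L))
  b <- gen$bundle
  pm <- assign_promoter_probes(b$methylation$manifest, b$panel)
  assoc <- methylation_expression_association(b$methylation, pm,
                                              b$expression, b$samples,
                                              b$panel)
  planted <- rownames(gen$truth$silencing)[gen$truth$silencing[, "C01"] > 0]
  calls <- assoc$call[assoc$cancer_type == "C01" & assoc$gene %in% planted]
  expect_gte(mean(calls == "silencing"), 0.9)
  null_genes <- setdiff(rownames(gen$truth$silencing), planted)
  null_calls <- assoc$call[assoc$cancer_type == "C05" &
                             assoc$gene %in% null_genes]
  expect_lte(mean(null_calls != "none"), 0.2)
})

test_that("planted mean beta is recovered within 0.05 at 50 samples", {
  gen <- generate_cohort(brcaness_design(seed = 22L, n_tumor = 50L,
                                         n_normal = 5L))
  b <- gen$bundle
  pm <- assign_promoter_probes(b$methylation$manifest, b$panel)
  prof <- promoter_means(b$methylation, pm, b$samples, b$panel)
  est <- prof$mean[rownames(gen$truth$meth_beta), colnames(gen$truth$meth_beta)]
  expect_lt(max(abs(est - gen$truth$meth_beta), na.rm = TRUE), 0.05)
})
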