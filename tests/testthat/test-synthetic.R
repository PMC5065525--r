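# Generators: determinism, contracts, null behaviour, truth recovery.

small_cfg <- function(...) {
  sim_config(n_te_loci = c(SVA = 200L, `HERVH-int` = 150L, LTR7 = 150L,
                           AluY = 300L),
             n_genes = 40L, library_size = 8e4,
             stage_markers = c(morula = 40L),
             stage_marker_naive_up = c(morula = 25L), ...)
}

test_that("every generator is a pure function of (cfg, seed)", {
  cfg <- small_cfg()
  a <- gen_te_counts(cfg, seed = 7L); b <- gen_te_counts(cfg, seed = 7L)
  expect_identical(a$counts, b$counts)
  expect_identical(a$truth, b$truth)
  expect_false(identical(gen_te_counts(cfg, 8L)$counts, a$counts))

  e1 <- gen_embryo_counts(cfg, 7L); e2 <- gen_embryo_counts(cfg, 7L)
  expect_identical(e1$counts, e2$counts)
  # embryo and ESC worlds share the annotation and truth
  expect_identical(rownames(e1$counts), rownames(a$counts))

  m1 <- gen_methylome(cfg, 7L); m2 <- gen_methylome(cfg, 7L)
  expect_identical(m1$calls, m2$calls)
  q1 <- gen_qpcr_plate(cfg, 7L); q2 <- gen_qpcr_plate(cfg, 7L)
  expect_identical(q1$unknowns, q2$unknowns)
  al1 <- gen_allelic_counts(cfg, 7L); al2 <- gen_allelic_counts(cfg, 7L)
  expect_identical(al1$table, al2$table)
})

test_that("null world (no effect, no dispersion) gives ~5% raw-p positives", {
  cfg <- sim_config(n_te_loci = c(AluY = 3000L), n_genes = 10L,
                    library_size = 3e5, dispersion = 0, effect_log2fc = 0,
                    naive_up_fraction = c(SVA = 0),
                    primed_up_fraction = c(LTR7 = 0),
                    stage_markers = c(), stage_marker_naive_up = c())
  w <- gen_te_counts(cfg, seed = 21L)
  primed <- w$sheet$sample_id[w$sheet$state == "primed"]
  naive <- w$sheet$sample_id[grepl("^naive", w$sheet$state)]
  de <- differential_expression(w$counts, primed, naive)
  p <- de$p[de$detected]
  expect_gt(length(p), 2000)
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.02)
  # fold + BH gates drive calls to ~0 under the null
  expect_lt(mean(de$call != "no_change"), 0.005)
})

test_that("DE recovers >= 95% of designated naive-up loci (2-fold, p<0.05)", {
  cfg <- small_cfg()
  w <- gen_te_counts(cfg, seed = 31L)
  primed <- w$sheet$sample_id[w$sheet$state == "primed"]
  naive <- w$sheet$sample_id[grepl("^naive", w$sheet$state)]
  de <- differential_expression(w$counts, primed, naive, use_raw_p = TRUE)
  up <- w$truth$id[w$truth$direction == "naive_up" & w$truth$log2mu >= 3]
  expect_gt(length(up), 80)
  hit <- de$call[match(up, de$feature_id)] == "up_in_naive"
  expect_gte(mean(hit), 0.95)
})

test_that("embryo generator contracts and stage structure hold", {
  cfg <- small_cfg()
  expect_error(gen_embryo_counts(sim_config(embryo_stages = "morula",
                                            stage_markers = c())),
               ">= 2 embryo stages")
  expect_error(gen_embryo_counts(sim_config(embryo_cells = 3L)),
               ">= 5 cells")
  emb <- gen_embryo_counts(cfg, 5L)
  expect_equal(ncol(emb$counts),
               length(cfg$embryo_stages) * cfg$embryo_cells)
  # a stage without designated markers yields an (almost) empty set
  sets <- suppressWarnings(stage_specific_features(emb$counts, emb$sheet))
  expect_lt(nrow(sets$oocyte), 0.005 * nrow(emb$counts) + 3)
  des <- emb$truth$feature_id[emb$truth$stage == "morula"]
  expect_gte(mean(des %in% sets$morula$feature_id), 0.9)
})

test_that("methylome generator rejects zero coverage and hits design levels", {
  expect_error(sim_config(methylome = list(coverage_mean = 0)),
               "coverage_mean")
  cfg <- sim_config(methylome = list(n_cpg = 30000L, n_ch = 30000L,
                                     n_x_cgis = 0L),
                    imprint = list(n_dmrs = 0L, n_erased = 0L))
  m <- gen_methylome(cfg, 9L)
  expect_equal(global_level(m$calls$naive, "CpG"), 0.269, tolerance = 0.02)
  expect_equal(global_level(m$calls$naive, "CH"), 0.0019,
               tolerance = 0.10)
  expect_true(all(m$calls$naive$meth_reads <= m$calls$naive$total_reads))
  expect_true(all(m$calls$naive$total_reads >= 1L))
})

test_that("allelic extremes classify as designed and truth scores recovery", {
  cfg0 <- sim_config(allelic = list(n_genes = 120L,
                                    biallelic_fraction = c(primed = 0,
                                                           naive = 1)))
  al <- gen_allelic_counts(cfg0, 13L)
  genes <- filter_informative(al$table)
  cl <- classify_allelic(al$table[al$table$gene_id %in% genes, ])
  ps <- cl$per_sample
  # fraction-1 design: essentially all calls biallelic (binomial read noise
  # can push a rare gene's minor fraction under the band)
  expect_true(all(ps[grepl("^naive", names(ps))] >= 0.97))
  expect_true(all(ps[grepl("^primed", names(ps))] < 0.05))

  cfg1 <- sim_config(allelic = list(n_genes = 400L,
                                    biallelic_fraction = c(primed = 0.5)))
  al1 <- gen_allelic_counts(cfg1, 13L)
  cl1 <- classify_allelic(al1$table)
  # recovery of the intermediate fraction within the binomial 95% CI
  expect_lt(abs(mean(cl1$per_sample) - 0.5), 1.96 * sqrt(0.25 / 400))
})

test_that("qPCR generator: analytic spacing, detection spike, ceiling flags", {
  cfg <- sim_config(qpcr = list(noise_sd = 0,
                                conditions = list(x = list(
                                  n = 5L, positive_fractions = 1e-4))))
  pl <- gen_qpcr_plate(cfg, 2L)
  expect_equal(diff(pl$standards$ct), rep(log2(10) * 1, 4) * 1,
               tolerance = 1e-9)
  expect_equal(diff(pl$standards$ct)[1], 3.321928, tolerance = 1e-6)
  res <- call_embryos(pl)
  spiked <- res$per_embryo[!res$per_embryo$non_detect, ]
  expect_equal(nrow(spiked), 1L)
  expect_true(spiked$positive)
  expect_equal(spiked$est_fraction, 1e-4, tolerance = 1e-6)
  expect_error(gen_qpcr_plate(sim_config(qpcr = list(
    standards_log10 = c(-1, -2, -3)))), "4 decades")
})
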