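# Methylation levels, Mann-Whitney contrast, DMR erasure, X CGIs.

test_that("global weighted level: trivial arithmetic and edge cases", {
  expect_equal(global_level(toy_allc("c", 1:3, c(0L, 0L, 0L),
                                     c(10L, 10L, 10L))), 0)
  expect_equal(global_level(toy_allc("c", 1:3, c(10L, 10L, 10L),
                                     c(10L, 10L, 10L))), 1)
  expect_equal(global_level(toy_allc("c", 1:2, c(3L, 7L), c(10L, 10L))),
               0.5)
  expect_warning(lv <- global_level(toy_allc("c", 1L, 1L, 5L), "CH"),
                 "no covered")
  expect_true(is.na(lv))
})

test_that("region levels use half-open membership and match brute force", {
  calls <- toy_allc("chr1", c(100L, 200L), c(3L, 7L), c(10L, 10L))
  regions <- toy_genes("chr1", c(99L, 500L), c(200L, 600L),
                       id = c("hit", "empty"))
  lv <- region_levels(calls, regions)
  expect_equal(lv$weighted_level[lv$region_id == "hit"], 0.5)
  expect_equal(lv$n_sites[lv$region_id == "hit"], 2L)
  expect_true(is.na(lv$weighted_level[lv$region_id == "empty"]))
  # pos 100 (1-based) is 0-based 99: inside [99,200); pos 200 -> 199 inside
  calls2 <- toy_allc("chr1", c(99L, 201L), c(10L, 10L), c(10L, 10L))
  lv2 <- region_levels(calls2, regions)
  expect_equal(lv2$n_sites[lv2$region_id == "hit"], 0L)

  withr::with_seed(303L, {
    pos <- sort(sample.int(5e4, 800L))
    calls3 <- toy_allc("chr1", pos, rbinom(800, 20, 0.4), rep(20L, 800))
    rs <- sample.int(5e4, 100L)
    regions3 <- toy_genes("chr1", rs, rs + 700L,
                          id = sprintf("r%03d", 1:100))
  })
  lv3 <- region_levels(calls3, regions3)
  for (i in seq_len(100)) {                      # O(sites x regions) oracle
    inside <- (calls3$pos - 1L) >= rs[i] & (calls3$pos - 1L) < rs[i] + 700L
    want <- if (any(inside)) sum(calls3$meth_reads[inside]) /
      sum(calls3$total_reads[inside]) else NA_real_
    expect_equal(lv3$weighted_level[i], want)
  }
  # global equals a single whole-genome region
  whole <- toy_genes("chr1", 0L, 10^6, id = "genome")
  expect_equal(region_levels(calls3, whole)$weighted_level,
               global_level(calls3))
})

test_that("Mann-Whitney contrast matches exhaustive U and detects shifts", {
  lv <- data.frame(region_id = sprintf("r%02d", 1:16), context = "CpG",
                   weighted_level = c(0.1, 0.2, 0.15, 0.30, 0.22, 0.18,
                                      0.45, 0.52, 0.38, 0.41, 0.55, 0.60,
                                      0.35, 0.48, 0.50, 0.42),
                   n_sites = 10L, mean_coverage = 30)
  over <- sprintf("r%02d", 1:6); back <- sprintf("r%02d", 7:16)
  res <- overexpressed_te_methylation(lv, over, back)
  a <- lv$weighted_level[1:6]; b <- lv$weighted_level[7:16]
  U_brute <- sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  expect_equal(res$U, U_brute)
  expect_lt(res$p, 0.05)
  expect_lt(res$median_over, res$median_back)

  same <- overexpressed_te_methylation(lv, sprintf("r%02d", 7:11),
                                       sprintf("r%02d", 12:16))
  expect_gt(same$p, 0.2)
  tiny <- overexpressed_te_methylation(lv, "r01", back)
  expect_true(is.na(tiny$p))
  expect_false(is.na(tiny$median_over))
})

test_that("hypomethylated overexpressed set is detected (power)", {
  withr::with_seed(17L, {
    lv <- data.frame(
      region_id = sprintf("t%03d", 1:250), context = "CpG",
      weighted_level = c(rbeta(50, 8, 12) - 0.2, rbeta(200, 8, 12)),
      n_sites = 10L, mean_coverage = 30)
    lv$weighted_level <- pmax(lv$weighted_level, 0)
  })
  res <- overexpressed_te_methylation(lv, sprintf("t%03d", 1:50),
                                      sprintf("t%03d", 51:250))
  expect_lt(res$p, 0.05)
})

test_that("imprinted-DMR erasure verdicts follow the trajectory rule", {
  mk <- function(lv) data.frame(region_id = c("d1", "d2", "d3"),
                                context = "CpG", weighted_level = lv,
                                n_sites = 20L, mean_coverage = 30)
  th <- nb_thresholds()
  res <- classify_imprinted_dmrs(mk(c(0.5, 0.5, 0.2)),
                                 mk(c(0.1, 0.1, 0.1)),
                                 mk(c(0.1, 0.5, 0.1)), th)
  expect_equal(res$calls$verdict, c("erased", "retained", "ineligible"))
  expect_equal(res$fraction_erased, 0.5)
  all_den <- classify_imprinted_dmrs(mk(c(0.5, 0.5, 0.2)),
                                     mk(c(0.1, 0.1, 0.1)),
                                     mk(c(0.1, 0.5, 0.1)), th,
                                     denominator = "all")
  expect_equal(all_den$fraction_erased, 1 / 3)
  # coverage guard
  low <- mk(c(0.5, 0.5, 0.5)); low$n_sites <- 2L
  guard <- classify_imprinted_dmrs(low, mk(c(0.1, 0.1, 0.1)),
                                   mk(c(0.1, 0.1, 0.1)), th)
  expect_true(all(guard$calls$verdict == "ineligible"))
  expect_true(all(grepl("coverage", guard$calls$reason)))
})

test_that("erasure classification is monotone in naive/reprimed levels", {
  th <- nb_thresholds()
  mk <- function(lv) data.frame(region_id = "d", context = "CpG",
                                weighted_level = lv, n_sites = 20L,
                                mean_coverage = 30)
  verdict <- function(nv, rv)
    classify_imprinted_dmrs(mk(0.5), mk(nv), mk(rv), th)$calls$verdict
  for (nv in seq(0, 0.6, by = 0.1)) for (rv in seq(0, 0.6, by = 0.1)) {
    v <- verdict(nv, rv)
    if (v == "erased") {
      # decreasing either level can never flip erased -> retained
      expect_equal(verdict(max(nv - 0.1, 0), rv), "erased")
      expect_equal(verdict(nv, max(rv - 0.1, 0)), "erased")
    }
  }
})

test_that("X-linked CGI medians flag the primed-female signature", {
  cfg <- sim_config(methylome = list(n_cpg = 500L, n_ch = 500L,
                                     n_x_cgis = 120L))
  m <- gen_methylome(cfg, 19L)
  cg <- lapply(m$calls, region_levels, regions = m$x_cgis)
  sheet <- data.frame(sample_id = c("primed_m", "naive_m", "reprimed_m"),
                      state = c("primed", "naive_5iLA", "reprimed"),
                      stage = NA, sex = "female", replicate = 1L)
  xq <- xlinked_cgi_methylation(list(primed_m = cg$primed,
                                     naive_m = cg$naive,
                                     reprimed_m = cg$reprimed), sheet)
  expect_true(xq$flagged_intermediate[xq$sample_id == "primed_m"])
  expect_false(xq$flagged_intermediate[xq$sample_id == "naive_m"])
  expect_lt(xq$median[xq$sample_id == "naive_m"], 0.3)
  empty <- cg$primed; empty$weighted_level <- NA_real_
  expect_error(xlinked_cgi_methylation(list(primed_m = empty), sheet),
               "no covered")
})
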