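# Normalization, Welch/BH differential expression, polarization, top-N,
# top-SD clustering, PCA -- each against an independent oracle where the
# contract is numeric.

test_that("median-of-ratios size factors behave and match a hand oracle", {
  m <- toy_counts(50L, 4L, mu = 80)
  expect_equal(normalize_counts(cbind(m, m)[, 1:4])$size_factors,
               normalize_counts(m)$size_factors)
  same <- matrix(rep(m[, 1], 4), ncol = 4,
                 dimnames = list(rownames(m), paste0("s", 1:4)))
  expect_equal(unname(normalize_counts(same)$size_factors), rep(1, 4))

  doubled <- cbind(a = m[, 1], b = 2L * m[, 1])
  sf <- normalize_counts(doubled)$size_factors
  expect_equal(unname(sf["b"] / sf["a"]), 2)

  # independent reimplementation: per-sample median of count/geomean
  sf2 <- normalize_counts(m)$size_factors
  gm <- apply(m, 1, function(r) prod(r)^(1 / length(r)))
  keep <- apply(m, 1, function(r) all(r > 0))
  oracle <- apply(m[keep, ], 2, function(col)
    median(col / gm[keep]))
  expect_equal(unname(sf2), unname(oracle))

  z <- m
  z[cbind(seq_len(nrow(z)), rep_len(seq_len(ncol(z)), nrow(z)))] <- 0L
  expect_warning(normalize_counts(z), "library-size")   # no all-positive row
})

test_that("differential expression: identity, antisymmetry, group size", {
  m <- toy_counts(40L, 6L, mu = 100)
  colnames(m) <- c(paste0("a", 1:3), paste0("b", 1:3))
  mm <- cbind(m[, 1:3], m[, 1:3]); colnames(mm) <- colnames(m)
  de0 <- differential_expression(mm, paste0("a", 1:3), paste0("b", 1:3))
  expect_true(all(de0$log2fc == 0))
  expect_true(all(de0$call == "no_change"))

  de <- differential_expression(m, paste0("a", 1:3), paste0("b", 1:3),
                                nameA = "A", nameB = "B")
  sw <- differential_expression(m, paste0("b", 1:3), paste0("a", 1:3),
                                nameA = "B", nameB = "A")
  expect_equal(de$log2fc, -sw$log2fc)
  expect_equal(de$p, sw$p)
  mirrored <- c(up_in_A = "up_in_A", up_in_B = "up_in_B",
                no_change = "no_change")
  expect_equal(de$call, unname(mirrored[sw$call]))
  expect_error(differential_expression(m, "a1", paste0("b", 1:3)),
               ">= 2 samples")
  # invariants of the result type
  ok <- !is.na(de$p)
  expect_true(all(de$padj[ok] >= de$p[ok]))
  expect_true(all(de$detected | de$call == "no_change"))
})

test_that("Welch t and BH match a step-by-step oracle on a toy matrix", {
  m <- toy_counts(20L, 6L, seed = 55L, mu = 120)
  colnames(m) <- c(paste0("a", 1:3), paste0("b", 1:3))
  de <- differential_expression(m, paste0("a", 1:3), paste0("b", 1:3))
  nrm <- normalize_counts(m)$normalized
  lg <- log2(nrm + 1)
  oracle_p <- vapply(seq_len(20), function(i)
    stats::t.test(lg[i, 4:6], lg[i, 1:3])$p.value, numeric(1))
  expect_equal(de$p[!is.na(de$p)], oracle_p[!is.na(de$p)], tolerance = 1e-12)
  # brute-force BH: sorted p * m / rank with running minimum
  p <- de$p[de$detected]
  o <- order(p); mth <- length(p)
  adj <- p[o] * mth / seq_len(mth)
  for (i in (mth - 1):1) adj[i] <- min(adj[i], adj[i + 1])
  expect_equal(de$padj[de$detected][o], pmin(adj, 1), tolerance = 1e-12)
})

test_that("BH agrees with its brute-force definition on random inputs", {
  withr::with_seed(77L, {
    for (rep in 1:5) {
      p <- runif(50)^2
      adj <- bh_adjust(p)
      o <- order(p); m <- length(p)
      brute <- p[o] * m / seq_len(m)
      for (i in (m - 1):1) brute[i] <- min(brute[i], brute[i + 1])
      expect_equal(adj[o], pmin(brute, 1), tolerance = 1e-12)
      expect_equal(adj, stats::p.adjust(p, "BH"), tolerance = 1e-12)
    }
  })
})

test_that("polarization summaries reproduce the printed worked examples", {
  # the printed counts are the input: 847 detected HERVH-int, 610 DE of
  # which 546 primed-higher; 539 detected SVA-D, 530 DE, all naive-higher
  mk_de <- function(fam, n_det, n_naive, n_primed, offset = 0L) {
    n <- n_det
    id <- sprintf("%s_%04d", fam, seq_len(n) + offset)
    call <- c(rep("up_in_naive", n_naive), rep("up_in_primed", n_primed),
              rep("no_change", n - n_naive - n_primed))
    data.frame(feature_id = id, base_mean = 10, log2fc = 0, p = 0.5,
               padj = 0.5, call = call, detected = TRUE)
  }
  de <- rbind(mk_de("HERVH-int", 847L, 64L, 546L),
              mk_de("SVA-D", 539L, 530L, 0L))
  fams <- setNames(sub("_[0-9]+$", "", de$feature_id), de$feature_id)
  pol <- polarization_summary(de, fams)
  hervh <- pol[pol$family == "HERVH-int", ]
  expect_equal(hervh$n_de, 610L)
  expect_equal(hervh$pct_de, 72.0)
  expect_equal(hervh$pct_up_primed_of_de, 89.5)
  svad <- pol[pol$family == "SVA-D", ]
  expect_equal(svad$pct_de, 98.3)
  expect_equal(svad$pct_up_naive_of_de, 100.0)
  # naive + primed percentages cover the DE set
  expect_true(all(abs(pol$pct_up_naive_of_de + pol$pct_up_primed_of_de -
                        100) <= 0.1))
})

test_that("half-up rounding is used for printed percentages", {
  expect_equal(round_half_up(89.45, 1), 89.5)
  expect_equal(round_half_up(72.049, 1), 72.0)
  expect_equal(round_half_up(0.05, 1), 0.1)
})

test_that("top-n composition follows the rank oracle and handles ties", {
  de <- data.frame(feature_id = sprintf("f%02d", 1:10), base_mean = 1,
                   log2fc = c(5, 4, 3, 3, 3, 2, 1, -6, -2, 0.1),
                   p = 0.001, padj = 0.001,
                   call = c(rep("up_in_naive", 7), rep("up_in_primed", 2),
                            "no_change"),
                   detected = TRUE)
  subfam <- setNames(rep(c("SVA_D", "SVA_F"), 5), de$feature_id)
  top <- top_n_composition(de, 4L, subfam)
  expect_equal(top$n_actual, 6L)   # |lfc| 6,5,4 then a three-way tie at 3
  expect_equal(top$n_requested, 4L)
  expect_equal(sum(top$tally), 6L)
  # full sort oracle
  dd <- de[de$call != "no_change", ]
  cut <- sort(abs(dd$log2fc), decreasing = TRUE)[4]
  expect_equal(sum(top$tally),
               sum(abs(dd$log2fc) >= cut))
  expect_error(top_n_composition(de, 100L, subfam), "exceeds")
  sgn <- top_n_composition(de, 2L, subfam, rank_key = "signed")
  expect_equal(sgn$n_actual, 2L)
})

test_that("top-SD selection equals the sort oracle and splits the states", {
  cfg <- sim_config(n_te_loci = c(SVA = 400L, LTR7 = 400L), n_genes = 20L,
                    library_size = 1e5, stage_markers = c(),
                    stage_marker_naive_up = c())
  w <- gen_te_counts(cfg, seed = 9L)
  cl <- top_sd_cluster(w$counts, 300L)
  lg <- log2(normalize_counts(w$counts)$normalized + 1)
  sds <- apply(lg, 1, sd)
  oracle <- rownames(w$counts)[order(sds, decreasing = TRUE)][1:300]
  expect_setequal(cl$features, oracle)
  truth <- ifelse(grepl("^naive", w$sheet$state), 1L, 2L)
  expect_equal(ari(cl$labels, truth), 1)
  expect_error(top_sd_cluster(matrix(5L, 4, 4,
                                     dimnames = list(letters[1:4],
                                                     LETTERS[1:4])), 2L),
               "zero variance")
})

test_that("PCA: duplicated samples coincide, variance sums <= 1, states split", {
  cfg <- sim_config(n_te_loci = c(SVA = 300L, LTR7 = 300L), n_genes = 20L,
                    library_size = 1e5, stage_markers = c(),
                    stage_marker_naive_up = c())
  w <- gen_te_counts(cfg, seed = 10L)
  m <- cbind(w$counts, dup = w$counts[, 1])
  pc <- pca_samples(m)
  expect_equal(pc$coords[1, ], pc$coords[ncol(m), ],
               ignore_attr = TRUE)
  expect_lte(sum(pc$var_explained), 1)
  pc2 <- pca_samples(w$counts)
  naive <- grepl("^naive", w$sheet$state)
  expect_true(max(pc2$coords[naive, "PC1"]) < min(pc2$coords[!naive, "PC1"]) ||
                min(pc2$coords[naive, "PC1"]) > max(pc2$coords[!naive, "PC1"]))
  expect_error(pca_samples(w$counts[1, , drop = FALSE]), ">= 2 features")
})
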