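#' Simulation configuration
#'
#' One validated configuration object drives every generator. Defaults state
#' the simulated world once: negative-binomial RNA-seq counts with a 2-fold
#' (log2 effect 2... i.e. 4x at log2fc=2) state effect on designated loci,
#' 3 replicates per culture state, 30x methylome coverage, the
#' naive/primed global methylation levels, and the imprinted-DMR erasure
#' split. Presets used by the acceptance suite pin these (see
#' [sim_preset()]).
#'
#' @param seed default seed used when a generator is not given one
#' @param n_te_loci named integer vector, TE loci per family
#' @param n_genes number of genes
#' @param n_replicates replicates per culture state
#' @param esc_states culture states simulated in the ESC count matrix
#' @param library_size mean total counts per ESC sample
#' @param dispersion NB overdispersion phi (0 = Poisson)
#' @param effect_log2fc log2 fold effect carried by designated loci
#' @param naive_up_fraction named fractions of each family designated
#'   naive-up
#' @param primed_up_fraction named fractions designated primed-up
#' @param embryo_stages stages simulated in the embryo matrix
#' @param embryo_cells cells per stage
#' @param stage_markers named counts of stage-specific marker TEs
#' @param stage_marker_naive_up named counts of those markers drawn from the
#'   naive-up truth (the rest are drawn from unpolarized loci)
#' @param embryo_dispersion NB phi for single cells
#' @param embryo_effect_log2fc log2 fold carried by a marker in its stage
#' @param embryo_library_scale single-cell library size relative to ESC
#' @param methylome list: n_cpg, n_ch, coverage_mean, global_level (named,
#'   per state), ch_level (named), n_x_cgis, x_cgi_level (named,
#'   "intermediate" or "low")
#' @param imprint list: n_dmrs, n_erased, cpgs_per_dmr, primed_level_range,
#'   erased_level, protected_reprimed_level
#' @param allelic list: n_genes, coverage_mean, biallelic_fraction (named,
#'   per state), error_rate
#' @param qpcr list: intercept, slope, noise_sd, ct_ceiling, standards_log10,
#'   conditions (named list with n and positive_fractions)
#' @return object of class `nb_sim_config`
#' @export
sim_config <- function(
    seed = 1L,
    n_te_loci = c(SVA = 1500L, LTR5_Hs = 200L, `HERVH-int` = 1500L,
                  LTR7 = 1500L, AluY = 3000L, L1HS = 2500L),
    n_genes = 300L,
    n_replicates = 3L,
    esc_states = c("primed", "naive_5iLA", "naive_4iLA", "naive_t2iL_DOX"),
    library_size = 5e5,
    dispersion = 0.05,
    effect_log2fc = 2.0,
    naive_up_fraction = c(SVA = 0.70, LTR5_Hs = 0.70),
    primed_up_fraction = c(`HERVH-int` = 0.72, LTR7 = 0.60),
    embryo_stages = c("oocyte", "four_cell", "eight_cell", "morula",
                      "late_blastocyst_EPI", "late_blastocyst_TE"),
    embryo_cells = 8L,
    stage_markers = c(morula = 200L, late_blastocyst_EPI = 150L,
                      eight_cell = 100L),
    stage_marker_naive_up = c(morula = 124L, late_blastocyst_EPI = 94L),
    embryo_dispersion = 0.3,
    embryo_effect_log2fc = 2.0,
    embryo_library_scale = 0.5,
    methylome = list(),
    imprint = list(),
    allelic = list(),
    qpcr = list()) {
  methylome <- utils::modifyList(list(
    n_cpg = 20000L, n_ch = 20000L, coverage_mean = 30,
    global_level = c(naive = 0.269, primed = 0.810, reprimed = 0.780),
    ch_level = c(naive = 0.0019, primed = 0.0045, reprimed = 0.0045),
    n_x_cgis = 463L,
    x_cgi_level = c(naive = "low", primed = "intermediate",
                    reprimed = "intermediate")), methylome)
  imprint <- utils::modifyList(list(
    n_dmrs = 100L, n_erased = 77L, cpgs_per_dmr = 20L,
    primed_level_range = c(0.35, 0.65), erased_level = 0.05,
    protected_reprimed_level = 0.50), imprint)
  allelic <- utils::modifyList(list(
    n_genes = 200L, coverage_mean = 30,
    biallelic_fraction = c(primed = 0.10, naive = 0.90),
    error_rate = 0.02), allelic)
  user_conditions <- qpcr$conditions
  qpcr <- utils::modifyList(list(
    intercept = 17, slope = -log2(10) * 1,  # -3.321928: 100% efficiency
    noise_sd = 0.15, ct_ceiling = 38,
    standards_log10 = c(-1, -2, -3, -4, -5),
    conditions = list(naive_4iLA = list(
      n = 20L, positive_fractions = c(1e-4, 3e-4)))), qpcr)
  # conditions are replaced, not merged, when supplied
  if (!is.null(user_conditions)) qpcr$conditions <- user_conditions
  cfg <- list(seed = as.integer(seed), n_te_loci = n_te_loci,
              n_genes = as.integer(n_genes),
              n_replicates = as.integer(n_replicates),
              esc_states = esc_states, library_size = library_size,
              dispersion = dispersion, effect_log2fc = effect_log2fc,
              naive_up_fraction = naive_up_fraction,
              primed_up_fraction = primed_up_fraction,
              embryo_stages = embryo_stages,
              embryo_cells = as.integer(embryo_cells),
              stage_markers = stage_markers,
              stage_marker_naive_up = stage_marker_naive_up,
              embryo_dispersion = embryo_dispersion,
              embryo_effect_log2fc = embryo_effect_log2fc,
              embryo_library_scale = embryo_library_scale,
              methylome = methylome, imprint = imprint, allelic = allelic,
              qpcr = qpcr)
  validate_sim_config(cfg)
  structure(cfg, class = "nb_sim_config")
}

validate_sim_config <- function(cfg) {
  if (any(cfg$n_te_loci < 0)) stop_nb("n_te_loci must be non-negative")
  if (cfg$dispersion < 0) stop_nb("dispersion must be >= 0")
  if (cfg$methylome$coverage_mean < 1)
    stop_nb("methylome coverage_mean must be >= 1")
  if (cfg$allelic$coverage_mean < 1)
    stop_nb("allelic coverage_mean must be >= 1")
  im <- cfg$imprint
  if (im$n_erased > im$n_dmrs) stop_nb("n_erased must be <= n_dmrs")
  fr <- c(cfg$naive_up_fraction, cfg$primed_up_fraction,
          cfg$allelic$biallelic_fraction, im$erased_level,
          im$protected_reprimed_level, cfg$methylome$global_level,
          cfg$methylome$ch_level)
  if (any(fr < 0 | fr > 1)) stop_nb("all fractions must lie in [0,1]")
  extra <- setdiff(names(cfg$stage_markers), cfg$embryo_stages)
  if (length(extra)) stop_nb("stage_markers for unknown stage(s): %s",
                             paste(extra, collapse = ", "))
  invisible(cfg)
}

#' Named simulation presets
#'
#' Presets pin the parameters used by the acceptance suite:
#' * `default` - the full-size ESC world (>= 10,000 TE loci) used for
#'   clustering/PCA checks.
#' * `concordance_morula` / `concordance_epiblast` - one shared world with
#'   876 morula-specific markers (543 naive-up) and 475 epiblast-specific
#'   markers (299 naive-up); the preset name selects the scored stage.
#' * `imprint_4iLA` / `imprint_5iLA` - 100 imprinted DMRs, 20 CpGs each,
#'   30x coverage, 77 vs 71 designed erased.
#' * `methylome_global` - 100,000 CpG + 100,000 CH sites at the naive
#'   (26.9% CpG, 0.19% CH) and primed (81.0% CpG, 0.45% CH) design levels.
#' * `chimera_4iLA` - 660 injected embryos, 6 true positives.
#'
#' @param name preset name
#' @param seed global seed stored in the config
#' @return `nb_sim_config`
#' @export
sim_preset <- function(name = c("default", "concordance_morula",
                                "concordance_epiblast", "imprint_4iLA",
                                "imprint_5iLA", "methylome_global",
                                "chimera_4iLA"),
                       seed = 1L) {
  name <- match.arg(name)
  switch(name,
    default = sim_config(seed = seed),
    concordance_morula = ,
    concordance_epiblast = sim_config(
      seed = seed,
      n_te_loci = c(SVA = 1400L, LTR5_Hs = 150L, `HERVH-int` = 1000L,
                    LTR7 = 1000L, AluY = 500L),
      n_genes = 150L, library_size = 4e5,
      stage_markers = c(morula = 876L, late_blastocyst_EPI = 475L,
                        eight_cell = 120L, four_cell = 120L, oocyte = 120L,
                        late_blastocyst_TE = 120L),
      stage_marker_naive_up = c(morula = 543L, late_blastocyst_EPI = 299L)),
    imprint_4iLA = sim_config(
      seed = seed,
      methylome = list(n_cpg = 5000L, n_ch = 5000L),
      imprint = list(n_dmrs = 100L, n_erased = 77L)),
    imprint_5iLA = sim_config(
      seed = seed,
      methylome = list(n_cpg = 5000L, n_ch = 5000L),
      imprint = list(n_dmrs = 100L, n_erased = 71L)),
    methylome_global = sim_config(
      seed = seed,
      # a pure genome-wide methylome: the global design levels are realized
      # exactly, with no imprinted-DMR or CGI sites mixed in
      methylome = list(n_cpg = 100000L, n_ch = 100000L, n_x_cgis = 0L),
      imprint = list(n_dmrs = 0L, n_erased = 0L)),
    chimera_4iLA = sim_config(
      seed = seed,
      # positives span 1.5 to 5 human cells per 10,000 mouse cells, i.e.
      # clearly at or above the assay's 1e-4 detection line
      qpcr = list(conditions = list(naive_4iLA = list(
        n = 660L,
        positive_fractions = c(1.5e-4, 2e-4, 2.5e-4, 3e-4, 4e-4, 5e-4))))))
}

# Family-typical element lengths (bp) on the toy genome.
te_family_length <- function(fam) {
  len <- c(SVA = 1500L, LTR5_Hs = 1000L, `HERVH-int` = 5000L, LTR7 = 450L,
           AluY = 300L, L1HS = 6000L)
  out <- unname(len[fam])
  out[is.na(out)] <- 1200L
  out
}

sva_subfamilies <- c("SVA_A", "SVA_B", "SVA_C", "SVA_D", "SVA_E", "SVA_F")
sva_subfamily_weights <- c(0.08, 0.07, 0.10, 0.35, 0.20, 0.20)

# Shared annotation layer: gene cassettes on toy chromosomes with TE slots at
# designed distance bins, intergenic desert TEs, per-locus naive/primed
# direction truth, baseline expression, and stage-marker assignment. Pure
# function of (cfg, seed); both the ESC and the embryo generator call it so
# their feature ids and truth align.
sim_annotation <- function(cfg, seed = cfg$seed) {
  withr::with_seed(substream_seed(seed, "annotation"), {
    n_te <- sum(cfg$n_te_loci)
    fam <- sample(rep(names(cfg$n_te_loci), times = cfg$n_te_loci))
    sub <- fam
    is_sva <- fam == "SVA"
    sub[is_sva] <- sample(sva_subfamilies, sum(is_sva), replace = TRUE,
                          prob = sva_subfamily_weights)
    te_len <- te_family_length(fam)
    id <- sprintf("%s.%05d", sub, seq_len(n_te))

    n_genes <- cfg$n_genes
    chroms <- paste0("chrS", 1:4)
    gene_len <- 20000L
    # near-gene slots: (offset from gene end unless in_gene, length cap)
    slots <- data.frame(
      bin = c("in_gene", "lt2.5kb", "2.5_5kb", "5_10kb", "10_20kb"),
      offset = c(NA, 1000L, 3000L, 7000L, 15000L),
      cap = c(8000L, 1400L, 1800L, 2800L, 4800L))
    n_near <- min(n_te, nrow(slots) * n_genes)
    n_desert <- n_te - n_near
    desert_per_gene <- ceiling(n_desert / n_genes)
    desert_span <- desert_per_gene * 7000L
    cassette <- gene_len + 20000L + 30000L + desert_span + 50000L

    gi <- seq_len(n_genes)
    g_chrom <- chroms[((gi - 1L) %% length(chroms)) + 1L]
    g_slot <- (gi - 1L) %/% length(chroms)
    g_start <- 100000L + g_slot * cassette          # 0-based
    g_end <- g_start + gene_len
    g_strand <- sample(c("+", "-"), n_genes, replace = TRUE)
    gene_id <- sprintf("gene%04d", gi)

    te_chrom <- character(n_te); te_start <- integer(n_te)
    te_end <- integer(n_te); host <- integer(n_te)
    design_bin <- character(n_te)
    k <- 0L
    for (g in gi) {                                  # near-gene slots
      for (s in seq_len(nrow(slots))) {
        if (k >= n_near) break
        k <- k + 1L
        host[k] <- g
        design_bin[k] <- slots$bin[s]
        len <- min(te_len[k], slots$cap[s])
        st <- if (slots$bin[s] == "in_gene") g_start[g] + 5000L
              else g_end[g] + slots$offset[s]
        te_chrom[k] <- g_chrom[g]; te_start[k] <- st; te_end[k] <- st + len
      }
    }
    if (n_desert > 0L) {                             # intergenic deserts
      g <- 1L; slot <- 0L
      for (j in seq_len(n_desert)) {
        k <- k + 1L
        if (slot >= desert_per_gene) { slot <- 0L; g <- g + 1L }
        if (g > n_genes) g <- 1L  # wrap (should not happen)
        st <- g_end[g] + 30000L + slot * 7000L
        len <- min(te_len[k], 6500L)
        host[k] <- NA_integer_; design_bin[k] <- "desert"
        te_chrom[k] <- g_chrom[g]; te_start[k] <- st; te_end[k] <- st + len
        slot <- slot + 1L
      }
    }
    te_strand <- sample(c("+", "-"), n_te, replace = TRUE)

    # polarization truth
    direction <- rep("none", n_te)
    for (f in names(cfg$naive_up_fraction)) {
      idx <- which(fam == f)
      n_up <- round(length(idx) * cfg$naive_up_fraction[[f]])
      direction[sample(idx, n_up)] <- "naive_up"
    }
    for (f in names(cfg$primed_up_fraction)) {
      idx <- which(fam == f & direction == "none")
      n_up <- round(length(idx) * cfg$primed_up_fraction[[f]])
      direction[sample(idx, n_up)] <- "primed_up"
    }

    base_mean <- cfg$library_size / n_te
    log2mu <- rnorm(n_te, log2(base_mean), 1.5)

    # stage markers: naive-up quota from the naive_up pool, rest unpolarized.
    # Markers are drawn from detectably expressed loci (baseline mean >= 8
    # counts): a stage-enriched feature is by construction expressed.
    marker_stage <- rep(NA_character_, n_te)
    marker_naive_up <- rep(FALSE, n_te)
    expressed <- log2mu >= 3
    pool_up <- which(direction == "naive_up" & expressed)
    pool_none <- which(direction == "none" & expressed)
    for (st in names(cfg$stage_markers)) {
      n_m <- cfg$stage_markers[[st]]
      n_up <- if (st %in% names(cfg$stage_marker_naive_up))
        cfg$stage_marker_naive_up[[st]] else 0L
      if (n_up > length(pool_up) || (n_m - n_up) > length(pool_none))
        stop_nb("not enough loci to assign %d markers for stage %s", n_m, st)
      take_up <- if (n_up > 0L) sample_exact(pool_up, n_up) else integer(0)
      pool_up <- setdiff(pool_up, take_up)
      take_none <- sample_exact(pool_none, n_m - n_up)
      pool_none <- setdiff(pool_none, take_none)
      marker_stage[c(take_up, take_none)] <- st
      marker_naive_up[take_up] <- TRUE
    }

    coupling_w <- c(in_gene = 0.9, lt2.5kb = 0.7, `2.5_5kb` = 0.5,
                    `5_10kb` = 0.3, `10_20kb` = 0.15, desert = 0)[design_bin]
    gene_log2mu <- rnorm(n_genes, log2(cfg$library_size / n_genes), 1.5)

    tes <- GenomicRanges::GRanges(te_chrom,
      IRanges::IRanges(start = te_start + 1L, end = te_end),
      strand = te_strand)
    tes$id <- id; tes$family <- fam; tes$subfamily <- sub
    tes$merged <- FALSE; tes$constituents <- ""
    genes <- GenomicRanges::GRanges(g_chrom,
      IRanges::IRanges(start = g_start + 1L, end = g_end),
      strand = g_strand)
    genes$id <- gene_id
    genes$is_krab_zfp <- seq_len(n_genes) <= round(0.1 * n_genes)
    genes$is_imprinted <- FALSE
    genes$is_x_linked <- FALSE

    truth <- data.frame(id = id, family = fam, subfamily = sub,
                        direction = direction, marker_stage = marker_stage,
                        marker_naive_up = marker_naive_up,
                        design_bin = design_bin, host_gene = gene_id[host],
                        coupling_w = unname(coupling_w), log2mu = log2mu,
                        stringsAsFactors = FALSE)
    list(tes = tes, genes = genes, truth = truth,
         gene_log2mu = setNames(gene_log2mu, gene_id))
  })
}

# sample() without the scalar-x surprise
sample_exact <- function(x, n) x[sample.int(length(x), n)]

rnbinom_mu <- function(n, mu, phi) {
  if (phi <= 0) rpois(n, mu) else rnbinom(n, size = 1 / phi, mu = mu)
}

#' Simulate the naive/primed ESC TE (and gene) count matrices
#'
#' Negative-binomial locus-level counts over the shared toy annotation.
#' Designated naive-up loci (SVA, LTR5_Hs by default) carry
#' `+effect_log2fc` in the naive states, designated primed-up loci
#' (HERVH-int, LTR7) carry it in primed samples. Gene expression carries a
#' per-sample latent factor that propagates to nearby TEs with a weight that
#' decays with distance bin, so TE-gene correlation is greatest near genes
#' and tails off with distance.
#'
#' @param cfg [sim_config()] object
#' @param seed integer seed (defaults to `cfg$seed`)
#' @return list with `counts` (TE matrix), `gene_counts`, `sheet`, `tes`,
#'   `genes` (GRanges annotations), `pairs` truth columns in `truth`
#' @export
gen_te_counts <- function(cfg, seed = cfg$seed) {
  validate_sim_config(cfg)
  ann <- sim_annotation(cfg, seed)
  states <- rep(cfg$esc_states, each = cfg$n_replicates)
  sheet <- data.frame(
    sample_id = paste0(states, "_r", rep(seq_len(cfg$n_replicates),
                                         times = length(cfg$esc_states))),
    state = states, stage = NA_character_, sex = "female",
    replicate = rep(seq_len(cfg$n_replicates), times = length(cfg$esc_states)),
    stringsAsFactors = FALSE)
  n_s <- nrow(sheet)
  naive <- grepl("^naive", sheet$state)
  tr <- ann$truth
  withr::with_seed(substream_seed(seed, "te_counts"), {
    z <- matrix(rnorm(length(ann$gene_log2mu) * n_s, 0, 0.6),
                nrow = length(ann$gene_log2mu),
                dimnames = list(names(ann$gene_log2mu), sheet$sample_id))
    gene_mu <- 2^(ann$gene_log2mu + z)
    gene_counts <- matrix(
      rnbinom_mu(length(gene_mu), as.vector(gene_mu), cfg$dispersion),
      nrow = nrow(gene_mu), dimnames = dimnames(gene_mu))
    eff <- outer(tr$direction == "naive_up", naive) +
      outer(tr$direction == "primed_up", !naive)
    zi <- matrix(0, nrow(tr), n_s)
    hosted <- !is.na(tr$host_gene)
    zi[hosted, ] <- z[tr$host_gene[hosted], , drop = FALSE] *
      tr$coupling_w[hosted]
    mu <- 2^(tr$log2mu + cfg$effect_log2fc * eff + zi)
    counts <- matrix(rnbinom_mu(length(mu), as.vector(mu), cfg$dispersion),
                     nrow = nrow(mu),
                     dimnames = list(tr$id, sheet$sample_id))
  })
  list(counts = counts, gene_counts = gene_counts, sheet = sheet,
       tes = ann$tes, genes = ann$genes, truth = tr)
}

#' Simulate single-cell embryo TE counts with stage-specific markers
#'
#' Each designated marker locus is elevated by `embryo_effect_log2fc` in its
#' stage only; morula and epiblast markers are drawn preferentially from the
#' naive-up (SVA/LTR5_Hs) truth per the preset quotas, which is what creates
#' the naive-morula convergence the concordance stage measures.
#'
#' @inheritParams gen_te_counts
#' @return list with `counts`, `sheet`, `truth` (stage-marker table),
#'   `tes` annotation
#' @export
gen_embryo_counts <- function(cfg, seed = cfg$seed) {
  validate_sim_config(cfg)
  if (length(cfg$embryo_stages) < 2L) stop_nb("need >= 2 embryo stages")
  if (cfg$embryo_cells < 5L) stop_nb("need >= 5 cells per stage")
  ann <- sim_annotation(cfg, seed)
  tr <- ann$truth
  sheet <- data.frame(
    sample_id = paste0(rep(cfg$embryo_stages, each = cfg$embryo_cells), "_c",
                       rep(seq_len(cfg$embryo_cells),
                           times = length(cfg$embryo_stages))),
    state = "embryo",
    stage = rep(cfg$embryo_stages, each = cfg$embryo_cells),
    sex = "unknown",
    replicate = rep(seq_len(cfg$embryo_cells),
                    times = length(cfg$embryo_stages)),
    stringsAsFactors = FALSE)
  withr::with_seed(substream_seed(seed, "embryo_counts"), {
    eff <- outer(tr$marker_stage, sheet$stage, function(a, b)
      !is.na(a) & a == b)
    mu <- 2^(tr$log2mu + cfg$embryo_effect_log2fc * eff)
    # fixed per-cell sequencing budget: counts are compositional, so a
    # marker-heavy stage must not inflate its cells' library sizes
    target <- cfg$library_size * cfg$embryo_library_scale
    mu <- sweep(mu, 2L, target / colSums(mu), "*")
    counts <- matrix(
      rnbinom_mu(length(mu), as.vector(mu), cfg$embryo_dispersion),
      nrow = nrow(mu), dimnames = list(tr$id, sheet$sample_id))
  })
  marker_truth <- tr[!is.na(tr$marker_stage),
                     c("id", "marker_stage", "marker_naive_up")]
  names(marker_truth) <- c("feature_id", "stage", "naive_up")
  list(counts = counts, sheet = sheet, truth = marker_truth, tes = ann$tes)
}

# Bimodal per-site CpG level model with exact design mean:
# f * Beta(9,1) + (1-f) * Beta(0.3,9.7), means 0.9 / 0.03.
cpg_site_levels <- function(n, mean_level) {
  hi_mean <- 0.9; lo_mean <- 0.03
  f <- (mean_level - lo_mean) / (hi_mean - lo_mean)
  f <- min(max(f, 0), 1)
  hi <- runif(n) < f
  lev <- numeric(n)
  lev[hi] <- rbeta(sum(hi), 9, 1)
  lev[!hi] <- rbeta(sum(!hi), 0.3, 9.7)
  lev
}

#' Simulate per-cytosine methylomes, imprinted DMRs and X-linked CGIs
#'
#' Per state: `n_cpg` genomic CpG sites at the state's design global level
#' (bimodal per-site levels, exact mixture mean), `n_ch` CH sites at the
#' design CH level, imprinted DMRs following the preset erasure trajectories,
#' and X-linked promoter CGIs (intermediate in primed-female-like states, low
#' otherwise). Coverage is Poisson(`coverage_mean`) floored at 1; methylated
#' reads are Binomial(coverage, site level).
#'
#' @inheritParams gen_te_counts
#' @return list with `calls` (named list of allc tables per state), `dmrs`
#'   and `x_cgis` (GRanges), `dmr_truth`
#' @export
gen_methylome <- function(cfg, seed = cfg$seed) {
  validate_sim_config(cfg)
  me <- cfg$methylome; im <- cfg$imprint
  states <- names(me$global_level)
  withr::with_seed(substream_seed(seed, "methylome"), {
    # site grids (shared across states)
    cpg_pos <- seq.int(1000L, by = 50L, length.out = me$n_cpg)
    ch_pos <- seq.int(1025L, by = 50L, length.out = me$n_ch)
    dmr_start <- seq.int(1000L, by = 5000L, length.out = im$n_dmrs)  # 0-based
    dmr_ids <- sprintf("dmr%03d", seq_len(im$n_dmrs))
    dmr_cpg_pos <- as.vector(t(outer(dmr_start,
                                     seq.int(20L, by = 40L,
                                             length.out = im$cpgs_per_dmr),
                                     `+`)))            # 0-based offsets
    cgi_start <- seq.int(5000L, by = 10000L, length.out = me$n_x_cgis)
    cgi_ids <- sprintf("xcgi%03d", seq_len(me$n_x_cgis))
    n_cgi_site <- 15L
    cgi_pos <- as.vector(t(outer(cgi_start,
                                 seq.int(10L, by = 30L,
                                         length.out = n_cgi_site), `+`)))
    # design levels
    primed_dmr_level <- runif(im$n_dmrs, im$primed_level_range[1],
                              im$primed_level_range[2])
    erased <- logical(im$n_dmrs)
    erased[sample.int(im$n_dmrs, im$n_erased)] <- TRUE
    cgi_intermediate <- runif(me$n_x_cgis, 0.35, 0.65)

    calls <- list()
    for (st in states) {
      lev_cpg <- cpg_site_levels(me$n_cpg, me$global_level[[st]])
      lev_ch <- rep(me$ch_level[[st]], me$n_ch)
      dmr_lev <- switch(st,
        primed = primed_dmr_level,
        reprimed = ifelse(erased, im$erased_level,
                          im$protected_reprimed_level),
        rep(im$erased_level, im$n_dmrs))            # naive-like states
      cgi_lev <- if (identical(me$x_cgi_level[[st]], "intermediate"))
        cgi_intermediate else rbeta(me$n_x_cgis, 1.6, 18.4)  # mean 0.08
      tab <- data.table::data.table(
        chrom = c(rep("chrS1", me$n_cpg), rep("chrS1", me$n_ch),
                  rep("chrS4", length(dmr_cpg_pos)),
                  rep("chrX", length(cgi_pos))),
        pos = c(cpg_pos, ch_pos, dmr_cpg_pos + 1L, cgi_pos + 1L),
        strand = "+",
        context = c(rep("CpG", me$n_cpg), rep("CH", me$n_ch),
                    rep("CpG", length(dmr_cpg_pos)),
                    rep("CpG", length(cgi_pos))),
        level = c(lev_cpg, lev_ch,
                  rep(dmr_lev, each = im$cpgs_per_dmr),
                  rep(cgi_lev, each = n_cgi_site)))
      tab$total_reads <- pmax(1L, rpois(nrow(tab), me$coverage_mean))
      tab$meth_reads <- rbinom(nrow(tab), tab$total_reads, tab$level)
      tab$level <- NULL
      calls[[st]] <- tab
    }
    id_ranges <- function(chrom, start0, width, ids) {
      gr <- GenomicRanges::GRanges(rep(chrom, length(start0)),
        IRanges::IRanges(start = start0 + 1L, end = start0 + width),
        strand = rep("*", length(start0)))
      gr$id <- ids
      gr
    }
    dmrs <- id_ranges("chrS4", dmr_start, 1000L, dmr_ids)
    x_cgis <- id_ranges("chrX", cgi_start, 500L, cgi_ids)
    dmr_truth <- data.frame(dmr_id = dmr_ids, erased = erased,
                            primed_level = primed_dmr_level,
                            stringsAsFactors = FALSE)
  })
  list(calls = calls, dmrs = dmrs, x_cgis = x_cgis, dmr_truth = dmr_truth)
}

#' Simulate allele-specific SNP read counts for X-linked genes
#'
#' Per gene and state a gene is biallelic with the state's
#' `biallelic_fraction` (allelic ratio ~ Beta(20,20)) or monoallelic toward
#' a per-gene major allele with a small error rate; reads are
#' Binomial(coverage, ratio) with Poisson coverage.
#'
#' @inheritParams gen_te_counts
#' @return list with `table` (long allelic count table), `truth`, `sheet`
#' @export
gen_allelic_counts <- function(cfg, seed = cfg$seed) {
  validate_sim_config(cfg)
  al <- cfg$allelic
  states <- names(al$biallelic_fraction)
  sheet <- data.frame(
    sample_id = paste0(rep(states, each = cfg$n_replicates), "_a",
                       rep(seq_len(cfg$n_replicates), times = length(states))),
    state = ifelse(rep(states, each = cfg$n_replicates) == "naive",
                   "naive_5iLA",
                   rep(states, each = cfg$n_replicates)),
    stage = NA_character_, sex = "female",
    replicate = rep(seq_len(cfg$n_replicates), times = length(states)),
    stringsAsFactors = FALSE)
  grp <- rep(states, each = cfg$n_replicates)
  withr::with_seed(substream_seed(seed, "allelic"), {
    gid <- sprintf("xgene%04d", seq_len(al$n_genes))
    escapes <- seq_len(al$n_genes) <= round(0.05 * al$n_genes)
    major_ref <- runif(al$n_genes) < 0.5
    rows <- list()
    truth <- list()
    for (si in seq_along(states)) {
      st <- states[si]
      biallelic <- runif(al$n_genes) < al$biallelic_fraction[[st]]
      truth[[st]] <- data.frame(gene_id = gid, state = st,
                                biallelic = biallelic)
      for (r in which(grp == st)) {
        cov <- pmax(1L, rpois(al$n_genes, al$coverage_mean))
        ratio <- ifelse(biallelic, rbeta(al$n_genes, 20, 20),
                        ifelse(major_ref, al$error_rate, 1 - al$error_rate))
        alt <- rbinom(al$n_genes, cov, ratio)
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = gid, sample_id = sheet$sample_id[r],
          ref_reads = cov - alt, alt_reads = alt, escapes_xci = escapes)
      }
    }
  })
  list(table = do.call(rbind, rows), truth = do.call(rbind, truth),
       sheet = sheet)
}

#' Simulate a human-mtDNA qPCR plate
#'
#' Standards follow `ct = intercept + slope * log10(human_fraction)` with
#' Gaussian noise (`slope = -3.321928` is a 100%-efficiency assay); unknowns
#' are negative embryos (non-detects at the Ct ceiling) plus the spiked
#' positives of the condition's `positive_fractions`.
#'
#' @inheritParams gen_te_counts
#' @return list with `standards`, `unknowns`, `ct_ceiling`, `truth`
#' @export
gen_qpcr_plate <- function(cfg, seed = cfg$seed) {
  validate_sim_config(cfg)
  q <- cfg$qpcr
  if (diff(range(q$standards_log10)) < 4)
    stop_nb("qPCR dilution series must span >= 4 decades")
  withr::with_seed(substream_seed(seed, "qpcr"), {
    standards <- data.frame(
      log10_human_fraction = q$standards_log10,
      ct = q$intercept + q$slope * q$standards_log10 +
        rnorm(length(q$standards_log10), 0, q$noise_sd))
    rows <- list()
    for (cond in names(q$conditions)) {
      cc <- q$conditions[[cond]]
      n_pos <- length(cc$positive_fractions)
      frac <- c(cc$positive_fractions, rep(0, cc$n - n_pos))
      frac <- sample(frac)                      # shuffle plate order
      ct <- ifelse(frac > 0,
                   q$intercept + q$slope * log10(pmax(frac, 1e-12)) +
                     rnorm(cc$n, 0, q$noise_sd),
                   NA_real_)
      non_detect <- is.na(ct) | ct >= q$ct_ceiling
      rows[[cond]] <- data.frame(
        embryo_id = sprintf("%s_e%04d", cond, seq_len(cc$n)),
        condition = cond, ct = ct, non_detect = non_detect,
        true_fraction = frac)
    }
  })
  unknowns <- do.call(rbind, rows)
  rownames(unknowns) <- NULL
  list(standards = standards,
       unknowns = unknowns[, c("embryo_id", "condition", "ct", "non_detect")],
       ct_ceiling = q$ct_ceiling,
       truth = unknowns[, c("embryo_id", "condition", "true_fraction")])
}
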