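#' Run the full benchmark pipeline from a YAML config
#'
#' The config names a simulation preset (or explicit inputs), the output
#' directory, the seed, optional threshold overrides, and the stages to run
#' (`te_de`, `concordance`, `te_gene`, `methylome`, `allelic`, `chimera`).
#' Each stage writes its TSV tables under `outdir` and contributes to
#' `summary.json`; thresholds actually used are logged in the summary.
#' Stages absent from the config are skipped and noted. Output is
#' deterministic given the seed (each stage draws from a named substream).
#' Any stage failure aborts with the stage name and cause.
#'
#' @param config path to a YAML file, or an equivalent named list
#' @return the summary list, invisibly; side effect: files under `outdir`
#' @export
run_pipeline <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  seed <- as.integer(cfg$seed %||% 1L)
  outdir <- cfg$outdir %||% "naivebench_out"
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  th <- resolve_thresholds(cfg$thresholds)
  sim <- sim_preset(cfg$preset %||% "default", seed = seed)
  stages_cfg <- cfg$stages %||% list()
  all_stages <- c("te_de", "concordance", "te_gene", "methylome", "allelic",
                  "chimera")
  requested <- intersect(all_stages, names(stages_cfg))
  skipped <- setdiff(all_stages, requested)

  summary <- list(preset = cfg$preset %||% "default", seed = seed,
                  thresholds = unclass(th), stages = list(),
                  skipped = as.list(skipped))
  world <- NULL
  need_world <- any(c("te_de", "concordance", "te_gene") %in% requested)
  if (need_world) {
    world <- gen_te_counts(sim, seed)
    write_count_matrix(world$counts, file.path(outdir, "te_counts.tsv"))
    write_count_matrix(world$gene_counts,
                       file.path(outdir, "gene_counts.tsv"))
    write_sample_sheet(world$sheet, file.path(outdir, "samples.csv"))
    write_te_annotation(world$tes, file.path(outdir, "te_annotation.tsv"))
    write_gene_annotation(world$genes,
                          file.path(outdir, "gene_annotation.tsv"))
  }
  run_stage <- function(name, fun) {
    if (!name %in% requested) return()
    res <- tryCatch(fun(), error = function(e)
      stop_nb("stage '%s' failed: %s", name, conditionMessage(e)))
    summary$stages[[name]] <<- res
  }

  de <- NULL
  run_stage("te_de", function() {
    primed <- world$sheet$sample_id[world$sheet$state == "primed"]
    naive <- world$sheet$sample_id[grepl("^naive", world$sheet$state)]
    de <<- differential_expression(world$counts, primed, naive, th)
    data.table::fwrite(de, file.path(outdir, "te_de.tsv"), sep = "\t")
    fam <- setNames(world$truth$family, world$truth$id)
    pol <- polarization_summary(de, fam)
    data.table::fwrite(pol, file.path(outdir, "te_polarization.tsv"),
                       sep = "\t")
    list(n_features = nrow(de), n_detected = sum(de$detected),
         n_de = sum(de$call != "no_change"),
         n_up_naive = sum(de$call == "up_in_naive"),
         n_up_primed = sum(de$call == "up_in_primed"))
  })
  run_stage("concordance", function() {
    emb <- gen_embryo_counts(sim, seed)
    write_count_matrix(emb$counts, file.path(outdir, "embryo_counts.tsv"))
    write_sample_sheet(emb$sheet, file.path(outdir, "embryo_samples.csv"))
    sets <- stage_specific_features(emb$counts, emb$sheet, th)
    primed <- world$sheet$sample_id[world$sheet$state == "primed"]
    naive <- world$sheet$sample_id[grepl("^naive", world$sheet$state)]
    # per-stage concordance is scored with the raw-p, 2-fold rule
    de_raw <- differential_expression(world$counts, primed, naive, th,
                                      use_raw_p = TRUE)
    conc <- concordance(sets, de_raw)
    data.table::fwrite(conc, file.path(outdir, "concordance.tsv"),
                       sep = "\t")
    lapply(split(conc, conc$stage), function(d)
      list(n_specific = d$n_specific, frac_up_naive = d$frac_up_naive,
           frac_up_primed = d$frac_up_primed))
  })
  run_stage("te_gene", function() {
    pairs <- assign_te_to_gene(world$tes, world$genes, seed = seed)
    nt <- normalize_counts(world$counts)$normalized
    ng <- normalize_counts(world$gene_counts)$normalized
    tg <- te_gene_correlation(pairs, nt, ng)
    data.table::fwrite(tg$summary, file.path(outdir, "te_gene_summary.tsv"),
                       sep = "\t")
    data.table::fwrite(tg$per_pair, file.path(outdir, "te_gene_pairs.tsv"),
                       sep = "\t")
    setNames(as.list(tg$summary$median_r), tg$summary$bin)
  })
  run_stage("methylome", function() {
    my <- gen_methylome(sim, seed)
    res <- list()
    for (st in names(my$calls)) {
      write_allc(my$calls[[st]], file.path(outdir,
                                           paste0("allc_", st, ".tsv")))
      res[[paste0("global_mCpG_", st)]] <- global_level(my$calls[[st]], "CpG")
      res[[paste0("global_mCH_", st)]] <- global_level(my$calls[[st]], "CH")
    }
    lv <- lapply(my$calls, region_levels, regions = my$dmrs)
    imp <- classify_imprinted_dmrs(lv$primed, lv$naive, lv$reprimed, th)
    data.table::fwrite(imp$calls, file.path(outdir, "imprint_dmrs.tsv"),
                       sep = "\t")
    res$fraction_erased <- imp$fraction_erased
    cg <- lapply(my$calls, region_levels, regions = my$x_cgis)
    xsheet <- data.frame(
      sample_id = paste0(names(cg), "_m1"),
      state = ifelse(names(cg) == "naive", "naive_5iLA", names(cg)),
      stage = NA_character_, sex = "female", replicate = 1L)
    xq <- xlinked_cgi_methylation(setNames(cg, xsheet$sample_id), xsheet, th)
    data.table::fwrite(xq, file.path(outdir, "x_cgi_methylation.tsv"),
                       sep = "\t")
    res$x_cgi_median <- setNames(as.list(xq$median), names(cg))
    res
  })
  run_stage("allelic", function() {
    al <- gen_allelic_counts(sim, seed)
    data.table::fwrite(al$table, file.path(outdir, "allelic_counts.tsv"),
                       sep = "\t")
    genes <- filter_informative(al$table,
                                min_reads = th$min_allelic_reads)
    cl <- classify_allelic(al$table[al$table$gene_id %in% genes, ],
                           min_reads = th$min_allelic_reads)
    data.table::fwrite(cl$calls, file.path(outdir, "allelic_calls.tsv"),
                       sep = "\t")
    list(n_informative = length(genes),
         biallelic_fraction = as.list(cl$per_sample))
  })
  run_stage("chimera", function() {
    plate <- gen_qpcr_plate(sim, seed)
    res <- call_embryos(plate, threshold = th$detection_limit)
    data.table::fwrite(res$per_embryo, file.path(outdir, "embryo_calls.tsv"),
                       sep = "\t")
    data.table::fwrite(res$summary, file.path(outdir, "chimera_summary.tsv"),
                       sep = "\t")
    list(slope = res$curve$slope, efficiency = res$curve$efficiency,
         summary = lapply(split(res$summary, res$summary$condition),
                          function(d) list(n_tested = d$n_tested,
                                           n_positive = d$n_positive,
                                           pct_positive = d$pct_positive)))
  })
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE,
                       null = "null")
  invisible(summary)
}

#' Command-line entry point
#'
#' `naivebench <subcommand> --config file.yaml [--seed N] [--out dir]
#' [--preset name]`. Subcommands: `simulate` (write preset inputs), `run`
#' (full pipeline) and the individual stage names (`te-de`, `concordance`,
#' `te-gene`, `methylome`, `imprint`, `allelic`, `profile`, `chimera`),
#' which run the pipeline restricted to that stage.
#'
#' @param argv character vector of CLI arguments
#' @return exit status, invisibly
#' @export
naivebench_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: naivebench <simulate|run|te-de|concordance|te-gene|methylome|",
    "imprint|allelic|profile|chimera> [--config F] [--seed N] [--out D]",
    "[--preset P]")
  if (!length(argv)) { message(usage); return(invisible(1L)) }
  sub <- argv[1]
  opt <- list(seed = 1L, out = "naivebench_out", preset = "default",
              config = NULL)
  i <- 2L
  while (i <= length(argv)) {
    key <- sub("^--", "", argv[i])
    if (!key %in% names(opt) || i == length(argv))
      { message(usage); return(invisible(1L)) }
    opt[[key]] <- argv[i + 1L]
    i <- i + 2L
  }
  opt$seed <- as.integer(opt$seed)
  cfg <- if (!is.null(opt$config)) yaml::read_yaml(opt$config) else list()
  cfg$seed <- cfg$seed %||% opt$seed
  cfg$outdir <- cfg$outdir %||% opt$out
  cfg$preset <- cfg$preset %||% opt$preset
  stage_map <- c(`te-de` = "te_de", concordance = "concordance",
                 `te-gene` = "te_gene", methylome = "methylome",
                 imprint = "methylome", allelic = "allelic",
                 profile = "te_gene", chimera = "chimera")
  if (sub == "simulate") {
    cfg$stages <- cfg$stages %||%
      setNames(rep(list(list()), 2), c("te_de", "chimera"))
    sim <- sim_preset(cfg$preset, seed = cfg$seed)
    world <- gen_te_counts(sim, cfg$seed)
    dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
    write_count_matrix(world$counts, file.path(cfg$outdir, "te_counts.tsv"))
    write_sample_sheet(world$sheet, file.path(cfg$outdir, "samples.csv"))
    write_te_annotation(world$tes,
                        file.path(cfg$outdir, "te_annotation.tsv"))
    message("wrote preset '", cfg$preset, "' inputs to ", cfg$outdir)
    return(invisible(0L))
  }
  if (sub == "run") {
    if (is.null(cfg$stages))
      cfg$stages <- setNames(rep(list(list()), 6),
                             c("te_de", "concordance", "te_gene",
                               "methylome", "allelic", "chimera"))
  } else if (sub %in% names(stage_map)) {
    cfg$stages <- setNames(list(list()), stage_map[[sub]])
  } else {
    message(usage); return(invisible(1L))
  }
  run_pipeline(cfg)
  message("pipeline done; summary at ",
          file.path(cfg$outdir, "summary.json"))
  invisible(0L)
}
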