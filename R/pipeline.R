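# End-to-end orchestration over synthetic paired-condition data: simulate ->
# balance -> compartments/saddle -> TADs -> loops -> features -> integration,
# with every output written as plain text and a manifest of parameters and
# checksums. Outputs are byte-identical across reruns of the same config.

#' Pipeline parameter set
#'
#' All analysis thresholds in one place, echoed into the output manifest.
#' Defaults: insulation window 10 bins, threshold 0.1, ignore_diags 2,
#' min_dist_bad_bin 5; TAD stable fraction 0.75; loop FDR 0.05, comparison
#' f 0.5 and slop 40 kb; DAR gates log2FC 0.5 / FDR 0.05; DEG gates
#' q 0.01 / FC 1.5; expression classes FPKM 100 / 1; promoter 3 kb.
#'
#' @param ... overrides of the defaults.
#' @return named list of parameters.
#' @export
pipeline_params <- function(...) {
  p <- list(window_bins = 10, insulation_threshold = 0.1, ignore_diags = 2,
            min_dist_bad_bin = 5, stable_frac = 0.75,
            loop_fdr = 0.05, loop_max_dist_bp = 2e6,
            loop_f = 0.5, loop_slop_bp = 40000,
            dar_lfc = 0.5, dar_fdr = 0.05,
            deg_q = 0.01, deg_fc = 1.5,
            fpkm_high = 100, fpkm_low = 1,
            promoter_bp = 3000, n_reps = 3,
            saddle_qrange = c(0.02, 0.98), saddle_quantiles = 10)
  over <- list(...)
  unknown <- setdiff(names(over), names(p))
  if (length(unknown)) {
    stop("unknown pipeline parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  p[names(over)] <- over
  p
}

#' Run the full synthetic-data pipeline
#'
#' Simulates a paired-condition dataset from `config`, runs every analysis
#' stage and writes plain-text outputs plus `manifest.json` into `outdir`.
#' Deterministic: rerunning with the same config and params writes
#' byte-identical files.
#'
#' @param config a [sim_config()].
#' @param outdir output directory (created if needed).
#' @param params a [pipeline_params()] list.
#' @return (invisibly) a result bundle: truth, maps, tracks, tables and the
#'   manifest.
#' @export
run_pipeline <- function(config, outdir, params = pipeline_params()) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(outdir, f)
  files <- character(0)
  emit <- function(writer, x, f) { writer(x, out(f)); files <<- c(files, f) }

  truth <- make_genome(config)
  emit(function(x, p) write_genes(x, p), truth$genes, "genes.tsv")

  maps <- list(); zmaps <- list(); comp <- list(); saddles <- list()
  ins <- list(); bounds <- list(); tads <- list(); loopsets <- list()
  for (cond in SIM_CONDITIONS) {
    m <- simulate_contacts(truth, config, cond)
    m <- balance(m)
    maps[[cond]] <- m
    emit(write_contacts, m, sprintf("contacts_%s.tsv", cond))
    zmaps[[cond]] <- zscore(m)
    dens <- gene_density_track(truth$genes, m)
    comp[[cond]] <- call_compartments(m, dens)
    emit(function(x, p) data.table::fwrite(x, p, sep = "\t"),
         data.table::as.data.table(comp[[cond]]),
         sprintf("compartments_%s.tsv", cond))
    saddles[[cond]] <- saddle(m, comp[[cond]],
                              qrange = params$saddle_qrange,
                              n_quantiles = params$saddle_quantiles)
    ins[[cond]] <- insulation_track(m, window_bins = params$window_bins,
                                    ignore_diags = params$ignore_diags)
    bounds[[cond]] <- call_boundaries(ins[[cond]],
                                      threshold = params$insulation_threshold,
                                      min_dist_bad_bin = params$min_dist_bad_bin)
    tads[[cond]] <- derive_tads(bounds[[cond]], m)
    emit(function(x, p) write_bed(data.table::data.table(
      chrom = x$chrom, start = x$start, end = x$end,
      name = "tad", score = 0), p), tads[[cond]],
      sprintf("tads_%s.bed", cond))
    loopsets[[cond]] <- call_loops(m, max_dist_bp = params$loop_max_dist_bp,
                                   fdr = params$loop_fdr)
    emit(write_bedpe, loopsets[[cond]], sprintf("loops_%s.bedpe", cond))
  }

  switches <- classify_switches(comp$control, comp$treatment)
  emit(function(x, p) data.table::fwrite(x, p, sep = "\t"),
       switches$table, "compartment_switches.tsv")
  diff_map <- difference(zmaps$control, zmaps$treatment)
  tad_cmp <- classify_tad_changes(tads$control, tads$treatment,
                                  stable_frac = params$stable_frac)
  emit(function(x, p) data.table::fwrite(x, p, sep = "\t"),
       tad_cmp$tads, "tad_comparison.tsv")
  bnd_cmp <- compare_boundaries(bounds$control, bounds$treatment)
  loop_cmp <- compare_loops(loopsets$control, loopsets$treatment,
                            f = params$loop_f, slop_bp = params$loop_slop_bp)

  ## features
  tracks <- lapply(stats::setNames(SIM_CONDITIONS, SIM_CONDITIONS),
                   function(cond) simulate_tracks(truth, config, cond))
  ocrs <- lapply(stats::setNames(SIM_CONDITIONS, SIM_CONDITIONS),
                 function(cond) classify_ocrs(tracks[[cond]]$peaks$ATAC,
                                              truth$genes))
  for (cond in SIM_CONDITIONS) {
    emit(function(x, p) write_bed(data.table::data.table(
      chrom = x$chrom, start = x$start, end = x$end, name = x$locality,
      score = 0), p), ocrs[[cond]], sprintf("ocrs_%s.bed", cond))
  }
  expr <- simulate_expression(truth, config, n_reps = params$n_reps)
  emit(write_expression, expr, "expression.tsv")
  degs <- deg_call(expr, q_cut = params$deg_q, fc_cut = params$deg_fc,
                   high_cut = params$fpkm_high, low_cut = params$fpkm_low)
  emit(function(x, p) data.table::fwrite(x, p, sep = "\t"), degs, "degs.tsv")

  # replicate ATAC/K27 counts over consensus regions: Poisson reads around
  # a condition-dependent rate (peak present vs absent), seeded from config
  consensus <- function(mark) {
    u <- GenomicRanges::reduce(c(gr_from_bed(tracks$control$peaks[[mark]]),
                                 gr_from_bed(tracks$treatment$peaks[[mark]])))
    bed_from_gr(u)
  }
  region_counts <- function(mark, cond, n_reps = 2) {
    regs <- consensus(mark)
    present <- overlaps_any(regs$chrom, regs$start, regs$end,
                            tracks[[cond]]$peaks[[mark]])
    set.seed(stage_seed(config$seed, paste("counts", mark, cond)))
    matrix(stats::rpois(nrow(regs) * n_reps,
                        rep(ifelse(present, 100, 10), n_reps)),
           ncol = n_reps)
  }
  dars <- list()
  for (mark in c("ATAC", "H3K27me3")) {
    regs <- consensus(mark)
    dars[[mark]] <- differential_regions(
      region_counts(mark, "control"), region_counts(mark, "treatment"),
      libsizes_of(regs), libsizes_of(regs),
      regions = regs, lfc_cut = params$dar_lfc, fdr_cut = params$dar_fdr)
    emit(function(x, p) data.table::fwrite(x, p, sep = "\t"),
         dars[[mark]], sprintf("diffregions_%s.tsv", mark))
  }

  ## integration (control-condition loop set as the reference)
  loops_cls <- classify_loops(loopsets$control, truth$genes)
  docr_links <- docr_gene_loops(loops_cls, ocrs$control, truth$genes,
                                promoter_halfwidth = params$promoter_bp)
  sw_genes <- genes_in_switched_bins(switches, truth$genes, degs)
  cases <- classify_histone_cases(
    data.table::as.data.table(ocrs$control)[locality == "distal"],
    tracks$control$peaks)
  enhancers <- call_enhancers(cases, truth$genes,
                              promoter_halfwidth = params$promoter_bp)

  summary <- list(
    conditions = SIM_CONDITIONS,
    n_bins = truth$n_bins * config$n_chroms,
    switch_counts = as.list(switches$counts),
    saddle_strength = lapply(saddles, function(s) as.list(s$strength)),
    tad_counts = lapply(tads, nrow),
    tad_change_counts = as.list(tad_cmp$counts),
    boundary_shared = nrow(bnd_cmp$shared),
    loop_counts = lapply(loopsets, nrow),
    loop_common = nrow(loop_cmp$common),
    ocr_local_fraction = lapply(ocrs, function(o) mean(o$locality == "local")),
    n_deg = sum(degs$call != "ns"),
    n_enhancers = nrow(enhancers),
    docr_anchored_fraction = docr_links$anchored_fraction)
  jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  files <- c(files, "summary.json")

  manifest <- list(package = "chromarch",
                   version = as.character(utils::packageVersion("chromarch")),
                   seed = config$seed,
                   sim_config = unclass(config),
                   params = params,
                   stages = c("simulate", "balance", "compartments", "saddle",
                              "tads", "loops", "features", "integration"),
                   outputs = as.list(stats::setNames(
                     unname(tools::md5sum(file.path(outdir, files))), files)))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(truth = truth, maps = maps, compartments = comp,
                 switches = switches, saddles = saddles,
                 insulation = ins, boundaries = bounds, tads = tads,
                 tad_comparison = tad_cmp, boundary_comparison = bnd_cmp,
                 difference = diff_map, loops = loopsets,
                 loop_comparison = loop_cmp, ocrs = ocrs, degs = degs,
                 dars = dars, docr_links = docr_links,
                 switched_genes = sw_genes, enhancers = enhancers,
                 manifest = manifest, outdir = outdir))
}

libsizes_of <- function(regs) rep(1e6, 2)
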