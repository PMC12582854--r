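# End-to-end synthetic pipeline driver: generate inputs, filter SNPs, build
# divergence/mutation maps, estimate and rescale the recombination map, and
# run the multi-scale correlation analysis. Every stage is a thin call into
# the module functions so the driver stays a narrative.

#' Pipeline configuration
#'
#' Validated bag of parameters for [run_pipeline()]. All numeric fields must
#' be positive; the output directory is created if absent.
#'
#' @param outdir Output directory.
#' @param scaffold_length Toy scaffold length in bp.
#' @param gc GC fraction of the toy scaffold.
#' @param n_dip Diploid sample size.
#' @param mu Mutation rate (per bp per gen) used for simulation and the
#'   rho -> r conversion.
#' @param branch_gens Lineage length in generations for substitutions.
#' @param G,T_years Generation time (years) and divergence time (years) for
#'   the mutation-rate map.
#' @param div_window,div_step Divergence map window/step (bp).
#' @param flank Functional-region flank to mask (bp).
#' @param rec_window Recombination estimation window (bp).
#' @param agg_window,agg_step Aggregation window/step (bp).
#' @param pair_span Composite-likelihood pair span (SNPs).
#' @param target_cM Pedigree map length target for rescaling (cM). Scaled to
#'   the toy genome as `target_cM * scaffold_length / 2.3e9` unless
#'   `rescale_to_genome = FALSE`.
#' @param rescale_to_genome Scale `target_cM` by toy-genome size?
#' @param fold Outlier fold threshold.
#' @param alpha Significance level for correlation flags.
#' @param exon_density,mean_exon_len Annotation generator settings.
#' @param n_motifs,motif_enrichment Motif generator settings.
#' @param table_reps,table_grid Lookup-table settings.
#' @param model Demographic model for simulation and the lookup table.
#' @param true_rec_track Optional [rate_track()] (cM/Mb) of true rates; a
#'   two-level hot/cold track is generated when `NULL`.
#' @param bin Feature-track bin (bp).
#' @param seed Master seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(outdir = tempfile("ayemaps_run_"),
                            scaffold_length = 2e6, gc = 0.41,
                            n_dip = 5, mu = AYE_MU_YOUNG,
                            branch_gens = 54.9e6 / 5,
                            G = 5, T_years = 54.9e6,
                            div_window = 2e5, div_step = 1e5,
                            flank = 2e3,
                            rec_window = 1e5,
                            agg_window = 5e5, agg_step = 2.5e5,
                            pair_span = 30,
                            target_cM = AYE_PEDIGREE_MAP_CM,
                            rescale_to_genome = TRUE,
                            fold = 100, alpha = 0.01,
                            exon_density = 0.02, mean_exon_len = 1000,
                            n_motifs = 25, motif_enrichment = 8,
                            table_reps = 3000,
                            table_grid = default_table_grid(),
                            model = equilibrium_model(),
                            true_rec_track = NULL,
                            bin = 1000, seed = 1) {
  cfg <- as.list(environment())
  num <- c("scaffold_length", "gc", "n_dip", "mu", "branch_gens", "G",
           "T_years", "div_window", "div_step", "rec_window", "agg_window",
           "agg_step", "pair_span", "target_cM", "fold", "alpha",
           "mean_exon_len", "table_reps", "bin")
  for (f in num) if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0) {
    stop("config field `", f, "` must be a positive number")
  }
  class(cfg) <- "pipeline_config"
  cfg
}

pipeline_stage <- function(name, expr) {
  message("[ayemaps] stage: ", name)
  tryCatch(expr, error = function(e) {
    stop("pipeline stage `", name, "` failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the synthetic end-to-end pipeline
#'
#' Generates a toy genome with known mutation- and recombination-rate
#' structure, applies the SNP filters, builds the divergence and
#' mutation-rate maps and the conversion table, estimates, filters, rescales
#' and aggregates the recombination map, compares motif vs non-motif rates,
#' and runs the wavelet correlation analysis. All artifacts are written under
#' `config$outdir`; the returned bundle holds every intermediate object.
#'
#' @param config A [pipeline_config()].
#' @return An invisible list bundle (also written to disk).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$outdir, ...)
  set.seed(config$seed)

  spec <- genome_spec("scaffold_1", config$scaffold_length, config$gc)

  sim <- pipeline_stage("simulate", {
    rec_truth <- config$true_rec_track
    if (is.null(rec_truth)) {
      # two-level landscape: cold background with hot second quarter
      w <- sliding_windows(spec, config$scaffold_length / 4)
      rec_truth <- rate_track(w$scaffold, w$start, w$end,
                              c(0.5, 2.5, 0.5, 0.5), units = "cM/Mb")
    }
    mu_truth <- uniform_rate_track(spec, config$mu,
                                   window = config$scaffold_length,
                                   units = "mut/bp/gen")
    list(
      sequence = simulate_sequence(spec, seed = config$seed + 1),
      subs = simulate_substitutions(spec, mu_truth, config$branch_gens,
                                    seed = config$seed + 2),
      panel = simulate_haplotypes(config$model, config$mu, rec_truth,
                                  2 * config$n_dip, config$scaffold_length,
                                  seed = config$seed + 3),
      ann = simulate_annotations(spec, config$exon_density,
                                 config$mean_exon_len, seed = config$seed + 4),
      motifs = place_motifs(spec, rec_truth, config$motif_enrichment,
                            config$n_motifs, seed = config$seed + 5),
      rec_truth = rec_truth, mu_truth = mu_truth
    )
  })

  snps <- pipeline_stage("filter", {
    ps <- panel_to_polymorphisms(sim$panel)
    cl <- filter_snp_clusters(ps)
    hw <- filter_hwe(cl$snps)
    message("[ayemaps]   removed ", cl$removed, " clustered + ",
            hw$removed, " het-excess SNPs of ", n_sites(ps))
    hw$snps
  })

  divmut <- pipeline_stage("divmut", {
    callable <- data.frame(scaffold = spec$scaffold, start = 0,
                           end = spec$length)
    mask <- build_accessibility_mask(sim$ann, callable, flank = config$flank,
                                     spec = spec)
    dmap <- windowed_divergence(sim$subs,
                                data.frame(scaffold = snps$scaffold,
                                           pos = snps$pos),
                                mask, spec, config$div_window, config$div_step)
    mmap <- mutation_rate_map(dmap, config$G, config$T_years)
    tbl1 <- rate_conversion_table(0.043, c(3, 5), c(54.9, 74.7),
                                  c(AYE_MU_YOUNG, AYE_MU_AVERAGE, AYE_MU_OLD))
    list(mask = mask, dmap = dmap, mmap = mmap, table1 = tbl1)
  })

  rec <- pipeline_stage("ldrec", {
    tab <- build_two_locus_table(2 * config$n_dip, config$table_grid,
                                 config$model, config$table_reps,
                                 seed = config$seed + 6)
    fine <- estimate_recombination_map(sim$panel, tab, config$rec_window,
                                       config$mu, config$pair_span)
    filt <- filter_outlier_windows(fine, config$fold)
    target <- if (isTRUE(config$rescale_to_genome)) {
      config$target_cM * config$scaffold_length / 2.3e9
    } else config$target_cM
    resc <- rescale_map(filt$map, target)
    agg <- aggregate_windows(resc$map, config$agg_window, config$agg_step)
    motif <- compare_motif_rates(resc$map, sim$motifs)
    list(table = tab, fine = fine, filtered = filt, rescaled = resc,
         aggregated = agg, motif_test = motif)
  })

  waves <- pipeline_stage("wavescale", {
    pi1k <- windowed_diversity(sim$panel, divmut$mask, spec, config$bin)
    d1k <- windowed_divergence(sim$subs,
                               data.frame(scaffold = snps$scaffold,
                                          pos = snps$pos),
                               divmut$mask, spec, config$bin, config$bin)
    # project the piecewise-constant fine map onto the 1 kb grid; single bins
    # rarely hold the >= 2 SNPs the estimator itself would need
    rho1k <- aggregate_windows(rec$rescaled$map, config$bin, config$bin)
    tracks <- bin_tracks(sim$sequence, sim$ann, pi1k, d1k, rho1k,
                         divmut$mask, bin = config$bin)
    halves <- decompose_halves(tracks)
    correlations <- do.call(rbind, lapply(names(halves), function(h) {
      df <- kendall_detail_correlations(halves[[h]]$decomps, config$alpha)
      cbind(scaffold = spec$scaffold[1], half = h, df)
    }))
    halves_log <- decompose_halves(tracks, log_rates = TRUE)
    models <- do.call(rbind, lapply(names(halves_log), function(h) {
      df <- scale_linear_models(halves_log[[h]]$decomps)
      cbind(scaffold = spec$scaffold[1], half = h, df)
    }))
    list(tracks = tracks, correlations = correlations, models = models)
  })

  pipeline_stage("write", {
    write_bed(sim$subs, out("substitutions.bed"))
    write_bed(sim$motifs, out("motifs.bed"))
    write_bed(divmut$mask, out("accessibility_mask.bed"))
    write_gff3(sim$ann, out("annotations.gff3"))
    write_vcf(snps, out("snps_filtered.vcf"))
    write_bedgraph(sim$rec_truth, out("true_recombination.bedGraph"))
    write_bedgraph(divmut$mmap, out("mutation_rate.bedGraph"), value = "mu")
    write_map_tsv(rec$rescaled$map, out("recombination_map.tsv"))
    write_map_tsv(rec$aggregated, out("recombination_map_1mb.tsv"))
    utils::write.table(waves$correlations, out("wavelet_correlations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(waves$models, out("wavelet_models.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    tb <- divmut$table1
    utils::write.table(
      data.frame(cell = c(outer(rownames(tb$mu), colnames(tb$mu), paste),
                          outer(rownames(tb$T_mya), colnames(tb$T_mya), paste)),
                 value = c(tb$mu, tb$T_mya)),
      out("conversion_table.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(c(
      paste("ayemaps version:", as.character(utils::packageVersion("ayemaps"))),
      paste("R version:", R.version.string),
      paste("seed:", config$seed),
      paste("scaffold_length:", config$scaffold_length),
      paste("mu:", config$mu), paste("pair_span:", config$pair_span),
      paste("popsizes:", ayeaye_size_history()$popsizes),
      paste("epochtimes:", ayeaye_size_history()$epochtimes)),
      out("run_log.txt"))
  })

  invisible(list(config = config, spec = spec, sim = sim, snps = snps,
                 divmut = divmut, rec = rec, waves = waves))
}
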