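# Orchestration: run every analysis stage on simulated or supplied inputs,
# with per-stage seeds, structured logs and a reproducibility manifest.

#' Derive a deterministic per-stage child seed
#'
#' Fans a single global seed out to stage-level seeds by stable hashing of
#' the stage name, so any stage can be re-run alone and reproduce its part
#' of a full run.
#'
#' @param seed Global integer seed.
#' @param stage Stage name.
#' @return Integer seed below 2^31.
#' @export
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h * 8191) %% 2147483647)
}

#' Default pipeline configuration
#'
#' All module parameters at their standard values; override any element via
#' `run_pipeline(config = list(...))` or a YAML file.
#'
#' @param seed Global seed.
#' @param out_dir Output directory.
#' @return Nested configuration list.
#' @export
pipeline_config <- function(seed = 1, out_dir = "stopshift_run") {
  list(
    seed = seed,
    out_dir = out_dir,
    code = "blastocrithidia",
    simulate = list(n_genes = 500, mean_cds_len = 300),
    hsp = list(frag_rate = 0.3, trim_max = 10),
    context = list(n_iter = 40, n_sample = 200, flank = 6, alpha = 0.05),
    somy = list(n_scaffolds = 100, median_cov = 50, cv = 0.1,
                scaffold_len = 20000),
    conserve = list(n_taxa = 9, n_glu_cols = 1066, n_trp_cols = 202,
                    n_other_cols = 800),
    abundance = list(slope = 5, noise = 0.3)
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(override[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

PIPELINE_STAGES <- c("simulate", "annotate", "stops", "codons", "context",
                     "somy", "conserve", "report")

#' Run the full analysis pipeline
#'
#' Stages run in dependency order (simulate, annotate, stops, codons,
#' context, somy, conserve, report); each writes tabular outputs and a log
#' line for every record it drops or flags, and the run manifest records the
#' resolved parameters and seed. Identical configuration and seed give
#' identical outputs.
#'
#' @param config A configuration list (see [pipeline_config()]) or the path
#'   to a YAML file of overrides.
#' @param stages Subset of stages to run (dependencies must have run into
#'   the same `out_dir` or be included).
#' @return Named list of stage results, invisibly.
#' @export
run_pipeline <- function(config = pipeline_config(), stages = PIPELINE_STAGES) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(pipeline_config(), config)
  unknown <- setdiff(names(config), names(pipeline_config()))
  if (length(unknown)) {
    abort(paste("unknown configuration key(s):", paste(unknown, collapse = ", ")))
  }
  stages <- match.arg(stages, PIPELINE_STAGES, several.ok = TRUE)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(cfg$out_dir, "run.log")
  log_line <- function(...) cat(paste0(..., "\n"), file = log_path, append = TRUE)
  code <- build_genetic_code(cfg$code)
  res <- list()

  if ("simulate" %in% stages) {
    spec <- do.call(genome_sim_spec,
                    c(cfg$simulate, list(code = code,
                                         seed = stage_seed(cfg$seed, "simulate"))))
    sim <- simulate_genome(spec)
    write_sim_genome(sim, file.path(cfg$out_dir, "sim"))
    log_line("simulate: ", nrow(sim$genes), " genes on ",
             nrow(sim$genome), " scaffolds")
    res$sim <- sim
  }
  sim <- res$sim
  if (is.null(sim) && any(c("annotate", "stops", "codons", "context") %in% stages)) {
    abort("stages after 'simulate' need its output; include 'simulate' or run it first.")
  }
  if (any(c("stops", "codons", "context") %in% stages) && !"annotate" %in% stages) {
    abort("'stops', 'codons' and 'context' depend on the 'annotate' stage.")
  }

  if ("annotate" %in% stages) {
    hsps <- simulate_hsp_table(sim, frag_rate = cfg$hsp$frag_rate,
                               trim_max = cfg$hsp$trim_max,
                               seed = stage_seed(cfg$seed, "annotate"))
    models <- annotate_genome(sim$genome, hsps, code, sl_sites = sim$sl_sites)
    readr::write_tsv(as_tibble(models), file.path(cfg$out_dir, "gene_models.tsv"))
    readr::write_tsv(exclusions(models), file.path(cfg$out_dir, "model_exclusions.tsv"))
    purrr::pwalk(exclusions(models), function(id, reason) {
      log_line("annotate: dropped ", id, " (", reason, ")")
    })
    res$hsps <- hsps
    res$models <- models
  }

  if ("stops" %in% stages) {
    cds <- models_to_cds(res$models, sim$genome, code)
    usage <- stop_usage_table(cds)
    flanks <- cut_flanks(res$models, sim$genome, width = 120, side = "3p")
    prof <- downstream_stop_profile(flanks, code)
    up <- upstream_stop_profile(cds)
    futr <- filtered_3utr_set(flanks, code)
    readr::write_tsv(usage, file.path(cfg$out_dir, "stop_usage.tsv"))
    readr::write_tsv(as_tibble(prof), file.path(cfg$out_dir, "downstream_stop_profile.tsv"))
    readr::write_tsv(up, file.path(cfg$out_dir, "upstream_stop_profile.tsv"))
    readr::write_tsv(as_tibble(futr), file.path(cfg$out_dir, "filtered_3utr.tsv"))
    log_line("stops: filtered 3'UTR fraction ", round(attr(futr, "fraction"), 3))
    res$stop_usage <- usage
    res$downstream_profile <- prof
    res$filtered_utr <- futr
    res$cds <- cds
  }

  if ("codons" %in% stages) {
    prof <- ifrc_summary(res$cds)
    ab <- simulate_abundance_table(prof, slope = cfg$abundance$slope,
                                   noise = cfg$abundance$noise,
                                   seed = stage_seed(cfg$seed, "codons"))
    w <- relative_adaptiveness(res$cds, abundance = ab)
    cai <- cai_score(res$cds, w)
    fit <- ifrc_correlates(prof, ab)
    readr::write_tsv(as_tibble(prof), file.path(cfg$out_dir, "ifrc_per_cds.tsv"))
    readr::write_tsv(ifrc_aggregate(prof), file.path(cfg$out_dir, "ifrc_aggregate.tsv"))
    readr::write_tsv(as_tibble(w), file.path(cfg$out_dir, "relative_adaptiveness.tsv"))
    readr::write_tsv(cai, file.path(cfg$out_dir, "cai.tsv"))
    readr::write_tsv(glance(fit), file.path(cfg$out_dir, "ifrc_abundance_fit.tsv"))
    res$ifrc <- prof
    res$cai <- cai
    res$abundance_fit <- fit
  }

  if ("context" %in% stages) {
    motifs <- stop_context_motifs(res$models, sim$genome,
                                  flank = cfg$context$flank)
    bg <- cds_nucleotide_background(res$cds)
    enr <- resampled_binomial_test(motifs, bg,
                                   n_iter = cfg$context$n_iter,
                                   n_sample = cfg$context$n_sample,
                                   alpha = cfg$context$alpha,
                                   seed = stage_seed(cfg$seed, "context"))
    readr::write_tsv(as_tibble(enr), file.path(cfg$out_dir, "stop_context_enrichment.tsv"))
    res$enrichment <- enr
  }

  if ("somy" %in% stages) {
    sseed <- stage_seed(cfg$seed, "somy")
    n <- cfg$somy$n_scaffolds
    planted <- with_seed_(sseed, sample(c(rep(2L, ceiling(0.7 * n)),
                                          sample(c(1L, 3L, 4L), n - ceiling(0.7 * n),
                                                 replace = TRUE))))
    somies <- tibble(scaffold = sprintf("cov_scf%03d", seq_len(n)),
                     length = cfg$somy$scaffold_len, somy = planted)
    track <- simulate_coverage_track(somies, median_cov = cfg$somy$median_cov,
                                     cv = cfg$somy$cv, seed = sseed + 1L)
    calls <- call_somy(track, somies %>% select("scaffold", "length"))
    readr::write_tsv(as_tibble(calls), file.path(cfg$out_dir, "somy_calls.tsv"))
    res$somy_truth <- somies
    res$somy_calls <- calls
  }

  if ("conserve" %in% stages) {
    cseed <- stage_seed(cfg$seed, "conserve")
    nt <- cfg$conserve$n_taxa
    gc <- seq(0.32, 0.55, length.out = nt)
    p_uar <- pmax(0, 0.9 - 1.6 * gc)
    p_uga <- pmax(0, 1.0 - 1.7 * gc)
    aln <- simulate_ortholog_alignment(
      n_taxa = nt, n_glu_cols = cfg$conserve$n_glu_cols,
      n_trp_cols = cfg$conserve$n_trp_cols,
      n_other_cols = cfg$conserve$n_other_cols,
      p_uar = p_uar, p_uga = p_uga, taxon_gc = gc, seed = cseed
    )
    summ <- conservation_summary(aln$alignment, aln$cds_map, code)
    corr <- correlate_species_metrics(summ)
    readr::write_tsv(as_tibble(summ), file.path(cfg$out_dir, "conservation_summary.tsv"))
    readr::write_tsv(corr, file.path(cfg$out_dir, "species_correlations.tsv"))
    res$conservation <- summ
    res$correlations <- corr
  }

  if ("report" %in% stages) {
    report <- list(seed = cfg$seed)
    if (!is.null(res$ifrc)) {
      agg <- ifrc_aggregate(res$ifrc)
      counts <- aggregate_codon_counts(attr(res$ifrc, "counts"))
      tot <- sum(counts$count)
      pick <- function(cod) counts$count[counts$codon == cod] / tot * 100
      report$uaa_pct <- pick("TAA"); report$uag_pct <- pick("TAG")
      report$uga_pct <- pick("TGA")
      report$glu1_pct <- 100 * agg$glu1; report$glu2_pct <- 100 * agg$glu2
    }
    if (!is.null(res$filtered_utr)) {
      report$filtered_3utr_pct <- 100 * attr(res$filtered_utr, "fraction")
      report$downstream_gc_pct <- 100 * mean(res$filtered_utr$gc_downstream, na.rm = TRUE)
    }
    if (!is.null(res$somy_calls)) {
      truth <- res$somy_truth
      cls <- classify_somy(truth$somy / 2)
      report$somy_accuracy_pct <- 100 * mean(
        as.character(res$somy_calls$somy_class[match(truth$scaffold, res$somy_calls$scaffold)]) ==
          as.character(cls))
    }
    jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
    res$report <- report
  }

  manifest <- list(seed = cfg$seed, stages = stages,
                   config = cfg[setdiff(names(cfg), "out_dir")],
                   out_dir = cfg$out_dir)
  manifest$config$code <- cfg$code
  yaml::write_yaml(manifest, file.path(cfg$out_dir, "manifest.yaml"))
  invisible(res)
}
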