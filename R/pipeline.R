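#' Run the full analysis pipeline
#'
#' Orchestrates the study workflow: marker validation (Hardy-Weinberg
#' and linkage batteries with excess-of-significance checks), dropout
#' estimation and correction, locus filtering, diversity and
#' differentiation summaries, LD effective population size, hybrid-class
#' simulation (scenario S1 from two reference populations, or S2 from
#' the island simulator), assignment by both engines, and power
#' evaluation against the simulation truth. All stages are seeded from
#' `config$seed`; a rerun with the same configuration is deterministic.
#'
#' @param config a named list (or path to a YAML file with the same
#'   fields): `input` (GENEPOP path) or `study_seed` (simulate the
#'   study-like panel instead), `outdir` (optional: write TSV outputs),
#'   `seed`, `ref1`, `ref2` (reference population labels for S1),
#'   `scenario` ("s1", "s2" or "none"), `mixture`, `per_class`,
#'   `mc_iters` (exact-test Monte Carlo size), `boot` (bootstrap reps),
#'   `nh_iters`, `nh_burn`, `nh_replicates` (MCMC settings),
#'   `thresholds`.
#' @return a `pipeline_bundle` list with one element per stage plus
#'   `log` (data.frame of stages, status, messages) and `partial`
#'   (TRUE if any stage failed).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the yaml package")
    config <- yaml::read_yaml(config)
  }
  cfg <- utils::modifyList(list(
    input = NULL, study_seed = NULL, outdir = NULL, seed = 1L,
    ref1 = "TRA", ref2 = "DRA", scenario = "s1",
    mixture = 50L, per_class = 100L,
    mc = list(demem = 1000, batches = 20, iters = 1000), mc_B = 2000L,
    boot = 1000L, nh_iters = 50000L, nh_burn = 10000L, nh_replicates = 3L,
    snap_shares = NULL, thresholds = c(0.5, 0.75, 0.9),
    island = NULL), config)
  bundle <- list(); logrows <- list()
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) e)
    ok <- !inherits(res, "error")
    logrows[[length(logrows) + 1L]] <<- data.frame(
      stage = name, status = if (ok) "ok" else "error",
      message = if (ok) "" else conditionMessage(res),
      stringsAsFactors = FALSE)
    if (ok) bundle[[name]] <<- res
    ok
  }
  seed <- as.integer(cfg$seed)

  ok <- stage("input", {
    if (!is.null(cfg$input)) read_genepop(cfg$input)
    else simulate_study(seed = if (is.null(cfg$study_seed)) seed else cfg$study_seed)$table
  })
  if (ok) {
    raw <- bundle$input
    stage("hw_battery", {
      b <- hw_battery(raw, "deficit", mc = cfg$mc, seed = seed + 10L)
      ex <- binomial_excess(sum(b$signif), nrow(b))
      list(battery = b, excess = ex)
    })
    stage("ld_battery", {
      b <- ld_battery(raw, B = cfg$mc_B, seed = seed + 20L)
      ex <- binomial_excess(sum(b$signif), nrow(b))
      list(battery = b, excess = ex)
    })
    stage("dropout", {
      m <- estimate_dropout(raw)
      list(model = m, corrected = correct_genotypes(raw, m, seed = seed + 30L))
    })
    stage("filter", {
      src <- if (!is.null(bundle$dropout)) bundle$dropout$corrected else raw
      filter_loci(src)
    })
  }
  if (!is.null(bundle$filter)) {
    tab <- bundle$filter$table
    stage("summary", summary_stats(tab, boot = cfg$boot, seed = seed + 40L))
    stage("differentiation", {
      glob <- wc_theta(tab, boot = cfg$boot, seed = seed + 50L)
      gtest <- exact_g_diff(tab, B = cfg$mc_B, seed = seed + 51L)
      pw <- pairwise_diff(tab, boot = cfg$boot, B = cfg$mc_B, seed = seed + 52L)
      list(global_theta = glob, global_g = gtest, pairwise = pw)
    })
    stage("ne", {
      res <- lapply(pop_names(tab), function(p)
        estimate_ne(tab, p, seed = seed + 60L))
      names(res) <- pop_names(tab)
      res
    })
    stage("outliers", fdist_scan(tab, reps = 5000L, seed = seed + 65L))
    if (cfg$scenario %in% c("s1", "s2")) {
      stage("scenario", {
        if (cfg$scenario == "s1")
          build_s1(tab, cfg$ref1, cfg$ref2, per_class = cfg$per_class,
                   mixture = cfg$mixture, seed = seed + 70L)
        else {
          icfg <- if (is.null(cfg$island)) island_default_config(seed = seed + 71L)
                  else do.call(island_config, cfg$island)
          build_s2(icfg, per_class = cfg$per_class, mixture = cfg$mixture,
                   seed = seed + 70L)
        }
      })
    }
  }
  if (!is.null(bundle$scenario)) {
    sc <- bundle$scenario
    mixpop <- setdiff(pop_names(sc$analysis), c(cfg$ref1, cfg$ref2, "A1", "B2"))
    refs <- intersect(pop_names(sc$analysis), c(cfg$ref1, cfg$ref2, "A1", "B2"))
    stage("assign_mcmc", newhybrids_fit(sc$analysis,
                                        iters = cfg$nh_iters, burn = cfg$nh_burn,
                                        replicates = cfg$nh_replicates,
                                        seed = seed + 80L, anchor = refs[1]))
    stage("assign_em", snapclust_fit(sc$analysis, seed = seed + 90L,
                                     anchor = refs[1]))
    mixrows <- which(sc$analysis$pop %in% mixpop)
    if (!is.null(bundle$assign_mcmc))
      stage("power_mcmc", power_table(bundle$assign_mcmc$q, sc$truth,
                                      rows = mixrows, thresholds = cfg$thresholds))
    if (!is.null(bundle$assign_em))
      stage("power_em", power_table(bundle$assign_em$q, sc$truth,
                                    rows = mixrows, thresholds = cfg$thresholds))
    if (!is.null(bundle$assign_mcmc))
      stage("replicate_agreement", replicate_agreement(bundle$assign_mcmc))
  }
  log <- do.call(rbind, logrows)
  bundle$log <- log
  bundle$partial <- any(log$status == "error")
  class(bundle) <- "pipeline_bundle"
  if (!is.null(cfg$outdir)) write_bundle(bundle, cfg$outdir)
  bundle
}

#' @export
print.pipeline_bundle <- function(x, ...) {
  cat("pipeline bundle", if (x$partial) "(PARTIAL)" else "(complete)", "\n")
  print(x$log, row.names = FALSE)
  invisible(x)
}

# write the tabular artifacts of a pipeline bundle as TSV files
write_bundle <- function(bundle, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  wtsv <- function(d, f)
    utils::write.table(d, file.path(outdir, f), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  if (!is.null(bundle$hw_battery)) wtsv(bundle$hw_battery$battery, "hw_battery.tsv")
  if (!is.null(bundle$ld_battery)) wtsv(bundle$ld_battery$battery, "ld_battery.tsv")
  if (!is.null(bundle$filter)) wtsv(bundle$filter$report, "filtered_loci.tsv")
  if (!is.null(bundle$summary)) wtsv(bundle$summary, "summary_stats.tsv")
  if (!is.null(bundle$outliers)) wtsv(bundle$outliers, "outlier_scan.tsv")
  if (!is.null(bundle$ne)) {
    ne <- do.call(rbind, lapply(names(bundle$ne), function(p) {
      r <- bundle$ne[[p]]
      data.frame(pop = p, ne = r$ne, lo = r$ci[1], hi = r$ci[2], r2 = r$r2)
    }))
    wtsv(ne, "ne_ld.tsv")
  }
  if (!is.null(bundle$differentiation)) {
    pw <- bundle$differentiation$pairwise
    wtsv(as.data.frame(as.table(pw$theta)), "pairwise_theta.tsv")
    wtsv(as.data.frame(as.table(pw$d_est)), "pairwise_dest.tsv")
  }
  if (!is.null(bundle$power_mcmc)) wtsv(bundle$power_mcmc, "power_mcmc.tsv")
  if (!is.null(bundle$power_em)) wtsv(bundle$power_em, "power_em.tsv")
  if (!is.null(bundle$assign_mcmc)) {
    for (r in seq_along(bundle$assign_mcmc$q))
      wtsv(cbind(id = rownames(bundle$assign_mcmc$q[[r]]),
                 as.data.frame(bundle$assign_mcmc$q[[r]])),
           sprintf("q_mcmc_rep%d.tsv", r))
  }
  if (!is.null(bundle$assign_em))
    wtsv(cbind(id = rownames(bundle$assign_em$q),
               as.data.frame(bundle$assign_em$q)), "q_em.tsv")
  wtsv(bundle$log, "run_log.tsv")
  invisible(outdir)
}
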