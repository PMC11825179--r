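#' Default run configuration
#'
#' Builds the nested configuration list consumed by [run_all()]. Either an
#' `inputs` block (paths to VCF, panel, layout, effects, outgroup, scores)
#' or a `simulate` block (arguments to [sim_config()]) must be present.
#' Stage blocks mirror the per-stage function parameters; setting a stage
#' block to `NULL` (e.g. `purging = NULL`) skips the stage and omits its
#' report section.
#'
#' @param inputs named list of input paths, or `NULL`.
#' @param simulate named list of [sim_config()] arguments, or `NULL`.
#' @param seed integer seed governing all stochastic stages (per-stage
#'   seeds are derived from it deterministically).
#' @param filters,roh,diversity,load,purging,sfs stage parameter blocks.
#' @return nested list of class `run_config`.
#' @export
run_config <- function(inputs = NULL, simulate = NULL, seed = 1L,
                       filters = list(max_missing_frac = 0.20),
                       roh = list(),
                       diversity = list(window_bp = 5e5),
                       load = list(focal_population = NULL),
                       purging = list(top_q = 0.001, n_blocks = 20L),
                       sfs = list(subsample_2n = 10L, mode = "expected")) {
  if (is.null(inputs) && is.null(simulate))
    stop("config needs an inputs block or a simulate block", call. = FALSE)
  structure(list(inputs = inputs, simulate = simulate,
                 seed = as.integer(seed), filters = filters, roh = roh,
                 diversity = diversity, load = load, purging = purging,
                 sfs = sfs),
            class = "run_config")
}

#' Read a run configuration from YAML
#' @param path YAML file path.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y), names(formals(run_config)))]
  do.call(run_config, args)
}

# derive a per-stage seed from the master seed (kept below 2^31)
.stage_seed <- function(seed, stage) {
  (as.integer(seed) * 1009L + match(stage, c("simulate", "sfs"),
                                    nomatch = 99L) * 7919L) %% 2147483587L
}

#' Run the full analysis pipeline
#'
#' Executes, in order: input loading (or simulation), site filters
#' (biallelic, hard filter if INFO present, per-population missingness),
#' ROH detection and inbreeding summary, windowed diversity and
#' heterozygosity, effect classification and polarization, load
#' tabulation, purging statistics (ROHf/non-ROHf, Rxy over all ordered
#' population pairs, conservation-weighted load) and the per-population
#' site-frequency spectra. Writes per-stage TSVs, a machine-readable JSON
#' report and a parameter log into `out_dir`; any stage failure aborts
#' with the stage name and leaves a `FAILED` marker.
#'
#' @param config a `run_config`, a YAML path, or a plain named list.
#' @param out_dir output directory, or `NULL` to skip writing files.
#' @return the report as a nested list (invisibly when `out_dir` is set).
#' @export
run_all <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  if (!inherits(config, "run_config")) {
    given <- names(config)
    config <- do.call(run_config,
                      config[intersect(given,
                                       names(formals(run_config)))])
    # a plain config without a purging block skips that stage
    if (!"purging" %in% given) config["purging"] <- list(NULL)
  }
  if (!is.null(out_dir))
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(paste0("purgekit ", as.character(
    utils::packageVersion("purgekit"))),
    paste0("R ", R.version.string),
    paste0("seed: ", config$seed),
    paste0("config: ", jsonlite::toJSON(.config_for_log(config),
                                        auto_unbox = TRUE)))
  stage <- "load_inputs"
  report <- list(seed = config$seed)
  on_fail <- function(e) {
    if (!is.null(out_dir))
      writeLines(c(log_lines, paste0("FAILED at stage: ", stage),
                   conditionMessage(e)),
                 file.path(out_dir, "FAILED"))
    stop("stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  }
  tryCatch({
    if (!is.null(config$simulate)) {
      sim_args <- config$simulate
      if (is.null(sim_args$seed))
        sim_args$seed <- .stage_seed(config$seed, "simulate")
      sim <- simulate_dataset(do.call(sim_config, sim_args))
      vt <- sim$vt; panel <- sim$panel; layout <- sim$layout
      effects_raw <- sim$effects; outgroup <- sim$outgroup
      scores <- sim$track
    } else {
      inp <- config$inputs
      vt <- read_vcf(inp$vcf)
      panel <- read_sample_panel(inp$panel)
      layout <- read_genome_layout(inp$layout, autosomes = inp$autosomes)
      effects_raw <- if (!is.null(inp$effects)) read_effects(inp$effects)
      else effects_from_ann(vt)
      outgroup <- if (!is.null(inp$outgroup)) read_outgroup(inp$outgroup)
      scores <- if (!is.null(inp$scores))
        utils::read.table(inp$scores, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
    }

    stage <- "filters"
    n0 <- n_sites(vt)
    vt <- filter_biallelic_snps(vt)
    vt <- apply_hard_filter(vt)
    mmf <- config$filters$max_missing_frac
    if (is.null(mmf)) mmf <- 0.20
    vt <- filter_missingness(vt, panel, max_missing_frac = mmf)
    report$filters <- list(n_input = n0, n_retained = n_sites(vt))

    stage <- "roh"
    params <- do.call(roh_params, config$roh)
    segs <- detect_roh(vt, params = params)
    segs <- filter_roh_min_length(segs,
                                  params$final_min_length_kb * 1000)
    inb <- summarize_inbreeding(segs, layout, panel)
    report$roh <- list(samples = inb$samples,
                       populations = inb$populations)

    stage <- "diversity"
    wb <- config$diversity$window_bp
    if (is.null(wb)) wb <- 5e5
    pi_res <- windowed_pi(vt, panel, layout, window_bp = wb)
    het <- individual_heterozygosity(vt)
    report$diversity <- list(pi = pi_res$genome, heterozygosity = het)

    stage <- "load"
    effects <- classify_effects(effects_raw)
    polar <- polarize(vt, outgroup, panel,
                      focal_population = config$load$focal_population)
    load <- tabulate_load(vt, effects, polar, panel)
    homr <- hom_load_ratio(load)
    report$load <- list(individual = load$individual,
                        population = load$population,
                        hom_ratio = homr$population)

    if (!is.null(config$purging)) {
      stage <- "purging"
      rohf <- rohf_statistics(vt, segs, effects, polar, panel)
      masks <- category_site_masks(vt, effects)
      track <- conservation_track(scores,
                                  top_q = config$purging$top_q %||% 0.001)
      gerp <- gerp_relative_load(vt, polar, track)
      pops <- names(panel$populations)
      rxy_rows <- list()
      if (length(pops) >= 2) {
        for (x in pops) for (y in setdiff(pops, x)) {
          for (cat in c("LoF", "dnsSNP", "missense", "synonymous")) {
            if (!any(masks[[cat]]) || !any(masks$intergenic)) next
            rr <- rxy(polar, x, y, masks[[cat]], masks$intergenic,
                      n_blocks = config$purging$n_blocks %||% 20L)
            rxy_rows[[length(rxy_rows) + 1L]] <- data.frame(
              pop_x = x, pop_y = y, category = cat, r = rr$r,
              se = rr$se, stringsAsFactors = FALSE)
          }
        }
      }
      report$purging <- list(
        rohf = rohf$population,
        rxy = if (length(rxy_rows)) do.call(rbind, rxy_rows),
        gerp = gerp)
    }

    stage <- "sfs"
    if (!is.null(config$sfs)) {
      set.seed(.stage_seed(config$seed, "sfs"))
      sfs_list <- list()
      for (p in names(panel$populations)) {
        s2n <- config$sfs$subsample_2n %||% 10L
        res <- sfs(polar, effects, panel, p, subsample_2n = s2n,
                   mode = config$sfs$mode %||% "expected")
        sfs_list[[p]] <- list(
          spectra = res$spectra,
          n_sites = res$n_sites,
          proportion_fixed = as.list(proportion_fixed(res)))
      }
      report$sfs <- sfs_list
    }
  }, error = on_fail)

  if (!is.null(out_dir)) {
    write_roh_segments(segs, file.path(out_dir, "roh_segments.tsv"))
    utils::write.table(pi_res$windows,
                       file.path(out_dir, "windowed_pi.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(het, file.path(out_dir, "heterozygosity.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(load$individual,
                       file.path(out_dir, "load_counts.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(report$purging)) {
      utils::write.table(report$purging$rohf,
                         file.path(out_dir, "rohf.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      if (!is.null(report$purging$rxy))
        utils::write.table(report$purging$rxy,
                           file.path(out_dir, "rxy.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(report$purging$gerp,
                         file.path(out_dir, "gerp_load.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    writeLines(log_lines, file.path(out_dir, "run.log"))
    return(invisible(report))
  }
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.config_for_log <- function(config) {
  # fill in defaulted values so the run is reconstructible from the log
  config <- unclass(config)
  config$roh <- unclass(do.call(roh_params, config$roh %||% list()))
  config
}

#' Validate a pipeline report against the shipped schema
#'
#' Checks the structural contract of a [run_all()] report: required
#' top-level sections and required fields within each, per the JSON schema
#' shipped at `inst/schema/report.schema.json`.
#'
#' @param report report list (or path to a report JSON).
#' @return `TRUE` invisibly; stops with a message on violation.
#' @export
validate_report <- function(report) {
  if (is.character(report)) report <- jsonlite::read_json(report)
  schema <- jsonlite::read_json(system.file("schema",
                                            "report.schema.json",
                                            package = "purgekit"))
  need <- unlist(schema$required)
  missing <- setdiff(need, names(report))
  if (length(missing))
    stop("report lacks required section(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  for (sec in intersect(names(schema$properties), names(report))) {
    req <- unlist(schema$properties[[sec]]$required)
    missing <- setdiff(req, names(report[[sec]]))
    if (length(missing))
      stop("report section '", sec, "' lacks field(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}
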