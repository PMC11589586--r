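# End-to-end orchestration: simulate or ingest, QC, HBD model fit,
# inbreeding coefficients, diversity, landscape, load statistics, with a
# manifest for reproducibility.

#' Pipeline configuration
#'
#' Either a set of real input paths (`vcf`, plus optional `population_map`,
#' `map`, `categories`, `genes`) or a [sim_config()] — exactly one of the
#' two. Stage toggles and per-stage parameter blocks mirror each stage's
#' defaults. Configurations can also be read from a YAML file whose keys
#' match these arguments (with `sim:` holding [sim_config()] arguments).
#'
#' @param inputs named list of input paths, or `NULL` when simulating.
#' @param sim a [sim_config()], or `NULL` when reading real inputs.
#' @param stages character vector of stages to run, in dependency order
#'   from `simulate`/`ingest` through `qc`, `hbd`, `inbreeding`,
#'   `diversity`, `landscape`, `load`.
#' @param qc,hbd,diversity,landscape,load named lists overriding stage
#'   parameters (see the stage functions for names).
#' @param seed global seed propagated to every stochastic stage.
#' @param outdir output directory; stage outputs land in
#'   `<outdir>/<stage>/`.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(inputs = NULL, sim = NULL,
                            stages = c("simulate", "qc", "hbd",
                                       "inbreeding", "diversity",
                                       "landscape", "load"),
                            qc = list(), hbd = list(), diversity = list(),
                            landscape = list(), load = list(),
                            seed = 1L, outdir = tempfile("hbdload_run_")) {
  if (is.null(inputs) == is.null(sim))
    stop("provide exactly one of real inputs or a simulation config")
  structure(list(inputs = inputs, sim = sim, stages = stages, qc = qc,
                 hbd = hbd, diversity = diversity, landscape = landscape,
                 load = load, seed = as.integer(seed), outdir = outdir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with keys matching [pipeline_config()] arguments.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- if (!is.null(y$sim)) do.call(sim_config, y$sim)
  do.call(pipeline_config,
          c(list(inputs = y$inputs, sim = sim),
            y[setdiff(names(y), c("inputs", "sim"))]))
}

.write_tsv <- function(df, dir, name) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- file.path(dir, name)
  utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
  p
}

#' Run the analysis pipeline
#'
#' Executes the enabled stages in dependency order; every stage writes its
#' tables under `<outdir>/<stage>/` and is recorded in a manifest (stage,
#' parameters, input-file hashes, seed). Reruns with the same
#' configuration and seed reproduce every output.
#'
#' @param config a [pipeline_config()] or the path of a YAML file.
#' @return list with the in-memory stage results (`panel`, `truth`,
#'   `fit`, `inbreeding`, `diversity`, `windows`, `load`, `rxy`), the
#'   `outdir` and the manifest.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  outdir <- config$outdir
  stages <- config$stages
  manifest <- list(seed = config$seed, stages = list())
  res <- list(outdir = outdir)
  note <- function(stage, params, files) {
    manifest$stages[[stage]] <<- list(
      parameters = params,
      outputs = stats::setNames(as.character(tools::md5sum(files)),
                                basename(files)))
  }

  # --- simulate / ingest -----------------------------------------------
  if ("simulate" %in% stages) {
    if (is.null(config$sim)) stop("simulate stage enabled but no sim config")
    sim <- config$sim
    sim$seed <- config$seed
    gen <- generate_panel(sim)
    res$panel <- gen$panel; res$truth <- gen$truth
    d <- file.path(outdir, "simulate")
    if (!dir.exists(d)) dir.create(d, recursive = TRUE)
    f <- c(write_genotypes(res$panel, file.path(d, "panel.vcf")),
           write_population_table(res$panel, file.path(d, "populations.tsv")),
           write_category_table(res$panel, file.path(d, "categories.tsv")),
           write_genetic_map(res$panel, file.path(d, "genetic_map.tsv")),
           write_truth_bed(res$truth, file.path(d, "truth_tracts.bed")),
           write_truth_summary(res$truth, file.path(d, "truth_summary.tsv")))
    note("simulate", unclass(sim)[c("n_populations", "n_individuals",
                                    "n_scaffolds", "n_sites", "seed")], f)
  } else if (any(stages != "simulate")) {
    if (is.null(config$inputs$vcf)) stop("no VCF input for the ingest stage")
    res$panel <- read_genotypes(config$inputs$vcf,
                                population_map = config$inputs$population_map,
                                category_table = config$inputs$categories)
    map <- if (!is.null(config$inputs$map)) genetic_map(config$inputs$map)
    res$panel <- interpolate_genetic_positions(res$panel, map)
  }

  # --- qc ---------------------------------------------------------------
  if ("qc" %in% stages) {
    if (is.null(res$panel)) stop("qc stage needs the simulate/ingest stage")
    p <- utils::modifyList(list(min_depth = 5, sd_multiplier = 3,
                                min_mac = 3, max_missing = 0.10), config$qc)
    if (!is.null(res$panel$depth))
      res$panel <- mask_by_depth(res$panel, p$min_depth, p$sd_multiplier)
    res$panel <- filter_sites(res$panel, p$min_mac, p$max_missing)
    rep <- attr(res$panel, "filter_report")
    f <- .write_tsv(data.frame(rule = names(rep), count = as.integer(rep)),
                    file.path(outdir, "qc"), "filter_report.tsv")
    note("qc", p, f)
  }

  # --- hbd --------------------------------------------------------------
  if ("hbd" %in% stages) {
    if (is.null(res$panel)) stop("hbd stage needs a panel")
    p <- utils::modifyList(list(rates = .DEFAULT_RATES, error = 0.001,
                                T = 1024, freq_scope = "population"),
                           config$hbd)
    res$fit <- hbd_fit(res$panel, rates = p$rates, error = p$error,
                       T = p$T, freq_scope = p$freq_scope)
    d <- file.path(outdir, "hbd")
    f <- c(.write_tsv(res$fit$records, d, "individuals.tsv"),
           .write_tsv(res$fit$segments, d, "segments.tsv"),
           .write_tsv(cbind(id = rownames(coef(res$fit)),
                            as.data.frame(coef(res$fit))), d, "mixing.tsv"))
    note("hbd", p[c("error", "T", "freq_scope")], f)
  }

  # --- inbreeding -------------------------------------------------------
  if ("inbreeding" %in% stages) {
    if (is.null(res$fit)) stop("inbreeding stage needs the hbd stage")
    rec <- inbreeding_records(res$fit, res$panel)
    res$inbreeding <- rec
    f <- .write_tsv(rec, file.path(outdir, "inbreeding"), "records.tsv")
    note("inbreeding", list(), f)
  }

  # --- diversity --------------------------------------------------------
  if ("diversity" %in% stages) {
    if (is.null(res$panel)) stop("diversity stage needs a panel")
    p <- utils::modifyList(list(block_bp = 1e6, reps = 1000, mu = 4.6e-9),
                           config$diversity)
    res$diversity <- diversity_table(res$panel, block_bp = p$block_bp,
                                     reps = p$reps, mu = p$mu,
                                     seed = config$seed)
    f <- .write_tsv(res$diversity, file.path(outdir, "diversity"),
                    "diversity.tsv")
    note("diversity", p, f)
  }

  # --- landscape --------------------------------------------------------
  if ("landscape" %in% stages) {
    if (is.null(res$fit)) stop("landscape stage needs the hbd stage")
    p <- utils::modifyList(list(width = 1e5, step = 2e4,
                                min_scaffold_snps = 10000, tail = 0.025),
                           config$landscape)
    track <- per_snp_hbd_probability(res$fit)
    win <- window_average(track, width = p$width, step = p$step,
                          min_scaffold_snps = p$min_scaffold_snps,
                          scaffold_lengths = res$panel$scaffold_lengths)
    if (nrow(win) && any(!is.na(win$prob)))
      win <- hbd_islands_deserts(win, tail = p$tail)
    res$windows <- win
    f <- .write_tsv(win, file.path(outdir, "landscape"), "windows.tsv")
    note("landscape", p, f)
  }

  # --- load -------------------------------------------------------------
  if ("load" %in% stages) {
    if (is.null(res$panel)) stop("load stage needs a panel")
    p <- utils::modifyList(list(reps = 1000, block_bp = 5e6,
                                l2_form = "literal", groups = NULL),
                           config$load)
    usets <- list()
    for (pop in unique(res$panel$individuals$population)) {
      sub <- res$panel[res$panel$individuals$population == pop, ]
      usets[[pop]] <- if (nrow(sub$dosage) >= 2)
        unrelated_set(allele_sharing_matrix(sub)) else sub$individuals$id
    }
    calls <- call_minor_alleles(res$panel, usets, reps = p$reps,
                                seed = config$seed)
    res$load <- individual_load_counts(res$panel, calls)
    d <- file.path(outdir, "load")
    f <- .write_tsv(res$load, d, "load_counts.tsv")
    grps <- p$groups
    if (is.null(grps)) {
      g <- unique(res$panel$individuals$group)
      if (length(g) == 2) grps <- g
    }
    if (!is.null(grps)) {
      res$rxy <- tryCatch(
        rxy(res$panel, calls, grps[1], grps[2], l2_form = p$l2_form,
            block_bp = p$block_bp),
        error = function(e) { warning(conditionMessage(e)); NULL })
      if (!is.null(res$rxy))
        f <- c(f, .write_tsv(res$rxy, d, "rxy.tsv"))
    }
    note("load", p[c("reps", "block_bp", "l2_form")], f)
  }

  res$manifest <- manifest
  mpath <- file.path(outdir, "manifest.yaml")
  yaml::write_yaml(manifest, mpath)
  res
}
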