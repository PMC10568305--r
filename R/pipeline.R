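# End-to-end orchestration: simulate (or read) -> cluster -> classify ->
# rarefy -> fit -> ANI -> single-copy-core NJ tree, with a machine-readable
# JSON run report. Identical config + seed gives identical numeric outputs.

#' Run configuration
#'
#' Exactly one input source must be given: either `input` (a directory of
#' per-genome `.faa` protein FASTAs, with optional matching `.fna`
#' assemblies) or `sim` (simulation parameters).
#'
#' @param input Directory of input FASTAs, or `NULL`.
#' @param sim A [sim_params()] object (or a list of its arguments), or
#'   `NULL`.
#' @param clustering,scoring,ani Parameter blocks.
#' @param n_perm,seed Rarefaction settings.
#' @param outdir Output directory.
#' @param stages Stages to run, a subset of
#'   `c("cluster", "rarefy", "fit", "ani", "tree")`.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(input = NULL, sim = NULL,
                       clustering = clustering_params(),
                       scoring = scoring_params("protein"),
                       ani = ani_params(),
                       n_perm = 100L, seed = 1L,
                       outdir = tempfile("panforge_run_"),
                       stages = c("cluster", "rarefy", "fit", "ani", "tree")) {
  if (is.null(input) == is.null(sim))
    pf_stop("exactly one of 'input' (files) or 'sim' (simulation) required",
            "config")
  if (!is.null(sim) && !inherits(sim, "sim_params"))
    sim <- do.call(sim_params, sim)
  stages <- match.arg(stages, several.ok = TRUE)
  structure(list(input = input, sim = sim, clustering = clustering,
                 scoring = scoring, ani = ani, n_perm = as.integer(n_perm),
                 seed = as.integer(seed), outdir = outdir, stages = stages),
            class = "run_config")
}

#' Read a YAML run configuration
#'
#' Top-level keys mirror the [run_config()] arguments; parameter blocks
#' (`sim`, `clustering`, `scoring`, `ani`) are given as key-value maps of the
#' corresponding constructor arguments.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list(input = y$input,
               sim = if (!is.null(y$sim)) do.call(sim_params, y$sim))
  if (!is.null(y$clustering))
    args$clustering <- do.call(clustering_params, y$clustering)
  if (!is.null(y$scoring)) args$scoring <- do.call(scoring_params, y$scoring)
  if (!is.null(y$ani)) args$ani <- do.call(ani_params, y$ani)
  for (k in c("n_perm", "seed", "outdir", "stages"))
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  do.call(run_config, args)
}

read_genome_dir <- function(dir) {
  faa <- sort(list.files(dir, "\\.faa$", full.names = TRUE))
  if (!length(faa)) pf_stop(paste0("no .faa files in ", dir), "config")
  proteins <- purrr::map_dfr(faa, function(f) {
    g <- sub("\\.faa$", "", basename(f))
    x <- read_fasta(f, "protein")
    tibble(genome_id = g, gene_id = paste0(g, "|", names(x)),
           seq = as.character(x))
  })
  fna <- sort(list.files(dir, "\\.fna$", full.names = TRUE))
  genomes <- if (length(fna)) {
    setNames(lapply(fna, read_fasta, alphabet = "nucleotide"),
             sub("\\.fna$", "", basename(fna)))
  }
  list(proteins = proteins, genomes = genomes)
}

#' Run the pan-genome pipeline
#'
#' Executes the requested stages in dependency order and writes every result
#' (edge list, family membership, presence/absence matrix, rarefaction
#' curves, fit reports, ANI matrix, Newick tree) under `config$outdir`,
#' together with `report.json` echoing parameters, seeds, versions, timings
#' and output paths.
#'
#' @param config A [run_config()] (or a YAML path).
#' @return The run report, invisibly (list, also serialized as JSON).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  t_start <- Sys.time()
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$outdir, ...)
  report <- list(package = "panforge",
                 version = as.character(utils::packageVersion("panforge")),
                 seed = config$seed, stages = config$stages,
                 parameters = list(
                   clustering = unclass(config$clustering),
                   scoring = unclass(config$scoring)[
                     setdiff(names(config$scoring), "matrix")],
                   ani = unclass(config$ani)[
                     setdiff(names(unclass(config$ani)), "scoring")],
                   n_perm = config$n_perm,
                   sim = if (!is.null(config$sim)) unclass(config$sim)),
                 outputs = list(), timings = list(), warnings = list())
  stage_time <- function(nm, expr) {
    t0 <- Sys.time()
    v <- force(expr)
    report$timings[[nm]] <<- round(as.numeric(Sys.time() - t0, units = "secs"), 3)
    v
  }

  # --- inputs ---------------------------------------------------------------
  dat <- stage_time("input", {
    if (!is.null(config$sim)) {
      sim <- simulate_pangenome(config$sim, nucleotide = TRUE)
      write_pangenome(sim, out("simulated"))
      report$outputs$simulated <- out("simulated")
      list(proteins = sim$proteins, genomes = sim$genomes, truth = sim$truth)
    } else {
      read_genome_dir(config$input)
    }
  })
  genome_ids <- sort(unique(dat$proteins$genome_id))

  families <- NULL; part <- NULL; pa <- NULL
  if ("cluster" %in% config$stages) {
    edges <- stage_time("all_vs_all",
      all_vs_all(dat$proteins, config$clustering, config$scoring))
    readr::write_tsv(edges, out("edges.tsv"))
    families <- build_families(edges, dat$proteins)
    readr::write_tsv(families, out("families.tsv"))
    pa <- families_to_pa(families, genome_ids)
    write_pa_matrix(pa, out("pa_matrix.tsv"))
    part <- classify_families(pa, genome_ids)
    jsonlite::write_json(glance(part), out("partition.json"),
                         auto_unbox = TRUE, digits = NA)
    report$outputs[c("edges", "families", "pa_matrix", "partition")] <-
      out(c("edges.tsv", "families.tsv", "pa_matrix.tsv", "partition.json"))
  }

  curves <- NULL
  if ("rarefy" %in% config$stages && !is.null(pa)) {
    curves <- stage_time("rarefy", rarefy(pa, config$n_perm, config$seed))
    readr::write_tsv(curves$summary, out("curves.tsv"))
    report$outputs$curves <- out("curves.tsv")
  }

  if ("fit" %in% config$stages && !is.null(curves)) {
    fits <- stage_time("fit", {
      hf <- fit_heaps(curves$summary$x, curves$summary$pan_mean)
      cf <- tryCatch(fit_decay(curves$summary$x, curves$summary$core_mean),
                     error = function(e) NULL)
      nf <- tryCatch(fit_decay(curves$summary$x[-1], curves$summary$new_mean[-1]),
                     error = function(e) NULL)
      list(heaps = hf, core_decay = cf, new_decay = nf)
    })
    fit_json <- list(
      heaps = as.list(glance(fits$heaps)),
      openness = classify_openness(fits$heaps),
      core_decay = if (!is.null(fits$core_decay)) as.list(glance(fits$core_decay)),
      new_decay = if (!is.null(fits$new_decay)) as.list(glance(fits$new_decay)))
    jsonlite::write_json(fit_json, out("fits.json"), auto_unbox = TRUE,
                         digits = NA)
    report$outputs$fits <- out("fits.json")
  }

  if ("ani" %in% config$stages && !is.null(dat$genomes) &&
      length(dat$genomes) >= 2) {
    am <- stage_time("ani", ani_matrix(dat$genomes, config$ani))
    write_ani_matrix(am, out("ani_matrix.tsv"))
    readr::write_tsv(am$clusters, out("ani_clusters.tsv"))
    report$outputs[c("ani_matrix", "ani_clusters")] <-
      out(c("ani_matrix.tsv", "ani_clusters.tsv"))
  }

  if ("tree" %in% config$stages && !is.null(families)) {
    scc <- extract_single_copy_core(families, genome_ids)
    if (length(scc) >= 1 && length(genome_ids) >= 3) {
      tree <- stage_time("tree", {
        dm <- core_distances(dat$proteins, families, scc, config$scoring)
        readr::write_tsv(tidy(dm), out("core_distances.tsv"))
        nj_tree(dm)
      })
      write_newick(tree, out("tree.nwk"))
      report$outputs[c("core_distances", "tree")] <-
        out(c("core_distances.tsv", "tree.nwk"))
    } else {
      report$warnings <- c(report$warnings,
                           "tree stage skipped: need >= 3 genomes and >= 1 single-copy core family")
    }
  }

  report$elapsed_secs <- round(as.numeric(Sys.time() - t_start,
                                          units = "secs"), 3)
  jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  report$outputs$report <- out("report.json")
  invisible(report)
}
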