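#' Run the full screen analysis pipeline
#'
#' Executes simulate -> metrics -> score -> enrich on a synthetic screen
#' described by a run configuration, writing all primary artifacts and a
#' manifest to `out_dir`. Two runs with the same configuration (including
#' seed) produce byte-identical outputs; the manifest records the package
#' version, seed and per-file MD5 hashes and deliberately contains no
#' timestamp.
#'
#' Readouts scored per compound: `habituation_41_50`, `habituation_51_60`,
#' `ppi_pct`, `any_init_low_pct`, `any_init_high_pct`. Hit directions follow
#' the screening question: increase for habituation/PPI, increase for
#' low-intensity initiation, decrease for high-intensity initiation.
#'
#' @param config a `run_config` (see [read_run_config()] / [as_run_config()]).
#' @param quiet suppress stage messages.
#' @return (invisibly) list with the in-memory artifacts: `group_means`,
#'   `controls`, `zscores`, `hits`, `enrichment`, `manifest`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (!inherits(config, "run_config")) config <- as_run_config(config)
  say <- function(stage, fmt, ...) {
    if (!quiet) message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      .stopf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)))
  }
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  behavior <- do.call(behavior_config,
                      c(config$behavior, list(drug_effects = config$drug_effects)))
  sched <- build_screen_schedule()

  say("simulate", "%d days x %d compounds, groups of %d, seed %d",
      config$n_days, config$compounds_per_day, config$group_size, config$seed)
  sim <- run_stage("simulate", {
    scr <- simulate_screen(config$n_days, config$compounds_per_day,
                           config$group_size, behavior, seed = config$seed,
                           dose = config$dose)
    lib <- make_library(config$n_days * config$compounds_per_day,
                        config$class_sizes, seed = config$seed)
    list(scr = scr, lib = lib)
  })

  say("metrics", "summarizing %d larvae", nrow(sim$scr$meta))
  group_means <- run_stage("metrics", {
    summ <- summarize_behavior(sim$scr$events, sched)
    meta_cols <- sim$scr$meta[, .(larva_id, compound_id, day_id, group_id, role)]
    summ <- meta_cols[summ, on = "larva_id"]
    readouts <- c("habituation_41_50", "habituation_51_60", "ppi_pct",
                  "any_init_low_pct", "any_init_high_pct")
    gm <- summ[excluded == FALSE,
               c(.(n = .N), lapply(.SD, function(v) mean(v, na.rm = TRUE))),
               by = .(group_id, day_id, role, compound_id),
               .SDcols = readouts]
    gm
  })

  say("score", "z-scoring %d groups against pooled controls",
      sum(group_means$role == "treated"))
  readouts <- c("habituation_41_50", "habituation_51_60", "ppi_pct",
                "any_init_low_pct", "any_init_high_pct")
  directions <- c(habituation_41_50 = "increase", habituation_51_60 = "increase",
                  ppi_pct = "increase", any_init_low_pct = "increase",
                  any_init_high_pct = "decrease")
  scored <- run_stage("score", {
    controls <- lapply(stats::setNames(readouts, readouts), function(r)
      control_distribution(group_means[role == "control"][[r]], readout = r))
    zs <- rbindlist(lapply(readouts, function(r) {
      tr <- group_means[role == "treated"]
      data.table(compound_id = tr$compound_id, readout = r,
                 treated_mean = tr[[r]], z = zscore(tr[[r]], controls[[r]]))
    }))
    hits <- rbindlist(lapply(readouts, function(r) {
      h <- call_hits(zs[readout == r, .(compound_id, z)],
                     direction = directions[[r]], alpha = config$alpha)
      h[, readout := r][, direction := directions[[r]]]
    }))
    list(controls = controls, zscores = zs, hits = hits)
  })

  say("enrich", "testing target-class enrichment per readout")
  enrichment <- run_stage("enrich", {
    rbindlist(lapply(readouts, function(r) {
      hit_ids <- scored$hits[readout == r & hit == TRUE, compound_id]
      e <- enrich_targets(hit_ids, sim$lib, alpha = config$enrich_alpha)
      e[, readout := r]
    }))
  })

  files <- c(schedule = file.path(out_dir, "schedule.json"),
             library = file.path(out_dir, "library.csv"),
             group_means = file.path(out_dir, "group_means.tsv"),
             zscores = file.path(out_dir, "zscores.tsv"),
             hits = file.path(out_dir, "hits.tsv"),
             enrichment = file.path(out_dir, "enrichment.tsv"))
  write_schedule_json(sched, files["schedule"])
  fwrite(sim$lib, files["library"])
  fwrite(group_means, files["group_means"], sep = "\t")
  fwrite(scored$zscores, files["zscores"], sep = "\t")
  fwrite(scored$hits, files["hits"], sep = "\t")
  fwrite(enrichment, files["enrichment"], sep = "\t")

  manifest <- list(
    package = "startlescreen",
    version = as.character(utils::packageVersion("startlescreen")),
    seed = config$seed,
    config = unclass(config),
    files = as.list(tools::md5sum(unname(files)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("done", "artifacts in %s", out_dir)
  invisible(list(group_means = group_means, controls = scored$controls,
                 zscores = scored$zscores, hits = scored$hits,
                 enrichment = enrichment, manifest = manifest))
}

# tiny --flag value parser; returns named list plus positional args
.parse_args <- function(args) {
  out <- list(positional = character(0))
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      key <- sub("^--", "", a)
      if (i == length(args) || startsWith(args[i + 1L], "--"))
        .stopf("missing value for --%s", key)
      out[[key]] <- args[i + 1L]
      i <- i + 2L
    } else {
      out$positional <- c(out$positional, a)
      i <- i + 1L
    }
  }
  out
}

.cli_need <- function(opts, key, sub) {
  if (is.null(opts[[key]])) .stopf("%s: --%s is required", sub, key)
  opts[[key]]
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write a synthetic cohort), `metrics` (per-larva
#' and group summaries from an event table), `score` (z-scores + hits from a
#' group-means table), `enrich` (target enrichment from a hits table and
#' library), `map` (voxelwise z-map from a stacks CSV), `quant punnett`
#' (expected cross ratios), and `run` (full pipeline from a JSON config).
#' Every stochastic subcommand requires `--seed`.
#'
#' @param args character vector of command-line arguments (defaults to the
#'   calling command line).
#' @return invisibly, the subcommand's primary result.
#' @export
run_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L)
    .stopf("usage: startlescreen <simulate|metrics|score|enrich|map|quant|run> [options]")
  sub <- args[1]
  opts <- .parse_args(args[-1])
  pick_schedule <- function() {
    assay <- if (is.null(opts$assay)) "screen" else opts$assay
    switch(assay, screen = build_screen_schedule(),
           habituation = build_habituation_schedule(),
           .stopf("unknown --assay '%s'", assay))
  }
  switch(sub,
    simulate = {
      seed <- as.integer(.cli_need(opts, "seed", "simulate"))
      out <- .cli_need(opts, "out", "simulate")
      n <- as.integer(if (is.null(opts$n)) 96 else opts$n)
      sched <- pick_schedule()
      set.seed(seed)
      geno <- sample_cross_genotypes(n)
      meta <- data.table(larva_id = sprintf("L%04d", seq_len(n)),
                         genotype_a = geno$genotype_a, genotype_b = geno$genotype_b)
      ev <- simulate_cohort(sched, meta, behavior_config(), seed = seed)
      write_events(ev, out)
      invisible(ev)
    },
    metrics = {
      ev <- read_events(.cli_need(opts, "events", "metrics"))
      sched <- pick_schedule()
      summ <- summarize_behavior(ev, sched)
      fwrite(summ, .cli_need(opts, "out", "metrics"), sep = "\t")
      invisible(summ)
    },
    score = {
      gm <- fread(.cli_need(opts, "groups", "score"))
      readout <- .cli_need(opts, "readout", "score")
      direction <- if (is.null(opts$direction)) "increase" else opts$direction
      alpha <- as.numeric(if (is.null(opts$alpha)) 0.01 else opts$alpha)
      ctrl <- control_distribution(gm[role == "control"][[readout]], readout)
      tr <- gm[role == "treated"]
      res <- data.table(compound_id = tr$compound_id,
                        z = zscore(tr[[readout]], ctrl))
      res <- call_hits(res, direction = direction, alpha = alpha)
      fwrite(res, .cli_need(opts, "out", "score"), sep = "\t")
      invisible(res)
    },
    enrich = {
      hits_tab <- fread(.cli_need(opts, "hits", "enrich"))
      lib <- fread(.cli_need(opts, "library", "enrich"))
      alpha <- as.numeric(if (is.null(opts$alpha)) 0.05 else opts$alpha)
      res <- enrich_targets(hits_tab[hit == TRUE, compound_id], lib, alpha = alpha)
      fwrite(res, .cli_need(opts, "out", "enrich"), sep = "\t")
      invisible(res)
    },
    map = {
      stacks <- read_stacks_csv(.cli_need(opts, "stacks", "map"))
      q <- as.numeric(if (is.null(opts$q)) 5e-5 else opts$q)
      zm <- apply_fdr(voxelwise_map(stacks$group_a, stacks$group_b), q)
      dims <- dim(zm$z)
      g <- as.data.table(expand.grid(x = seq_len(dims[1]), y = seq_len(dims[2]),
                                     z_slice = seq_len(dims[3])))
      g[, `:=`(z = as.vector(zm$z), p = as.vector(zm$p),
               significant = as.vector(zm$sig_mask))]
      fwrite(g, .cli_need(opts, "out", "map"), sep = "\t")
      invisible(zm)
    },
    quant = {
      what <- opts$positional[1]
      if (identical(what, "punnett")) {
        res <- punnett_expected(.cli_need(opts, "parent1", "quant punnett"),
                                .cli_need(opts, "parent2", "quant punnett"))
        cat(paste(sprintf("%s\t%g", names(res), res), collapse = "\n"), "\n", sep = "")
        invisible(res)
      } else if (identical(what, "fluor")) {
        res <- corrected_fluorescence(
          as.numeric(.cli_need(opts, "density", "quant fluor")),
          as.numeric(.cli_need(opts, "roi-area", "quant fluor")),
          as.numeric(.cli_need(opts, "background", "quant fluor")),
          as.numeric(.cli_need(opts, "brain-area", "quant fluor")))
        cat(sprintf("total\t%g\nper_area\t%g\n", res$total, res$per_area))
        invisible(res)
      } else .stopf("quant: unknown subcommand '%s' (punnett|fluor)", what)
    },
    run = {
      cfg <- read_run_config(.cli_need(opts, "config", "run"))
      if (!is.null(opts$out)) cfg$out_dir <- opts$out
      if (!is.null(opts$seed)) cfg$seed <- as.integer(opts$seed)
      invisible(run_pipeline(cfg))
    },
    .stopf("unknown subcommand '%s'", sub)
  )
}
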