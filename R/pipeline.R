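.config_defaults <- function() list(
  seed = 1L,
  synthetic = list(),          # overrides for synthetic_config()
  input = NULL,                # or list(genome=, chrom_sizes=, repeats=, peaks=, tracks=)
  stages = list(classify = TRUE, consensus = TRUE, enrichment = TRUE,
                signal = TRUE, occupancy = TRUE),
  classify = list(min_overlap = 1L),
  consensus = list(max_rounds = 5L, max_sequences = 100L),
  enrichment = list(n_randomizations = 1000L, mode = "same_chromosome",
                    min_overlap = 1L),
  signal = list(flank = 1000L, bin_size = 100L, body_bins = 10L,
                trim_fraction = 0.5, top_k = 100L, pseudocount = NULL,
                control_track = "IgG"),
  occupancy = list(min_replicate_support = 2L))

#' Validate and complete a pipeline configuration
#'
#' Accepts a raw list or a YAML/JSON file path, fills in every default,
#' rejects unknown keys and reports all out-of-range values at once. An
#' empty config is a fully defaulted synthetic run.
#'
#' @param config a list, or the path of a YAML (or JSON) config file.
#' @return A validated `pipeline_config` list.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("no such config file: ", config)
    config <- if (grepl("\\.json$", config))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
    if (is.null(config)) config <- list()
  }
  if (!is.list(config)) stop("config must be a list or a file path")
  defaults <- .config_defaults()
  problems <- character(0)

  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    problems <- c(problems, paste0("unknown key: ", unknown))
  cfg <- utils::modifyList(defaults, config[intersect(names(config),
                                                      names(defaults))],
                           keep.null = TRUE)
  for (sec in c("stages", "classify", "consensus", "enrichment", "signal",
                "occupancy")) {
    bad <- setdiff(names(cfg[[sec]]), names(defaults[[sec]]))
    if (length(bad))
      problems <- c(problems, paste0("unknown key: ", sec, ".", bad))
  }

  chk <- function(ok, msg) if (!isTRUE(ok)) problems <<- c(problems, msg)
  chk(is.numeric(cfg$seed) && cfg$seed == round(cfg$seed),
      "seed must be an integer")
  chk(cfg$classify$min_overlap >= 1, "classify.min_overlap must be >= 1")
  chk(cfg$consensus$max_rounds >= 1, "consensus.max_rounds must be >= 1")
  chk(cfg$enrichment$n_randomizations >= 1,
      "enrichment.n_randomizations must be >= 1 (minimum 1)")
  chk(cfg$enrichment$mode %in% c("same_chromosome", "genome_wide"),
      "enrichment.mode must be same_chromosome or genome_wide")
  chk(cfg$enrichment$min_overlap >= 1, "enrichment.min_overlap must be >= 1")
  chk(cfg$signal$trim_fraction >= 0 && cfg$signal$trim_fraction < 50,
      "signal.trim_fraction must be in [0, 50)")
  chk(cfg$signal$bin_size >= 1, "signal.bin_size must be >= 1")
  chk(cfg$signal$flank >= 0 &&
        cfg$signal$flank %% cfg$signal$bin_size == 0,
      "signal.flank must be a non-negative multiple of signal.bin_size")
  chk(cfg$signal$body_bins >= 1, "signal.body_bins must be >= 1")
  chk(cfg$signal$top_k >= 1, "signal.top_k must be >= 1")
  chk(cfg$occupancy$min_replicate_support >= 1,
      "occupancy.min_replicate_support must be >= 1")
  if (length(problems))
    stop("invalid configuration:\n  ", paste(problems, collapse = "\n  "))
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "pipeline_config")
}

.log_stage <- function(stage, event, ...) {
  kv <- list(...)
  extra <- if (length(kv))
    paste(names(kv), vapply(kv, format, ""), sep = "=", collapse = " ")
  else ""
  message(sprintf("[%s] %s %s", stage, event, extra))
}

#' Run the satellite-array analysis pipeline end to end
#'
#' Executes the stages in dependency order on a synthetic dataset (or on
#' user files named in the config's `input` block): generation ->
#' bound/unbound classification -> consensus and per-copy divergence ->
#' group summaries -> randomization enrichment test -> signal
#' aggregation -> occupancy subsets and repeat fractions. Every output is
#' written under `out_dir` with a stable filename, every parameter and
#' seed is logged, and a machine-readable `report.json` summarizes the
#' run. A stage failure aborts with the stage name and leaves a
#' `FAILED_<stage>` marker file next to the partial outputs.
#'
#' @param config a raw config list or YAML/JSON path (see
#'   [validate_config()]).
#' @param out_dir output directory, created if missing.
#' @param seed optional integer overriding the config seed.
#' @return The report, invisibly (also written as `report.json`).
#' @export
run_pipeline <- function(config = list(), out_dir, seed = NULL) {
  cfg <- validate_config(config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)
  report <- list(package = "satrep",
                 version = as.character(utils::packageVersion("satrep")),
                 seed = cfg$seed, config = unclass(cfg), outputs = list())
  stage <- "setup"
  run_stage <- function(name, fun) {
    stage <<- name
    t0 <- proc.time()[["elapsed"]]
    out <- fun()
    .log_stage(name, "done", seconds = round(proc.time()[["elapsed"]] - t0, 2))
    out
  }
  tryCatch({
    # data ------------------------------------------------------------
    ds <- run_stage("data", function() {
      if (!is.null(cfg$input)) .load_input_dataset(cfg$input)
      else {
        sc <- do.call(synthetic_config,
                      utils::modifyList(list(seed = cfg$seed),
                                        cfg$synthetic))
        .log_stage("data", "simulate", seed = sc$seed,
                   n_bound = sc$n_bound, n_unbound = sc$n_unbound)
        generate_dataset(sc, dir = p("synthetic"))
      }
    })
    copies <- ds$repeats
    # the generator's truth labels never leak into the analysis stages
    mcols(copies)$bound <- NULL
    mcols(copies)$divergence <- NULL
    peak_union <- merge_intervals(do.call(c, ds$peaks$binding))

    # classification --------------------------------------------------
    if (isTRUE(cfg$stages$classify)) {
      copies <- run_stage("classify", function() {
        .log_stage("classify", "params",
                   min_overlap = cfg$classify$min_overlap)
        classify_copies(copies, peak_union, cfg$classify$min_overlap)
      })
      report$n_bound <- sum(mcols(copies)$bound)
      report$n_unbound <- sum(!mcols(copies)$bound)
    }

    # consensus + divergence ------------------------------------------
    if (isTRUE(cfg$stages$consensus)) {
      stage <- "consensus"
      if (is.null(mcols(copies)$bound))
        stop("consensus stage needs classification labels; ",
             "enable the classify stage")
      cons_stage <- run_stage("consensus", function() {
        seqs <- extract_repeat_sequences(ds$genome, copies)
        use <- seqs[seq_len(min(length(seqs),
                                cfg$consensus$max_sequences))]
        model <- build_consensus(use, cfg$consensus$max_rounds)
        writeXStringSet(DNAStringSet(c(consensus = model$consensus)),
                        p("consensus.fa"))
        list(model = model,
             divergence = copy_divergence(seqs, model$consensus))
      })
      cons <- cons_stage$model
      mcols(copies)$divergence <- cons_stage$divergence
      report$outputs$consensus <- p("consensus.fa")
      report$consensus_length <- nchar(cons$consensus)

      gs <- run_stage("group_summary", function()
        group_summary(copies))
      write.table(gs$stats, p("group_summary.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      write_labeled_copies(copies, p("repeats_labeled.tsv"))
      report$outputs$group_summary <- p("group_summary.tsv")
      report$outputs$labeled_copies <- p("repeats_labeled.tsv")
      report$group_summary <- gs$stats
      report$t_length_p <- gs$t_length$p
      report$t_divergence_p <- gs$t_divergence$p
    }

    # enrichment -------------------------------------------------------
    if (isTRUE(cfg$stages$enrichment)) {
      enr <- run_stage("enrichment", function() {
        .log_stage("enrichment", "params",
                   N = cfg$enrichment$n_randomizations,
                   mode = cfg$enrichment$mode, seed = cfg$seed)
        run_enrichment_test(
          peak_union, ds$repeats, ds$layout,
          N = cfg$enrichment$n_randomizations,
          mode = cfg$enrichment$mode,
          min_overlap = cfg$enrichment$min_overlap, seed = cfg$seed)
      })
      write.table(as.data.frame(enr), p("enrichment.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      report$outputs$enrichment <- p("enrichment.tsv")
      report$enrichment <- as.data.frame(enr)
    }

    # signal aggregation ----------------------------------------------
    if (isTRUE(cfg$stages$signal)) {
      report$signal <- run_stage("signal", function() {
        ctl_name <- cfg$signal$control_track
        ctl <- ds$tracks[[ctl_name]]
        out <- list()
        for (nm in setdiff(names(ds$tracks), ctl_name)) {
          trk <- ds$tracks[[nm]]
          if (!is.null(ctl))
            trk <- fold_enrichment_track(trk, ctl,
                                         cfg$signal$pseudocount)
          m <- extract_signal_matrix(trk, ds$repeats,
                                     flank = cfg$signal$flank,
                                     bin_size = cfg$signal$bin_size,
                                     body_bins = cfg$signal$body_bins)
          prof <- trimmed_mean_profile(m, cfg$signal$trim_fraction)
          fm <- per_feature_mean(m)
          write_signal_matrix(m, p(paste0("matrix_", nm, ".tsv")))
          write.table(data.frame(bin = names(prof$profile),
                                 value = prof$profile),
                      p(paste0("profile_", nm, ".tsv")), sep = "\t",
                      quote = FALSE, row.names = FALSE)
          write.table(data.frame(feature = names(fm), mean = fm),
                      p(paste0("feature_mean_", nm, ".tsv")), sep = "\t",
                      quote = FALSE, row.names = FALSE)
          out[[nm]] <- list(profile_peak = max(prof$profile),
                            mean_of_feature_means = mean(fm))
        }
        out
      })
    }

    # occupancy --------------------------------------------------------
    if (isTRUE(cfg$stages$occupancy) &&
        length(ds$peaks$conditions) >= 2) {
      occ <- run_stage("occupancy", function() {
        cs <- ds$peaks$conditions
        occupancy_subsets(cs[[1L]], cs[[2L]],
                          min(cfg$occupancy$min_replicate_support,
                              lengths(cs)),
                          ds$layout)
      })
      for (nm in c("a_only", "b_only", "shared"))
        write_bed(occ[[nm]], p(paste0("occupancy_", nm, ".bed")))
      fr <- repeat_fraction_of_subsets(occ, ds$repeats)
      write.table(data.frame(subset = rownames(fr), fr), p("fractions.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      report$outputs$fractions <- p("fractions.tsv")
      report$occupancy <- data.frame(subset = rownames(fr), fr)
    }

    report$elapsed <- NULL
    jsonlite::write_json(report, p("report.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, force = TRUE)
    .log_stage("pipeline", "complete", out = out_dir)
    invisible(report)
  }, error = function(e) {
    file.create(p(paste0("FAILED_", stage)))
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

# Load a user dataset from config$input paths into the synthetic_dataset
# shape the pipeline stages consume.
.load_input_dataset <- function(input) {
  need <- c("chrom_sizes", "genome", "repeats")
  missing_keys <- setdiff(need, names(input))
  if (length(missing_keys))
    stop("input block missing: ", paste(missing_keys, collapse = ", "))
  layout <- read_chrom_sizes(input$chrom_sizes)
  genome <- readDNAStringSet(input$genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  repeats <- read_bed(input$repeats, layout)
  if (is.null(mcols(repeats)$class)) mcols(repeats)$class <- "repeat"
  peaks <- lapply(input$peaks, read_bed, layout = layout)
  tracks <- lapply(input$tracks, read_bedgraph, layout = layout)
  list(layout = layout, genome = genome, repeats = repeats,
       peaks = list(binding = peaks, conditions = list()),
       tracks = tracks, counts = NULL, truth = NULL, config = NULL)
}
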