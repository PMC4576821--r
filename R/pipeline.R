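pipeline_blocks <- c("seed", "out_dir", "stages", "inputs", "simulate",
                     "fit", "trajectory", "shells")

check_keys <- function(x, allowed, where) {
  extra <- setdiff(names(x), allowed)
  if (length(extra)) {
    stop("unknown ", where, " key(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
}

#' Run the full analysis pipeline
#'
#' Chains the stages `simulate` (synthetic campaign, traces and toy
#' structure), `fit` (model selection and phase fits on every trace),
#' `trajectory` (trade-off report) and `shells` (triad shell assignment
#' and enrichment) over a directory of inputs, writing per-stage plain-text
#' outputs plus a run manifest with parameters, seeds, package version and
#' file checksums. Re-running with an identical config reproduces
#' identical outputs (the manifest differs only in its timestamp). A stage
#' failure renames that stage's partial outputs to `*.partial` and aborts
#' with the stage named.
#'
#' @param config a named list, or the path of a YAML file holding one.
#'   Recognised top-level keys: `seed` (mandatory), `out_dir` (mandatory),
#'   `stages` (default all four), `inputs` (paths `traces`, `trajectory`,
#'   `pdb`, `mutations` — any omitted input is produced by the simulate
#'   stage), `simulate`, `fit`, `trajectory`, `shells` (per-stage parameter
#'   blocks). Unknown keys are rejected.
#' @return the manifest, invisibly (also written to
#'   `out_dir/manifest.json`)
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("config file not found: ", config,
                                   call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  check_keys(config, pipeline_blocks, "config")
  if (is.null(config$seed)) stop("config$seed is mandatory", call. = FALSE)
  if (is.null(config$out_dir)) stop("config$out_dir is mandatory",
                                    call. = FALSE)
  seed <- as.integer(config$seed)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- config$stages %||% c("simulate", "fit", "trajectory", "shells")
  inputs <- config$inputs %||% list()
  check_keys(inputs, c("traces", "trajectory", "pdb", "mutations"), "inputs")

  manifest <- list(package = "nucleoperm",
                   version = as.character(utils::packageVersion("nucleoperm")),
                   seed = seed, stages = stages,
                   config = config, outputs = list())
  stage_files <- character(0)
  run_stage <- function(name, fn) {
    stage_files <<- character(0)
    tryCatch(fn(), error = function(e) {
      for (f in stage_files) {
        if (file.exists(f)) file.rename(f, paste0(f, ".partial"))
      }
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  emit <- function(path) {
    stage_files <<- c(stage_files, path)
    path
  }

  paths <- list(traces = inputs$traces, trajectory = inputs$trajectory,
                pdb = inputs$pdb, mutations = inputs$mutations)
  sim_objects <- list()

  if ("simulate" %in% stages) {
    run_stage("simulate", function() {
      sim_cfg <- config$simulate %||% list()
      check_keys(sim_cfg, c("screen", "traces", "structure"), "simulate")
      scr_args <- sim_cfg$screen %||% list()
      scr_args$seed <- seed
      scr <- do.call(screen_config, scr_args)
      camp <- simulate_de(scr)
      sim_objects$campaign <<- camp
      if (is.null(paths$trajectory)) {
        paths$trajectory <<- emit(file.path(out_dir, "trajectory.csv"))
        write_trajectory(camp, paths$trajectory)
      }
      if (is.null(paths$traces)) {
        tr_cfg <- sim_cfg$traces %||% list()
        check_keys(tr_cfg, c("n_points", "t_max", "noise_sd"),
                   "simulate$traces")
        noise <- tr_cfg$noise_sd %||% 0.02
        npts <- tr_cfg$n_points %||% 60
        ends <- camp[c(1, nrow(camp)), ]
        traces <- lapply(seq_len(2), function(i) {
          kobs2 <- ends$ser_constant[i] * 1e-6  # at E0 = 1 uM
          tmax <- tr_cfg$t_max %||% min(4 / kobs2, 1e5)
          generate_trace(list(A1 = 0.4, kobs1 = 40 * kobs2,
                              A2 = 0.6, kobs2 = kobs2),
                         assay_conditions(1, 1), n_points = npts,
                         t_max = tmax, noise_sd = noise,
                         seed = seed + i,
                         variant_id = ends$variant_id[i])
        })
        paths$traces <<- emit(file.path(out_dir, "traces.csv"))
        write_traces(traces, paths$traces)
      }
      if (is.null(paths$pdb)) {
        st_cfg <- sim_cfg$structure %||% list()
        check_keys(st_cfg, c("shell_counts"), "simulate$structure")
        counts <- unlist(st_cfg$shell_counts %||%
                           c(first = 3, second = 12, third = 10, beyond = 20))
        ts <- toy_structure(3 + sum(counts), counts, seed = seed)
        sim_objects$toy <<- ts
        paths$pdb <<- emit(file.path(out_dir, "structure.pdb"))
        write_pdb(ts, paths$pdb)
      }
      if (is.null(paths$mutations)) {
        # synthetic mutated positions: second-shell heavy, as in a
        # triad-proximal adaptive campaign (9 second + 4 third shell)
        ts <- sim_objects$toy
        picks <- withr::with_seed(seed, c(
          sample(ts$residues$resno[ts$residues$shell == "second"], 9),
          sample(ts$residues$resno[ts$residues$shell == "third"], 4)))
        muts <- data.frame(position = picks, from_aa = "G", to_aa = "A",
                           round = "synthetic", kind = "point")
        paths$mutations <<- emit(file.path(out_dir,
                                           "structure_mutations.csv"))
        utils::write.csv(muts, paths$mutations, row.names = FALSE,
                         quote = FALSE)
      }
      invisible(NULL)
    })
  }

  fits <- NULL
  if ("fit" %in% stages) {
    run_stage("fit", function() {
      fit_cfg <- config$fit %||% list()
      check_keys(fit_cfg, c("model", "alpha", "n_starts", "e0_um"), "fit")
      if (is.null(paths$traces)) stop("no traces input", call. = FALSE)
      e0 <- fit_cfg$e0_um %||% 1
      traces <- read_traces(paths$traces, assay_conditions(E0 = e0, S0 = e0))
      model <- fit_cfg$model %||% "auto"
      n_starts <- fit_cfg$n_starts %||% 20
      fits <<- lapply(traces, function(tr) {
        if (model == "auto") {
          select_model(tr, alpha = fit_cfg$alpha %||% 0.05,
                       n_starts = n_starts, seed = seed)
        } else {
          fit_curve(tr, model, n_starts = n_starts, seed = seed)
        }
      })
      write_fits_json(fits, emit(file.path(out_dir, "fits.json")))
      invisible(NULL)
    })
  }

  if ("trajectory" %in% stages) {
    run_stage("trajectory", function() {
      tj_cfg <- config$trajectory %||% list()
      check_keys(tj_cfg, c("reference_round", "threshold"), "trajectory")
      tab <- if (!is.null(sim_objects$campaign)) {
        sim_objects$campaign
      } else {
        if (is.null(paths$trajectory)) stop("no trajectory input",
                                            call. = FALSE)
        read_trajectory(paths$trajectory)
      }
      rep <- tradeoff_report(tab,
                             reference_round = tj_cfg$reference_round %||% 0,
                             threshold = tj_cfg$threshold %||% 4)
      jsonlite::write_json(unclass(rep),
                           emit(file.path(out_dir, "trajectory_report.json")),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE,
                           dataframe = "columns")
      invisible(NULL)
    })
  }

  if ("shells" %in% stages) {
    run_stage("shells", function() {
      sh_cfg <- config$shells %||% list()
      check_keys(sh_cfg, c("triad", "chain", "target_shell",
                           "n_permutations"), "shells")
      if (is.null(paths$pdb)) stop("no structure input", call. = FALSE)
      if (is.null(paths$mutations)) stop("no mutations input", call. = FALSE)
      model <- parse_structure(paths$pdb)
      triad <- if (!is.null(sh_cfg$triad)) {
        triad_definition(sh_cfg$triad, model)
      } else if (!is.null(sim_objects$toy)) {
        triad_definition(sim_objects$toy$triad, model)
      } else {
        triad_definition(NULL, model)  # SITE-record fallback
      }
      chain <- sh_cfg$chain %||% model$atoms$chain[1]
      muts <- read_mutations(paths$mutations)
      st <- shell_table(model, triad, chain = chain)
      utils::write.csv(st, emit(file.path(out_dir, "shells.csv")),
                       row.names = FALSE, quote = FALSE)
      enr <- shell_enrichment(model, triad, muts,
                              target_shell = sh_cfg$target_shell %||%
                                "second",
                              chain = chain,
                              n_permutations = sh_cfg$n_permutations %||%
                                10000,
                              seed = seed)
      enr$shell_sizes <- as.list(enr$shell_sizes)
      jsonlite::write_json(unclass(enr),
                           emit(file.path(out_dir, "enrichment.json")),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      invisible(NULL)
    })
  }

  outputs <- Filter(function(p) !is.null(p) && file.exists(p),
                    c(paths, list(
                      fits = file.path(out_dir, "fits.json"),
                      trajectory_report = file.path(out_dir,
                                                    "trajectory_report.json"),
                      shells = file.path(out_dir, "shells.csv"),
                      enrichment = file.path(out_dir, "enrichment.json"))))
  manifest$outputs <- lapply(outputs, function(p) {
    list(path = p, md5 = unname(tools::md5sum(p)))
  })
  manifest$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", force = TRUE)
  invisible(manifest)
}
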