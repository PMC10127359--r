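# Project plumbing: run configuration, input validation, the staged pipeline
# (simulate -> derive -> signal -> fit), artifact manifest and logging. All
# randomness flows from the single run seed through per-stage substreams, so
# adding a stage never perturbs earlier stages' draws.

PIPELINE_STAGES <- c("simulate", "derive", "signal", "fit_general", "fit_relative")

#' Default pipeline configuration
#'
#' @return Named list with every recognised field: `stages`, `seed`,
#'   `horizon_h`, `unit_h`, `n_randomizations`, `reference_guild`,
#'   `reference_species`, `simulate` (species-parameter file, cohort sizes,
#'   measurement noise) and `inputs` (paths to existing `individuals.csv`,
#'   `weighings.csv`, Newick tree when the simulate stage is not run).
#' @export
default_run_config <- function() {
  list(
    stages = PIPELINE_STAGES,
    seed = 1,
    horizon_h = 96,
    unit_h = 0.5,
    n_randomizations = 999,
    reference_guild = "dweller",
    reference_species = NULL,
    simulate = list(
      species_params = NULL, # NULL -> demo table shipped with the package
      n_individuals = NULL, # NULL -> demo cohort sizes
      measurement_noise_sd_mg = 0.1
    ),
    inputs = list(individuals = NULL, weighings = NULL, tree = NULL)
  )
}

#' Load and validate a run configuration
#'
#' Reads a YAML file (or takes a list), fills unset fields from
#' [default_run_config()], and rejects unknown stages or fields before any
#' computation happens.
#'
#' @param config Path to a YAML file, or a named list.
#' @return Validated config list.
#' @export
run_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) abort(paste0("config file not found: ", config))
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  defaults <- default_run_config()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0) {
    abort(paste0("unknown config field(s): ", paste(unknown, collapse = ", ")))
  }
  cfg <- utils::modifyList(defaults, config)
  bad <- setdiff(cfg$stages, PIPELINE_STAGES)
  if (length(bad) > 0) {
    abort(paste0("unknown stage(s): ", paste(bad, collapse = ", ")))
  }
  check_scalar(cfg$seed, "seed", integer = TRUE)
  check_scalar(cfg$horizon_h, "horizon_h", lower = 0, strict = TRUE)
  check_scalar(cfg$n_randomizations, "n_randomizations", lower = 99, integer = TRUE)
  cfg
}

#' Cross-validate the raw input tables and tree
#'
#' Report-based validation (it never stops at the first problem): orphan
#' weighing rows, non-increasing timestamps, dead-before-alive sequences,
#' individuals with no weighings, and modelled species missing from the tree.
#'
#' @param individuals,weighings Input tables (see [derive_traits()]).
#' @param tree Optional `phylo` object for the comparative stage.
#' @return Tibble with columns `check`, `item`, `message`; zero rows means
#'   the inputs are clean.
#' @export
validate_inputs <- function(individuals, weighings, tree = NULL) {
  individuals <- tibble::as_tibble(individuals)
  weighings <- tibble::as_tibble(weighings)
  problems <- list()
  note <- function(check, item, msg) {
    problems[[length(problems) + 1]] <<- tibble::tibble(
      check = check, item = as.character(item), message = msg
    )
  }
  orphan <- which(!weighings$individual_id %in% individuals$individual_id)
  for (i in orphan) {
    note("orphan_weighing", paste0("row ", i), sprintf(
      "weighing row %d references unknown individual `%s`", i, weighings$individual_id[i]
    ))
  }
  for (id in unique(individuals$individual_id)) {
    w <- weighings[weighings$individual_id == id, ]
    if (nrow(w) == 0) {
      note("no_weighings", id, sprintf("individual `%s` has no weighings", id))
      next
    }
    if (any(diff(w$time_h) <= 0)) {
      note("timestamps", id, sprintf("individual `%s` has non-increasing timestamps", id))
    }
    alive <- as.logical(w$alive)
    if (!alive[1]) note("first_dead", id, sprintf("individual `%s` starts dead", id))
    if (any(diff(alive) > 0)) {
      note("revival", id, sprintf("individual `%s` returns to life", id))
    }
  }
  if (!is.null(tree)) {
    missing_sp <- setdiff(unique(individuals$species), tree$tip.label)
    for (sp in missing_sp) {
      note("species_not_in_tree", sp, sprintf("species `%s` is not a tip of the tree", sp))
    }
  }
  if (length(problems) == 0) {
    tibble::tibble(check = character(), item = character(), message = character())
  } else {
    dplyr::bind_rows(problems)
  }
}

write_tsv_text <- function(text, path) {
  writeLines(text, path)
  path
}

#' Run the full analysis pipeline
#'
#' Executes the requested stages in order -- simulate the assay (and a
#' pure-birth tree over the species when none is supplied), derive traits,
#' run the phylogenetic screen, fit the general-effects mixed model (with
#' fractional water content offered to the pruning step) and the
#' relative-effects model -- writing every artifact plus a manifest with
#' content hashes, a resolved copy of the configuration and a run log into
#' `out_dir`. A failing stage leaves the artifacts of completed stages
#' intact and reports which stage failed.
#'
#' @param config A [run_config()] list or YAML path.
#' @param out_dir Output directory (created if needed).
#' @param seed Optional override of the config seed.
#' @return Invisibly, a list with `manifest` (tibble: file, stage, md5) and
#'   the key in-memory results per stage.
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("aridtrait-run-"), seed = NULL) {
  cfg <- run_config(config)
  if (!is.null(seed)) cfg$seed <- seed
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(...))
    cat(line, "\n", file = log_path, append = TRUE, sep = "")
    message(line)
  }
  yaml::write_yaml(cfg, file.path(out_dir, "resolved_config.yaml"))
  artifacts <- tibble::tibble(file = "resolved_config.yaml", stage = "config")
  results <- list()
  state <- list(individuals = NULL, weighings = NULL, tree = NULL, traits = NULL)

  add_artifact <- function(file, stage) {
    artifacts <<- dplyr::bind_rows(artifacts, tibble::tibble(file = file, stage = stage))
  }

  load_inputs <- function() {
    if (is.null(state$individuals)) {
      ip <- cfg$inputs$individuals %||% file.path(out_dir, "individuals.csv")
      wp <- cfg$inputs$weighings %||% file.path(out_dir, "weighings.csv")
      for (p in c(ip, wp)) if (!file.exists(p)) abort(paste0("missing input file: ", p))
      state$individuals <<- tibble::as_tibble(read.csv(ip))
      state$weighings <<- tibble::as_tibble(read.csv(wp))
      state$weighings$alive <<- as.logical(state$weighings$alive)
    }
    if (is.null(state$tree)) {
      tp <- cfg$inputs$tree %||% file.path(out_dir, "tree.nwk")
      if (file.exists(tp)) state$tree <<- read_newick(file = tp)
    }
  }

  for (stage in cfg$stages) {
    logf("stage %s: start", stage)
    ok <- tryCatch(
      {
        switch(stage,
          simulate = {
            sp <- if (is.null(cfg$simulate$species_params)) {
              demo_species_params()
            } else {
              tibble::as_tibble(read.csv(cfg$simulate$species_params))
            }
            n_ind <- cfg$simulate$n_individuals %||%
              (if ("n_individuals" %in% names(sp)) sp$n_individuals else 10)
            acfg <- assay_config(
              sp, n_ind,
              horizon_h = cfg$horizon_h,
              measurement_noise_sd_mg = cfg$simulate$measurement_noise_sd_mg,
              seed = substream_seed(cfg$seed, "simulate")
            )
            sim <- simulate_assay(acfg)
            state$individuals <- sim$individuals
            state$weighings <- sim$weighings
            tree <- simulate_tree(nrow(sp), seed = substream_seed(cfg$seed, "tree"))
            tree$tip.label <- sp$species
            state$tree <- tree
            w_out <- dplyr::mutate(sim$weighings, alive = as.integer(.data$alive))
            write.csv(sim$individuals, file.path(out_dir, "individuals.csv"), row.names = FALSE)
            write.csv(w_out, file.path(out_dir, "weighings.csv"), row.names = FALSE)
            jsonlite::write_json(sim$ground_truth, file.path(out_dir, "ground_truth.json"),
              digits = NA, auto_unbox = TRUE
            )
            ape::write.tree(tree, file.path(out_dir, "tree.nwk"))
            for (f in c("individuals.csv", "weighings.csv", "ground_truth.json", "tree.nwk")) {
              add_artifact(f, stage)
            }
            results$simulate <- sim
          },
          derive = {
            load_inputs()
            report <- validate_inputs(state$individuals, state$weighings)
            if (nrow(report) > 0) {
              abort(paste0(
                "input validation failed:\n",
                paste(report$message, collapse = "\n")
              ))
            }
            traits <- derive_traits(state$individuals, state$weighings, horizon_h = cfg$horizon_h)
            state$traits <- traits
            write.csv(traits, file.path(out_dir, "traits.csv"), row.names = FALSE)
            write.csv(species_summary(traits), file.path(out_dir, "species_summary.csv"),
              row.names = FALSE
            )
            add_artifact("traits.csv", stage)
            add_artifact("species_summary.csv", stage)
            results$derive <- traits
          },
          signal = {
            load_inputs()
            if (is.null(state$tree)) abort("the signal stage needs a tree (simulate one or set inputs$tree)")
            if (is.null(state$traits)) {
              tp <- file.path(out_dir, "traits.csv")
              if (!file.exists(tp)) abort("run the derive stage (or provide traits.csv) before `signal`")
              state$traits <- tibble::as_tibble(read.csv(tp))
            }
            report <- validate_inputs(state$individuals, state$weighings, state$tree)
            if (any(report$check == "species_not_in_tree")) {
              abort(paste0(
                "signal stage refused: ",
                paste(report$message[report$check == "species_not_in_tree"], collapse = "; ")
              ))
            }
            summ <- species_summary(state$traits)
            summ$ns_code <- encode_nesting(summ$nesting_strategy)
            sp_traits <- dplyr::select(
              summ, "species",
              dr = "dr_mean", wlr = "wlr_mean", wlt = "wlt_mean",
              fwc = "fwc_mean", bm = "bm_mean", ns = "ns_code"
            )
            usable <- names(sp_traits)[-1][vapply(
              sp_traits[-1], function(x) all(is.finite(x)), logical(1)
            )]
            scr <- phylo_screen(sp_traits, state$tree,
              traits = usable,
              n_randomizations = cfg$n_randomizations,
              seed = substream_seed(cfg$seed, "signal")
            )
            scr$signal$note <- ifelse(scr$signal$trait == "ns",
              "ordinal coding dweller<tunneler<roller is an assumption", ""
            )
            write.table(scr$signal, file.path(out_dir, "signal.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE
            )
            write.table(scr$correlations, file.path(out_dir, "pic_correlations.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE
            )
            add_artifact("signal.tsv", stage)
            add_artifact("pic_correlations.tsv", stage)
            results$signal <- scr
          },
          fit_general = {
            load_inputs()
            if (is.null(state$traits)) {
              state$traits <- derive_traits(state$individuals, state$weighings, cfg$horizon_h)
            }
            design <- build_general_design(state$traits,
              horizon_h = cfg$horizon_h, unit_h = cfg$unit_h,
              reference_guild = cfg$reference_guild, include_fwc = TRUE
            )
            fit <- fit_glmm(design)
            fit <- prune_nonsignificant(fit, "fractional_water_content")
            write_tsv_text(fit_report(fit, format = "tsv"), file.path(out_dir, "general_fit.tsv"))
            add_artifact("general_fit.tsv", stage)
            results$fit_general <- fit
          },
          fit_relative = {
            load_inputs()
            if (is.null(state$traits)) {
              state$traits <- derive_traits(state$individuals, state$weighings, cfg$horizon_h)
            }
            design <- build_relative_design(state$traits,
              horizon_h = cfg$horizon_h, unit_h = cfg$unit_h,
              reference_species = cfg$reference_species
            )
            fit <- fit_glm(design)
            write_tsv_text(fit_report(fit, format = "tsv"), file.path(out_dir, "relative_fit.tsv"))
            add_artifact("relative_fit.tsv", stage)
            results$fit_relative <- fit
          }
        )
        TRUE
      },
      error = function(e) {
        logf("stage %s: FAILED (%s)", stage, conditionMessage(e))
        abort(sprintf("pipeline stage `%s` failed: %s", stage, conditionMessage(e)))
      }
    )
    logf("stage %s: done", stage)
  }

  meta <- list(
    seed = cfg$seed, horizon_h = cfg$horizon_h, unit_h = cfg$unit_h,
    trials_convention = sprintf(
      "desiccation resistance modelled as successes out of %d units of %g h",
      as.integer(round(cfg$horizon_h / cfg$unit_h)), cfg$unit_h
    ),
    pseudo_r2 = "squared Pearson correlation of observed vs fitted proportions",
    stages = cfg$stages
  )
  jsonlite::write_json(meta, file.path(out_dir, "fit_meta.json"), auto_unbox = TRUE)
  add_artifact("fit_meta.json", "meta")
  manifest <- dplyr::mutate(
    artifacts,
    md5 = unname(tools::md5sum(file.path(out_dir, .data$file)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"), auto_unbox = TRUE)
  logf("pipeline complete: %d artifacts", nrow(manifest))
  invisible(list(manifest = manifest, results = results, out_dir = out_dir))
}
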