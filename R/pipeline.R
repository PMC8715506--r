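#' Full analysis pipeline
#'
#' Orchestrates synth -> sample -> features -> dimred -> importance ->
#' network -> paths from a single configuration (an R list or a JSON
#' file), writing every stage's outputs plus a manifest with parameters,
#' seed and content hashes into a run directory. One top-level seed drives
#' every stochastic stage through per-stage derived streams, so re-running
#' an identical config reproduces identical outputs.
#'
#' @name pipeline
NULL

default_config <- function() {
  list(
    seed = 1,
    stages = c("synth", "sample", "features", "dimred", "importance", "network", "paths"),
    synth = list(
      n_residues = 30, n_frames = 300, n_communities = 2,
      discriminative_residues = c(5, 12, 19), shift = 3,
      path_residues = seq(2, 29, by = 3),
      rho_in = 0.5, rho_out = 0.05, rho_path = 0.9,
      sigma = 0.4, jitter_sd = 0.2, labels = c("unbound", "bound")
    ),
    # short segments in a slowly relaxing (high-friction) basin: the regime
    # where the center stops drifting while the swarm spread accumulates
    sample = list(
      n_replicas = 24, n_steps = 50, max_iterations = 8,
      barrier_height = 8, friction = 20, temperature = 1,
      minima = list(c(-2, 0), c(2, 0)), start = c(-2, 0.2), weight_law = "exp"
    ),
    features = list(transform = "inverse_closest_heavy", min_sep = 3),
    dimred = list(n_components = 4),
    importance = list(methods = c("kl", "mlp_lrp", "pca"), hidden = 64),
    # superpose = FALSE: synthetic frames share one global frame already;
    # set TRUE for real trajectories. ensemble = NULL analyses the first
    # (reference-state) ensemble.
    network = list(
      cutoff = 4.5, occupancy = 0.75, w_max = 20, ensemble = NULL,
      superpose = FALSE
    ),
    paths = list(source = NULL, sink = NULL, tolerance = 1)
  )
}

merge_config <- function(base, user) {
  for (key in names(user)) {
    if (is.list(base[[key]]) && is.list(user[[key]]) && !is.null(names(user[[key]]))) {
      base[[key]] <- merge_config(base[[key]], user[[key]])
    } else {
      base[[key]] <- user[[key]]
    }
  }
  base
}

#' Validate and normalise a pipeline configuration
#'
#' @param config An R list or path to a JSON config file. Unset keys take
#'   their defaults; `seed` is mandatory for any run containing a
#'   stochastic stage.
#' @return The merged configuration list.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) abort(sprintf("config file not found: %s", config))
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) abort("config must be a list or a JSON file path")
  cfg <- merge_config(default_config(), config)
  known <- default_config()$stages
  unknown <- setdiff(cfg$stages, known)
  if (length(unknown) > 0) {
    abort(paste0("unknown stage(s): ", paste(unknown, collapse = ", ")))
  }
  if (is.null(cfg$seed) || !is.finite(cfg$seed)) abort("config must set an integer seed")
  for (key in c("topology", "trajectories")) {
    paths <- unlist(cfg$input[[key]])
    if (length(paths) == 0) next
    missing <- paths[!file.exists(paths)]
    if (length(missing) > 0) {
      abort(paste0("config references missing file(s): ", paste(missing, collapse = ", ")))
    }
  }
  cfg
}

hash_files <- function(paths) {
  md5 <- tools::md5sum(paths)
  tibble(file = basename(paths), md5 = unname(md5))
}

#' Run the analysis pipeline
#'
#' @param config Configuration list or JSON path; see [validate_config()]
#'   and the package vignette for the keys each stage accepts.
#' @param out_dir Run directory (created if needed).
#' @return Invisibly, the manifest list (also written as
#'   `manifest.json` in `out_dir`).
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("allokit_run_")) {
  cfg <- validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(cfg$seed)
  files <- character(0)
  emit <- function(path) {
    files <<- c(files, path)
    path
  }
  state <- list()

  run_stage <- function(name, fun) {
    tryCatch(fun(), error = function(e) {
      abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  if ("synth" %in% cfg$stages) {
    run_stage("synth", function() {
      sp <- cfg$synth
      truth <- planted_truth(
        n_residues = sp$n_residues, n_communities = sp$n_communities,
        discriminative_residues = sp$discriminative_residues, shift = sp$shift,
        path_residues = sp$path_residues, seed = derive_seed(seed, "synth")
      )
      gen <- generate_two_state_ensembles(
        sp$n_residues, sp$n_frames, truth,
        rho_in = sp$rho_in, rho_out = sp$rho_out, rho_path = sp$rho_path,
        sigma = sp$sigma, jitter_sd = sp$jitter_sd, labels = sp$labels
      )
      state$model <<- gen$model
      state$ensembles <<- gen$ensembles
      state$truth <<- truth
      write_ensemble_pdb(gen$ensembles[[1]], gen$model, emit(file.path(out_dir, "ensemble_a.pdb")))
      write_ensemble_pdb(gen$ensembles[[2]], gen$model, emit(file.path(out_dir, "ensemble_b.pdb")))
      write_truth_tsv(truth, emit(file.path(out_dir, "truth.tsv")))
    })
  } else if (!is.null(cfg$input$topology)) {
    run_stage("load", function() {
      state$model <<- read_structure(cfg$input$topology, label_map = cfg$input$label_map)
      trajs <- cfg$input$trajectories
      state$ensembles <<- lapply(seq_along(trajs), function(i) {
        read_ensemble(trajs[[i]], state$model, names(trajs)[i] %||% paste0("class", i))
      })
    })
  }

  if ("sample" %in% cfg$stages) {
    run_stage("sample", function() {
      sp <- cfg$sample
      minima <- sp$minima
      if (is.matrix(minima)) minima <- asplit(minima, 1) # JSON round trip
      spec <- double_well_spec(
        minima = minima,
        barrier_height = sp$barrier_height, friction = sp$friction,
        temperature = sp$temperature
      )
      trace <- run_controller(
        make_langevin_backend(spec),
        start = sp$start, n_replicas = sp$n_replicas, n_steps = sp$n_steps,
        max_iter = sp$max_iterations, seed = derive_seed(seed, "sample"),
        law = sp$weight_law
      )
      state$trace <<- trace
      readr::write_csv(tidy(trace), emit(file.path(out_dir, "controller_trace.csv")))
    })
  }

  needs_fm <- any(c("features", "dimred", "importance") %in% cfg$stages)
  if (needs_fm) {
    if (is.null(state$ensembles)) abort("stage 'features' failed: no input ensembles (enable synth or provide input)")
    run_stage("features", function() {
      fp <- cfg$features
      state$fm <<- featurize(state$ensembles, state$model,
        transform = fp$transform, min_sep = fp$min_sep
      )
      if ("features" %in% cfg$stages) {
        write_feature_csv(
          state$fm,
          emit(file.path(out_dir, "features.csv")),
          emit(file.path(out_dir, "feature_descriptors.csv"))
        )
      }
    })
  }

  if ("dimred" %in% cfg$stages) {
    run_stage("dimred", function() {
      k <- min(
        cfg$dimred$n_components,
        nrow(state$fm$values) - 1, ncol(state$fm$values)
      )
      proj <- fit_pca(state$fm, n_components = k)
      state$pca <<- proj
      readr::write_csv(tidy(proj), emit(file.path(out_dir, "pca_embedding.csv")))
      sub <- min(nrow(state$fm$values), 200) # MDS is O(n^2) in frames
      mds <- fit_mds(state$fm$values[seq_len(sub), , drop = FALSE], n_components = 2)
      mds$labels <- state$fm$labels[seq_len(sub)]
      readr::write_csv(tidy(mds), emit(file.path(out_dir, "mds_embedding.csv")))
    })
  }

  if ("importance" %in% cfg$stages) {
    run_stage("importance", function() {
      profiles <- importance_profiles(
        state$ensembles, state$model,
        methods = cfg$importance$methods,
        hidden = cfg$importance$hidden,
        seed = derive_seed(seed, "importance")
      )
      state$profiles <<- profiles
      readr::write_csv(profiles, emit(file.path(out_dir, "importance.csv")))
      top <- profiles |> filter(.data$method == profiles$method[1])
      write_importance_pdb(state$model, top, emit(file.path(out_dir, "importance.pdb")))
    })
  }

  if (any(c("network", "paths") %in% cfg$stages)) {
    run_stage("network", function() {
      np <- cfg$network
      labels <- vapply(state$ensembles, function(e) e$class_label, character(1))
      which_e <- if (is.null(np$ensemble)) 1L else which(labels == np$ensemble)[1]
      if (is.na(which_e)) abort(sprintf("no ensemble labelled '%s'", np$ensemble))
      ens <- state$ensembles[[which_e]]
      edges <- contact_edges(ens, state$model, cutoff = np$cutoff, occupancy = np$occupancy)
      cmat <- correlation_matrix(ens, state$model, superpose = np$superpose)
      net <- build_network(edges, cmat, w_max = np$w_max)
      net <- girvan_newman(net)
      state$net <<- net
      readr::write_csv(tidy(net), emit(file.path(out_dir, "edges.csv")))
      readr::write_csv(net$communities, emit(file.path(out_dir, "communities.csv")))
    })
  }

  if ("paths" %in% cfg$stages) {
    run_stage("paths", function() {
      pp <- cfg$paths
      src <- pp$source %||% state$truth$path_residues[1]
      snk <- pp$sink %||% state$truth$path_residues[length(state$truth$path_residues)]
      if (is.null(src) || is.null(snk)) abort("paths stage needs source and sink residues")
      res <- suboptimal_paths(state$net, src, snk, tolerance = pp$tolerance)
      jsonlite::write_json(
        list(
          source = src, sink = snk, optimal = res$path, length = res$length,
          suboptimal = lapply(seq_len(nrow(res$suboptimal)), function(i) {
            list(path = res$suboptimal$path[[i]], length = res$suboptimal$length[i])
          })
        ),
        emit(file.path(out_dir, "paths.json")),
        auto_unbox = TRUE, digits = NA
      )
      state$paths <<- res
    })
  }

  manifest <- list(
    seed = seed,
    stages = cfg$stages,
    parameters = cfg[setdiff(names(cfg), c("seed", "stages"))],
    files = hash_files(files)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(c(manifest, list(out_dir = out_dir, state = state)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Plot microswitch distributions
#'
#' @param reports Tibble from [microswitches()] (bind rows over ensembles
#'   for a class comparison).
#' @return A ggplot of per-class densities, one panel per microswitch.
#' @export
plot_microswitches <- function(reports) {
  long <- tidyr::pivot_longer(reports, c("tm6_tm3", "yy", "npxxy_rmsd"),
    names_to = "microswitch", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$value, fill = .data$label)) +
    ggplot2::geom_density(alpha = 0.5) +
    ggplot2::facet_wrap(~microswitch, scales = "free") +
    ggplot2::labs(x = "value (Å)", y = "density", fill = "class") +
    ggplot2::theme_minimal()
}
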