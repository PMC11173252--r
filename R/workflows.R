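#' Experiment configuration
#'
#' Validated end-to-end configuration for [run_landscape()]: system choice,
#' simulation settings, training settings, evaluation settings and optional
#' reduction. Round-trips through YAML via [write_experiment_config()] /
#' [read_experiment_config()].
#'
#' @param system an `eprnet_system` or a config list accepted by
#'   [system_from_config()].
#' @param D noise strength.
#' @param simulate list: n_traj, t_final, dt, init, seed (passed to
#'   [simulate_ensemble()]); set `analytic = TRUE` to draw from the system's
#'   exact steady sampler instead.
#' @param train list merged into [training_config()] (lambda1, lambda2,
#'   enhancement, epochs, batch_size, lr, hidden, seed).
#' @param evaluate list: `reference` one of "fpe" (2D only), "analytic",
#'   "none"; `resolution`; `threshold` (relative energy cut, in units of D).
#' @param reduce optional list: z_indices, grid, and train settings for the
#'   reduced stage.
#' @param name run label.
#' @export
experiment_config <- function(system, D, simulate = list(), train = list(),
                              evaluate = list(reference = "none"),
                              reduce = NULL, name = "run") {
  if (!inherits(system, "eprnet_system")) {
    system <- system_from_config(system)
  }
  stopifnot(is.numeric(D), D > 0)
  sim <- utils::modifyList(list(n_traj = 10000L, t_final = 20, dt = 0.01,
                                init = "auto", seed = 1L, analytic = FALSE),
                           simulate)
  tr_args <- utils::modifyList(list(D = D), train)
  tcfg <- do.call(training_config, tr_args)
  ev <- utils::modifyList(list(reference = "none", resolution = 201L,
                               threshold = 20), evaluate)
  if (!ev$reference %in% c("fpe", "analytic", "none")) {
    stop("evaluate$reference must be one of 'fpe', 'analytic', 'none'")
  }
  if (ev$reference == "fpe" && system$dim != 2L) {
    stop("the finite-element reference is only available in 2D")
  }
  if (ev$reference == "analytic" && is.null(system$potential)) {
    stop("evaluate$reference = 'analytic' needs a system with a known potential")
  }
  if (!is.null(reduce)) {
    reduce$spec <- reduced_spec(reduce$z_indices,
                                reduce$reduced_domain %||% NULL,
                                reduce$grid %||% 64L)
  }
  structure(list(system = system, D = D, simulate = sim, train = tcfg,
                 evaluate = ev, reduce = reduce, name = name),
            class = "eprnet_experiment")
}

#' Write / read an experiment configuration as YAML
#'
#' Only serializable settings are stored; the system is stored as its
#' [system_from_config()] description, so custom in-memory systems must carry
#' `meta$config` to round-trip.
#'
#' @param config an `eprnet_experiment`.
#' @param path YAML file path.
#' @export
write_experiment_config <- function(config, path) {
  syscfg <- config$system$meta$config
  if (is.null(syscfg)) {
    stop("this system carries no serializable description (meta$config); ",
         "build it via system_from_config() to round-trip")
  }
  tr <- config$train
  out <- list(name = config$name, D = config$D, system = syscfg,
              simulate = config$simulate,
              train = tr[c("lambda1", "lambda2", "enhancement", "epochs",
                           "batch_size", "lr", "hidden", "seed",
                           "trace_every")],
              evaluate = config$evaluate)
  if (!is.null(config$reduce)) {
    rd <- config$reduce
    rd$spec <- NULL
    out$reduce <- rd
  }
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_experiment_config
#' @export
read_experiment_config <- function(path) {
  raw <- yaml::read_yaml(path)
  experiment_config(system = raw$system, D = raw$D,
                    simulate = raw$simulate %||% list(),
                    train = raw$train %||% list(),
                    evaluate = raw$evaluate %||% list(reference = "none"),
                    reduce = raw$reduce, name = raw$name %||% "run")
}

stage <- function(label, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", label, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run a full landscape-construction experiment
#'
#' Simulate steady samples, build the enhanced set when the configuration asks
#' for one, train the potential, evaluate against the configured reference and
#' optionally train a reduced 2D landscape. All artifacts are written into
#' `out_dir`: `config.yaml` (when serializable), `samples.csv`,
#' `model.json`, `trace.csv`, `metrics.json` and, when reduction is on,
#' `reduced_model.json` and `reduced_grid.csv`. Outputs contain no timestamps,
#' so a rerun with the same configuration is byte-identical.
#'
#' @param config an `eprnet_experiment`.
#' @param out_dir run directory (created if missing).
#' @return list with the fit, metrics, samples and paths (invisibly the same
#'   data is on disk).
#' @export
run_landscape <- function(config, out_dir) {
  if (!inherits(config, "eprnet_experiment")) stop("need an eprnet_experiment")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  system <- config$system
  sim <- config$simulate

  samples <- stage("simulate", {
    if (isTRUE(sim$analytic)) {
      analytic_samples(system, sim$n_traj, config$D, seed = sim$seed)
    } else {
      simulate_ensemble(system, config$D, n_traj = sim$n_traj,
                        t_final = sim$t_final, dt = sim$dt, init = sim$init,
                        seed = sim$seed)
    }
  })
  write_samples(samples, file.path(out_dir, "samples.csv"))

  fit <- stage("train", train_potential(system, samples, NULL, config$train))
  save_model(fit$model, file.path(out_dir, "model.json"))
  utils::write.csv(fit$trace, file.path(out_dir, "trace.csv"),
                   row.names = FALSE)

  metrics <- list(method = fit$method,
                  final_epr_loss = fit$trace$epr[nrow(fit$trace)],
                  final_hjb_loss = fit$trace$hjb[nrow(fit$trace)],
                  epr_estimate = estimate_epr(fit$model, samples, system))
  ev <- config$evaluate
  metrics <- c(metrics, stage("evaluate", {
    if (ev$reference == "none") {
      list()
    } else {
      # unbounded systems: evaluation box from the sample range, 20% padded
      dom <- system$domain
      if (is.null(dom)) {
        Xs <- states_of(samples)
        rg <- t(apply(Xs, 2L, range))
        pad <- 0.2 * (rg[, 2] - rg[, 1])
        dom <- cbind(rg[, 1] - pad, rg[, 2] + pad)
      }
      ref <- if (ev$reference == "fpe") {
        solve_fpe_reference_2d(system, config$D, resolution = ev$resolution,
                               domain = dom)
      } else if (system$dim == 2L) {
        reference_from_potential(system$potential, dom, config$D,
                                 resolution = ev$resolution)
      } else {
        system$potential # sample-based comparison in high dimension
      }
      pts <- if (system$dim > 2L) states_of(samples) else NULL
      list(rrmse = rrmse(fit$model, ref, D = config$D, eval_points = pts,
                         threshold = ev$threshold),
           rmae = rmae(fit$model, ref, D = config$D, eval_points = pts,
                       threshold = ev$threshold))
    }
  }))

  reduced <- NULL
  if (!is.null(config$reduce)) {
    reduced <- stage("reduce", {
      rd <- config$reduce
      rtrain <- utils::modifyList(list(D = config$D), rd$train %||% list())
      rcfg <- do.call(training_config, rtrain)
      rfit <- train_reduced_potential(system, samples, rd$spec, rcfg)
      save_model(rfit$model, file.path(out_dir, "reduced_model.json"))
      spec2 <- rd$spec
      if (is.null(spec2$reduced_domain)) {
        Z <- states_of(samples)[, spec2$z_indices, drop = FALSE]
        spec2$reduced_domain <- rbind(range(Z[, 1]), range(Z[, 2]))
      }
      g1 <- seq(spec2$reduced_domain[1, 1], spec2$reduced_domain[1, 2],
                length.out = spec2$grid)
      g2 <- seq(spec2$reduced_domain[2, 1], spec2$reduced_domain[2, 2],
                length.out = spec2$grid)
      Zg <- as.matrix(expand.grid(g1, g2))
      Ug <- matrix(potential_value(rfit$model, Zg), length(g1), length(g2))
      rref <- reference_solution(g1, g2, Ug, config$D, "reduced-fit")
      write_reduced_grid(rref, file.path(out_dir, "reduced_grid.csv"))
      rfit
    })
  }

  jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  cfg_path <- file.path(out_dir, "config.yaml")
  if (!is.null(system$meta$config)) {
    tryCatch(write_experiment_config(config, cfg_path),
             error = function(e) NULL)
  }
  list(fit = fit, metrics = metrics, samples = samples, reduced = reduced,
       out_dir = out_dir)
}

#' Benchmark a set of experiments across seeds
#'
#' Runs each named experiment at every seed and tabulates the requested metrics
#' as mean and standard deviation across seeds; cells that error are reported
#' as NA with the message collected in `failures`.
#'
#' @param configs named list of `eprnet_experiment` objects.
#' @param seeds integer vector of at least 2 seeds.
#' @param out_dir parent directory for the run directories.
#' @param metrics which metric names to tabulate.
#' @return data.frame with columns experiment, metric, mean, sd, n; attribute
#'   `failures` lists failed cells.
#' @export
run_benchmark_table <- function(configs, seeds, out_dir,
                                metrics = c("rrmse", "rmae")) {
  if (length(seeds) < 2L) stop("benchmarking needs at least 2 seeds")
  if (is.null(names(configs)) || any(names(configs) == "")) {
    stop("configs must be a named list")
  }
  failures <- list()
  vals <- list()
  for (nm in names(configs)) {
    for (sd in seeds) {
      cfg <- configs[[nm]]
      cfg$simulate$seed <- as.integer(sd)
      cfg$train$seed <- as.integer(sd)
      res <- tryCatch(
        run_landscape(cfg, file.path(out_dir, paste0(nm, "_seed", sd))),
        error = function(e) e)
      if (inherits(res, "error")) {
        failures[[paste0(nm, "/seed", sd)]] <- conditionMessage(res)
        next
      }
      for (m in metrics) {
        v <- res$metrics[[m]]
        vals[[length(vals) + 1L]] <- data.frame(
          experiment = nm, metric = m, seed = sd,
          value = if (is.null(v)) NA_real_ else v)
      }
    }
  }
  long <- do.call(rbind, vals)
  agg <- do.call(rbind, lapply(split(long, list(long$experiment, long$metric),
                                     drop = TRUE), function(d) {
    data.frame(experiment = d$experiment[1], metric = d$metric[1],
               mean = mean(d$value, na.rm = TRUE),
               sd = stats::sd(d$value, na.rm = TRUE),
               n = sum(is.finite(d$value)))
  }))
  rownames(agg) <- NULL
  utils::write.csv(agg, file.path(out_dir, "benchmark.csv"), row.names = FALSE)
  attr(agg, "failures") <- failures
  agg
}
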