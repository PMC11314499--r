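STAGE_ORDER <- c("simulate", "tica", "cluster", "msm", "tpt", "energy")

config_hash <- function(x) {
  # stable content hash of a config subtree via its canonical JSON
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA), f)
  unname(tools::md5sum(f))
}

#' Validate a pipeline run configuration
#'
#' Checks stage names and per-stage required parameters before anything
#' runs, reporting every violation at once.
#'
#' @param config a named list (see [run_pipeline()]) or a YAML file path.
#' @return The normalized config list, invisibly; errors on violations.
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  problems <- character(0)
  if (is.null(config$seed)) problems <- c(problems, "missing global 'seed'")
  if (is.null(config$out_dir)) problems <- c(problems, "missing 'out_dir'")
  if (is.null(config$frame_interval)) config$frame_interval <- 1
  st <- config$stages
  if (is.null(st) || length(st) == 0) {
    problems <- c(problems, "no stages configured")
  } else {
    bad <- setdiff(names(st), STAGE_ORDER)
    if (length(bad) > 0)
      problems <- c(problems, paste0("unknown stage(s): ",
                                     paste(bad, collapse = ", ")))
    req <- list(simulate = "n_steps", cluster = "k", msm = "lags",
                tpt = c("source", "sink"),
                energy = c("n_receptor", "n_ligand"))
    for (s in intersect(names(st), names(req))) {
      miss <- setdiff(req[[s]], names(st[[s]]))
      if (s == "cluster" && "k_grid" %in% names(st[[s]])) miss <- setdiff(miss, "k")
      if (length(miss) > 0)
        problems <- c(problems, sprintf("stage '%s': missing parameter(s) %s",
                                        s, paste(miss, collapse = ", ")))
    }
  }
  if (length(problems) > 0)
    stop("invalid configuration:\n  - ",
         paste(problems, collapse = "\n  - "))
  invisible(config)
}

#' Demo configuration: double-well kinetics end to end
#'
#' Brownian dynamics on a symmetric 1D double well, TICA on the
#' coordinate plus noise features, 2-state k-means discretization, MSM
#' estimation with CK validation, and TPT from the left to the right
#' well. A small toy complex provides the optional energy stage.
#'
#' @param seed global seed.
#' @param out_dir output directory.
#' @param n_steps trajectory length (default 2e6, enough well hops for
#'   ~1% population accuracy).
#' @param with_energy include the MM-GBSA/SIE stage (default TRUE).
#' @return A config list for [run_pipeline()].
#' @export
demo_config <- function(seed = 1L, out_dir = tempfile("allokin_run_"),
                        n_steps = 2000000L, with_energy = TRUE) {
  stages <- list(
    simulate = list(kind = "double_well", n_steps = n_steps, dt = 5e-3,
                    centers = c(-1, 1), barrier = 1.5, n_noise_features = 4),
    tica = list(lag = 10, ridge = 1e-8),
    cluster = list(k = 10, restarts = 10, fit_stride = 10),
    msm = list(lags = c(10, 20, 50, 100, 200), ck_k = c(2, 3),
               reversible = TRUE, macrostates = 2),
    tpt = list(source = 1, sink = 2))
  if (with_energy)
    stages$energy <- list(n_receptor = 12, n_ligand = 4, snapshots = 5,
                          method = "both")
  list(seed = as.integer(seed), out_dir = out_dir, frame_interval = 0.001,
       stages = stages)
}

run_stage_cached <- function(name, out_dir, cfg_piece, upstream_hash, fun) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  state_file <- file.path(out_dir, paste0("stage_", name, ".rds"))
  h <- config_hash(list(cfg = cfg_piece, upstream = upstream_hash))
  if (file.exists(state_file)) {
    cached <- readRDS(state_file)
    if (identical(cached$hash, h)) {
      message(sprintf("[%s] up to date, skipping", name))
      return(cached)
    }
  }
  t0 <- Sys.time()
  res <- fun()
  res$hash <- h
  res$wall_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  saveRDS(res, state_file)
  message(sprintf("[%s] done in %.1f s", name, res$wall_s))
  res
}

#' Run the configured analysis pipeline
#'
#' Executes the configured stages in dependency order
#' (simulate -> tica -> cluster -> msm -> tpt; energy independently on a
#' toy complex), writing tables under `out_dir` together with a manifest
#' of output checksums and a one-page text summary. Stages are cached:
#' re-running with an unchanged config and seed skips stages whose
#' inputs are unchanged, and deleting one stage's state recomputes only
#' that stage. Any stage failure aborts with the stage name and leaves a
#' FAILED marker next to the partial outputs.
#'
#' @param config list or YAML path; see [demo_config()] for the shape.
#' @return Object of class `report_bundle`: stage results, `files`,
#'   `manifest` (data frame of file checksums), `summary` (character).
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  st <- config$stages
  seed <- config$seed
  fi <- config$frame_interval
  bundle <- list(config = config, files = character(0))
  fail <- function(stage, e) {
    writeLines(c(stage, conditionMessage(e)), file.path(out, "FAILED"))
    stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  }
  prev_hash <- config_hash(list(seed = seed, frame_interval = fi))

  if ("simulate" %in% names(st)) {
    p <- st$simulate
    res <- tryCatch(run_stage_cached("simulate", out, p, prev_hash, function() {
      spec <- potential_spec(1L, as.list(p$centers %||% c(-1, 1)),
                             barrier_heights = p$barrier %||% 3)
      ct <- simulate_brownian(spec, p$n_steps, dt = p$dt %||% 1e-3,
                              seed = split_seed(seed, 1L))
      nn <- p$n_noise_features %||% 0
      feats <- ct$frames
      if (nn > 0) {
        set.seed(split_seed(seed, 2L))
        feats <- cbind(feats, matrix(stats::rnorm(nrow(feats) * nn),
                                     ncol = nn))
      }
      f <- file.path(out, "trajectory.txt")
      utils::write.table(round(ct$frames, 6), f, row.names = FALSE,
                         col.names = FALSE)
      list(ctraj = ct, features = feats, wells = assign_wells(ct),
           files = f)
    }), error = function(e) fail("simulate", e))
    bundle$simulate <- res
    prev_hash <- res$hash
  }

  if ("tica" %in% names(st)) {
    p <- st$tica
    res <- tryCatch(run_stage_cached("tica", out, p, prev_hash, function() {
      fmx <- feature_matrix(bundle$simulate$features, frame_interval = fi)
      mod <- estimate_tica(fmx, lag = p$lag %||% 1L, ridge = p$ridge %||% 0)
      Y <- tica_project(mod, fmx, dim = max(mod$dim, 1L))
      f <- file.path(out, "tica_eigenvalues.csv")
      utils::write.csv(data.frame(component = seq_along(mod$eigenvalues),
                                  eigenvalue = mod$eigenvalues),
                       f, row.names = FALSE)
      list(model = mod, Y = Y, files = f)
    }), error = function(e) fail("tica", e))
    bundle$tica <- res
    prev_hash <- res$hash
  }

  if ("cluster" %in% names(st)) {
    p <- st$cluster
    res <- tryCatch(run_stage_cached("cluster", out, p, prev_hash, function() {
      Y <- if (!is.null(bundle$tica)) bundle$tica$Y
           else bundle$simulate$features
      # centers are fit on a strided subset (cheap, statistically
      # equivalent for dense trajectories); every frame is then assigned
      stride <- p$fit_stride %||% 1L
      Yfit <- Y[seq(1, nrow(Y), by = stride), , drop = FALSE]
      if (!is.null(p$k_grid)) {
        sel <- select_k(Yfit, p$k_grid, n_restarts = p$restarts %||% 10L,
                        seed = split_seed(seed, 3L))
        k <- sel$k
      } else {
        sel <- NULL
        k <- p$k
      }
      cm <- cluster_kmeans(Yfit, k, n_restarts = p$restarts %||% 10L,
                           seed = split_seed(seed, 4L))
      dtraj <- assign_clusters(cm, Y)
      f1 <- file.path(out, "cluster_centers.csv")
      utils::write.csv(as.data.frame(cm$centers), f1, row.names = FALSE)
      f2 <- file.path(out, "dtraj.txt")
      utils::write.table(dtraj, f2, row.names = FALSE, col.names = FALSE)
      list(model = cm, dtraj = dtraj, k_selection = sel, files = c(f1, f2))
    }), error = function(e) fail("cluster", e))
    bundle$cluster <- res
    prev_hash <- res$hash
  }

  if ("msm" %in% names(st)) {
    p <- st$msm
    res <- tryCatch(run_stage_cached("msm", out, p, prev_hash, function() {
      dtraj <- bundle$cluster$dtraj
      lags <- as.integer(p$lags)
      its <- implied_timescales(dtraj, lags, frame_interval = fi,
                                reversible = p$reversible %||% TRUE)
      lag <- tryCatch(select_markov_time(its), error = function(e) lags[1])
      model <- estimate_msm(count_matrix(dtraj, lag),
                            reversible = p$reversible %||% TRUE,
                            lag = lag, frame_interval = fi)
      ck <- ck_test(dtraj, lag, k_values = p$ck_k %||% c(2L, 3L),
                    reversible = p$reversible %||% TRUE)
      map <- NULL
      if (!is.null(p$macrostates) && p$macrostates < nrow(model$P))
        map <- coarse_grain(model, p$macrostates,
                            seed = split_seed(seed, 5L))
      f1 <- file.path(out, "transition_matrix.csv")
      utils::write.csv(as.data.frame(model$P), f1, row.names = FALSE)
      f2 <- file.path(out, "implied_timescales.csv")
      utils::write.csv(its, f2, row.names = FALSE)
      f3 <- file.path(out, "ck_test.csv")
      utils::write.csv(ck$deviations, f3, row.names = FALSE)
      list(model = model, its = its, markov_lag = lag, ck = ck,
           macro = map, files = c(f1, f2, f3))
    }), error = function(e) fail("msm", e))
    bundle$msm <- res
    prev_hash <- res$hash
  }

  if ("tpt" %in% names(st)) {
    p <- st$tpt
    res <- tryCatch(run_stage_cached("tpt", out, p, prev_hash, function() {
      model <- bundle$msm$model
      map <- bundle$msm$macro
      # endpoints given as macrostates when a coarse-graining exists,
      # else as microstate indices
      to_set <- function(x) {
        if (!is.null(map)) which(map$assignment %in% x) else as.integer(x)
      }
      A <- to_set(p$source); B <- to_set(p$sink)
      fx <- flux_matrix(model, A, B)
      pw <- decompose_pathways(fx, min_fraction = p$min_fraction %||% 0.01)
      labels <- if (!is.null(map)) {
        lab <- character(nrow(model$P))
        for (m in seq_len(map$n_macrostates)) {
          mem <- which(map$assignment == m)
          base <- if (m %in% p$source) "SA" else if (m %in% p$sink) "SB"
                  else paste0("S", m)
          lab[mem] <- if (length(mem) == 1) base
                      else paste0(base, ".", seq_along(mem))
        }
        lab
      } else paste0("S", seq_len(nrow(model$P)))
      tab <- pathway_report(pw, labels)
      f <- file.path(out, "pathways.tsv")
      write_pathway_table(tab, f)
      list(flux = fx, pathways = pw, table = tab, files = f)
    }), error = function(e) fail("tpt", e))
    bundle$tpt <- res
    prev_hash <- res$hash
  }

  if ("energy" %in% names(st)) {
    p <- st$energy
    res <- tryCatch(run_stage_cached("energy", out, p, prev_hash, function() {
      sys <- make_toy_complex(p$n_receptor, p$n_ligand,
                              seed = split_seed(seed, 6L))
      # small rigid-jitter pseudo-trajectory of the complex
      set.seed(split_seed(seed, 8L))
      ns <- p$snapshots %||% 5L
      frames <- lapply(seq_len(ns), function(i)
        sys$coords + matrix(stats::rnorm(length(sys$coords), sd = 0.05),
                            ncol = 3))
      trj <- trajectory(frames, topology = sys, frame_interval = fi)
      gb <- mmgbsa(trj, sys, n_snapshots = ns,
                   n_sphere_points = p$n_sphere_points %||% 480L)
      se <- sie_from_system(sys, n_sphere_points = p$n_sphere_points %||% 480L)
      f <- file.path(out, "energy_terms.tsv")
      utils::write.table(
        data.frame(term = names(gb$terms), average = unname(gb$terms),
                   sd = c(unname(gb$sd), NA)),
        f, sep = "\t", quote = FALSE, row.names = FALSE)
      list(system = sys, mmgbsa = gb, sie = se, files = f)
    }), error = function(e) fail("energy", e))
    bundle$energy <- res
    prev_hash <- res$hash
  }

  bundle$files <- unlist(lapply(bundle[STAGE_ORDER], function(s) s$files))
  sums <- tools::md5sum(bundle$files)
  bundle$manifest <- data.frame(file = basename(names(sums)),
                                md5 = unname(sums), row.names = NULL)
  utils::write.csv(bundle$manifest, file.path(out, "manifest.csv"),
                   row.names = FALSE)
  class(bundle) <- "report_bundle"
  bundle$summary <- summarize_bundle(bundle)
  writeLines(bundle$summary, file.path(out, "summary.txt"))
  bundle
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' One-page text summary of a pipeline run
#'
#' Reports the macrostate count and populations, the selected Markov
#' time, the Chapman--Kolmogorov verdict at the 5% threshold, the top
#' transition pathways and the energy table. Stages that were not
#' configured are reported as "not run".
#'
#' @param bundle a [run_pipeline()] result.
#' @return Character vector of summary lines.
#' @export
summarize_bundle <- function(bundle) {
  lines <- c("== allokin pipeline summary ==",
             sprintf("seed: %d", bundle$config$seed))
  if (!is.null(bundle$msm)) {
    m <- bundle$msm
    lines <- c(lines,
               sprintf("Markov time: %d frames (%.3g ns)", m$markov_lag,
                       m$markov_lag * bundle$config$frame_interval),
               sprintf("CK test: %s (threshold %.0f%%; max deviation %.3f)",
                       if (m$ck$pass) "PASS" else "FAIL",
                       100 * m$ck$threshold, max(m$ck$deviations$deviation)))
    if (!is.null(m$macro)) {
      lines <- c(lines,
                 sprintf("macrostates: %d, populations: %s",
                         m$macro$n_macrostates,
                         paste(sprintf("%.3f", m$macro$populations),
                               collapse = ", ")))
    }
  } else lines <- c(lines, "MSM: not run")
  if (!is.null(bundle$tpt)) {
    tab <- bundle$tpt$table
    lines <- c(lines, "top pathways:",
               utils::capture.output(print(tab, row.names = FALSE)))
  } else lines <- c(lines, "TPT: not run")
  if (!is.null(bundle$energy)) {
    gb <- bundle$energy$mmgbsa
    lines <- c(lines,
               sprintf("MM-GBSA dGbind = %.2f kcal/mol (entropy: %s)",
                       gb$dGbind, gb$entropy_label),
               sprintf("SIE dGbind = %.2f kcal/mol", bundle$energy$sie$dGbind))
  } else lines <- c(lines, "energy: not run")
  lines
}
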