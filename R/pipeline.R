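# Pipeline configuration, stage runner, artifact manifest.

pkg_version <- function() as.character(utils::packageVersion("recruitkin"))

# CSV with a one-line header comment carrying the tool version and the
# config hash; read back with read_csv_c().
write_csv_c <- function(df, path, config_hash = "none") {
  con <- file(path, "w")
  writeLines(sprintf("# recruitkin %s config=%s", pkg_version(), config_hash),
             con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, qmethod = "double")
  close(con)
  invisible(path)
}

#' Read a pipeline CSV artifact
#'
#' Reads a CSV written by the pipeline, skipping the `#` header comment.
#'
#' @param path CSV file path.
#' @return a data.frame.
#' @export
read_csv_c <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

known_keys <- function(what) {
  switch(what,
    top = c("stages", "out_dir", "seed", "simulate", "measure", "kinetics",
            "foci", "survival"),
    simulate = c("conditions", names(formals(stripe_sim_config))),
    measure = c("track", "search", "stacks", "rois"),
    kinetics = c("pre_frame", "var_equal", "measurements"),
    foci = c("n_experiments", "conditions",
             names(formals(simulate_foci_stack)),
             "threshold", "rel_thresh", "detect_min_sep"),
    survival = c("conditions", "dispersion", "table",
                 names(formals(simulate_survival_counts))))
}

check_keys <- function(cfg, what) {
  unknown <- setdiff(names(cfg), known_keys(what))
  if (length(unknown) > 0L)
    stopf("unknown %s config key(s): %s", what, paste(unknown, collapse = ", "))
  cfg
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order — `simulate` (stripe
#' movies per condition: TIFF + ROI JSON + ground-truth CSV), `measure`
#' (TIFF + ROIs to measurement CSV), `kinetics` (per-cell curves,
#' normalized aggregate, condition comparison, plot), `foci` (simulated
#' z-stacks, detection, burden summary) and `survival` (colony tables to
#' surviving-fraction curve) — and writes a JSON manifest listing every
#' artifact with its MD5 hash plus the config snapshot. A stage failure
#' aborts with an error naming the stage.
#'
#' @param config a config list or a path to a JSON config file. Top-level
#'   keys: `stages` (character vector), `out_dir`, `seed`, and one list
#'   per stage with its parameters (unknown keys are rejected).
#'   `simulate$conditions` is a named list of [stripe_sim_config()]
#'   overrides per condition.
#' @param out_dir output directory (overrides the config).
#' @param seed master seed (overrides the config).
#' @return invisibly, the manifest list (element `files` maps artifact
#'   names to paths and MD5 hashes).
#' @export
run_pipeline <- function(config = list(), out_dir = NULL, seed = NULL) {
  if (is.character(config)) config <- jsonlite::fromJSON(config,
                                                         simplifyDataFrame = FALSE)
  check_keys(config, "top")
  stages <- config$stages %||% "demo"
  if (identical(stages, "demo") || "demo" %in% stages)
    stages <- c("simulate", "measure", "kinetics")
  out_dir <- out_dir %||% config$out_dir %||% stopf("out_dir is required")
  seed <- as.integer(seed %||% config$seed %||% 1L)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_hash <- substr(tools::md5sum(
    textConnection_write(jsonlite::toJSON(config, auto_unbox = TRUE),
                         file.path(out_dir, "config_snapshot.json"))), 1, 8)

  log_path <- file.path(out_dir, "run.log")
  logf <- function(fmt, ...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(fmt, ...))
    message(line)
    cat(line, "\n", file = log_path, append = TRUE)
  }
  artifacts <- character(0)
  add <- function(path) artifacts <<- c(artifacts, path)
  run_stage <- function(name, expr) {
    t0 <- Sys.time()
    logf("stage %s: start (seed %d)", name, seed)
    ok <- tryCatch({ expr; TRUE }, error = function(e) {
      stopf("stage '%s' failed: %s", name, conditionMessage(e))
    })
    logf("stage %s: done in %.1fs", name,
         as.numeric(difftime(Sys.time(), t0, units = "secs")))
  }

  sims <- list()
  if ("simulate" %in% stages) run_stage("simulate", {
    sc <- check_keys(config$simulate %||% list(), "simulate")
    conds <- sc$conditions %||% list(control = list())
    base <- sc[setdiff(names(sc), "conditions")]
    for (i in seq_along(conds)) {
      cname <- names(conds)[i]
      args <- utils::modifyList(base, conds[[i]])
      args$seed <- subseed(seed, 10L, i)
      cfg <- do.call(stripe_sim_config, args)
      sim <- simulate_stripe_movie(cfg)
      sims[[cname]] <- sim
      p_tif <- file.path(out_dir, paste0("stack_", cname, ".tif"))
      p_roi <- file.path(out_dir, paste0("rois_", cname, ".json"))
      p_gt <- file.path(out_dir, paste0("truth_", cname, ".csv"))
      write_tiff(sim$stack, p_tif); add(p_tif)
      write_roi_json(sim$rois, p_roi); add(p_roi)
      write_csv_c(sim$truth$true_means, p_gt, cfg_hash); add(p_gt)
    }
  })

  meas <- list()
  if ("measure" %in% stages) run_stage("measure", {
    mc <- check_keys(config$measure %||% list(), "measure")
    inputs <- if (length(sims) > 0) {
      lapply(sims, function(s) list(stack = s$stack, rois = s$rois))
    } else {
      stacks <- mc$stacks %||% stopf("measure needs simulated input or 'stacks' paths")
      rois <- mc$rois %||% stopf("measure needs 'rois' paths")
      stats::setNames(lapply(seq_along(stacks), function(i)
        list(stack = read_tiff(stacks[[i]]), rois = read_roi_json(rois[[i]]))),
        names(stacks) %||% sprintf("condition%d", seq_along(stacks)))
    }
    for (cname in names(inputs)) {
      inp <- inputs[[cname]]
      rois <- inp$rois
      if (!is.null(mc$track) && !identical(mc$track, "provided")) {
        rois1 <- roi_set(cells = lapply(rois$cells, function(cf) cf[1]),
                         background = rois$background[1], validate = FALSE)
        rois <- track_rois(inp$stack, rois1, method = mc$track,
                           search = mc$search %||% 8L)
      }
      m <- measure_rois(inp$stack, rois)
      meas[[cname]] <- m
      p <- file.path(out_dir, paste0("measurements_", cname, ".csv"))
      write_csv_c(m, p, cfg_hash); add(p)
    }
  })

  if ("kinetics" %in% stages) run_stage("kinetics", {
    kc <- check_keys(config$kinetics %||% list(), "kinetics")
    if (length(meas) == 0L) {
      paths <- kc$measurements %||% stopf("kinetics needs measurements")
      meas <- stats::setNames(lapply(paths, read_csv_c),
                              names(paths) %||% sprintf("condition%d", seq_along(paths)))
    }
    curves <- list(); aggs <- list()
    for (cname in names(meas)) {
      cu <- sx_curves(meas[[cname]])
      curves[[cname]] <- cu
      agg <- normalize_to_t0(aggregate_curves(cu, condition = cname,
                                              pre_frame = kc$pre_frame %||% 1L))
      aggs[[cname]] <- agg
      p1 <- file.path(out_dir, paste0("curves_", cname, ".csv"))
      write_csv_c(cu, p1, cfg_hash); add(p1)
      p2 <- file.path(out_dir, paste0("aggregate_", cname, ".csv"))
      write_csv_c(cbind(as.data.frame(agg),
                        offset = attr(agg, "offset")), p2, cfg_hash); add(p2)
    }
    if (length(curves) >= 2L) {
      cmp <- compare_conditions(curves[[1]], curves[[2]],
                                var_equal = kc$var_equal %||% TRUE)
      p <- file.path(out_dir, "comparison.csv")
      write_csv_c(cmp, p, cfg_hash); add(p)
    }
    p <- file.path(out_dir, "recruitment.png")
    plot_aggregate(aggs, path = p); add(p)
  })

  if ("foci" %in% stages) run_stage("foci", {
    fc <- check_keys(config$foci %||% list(), "foci")
    n_exp <- fc$n_experiments %||% 3L
    conds <- fc$conditions %||% list(control = list())
    sim_args <- fc[intersect(names(fc), names(formals(simulate_foci_stack)))]
    tables <- list()
    for (ci in seq_along(conds)) {
      cname <- names(conds)[ci]
      rows <- list()
      for (e in seq_len(n_exp)) {
        args <- utils::modifyList(sim_args, conds[[ci]])
        args$seed <- subseed(seed, 20L, ci, e)
        fs <- do.call(simulate_foci_stack, args)
        det <- do.call(rbind, lapply(seq_along(fs$stacks), function(ti) {
          d <- detect_foci(fs$stacks[[ti]], fs$masks[[ti]],
                           rel_thresh = fc$rel_thresh %||% 1.3,
                           min_sep = fc$detect_min_sep %||% 4)
          d$timepoint_h <- unique(fs$truth$timepoint_h)[ti]
          d
        }))
        det$experiment <- e; det$condition <- cname
        rows[[e]] <- det
      }
      tables[[cname]] <- do.call(rbind, rows)
    }
    all_counts <- do.call(rbind, tables)
    p1 <- file.path(out_dir, "foci_counts.csv")
    write_csv_c(all_counts, p1, cfg_hash); add(p1)
    summaries <- lapply(tables, foci_fraction, threshold = fc$threshold %||% 10L)
    p2 <- file.path(out_dir, "foci_summary.csv")
    write_csv_c(do.call(rbind, lapply(summaries, as.data.frame)), p2, cfg_hash)
    add(p2)
    if (length(summaries) >= 2L) {
      p3 <- file.path(out_dir, "foci_comparison.csv")
      write_csv_c(compare_foci(summaries[[1]], summaries[[2]]), p3, cfg_hash)
      add(p3)
    }
  })

  if ("survival" %in% stages) run_stage("survival", {
    vc <- check_keys(config$survival %||% list(), "survival")
    tab <- if (!is.null(vc$table)) read_csv_c(vc$table) else {
      conds <- vc$conditions %||% list(control = list(lambda = 0.25))
      sim_args <- vc[intersect(names(vc), names(formals(simulate_survival_counts)))]
      do.call(rbind, lapply(seq_along(conds), function(ci) {
        args <- utils::modifyList(sim_args, conds[[ci]])
        args$condition <- names(conds)[ci]
        if (is.null(args$doses)) args$doses <- c(0, 1, 2, 4, 8)
        args$seed <- subseed(seed, 30L, ci)
        do.call(simulate_survival_counts, args)
      }))
    }
    p0 <- file.path(out_dir, "colony_counts.csv")
    write_csv_c(tab, p0, cfg_hash); add(p0)
    sf <- surviving_fraction(tab, dispersion = vc$dispersion %||% "sem")
    p1 <- file.path(out_dir, "survival_curve.csv")
    write_csv_c(as.data.frame(sf), p1, cfg_hash); add(p1)
    p2 <- file.path(out_dir, "survival.png")
    plot_survival(sf, path = p2); add(p2)
  })

  manifest <- list(tool = "recruitkin", version = pkg_version(), seed = seed,
                   config = config,
                   files = lapply(stats::setNames(artifacts, basename(artifacts)),
                                  function(p) list(path = p,
                                                   md5 = unname(tools::md5sum(p)))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  logf("wrote %d artifacts + manifest", length(artifacts))
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# write text to a file and return the path (helper for hashing a config
# snapshot with tools::md5sum, which wants a file)
textConnection_write <- function(txt, path) {
  writeLines(as.character(txt), path)
  path
}
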