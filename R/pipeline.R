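#' Read and validate a pipeline run configuration
#'
#' Configurations are YAML or JSON with the layout documented in
#' [run_pipeline()]. Validation is schema-first: required fields are checked
#' before any computation starts.
#'
#' @param path Path to a `.yaml`/`.yml`/`.json` config file, or an already
#'   constructed list.
#' @return Validated config list (class `run_config`).
#' @export
read_run_config <- function(path) {
  config <- if (is.list(path)) path else {
    ext <- tolower(tools::file_ext(path))
    if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
    else if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
    else abort("config must be YAML or JSON")
  }
  validate_run_config(config)
}

validate_run_config <- function(config) {
  need <- function(ok, msg) if (!ok) abort(paste0("config error: ", msg))
  need(is.list(config), "config must be a mapping")
  need(!is.null(config$input), "missing `input` section")
  inp <- config$input
  need(!is.null(inp$langevin) || !is.null(inp$helix_fixture) ||
         !is.null(inp$trajectory),
       "`input` needs one of: langevin, helix_fixture, trajectory")
  if (!is.null(inp$trajectory))
    need(!is.null(inp$selection), "`input$selection` required for trajectory input")
  if (!is.null(config$tica))
    need(!is.null(config$tica$lag_time) || !is.null(config$tica$lag_frames),
         "`tica` needs lag_time or lag_frames")
  if (!is.null(config$msm))
    need(!is.null(config$msm$lag_time) || !is.null(config$msm$lag_frames),
         "`msm` needs lag_time or lag_frames")
  need(!is.null(config$msm) || !is.null(config$contacts),
       "config declares no analysis stage (msm or contacts)")
  if (!is.null(config$msm))
    need(!is.null(config$tica), "`msm` requires a `tica` section")
  config$seed <- config$seed %||% 1L
  config$temperature <- config$temperature %||% 300
  config$time_unit_seconds <- config$time_unit_seconds %||% 1e-6
  if (!is.null(config$msm)) config$msm$n_macro <- config$msm$n_macro %||% 2L
  structure(config, class = c("run_config", "list"))
}

# one global seed deterministically derives all module seeds
derive_seeds <- function(seed, n = 10) {
  withr::with_seed(as.integer(seed), sample.int(.Machine$integer.max - 1, n))
}

lag_in_frames <- function(section, frame_interval) {
  if (!is.null(section$lag_frames)) return(as.integer(section$lag_frames))
  max(1L, as.integer(round(section$lag_time / frame_interval)))
}

#' Run the full conformational-kinetics pipeline
#'
#' Orchestrates synthesise/ingest, featurisation, tICA, microstate k-means,
#' reversible MSM estimation (with optional implied-timescale and
#' Chapman-Kolmogorov validation), PCCA+ coarse-graining, MFPT kinetics, the
#' 1D free-energy profile, and (for fixture input) the per-state contact
#' table. Every stage logs one line; all randomness derives from the single
#' config seed. When the output directory already holds a report whose
#' config hash matches, the cached report is returned untouched.
#'
#' Config layout (YAML/JSON):
#' \preformatted{
#' seed: 1
#' temperature: 300           # K
#' time_unit_seconds: 1e-6    # physical meaning of one trajectory time unit
#' input:
#'   langevin:                # or helix_fixture: {jitter_sd, frames_per_state}
#'     wells: {centers: [-1, 1], depth: 4.5, width: 0.45}
#'     kT: 1.0
#'     dt: 0.005
#'     n_steps: 2000000
#'   stride: 5                # optional frame thinning
#'   # trajectory: path.pdb   # or an on-disk trajectory
#'   # topology: top.pdb
#'   # selection: 'name == "CA"'
#' tica: {lag_time: 1.0, n_components: 1}
#' msm:  {k: 50, lag_time: 1.0, n_macro: 2}
#' validate: {ck_factors: [2, 3], timescale_lags: [20, 40, 80]}
#' contacts: {cutoff: 4.0, threshold: 0.5}
#' }
#'
#' @param config Path to a config file or a config list.
#' @param seed Optional override of the config seed.
#' @param outdir Output directory for artifacts (default: a temp directory).
#' @param quiet Suppress per-stage log lines.
#' @return Object of class `run_report`: per-stage summaries, artifact
#'   paths, the config hash, and the fitted objects (`$objects`).
#' @export
run_pipeline <- function(config, seed = NULL, outdir = NULL, quiet = FALSE) {
  config <- read_run_config(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  outdir <- outdir %||% config$outdir %||% tempfile("vsdk_run_")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  cfg_hash <- rlang::hash(config[setdiff(names(config), "outdir")])
  report_path <- file.path(outdir, "report.json")
  if (file.exists(report_path)) {
    old <- jsonlite::read_json(report_path, simplifyVector = TRUE)
    if (identical(old$config_hash, cfg_hash)) {
      if (!quiet) message("[pipeline] cached report matches config hash; skipping")
      old$cached <- TRUE
      class(old) <- "run_report"
      return(old)
    }
  }
  log_stage <- function(...) if (!quiet) message("[pipeline] ", sprintf(...))
  seeds <- derive_seeds(config$seed, 10)
  stages <- list()
  objects <- list()
  artifacts <- character()
  write_report <- function(status) {
    report <- list(package_version = as.character(utils::packageVersion("vsdkinetics")),
                   config_hash = cfg_hash, seed = config$seed,
                   status = status, stages = stages, artifacts = artifacts)
    jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, force = TRUE)
    report
  }
  run_stage <- function(name, fun) {
    t0 <- Sys.time()
    res <- tryCatch(fun(), error = function(e) {
      stages[[name]] <<- list(status = "error", message = conditionMessage(e))
      write_report("failed")
      abort(sprintf("stage `%s` failed: %s", name, conditionMessage(e)))
    })
    log_stage("%-12s %.2fs", name,
              as.numeric(difftime(Sys.time(), t0, units = "secs")))
    res
  }

  # -- input ----------------------------------------------------------------
  traj <- NULL
  series <- run_stage("input", function() {
    inp <- config$input
    if (!is.null(inp$langevin)) {
      lg <- inp$langevin
      wells <- lg$wells
      pot <- potential_spec(unlist(wells$centers),
                            depth = wells$depth %||% 4,
                            width = wells$width %||% 0.5)
      spec <- langevin_spec(pot, kT = lg$kT %||% 1,
                            friction = lg$friction %||% 1,
                            dt = lg$dt %||% 1e-3,
                            n_steps = lg$n_steps %||% 1e5,
                            x0 = lg$x0 %||% NULL, seed = seeds[1])
      s <- generate_langevin(spec)
      stride <- inp$stride %||% 1L
      if (stride > 1) {
        s <- feature_series(s$values[seq(1, nrow(s$values), stride), , drop = FALSE],
                            frame_interval = s$frame_interval * stride,
                            provenance = s$provenance)
      }
      stages$input <<- list(kind = "langevin", n_frames = nrow(s$values),
                            frame_interval = s$frame_interval)
      list(s)
    } else if (!is.null(inp$helix_fixture)) {
      hf <- inp$helix_fixture
      spec <- default_helix_spec(jitter_sd = hf$jitter_sd %||% 0.3,
                                 frames_per_state = hf$frames_per_state %||% 50,
                                 seed = seeds[1])
      traj <<- generate_helix_fixture(spec)
      s <- extract_features(traj, which(traj$atoms$mobile))
      stages$input <<- list(kind = "helix_fixture", n_frames = nrow(s$values))
      list(s)
    } else {
      traj <<- read_trajectory(inp$trajectory, inp$topology,
                               frame_interval = inp$frame_interval %||% 1)
      s <- extract_features(traj, inp$selection)
      stages$input <<- list(kind = "trajectory", n_frames = nrow(s$values))
      list(s)
    }
  })
  fi <- series[[1]]$frame_interval
  tica <- assignment <- model <- macro <- profile <- NULL

  if (!is.null(config$msm)) {

  # -- tICA -----------------------------------------------------------------
  tica <- run_stage("tica", function() {
    lag <- lag_in_frames(config$tica, fi)
    m <- fit_tica(series, lag = lag,
                  n_components = config$tica$n_components)
    stages$tica <<- list(lag_frames = lag, n_components = m$n_components,
                         top_eigenvalues = signif(head(m$eigenvalues, 4), 6))
    m
  })
  projected <- project_tica(tica, series)
  if (inherits(projected, "feature_series")) projected <- list(projected)

  # -- microstates ----------------------------------------------------------
  assignment <- run_stage("microstates", function() {
    nf <- sum(vapply(projected, function(s) nrow(s$values), integer(1)))
    k <- config$msm$k %||% min(100L, max(2L, nf %/% 50L))
    a <- kmeans_microstates(projected, k = k, seed = seeds[2])
    stages$microstates <<- list(k = a$k, inertia = a$inertia)
    a
  })

  # -- MSM ------------------------------------------------------------------
  model <- run_stage("msm", function() {
    lag <- lag_in_frames(config$msm, fi)
    m <- estimate_msm(assignment, lag)
    stages$msm <<- list(
      lag_frames = lag, n_states = nrow(m$T),
      fraction_states = m$connectivity$fraction_states,
      fraction_counts = m$connectivity$fraction_counts,
      detailed_balance_residual = m$residuals$detailed_balance)
    m
  })

  # -- validation (optional) ------------------------------------------------
  if (!is.null(config$validate$timescale_lags)) {
    run_stage("timescales", function() {
      its <- implied_timescales(assignment,
                                as.integer(config$validate$timescale_lags),
                                n_timescales = 3)
      path <- file.path(outdir, "implied_timescales.tsv")
      utils::write.table(its, path, sep = "\t", row.names = FALSE, quote = FALSE)
      artifacts <<- c(artifacts, path)
      objects$implied_timescales <<- its
      stages$timescales <<- list(lags = config$validate$timescale_lags)
      its
    })
  }
  if (!is.null(config$validate$ck_factors)) {
    run_stage("ck_test", function() {
      ck <- ck_test(assignment, model,
                    factors = as.integer(config$validate$ck_factors),
                    n_macro_sets = config$msm$n_macro, seed = seeds[3])
      objects$ck <<- ck
      stages$ck_test <<- list(pass = ck$pass, factors = ck$factors)
      ck
    })
  }

  # -- macrostates & kinetics ----------------------------------------------
  macro <- run_stage("macrostates", function() {
    m <- pcca_plus(model, config$msm$n_macro)
    stages$macrostates <<- list(n_macro = m$n_macro,
                                weights = signif(m$weights, 6))
    m
  })
  profile <- run_stage("kinetics", function() {
    kin <- kinetics_table(macro)
    # MFPTs to seconds for the TST barriers
    kin_s <- kin
    kin_s$mfpt <- kin$mfpt * config$time_unit_seconds
    kin_s$rate <- ifelse(kin_s$mfpt > 0, 1 / kin_s$mfpt, NA_real_)
    ordering <- order_macrostates(macro, assignment$centers)
    prof <- build_profile(macro, kin_s, ordering = ordering,
                          temperature = config$temperature)
    kpath <- file.path(outdir, "kinetics.tsv")
    utils::write.table(kin, kpath, sep = "\t", row.names = FALSE, quote = FALSE)
    ppath <- file.path(outdir, "profile.json")
    jsonlite::write_json(list(states = prof$states, barriers = prof$barriers,
                              temperature = prof$temperature),
                         ppath, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    artifacts <<- c(artifacts, kpath, ppath)
    objects$kinetics <<- kin
    stages$kinetics <<- list(
      mfpt = setNames(kin$mfpt, paste0(kin$from, "->", kin$to)),
      barriers_kJmol = setNames(prof$barriers$barrier,
                                paste0(prof$barriers$from, "->",
                                       prof$barriers$to)))
    prof
  })

  }  # end MSM branch

  # -- contacts (fixture / trajectory input only) ---------------------------
  contacts <- NULL
  if (!is.null(traj) && !is.null(config$contacts)) {
    contacts <- run_stage("contacts", function() {
      ct <- detect_ion_pairs(traj, cutoff = config$contacts$cutoff %||% 4.0,
                             threshold = config$contacts$threshold %||% 0.5)
      cpath <- file.path(outdir, "contacts.tsv")
      utils::write.table(ct, cpath, sep = "\t", row.names = FALSE, quote = FALSE)
      artifacts <<- c(artifacts, cpath)
      stages$contacts <<- list(n_rows = nrow(ct),
                               cutoff = attr(ct, "cutoff"))
      ct
    })
  }

  report <- write_report("ok")
  report$objects <- list(series = series, tica = tica,
                         assignment = assignment, model = model,
                         macro = macro, profile = profile,
                         contacts = contacts)
  report$objects <- c(report$objects, objects)
  class(report) <- "run_report"
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> status %s, seed %s, config %s\n",
              x$status, x$seed, substr(x$config_hash, 1, 8)))
  for (nm in names(x$stages)) {
    cat(sprintf("  %-12s %s\n", nm,
                paste(names(x$stages[[nm]]), "=",
                      vapply(x$stages[[nm]], function(v)
                        paste(signif_if_num(v), collapse = ","), ""),
                      collapse = "; ")))
  }
  invisible(x)
}

signif_if_num <- function(v) if (is.numeric(v)) signif(v, 4) else v
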