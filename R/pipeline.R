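## pipeline: end-to-end experiments (length x salt sweeps, fixed-mass
## comparisons) with seeded replicates and tabular outputs.

#' Experiment configuration
#'
#' The receptor is either a `solenoid_spec` (a toy receptor is generated)
#' or a list with elements `model`, `annotation`, `sites` (e.g. built
#' from a crystal-structure trace via [parse_calpha_trace()] and
#' [model_missing_regions()]).
#'
#' @param receptor `solenoid_spec` or list(model, annotation, sites).
#' @param pr_lengths Poly-PR repeat numbers to sweep (chain length 2n).
#' @param salts_mM Salt concentrations to sweep, mM.
#' @param seeds Replicate seeds.
#' @param copies Poly-PR copies per run.
#' @param n_steps,save_interval,box,timestep,temperature,friction
#'   Simulation settings (see [sim_config()]). `box = NULL` chooses
#'   4x the receptor radius-of-gyration estimate.
#' @param equilibration_fraction Discarded initial fraction.
#' @param outdir Optional output directory for TSV tables.
#' @return List of class `experiment_config`.
#' @export
experiment_config <- function(receptor = solenoid_spec(),
                              pr_lengths = c(7L, 20L, 35L, 50L),
                              salts_mM = c(100, 200), seeds = 1:5,
                              copies = 1L, n_steps = 200000L,
                              save_interval = 500L, box = NULL,
                              timestep = 0.02, temperature = 300,
                              friction = 0.02,
                              equilibration_fraction = 0.2,
                              outdir = NULL) {
  structure(as.list(environment()), class = "experiment_config")
}

.resolve_receptor <- function(receptor) {
  if (inherits(receptor, "solenoid_spec")) {
    toy <- generate_toy_solenoid(receptor)
    list(model = toy$model, annotation = toy$annotation,
         sites = toy$sites)
  } else {
    stopifnot(is.list(receptor), inherits(receptor$model, "cg_model"))
    receptor
  }
}

.auto_box <- function(model) {
  p <- sweep(model$positions, 2, colMeans(model$positions))
  rg <- sqrt(mean(rowSums(p^2)))
  max(10, ceiling(4 * rg))
}

## one (length, salt, seed) arm: build, simulate, analyze
.run_arm <- function(receptor, n_pr, salt, seed, cfg, copies = 1L) {
  params <- ff_params(salt_mM = salt, temperature = cfg$temperature)
  box <- if (is.null(cfg$box)) .auto_box(receptor$model) else cfg$box
  prs <- lapply(seq_len(copies), function(c)
    build_polypr(n_pr, seed = seed * 1000L + c,
                 chain_id = paste0("PR", n_pr, "_", c)))
  sc <- sim_config(box = box, n_steps = cfg$n_steps,
                   timestep = cfg$timestep,
                   temperature = cfg$temperature,
                   friction = cfg$friction,
                   save_interval = cfg$save_interval, seed = seed,
                   equilibration_fraction = cfg$equilibration_fraction)
  traj <- run_simulation(c(list(receptor$model), prs), sc, params,
                         roles = c("kap", rep("pr", copies)))
  analyze_trajectory(traj, receptor$annotation, receptor$sites)
}

.arm_row <- function(res, n_pr, salt, seed, copies = 1L) {
  data.frame(
    length = n_pr, salt_mM = salt, seed = seed, copies = copies,
    status = "ok",
    Ct = res$Ct, Ct_normalized = res$Ct_normalized,
    Ct_err = res$Ct_uncertainty,
    Pb = res$Pb, Pb_any = res$Pb_any, Pb_err = res$Pb_uncertainty,
    n_sites = length(res$contact_sites),
    Ncontact_A = res$Ncontact_by_region[["A"]],
    Ncontact_B = res$Ncontact_by_region[["B"]],
    Ncontact_linker = res$Ncontact_by_region[["linker"]],
    Nshared_cargo = res$Nshared_by_class[["cargo"]],
    Nshared_ibb = res$Nshared_by_class[["ibb"]],
    Nshared_rangtp = res$Nshared_by_class[["rangtp"]],
    Nshared_fg_nup = res$Nshared_by_class[["fg_nup"]])
}

#' Length x salt sweep
#'
#' Runs one simulation per (poly-PR length, salt, seed) and tabulates
#' Ct, normalized Ct, Pb, region-resolved contact counts and
#' binding-site overlap. Failed runs are recorded with status "failed"
#' and skipped in the aggregate.
#'
#' @param config An `experiment_config`.
#' @return List: `table` (one row per run), `aggregate` (mean over seeds
#'   with half-standard-deviation uncertainties), `n_failed`.
#' @export
run_length_salt_sweep <- function(config) {
  receptor <- .resolve_receptor(config$receptor)
  rows <- list()
  for (n_pr in config$pr_lengths)
    for (salt in config$salts_mM)
      for (seed in config$seeds) {
        res <- tryCatch(
          .run_arm(receptor, n_pr, salt, seed, config, config$copies),
          error = function(e) e)
        rows[[length(rows) + 1L]] <-
          if (inherits(res, "error"))
            data.frame(length = n_pr, salt_mM = salt, seed = seed,
                       copies = config$copies, status = "failed",
                       Ct = NA, Ct_normalized = NA, Ct_err = NA, Pb = NA,
                       Pb_any = NA, Pb_err = NA, n_sites = NA,
                       Ncontact_A = NA, Ncontact_B = NA,
                       Ncontact_linker = NA, Nshared_cargo = NA,
                       Nshared_ibb = NA, Nshared_rangtp = NA,
                       Nshared_fg_nup = NA)
          else .arm_row(res, n_pr, salt, seed, config$copies)
      }
  tab <- do.call(rbind, rows)
  ok <- tab[tab$status == "ok", ]
  agg <- NULL
  if (nrow(ok)) {
    sp <- split(ok, list(ok$length, ok$salt_mM), drop = TRUE)
    agg <- do.call(rbind, lapply(sp, function(g) data.frame(
      length = g$length[1], salt_mM = g$salt_mM[1], n_seeds = nrow(g),
      Ct = mean(g$Ct),
      Ct_err = if (nrow(g) > 1) scalar_uncertainty(g$Ct) else g$Ct_err[1],
      Ct_normalized = mean(g$Ct_normalized),
      Pb = mean(g$Pb),
      Pb_err = if (nrow(g) > 1) scalar_uncertainty(g$Pb) else g$Pb_err[1],
      Ncontact_A = mean(g$Ncontact_A), Ncontact_B = mean(g$Ncontact_B),
      Ncontact_linker = mean(g$Ncontact_linker))))
    rownames(agg) <- NULL
  }
  if (!is.null(config$outdir)) {
    dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
    write.table(tab, file.path(config$outdir, "sweep_runs.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(agg))
      write.table(agg, file.path(config$outdir, "sweep_aggregate.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(table = tab, aggregate = agg,
       n_failed = sum(tab$status == "failed"))
}

#' Fixed-mass-concentration comparison
#'
#' Compares groups ("arms") that hold the total number of PR repeat
#' units n_PR constant while trading copy number against chain length
#' (e.g. 10 x PR7 vs 2 x PR35, both n_PR = 70).
#'
#' @param config An `experiment_config`; its `pr_lengths`/`copies` are
#'   ignored in favour of `arms`.
#' @param arms List of `list(copies =, length =)`; all arms must have
#'   equal copies x length.
#' @param salt_mM Salt concentration for the comparison.
#' @return List: `table` (one row per arm x seed), `n_pr` (shared total).
#' @export
run_fixed_mass_comparison <- function(config, arms, salt_mM = 100) {
  n_pr_tot <- vapply(arms, function(a) a$copies * a$length, numeric(1))
  if (length(unique(n_pr_tot)) != 1L)
    stop("arms have unequal total repeat units n_PR: ",
         paste(n_pr_tot, collapse = ", "))
  receptor <- .resolve_receptor(config$receptor)
  rows <- list()
  for (a in arms)
    for (seed in config$seeds) {
      res <- .run_arm(receptor, a$length, salt_mM, seed, config,
                      a$copies)
      r <- .arm_row(res, a$length, salt_mM, seed, a$copies)
      rows[[length(rows) + 1L]] <- r
    }
  tab <- do.call(rbind, rows)
  if (!is.null(config$outdir)) {
    dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
    write.table(tab, file.path(config$outdir, "fixed_mass.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(table = tab, n_pr = n_pr_tot[1])
}

## ---- command-line interface ---------------------------------------------

.cli_usage <- function() {
  paste(
    "kapcg <command> [options]",
    "",
    "Commands:",
    "  make-toy  --spec <cfg>  --out <dir>   generate toy solenoid files",
    "  simulate  --config <cfg> --out <traj> [--log <tsv>]",
    "  analyze   --traj <file> [--regions <tsv>] [--sites <tsv>]",
    "            --out <dir>",
    "  sweep     --config <cfg> --out <dir>  length x salt sweep",
    "  --help                                this message",
    sep = "\n")
}

.cli_opts <- function(argv) {
  opts <- list()
  i <- 1L
  while (i <= length(argv)) {
    a <- argv[i]
    if (!startsWith(a, "--"))
      stop("unexpected argument: ", a)
    if (i == length(argv) || startsWith(argv[i + 1L], "--"))
      stop("missing value for ", a)
    opts[[substring(a, 3)]] <- argv[i + 1L]
    i <- i + 2L
  }
  opts
}

#' Command-line entry point
#'
#' Subcommands: `make-toy`, `simulate`, `analyze`, `sweep`. Configs are
#' flat `key: value` text files. Returns an exit status (0 = success)
#' rather than quitting, so it is scriptable and testable; the installed
#' `inst/cli/kapcg` wrapper forwards the status to `quit()`.
#'
#' @param argv Character vector of command-line arguments.
#' @return Integer exit status, invisibly.
#' @export
cli_entry <- function(argv = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (length(argv) == 0L || argv[1] %in% c("--help", "-h", "help")) {
      message(.cli_usage())
      return(invisible(if (length(argv) == 0L) 2L else 0L))
    }
    cmd <- argv[1]
    opts <- .cli_opts(argv[-1])
    switch(cmd,
      "make-toy" = {
        kv <- if (!is.null(opts$spec)) .read_kv_file(opts$spec) else list()
        spec <- do.call(solenoid_spec, kv)
        toy <- generate_toy_solenoid(spec)
        dir.create(opts$out, showWarnings = FALSE, recursive = TRUE)
        write_cg_model(toy$model, file.path(opts$out, "receptor.json"))
        write_region_annotation(toy$annotation,
                                file.path(opts$out, "regions.tsv"))
        write_binding_sites(toy$sites, file.path(opts$out, "sites.tsv"))
        message("toy receptor: ", nchar(toy$model$sequence),
                " residues, NCPR ", sprintf("%.4f", toy$ncpr))
        0L
      },
      "simulate" = {
        kv <- .read_kv_file(opts$config)
        receptor <- read_cg_model(kv$receptor_model)
        n_pr <- if (!is.null(kv$pr_repeats)) kv$pr_repeats else 25
        copies <- if (!is.null(kv$copies)) kv$copies else 1
        seed <- if (!is.null(kv$seed)) kv$seed else 1
        prs <- lapply(seq_len(copies), function(c)
          build_polypr(n_pr, seed = seed * 1000 + c))
        params <- ff_params(
          salt_mM = if (!is.null(kv$salt_mM)) kv$salt_mM else 200)
        sc <- sim_config(
          box = if (!is.null(kv$box)) kv$box else .auto_box(receptor),
          n_steps = if (!is.null(kv$n_steps)) kv$n_steps else 200000,
          save_interval = if (!is.null(kv$save_interval))
            kv$save_interval else 500,
          seed = seed)
        traj <- run_simulation(c(list(receptor), prs), sc, params,
                               roles = c("kap", rep("pr", copies)))
        write_trajectory(traj, opts$out)
        if (!is.null(opts$log))
          write.table(as.data.frame(traj$energy_log), opts$log,
                      sep = "\t", quote = FALSE, row.names = FALSE)
        message("wrote ", dim(traj$frames)[3], " frames to ", opts$out)
        0L
      },
      "analyze" = {
        traj <- read_trajectory(opts$traj)
        ann <- if (!is.null(opts$regions))
          read_region_annotation(opts$regions) else NULL
        sites <- if (!is.null(opts$sites))
          read_binding_sites(opts$sites) else NULL
        res <- analyze_trajectory(traj, ann, sites)
        write_contact_results(res, opts$out)
        print(res)
        0L
      },
      "sweep" = {
        kv <- .read_kv_file(opts$config)
        spec_keys <- intersect(names(kv), names(formals(solenoid_spec)))
        spec <- do.call(solenoid_spec, kv[spec_keys])
        cfg <- experiment_config(
          receptor = spec,
          pr_lengths = if (!is.null(kv$pr_lengths)) kv$pr_lengths
            else c(7, 35),
          salts_mM = if (!is.null(kv$salts_mM)) kv$salts_mM
            else c(100, 200),
          seeds = if (!is.null(kv$seeds)) kv$seeds else 1:3,
          n_steps = if (!is.null(kv$n_steps)) kv$n_steps else 100000,
          outdir = opts$out)
        sw <- run_length_salt_sweep(cfg)
        message("sweep complete: ", nrow(sw$table), " runs, ",
                sw$n_failed, " failed")
        if (sw$n_failed > 0) 1L else 0L
      },
      {
        message("unknown command: ", cmd, "\n\n", .cli_usage())
        2L
      })
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(as.integer(status))
}
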