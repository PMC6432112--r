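# Deterministic output formats and the command-line entry point.
# CSV columns carry 17 significant digits (lossless double round-trip);
# every artifact gets a JSON sidecar echoing the effective configuration.

.format_version <- "wlcbuckle-csv-1"

#' Write a result table as lossless CSV with a JSON metadata sidecar
#'
#' Numeric columns are written with 17 significant digits so that reading
#' the file back reproduces the doubles exactly. The metadata (effective
#' configuration, seeds, tolerances, format version tag) is written next
#' to the CSV as `<path>.json`.
#'
#' @param df data frame to write.
#' @param path output CSV path.
#' @param meta named list of metadata; the format version tag and a
#'   timestamp are added.
#' @return `path`, invisibly.
#' @export
write_result_csv <- function(df, path, meta = list()) {
  out <- df
  for (j in seq_along(out))
    if (is.numeric(out[[j]]))
      out[[j]] <- formatC(out[[j]], digits = 17, format = "g")
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  meta$format_version <- .format_version
  meta$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write chain conformations in XYZ format
#'
#' One frame per sampled conformation, element tag "C", coordinates in
#' 2lp units.
#'
#' @param snapshots matrix with `3 * Nb` rows (as returned in the
#'   `snapshots` field of a `wlc_mcrun`) or a single `3 x Nb` matrix.
#' @param path output path.
#' @param comment per-frame comment prefix.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(snapshots, path, comment = "wlc conformation") {
  if (is.matrix(snapshots) && nrow(snapshots) %% 3 == 0 && ncol(snapshots) >= 1 &&
      nrow(snapshots) > 3) {
    frames <- lapply(seq_len(ncol(snapshots)),
                     function(j) matrix(snapshots[, j], nrow = 3))
  } else {
    frames <- list(snapshots)
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(frames)) {
    fr <- frames[[k]]
    writeLines(as.character(ncol(fr)), con)
    writeLines(paste(comment, k), con)
    writeLines(sprintf("C %.10f %.10f %.10f", fr[1, ], fr[2, ], fr[3, ]), con)
  }
  invisible(path)
}

# ---- command-line interface -------------------------------------------------

.cli_usage <- "usage: wlcbuckle <command> [--flag value ...]

commands:
  greens          --N <f> [--r-points n] [--method residue|contour] --out f.csv
  elastica        --N <f> [--f-over-fE-min a --f-over-fE-max b --f-points n] --out f.csv
  elastica-energy --N <f> [--R-points n] --out f.csv
  buckle          --N <f> [--f-min a --f-max b --f-points n] --out f.csv
  critical        --N-min a --N-max b [--N-points n] [--f-points n] --out f.csv
  mc              --N <f> --Nb <n> --ensemble fixed-R|fixed-f (--R x | --f-over-fE x)
                  [--sweeps n --equil n --stride n --snapshots n] --seed s --out f.json
  thermo          --N <f> --Nb <n> [--R-points n] [--e0-mode empirical|paper]
                  --seed s --out f.csv
  reproduce       fig2|fig3 --out f.csv [--seed s]
global flags: --config <yaml> (defaults override), --log-level info|quiet"

.parse_flags <- function(argv) {
  flags <- list()
  pos <- character()
  i <- 1L
  while (i <= length(argv)) {
    a <- argv[i]
    if (startsWith(a, "--")) {
      key <- sub("^--", "", a)
      if (i == length(argv) || startsWith(argv[i + 1], "--"))
        stop("flag --", key, " needs a value")
      flags[[key]] <- argv[i + 1]
      i <- i + 2L
    } else {
      pos <- c(pos, a)
      i <- i + 1L
    }
  }
  list(flags = flags, positional = pos)
}

.flag_num <- function(flags, name, default = NULL) {
  if (!is.null(flags[[name]])) as.numeric(flags[[name]])
  else if (!is.null(default)) default
  else stop("missing required flag --", name)
}
.flag_chr <- function(flags, name, default = NULL) {
  if (!is.null(flags[[name]])) flags[[name]]
  else if (!is.null(default)) default
  else stop("missing required flag --", name)
}

#' Command-line entry point
#'
#' Dispatches the `wlcbuckle` subcommands (see the package CLI script in
#' `inst/cli/`) and writes CSV/JSON/XYZ artifacts. A YAML file given via
#' `--config` overrides any numeric default; the effective configuration
#' is echoed into each artifact's JSON sidecar.
#'
#' @param argv character vector of command-line arguments (excluding the
#'   program name).
#' @return exit status (0 on success), invisibly.
#' @export
run_command <- function(argv) {
  if (length(argv) == 0 || argv[1] %in% c("-h", "--help", "help")) {
    message(.cli_usage)
    return(invisible(0L))
  }
  cmd <- argv[1]
  pa <- .parse_flags(argv[-1])
  fl <- pa$flags
  if (!is.null(fl$config)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("--config requires the yaml package")
    cfg <- yaml::read_yaml(fl$config)
    for (k in names(cfg)) if (is.null(fl[[k]])) fl[[k]] <- cfg[[k]]
  }
  quiet <- identical(fl[["log-level"]], "quiet")
  say <- function(...) if (!quiet) message(...)
  out <- fl$out
  t0 <- Sys.time()

  status <- switch(cmd,
    greens = {
      N <- .flag_num(fl, "N")
      n_r <- as.integer(.flag_num(fl, "r-points", 400))
      g <- greens_r_N(N, n_r = n_r)
      df <- data.frame(r = g$r, G = g$G, r2G = g$r2G, F0 = g$F0)
      write_result_csv(df, out, meta = list(
        command = "greens", N = N, r_points = n_r, K_max = g$K_max,
        norm_check = g$norm_check, moment_check = g$moment_check,
        diagnostics = g$diagnostics))
      say("greens: N = ", N, ", normalization ", format(g$norm_check, digits = 8))
      0L
    },
    elastica = {
      N <- .flag_num(fl, "N")
      a <- .flag_num(fl, "f-over-fE-min", 0)
      b <- .flag_num(fl, "f-over-fE-max", 4)
      n <- as.integer(.flag_num(fl, "f-points", 101))
      fE <- euler_force(N)
      fr <- seq(a, b, length.out = n)
      ext <- elastica_extension(N, fr * fE)
      write_result_csv(data.frame(f_over_fE = fr, extension = ext), out,
                       meta = list(command = "elastica", N = N, fE = fE))
      0L
    },
    `elastica-energy` = {
      N <- .flag_num(fl, "N")
      n <- as.integer(.flag_num(fl, "R-points", 50))
      RL <- seq(1 / n, 1, length.out = n)
      eb <- vapply(RL, function(x) min_bend_energy_at_R(N, x * N)$bend_energy,
                   numeric(1))
      write_result_csv(data.frame(R_over_L = RL, E_bend_kBT = eb), out,
                       meta = list(command = "elastica-energy", N = N))
      0L
    },
    buckle = {
      N <- .flag_num(fl, "N")
      fx <- force_extension(N,
        n_f = as.integer(.flag_num(fl, "f-points", 121)),
        f_span = c(.flag_num(fl, "f-min", -1), .flag_num(fl, "f-max", 4)))
      write_result_csv(data.frame(f_over_fE = fx$f_grid / fx$fE,
                                  Rmin_over_L = fx$Rmin_over_L,
                                  alphaF = fx$alphaF), out,
                       meta = list(command = "buckle", N = N, fE = fx$fE,
                                   fc = fx$fc, fc_over_fE = fx$fc_over_fE))
      say("buckle: fc/fE = ", format(fx$fc_over_fE, digits = 6))
      0L
    },
    critical = {
      Ng <- seq(.flag_num(fl, "N-min"), .flag_num(fl, "N-max"),
                length.out = as.integer(.flag_num(fl, "N-points", 15)))
      cs <- critical_force_surface(Ng,
        n_f = as.integer(.flag_num(fl, "f-points", 121)))
      write_result_csv(cs$table, out, meta = list(command = "critical",
                                                  N_grid = Ng))
      surf_path <- sub("([.]csv)?$", "_surface.csv", out)
      write_result_csv(cs$surface, surf_path,
                       meta = list(command = "critical-surface", N_grid = Ng))
      say("critical: max elevation ",
          format(100 * (max(cs$table$fc_over_fE, na.rm = TRUE) - 1),
                 digits = 4), "%")
      0L
    },
    mc = {
      N <- .flag_num(fl, "N")
      Nb <- as.integer(.flag_num(fl, "Nb"))
      ens <- .flag_chr(fl, "ensemble")
      seed <- as.integer(.flag_num(fl, "seed", 1))
      cfg <- list(n_sweeps = .flag_num(fl, "sweeps", 2e5),
                  n_equil = .flag_num(fl, "equil", 2e4),
                  sample_stride = .flag_num(fl, "stride", 10),
                  n_snapshots = .flag_num(fl, "snapshots", 0))
      run <- if (ens == "fixed-R") {
        mc_fixed_R(build_chain(N, Nb, R_init = .flag_num(fl, "R")),
                   seed = seed, config = cfg)
      } else {
        f <- .flag_num(fl, "f-over-fE", NA) * euler_force(N)
        if (is.na(f)) f <- .flag_num(fl, "f")
        mc_fixed_f(build_chain(N, Nb), f = f, seed = seed, config = cfg)
      }
      res <- list(command = "mc", ensemble = run$ensemble, N = N, Nb = Nb,
                  constraint = run$constraint, seed = seed, config = run$config,
                  Epoly_mean = run$Epoly_mean, Epoly_sem = run$Epoly_sem,
                  acceptance_rate = run$acceptance_rate,
                  delta_crank = run$delta_crank, delta_pivot = run$delta_pivot,
                  mean_R = if (length(run$R_samples)) mean(run$R_samples) else NULL,
                  format_version = .format_version)
      jsonlite::write_json(res, out, auto_unbox = TRUE, digits = NA, pretty = TRUE)
      if (!is.null(fl$xyz) && cfg$n_snapshots > 0)
        write_xyz(run$snapshots, fl$xyz)
      say("mc: <Epoly> = ", format(run$Epoly_mean, digits = 8), " +/- ",
          format(run$Epoly_sem, digits = 3))
      0L
    },
    thermo = {
      N <- .flag_num(fl, "N")
      Nb <- as.integer(.flag_num(fl, "Nb"))
      npt <- as.integer(.flag_num(fl, "R-points", 14))
      seed <- as.integer(.flag_num(fl, "seed", 1))
      mode <- .flag_chr(fl, "e0-mode", "empirical")
      th <- thermo_sweep(N, Nb, R_over_L = seq(0.4, 0.95, length.out = npt),
                         seed = seed, e0_mode = mode)
      write_result_csv(
        data.frame(R_over_L = th$R_over_L, F = th$F,
                   Epoly_minus_E0 = th$Epoly_mean - th$E0, TS = th$TS,
                   E_elastica = th$E_elastica),
        out, meta = list(command = "thermo", N = N, Nb = Nb, seed = seed,
                         E0 = th$E0[1], e0_mode = mode))
      0L
    },
    reproduce = {
      what <- pa$positional[1]
      seed <- as.integer(.flag_num(fl, "seed", 1))
      if (identical(what, "fig2")) {
        run_command(c("critical", "--N-min", "0.25", "--N-max", "2",
                      "--N-points", "15", "--out", out))
      } else if (identical(what, "fig3")) {
        run_command(c("thermo", "--N", "0.25", "--Nb", "51",
                      "--seed", as.character(seed), "--out", out))
      } else stop("unknown reproduce target: ", what)
      0L
    },
    {
      message("unknown command: ", cmd, "\n", .cli_usage)
      1L
    })
  say("done in ", format(as.numeric(Sys.time() - t0, units = "secs"),
                         digits = 3), " s")
  invisible(status)
}
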