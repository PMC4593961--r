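# End-to-end pipeline and command-line entry point.
#
# Stages (each also available as a CLI subcommand): simulate -> preprocess
# -> map -> stats -> report.  Long-format tidy tables are the single
# interchange format between the stats and report stages; figures and
# interpolated maps are regenerable artifacts, never inputs.

#' SSD contrast tables over per-subject condition maps
#'
#' Computes the three standard map contrasts from a nested map list as
#' produced by [analyze_cohort()]:
#' \describe{
#'   \item{`four_vs_single`}{four-finger vs each single-finger map, within
#'     each effort x constraint cell;}
#'   \item{`dynamic_vs_static`}{dynamic vs static map of the same finger
#'     and effort;}
#'   \item{`high_vs_low`}{high- vs low-effort map of the same finger and
#'     constraint.}
#' }
#' Maps are max-normalized before comparison; pairs in which either map is
#' degenerate (all zero) are dropped.
#'
#' @param maps Nested list `maps[[subject]][[condition_id]]` of `rms_map`s,
#'   condition ids `finger_effort_constraint`.
#' @param contrast One of `"four_vs_single"`, `"dynamic_vs_static"`,
#'   `"high_vs_low"`.
#' @return Tidy data frame: `subject`, `finger`, `effort`, `constraint`
#'   (the varying factor reported as `a_vs_b` columns where contrasted),
#'   `ssd`.
#' @export
ssd_contrasts <- function(maps, contrast = c("four_vs_single",
                                             "dynamic_vs_static",
                                             "high_vs_low")) {
  contrast <- match.arg(contrast)
  rows <- list()
  cid <- function(f, e, c) paste(f, e, c, sep = "_")
  singles <- c("index", "middle", "ring", "little")
  for (s in seq_along(maps)) {
    ms <- maps[[s]]
    add <- function(a, b, finger, effort, constraint) {
      if (is.null(ms[[a]]) || is.null(ms[[b]])) return()
      na <- normalize_map(ms[[a]]); nb <- normalize_map(ms[[b]])
      if (isTRUE(na$degenerate) || isTRUE(nb$degenerate)) return()
      rows[[length(rows) + 1L]] <<- data.frame(
        subject = s, finger = finger, effort = effort,
        constraint = constraint, ssd = map_ssd(na, nb)$ssd_percent,
        stringsAsFactors = FALSE)
    }
    for (e in c("high", "low")) for (cc in c("dynamic", "static")) {
      if (contrast == "four_vs_single") {
        for (f in singles) add(cid("four", e, cc), cid(f, e, cc), f, e, cc)
      }
    }
    if (contrast == "dynamic_vs_static") {
      for (f in c(singles, "four")) for (e in c("high", "low")) {
        add(cid(f, e, "dynamic"), cid(f, e, "static"), f, e,
            "dynamic_vs_static")
      }
    }
    if (contrast == "high_vs_low") {
      for (f in c(singles, "four")) for (cc in c("dynamic", "static")) {
        add(cid(f, "high", cc), cid(f, "low", cc), f, "high_vs_low", cc)
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(subject = integer(), finger = character(),
                      effort = character(), constraint = character(),
                      ssd = numeric()))
  }
  do.call(rbind, rows)
}

#' Pairwise SSD between two finger conditions across subjects
#'
#' Convenience for finger-vs-finger map comparisons (e.g. index vs middle)
#' at a fixed effort and constraint.
#'
#' @param maps As in [ssd_contrasts()].
#' @param finger_a,finger_b Finger labels.
#' @param effort,constraint Fixed condition cell (defaults high, dynamic).
#' @return Data frame `subject`, `ssd`.
#' @export
ssd_between_fingers <- function(maps, finger_a, finger_b, effort = "high",
                                constraint = "dynamic") {
  cid_a <- paste(finger_a, effort, constraint, sep = "_")
  cid_b <- paste(finger_b, effort, constraint, sep = "_")
  out <- lapply(seq_along(maps), function(s) {
    ma <- maps[[s]][[cid_a]]; mb <- maps[[s]][[cid_b]]
    if (is.null(ma) || is.null(mb)) return(NULL)
    na <- normalize_map(ma); nb <- normalize_map(mb)
    if (isTRUE(na$degenerate) || isTRUE(nb$degenerate)) return(NULL)
    data.frame(subject = s, ssd = map_ssd(na, nb)$ssd_percent)
  })
  do.call(rbind, out)
}

pipeline_defaults <- function() {
  list(
    n_rows = 7L, n_cols = 9L,
    n_subjects = 10L,
    seed = 20151006L,
    low_hz = 20, high_hz = 400, filter_order = 2L,
    floor_at_zero = TRUE,
    ssd_denominator = "sum_of_squares",
    interpolation_factor = 6L,
    noise_rms = 0.05,
    conditions = "all",
    out_dir = "semgmap-report"
  )
}

#' Assemble a pipeline configuration
#'
#' Merges user settings over documented defaults.  Settings mirror the CLI
#' flags; a JSON config file can supply any subset, and CLI flags override
#' the file.
#'
#' @param ... Named overrides of the defaults (see
#'   `semgmap:::pipeline_defaults()`).
#' @param file Optional path of a JSON config file.
#' @return Named list of class `pipeline_config`.
#' @export
pipeline_config <- function(..., file = NULL) {
  cfg <- pipeline_defaults()
  if (!is.null(file)) {
    user <- jsonlite::read_json(file, simplifyVector = TRUE)
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown)) {
      stop("unknown config fields in ", file, ": ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    cfg[names(user)] <- user
  }
  dots <- list(...)
  dots <- dots[!vapply(dots, is.null, logical(1))]
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stop("unknown config fields: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(dots)] <- dots
  structure(cfg, class = "pipeline_config")
}

config_hash <- function(cfg) {
  # hash the analysis-relevant settings only, not where results are written
  cfg <- unclass(cfg)
  cfg$out_dir <- NULL
  s <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  sprintf("%08x", str_seed(as.character(s)))
}

write_stamped_csv <- function(df, path, cfg) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# config_hash: %s seed: %d", config_hash(cfg),
                     cfg$seed), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

read_stamped_csv <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Run the complete analysis pipeline
#'
#' Simulates (or, via the staged CLI, loads) a cohort, preprocesses every
#' recording, builds activation maps, computes centroid and SSD tables for
#' the three standard contrasts, runs the group-level repeated-measures
#' ANOVAs, and writes all tables plus display-interpolated maps under
#' `cfg$out_dir`.  Every output file embeds the configuration hash and
#' seed, so a rerun with the same config is reproducible and verifiably
#' so.
#'
#' @param cfg A [pipeline_config()].
#' @param verbose Print stage progress.
#' @return Invisibly, a list with `summary`, `ssd` (per-contrast tables),
#'   `anova` (per-response tables), and the output directory.
#' @export
run_analysis <- function(cfg = pipeline_config(), verbose = TRUE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  say <- function(...) if (verbose) message(...)
  say("config hash ", config_hash(cfg),
      " | seed ", cfg$seed,
      " | floor_at_zero ", cfg$floor_at_zero,
      " | ssd_denominator ", cfg$ssd_denominator,
      " | interpolation_factor ", cfg$interpolation_factor)
  grid <- build_grid(cfg$n_rows, cfg$n_cols)
  sim <- simulation_config(grid = grid, noise_rms = cfg$noise_rms,
                           seed = cfg$seed)
  cohort <- generate_cohort(sim, n_subjects = cfg$n_subjects,
                            seed = cfg$seed)
  conditions <- if (identical(cfg$conditions, "all")) NULL else
    utils::read.csv(text = cfg$conditions, stringsAsFactors = FALSE)
  say("simulating and preprocessing ", cfg$n_subjects, " subject(s)...")
  res <- analyze_cohort(cohort, conditions = conditions,
                        floor_at_zero = cfg$floor_at_zero,
                        verbose = verbose)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  write_stamped_csv(res$summary, file.path(cfg$out_dir, "summary.csv"), cfg)

  ssd_tabs <- list()
  for (ct in c("four_vs_single", "dynamic_vs_static", "high_vs_low")) {
    tab <- ssd_contrasts(res$maps, ct)
    ssd_tabs[[ct]] <- tab
    if (nrow(tab)) {
      write_stamped_csv(tab, file.path(cfg$out_dir,
                                       paste0("ssd_", ct, ".csv")), cfg)
    }
  }

  anova_tabs <- list()
  n_cond_per_subj <- table(res$summary$subject)
  full_design <- length(unique(res$summary$subject)) >= 2 &&
    all(n_cond_per_subj == 20)
  if (full_design) {
    say("group statistics...")
    for (resp in c("mean_rms", "cx", "cy")) {
      tab <- res$summary
      tab$response <- tab[[resp]]
      if (any(is.na(tab$response))) next
      an <- rm_anova(tab, c("finger", "effort", "constraint"))
      anova_tabs[[resp]] <- an
      write_stamped_csv(an, file.path(cfg$out_dir,
                                      paste0("anova_", resp, ".csv")), cfg)
    }
    ssd4 <- ssd_tabs$four_vs_single
    if (nrow(ssd4)) {
      ssd4$response <- ssd4$ssd
      an <- rm_anova(ssd4, c("finger", "effort", "constraint"))
      anova_tabs$ssd_four_vs_single <- an
      write_stamped_csv(an, file.path(cfg$out_dir,
                                      "anova_ssd_four_vs_single.csv"), cfg)
    }
    # two-way designs on the remaining SSD contrasts
    sdys <- ssd_tabs$dynamic_vs_static
    if (nrow(sdys)) {
      sdys$response <- sdys$ssd
      an <- rm_anova(sdys, c("finger", "effort"))
      anova_tabs$ssd_dynamic_vs_static <- an
      write_stamped_csv(an, file.path(cfg$out_dir,
                                      "anova_ssd_dynamic_vs_static.csv"), cfg)
    }
    shl <- ssd_tabs$high_vs_low
    if (nrow(shl)) {
      shl$response <- shl$ssd
      an <- rm_anova(shl, c("finger", "constraint"))
      anova_tabs$ssd_high_vs_low <- an
      write_stamped_csv(an, file.path(cfg$out_dir,
                                      "anova_ssd_high_vs_low.csv"), cfg)
    }
  } else {
    say("single subject or partial design: group statistics skipped ",
        "(noted in report)")
    writeLines("group statistics skipped: need >= 2 subjects with the full
20-condition design", file.path(cfg$out_dir, "NO_GROUP_STATS.txt"))
  }

  # display maps (subject-average per condition), interpolated for display
  say("writing display maps...")
  cond_ids <- unique(unlist(lapply(res$maps, names)))
  map_dir <- file.path(cfg$out_dir, "maps")
  dir.create(map_dir, showWarnings = FALSE)
  for (cid in cond_ids) {
    ms <- lapply(res$maps, function(x) x[[cid]])
    ms <- ms[!vapply(ms, is.null, logical(1))]
    if (!length(ms)) next
    avg <- Reduce(`+`, lapply(ms, function(m) m$values)) / length(ms)
    avg_map <- build_map(as.numeric(t(avg)), grid, condition = cid)
    write_map(avg_map, file.path(map_dir, paste0(cid, ".tsv")))
    dense <- interpolate_for_display(avg_map, cfg$interpolation_factor)
    utils::write.table(dense,
                       file.path(map_dir, paste0(cid, "_display.tsv")),
                       sep = "\t", row.names = FALSE, col.names = FALSE)
  }
  say("done: ", cfg$out_dir)
  invisible(list(summary = res$summary, ssd = ssd_tabs, anova = anova_tabs,
                 maps = res$maps, out_dir = cfg$out_dir))
}

cli_exit_usage <- 64L    # bad flags / unknown subcommand
cli_exit_data <- 65L     # malformed input data
cli_exit_internal <- 70L # unexpected failure

#' Command-line entry point
#'
#' Subcommands: `simulate` (write synthetic recordings),
#' `preprocess` (filter a recording file and write per-condition RMS
#' vectors), `map` (RMS vector or matrix file to map, centroid, SSD),
#' `stats` (repeated-measures ANOVA on a tidy CSV), and `report` (full
#' [run_analysis()] pipeline).  Run with `--help` after a subcommand for
#' its flags.  Designed to be called from a launcher script, e.g.
#' `Rscript -e 'semgmap::semg_cli()' report --seed 1 --out-dir out`.
#'
#' @param args Character vector of CLI arguments (defaults to the
#'   command line).
#' @return Integer exit code, invisibly (0 on success; usage errors 64,
#'   data errors 65, internal errors 70).
#' @export
semg_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0 || args[1] %in% c("-h", "--help")) {
    cat("usage: semg_cli <simulate|preprocess|map|stats|report> [flags]\n")
    return(invisible(if (length(args) == 0) cli_exit_usage else 0L))
  }
  sub <- args[1]
  rest <- args[-1]
  handler <- switch(sub,
                    simulate = cli_simulate,
                    preprocess = cli_preprocess,
                    map = cli_map,
                    stats = cli_stats,
                    report = cli_report,
                    NULL)
  if (is.null(handler)) {
    message("unknown subcommand: ", sub)
    return(invisible(cli_exit_usage))
  }
  code <- tryCatch(handler(rest),
    data_error = function(e) { message("data error: ",
                                       conditionMessage(e)); cli_exit_data },
    error = function(e) { message("error: ", conditionMessage(e))
                          cli_exit_internal })
  invisible(if (is.null(code)) 0L else code)
}

data_stop <- function(...) {
  stop(structure(class = c("data_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

cli_simulate <- function(args) {
  spec <- list(
    optparse::make_option("--out-dir", type = "character",
                          default = "sim-out", dest = "out_dir"),
    optparse::make_option("--seed", type = "integer", default = 20151006L),
    optparse::make_option("--noise-rms", type = "double", default = 0.05,
                          dest = "noise_rms"),
    optparse::make_option("--finger", type = "character", default = "index"),
    optparse::make_option("--effort", type = "character", default = "high"),
    optparse::make_option("--constraint", type = "character",
                          default = "dynamic")
  )
  o <- optparse::parse_args(optparse::OptionParser(option_list = spec),
                            args = args)
  cfg <- simulation_config(noise_rms = o$noise_rms, seed = o$seed)
  sim <- simulate_recording(cfg, o$finger, o$effort, o$constraint)
  dir.create(o$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- file.path(o$out_dir, sprintf("%s_%s_%s.tsv", o$finger, o$effort,
                                    o$constraint))
  write_recording(sim$recording, p)
  write_map(sim$truth$map, file.path(o$out_dir, "truth_map.tsv"))
  message("wrote ", p, " (+ sidecar, truth map)")
  0L
}

cli_preprocess <- function(args) {
  spec <- list(
    optparse::make_option("--recording", type = "character"),
    optparse::make_option("--out", type = "character", default = "rms.tsv"),
    optparse::make_option("--no-floor", action = "store_true",
                          default = FALSE, dest = "no_floor")
  )
  o <- optparse::parse_args(optparse::OptionParser(option_list = spec),
                            args = args)
  if (is.null(o$recording)) data_stop("--recording is required")
  if (!file.exists(o$recording)) {
    data_stop("missing recording file: ", o$recording,
              " (run the `simulate` stage first, or point --recording at ",
              "an existing matrix file)")
  }
  rec <- read_recording(o$recording)
  rec <- emg_bandpass(rec)
  rms <- condition_rms(rec, floor_at_zero = !o$no_floor)
  utils::write.table(data.frame(channel = seq_along(rms), rms = rms),
                     o$out, sep = "\t", row.names = FALSE)
  message("wrote ", o$out)
  0L
}

cli_map <- function(args) {
  spec <- list(
    optparse::make_option("--rms", type = "character",
                          help = "per-channel RMS table from `preprocess`"),
    optparse::make_option("--matrix", type = "character",
                          help = "alternatively, a raw rows x cols matrix"),
    optparse::make_option("--rows", type = "integer", default = 7L),
    optparse::make_option("--cols", type = "integer", default = 9L),
    optparse::make_option("--out", type = "character", default = "map.tsv")
  )
  o <- optparse::parse_args(optparse::OptionParser(option_list = spec),
                            args = args)
  if (!is.null(o$matrix)) {
    if (!file.exists(o$matrix)) data_stop("missing matrix file: ", o$matrix)
    m <- as.matrix(utils::read.table(o$matrix))
    grid <- build_grid(nrow(m), ncol(m))
    map <- build_map(as.numeric(t(m)), grid)
  } else if (!is.null(o$rms)) {
    if (!file.exists(o$rms)) {
      data_stop("missing RMS file: ", o$rms, " (run `preprocess` first)")
    }
    v <- utils::read.table(o$rms, header = TRUE)$rms
    grid <- build_grid(o$rows, o$cols)
    map <- build_map(v, grid)
  } else {
    data_stop("one of --rms or --matrix is required")
  }
  write_map(map, o$out)
  cen <- map_centroid(map)
  cat(sprintf("centroid: cx = %.4f%% circumference, cy = %.4f%% length\n",
              cen[["cx"]], cen[["cy"]]))
  0L
}

cli_stats <- function(args) {
  spec <- list(
    optparse::make_option("--table", type = "character"),
    optparse::make_option("--factors", type = "character",
                          default = "finger,effort,constraint"),
    optparse::make_option("--response", type = "character",
                          default = "response"),
    optparse::make_option("--out", type = "character", default = "anova.csv")
  )
  o <- optparse::parse_args(optparse::OptionParser(option_list = spec),
                            args = args)
  if (is.null(o$table)) data_stop("--table is required")
  if (!file.exists(o$table)) data_stop("missing table: ", o$table)
  tab <- read_stamped_csv(o$table)
  n_subj <- length(unique(tab$subject))
  if (n_subj < 2) data_stop("insufficient data: repeated-measures ANOVA ",
                            "needs >= 2 subjects, got ", n_subj)
  res <- rm_anova(tab, strsplit(o$factors, ",")[[1]],
                  response = o$response)
  utils::write.csv(res, o$out, row.names = FALSE)
  message("wrote ", o$out)
  0L
}

cli_report <- function(args) {
  spec <- list(
    optparse::make_option("--config", type = "character", default = NULL),
    optparse::make_option("--seed", type = "integer", default = NULL),
    optparse::make_option("--subjects", type = "integer", default = NULL,
                          dest = "n_subjects"),
    optparse::make_option("--out-dir", type = "character", default = NULL,
                          dest = "out_dir"),
    optparse::make_option("--quiet", action = "store_true", default = FALSE)
  )
  o <- optparse::parse_args(optparse::OptionParser(option_list = spec),
                            args = args)
  cfg <- pipeline_config(seed = o$seed, n_subjects = o$n_subjects,
                         out_dir = o$out_dir, file = o$config)
  run_analysis(cfg, verbose = !o$quiet)
  0L
}
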