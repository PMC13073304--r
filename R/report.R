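REPORT_SCHEMA_VERSION <- "1.0"

#' Run the full screening and risk pipeline
#'
#' Executes the four analysis stages on a samples CSV — QC acceptance,
#' detection-frequency and compliance screening, chemometrics
#' (correlation, PCA, Ward clustering, outlier flagging), and
#' deterministic risk assessment — and writes a report bundle to
#' `outdir`: `report.json` plus `risk.csv`, `exceedance.csv`,
#' `pca_scores.csv`, `correlation.csv` and `dendrogram.nwk`. Reruns on
#' identical inputs produce byte-identical outputs.
#'
#' @param samples_path Samples CSV (see [read_samples()]).
#' @param qc_path QC CSV (element, recovery_pct, rsd_pct, lod, loq);
#'   `NULL` uses the packaged [reference_qc()] table.
#' @param standard Name of a packaged standard (see
#'   [regulatory_standard()]) or a `regulatory_standard` object.
#' @param scenario An [exposure_scenario()], or path to a JSON scenario
#'   config; `NULL` uses [default_scenario()].
#' @param outdir Output directory (created if needed).
#' @param summary_policy Censoring policy for chemometrics and
#'   summaries (default `"half_loq"`).
#' @param risk_policy Censoring policy for dose computation (default
#'   `"zero"`).
#' @return The report, invisibly (a named list mirroring
#'   `report.json`).
#' @export
run_pipeline <- function(samples_path, qc_path = NULL,
                         standard = "efsa_2020_640", scenario = NULL,
                         outdir = ".", summary_policy = "half_loq",
                         risk_policy = "zero") {
  qc <- if (is.null(qc_path)) {
    reference_qc()
  } else {
    if (!file.exists(qc_path)) stop_io("QC file not found: ", qc_path)
    validate_qc_table(read.csv(qc_path, stringsAsFactors = FALSE))
  }
  if (is.character(standard)) standard <- regulatory_standard(standard)
  scenario <- load_scenario(scenario)
  samples <- read_samples(samples_path, qc = qc)
  if (n_samples(samples) == 0L) stop("samples file has no rows: ", samples_path)

  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  verdict <- evaluate_qc(qc)
  cens <- censoring_summary(samples)
  detfreq <- lapply(setNames(nm = PROPOLIS_ELEMENTS), function(el) {
    detection_frequency(samples, el, rounding = "two_dp")
  })

  screen <- screen_samples(samples, standard)
  exceed <- screen[screen$verdict == "exceed", ]
  mn_max <- max(concentration_matrix(samples, summary_policy)[, "Mn"])
  mn_chk <- mn_intake_check(mn_max, scenario$ingr,
                            bound = standard$mn_intake_bound_mg_day %||% 3)

  corr <- correlation_report(samples, policy = summary_policy)
  pca <- run_pca(samples, policy = summary_policy)
  dendro <- ward_cluster(samples, policy = summary_policy)
  outliers <- flag_outliers(pca)

  risk <- assess_dataset(samples, scenario, policy = risk_policy)

  write.csv(risk, file.path(outdir, "risk.csv"), row.names = FALSE)
  write.csv(exceed, file.path(outdir, "exceedance.csv"), row.names = FALSE)
  write.csv(data.frame(sample_id = rownames(pca$scores), pca$scores),
            file.path(outdir, "pca_scores.csv"), row.names = FALSE)
  write.csv(data.frame(element = rownames(corr$matrix), corr$matrix),
            file.path(outdir, "correlation.csv"), row.names = FALSE)
  export_newick(dendro, file.path(outdir, "dendrogram.nwk"))

  report <- list(
    schema_version = REPORT_SCHEMA_VERSION,
    qc = verdict,
    censoring = cens,
    detection_frequency = detfreq,
    exceedance = list(
      standard = standard$name,
      n_exceedances = nrow(exceed),
      records = exceed[, c("sample_id", "element", "value", "limit", "rule")]
    ),
    mn_intake = list(max_concentration_ppm = mn_max,
                     intake_mg_day = mn_chk$intake_mg_day,
                     exceeds = mn_chk$exceeds),
    correlation = list(matrix = corr$matrix, labels = corr$labels),
    pca = list(explained_variance_pct = as.list(pca$explained_variance_pct),
               loadings = pca$loadings,
               outliers = as.list(outliers)),
    cluster = list(merge = dendro$merge, height = dendro$height,
                   labels = dendro$labels,
                   three_group_cut = as.list(stats::cutree(dendro, k = min(3, n_samples(samples))))),
    risk = risk
  )
  validate_report(report)
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(report)
}

load_scenario <- function(scenario) {
  if (is.null(scenario)) return(default_scenario())
  if (inherits(scenario, "exposure_scenario")) return(scenario)
  if (is.character(scenario)) {
    if (!file.exists(scenario)) stop_io("scenario file not found: ", scenario)
    cfg <- jsonlite::read_json(scenario, simplifyVector = TRUE)
    return(exposure_scenario(ingr = cfg$ingr, ef = cfg$ef, ed = cfg$ed,
                             bw = cfg$bw,
                             at_rule = cfg$at_rule %||% "match_ed",
                             life_expectancy = cfg$life_expectancy %||% 75.5))
  }
  stop("scenario must be NULL, an exposure_scenario, or a JSON path")
}

#' Validate a report against the shipped schema
#'
#' Checks the report's `schema_version` and the presence of every
#' top-level section the packaged `report-schema.json` requires.
#'
#' @param report A report list as produced by [run_pipeline()].
#' @return `TRUE` invisibly; errors describe any violation.
#' @export
validate_report <- function(report) {
  schema <- jsonlite::read_json(
    system.file("extdata", "report-schema.json", package = "propolistox",
                mustWork = TRUE),
    simplifyVector = TRUE)
  if (!identical(report$schema_version, schema$schema_version)) {
    stop("report schema_version ", report$schema_version,
         " does not match schema ", schema$schema_version)
  }
  miss <- setdiff(schema$required, names(report))
  if (length(miss)) stop("report is missing section(s): ",
                         paste(miss, collapse = ", "))
  invisible(TRUE)
}

#' Write the 12-sample reference fixture to CSV
#'
#' @param path Output CSV path.
#' @param seed Fixture seed (see [build_paper_fixture()]).
#' @return `path`, invisibly.
#' @export
make_fixture <- function(path, seed = 1L) {
  write_samples(build_paper_fixture(seed), path)
}

#' Command-line entry point
#'
#' Dispatches the packaged subcommands. Usage:
#' `propolistox <subcommand> [options]` with subcommands
#' \describe{
#'   \item{fixture}{Write the 12-sample reference fixture
#'     (`--outdir`, `--seed`).}
#'   \item{generate}{Write a synthetic dataset from
#'     [default_paper_spec()] (`--n`, `--seed`, `--outdir`).}
#'   \item{all}{Run the full pipeline (`--input`, `--qc`, `--standard`,
#'     `--scenario`, `--policy`, `--outdir`).}
#'   \item{qc, screen, chemometrics, risk}{Run the full pipeline and
#'     keep only that stage's outputs in the printed summary.}
#' }
#' An executable wrapper is installed at
#' `system.file("cli", "propolistox.R", package = "propolistox")`.
#'
#' @param args Character vector of command-line arguments (default:
#'   the process command line).
#' @return Integer exit status, invisibly: 0 on success, 2 for missing
#'   input files, 1 for other errors.
#' @export
propolistox_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  subcommands <- c("fixture", "generate", "qc", "screen", "chemometrics",
                   "risk", "all")
  if (length(args) == 0L || !args[1] %in% subcommands) {
    message("usage: propolistox {", paste(subcommands, collapse = "|"),
            "} [options]")
    return(invisible(1L))
  }
  sub <- args[1]
  opts <- parse_cli_options(args[-1])

  status <- tryCatch({
    if (sub == "fixture") {
      path <- file.path(opts$outdir, "fixture.csv")
      dir.create(opts$outdir, recursive = TRUE, showWarnings = FALSE)
      make_fixture(path, seed = opts$seed)
      if (opts$verbose) message("wrote ", path)
    } else if (sub == "generate") {
      dir.create(opts$outdir, recursive = TRUE, showWarnings = FALSE)
      path <- file.path(opts$outdir, "synthetic.csv")
      write_samples(generate_samples(default_paper_spec(opts$n, opts$seed)),
                    path)
      if (opts$verbose) message("wrote ", path)
    } else {
      if (is.null(opts$input)) stop("--input is required for '", sub, "'")
      report <- run_pipeline(opts$input, qc_path = opts$qc,
                             standard = opts$standard,
                             scenario = opts$scenario, outdir = opts$outdir,
                             risk_policy = opts$policy)
      if (opts$verbose) {
        message("stages complete; report at ",
                file.path(opts$outdir, "report.json"))
      }
      print_stage_summary(sub, report)
    }
    0L
  },
  propolistox_io_error = function(e) {
    message("error: ", conditionMessage(e))
    2L
  },
  error = function(e) {
    message("error in stage '", sub, "': ", conditionMessage(e))
    1L
  })
  invisible(status)
}

parse_cli_options <- function(args) {
  spec <- list(
    optparse::make_option("--input", type = "character", default = NULL),
    optparse::make_option("--qc", type = "character", default = NULL),
    optparse::make_option("--standard", type = "character",
                          default = "efsa_2020_640"),
    optparse::make_option("--scenario", type = "character", default = NULL),
    optparse::make_option("--policy", type = "character", default = "zero"),
    optparse::make_option("--seed", type = "integer", default = 1L),
    optparse::make_option("--n", type = "integer", default = 12L),
    optparse::make_option("--outdir", type = "character", default = "."),
    optparse::make_option("--verbose", action = "store_true", default = FALSE)
  )
  optparse::parse_args(optparse::OptionParser(option_list = spec),
                       args = args)
}

print_stage_summary <- function(sub, report) {
  if (sub %in% c("qc", "all")) {
    cat("QC acceptance:\n"); print(report$qc)
  }
  if (sub %in% c("screen", "all")) {
    cat(sprintf("Exceedances under %s: %d\n",
                report$exceedance$standard, report$exceedance$n_exceedances))
    if (report$exceedance$n_exceedances > 0) {
      print(report$exceedance$records, row.names = FALSE)
    }
  }
  if (sub %in% c("chemometrics", "all")) {
    cat("PCA explained variance (%):\n")
    print(unlist(report$pca$explained_variance_pct))
    cat("PCA outliers:", paste(unlist(report$pca$outliers), collapse = ", "),
        "\n")
  }
  if (sub %in% c("risk", "all")) {
    cat("Max HQ:", max(report$risk$hq), "  Max CR:",
        max(report$risk$cr, na.rm = TRUE), "\n")
  }
  invisible(NULL)
}
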