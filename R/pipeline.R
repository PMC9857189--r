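#' Pipeline configuration
#'
#' Reads the JSON config used by the `giscan` command-line script and the
#' `run_*` stage functions, fills defaults, and applies overrides (CLI flags
#' win over file values).
#'
#' Recognised keys: `out_dir`, `data_dir` (a [write_cohort()]-layout
#' directory with `panel.tsv`, `bins.tsv`, `controls/`, `patients/`,
#' `clinical.csv`), `seed`, `z_amp`, `z_del`, `gi_features` (`"bin"` or
#' `"gene"`), `include_sex_chroms`, `norm` (a list of [norm_config()]
#' arguments), `sim` (a list of [sim_config()] arguments), `make_plots`.
#'
#' @param path optional JSON file.
#' @param overrides named list merged over the file values.
#' @return a `pipeline_config` list with a `hash` fingerprint.
#' @export
pipeline_config <- function(path = NULL, overrides = list()) {
  cfg <- list(out_dir = ".", data_dir = NULL, seed = 1,
              z_amp = 2, z_del = -2, gi_features = "bin",
              include_sex_chroms = FALSE, norm = list(), sim = list(),
              make_plots = FALSE)
  if (!is.null(path)) {
    if (!file.exists(path)) stop_giscan("config file not found: %s", path)
    file_cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
    unknown <- setdiff(names(file_cfg), names(cfg))
    if (length(unknown) > 0)
      stop_giscan("unknown config key(s): %s", paste(unknown, collapse = ", "))
    cfg[names(file_cfg)] <- file_cfg
  }
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown) > 0)
    stop_giscan("unknown config key(s): %s", paste(unknown, collapse = ", "))
  cfg[names(overrides)] <- overrides
  cfg$hash <- fnv1a(jsonlite::toJSON(cfg[sort(names(cfg))], auto_unbox = TRUE))
  class(cfg) <- "pipeline_config"
  cfg
}

table_header <- function(config) {
  sprintf("# giscan %s config=%s",
          as.character(utils::packageVersion("giscan")), config$hash)
}

write_stamped_table <- function(tab, path, config) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(table_header(config), con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_manifest <- function(config, stage, inputs, outputs) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(stage = stage, package_version = as.character(utils::packageVersion("giscan")),
         config_hash = config$hash, timestamp = format(Sys.time(), tz = "UTC"),
         inputs = inputs, outputs = outputs),
    file.path(config$out_dir, sprintf("manifest_%s.json", stage)),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

log_msg <- function(fmt, ...) {
  message(sprintf(paste0("[giscan] ", fmt), ...))
}

#' Pipeline stage: simulate a cohort to disk
#'
#' @param config a [pipeline_config()].
#' @return output directory, invisibly.
#' @export
run_simulate <- function(config) {
  sim_args <- config$sim
  sim_args$seed <- sim_args$seed %||% config$seed
  cfg <- do.call(sim_config, sim_args)
  cohort <- simulate_cohort(cfg)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  write_cohort(cohort, config$out_dir)
  log_msg("simulated %d controls + %d patients into %s",
          cfg$n_controls, cfg$n_patients, config$out_dir)
  write_manifest(config, "simulate", inputs = list(seed = cfg$seed),
                 outputs = list(dir = config$out_dir))
  invisible(config$out_dir)
}

read_profile_dir <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.tsv$", full.names = TRUE))
  lapply(files, read_depth_profile)
}

#' Pipeline stage: normalize, reference, Z-score, call, Gi
#'
#' Chains LOESS GC normalization of every sample, the healthy-control
#' reference model, per-patient Z-scores, threshold CNV calls over the gene
#' panel, and Gi scores for all samples. Writes `z_matrix.tsv`,
#' `cnv_calls.tsv` and `gi_scores.tsv` (each stamped with the package
#' version and config hash) into `out_dir`.
#'
#' @param config a [pipeline_config()] whose `data_dir` holds the cohort.
#' @return list with the in-memory results, invisibly.
#' @export
run_score <- function(config) {
  if (is.null(config$data_dir)) stop_giscan("config needs data_dir")
  dd <- config$data_dir
  panel <- load_gene_panel(file.path(dd, "panel.tsv"))
  controls <- read_profile_dir(file.path(dd, "controls"))
  patients <- read_profile_dir(file.path(dd, "patients"))
  if (length(controls) == 0) stop_giscan("no control profiles in %s", dd)
  if (length(patients) == 0) stop_giscan("no patient profiles in %s", dd)
  ncfg <- do.call(norm_config, config$norm)
  controls <- lapply(controls, loess_gc_normalize, cfg = ncfg)
  patients <- lapply(patients, loess_gc_normalize, cfg = ncfg)
  ref <- build_reference(controls)
  z_controls <- lapply(controls, zscore, ref = ref)
  z_patients <- lapply(patients, zscore, ref = ref)
  n_flagged <- sum(!is.na(patients[[1]]$flag))
  log_msg("scored %d patients against %d controls over %d features (%d flagged)",
          length(patients), length(controls), length(ref$feature_ids), n_flagged)

  calls <- do.call(rbind, lapply(z_patients, cnv_call_table, panel = panel,
                                 z_amp = config$z_amp, z_del = config$z_del))
  z_all <- c(z_controls, z_patients)
  zmat <- data.frame(feature_id = z_all[[1]]$feature_id,
                     check.names = FALSE)
  for (zp in z_all) zmat[[attr(zp, "sample_id")]] <- zp$z
  gi <- do.call(rbind, lapply(z_all, function(zp) {
    g <- gi_score(zp, features = config$gi_features,
                  include_sex_chroms = config$include_sex_chroms)
    data.frame(sample_id = g$sample_id, gi = g$gi, n_features = g$n_features,
               cohort = if (g$sample_id %in% vapply(z_controls, attr, "", "sample_id"))
                 "control" else "patient",
               stringsAsFactors = FALSE)
  }))

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  write_stamped_table(zmat, file.path(config$out_dir, "z_matrix.tsv"), config)
  write_stamped_table(calls, file.path(config$out_dir, "cnv_calls.tsv"), config)
  write_stamped_table(gi, file.path(config$out_dir, "gi_scores.tsv"), config)
  write_manifest(config, "score",
                 inputs = list(data_dir = dd, n_controls = length(controls),
                               n_patients = length(patients)),
                 outputs = list(z_matrix = "z_matrix.tsv",
                                cnv_calls = "cnv_calls.tsv",
                                gi_scores = "gi_scores.tsv"))
  invisible(list(reference = ref, calls = calls, z_matrix = zmat, gi = gi))
}

#' Pipeline stage: survival integration
#'
#' Runs the per-gene DFS and OS univariate screens (with the eligibility
#' rules) over the call table from [run_score()], and the median-CA125
#' four-subgroup analysis for every DFS-eligible gene. Patients without OS
#' follow-up are dropped from OS analyses (and the analyzed n logged), not
#' censored at zero. Writes `gene_screens.tsv`, `ca125_subgroups.tsv` and
#' `ca125_subgroup_tests.tsv`; with `make_plots = TRUE`, KM panels as PNG.
#'
#' @param config a [pipeline_config()]; expects `cnv_calls.tsv` in `out_dir`
#'   (or `data_dir`) and `clinical.csv` in `data_dir`.
#' @return list with the screen and subgroup tables, invisibly.
#' @export
run_survival <- function(config) {
  calls_path <- file.path(config$out_dir, "cnv_calls.tsv")
  if (!file.exists(calls_path))
    calls_path <- file.path(config$data_dir, "cnv_calls.tsv")
  if (!file.exists(calls_path)) stop_giscan("cnv_calls.tsv not found; run score first")
  calls <- read.delim(calls_path, comment.char = "#", stringsAsFactors = FALSE)
  clinical <- read_clinical(file.path(config$data_dir, "clinical.csv"))
  genes <- unique(calls$gene)
  pid <- clinical$patient_id

  group_for <- function(gene) {
    g <- calls[calls$gene == gene, ]
    grp <- g$group[match(pid, g$sample_id)]
    if (any(is.na(grp)))
      stop_giscan("patients missing from call table for %s: %s", gene,
                  paste(pid[is.na(grp)], collapse = ", "))
    grp
  }

  os_ok <- !is.na(clinical$os_months) & !is.na(clinical$os_event)
  log_msg("OS analyses use %d of %d patients (%d without OS follow-up)",
          sum(os_ok), nrow(clinical), sum(!os_ok))

  screens <- do.call(rbind, lapply(genes, function(gene) {
    grp <- group_for(gene)
    dfs <- univariate_gene_screen(
      grp, data.frame(time = clinical$dfs_months, event = clinical$dfs_event),
      endpoint = "DFS")
    os <- univariate_gene_screen(
      grp[os_ok], data.frame(time = clinical$os_months[os_ok],
                             event = clinical$os_event[os_ok]),
      endpoint = "OS")
    rbind(
      data.frame(gene = gene, endpoint = "DFS", n = nrow(clinical),
                 n_carriers = dfs$n_carriers,
                 n_carrier_events = dfs$n_carrier_events,
                 chi_square = dfs$chi_square, p = dfs$p,
                 eligible = dfs$eligible, stringsAsFactors = FALSE),
      data.frame(gene = gene, endpoint = "OS", n = sum(os_ok),
                 n_carriers = os$n_carriers,
                 n_carrier_events = os$n_carrier_events,
                 chi_square = os$chi_square, p = os$p,
                 eligible = os$eligible, stringsAsFactors = FALSE))
  }))
  # BH-adjusted p for information only; the screening rule itself uses raw p
  screens$p_bh <- NA_real_
  for (ep in c("DFS", "OS")) {
    sel <- screens$endpoint == ep & !is.na(screens$p)
    screens$p_bh[sel] <- stats::p.adjust(screens$p[sel], method = "BH")
  }

  eligible_genes <- unique(screens$gene[screens$endpoint == "DFS" &
                                          screens$eligible])
  sub_rows <- list()
  test_rows <- list()
  for (gene in eligible_genes) {
    grp <- group_for(gene)
    for (ep in c("DFS", "OS")) {
      rec <- if (ep == "OS") clinical[os_ok, ] else clinical
      g <- if (ep == "OS") grp[os_ok] else grp
      res <- tryCatch(suppressWarnings(ca125_subgroups(g, rec, endpoint = ep)),
                      error = function(e) NULL)
      if (is.null(res)) next
      sub <- res$subgroups
      sub$gene <- gene
      sub$endpoint <- ep
      sub_rows[[paste(gene, ep)]] <- sub
      test_rows[[paste(gene, ep)]] <- data.frame(
        gene = gene, endpoint = ep, median_ca125 = res$median_ca125,
        chi_square = res$logrank$chi_square, df = res$logrank$df,
        p = res$logrank$p, stringsAsFactors = FALSE)
      if (isTRUE(config$make_plots)) {
        png_path <- file.path(config$out_dir,
                              sprintf("km_%s_%s.png", gene, ep))
        grDevices::png(png_path, width = 720, height = 540)
        outc <- if (ep == "OS") {
          data.frame(time = rec$os_months, event = rec$os_event)
        } else {
          data.frame(time = rec$dfs_months, event = rec$dfs_event)
        }
        plot_km(outc, sub$label[match(rec$patient_id, sub$patient_id)],
                main = sprintf("%s %s by CNV/CA125 subgroup", gene, ep))
        grDevices::dev.off()
      }
    }
  }
  subgroups <- do.call(rbind, sub_rows)
  subgroup_tests <- do.call(rbind, test_rows)

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  write_stamped_table(screens, file.path(config$out_dir, "gene_screens.tsv"),
                      config)
  if (!is.null(subgroups))
    write_stamped_table(subgroups,
                        file.path(config$out_dir, "ca125_subgroups.tsv"), config)
  if (!is.null(subgroup_tests))
    write_stamped_table(subgroup_tests,
                        file.path(config$out_dir, "ca125_subgroup_tests.tsv"),
                        config)
  write_manifest(config, "survival",
                 inputs = list(calls = calls_path,
                               n_patients = nrow(clinical),
                               n_os_analyzed = sum(os_ok)),
                 outputs = list(screens = "gene_screens.tsv"))
  invisible(list(screens = screens, subgroups = subgroups,
                 subgroup_tests = subgroup_tests))
}

#' Pipeline stage: summary report
#'
#' Collates the Gi comparison (patients vs controls) and the headline screen
#' results into `report.json`.
#'
#' @param config a [pipeline_config()].
#' @return the report list, invisibly.
#' @export
run_report <- function(config) {
  gi <- read.delim(file.path(config$out_dir, "gi_scores.tsv"),
                   comment.char = "#", stringsAsFactors = FALSE)
  screens <- read.delim(file.path(config$out_dir, "gene_screens.tsv"),
                        comment.char = "#", stringsAsFactors = FALSE)
  cmp <- compare_gi(gi$gi[gi$cohort == "patient"],
                    gi$gi[gi$cohort == "control"])
  hits <- screens[screens$eligible & !is.na(screens$p) & screens$p < 0.05, ]
  report <- list(
    gi_wilcoxon_p = cmp$p,
    gi_median_patient = median(gi$gi[gi$cohort == "patient"]),
    gi_median_control = median(gi$gi[gi$cohort == "control"]),
    significant_screens = hits[order(hits$p), c("gene", "endpoint", "p")])
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_manifest(config, "report", inputs = list(out_dir = config$out_dir),
                 outputs = list(report = "report.json"))
  invisible(report)
}
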