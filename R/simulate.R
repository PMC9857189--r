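#' Simulation configuration
#'
#' Describes the synthetic world the generator emulates: a cohort of healthy
#' controls and ovarian-cancer patients profiled by shallow WGS on a compact
#' synthetic genome, with GC-biased negative-binomial coverage, panel-gene
#' CNV events diluted by tumor fraction, background instability segments, and
#' clinical outcomes whose hazards depend on planted CNV status.
#'
#' Defaults mirror the motivating study's design: 20 controls, 40 patients,
#' 100 kb bins, ~5x fold-coverage (the per-sample coverage actually measured
#' there), and the 33-gene panel relocated onto the synthetic genome with its
#' real gene lengths. A planted amplification is copy state 4 (+2 copies) and
#' a deletion copy state 0; the observed depth ratio over a planted segment
#' follows the standard cfDNA mixture dilution `1 + tf * (cs - 2) / 2` at
#' tumor fraction `tf`.
#'
#' @param seed master seed; all randomness flows from it via named
#'   substreams (genome, controls, patients, events, survival, ca125).
#' @param n_controls,n_patients cohort sizes (defaults 20 / 40).
#' @param bin_size bin width in bp (default 100,000).
#' @param genome named vector of synthetic chromosome lengths; default four
#'   25 Mb chromosomes (1,000 bins at the default bin size). Panel genes are
#'   placed on all but the last chromosome; background instability segments
#'   are drawn on the last, so planted gene truth stays unambiguous.
#' @param mean_depth fold-coverage (default 5).
#' @param read_length nominal read length in bp (default 100).
#' @param gc_bias `"none"`, `"linear"` or `"quadratic"` (default) shape of
#'   the coverage-vs-GC curve.
#' @param gc_bias_amplitude fractional depth change across the GC range
#'   (default 0.3).
#' @param gc_center GC at which the bias curve is centred (default 0.45).
#' @param gc_beta_conc concentration of the Beta distribution generating
#'   per-feature GC (mean 0.42; default concentration 60 gives SD ~0.06,
#'   human-like 100 kb bins).
#' @param overdispersion negative-binomial overdispersion of bin counts
#'   (`var = mu + overdispersion * mu^2`); 0 means Poisson. Default 0.005
#'   (~7% extra-Poisson CV, mid-range for GC-corrected shallow-WGS bins).
#' @param tumor_fraction_range per-patient tumor fraction is drawn uniformly
#'   from this interval (default \[0.2, 0.8\]).
#' @param amp_copy_state,del_copy_state planted copy states (defaults 4 / 0).
#' @param event_pad bp added on each side of an altered gene to form its
#'   planted segment (default 50,000).
#' @param n_background_segments,background_segment_size per-patient count and
#'   size of background instability segments (defaults 3 and 5 Mb).
#' @param dfs_hazard_ratio_per_flag,os_hazard_ratio_per_flag multiplicative
#'   hazard per planted risk-gene event (defaults 6).
#' @param risk_genes genes whose planted events carry the hazard ratio
#'   (default `"RAB25"`).
#' @param dfs_median_null,os_median_null baseline median event times in
#'   months for non-carriers (defaults 30 / 60).
#' @param censor_range administrative censoring window in months (default
#'   \[36, 72\]).
#' @param ca125_meanlog,ca125_sdlog log-normal CA125 parameters; defaults
#'   `log(575.5)` (the study's median) and 1.5.
#' @param ca125_shift_per_event upward shift of `meanlog` per planted gene
#'   event (default 0.15).
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1,
                       n_controls = 20, n_patients = 40,
                       bin_size = 100000,
                       genome = c(chrS1 = 25e6, chrS2 = 25e6,
                                  chrS3 = 25e6, chrS4 = 25e6),
                       mean_depth = 5, read_length = 100,
                       gc_bias = c("quadratic", "linear", "none"),
                       gc_bias_amplitude = 0.3, gc_center = 0.45,
                       gc_beta_conc = 60,
                       overdispersion = 0.005,
                       tumor_fraction_range = c(0.2, 0.8),
                       amp_copy_state = 4, del_copy_state = 0,
                       event_pad = 50000,
                       n_background_segments = 3,
                       background_segment_size = 5e6,
                       dfs_hazard_ratio_per_flag = 6,
                       os_hazard_ratio_per_flag = 6,
                       risk_genes = "RAB25",
                       dfs_median_null = 30, os_median_null = 60,
                       censor_range = c(36, 72),
                       ca125_meanlog = log(575.5), ca125_sdlog = 1.5,
                       ca125_shift_per_event = 0.15) {
  gc_bias <- match.arg(gc_bias)
  if (n_controls < 2) stop_giscan("n_controls must be >= 2")
  if (overdispersion < 0) stop_giscan("overdispersion must be >= 0")
  if (any(tumor_fraction_range < 0 | tumor_fraction_range > 1))
    stop_giscan("tumor_fraction_range must lie in [0, 1]")
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

# GC-dependent coverage efficiency, >= 0.05. Quadratic peaks at gc_center
# and falls toward both GC extremes, the shape seen in real libraries.
gc_bias_factor <- function(cfg, gc) {
  x <- (gc - cfg$gc_center) / 0.25
  b <- switch(cfg$gc_bias,
              none = rep(1, length(gc)),
              linear = 1 + cfg$gc_bias_amplitude * x,
              quadratic = 1 + cfg$gc_bias_amplitude * (1 - x^2))
  pmax(b, 0.05)
}

#' Expected depth under the cfDNA dilution model
#'
#' `mean_depth * bias(gc) * (1 + tf * (copy_state - 2) / 2)`: copy state 4 at
#' tumor fraction 1 doubles the expected depth; copy state 3 at tf 0.5 gives
#' a 1.25 ratio; tf 0 is flat regardless of the planted state.
#'
#' @param cfg a [sim_config()].
#' @param gc GC fraction(s).
#' @param copy_state planted copy state(s), diploid = 2.
#' @param tf tumor fraction in \[0, 1\].
#' @return expected fold-coverage per feature.
#' @export
expected_depth <- function(cfg, gc, copy_state = 2, tf = 0) {
  if (any(tf < 0 | tf > 1)) stop_giscan("tumor fraction must be in [0, 1]")
  cfg$mean_depth * gc_bias_factor(cfg, gc) * (1 + tf * (copy_state - 2) / 2)
}

# Synthetic genome: bin grid with GC, plus the panel genes relocated onto the
# non-background chromosomes at even spacing (real gene lengths preserved).
sim_genome <- function(cfg, panel = load_gene_panel(default_panel_path())) {
  grid <- make_bin_grid(cfg$genome, cfg$bin_size)
  with_seed(sub_seed(cfg$seed, "genome"), {
    a <- 0.42 * cfg$gc_beta_conc
    b <- cfg$gc_beta_conc - a
    grid$gc <- rbeta(nrow(grid), a, b)
    gene_chroms <- names(cfg$genome)[-length(cfg$genome)]
    n_per <- ceiling(nrow(panel) / length(gene_chroms))
    placed <- panel
    for (i in seq_len(nrow(panel))) {
      ci <- ((i - 1) %% length(gene_chroms)) + 1
      slot <- ((i - 1) %/% length(gene_chroms)) + 1
      span <- cfg$genome[[gene_chroms[ci]]] / (n_per + 1)
      len <- panel$end[i] - panel$start[i]
      placed$chrom[i] <- gene_chroms[ci]
      placed$start[i] <- round(slot * span)
      placed$end[i] <- placed$start[i] + len
    }
    placed$gc <- rbeta(nrow(panel), a, b)
    list(grid = grid, panel = validate_gene_panel(placed),
         background_chrom = names(cfg$genome)[length(cfg$genome)])
  })
}

# copy-state factor per feature given planted events, weighted by overlap
event_factor <- function(features, events, tf) {
  fac <- rep(1, nrow(features))
  if (is.null(events) || nrow(events) == 0 || tf == 0) return(fac)
  for (i in seq_len(nrow(events))) {
    ev <- events[i, ]
    same <- features$chrom == ev$chrom
    ov <- pmin(features$end, ev$end) - pmax(features$start, ev$start)
    hit <- same & ov > 0
    frac <- pmin(1, ov[hit] / (features$end[hit] - features$start[hit]))
    fac[hit] <- fac[hit] * (1 + frac * tf * (ev$copy_state - 2) / 2)
  }
  pmax(fac, 0)
}

#' Simulate one sample's depth profile
#'
#' Draws per-feature read counts from a negative binomial with mean
#' `expected_depth(...) * feature_length / read_length`, converts back to
#' mean depth, and returns a `depth_profile`. Deterministic given `seed`.
#'
#' @param features feature frame (bins and/or genes) with `gc`; typically
#'   from the internal synthetic genome of [simulate_cohort()].
#' @param cfg a [sim_config()].
#' @param planted data frame of events (`chrom`, `start`, `end`,
#'   `copy_state`) or `NULL`.
#' @param tf tumor fraction in \[0, 1\].
#' @param seed RNG seed for this sample.
#' @param sample_id sample identifier.
#' @return a `depth_profile`.
#' @export
simulate_sample <- function(features, cfg, planted = NULL, tf = 0, seed = 1,
                            sample_id = "sim") {
  if (length(tf) != 1 || tf < 0 || tf > 1)
    stop_giscan("tumor fraction must be a scalar in [0, 1]")
  if (!is.null(planted) && nrow(planted) > 0) {
    lens <- setNames(as.numeric(cfg$genome), names(cfg$genome))
    out_of_bounds <- !(planted$chrom %in% names(lens)) |
      planted$start < 0 | planted$end > lens[planted$chrom]
    if (any(out_of_bounds))
      stop_giscan("planted event outside genome bounds")
  }
  len <- features$end - features$start
  mu_depth <- cfg$mean_depth * gc_bias_factor(cfg, features$gc) *
    event_factor(features, planted, tf)
  mu_counts <- mu_depth * len / cfg$read_length
  counts <- with_seed(seed, {
    if (cfg$overdispersion > 0) {
      rnbinom(length(mu_counts), mu = mu_counts, size = 1 / cfg$overdispersion)
    } else {
      rpois(length(mu_counts), mu_counts)
    }
  })
  features$raw_depth <- counts * cfg$read_length / len
  depth_profile(features, sample_id, total_reads = sum(counts))
}

#' Simulate a full control + patient cohort
#'
#' Controls carry no CNV. Each patient alters each panel gene independently
#' with probability equal to the gene's panel `occurring_freq` (amplified
#' genes to `amp_copy_state`, deleted genes to `del_copy_state`), each such
#' event padded to a segment; background instability segments are added on
#' the reserved background chromosome. DFS/OS times are exponential with the
#' hazard multiplied by `*_hazard_ratio_per_flag` per planted risk-gene
#' event; CA125 is log-normal, shifted upward with planted event burden.
#' Everything is reproducible from `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @param panel a `gene_panel`; default the packaged 33-gene panel.
#' @return a `sim_cohort` list: `controls`, `patients` (lists of
#'   `depth_profile`), `clinical` (a `clinical_table`), `truth` (planted
#'   per-gene 0/1 matrix, events, tumor fractions, survival parameters),
#'   `genome` (grid + relocated panel), `config`.
#' @export
simulate_cohort <- function(cfg = sim_config(),
                            panel = load_gene_panel(default_panel_path())) {
  genome <- sim_genome(cfg, panel)
  feats <- rbind(bin_feature_frame(genome$grid),
                 gene_feature_frame(genome$panel))

  controls <- lapply(seq_len(cfg$n_controls), function(i) {
    simulate_sample(feats, cfg, planted = NULL, tf = 0,
                    seed = sub_seed(cfg$seed, sprintf("control_%03d", i)),
                    sample_id = sprintf("HC%02d", i))
  })

  np <- cfg$n_patients
  ng <- nrow(genome$panel)
  truth_groups <- matrix(0L, nrow = np, ncol = ng,
                         dimnames = list(sprintf("OC%02d", seq_len(np)),
                                         genome$panel$gene))
  tfs <- with_seed(sub_seed(cfg$seed, "tumor_fraction"),
                   runif(np, cfg$tumor_fraction_range[1],
                         cfg$tumor_fraction_range[2]))
  alter <- with_seed(sub_seed(cfg$seed, "events"), {
    m <- matrix(runif(np * ng), np, ng)
    sweep(m, 2, genome$panel$occurring_freq, `<`)
  })
  bg_chrom <- genome$background_chrom
  bg_len <- cfg$genome[[bg_chrom]]
  events_by_patient <- vector("list", np)
  with_seed(sub_seed(cfg$seed, "background"), {
    for (i in seq_len(np)) {
      gidx <- which(alter[i, ])
      truth_groups[i, gidx] <- 1L
      gene_ev <- if (length(gidx) > 0) {
        data.frame(
          chrom = genome$panel$chrom[gidx],
          start = pmax(0, genome$panel$start[gidx] - cfg$event_pad),
          end = pmin(cfg$genome[genome$panel$chrom[gidx]],
                     genome$panel$end[gidx] + cfg$event_pad),
          copy_state = ifelse(genome$panel$direction[gidx] == "AMP",
                              cfg$amp_copy_state, cfg$del_copy_state),
          gene = genome$panel$gene[gidx], stringsAsFactors = FALSE)
      } else NULL
      bg_ev <- if (cfg$n_background_segments > 0) {
        starts <- round(runif(cfg$n_background_segments,
                              0, bg_len - cfg$background_segment_size))
        data.frame(chrom = bg_chrom, start = starts,
                   end = starts + cfg$background_segment_size,
                   copy_state = sample(c(1, 3, 4), cfg$n_background_segments,
                                       replace = TRUE),
                   gene = NA_character_, stringsAsFactors = FALSE)
      } else NULL
      events_by_patient[[i]] <- rbind(gene_ev, bg_ev)
    }
  })

  patients <- lapply(seq_len(np), function(i) {
    simulate_sample(feats, cfg, planted = events_by_patient[[i]], tf = tfs[i],
                    seed = sub_seed(cfg$seed, sprintf("patient_%03d", i)),
                    sample_id = sprintf("OC%02d", i))
  })

  clinical <- sim_clinical(cfg, truth_groups, genome$panel)

  truth <- list(gene_groups = truth_groups, events = events_by_patient,
                tumor_fraction = setNames(tfs, rownames(truth_groups)),
                risk_genes = cfg$risk_genes,
                dfs_hazard_ratio = cfg$dfs_hazard_ratio_per_flag,
                os_hazard_ratio = cfg$os_hazard_ratio_per_flag)
  structure(list(controls = controls, patients = patients,
                 clinical = clinical, truth = truth, genome = genome,
                 config = cfg),
            class = "sim_cohort")
}

# Clinical outcomes for simulated patients: exponential DFS/OS with
# per-risk-gene hazard multipliers, administrative censoring, log-normal
# CA125 shifted with event burden, Table-1-like stage/histology mix.
sim_clinical <- function(cfg, truth_groups, panel) {
  np <- nrow(truth_groups)
  ids <- rownames(truth_groups)
  risk_idx <- which(colnames(truth_groups) %in% cfg$risk_genes)
  n_flag <- if (length(risk_idx) > 0)
    rowSums(truth_groups[, risk_idx, drop = FALSE]) else rep(0, np)
  burden <- rowSums(truth_groups)
  with_seed(sub_seed(cfg$seed, "survival"), {
    rate_dfs <- log(2) / cfg$dfs_median_null *
      cfg$dfs_hazard_ratio_per_flag^n_flag
    rate_os <- log(2) / cfg$os_median_null *
      cfg$os_hazard_ratio_per_flag^n_flag
    t_rec <- rexp(np, rate_dfs)
    t_death <- t_rec + rexp(np, rate_os)  # death follows recurrence
    cens <- runif(np, cfg$censor_range[1], cfg$censor_range[2])
    dfs_months <- round(pmin(t_rec, cens), 1)
    dfs_event <- as.integer(t_rec <= cens)
    os_months <- round(pmin(t_death, cens), 1)
    os_event <- as.integer(t_death <= cens)
    dfs_months <- pmin(dfs_months, os_months)
  })
  ca125 <- with_seed(sub_seed(cfg$seed, "ca125"),
                     rlnorm(np, cfg$ca125_meanlog +
                              cfg$ca125_shift_per_event * burden,
                            cfg$ca125_sdlog))
  demo <- with_seed(sub_seed(cfg$seed, "demographics"), {
    list(stage = sample(c("I", "II", "III", "IV"), np, replace = TRUE,
                        prob = c(9, 2, 26, 3) / 40),
         hist = sample(c("HGSC", "LGSC", "mucinous", "endometrioid",
                         "clear_cell"), np, replace = TRUE,
                       prob = c(23, 3, 5, 4, 5) / 40),
         brca = sample(c("pathogenic", "wild_type"), np, replace = TRUE,
                       prob = c(0.15, 0.85)))
  })
  validate_clinical(data.frame(
    patient_id = ids, ca125 = round(ca125, 1), figo_stage = demo$stage,
    histology = demo$hist, dfs_months = dfs_months, dfs_event = dfs_event,
    os_months = os_months, os_event = os_event, brca_status = demo$brca,
    stringsAsFactors = FALSE))
}

#' Deterministic fixture cohort with the published panel frequencies
#'
#' Builds a cohort whose per-gene carrier counts are exactly
#' `round(occurring_freq * n_patients)` (half-up), assigned to seeded
#' pseudo-random patients, with a clinical table mirroring the published
#' cohort composition at n = 40: stages I/II/III/IV = 9/2/26/3, histology
#' HGSC/LGSC/mucinous/endometrioid/clear-cell = 23/3/5/4/5, 20 recurrences,
#' 6 BRCA-pathogenic patients, 3 patients lost to OS follow-up, and CA125
#' with cohort median 575.5 U/mL. For other n the composition scales by
#' largest remainder.
#'
#' @param panel a `gene_panel`.
#' @param n_patients cohort size (default 40).
#' @param seed RNG seed for carrier assignment and clinical noise.
#' @return list: `groups` (n x genes 0/1 matrix), `clinical`
#'   (a `clinical_table`).
#' @export
make_fixture_cohort <- function(panel, n_patients = 40, seed = 1) {
  if (n_patients < 1) stop_giscan("n_patients must be >= 1")
  if (any(panel$occurring_freq > 1)) stop_giscan("panel frequency > 1")
  ids <- sprintf("OC%02d", seq_len(n_patients))
  groups <- matrix(0L, n_patients, nrow(panel),
                   dimnames = list(ids, panel$gene))
  with_seed(sub_seed(seed, "fixture_carriers"), {
    for (j in seq_len(nrow(panel))) {
      k <- round_half_up(panel$occurring_freq[j] * n_patients)
      if (k > 0) groups[sample(n_patients, k), j] <- 1L
    }
  })

  alloc <- function(counts, n) {
    # largest-remainder apportionment of category counts to cohort size n
    q <- counts / sum(counts) * n
    base <- floor(q)
    rem <- n - sum(base)
    if (rem > 0) {
      o <- order(q - base, decreasing = TRUE)
      base[o[seq_len(rem)]] <- base[o[seq_len(rem)]] + 1
    }
    as.integer(base)
  }
  stage_n <- alloc(c(9, 2, 26, 3), n_patients)
  hist_n <- alloc(c(23, 3, 5, 4, 5), n_patients)
  n_rec <- round_half_up(20 / 40 * n_patients)
  n_brca <- round_half_up(6 / 40 * n_patients)
  n_os_lost <- round_half_up(3 / 40 * n_patients)

  clin <- with_seed(sub_seed(seed, "fixture_clinical"), {
    stage <- sample(rep(c("I", "II", "III", "IV"), stage_n))
    hist <- sample(rep(c("HGSC", "LGSC", "mucinous", "endometrioid",
                         "clear_cell"), hist_n))
    brca <- sample(rep(c("pathogenic", "wild_type"),
                       c(n_brca, n_patients - n_brca)))
    recurred <- sample(rep(c(1L, 0L), c(n_rec, n_patients - n_rec)))
    # recurrence times around the published median 11 mo [Q1 7, Q3 19.5];
    # follow-up around median 50 mo [37.5, 58]
    fup <- round(pmax(24, rlnorm(n_patients, log(50), 0.25)), 1)
    t_rec <- round(pmax(1, rlnorm(n_patients, log(11), 0.55)), 1)
    dfs_months <- ifelse(recurred == 1L, pmin(t_rec, fup), fup)
    dfs_event <- recurred
    died <- as.integer(recurred == 1L &
                         runif(n_patients) < 0.6)  # deaths among recurrers
    os_months <- ifelse(died == 1L,
                        round(pmin(dfs_months + rlnorm(n_patients, log(18), 0.5),
                                   fup * 1.2), 1),
                        fup)
    os_months <- pmax(os_months, dfs_months)
    ca125 <- rlnorm(n_patients, log(575.5), 1.4)
    ca125 <- round(ca125 * 575.5 / median(ca125), 1)  # pin the cohort median
    lost <- if (n_os_lost > 0) sample(n_patients, n_os_lost) else integer(0)
    os_months[lost] <- NA_real_
    os_event_v <- died
    os_event_v[lost] <- NA_integer_
    data.frame(patient_id = ids, ca125 = ca125, figo_stage = stage,
               histology = hist, dfs_months = dfs_months,
               dfs_event = dfs_event, os_months = os_months,
               os_event = os_event_v, brca_status = brca,
               stringsAsFactors = FALSE)
  })
  list(groups = groups, clinical = validate_clinical(clin))
}

#' Write a simulated cohort to a directory
#'
#' Emits the same plain-text formats the pipeline consumes: one depth TSV per
#' sample under `controls/` and `patients/`, the bin grid and relocated panel
#' tables, the clinical CSV, and a `truth.json` with the planted ground
#' truth.
#'
#' @param cohort a `sim_cohort`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "controls"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "patients"), recursive = TRUE, showWarnings = FALSE)
  for (p in cohort$controls)
    write_depth_profile(p, file.path(dir, "controls",
                                     paste0(attr(p, "sample_id"), ".tsv")))
  for (p in cohort$patients)
    write_depth_profile(p, file.path(dir, "patients",
                                     paste0(attr(p, "sample_id"), ".tsv")))
  grid <- cohort$genome$grid
  utils::write.table(as.data.frame(grid), file.path(dir, "bins.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_gene_panel(cohort$genome$panel, file.path(dir, "panel.tsv"))
  write_clinical(cohort$clinical, file.path(dir, "clinical.csv"))
  truth <- cohort$truth
  jsonlite::write_json(
    list(gene_groups = as.data.frame(truth$gene_groups),
         patient_ids = rownames(truth$gene_groups),
         tumor_fraction = truth$tumor_fraction,
         risk_genes = truth$risk_genes,
         dfs_hazard_ratio = truth$dfs_hazard_ratio,
         os_hazard_ratio = truth$os_hazard_ratio),
    file.path(dir, "truth.json"), digits = NA, auto_unbox = TRUE)
  invisible(dir)
}
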