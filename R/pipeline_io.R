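SUBJECT_MANDATORY <- c("subject_id", "status", "age_mri", "icv",
                       "hv_left_total", "hv_right_total",
                       "amyloid_suvr", "tracer")
SUBJECT_NUMERIC <- c("age_mri", "icv", "hv_left_total", "hv_right_total",
                     "amyloid_suvr")

#' Read a subject table
#'
#' Comma-separated, UTF-8, header row, "." decimal; tab-separated files are
#' accepted. Units: volumes mm^3, thicknesses mm, ages/education years.
#' Unknown columns are preserved. Missing values are empty fields and are
#' never imputed.
#'
#' @param path CSV/TSV file path.
#' @return subject data frame.
#' @export
read_subject_table <- function(path) {
  if (!file.exists(path)) stop_lateq("file not found: %s", path)
  first <- readLines(path, n = 1)
  sep <- if (grepl("\t", first)) "\t" else ","
  d <- read.csv(path, sep = sep, stringsAsFactors = FALSE)
  miss <- setdiff(SUBJECT_MANDATORY, names(d))
  if (length(miss)) {
    stop_lateq("subject table missing mandatory column(s): %s",
               paste(miss, collapse = ", "))
  }
  for (col in SUBJECT_NUMERIC) {
    v <- d[[col]]
    if (!is.numeric(v)) {
      suppressWarnings(num <- as.numeric(v))
      bad <- which(!is.na(v) & v != "" & is.na(num))
      if (length(bad)) {
        stop_lateq("non-numeric value in column '%s' at data row %d", col, bad[1])
      }
      d[[col]] <- num
    }
  }
  message(sprintf("read %d subjects from %s", nrow(d), path))
  d
}

#' Write a subject table as CSV
#' @param subjects subject data frame.
#' @param path output path.
#' @export
write_subject_table <- function(subjects, path) {
  write.csv(subjects, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a visit table
#' @param path CSV/TSV path with `subject_id`, `time_years` and score columns.
#' @return visit data frame.
#' @export
read_visit_table <- function(path) {
  if (!file.exists(path)) stop_lateq("file not found: %s", path)
  first <- readLines(path, n = 1)
  sep <- if (grepl("\t", first)) "\t" else ","
  d <- read.csv(path, sep = sep, stringsAsFactors = FALSE)
  miss <- setdiff(c("subject_id", "time_years"), names(d))
  if (length(miss)) {
    stop_lateq("visit table missing mandatory column(s): %s",
               paste(miss, collapse = ", "))
  }
  d
}

#' Write a visit table as CSV
#' @param visits visit data frame.
#' @param path output path.
#' @export
write_visit_table <- function(visits, path) {
  write.csv(visits, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write a mesh as an edge-list TSV
#'
#' First line is a vertex-count header (`n_vertices<TAB>n`), followed by one
#' tab-separated edge per line.
#'
#' @param mesh a [make_mesh()] graph.
#' @param path output path.
#' @export
write_mesh <- function(mesh, path) {
  validate_mesh(mesh)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("n_vertices\t%d", mesh$n_vertices), con)
  if (nrow(mesh$edges)) {
    writeLines(sprintf("%d\t%d", mesh$edges[, 1], mesh$edges[, 2]), con)
  }
  invisible(path)
}

#' Read a mesh edge-list TSV
#' @param path file written by [write_mesh()].
#' @return a `mesh_graph`.
#' @export
read_mesh <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(lines[1], "\t")[[1]]
  if (hdr[1] != "n_vertices") stop_lateq("missing vertex-count header line")
  n <- as.integer(hdr[2])
  edges <- if (length(lines) > 1) {
    do.call(rbind, lapply(strsplit(lines[-1], "\t"), as.integer))
  } else {
    matrix(integer(0), 0, 2)
  }
  mesh <- structure(list(n_vertices = n, edges = edges), class = "mesh_graph")
  validate_mesh(mesh)
  mesh
}

# Deterministic polynomial hash of a configuration's JSON serialization,
# reported in output metadata so runs are traceable to their settings.
config_hash <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = 10, force = TRUE)
  h <- 0
  for (byte in utf8ToInt(as.character(s))) {
    h <- (h * 31 + byte) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}

#' Pipeline run configuration
#'
#' @param cohort a [cohort_config()].
#' @param tfce a [tfce_params()]; the end-to-end run defaults to a reduced
#'   permutation count suitable for a desk-scale mesh.
#' @param stages character vector of stages to run, in dependency order,
#'   from `c("simulate", "stratify", "features", "maps", "trajectories",
#'   "validate")`.
#' @param mesh_vertices vertex count of the desk-scale mesh stage.
#' @param autopsy_n autopsy-arm size.
#' @param seed master seed recorded in all outputs.
#' @param out_dir output directory (created if needed).
#' @return list of class `run_config`.
#' @export
run_config <- function(cohort = cohort_config(),
                       tfce = tfce_params(n_perm = 250),
                       stages = c("simulate", "stratify", "features",
                                  "maps", "trajectories", "validate"),
                       mesh_vertices = 25,
                       autopsy_n = 400,
                       seed = 1L,
                       out_dir = tempfile("lateq_run_")) {
  stages <- match.arg(stages, several.ok = TRUE)
  structure(list(cohort = cohort, tfce = tfce, stages = stages,
                 mesh_vertices = mesh_vertices, autopsy_n = autopsy_n,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' Run the full enrichment pipeline on a synthetic cohort
#'
#' Chains simulate -> stratify -> features -> maps -> trajectories ->
#' validate and writes CSV tables, a JSON report and a Markdown summary to
#' `config$out_dir`. Identical seeds give identical reports. Stages that are
#' toggled off are marked skipped; stages whose prerequisites were skipped
#' refuse to run.
#'
#' @param config a [run_config()].
#' @return the report list (invisibly written as `report.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(
    package_version = as.character(packageVersion("lateq")),
    master_seed = config$seed,
    config_hash = config_hash(config[c("stages", "mesh_vertices",
                                       "autopsy_n", "seed")]),
    stages = list())
  done <- character(0)
  want <- function(stage) stage %in% config$stages
  need <- function(stage, deps) {
    missing_deps <- setdiff(deps, done)
    if (length(missing_deps)) {
      stop_lateq("stage '%s' requires skipped stage(s): %s", stage,
                 paste(missing_deps, collapse = ", "))
    }
  }
  cohort <- NULL
  strat <- NULL

  if (want("simulate")) {
    message("stage simulate: generating cohort")
    cohort <- generate_cohort(config$cohort, config$seed)
    write_subject_table(cohort$subjects,
                        file.path(config$out_dir, "subjects.csv"))
    write_visit_table(cohort$visits, file.path(config$out_dir, "visits.csv"))
    report$stages$simulate <- list(
      n_subjects = nrow(cohort$subjects),
      n_visits = nrow(cohort$visits))
    done <- c(done, "simulate")
  } else {
    report$stages$simulate <- "skipped"
  }

  if (want("stratify")) {
    need("stratify", "simulate")
    message("stage stratify: CU adjustment + quartile grouping")
    strat <- stratify_cohort(cohort$subjects)
    labels <- strat$subjects[, c("subject_id", "hv_adjusted",
                                 "group_assigned")]
    write.csv(labels, file.path(config$out_dir, "labels.csv"),
              row.names = FALSE)
    jsonlite::write_json(
      list(q25 = strat$cutoffs$q25, q50 = strat$cutoffs$q50,
           n_ref = strat$cutoffs$n_ref, master_seed = config$seed),
      file.path(config$out_dir, "cutoffs.json"), auto_unbox = TRUE)
    report$stages$stratify <- list(
      q25 = strat$cutoffs$q25, q50 = strat$cutoffs$q50,
      group_counts = as.list(table(strat$subjects$group_assigned)))
    done <- c(done, "stratify")
  } else {
    report$stages$stratify <- "skipped"
  }

  if (want("features")) {
    need("features", "stratify")
    message("stage features: asymmetry, ERC/PHC, amyloid, Tau-MaX GMM")
    feats <- compute_imaging_features(strat$subjects)
    write.csv(feats$features, file.path(config$out_dir, "features.csv"),
              row.names = FALSE)
    nonconv <- sum(!vapply(feats$gmm_fits, function(f) f$converged, TRUE))
    if (nonconv > 0) warning(sprintf("%d ROI mixture fit(s) not converged", nonconv))
    fsum <- aggregate(
      feats$features[, c("asymmetry_index", "erc_phc_ratio",
                         "taumax_global_gmm")],
      by = list(group = strat$subjects$group_assigned), FUN = mean)
    report$stages$features <- list(
      gmm_nonconverged = nonconv,
      group_means = fsum)
    done <- c(done, "features")
  } else {
    report$stages$features <- "skipped"
  }

  if (want("maps")) {
    need("maps", "stratify")
    message("stage maps: TFCE permutation + LME interaction maps")
    mesh <- make_mesh(config$mesh_vertices, "grid")
    keep <- strat$subjects$group_assigned %in% c("AD+sLATE-", "AD+sLATE+")
    grp <- droplevels(factor(strat$subjects$group_assigned[keep]))
    effect <- numeric(config$mesh_vertices)
    effect[seq_len(max(1, config$mesh_vertices %/% 5))] <- -0.15
    md <- generate_mesh_data(mesh, grp, effect, noise_sd = 0.15,
                             seed = derive_seed(config$seed, "maps"))
    dg <- two_group_design(md$design$group)
    res <- permutation_fwer(md$data, dg$X, dg$contrast, mesh, config$tfce)
    long <- generate_mesh_data_long(
      mesh, grp, slope_map = effect / 5, times = 0:3, noise_sd = 0.08,
      seed = derive_seed(config$seed, "maps_long"))
    lmap <- lme_interaction_map(long$data, long$meta)
    lmap$q <- bh_fdr(lmap$p)
    write.csv(data.frame(vertex = seq_along(res$p), t = res$t,
                         tfce = res$tfce, p_fwer = res$p,
                         lme_estimate = lmap$estimate, lme_q = lmap$q),
              file.path(config$out_dir, "vertex_stats.csv"),
              row.names = FALSE)
    report$stages$maps <- list(
      n_vertices = config$mesh_vertices,
      n_perm = config$tfce$n_perm,
      n_fwer_sig = sum(res$p < config$tfce$alpha, na.rm = TRUE),
      n_fdr_sig = sum(lmap$q < 0.05, na.rm = TRUE))
    done <- c(done, "maps")
  } else {
    report$stages$maps <- "skipped"
  }

  if (want("trajectories")) {
    need("trajectories", "stratify")
    message("stage trajectories: domain LME slope contrasts")
    keep <- strat$subjects$group_assigned %in%
      c("AD+sLATE-", "AD+sLATE+", "AD-sLATE+", "Abeta-CU")
    subs <- strat$subjects[keep, ]
    subs$group_assigned <- droplevels(subs$group_assigned)
    fits <- lapply(c("memory", "exec", "language"), function(dom) {
      fit_domain_lme(cohort$visits, subs, dom, group_col = "group_assigned")
    })
    names(fits) <- c("memory", "exec", "language")
    report$stages$trajectories <- lapply(fits, function(f) {
      list(singular_refit = f$singular_refit,
           slopes = f$slopes[, c("group", "time.trend")],
           contrasts = f$contrasts[, c("contrast", "estimate", "p.value")])
    })
    done <- c(done, "trajectories")
  } else {
    report$stages$trajectories <- "skipped"
  }

  if (want("validate")) {
    need("validate", "stratify")
    message("stage validate: autopsy enrichment")
    aut <- generate_autopsy_cohort(config$cohort, config$autopsy_n,
                                   derive_seed(config$seed, "validate"))
    cuts <- compute_quartile_cutoffs(aut$hv_adjusted)
    tab <- contingency_from_groups(aut, cuts)
    fe <- fisher_exact(tab)
    freqs <- enrichment_frequencies(tab)
    roc <- roc_curve(aut$hv_adjusted, aut$late_nc_stage >= 1)
    ss <- sens_spec_at_threshold(aut$hv_adjusted, aut$late_nc_stage >= 1,
                                 cuts$q25)
    val <- list(table = unclass(tab)[c("a", "b", "c", "d")],
                q1_late_pct = unname(freqs["q1"]),
                q3q4_late_pct = unname(freqs["q3q4"]),
                or = fe$or, p = fe$p, auc = roc$auc,
                youden = youden_optimal(roc),
                sens_spec_at_q25 = as.list(ss))
    jsonlite::write_json(val, file.path(config$out_dir, "validation.json"),
                         auto_unbox = TRUE, digits = NA)
    report$stages$validate <- val
    done <- c(done, "validate")
  } else {
    report$stages$validate <- "skipped"
  }

  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       dataframe = "rows")
  md <- c(sprintf("# lateq pipeline report"),
          sprintf("- package: %s", report$package_version),
          sprintf("- master seed: %d", report$master_seed),
          sprintf("- config hash: %s", report$config_hash),
          sprintf("- stages run: %s", paste(done, collapse = ", ")))
  if ("validate" %in% done) {
    v <- report$stages$validate
    md <- c(md, sprintf("- autopsy enrichment: Q1 %.1f%% vs Q3-Q4 %.1f%% LATE+, OR %.2f (p = %.2g)",
                        v$q1_late_pct, v$q3q4_late_pct, v$or, v$p))
  }
  writeLines(md, file.path(config$out_dir, "report.md"))
  invisible(report)
}
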