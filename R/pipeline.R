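# End-to-end orchestration: simulate (or load) -> edit -> LnVar track ->
# DHGLM track -> evaluation -> GWAS on both deregressed EBV sets -> report.
# Every stage writes plain-text artifacts into the run directory so stages
# can be re-run and inspected independently.

#' Default pipeline configuration
#'
#' @param outdir run directory.
#' @param seed master seed; all stage randomness derives from it.
#' @param simulate an [sim_config()] (set its `seed` from `seed` if you want
#'   a single master seed), or `NULL` to load data from `paths`.
#' @param paths named list with `pedigree`, `phenotypes`, `genotypes`,
#'   `map` when `simulate` is `NULL`.
#' @param stages character vector of stages to run, a subset of
#'   `c("simulate", "prep", "lnvar", "dhglm", "evaluate", "gwas", "report")`.
#' @param p_significant,p_suggestive,r2_min GWAS thresholds.
#' @param c_frac deregression constant.
#' @param crossval run the (costly) cross-validation inside `evaluate`?
#' @param dhglm_args extra arguments for [run_dhglm()].
#' @return config list.
#' @export
pipeline_config <- function(outdir = "littervar_run", seed = 1L,
                            simulate = sim_config(seed = seed),
                            paths = NULL,
                            stages = c("simulate", "prep", "lnvar", "dhglm",
                                       "evaluate", "gwas", "report"),
                            p_significant = 1e-6, p_suggestive = 1e-4,
                            r2_min = 0.2, c_frac = 0.5,
                            crossval = FALSE, dhglm_args = list()) {
  stopifnot(p_significant > 0, p_significant < 1,
            p_suggestive > 0, p_suggestive < 1)
  if (is.null(simulate) && is.null(paths)) {
    stop("either a simulate block or input paths must be given", call. = FALSE)
  }
  as.list(environment())
}

# tiny FNV-1a hash over the serialized object, for run manifests
config_hash <- function(x) {
  bytes <- serialize(x, NULL, version = 2)
  h <- 2166136261
  for (b in as.integer(bytes)) {
    h <- bitwXor(h, b)
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%08x", h)
}

pipe_write <- function(df, dir, name) {
  utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Run the litter-size variability pipeline
#'
#' Executes the configured stages in order and writes artifacts (TSV/JSON)
#' plus a manifest into the run directory. Stage outputs: edited phenotypes
#' and edit log (`prep`), LnVar phenotype and variability-model EBV
#' (`lnvar`), DHGLM components and EBV (`dhglm`), accuracies, EBV
#' correlation and optional cross-validation (`evaluate`), per-SNP
#' association tables and vQTL regions for both tracks (`gwas`), and a
#' human-readable summary (`report`).
#'
#' @param config a [pipeline_config()].
#' @return invisibly, the run directory; intermediate objects as attribute
#'   `state`.
#' @export
run_pipeline <- function(config) {
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  st <- list()
  log_con <- file(file.path(config$outdir, "run.log"), open = "wt")
  on.exit(close(log_con), add = TRUE)
  note <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S "), ...)
    writeLines(msg, log_con)
    message(msg)
  }
  stages <- config$stages
  manifest <- list(package_version = as.character(utils::packageVersion("littervar")),
                   seed = config$seed, stages = stages,
                   config_hash = config_hash(config[setdiff(names(config), "outdir")]))

  if ("simulate" %in% stages && !is.null(config$simulate)) {
    note("simulate: generating pedigree, genotypes, phenotypes")
    sim <- simulate_dataset(config$simulate, genotypes = TRUE)
    write_sim_data(sim, config$outdir)
    st$ped <- sim$ped; st$genotypes <- sim$genotypes
    st$raw_records <- sim$records; st$truth <- sim$truth
  } else {
    note("load: reading input files")
    st$ped <- read_pedigree_tsv(config$paths$pedigree)
    st$raw_records <- read_records_tsv(config$paths$phenotypes)
    if (!is.null(config$paths$genotypes)) {
      st$genotypes <- read_genotypes_tsv(config$paths$genotypes,
                                         config$paths$map)
    }
  }

  if ("prep" %in% stages) {
    note("prep: applying edit rules")
    st$records <- apply_edit_rules(st$raw_records)
    pipe_write(st$records, config$outdir, "phenotypes_edited.tsv")
    jsonlite::write_json(attr(st$records, "edit_log"),
                         file.path(config$outdir, "edit_log.json"),
                         auto_unbox = TRUE)
  }

  if ("lnvar" %in% stages) {
    note("lnvar: two-step log-variance track")
    st$lnvar <- lnvar_track(st$records, st$ped)
    ebv <- st$lnvar$var_fit$ebv
    pev <- st$lnvar$var_fit$pev
    pipe_write(data.frame(animal = names(ebv), ebv = ebv, pev = pev),
               config$outdir, "lnvar_ebv.tsv")
    vc <- st$lnvar$var_fit$vc
    jsonlite::write_json(
      list(var_a = vc$var_a, var_e = as.list(vc$var_e),
           h2 = heritability(vc$var_a, vc$var_e,
                             resid_weights = tabulate(st$lnvar$lnvar$group, 9)),
           gcv_sde = gcv_sde(vc$var_a)),
      file.path(config$outdir, "lnvar_components.json"),
      auto_unbox = TRUE, digits = NA)
  }

  if ("dhglm" %in% stages) {
    note("dhglm: bivariate mean/variance model")
    st$dhglm <- do.call(run_dhglm,
                        c(list(records = st$records, ped = st$ped),
                          config$dhglm_args))
    pipe_write(st$dhglm$ebv, config$outdir, "dhglm_ebv.tsv")
    jsonlite::write_json(
      list(var_a = st$dhglm$Ga[1, 1], var_av = st$dhglm$Ga[2, 2],
           cov_a_av = st$dhglm$Ga[1, 2],
           var_pe = st$dhglm$Gpe[1, 1], var_pev = st$dhglm$Gpe[2, 2],
           cov_pe_pev = st$dhglm$Gpe[1, 2],
           r_a_av = st$dhglm$r_a_av, r_pe_pev = st$dhglm$r_pe_pev,
           scaling_e = st$dhglm$s2e, scaling_ev = st$dhglm$s2ev,
           gcv_sde = gcv_sde(st$dhglm$Ga[2, 2]),
           var_av_below_floor = st$dhglm$Ga[2, 2] < 0.005,
           iterations = st$dhglm$iterations,
           converged = st$dhglm$converged),
      file.path(config$outdir, "dhglm_components.json"),
      auto_unbox = TRUE, digits = NA)
  }

  if ("evaluate" %in% stages) {
    note("evaluate: accuracy, EBV correlation",
         if (config$crossval) ", cross-validation" else "")
    lv_fit <- st$lnvar$var_fit
    acc_ln <- theoretical_accuracy(pmin(lv_fit$pev, lv_fit$vc$var_a),
                                   lv_fit$vc$var_a)
    dh <- st$dhglm
    acc_dh <- theoretical_accuracy(pmin(dh$ebv$pev_var, dh$Ga[2, 2]),
                                   dh$Ga[2, 2])
    pipe_write(data.frame(animal = names(lv_fit$ebv),
                          accuracy_lnvar = acc_ln,
                          accuracy_dhglm = acc_dh),
               config$outdir, "accuracy.tsv")
    cmp <- compare_methods(lv_fit$ebv,
                           stats::setNames(dh$ebv$ebv_var, dh$ebv$animal))
    eval_out <- list(ebv_correlation = cmp$correlation,
                     top_decile_overlap = cmp$top_decile_overlap,
                     mean_accuracy_lnvar = mean(acc_ln),
                     mean_accuracy_dhglm = mean(acc_dh))
    if (config$crossval) {
      cv <- run_cross_validation(st$records, st$ped, seed = config$seed,
                                 dhglm_args = config$dhglm_args)
      st$crossval <- cv
      eval_out$crossval_mean <- as.list(cv$summary)
      eval_out$crossval_p <- cv$t_test$p.value
    }
    st$evaluate <- eval_out
    jsonlite::write_json(eval_out, file.path(config$outdir, "evaluation.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  if ("gwas" %in% stages && !is.null(st$genotypes)) {
    note("gwas: QC, GRM and association on both dEBV sets")
    qc <- qc_genotypes(st$genotypes)
    jsonlite::write_json(attr(qc, "qc_report"),
                         file.path(config$outdir, "genotype_qc.json"),
                         auto_unbox = TRUE)
    grm <- compute_grm(qc)
    rownames(grm$G) <- colnames(grm$G) <- rownames(qc$geno)
    lv_fit <- st$lnvar$var_fit
    h2_ln <- heritability(lv_fit$vc$var_a, lv_fit$vc$var_e,
                          resid_weights = tabulate(st$lnvar$lnvar$group, 9))
    dbv_ln <- deregress_ebv(lv_fit$ebv, lv_fit$pev, st$ped,
                            sigma2_add = lv_fit$vc$var_a, h2 = h2_ln,
                            c_frac = config$c_frac)
    dh <- st$dhglm
    # variance-part residual variance: mean of W_v^-1 sigma2_ev
    var_ev <- dh$s2ev * mean(2 / (1 - dh$leverage))
    h2_dh <- heritability(dh$Ga[2, 2], var_ev, var_pe = dh$Gpe[2, 2])
    dbv_dh <- deregress_ebv(stats::setNames(dh$ebv$ebv_var, dh$ebv$animal),
                            stats::setNames(dh$ebv$pev_var, dh$ebv$animal),
                            st$ped, sigma2_add = dh$Ga[2, 2], h2 = h2_dh,
                            c_frac = config$c_frac)
    for (trk in c("lnvar", "dhglm")) {
      dbv <- if (trk == "lnvar") dbv_ln else dbv_dh
      res <- run_gwas(dbv, qc, grm, p_significant = config$p_significant,
                      p_suggestive = config$p_suggestive)
      st[[paste0("gwas_", trk)]] <- res
      write_gwas_results(res, file.path(config$outdir,
                                        paste0("gwas_", trk, ".tsv")))
      regions <- define_vqtl_regions(res, qc, r2_min = config$r2_min)
      st[[paste0("regions_", trk)]] <- regions
      pipe_write(regions, config$outdir, paste0("vqtl_regions_", trk, ".tsv"))
    }
  }

  if ("report" %in% stages) {
    note("report: summary tables")
    make_report(config$outdir, state = st)
  }

  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE)
  out <- config$outdir
  attr(out, "state") <- st
  invisible(out)
}

#' Summarise a pipeline run
#'
#' Builds the report artifacts from a completed run directory: a TNB
#' histogram table, a variance-component summary for both tracks, and a
#' plain-text summary (heritabilities, GCV, EBV correlation, region
#' counts). Fails with a list of missing stages if artifacts are absent.
#'
#' @param run_dir the pipeline output directory.
#' @param state optional in-memory pipeline state (used when available).
#' @return invisibly, the path of the summary file.
#' @export
make_report <- function(run_dir, state = NULL) {
  need <- c("phenotypes_edited.tsv", "lnvar_components.json",
            "dhglm_components.json")
  missing <- need[!file.exists(file.path(run_dir, need))]
  if (length(missing)) {
    stop("cannot build report; missing artifacts: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  rec <- utils::read.table(file.path(run_dir, "phenotypes_edited.tsv"),
                           header = TRUE, sep = "\t")
  brk <- seq(floor(min(rec$tnb)), ceiling(max(rec$tnb)) + 1)
  hist_df <- data.frame(tnb = brk[-length(brk)],
                        count = as.integer(table(cut(rec$tnb, brk,
                                                     right = FALSE))))
  pipe_write(hist_df, run_dir, "tnb_histogram.tsv")
  ln <- jsonlite::read_json(file.path(run_dir, "lnvar_components.json"))
  dh <- jsonlite::read_json(file.path(run_dir, "dhglm_components.json"))
  lines <- c(
    "litter-size variability run summary",
    sprintf("records: %d, sows: %d, mean TNB: %.2f (sd %.2f)",
            nrow(rec), length(unique(rec$sow)), mean(rec$tnb),
            stats::sd(rec$tnb)),
    sprintf("LnVar track: var_a = %.4g, h2 = %.3f, GCV_SDe = %.1f%%",
            ln$var_a, ln$h2, 100 * ln$gcv_sde),
    sprintf("DHGLM track: var_av = %.4g, r_a_av = %.2f, r_pe_pev = %.2f, GCV_SDe = %.1f%%",
            dh$var_av, dh$r_a_av, dh$r_pe_pev, 100 * dh$gcv_sde),
    sprintf("DHGLM scaling variances: %.3f / %.3f", dh$scaling_e,
            dh$scaling_ev)
  )
  if (isTRUE(dh$var_av_below_floor)) {
    lines <- c(lines,
               "note: no variance-genetics signal (sigma2_av below floor 0.005)")
  }
  ev_path <- file.path(run_dir, "evaluation.json")
  if (file.exists(ev_path)) {
    ev <- jsonlite::read_json(ev_path)
    lines <- c(lines, sprintf("EBV correlation between methods: %.3f",
                              ev$ebv_correlation))
  }
  for (trk in c("lnvar", "dhglm")) {
    rp <- file.path(run_dir, paste0("vqtl_regions_", trk, ".tsv"))
    if (file.exists(rp)) {
      rg <- utils::read.table(rp, header = TRUE, sep = "\t")
      lines <- c(lines, sprintf("vQTL regions (%s): %d", trk, nrow(rg)))
    } else {
      lines <- c(lines, sprintf("vQTL regions (%s): stage not run", trk))
    }
  }
  out <- file.path(run_dir, "summary.txt")
  writeLines(lines, out)
  invisible(out)
}
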