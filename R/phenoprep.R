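# Data editing and construction of the LnVar variability phenotype.

#' Apply litter-record editing rules
#'
#' Standard edits for total number born (TNB): records with TNB of 3 or
#' less are removed; TNB above 25 is recoded to 25; parities above 10 are
#' treated as parity 10; sows left with a single record are dropped (a
#' within-sow variance needs at least two litters).
#'
#' @param raw data.frame with columns `sow`, `parity`, `hys`, `tnb`.
#' @return edited data.frame with an `edit_log` attribute (counts per rule).
#' @export
apply_edit_rules <- function(raw) {
  req <- c("sow", "parity", "hys", "tnb")
  miss <- setdiff(req, names(raw))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  if (!is.numeric(raw$tnb)) stop("tnb must be numeric", call. = FALSE)
  if (!is.numeric(raw$parity)) stop("parity must be numeric", call. = FALSE)
  log <- list(n_input = nrow(raw))
  drop_small <- raw$tnb <= 3
  log$dropped_tnb_le3 <- sum(drop_small)
  out <- raw[!drop_small, , drop = FALSE]
  log$recoded_tnb_gt25 <- sum(out$tnb > 25)
  out$tnb[out$tnb > 25] <- 25
  log$recoded_parity_gt10 <- sum(out$parity > 10)
  out$parity[out$parity > 10] <- 10
  cnt <- table(out$sow)
  single <- names(cnt)[cnt < 2]
  log$dropped_single_record_sows <- length(single)
  out <- out[!out$sow %in% single, , drop = FALSE]
  log$n_output <- nrow(out)
  rownames(out) <- NULL
  attr(out, "edit_log") <- log
  out
}

#' Assign sows to record-count residual groups
#'
#' Sows are grouped by their number of litter records for heterogeneous
#' residual-variance modelling of the variability phenotype: group
#' `n_records - 1` for 2..9 records, and group 9 for 10 or more records,
#' giving nine groups.
#'
#' @param table edited [apply_edit_rules()] record table.
#' @return data.frame with `sow`, `n_records`, `group`.
#' @export
assign_record_groups <- function(table) {
  cnt <- table(table$sow)
  if (any(cnt < 2)) {
    stop("sow(s) with fewer than 2 records: run apply_edit_rules() first",
         call. = FALSE)
  }
  n_rec <- as.integer(cnt)
  data.frame(sow = names(cnt),
             n_records = n_rec,
             group = pmin(n_rec - 1L, 9L),
             stringsAsFactors = FALSE)
}

#' Log-transformed within-sow variance of residuals (LnVarTNB)
#'
#' For each sow, the sample variance (n - 1 denominator) of her residuals
#' from the repeatability animal model is computed and log-transformed.
#' Sows whose residual variance is exactly zero carry no information on the
#' log scale and are excluded (flagged in the `excluded` attribute).
#'
#' @param residuals_by_sow named list (or split vector) mapping sow id to
#'   her residual vector; every sow needs at least 2 finite residuals.
#' @return data.frame `sow`, `lnvar`, `n_records` with attribute `excluded`.
#' @export
compute_lnvar_phenotype <- function(residuals_by_sow) {
  ns <- vapply(residuals_by_sow, length, 0L)
  if (any(ns < 2)) stop("every sow needs at least 2 residuals", call. = FALSE)
  if (any(!vapply(residuals_by_sow, function(r) all(is.finite(r)), TRUE))) {
    stop("non-finite residuals", call. = FALSE)
  }
  v <- vapply(residuals_by_sow, stats::var, numeric(1))
  zero <- v <= 0
  out <- data.frame(sow = names(residuals_by_sow)[!zero],
                    lnvar = log(v[!zero]),
                    n_records = ns[!zero],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "excluded") <- names(residuals_by_sow)[zero]
  out
}

#' Herd-year-season of the first farrowing
#'
#' The fixed effect of the variability model is the farm-year-season code
#' of each sow's earliest recorded parity.
#'
#' @param records edited record table.
#' @return data.frame `sow`, `first_hys`.
#' @export
first_farrowing_hys <- function(records) {
  ord <- order(records$sow, records$parity)
  r <- records[ord, ]
  first <- !duplicated(r$sow)
  data.frame(sow = r$sow[first], first_hys = r$hys[first],
             stringsAsFactors = FALSE)
}

#' Run the two-step LnVar track
#'
#' Step 1 fits the repeatability animal model for TNB (fixed herd-year-season
#' and parity; additive and permanent-environment random effects) and takes
#' its residuals. Step 2 computes LnVarTNB per sow and fits the variability
#' animal model (fixed first-farrowing herd-year-season, additive genetic
#' effect, nine record-count residual-variance groups).
#'
#' @param records edited record table ([apply_edit_rules()]).
#' @param ped pedigree covering all sows.
#' @param start_mean,start_var optional starting (or fixed) variance
#'   components for the two steps.
#' @param reml estimate components (`TRUE`) or hold them at the start values.
#' @param se compute component standard errors for the variability model.
#' @param maxit REML iteration cap.
#' @return list with `mean_fit` (step 1, `lv_mm_fit`), `lnvar` (phenotype
#'   table), `var_fit` (step 2, `lv_mm_fit`), `groups`.
#' @export
lnvar_track <- function(records, ped, start_mean = NULL, start_var = NULL,
                        reml = TRUE, se = FALSE, maxit = 200L) {
  mean_fit <- fit_animal_model(records, "tnb", fixed = c("hys", "parity"),
                               ped = ped, animal = "sow",
                               permanent_env = "sow",
                               start = start_mean, reml = reml, se = FALSE,
                               maxit = maxit, compute_pev = FALSE)
  res_by_sow <- split(mean_fit$residuals, records$sow)
  lnvar <- compute_lnvar_phenotype(res_by_sow)
  groups <- assign_record_groups(records)
  fhys <- first_farrowing_hys(records)
  dat <- merge(lnvar, groups, by = "sow")
  dat$n_records <- dat$n_records.x
  dat <- merge(dat, fhys, by = "sow")
  var_fit <- fit_animal_model(dat, "lnvar", fixed = "first_hys", ped = ped,
                              animal = "sow", permanent_env = NULL,
                              resid_group = "group", start = start_var,
                              reml = reml, se = se, maxit = maxit)
  list(mean_fit = mean_fit, lnvar = dat, var_fit = var_fit, groups = groups)
}
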