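#' Default pipeline configuration
#'
#' @param tree Path to a Newick tree (or a `phylo` object).
#' @param traits Path to a trait CSV (or a data.frame).
#' @param ... Overrides: `stages` (subset of coding, regression, confounds,
#'   ordinal, tipages, pathway, fates), `seed`, `n_starts`,
#'   `mcmc` (list: iterations, burn_in, thin), `n_perm`, `horizons`,
#'   `n_reps`, `rates` (list: lambda_defended, mu_defended,
#'   lambda_undefended, mu_undefended; no defaults -- they are study inputs),
#'   `out_dir`.
#' @return A named configuration list.
#' @export
pipeline_config <- function(tree, traits, ...) {
  cfg <- list(
    tree = tree, traits = traits,
    stages = c("coding", "regression", "confounds", "ordinal", "tipages",
               "pathway", "fates"),
    seed = 1L, n_starts = 5L,
    mcmc = list(iterations = 22000, burn_in = 2000, thin = 20),
    n_perm = 999L, horizons = seq(5, 100, 5), n_reps = 1000L,
    rates = NULL, out_dir = NULL
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file path.
#' @return A configuration list (see [pipeline_config()]).
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  stopifnot(!is.null(raw$tree), !is.null(raw$traits))
  do.call(pipeline_config, raw)
}

.reg_record <- function(fit) {
  list(coefficients = as.list(fit$coefficients), se = as.list(fit$se),
       z = as.list(fit$z), p_value = as.list(fit$p_value),
       signal = fit$signal, alpha = fit$alpha, family = fit$family,
       n = fit$n, converged = fit$converged)
}

.lrt_record <- function(lrt) {
  rec <- list(statistic = lrt$statistic, df = lrt$df, p_value = lrt$p_value,
              log_likelihood_general = lrt$fit_general$log_likelihood,
              log_likelihood_restricted = lrt$fit_restricted$log_likelihood,
              rates_general = as.list(lrt$fit_general$rates))
  if (!is.null(lrt$ordering)) rec$ordering <- lrt$ordering
  rec
}

#' Run the full analysis pipeline
#'
#' Executes the configured stages in dependency order: dataset coding, then
#' phylogenetic regressions (logistic threat model with back-transformed
#' probability contrast, Poisson GEE of status, phylogenetic-vs-plain
#' comparison), the confound screen (if covariate columns are present), the
#' ordinal MCMC model, the terminal-branch-age contrast, the evolutionary
#' pathway tests (Pagel's correlation test and the directional test), and the
#' birth-death fate simulations (only when group rates are configured -- they
#' are study inputs with no defaults). A failing stage is recorded in the
#' report and the remaining stages still run. Results go to files; progress
#' is logged to stderr with stage-tagged lines.
#'
#' @param config A list from [pipeline_config()] or a YAML path.
#' @return An `analysis_report` list: `provenance` (package version, seeds,
#'   timestamp), `attrition`, and one record per stage. If `out_dir` is set,
#'   `report.json` and `report.txt` are written there.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  msg <- function(stage, ...) message("[", stage, "] ", ...)
  report <- list(provenance = list(
    package = "defrisk",
    version = as.character(utils::packageVersion("defrisk")),
    seed = config$seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")))

  run_stage <- function(stage, expr) {
    if (!stage %in% config$stages) return(NULL)
    msg(stage, "running")
    tryCatch(c(list(status = "ok"), expr()),
             error = function(e) {
               msg(stage, "FAILED: ", conditionMessage(e))
               list(status = "error", message = conditionMessage(e))
             })
  }

  tree <- if (inherits(config$tree, "phylo")) as_phylo_tree(config$tree)
          else read_newick(config$tree)
  traits <- if (is.data.frame(config$traits)) config$traits
            else read_trait_table(config$traits)

  dataset <- NULL
  report$coding <- run_stage("coding", function() {
    dataset <<- build_dataset(traits, tree)
    list(attrition = dataset$attrition,
         n_defended = sum(dataset$traits$chemical_defence == 1),
         n_threatened = sum(dataset$traits$threat == 1))
  })
  if (is.null(dataset)) stop("coding stage must run and succeed")
  tt <- dataset$traits
  dtree <- dataset$tree
  defence <- stats::setNames(tt$chemical_defence, tt$species)
  threat <- stats::setNames(tt$threat, tt$species)
  status <- stats::setNames(tt$status, tt$species)

  report$regression <- run_stage("regression", function() {
    logi <- phylo_logistic(dtree, threat,
                           data.frame(species = tt$species,
                                      defence = tt$chemical_defence))
    gee <- phylo_poisson_gee(dtree, status,
                             data.frame(species = tt$species,
                                        defence = tt$chemical_defence))
    cmp <- compare_phylo_vs_plain(dtree, threat,
                                  data.frame(species = tt$species,
                                             defence = tt$chemical_defence),
                                  family = "logistic")
    list(logistic = .reg_record(logi),
         threat_contrast = threat_probability_contrast(logi),
         poisson_gee = .reg_record(gee),
         phylo_vs_plain = list(aic_phylo = cmp$aic_phylo,
                               aic_plain = cmp$aic_plain,
                               winner = cmp$winner))
  })

  covnames <- intersect(c("absolute_latitude", "male_length",
                          "female_length", "ssd_index"), names(tt))
  report$confounds <- run_stage("confounds", function() {
    if (!length(covnames)) return(list(note = "no covariate columns present"))
    scr <- confound_screen(dtree, defence,
                           tt[, c("species", covnames), drop = FALSE])
    list(summary = scr$summary)
  })

  report$ordinal <- run_stage("ordinal", function() {
    m <- config$mcmc
    fit <- fit_ordinal_mcmc(dtree, status, defence,
                            iterations = m$iterations, burn_in = m$burn_in,
                            thin = m$thin,
                            seed = derive_seed(config$seed, "ordinal"))
    list(beta_mean = fit$mean, ci_lower = fit$ci_lower,
         ci_upper = fit$ci_upper, p_mcmc = fit$p_mcmc, ess = fit$ess,
         settings = fit$settings[c("iterations", "burn_in", "thin",
                                   "n_categories")])
  })

  report$tipages <- run_stage("tipages", function() {
    h <- tip_age_histogram(dtree, defence)
    pt <- young_tip_permutation_test(dtree, defence, cutoff = h$cutoff,
                                     n_perm = config$n_perm,
                                     seed = derive_seed(config$seed, "perm"))
    list(young_tip_excess = h$young_tip_excess, cutoff = h$cutoff,
         permutation_p = pt$p_value, n_perm = pt$n_perm, note = pt$note)
  })

  report$pathway <- run_stage("pathway", function() {
    states <- stats::setNames(joint_state_index(tt$chemical_defence, tt$threat),
                              tt$species)
    org <- count_origins(dtree, states)
    pg <- pagel_correlation_test(dtree, states, n_starts = config$n_starts,
                                 seed = derive_seed(config$seed, "pagel"))
    dr <- directional_test(dtree, states, n_starts = config$n_starts,
                           seed = derive_seed(config$seed, "directional"))
    list(parsimony_origins = org, pagel = .lrt_record(pg),
         directional = .lrt_record(dr))
  })

  report$fates <- run_stage("fates", function() {
    r <- config$rates
    if (is.null(r))
      return(list(note = paste("skipped: group birth/death rates are study",
                               "inputs and none were configured")))
    cd <- simulate_fate_curve(r$lambda_defended, r$mu_defended,
                              horizons = config$horizons,
                              n_reps = config$n_reps,
                              seed = derive_seed(config$seed, "fates"),
                              group = "defended")
    cu <- simulate_fate_curve(r$lambda_undefended, r$mu_undefended,
                              horizons = config$horizons,
                              n_reps = config$n_reps,
                              seed = derive_seed(config$seed, "fates"),
                              group = "undefended")
    cmp <- compare_groups(cd, cu)
    list(horizons = config$horizons,
         p_extinct_defended = cd$proportion_extinct,
         p_extinct_undefended = cu$proportion_extinct,
         ratio = cmp$table$ratio, stable_from = cmp$stable_from)
  })

  class(report) <- "analysis_report"
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(unclass(report),
                         file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null", na = "null")
    writeLines(format(report), file.path(config$out_dir, "report.txt"))
  }
  report
}

#' @export
format.analysis_report <- function(x, ...) {
  L <- c(paste0("defrisk analysis report (v", x$provenance$version,
                ", seed ", x$provenance$seed, ")"))
  if (!is.null(x$coding) && x$coding$status == "ok") {
    a <- x$coding$attrition
    L <- c(L, sprintf("coding: %d species in, %d retained (%d not on tree, %d defence unknown, %d IUCN not codable)",
                      a$input, a$retained, a$not_on_tree, a$defence_unknown,
                      a$iucn_not_codable))
  }
  if (!is.null(x$regression) && x$regression$status == "ok") {
    lg <- x$regression$logistic
    L <- c(L, sprintf("logistic threat ~ defence: beta = %.3f, s.e. = %.3f, z = %.3f, p = %.3g",
                      lg$coefficients[[2]], lg$se[[2]], lg$z[[2]],
                      lg$p_value[[2]]),
           sprintf("  relative increase in threat probability: %.1f%%",
                   100 * x$regression$threat_contrast$relative_increase),
           sprintf("Poisson GEE status ~ defence: beta = %.3f, s.e. = %.3f, p = %.3g",
                   x$regression$poisson_gee$coefficients[[2]],
                   x$regression$poisson_gee$se[[2]],
                   x$regression$poisson_gee$p_value[[2]]))
  }
  if (!is.null(x$ordinal) && x$ordinal$status == "ok")
    L <- c(L, sprintf("ordinal MCMC: beta = %.3f, 95%% CI (%.3f, %.3f), pMCMC = %.3g",
                      x$ordinal$beta_mean, x$ordinal$ci_lower,
                      x$ordinal$ci_upper, x$ordinal$p_mcmc))
  if (!is.null(x$tipages) && x$tipages$status == "ok")
    L <- c(L, sprintf("young-tip excess (< %g Myr): %.4f (permutation p = %.3g)",
                      x$tipages$cutoff, x$tipages$young_tip_excess,
                      x$tipages$permutation_p))
  if (!is.null(x$pathway) && x$pathway$status == "ok")
    L <- c(L, sprintf("Pagel correlation test: LR = %.3f, d.f. = %d, p = %.3g",
                      x$pathway$pagel$statistic, x$pathway$pagel$df,
                      x$pathway$pagel$p_value),
           sprintf("directional test: LR = %.3f, d.f. = %d, p = %.3g (%s)",
                   x$pathway$directional$statistic, x$pathway$directional$df,
                   x$pathway$directional$p_value,
                   x$pathway$directional$ordering$interpretation))
  if (!is.null(x$fates) && x$fates$status == "ok" && is.null(x$fates$note))
    L <- c(L, sprintf("fates: ratio stabilizes from %s Myr",
                      format(x$fates$stable_from)))
  paste(L, collapse = "\n")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Validate a report against the shipped JSON schema
#'
#' Structural check (required properties and primitive types) against
#' `inst/extdata/report-schema.json`. Not a full JSON-schema validator: it
#' covers the subset the schema uses (type, properties, required).
#'
#' @param report An `analysis_report` or a path to a report JSON.
#' @return `TRUE` invisibly, or an error describing the first violation.
#' @export
validate_report <- function(report) {
  if (is.character(report)) report <- jsonlite::read_json(report)
  schema <- jsonlite::read_json(system.file("extdata", "report-schema.json",
                                            package = "defrisk"))
  .check_schema(unclass(report), schema, "report")
  invisible(TRUE)
}

.check_schema <- function(x, schema, path) {
  ty <- schema$type
  if (identical(ty, "object")) {
    if (!is.list(x)) stop(path, ": expected object")
    for (req in schema$required %||% list())
      if (is.null(x[[req]])) stop(path, ": missing required field ", req)
    for (nm in names(schema$properties %||% list()))
      if (!is.null(x[[nm]]))
        .check_schema(x[[nm]], schema$properties[[nm]], paste0(path, ".", nm))
  } else if (identical(ty, "number")) {
    if (!is.numeric(x) && !is.null(x)) stop(path, ": expected number")
  } else if (identical(ty, "integer")) {
    if (!is.numeric(x)) stop(path, ": expected integer")
  } else if (identical(ty, "string")) {
    if (!is.character(x)) stop(path, ": expected string")
  }
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
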