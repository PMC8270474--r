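#' Validate a pipeline configuration
#'
#' Parses YAML or JSON configuration text (or an already-parsed list),
#' applies defaults, and validates strictly: every unknown key is an error,
#' so typos cannot silently change an analysis. All errors are aggregated
#' into one message.
#'
#' Recognized structure:
#' \preformatted{
#' inputs:
#'   cases: cases.csv            # required
#'   populations: populations.csv# required
#'   covariates: covariates.csv  # optional
#'   adjacency: edges.csv        # required (.csv edge list or .gal)
#' strata: [overall]             # of overall, male, female, cardia, non_cardia
#' periods: false                # spatio-temporal fits on/off
#' mcmc:                         # any of n_chains, n_iter, n_burn, thin, seed
#' out: output-dir
#' seed: 1
#' }
#'
#' @param config file path, raw YAML/JSON text, or a list
#' @return validated config list of class \code{run_config}
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (file.exists(config)) {
      raw <- paste(readLines(config), collapse = "\n")
    } else {
      raw <- config
    }
    config <- if (grepl("^\\s*\\{", raw)) {
      jsonlite::fromJSON(raw, simplifyVector = TRUE)
    } else {
      yaml::yaml.load(raw)
    }
  }
  if (!is.list(config)) stop("config must parse to a mapping")
  errs <- character(0)
  known_top <- c("inputs", "strata", "periods", "mcmc", "out", "seed")
  unknown <- setdiff(names(config), known_top)
  if (length(unknown)) {
    errs <- c(errs, paste0("unknown key(s): ", paste(unknown, collapse = ", ")))
  }
  inputs <- config$inputs %||% list()
  known_in <- c("cases", "populations", "covariates", "adjacency")
  unknown_in <- setdiff(names(inputs), known_in)
  if (length(unknown_in)) {
    errs <- c(errs, paste0("unknown inputs key(s): ",
                           paste(unknown_in, collapse = ", ")))
  }
  for (req in c("cases", "populations", "adjacency")) {
    if (is.null(inputs[[req]])) {
      errs <- c(errs, paste0("inputs.", req, " is required"))
    } else if (!file.exists(inputs[[req]])) {
      errs <- c(errs, paste0("inputs.", req, " not found: ", inputs[[req]]))
    }
  }
  if (!is.null(inputs$covariates) && !file.exists(inputs$covariates)) {
    errs <- c(errs, paste0("inputs.covariates not found: ", inputs$covariates))
  }
  strata <- unlist(config$strata %||% "overall")
  vocab <- c("overall", "male", "female", "cardia", "non_cardia")
  bad_strata <- setdiff(strata, vocab)
  if (length(bad_strata)) {
    errs <- c(errs, paste0("unknown strata: ", paste(bad_strata, collapse = ", "),
                           " (allowed: ", paste(vocab, collapse = ", "), ")"))
  }
  mcmc <- config$mcmc %||% list()
  known_mc <- c("n_chains", "n_iter", "n_burn", "thin", "seed")
  unknown_mc <- setdiff(names(mcmc), known_mc)
  if (length(unknown_mc)) {
    errs <- c(errs, paste0("unknown mcmc key(s): ",
                           paste(unknown_mc, collapse = ", ")))
  }
  if (!is.null(mcmc$n_burn) && !is.null(mcmc$n_iter) &&
      mcmc$n_burn >= mcmc$n_iter) {
    errs <- c(errs, "mcmc.n_burn must be smaller than mcmc.n_iter")
  }
  if (length(errs)) {
    stop("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "))
  }
  out <- list(inputs = inputs, strata = strata,
              periods = isTRUE(config$periods),
              mcmc = mcmc, out = config$out %||% "dismap-output",
              seed = as.integer(config$seed %||% 1L))
  class(out) <- "run_config"
  out
}

stratum_filters <- function(stratum) {
  switch(stratum,
         overall = list(sex = NULL, subsite = NULL),
         male = list(sex = "M", subsite = NULL),
         female = list(sex = "F", subsite = NULL),
         cardia = list(sex = NULL, subsite = "cardia"),
         non_cardia = list(sex = NULL, subsite = "non_cardia"),
         stop("unknown stratum: ", stratum))
}

#' Run the full disease-mapping pipeline
#'
#' Reproduces the analysis sequence end-to-end for each requested stratum:
#' standardized counts, the non-spatial GLM residual diagnostics with a
#' Moran's I permutation test, the Bayesian spatial fit (and the
#' spatio-temporal fit when \code{periods} is on), and the IRR / smoothed
#' risk tables. All artifacts land in \code{config$out} with a manifest
#' JSON. Strata whose filtered case table is empty are skipped with a
#' recorded reason; convergence problems are recorded in the manifest, not
#' fatal.
#'
#' @param config a \code{run_config} from \code{\link{validate_config}} (or
#'   anything it accepts)
#' @return the manifest, invisibly (also written to
#'   \code{<out>/manifest.json})
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) config <- validate_config(config)
  t0 <- Sys.time()
  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  cases <- stage("read_cases", read_cases_csv(config$inputs$cases))
  populations <- stage("read_populations",
                       read_populations_csv(config$inputs$populations))
  graph <- stage("read_adjacency", {
    if (grepl("\\.gal$", config$inputs$adjacency, ignore.case = TRUE)) {
      read_gal(config$inputs$adjacency)
    } else {
      read_edge_csv(config$inputs$adjacency,
                    sort(unique(populations$region_id)))
    }
  })
  covariates <- if (!is.null(config$inputs$covariates)) {
    stage("read_covariates",
          read_covariates_csv(config$inputs$covariates, region_ids(graph)))
  } else {
    NULL
  }

  mc <- config$mcmc
  spec <- model_spec(n_chains = mc$n_chains %||% 4L,
                     n_iter = mc$n_iter %||% 30000L,
                     n_burn = mc$n_burn %||% 10000L,
                     thin = mc$thin %||% 10L,
                     seed = mc$seed %||% config$seed)

  # --- diagnostics on the overall table ---
  diag_manifest <- stage("diagnostics", {
    ct <- expected_counts(cases, populations, region_ids(graph))
    pruned <- drop_zero_expected(ct, graph)
    X <- if (!is.null(covariates)) {
      covariate_matrix(covariates, region_ids(graph))[
        match(pruned$counts$region_ids, region_ids(graph)), , drop = FALSE]
    } else {
      NULL
    }
    glm_fit <- fit_poisson_glm(pruned$counts$Y[, 1L], pruned$counts$E[, 1L], X)
    resid <- residual_risk_ratio(pruned$counts$Y[, 1L], pruned$counts$E[, 1L],
                                 glm_fit, pruned$counts$region_ids)
    mt <- morans_i_permutation_test(resid$ratio, pruned$graph %||% graph,
                                    n_permutations = 999L, seed = config$seed)
    resid_path <- file.path(config$out, "residual_ratios.csv")
    utils::write.csv(resid, resid_path, row.names = FALSE, quote = FALSE)
    diag_path <- file.path(config$out, "diagnostics.json")
    jsonlite::write_json(list(I = mt$i_value, p_value = mt$p_value,
                              n_permutations = mt$n_permutations,
                              seed = mt$seed),
                         diag_path, auto_unbox = TRUE, digits = NA)
    list(diagnostics = basename(diag_path),
         residual_table = basename(resid_path),
         moran_i = mt$i_value, moran_p = mt$p_value)
  })

  strata_manifest <- list()
  for (st in config$strata) {
    f <- stratum_filters(st)
    entry <- tryCatch({
      ct <- if (config$periods) {
        expected_counts_by_period(cases, populations, region_ids(graph),
                                  sex = f$sex, subsite = f$subsite)
      } else {
        expected_counts(cases, populations, region_ids(graph),
                        sex = f$sex, subsite = f$subsite)
      }
      if (sum(ct$Y) == 0) {
        list(skipped = TRUE, reason = "no cases after stratum filter")
      } else {
        pruned <- drop_zero_expected(ct, graph)
        cv <- if (!is.null(covariates)) {
          cv_aligned <- covariates[match(pruned$counts$region_ids,
                                         covariates$region_id), , drop = FALSE]
          cv_aligned
        } else {
          NULL
        }
        g_st <- pruned$graph %||% graph
        fit <- if (config$periods) {
          fit_spatiotemporal(pruned$counts, cv, g_st, spec)
        } else {
          fit_spatial(pruned$counts, cv, g_st, spec)
        }
        base <- file.path(config$out, st)
        write_counts_csv(pruned$counts, paste0(base, "_counts.csv"))
        write_draws(fit, paste0(base, "_draws.csv"),
                    paste0(base, "_draws.json"))
        irr <- if (!is.null(cv)) irr_summary(fit) else NULL
        if (!is.null(irr)) write_irr_csv(irr, paste0(base, "_irr.csv"))
        risk <- smoothed_region_risk(fit, temporal = config$periods)
        write_risk_csv(risk, paste0(base, "_risk.csv"),
                       categorize_risk(risk$risk_median))
        list(skipped = FALSE,
             n_regions = length(pruned$counts$region_ids),
             total_cases = sum(ct$Y),
             files = paste0(st, c("_counts.csv", "_draws.csv",
                                  if (!is.null(irr)) "_irr.csv",
                                  "_risk.csv")),
             max_rhat = if (!is.null(fit$rhat)) max(fit$rhat) else NA,
             converged = fit$converged)
      }
    }, error = function(e) {
      list(skipped = TRUE, reason = conditionMessage(e))
    })
    strata_manifest[[st]] <- entry
  }

  manifest <- list(package = "dismap",
                   version = as.character(utils::packageVersion("dismap")),
                   seed = config$seed,
                   periods = config$periods,
                   mcmc = unclass(spec)[c("n_chains", "n_iter", "n_burn", "thin")],
                   diagnostics = diag_manifest,
                   strata = strata_manifest,
                   runtime_seconds = as.numeric(difftime(Sys.time(), t0,
                                                         units = "secs")))
  jsonlite::write_json(manifest, file.path(config$out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
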