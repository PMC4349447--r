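# Orchestration: one reproducible run of the full three-stage scan plus
# probes, with every table written as a TSV artifact, and a reporter that
# formats those artifacts (and only those artifacts) into a readable
# summary.

#' Pipeline configuration
#'
#' Collects every tunable of a run with its default. \code{p_crit = "auto"}
#' means the stage-2/3 inclusion/removal criterion is the stage-1 FDR
#' nominal critical value.
#'
#' @param q family-wide FDR rate for stage 1 (default 0.001).
#' @param prior_vars character vector of prior-hypothesis variables
#'   (exempted to \code{prior_alpha}).
#' @param prior_alpha nominal level for prior variables (default 0.05).
#' @param m_imputations,imp_iterations,imp_max_predictors chained-equation
#'   settings (defaults 5, 10, 20).
#' @param domain_method stage-2 stepwise method (default backwards).
#' @param final_method stage-3 method (default subset).
#' @param compare_methods also run forwards/backwards/subset at stage 3 and
#'   emit a consistency report (default TRUE).
#' @param p_crit numeric criterion or \code{"auto"}.
#' @param fill_value partner-encoding fill (default 0, the lowest feasible
#'   value).
#' @param interaction_p,quadratic_p probe criteria (default 0.001).
#' @param ordinal_bins outcome bins for the proportional-odds refit.
#' @param run_factor,run_tree toggle the factor-space and tree sensitivity
#'   analyses.
#' @param tree_alpha,tree_min_leaf CHAID-style tree settings.
#' @param prevalence_delta outcome shifts translated into tail-prevalence
#'   changes (default +/- 3 points).
#' @param seed run seed.
#' @return list of class \code{exwas_config}.
#' @export
exwas_config <- function(q = 0.001, prior_vars = character(0),
                         prior_alpha = 0.05, m_imputations = 5,
                         imp_iterations = 10, imp_max_predictors = 20,
                         domain_method = "backwards",
                         final_method = "subset", compare_methods = TRUE,
                         p_crit = "auto", fill_value = 0,
                         interaction_p = 0.001, quadratic_p = 0.001,
                         ordinal_bins = 20, run_factor = TRUE,
                         run_tree = TRUE, tree_alpha = 0.001,
                         tree_min_leaf = 50,
                         prevalence_delta = c(3, -3), seed = 1L) {
  structure(as.list(environment()), class = "exwas_config")
}

write_tsv <- function(x, dir, name) {
  utils::write.table(x, file.path(dir, name), sep = "\t",
                     row.names = FALSE, quote = FALSE, na = "")
}

#' Run the full exposome scan pipeline
#'
#' Executes, in order: degenerate-variable exclusion, standardization (the
#' scale record is frozen before imputation), partner encoding, the
#' univariable scan with the FDR criterion (and prior-hypothesis
#' exemptions), chained-equation imputation of the stage-1 survivors,
#' domain-specific models, the combined final model (re-estimated on every
#' imputation and pooled), the interaction/quadratic/mediation probes, the
#' sensitivity refits, and the prevalence-shift translation. Each stage
#' writes its table to \code{out_dir}; any stage error aborts with the
#' stage name after writing a partial-results manifest.
#'
#' @param em an \code{\link{exposome_matrix}} (raw scale).
#' @param outcome numeric outcome vector (\code{NA} = outcome missing;
#'   such subjects still inform imputation).
#' @param config an \code{\link{exwas_config}}.
#' @param out_dir run directory (created; default a tempdir subdirectory).
#' @param mediators optional named mediator matrix for the mediation probe.
#' @return invisibly, a list with all stage results and \code{out_dir}.
#' @export
run_pipeline <- function(em, outcome, config = exwas_config(),
                         out_dir = tempfile("exwas_run_"),
                         mediators = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  res <- list(out_dir = out_dir, config = config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      manifest <- list(status = "aborted", failed_stage = name,
                       message = conditionMessage(e),
                       stages_completed = names(res))
      jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                           auto_unbox = TRUE, pretty = TRUE)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  res$dropped <- stage("drop_degenerate", {
    dd <- drop_degenerate(em, outcome)
    em <- dd$matrix
    write_tsv(data.frame(dropped = dd$dropped), out_dir, "dropped.tsv")
    dd$dropped
  })
  em <- subset_exposome(em, setdiff(colnames(em$data), res$dropped))

  stage("standardize", {
    # the stage expression is a promise evaluated in this function's frame,
    # so plain assignment updates run_pipeline's `em`
    em <- standardize(em)
    em <- encode_partner_variables(em, config$fill_value)
    write_tsv(data.frame(name = names(em$scale), sd = em$scale),
              out_dir, "scale_record.tsv")
  })

  res$screen <- stage("screen", {
    scan <- univariable_scan(em, outcome)
    dec <- fdr_threshold(scan$p, config$q)
    scan <- apply_prior_hypotheses(scan, config$prior_vars, dec,
                                   config$prior_alpha)
    write_tsv(scan, out_dir, "screen.tsv")
    write_tsv(qq_plot_data(scan$p), out_dir, "qq.tsv")
    jsonlite::write_json(
      list(m = dec$m, q = dec$q, threshold = dec$threshold,
           critical_value = dec$critical_value,
           bonferroni_floor = dec$bonferroni_floor, n_pass = dec$n_pass,
           n_pass_with_priors = sum(scan$passes_fdr)),
      file.path(out_dir, "fdr.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
    scan
  })
  fdr <- attr(res$screen, "fdr")
  p_crit <- if (identical(config$p_crit, "auto")) {
    if (fdr$critical_value > 0) fdr$critical_value else config$q / fdr$m
  } else config$p_crit
  res$p_crit <- p_crit

  res$imputation <- stage("impute", {
    survivors <- res$screen$name[res$screen$passes_fdr]
    if (!length(survivors))
      stop("no stage-1 survivors; nothing to model")
    em_sel <- subset_exposome(em, survivors)
    mice_impute(em_sel, outcome, M = config$m_imputations,
                n_iter = config$imp_iterations, seed = config$seed,
                max_predictors = config$imp_max_predictors)
  })
  em1 <- complete_data(res$imputation, 1)   # designated selection dataset

  res$domains <- stage("domain_models", {
    dm <- domain_models(em1, outcome, res$screen,
                        method = config$domain_method, p_crit = p_crit)
    write_tsv(dm$table, out_dir, "domain_models.tsv")
    dm
  })

  res$final <- stage("final_model", {
    ff <- final_model(em1, outcome, res$domains,
                      method = config$final_method, p_crit = p_crit,
                      screen_results = res$screen)
    tab <- ff$table
    tab$rank_partial <- rank(-abs(tab$partial_r), ties.method = "first")
    write_tsv(tab[order(tab$rank_partial), ], out_dir, "final_model.tsv")
    if (!is.null(ff$tiers)) write_tsv(ff$tiers, out_dir, "tiers.tsv")
    ff
  })
  # Table-1-style summary with final-model counts per domain
  stage("domain_summary", {
    summ <- res$domains$summary
    summ$n_final <- vapply(summ$domain, function(dm)
      sum(em1$codebook$domain[match(res$final$terms, em1$codebook$name)]
          == dm), integer(1))
    write_tsv(summ, out_dir, "domain_summary.tsv")
    res$domains$summary <- summ
  })

  res$pooled <- stage("pool", {
    if (length(res$final$terms) && config$m_imputations > 1) {
      fits <- lapply(seq_len(config$m_imputations), function(i)
        refit_model(complete_data(res$imputation, i), outcome,
                    res$final$terms, p_crit))
      pooled <- pool_rubin(fits)
      write_tsv(pooled$table, out_dir, "final_model_pooled.tsv")
      pooled
    } else NULL
  })

  res$attenuation <- stage("attenuation", {
    if (nrow(res$domains$table)) {
      att <- attenuation_summary(res$screen, res$domains$table)
      write_tsv(att$table, out_dir, "attenuation.tsv")
      att
    } else NULL
  })

  res$interactions <- stage("interactions", {
    if (length(res$final$terms) >= 2) {
      sc <- interaction_scan(res$final, em1, outcome,
                             p_crit = config$interaction_p)
      write_tsv(sc, out_dir, "interactions.tsv")
      red <- reduce_interactions(sc, em1, outcome, res$final)
      if (nrow(red$retained))
        write_tsv(red$retained, out_dir, "interactions_reduced.tsv")
      list(scan = sc, reduced = red)
    } else NULL
  })

  res$quadratics <- stage("quadratics", {
    if (length(res$final$terms)) {
      qt <- quadratic_tests(res$final, em1, outcome,
                            p_crit = config$quadratic_p)
      write_tsv(qt, out_dir, "quadratics.tsv")
      qt
    } else NULL
  })

  res$mediation <- stage("mediation", {
    if (!is.null(mediators) && length(res$final$terms)) {
      md <- mediation_analysis(res$final, em1, outcome, mediators)
      write_tsv(md$table, out_dir, "mediation.tsv")
      md
    } else NULL
  })

  res$ordinal <- stage("ordinal_refit", {
    if (length(res$final$terms)) {
      of <- ordinal_refit(res$final, em1, outcome,
                          n_bins = config$ordinal_bins)
      write_tsv(of$table, out_dir, "ordinal_model.tsv")
      of
    } else NULL
  })

  res$consistency <- stage("consistency", {
    if (config$compare_methods && length(res$final$candidate_pool)) {
      fits <- list()
      for (mth in c("forwards", "backwards", "subset")) {
        fits[[mth]] <- if (mth == config$final_method) res$final else
          stepwise_fit(em1, outcome, res$final$candidate_pool,
                       method = mth, p_crit = p_crit)$fit
      }
      cr <- consistency_report(fits)
      write_tsv(cr$inclusion, out_dir, "consistency_inclusion.tsv")
      write_tsv(data.frame(method = names(cr$r_squared),
                           r_squared = cr$r_squared), out_dir,
                "consistency_r2.tsv")
      cr
    } else NULL
  })

  res$factors <- stage("factor_sensitivity", {
    if (config$run_factor) {
      survivors <- res$screen$name[res$screen$passes_fdr]
      fs <- factor_sensitivity(subset_exposome(em1, survivors), outcome,
                               p_crit = p_crit, final_fit = res$final)
      write_tsv(data.frame(factor = names(fs$attribution),
                           top_variable = fs$attribution,
                           selected = names(fs$attribution) %in%
                             fs$scores_fit$terms),
                out_dir, "factors.tsv")
      fs
    } else NULL
  })

  res$tree <- stage("chaid_tree", {
    if (config$run_tree && length(res$final$terms)) {
      tr <- chaid_tree(subset_exposome(em1, res$final$terms), outcome,
                       alpha_split = config$tree_alpha,
                       min_leaf = config$tree_min_leaf)
      write_tsv(chaid_edges(tr), out_dir, "tree_edges.tsv")
      writeLines(utils::capture.output(print(tr)),
                 file.path(out_dir, "tree.txt"))
      tr
    } else NULL
  })

  res$prevalence <- stage("prevalence", {
    y <- outcome[!is.na(outcome)]
    pv <- data.frame(delta = config$prevalence_delta,
                     prevalence = vapply(config$prevalence_delta,
                                         function(d) prevalence_shift(y, d),
                                         numeric(1)))
    write_tsv(pv, out_dir, "prevalence.tsv")
    pv
  })

  stage("manifest", {
    manifest <- list(status = "complete", seed = config$seed,
                     q = config$q, p_crit = p_crit,
                     n_subjects = nrow(em$data),
                     n_variables_screened = ncol(em$data),
                     n_dropped = length(res$dropped),
                     n_stage1 = sum(res$screen$passes_fdr),
                     n_domain_model = nrow(res$domains$table),
                     n_final = length(res$final$terms),
                     final_r_squared = res$final$r_squared,
                     package_version =
                       as.character(utils::packageVersion("exposcan")),
                     config = config[setdiff(names(config), "prior_vars")])
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  })
  invisible(res)
}

report_line <- function(...) paste0(..., collapse = "")

#' Format a run directory into a readable report
#'
#' Reads the TSV/JSON artifacts of a completed (or partial) run and formats
#' them into one text document: domain counts, the final model ranked by
#' partial correlation, attenuation, interaction/quadratic/mediation
#' sections and the sensitivity overlaps. Nothing is recomputed, so
#' regenerating the report from an archived run directory is byte-identical.
#' Missing artifacts are listed and the report is still produced.
#'
#' @param run_dir a directory written by \code{\link{run_pipeline}}.
#' @param file output file (default \code{report.txt} inside the run
#'   directory).
#' @return the report path, invisibly.
#' @export
make_report <- function(run_dir, file = file.path(run_dir, "report.txt")) {
  rd <- function(name) {
    p <- file.path(run_dir, name)
    if (file.exists(p)) utils::read.delim(p, check.names = FALSE) else NULL
  }
  missing_artifacts <- character(0)
  need <- function(name) {
    x <- rd(name)
    if (is.null(x)) missing_artifacts <<- c(missing_artifacts, name)
    x
  }
  out <- c("Exposome-wide association scan: run report",
           strrep("=", 44), "")
  man <- if (file.exists(file.path(run_dir, "manifest.json")))
    jsonlite::read_json(file.path(run_dir, "manifest.json"),
                        simplifyVector = TRUE) else NULL
  fdr <- if (file.exists(file.path(run_dir, "fdr.json")))
    jsonlite::read_json(file.path(run_dir, "fdr.json"),
                        simplifyVector = TRUE) else NULL
  if (!is.null(man) && identical(man$status, "complete")) {
    out <- c(out, sprintf("Subjects (analysis): see screen table; variables screened: %s (%s dropped as degenerate)",
                          man$n_variables_screened, man$n_dropped))
  } else if (!is.null(man)) {
    out <- c(out, sprintf("PARTIAL RUN: failed at stage '%s' (%s)",
                          man$failed_stage, man$message))
  }
  if (!is.null(fdr))
    out <- c(out, sprintf(
      "Stage 1: FDR q = %s over m = %s tests; criterion p <= %.6g (nominal %.6g); %s pass (%s with priors)",
      fdr$q, fdr$m, fdr$threshold, fdr$critical_value, fdr$n_pass,
      fdr$n_pass_with_priors), "")

  ds <- need("domain_summary.tsv")
  if (!is.null(ds)) {
    out <- c(out, "Domain-specific models", strrep("-", 24),
             sprintf("%-28s %7s %8s %4s %8s %6s", "domain", "total",
                     "stage1", "df", "R2", "final"),
             sprintf("%-28s %7d %8d %4d %7.2f%% %6d", ds$domain,
                     ds$n_total, ds$n_selected, ds$df,
                     100 * ds$r_squared, ds$n_final), "")
  }
  fm <- need("final_model.tsv")
  if (!is.null(fm)) {
    out <- c(out, "Final model (ranked by partial correlation)",
             strrep("-", 44))
    man_r2 <- if (!is.null(man) && !is.null(man$final_r_squared))
      sprintf("R^2 = %.2f%%", 100 * man$final_r_squared) else ""
    out <- c(out, man_r2,
             sprintf("%-18s %8s [%7s,%7s] %10s %8s", "term", "B", "lo",
                     "hi", "p", "partial r"),
             sprintf("%-18s %8.3f [%7.3f,%7.3f] %10.2e %8.3f", fm$term,
                     fm$B, fm$ci_lo, fm$ci_hi, fm$p, fm$partial_r), "")
    if (nrow(fm) == 0 || all(fm$term == ".partner_status."))
      out <- c(out, "(intercept-only final model)", "")
  }
  att <- rd("attenuation.tsv")
  if (!is.null(att) && nrow(att)) {
    ok <- !att$sign_flip & att$attenuation_pct >= 0
    out <- c(out, sprintf(
      "Attenuation under within-domain adjustment: mean %.0f%% (range %.0f%% to %.0f%%) over %d variables; %d sign flips reported separately",
      mean(att$attenuation_pct[ok]), min(att$attenuation_pct[ok]),
      max(att$attenuation_pct[ok]), sum(ok), sum(att$sign_flip)), "")
  }
  ints <- rd("interactions.tsv")
  if (!is.null(ints)) {
    nsig <- sum(ints$significant == "TRUE" | ints$significant == TRUE,
                na.rm = TRUE)
    out <- c(out, sprintf("Interactions: %d pairs tested, %d significant",
                          nrow(ints), nsig))
    red <- rd("interactions_reduced.tsv")
    if (!is.null(red) && nrow(red))
      out <- c(out, sprintf("  reduced to %d explanatory pair(s): %s",
                            nrow(red),
                            paste(red$var1, red$var2, sep = ":",
                                  collapse = ", ")))
    out <- c(out, "")
  }
  qd <- rd("quadratics.tsv")
  if (!is.null(qd)) {
    testable <- qd$testable == "TRUE" | qd$testable == TRUE
    out <- c(out, sprintf(
      "Non-linearity: %d of %d variables testable; %d significant quadratic term(s)",
      sum(testable, na.rm = TRUE), nrow(qd),
      sum(qd$significant == TRUE | qd$significant == "TRUE",
          na.rm = TRUE)), "")
  }
  md <- rd("mediation.tsv")
  if (!is.null(md) && nrow(md)) {
    top <- md[order(-md$attenuation_pct), ][seq_len(min(4, nrow(md))), ]
    out <- c(out, "Mediation: largest attenuations:",
             sprintf("  %-18s %5.0f%%%s", top$term, top$attenuation_pct,
                     ifelse(top$no_direct_effect == TRUE |
                              top$no_direct_effect == "TRUE",
                            " (consistent with no direct effect)", "")),
             "")
  }
  orz <- rd("ordinal_model.tsv")
  if (!is.null(orz) && nrow(orz)) {
    out <- c(out, sprintf(
      "Ordinal (proportional-odds) refit: %d terms; OR > 1 beneficial",
      nrow(orz)), "")
  }
  cr2 <- rd("consistency_r2.tsv")
  if (!is.null(cr2)) {
    out <- c(out, "Method consistency (R^2):",
             sprintf("  %-10s %.4f", cr2$method, cr2$r_squared), "")
  }
  pv <- rd("prevalence.tsv")
  if (!is.null(pv)) {
    out <- c(out, "Prevalence of the worst-10% tail under outcome shifts:",
             sprintf("  delta %+g points -> %.1f%%", pv$delta,
                     100 * pv$prevalence), "")
  }
  scr <- rd("screen.tsv")
  if (!is.null(scr) && "route" %in% names(scr)) {
    pri <- scr[scr$route == "prior", , drop = FALSE]
    if (nrow(pri))
      out <- c(out, sprintf(
        "Prior-hypothesis exemptions: %s", paste(pri$name,
                                                 collapse = ", ")), "")
  }
  if (length(missing_artifacts))
    out <- c(out, paste("Missing artifacts:",
                        paste(missing_artifacts, collapse = ", ")))
  writeLines(out, file)
  invisible(file)
}
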