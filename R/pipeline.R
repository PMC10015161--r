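#' Pipeline run configuration
#'
#' Collects paths and settings for an end-to-end run: alignment and
#' constraint inputs, an optional candidate-topology list, model and
#' resampling settings, an optional scenario-rule file and an output
#' directory. Configurations serialize to JSON and round-trip losslessly.
#'
#' @param alignment path to the aligned FASTA input.
#' @param constraint path to the OTU-constraint JSON.
#' @param out_dir output directory (created if absent).
#' @param trees optional path to a candidate-topology list (one Newick per
#'   line); `NULL` enumerates all topologies over the OTUs.
#' @param model `"JTT"` or `"Poisson"`.
#' @param k gamma categories.
#' @param optimize_alpha,optimize_pinv,share_rates,tests see [topo_test()].
#' @param B,scales,seed RELL settings, see [rell_config()].
#' @param rules optional path to a scenario-rule JSON; `NULL` uses
#'   [duplication_rules()].
#' @param verbose print stage progress.
#' @return an object of class `run_config`.
#' @export
run_config <- function(alignment, constraint, out_dir, trees = NULL,
                       model = "JTT", k = 4L, optimize_alpha = TRUE,
                       optimize_pinv = TRUE, share_rates = FALSE,
                       tests = TRUE, B = 10000L,
                       scales = seq(0.5, 1.4, by = 0.1), seed = 1L,
                       rules = NULL, verbose = FALSE) {
  structure(list(alignment = alignment, constraint = constraint,
                 out_dir = out_dir, trees = trees, model = model,
                 k = as.integer(k), optimize_alpha = optimize_alpha,
                 optimize_pinv = optimize_pinv, share_rates = share_rates,
                 tests = tests, B = as.integer(B),
                 scales = as.numeric(scales), seed = as.integer(seed),
                 rules = rules, verbose = verbose),
            class = "run_config")
}

#' @rdname run_config
#' @param path JSON file path.
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, x[!vapply(x, is.null, TRUE)])
}

#' Write a site log-likelihood matrix as TSV
#'
#' Row 1 holds the pattern multiplicities (label `weight`); the following
#' rows hold one tree each (label = Newick string), with per-pattern log
#' likelihoods in the pattern columns.
#'
#' @param sl a [site_loglik_matrix].
#' @param path output path.
#' @export
write_site_loglik <- function(sl, path) {
  stopifnot(inherits(sl, "site_loglik_matrix"))
  m <- rbind(sl$weights, sl$loglik)
  df <- data.frame(tree = c("weight", sl$trees), m, check.names = FALSE)
  colnames(df) <- c("tree", paste0("pattern_", seq_along(sl$weights)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full pipeline: enumerate, fit, test, classify, report
#'
#' Chains the whole analysis from files on disk and writes its artifacts:
#' the enumerated (or supplied) topologies (`topologies.nwk`), per-tree
#' fit summaries (`fits.tsv`), the site log-likelihood matrix
#' (`site_loglik.tsv`), the ranked table (`table.tsv` / `table.json`) and
#' a run log with the seed, package version and stage timings
#' (`run_log.txt`). A failing stage aborts with the stage name; a
#' `MANIFEST` file records which artifacts were completed.
#'
#' @param cfg a [run_config()].
#' @return the `topo_test` fit, invisibly.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- file.path(cfg$out_dir, "MANIFEST")
  log_path <- file.path(cfg$out_dir, "run_log.txt")
  writeLines(c("status: running"), manifest)
  done <- character()
  log_lines <- c(sprintf("topotest %s | seed %d | %s",
                         as.character(utils::packageVersion("topotest")),
                         cfg$seed, format(Sys.time(), "%Y-%m-%d %H:%M:%S")))
  t0 <- proc.time()[["elapsed"]]
  stage <- function(name, expr) {
    s <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      writeLines(c("status: failed", paste("failed stage:", name),
                   paste("done:", done)), manifest)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    log_lines <<- c(log_lines, sprintf("%-10s %8.2fs", name,
                                       proc.time()[["elapsed"]] - s))
    res
  }

  msa <- stage("read", {
    if (!file.exists(cfg$alignment)) stop("missing alignment: ", cfg$alignment)
    if (!file.exists(cfg$constraint)) stop("missing constraint: ",
                                           cfg$constraint)
    read_msa_fasta(cfg$alignment)
  })
  constraint <- read_constraint(cfg$constraint)
  topologies <- stage("enumerate", {
    tl <- if (is.null(cfg$trees)) enumerate_topologies(names(constraint$otus))
          else read_tree_list(cfg$trees)
    write_tree_list(tl, file.path(cfg$out_dir, "topologies.nwk"))
    done <<- c(done, "topologies.nwk")
    tl
  })
  rules <- if (is.null(cfg$rules)) duplication_rules() else
    read_rules(cfg$rules)
  fit <- stage("evaluate", topo_test(
    msa, constraint, topologies = topologies,
    model = subst_model(cfg$model, k = cfg$k),
    rell = rell_config(B = cfg$B, scales = cfg$scales, seed = cfg$seed),
    rules = rules, optimize_alpha = cfg$optimize_alpha,
    optimize_pinv = cfg$optimize_pinv, share_rates = cfg$share_rates,
    tests = cfg$tests, verbose = cfg$verbose))
  stage("report", {
    fits_df <- data.frame(
      tree = fit$site_loglik$trees,
      loglik = vapply(fit$fits, `[[`, 0, "loglik"),
      alpha = vapply(fit$fits, `[[`, 0, "alpha"),
      p_inv = vapply(fit$fits, `[[`, 0, "p_inv"),
      converged = vapply(fit$fits, `[[`, TRUE, "converged"))
    utils::write.table(fits_df, file.path(cfg$out_dir, "fits.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_site_loglik(fit$site_loglik,
                      file.path(cfg$out_dir, "site_loglik.tsv"))
    write_topo_table(fit$table, file.path(cfg$out_dir, "table"))
    done <<- c(done, "fits.tsv", "site_loglik.tsv", "table.tsv", "table.json")
    NULL
  })
  all_converged <- all(vapply(fit$fits, `[[`, TRUE, "converged"))
  log_lines <- c(log_lines,
                 sprintf("total      %8.2fs", proc.time()[["elapsed"]] - t0),
                 paste("converged:", all_converged))
  writeLines(log_lines, log_path)
  writeLines(c(if (all_converged) "status: complete" else
               "status: complete (partial convergence)",
               paste("done:", paste(done, collapse = " "))), manifest)
  invisible(fit)
}
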