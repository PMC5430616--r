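#' Validate a pipeline configuration
#'
#' Checks key names (unknown keys are an error), required fields, referenced
#' files, and per-stage parameter ranges before any stage runs.
#'
#' @param config nested list, or path to a YAML file with the same structure.
#'   Top-level keys: `input` (either `genotypes` + `format` +
#'   `cohort_samples`, or `simulate` with [cohort_spec()] fields), `qc`,
#'   `prune`, `pca`, `proxies`, `admixture`, `scan`, `bootstrap`,
#'   `output_dir`, `seed`.
#' @return the validated config (invisibly), with defaults filled in
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  allowed <- list(
    input = c("genotypes", "format", "cohort_samples", "simulate"),
    qc = c("call_rate_min", "maf_min"),
    prune = c("r2_max", "window_snps", "step_snps"),
    pca = c("n_components"),
    proxies = c("poles", "n_proxy"),
    admixture = c("K", "mode", "n_restarts", "tol", "max_iter"),
    scan = c("mode", "focal", "top_k", "merge_bp"),
    bootstrap = c("B", "alpha"),
    output_dir = NULL, seed = NULL)
  unknown <- setdiff(names(config), names(allowed))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  for (sec in intersect(names(config), names(allowed))) {
    if (!is.null(allowed[[sec]]) && is.list(config[[sec]])) {
      bad <- setdiff(names(config[[sec]]), allowed[[sec]])
      if (length(bad))
        stop("unknown config key(s) in '", sec, "': ",
             paste(bad, collapse = ", "))
    }
  }
  if (is.null(config$seed))
    stop("config must set an explicit seed (no clock seeding)")
  if (is.null(config$output_dir)) stop("config must set output_dir")
  if (is.null(config$input)) stop("config must have an input section")
  if (is.null(config$input$simulate)) {
    if (is.null(config$input$genotypes))
      stop("input needs either 'genotypes' or 'simulate'")
    if (!file.exists(config$input$genotypes) &&
        !file.exists(paste0(config$input$genotypes, ".bed")))
      stop("input genotype file not found: ", config$input$genotypes)
  }
  defaults <- list(
    qc = list(call_rate_min = 0.99, maf_min = 0.05),
    prune = list(r2_max = 0.3, window_snps = 50, step_snps = 5),
    pca = list(n_components = 10),
    proxies = list(n_proxy = 30),
    admixture = list(K = 3, mode = "supervised", n_restarts = 3,
                     tol = 1e-7, max_iter = 2000),
    scan = list(mode = "lsbl", focal = 2, top_k = 10, merge_bp = 1e6),
    bootstrap = list(B = 10000, alpha = 0.05))
  for (sec in names(defaults))
    config[[sec]] <- modifyList(defaults[[sec]], config[[sec]] %||% list())
  invisible(config)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: qc, prune, pca, proxies, admixture, frequencies,
#' scan, report.  Each stage writes its artifact under `output_dir` and is
#' recorded in a JSON manifest (parameters, seeds, input checksums, per-stage
#' sample/SNP counts).  Re-running with an identical config reproduces
#' identical outputs.
#'
#' With a `simulate` input the study is generated by [make_study()] and the
#' proxy poles default to the simulated ancestries (true pool membership is
#' NOT used: proxies are selected from PCA rankings like any reference
#' panel).
#'
#' @param config see [validate_config()]
#' @return the run manifest (list), invisibly
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  out <- config$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = config, stages = list())
  t_all <- proc.time()[3]
  log_con <- file(file.path(out, "run.log"), "w")
  on.exit(close(log_con), add = TRUE)
  say <- function(...) {
    msg <- paste0("[", format(Sys.time(), "%H:%M:%S"), "] ", ...)
    writeLines(msg, log_con)
    message(msg)
  }
  stage <- function(name, counts) {
    manifest$stages[[name]] <<- c(list(completed = TRUE), counts)
    say("stage ", name, ": ",
        paste(names(counts), unlist(counts), sep = "=", collapse = ", "))
  }

  # input
  if (!is.null(config$input$simulate)) {
    spec <- do.call(cohort_spec,
                    modifyList(config$input$simulate,
                               list(seed = config$seed)))
    study <- make_study(spec)
    gm <- study$combined
    cohort_ids <- sample_ids(study$cohort)
    write_genotypes(gm, file.path(out, "simulated.tsv"), "tsv")
  } else {
    gm <- read_genotypes(config$input$genotypes, config$input$format)
    cohort_ids <- readLines(config$input$cohort_samples)
    manifest$input_md5 <- unname(tools::md5sum(config$input$genotypes))
  }
  ref_ids <- setdiff(sample_ids(gm), cohort_ids)

  # 1 qc
  thr <- qc_thresholds(config$qc$call_rate_min, config$qc$maf_min)
  gm_qc <- filter_snps(gm, thr)
  stage("qc", list(n_samples = n_samples(gm_qc), n_snps = n_snps(gm_qc),
                   n_dropped = attr(gm_qc, "n_dropped")))

  # 2 prune
  kept <- ld_prune(gm_qc, config$prune$r2_max, config$prune$window_snps,
                   config$prune$step_snps)
  gm_pruned <- subset_geno(gm_qc, snps = kept)
  writeLines(kept, file.path(out, "pruned_snps.txt"))
  stage("prune", list(n_snps = length(kept)))

  # 3 pca (axes defined by the cohort; references projected)
  model <- pca_fit(gm_pruned, cohort_ids, config$pca$n_components)
  scores_ref <- pca_project(model, subset_geno(gm_pruned, samples = ref_ids))
  write_scores(rbind(model$scores, scores_ref), file.path(out, "pca.tsv"))
  stage("pca", list(n_components = ncol(model$loadings),
                    n_projected = nrow(scores_ref)))

  # 4 proxies
  poles <- config$proxies$poles
  if (is.null(poles)) {
    # no poles declared: alternate max/min along successive components
    K <- config$admixture$K
    combos <- expand.grid(direction = c("max", "min"),
                          pc_index = seq_len(ncol(scores_ref)),
                          stringsAsFactors = FALSE)
    if (K > nrow(combos))
      stop("need explicit proxy poles for K=", K, " with only ",
           ncol(scores_ref), " components")
    poles <- lapply(seq_len(K), function(k)
      list(ancestry = paste0("anc", k), pc_index = combos$pc_index[k],
           direction = combos$direction[k]))
  }
  rankings <- lapply(poles, function(p)
    rank_by_pc(scores_ref, p$pc_index, p$direction))
  names(rankings) <- vapply(poles, `[[`, "", "ancestry")
  panels <- select_proxies(rankings, config$proxies$n_proxy)
  write_panels(panels, file.path(out, "proxy_panels.tsv"))
  stage("proxies", list(n_panels = length(panels),
                        n_proxy = config$proxies$n_proxy))

  # 5 admixture
  assign <- proxy_assignment(panels)
  gm_fit <- subset_geno(gm_pruned, samples = c(cohort_ids, names(assign)))
  fit <- if (config$admixture$mode == "supervised")
    fit_supervised(gm_fit, proxy_assignment = assign, seed = config$seed,
                   n_restarts = config$admixture$n_restarts,
                   tol = config$admixture$tol,
                   max_iter = config$admixture$max_iter)
  else
    fit_unsupervised(gm_fit, config$admixture$K, seed = config$seed,
                     n_restarts = config$admixture$n_restarts,
                     tol = config$admixture$tol,
                     max_iter = config$admixture$max_iter)
  write_admixture(fit, file.path(out, "admixture"))
  stage("admixture", list(K = fit$K, loglik = round(fit$loglik, 2),
                          converged = fit$converged))

  # 6 frequencies on the full QC'd SNP set with Q fixed
  gm_all <- subset_geno(gm_qc, samples = rownames(fit$Q))
  P_all <- component_freqs_given_Q(gm_all, fit$Q)
  write.table(data.frame(snp_id = colnames(P_all), t(P_all),
                         check.names = FALSE),
              file.path(out, "component_freqs.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  stage("frequencies", list(n_snps = ncol(P_all)))

  # 7 scan
  tab <- if (config$scan$mode == "lsbl")
    scan_lsbl(P_all, focal = config$scan$focal, snps = gm_qc$snps)
  else
    stop("pairwise scan requires a comparison panel; run scan_pairwise directly")
  write_diff_table(tab, file.path(out, "scan.tsv"))
  regions <- top_regions(tab, config$scan$top_k, config$scan$merge_bp)
  write_regions(regions, file.path(out, "regions"))
  stage("scan", list(n_scored = nrow(tab), n_regions = nrow(regions)))

  # 8 report
  summ <- attr(tab, "summary")
  manifest$scan_summary <- as.list(summ)
  manifest$elapsed_s <- round(proc.time()[3] - t_all, 1)
  stage("report", list(n_outputs = length(list.files(out)) + 1L))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
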