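#' Validate a pipeline run configuration
#'
#' A run configuration is a named list (or YAML file) with fields: `stages`
#' (subset of `"simulate"`, `"strain"`, `"stats"`, `"roc"`, `"cluster"`),
#' `seed` (mandatory whenever a stochastic stage — simulate, roc bootstrap,
#' cluster — is enabled), `out_dir`, and optional blocks `cohort` (arguments
#' to [cohort_spec()]), `alpha` (phase-detection level-off fraction),
#' `n_boot`, `k_range`, `roc_features`, and `mesh_input` (directories of
#' externally tracked mesh sequences, bypassing simulation).
#'
#' @param config Named list or path to a YAML file.
#' @return The validated (and defaulted) config list.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  defaults <- list(stages = c("simulate", "strain"), alpha = 0.2,
                   n_boot = 2000, k_range = 2:6,
                   roc_features = c("global.contractile_sr",
                                    "global.reservoir_strain"))
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  bad <- setdiff(config$stages,
                 c("simulate", "strain", "stats", "roc", "cluster"))
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  stochastic <- intersect(config$stages, c("simulate", "roc", "cluster"))
  if (length(stochastic) && is.null(config$seed))
    stop("seed is mandatory with stochastic stage(s): ",
         paste(stochastic, collapse = ", "))
  if (!is.null(config$mesh_input)) {
    missing <- config$mesh_input[!dir.exists(config$mesh_input)]
    if (length(missing))
      stop("mesh_input path(s) do not exist: ", paste(missing, collapse = ", "))
  } else if (!"simulate" %in% config$stages &&
             any(c("strain", "stats", "roc", "cluster") %in% config$stages)) {
    stop("either enable the simulate stage or provide mesh_input paths")
  }
  if (is.null(config$out_dir)) stop("out_dir is required")
  config
}

units_header <- function(nms) {
  pct <- grepl("strain$", nms) | nms %in% c("laef", "lvef") |
    grepl("(reservoir|conduit|contractile)_strain", nms)
  srp <- grepl("_sr$", nms)
  ml <- grepl("_(edv|esv|sv)$", nms)
  mli <- grepl("_(edvi|esvi)$", nms)
  out <- nms
  out[pct] <- paste0(nms[pct], "[%]")
  out[srp] <- paste0(nms[srp], "[% per normalized time]")
  out[ml] <- paste0(nms[ml], "[mL]")
  out[mli] <- paste0(nms[mli], "[mL/m2]")
  out[nms == "bsa"] <- "bsa[m2]"
  out
}

#' Run the configured analysis pipeline
#'
#' Executes simulate -> strain -> stats/roc/cluster as configured and writes
#' a reproducible result bundle: per-subject phasic metrics and volumetrics
#' (`metrics.csv`, units in headers), global/regional strain curves
#' (`curves.csv`), statistical reports (`stats.json`) and a run manifest
#' (`manifest.json`: config, package version, R version, seed). Identical
#' manifest and inputs yield byte-identical outputs.
#'
#' @param config Named list or YAML path; see [validate_config()].
#' @return Invisibly, a list with the in-memory results (`table`, `curves`,
#'   `stats`) and the output paths.
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  table <- NULL; curves_rows <- list(); stats_out <- list()

  if (!is.null(config$mesh_input)) {
    seqs <- lapply(config$mesh_input, read_mesh_sequence)
    ids <- sprintf("S%03d", seq_along(seqs))
    rows <- list()
    for (i in seq_along(seqs)) {
      ana <- tryCatch(analyze_sequence(seqs[[i]], alpha = config$alpha),
                      error = function(e)
                        stop("strain stage failed for subject ", ids[i], ": ",
                             conditionMessage(e)))
      rows[[i]] <- as.data.frame(c(list(id = ids[i]), as.list(ana$features)),
                                 check.names = FALSE)
      curves_rows[[i]] <- curve_long(ids[i], ana$curves)
    }
    table <- do.call(rbind, rows)
  } else if ("simulate" %in% config$stages) {
    spec <- do.call(cohort_spec, c(config$cohort,
                                   list(seed = as.integer(config$seed))))
    cohort <- generate_cohort(spec, keep_sequences = TRUE,
                              alpha = config$alpha)
    table <- cohort$table
    for (i in seq_along(cohort$sequences)) {
      ana <- analyze_sequence(cohort$sequences[[i]], alpha = config$alpha)
      curves_rows[[i]] <- curve_long(table$id[i], ana$curves)
    }
  }

  feats <- intersect(phasic_feature_names(), names(table))
  if ("stats" %in% config$stages) {
    if (is.null(table$group)) stop("stats stage needs a group column")
    gs <- unique(table$group)
    if (length(gs) != 2) stop("stats stage needs exactly two groups")
    cont <- c(feats, intersect(c("la_edv", "la_esv", "la_edvi", "la_esvi",
                                 "la_sv", "laef", "lvef", "age", "bmi"),
                               names(table)))
    stats_out$group_comparisons <- lapply(stats::setNames(cont, cont),
      function(v) {
        a <- table[[v]][table$group == gs[1]]
        b <- table[[v]][table$group == gs[2]]
        as.list(t_test_groups(a, b))
      })
    reg_cols <- grep("^(septum|lateral|posterior|anterior|inferior)\\.contractile_strain$",
                     names(table), value = TRUE)
    if (length(reg_cols) == 5) {
      long <- data.frame(
        id = rep(table$id, times = 5),
        group = rep(table$group, times = 5),
        region = rep(sub("\\..*$", "", reg_cols), each = nrow(table)),
        value = unlist(table[reg_cols], use.names = FALSE))
      stats_out$mixed_anova_contractile_strain <-
        lapply(split(mixed_anova(long), seq_len(3)), as.list)
    }
  }
  if ("roc" %in% config$stages) {
    gs <- unique(table$group)
    lbl <- as.integer(table$group == gs[1])
    stats_out$roc <- lapply(stats::setNames(config$roc_features,
                                            config$roc_features),
      function(v) roc_analysis(table[[v]], lbl, n_boot = config$n_boot,
                               seed = as.integer(config$seed)))
  }
  if ("cluster" %in% config$stages) {
    X <- as.matrix(table[, feats])
    rownames(X) <- table$id
    cl <- cluster_phenotypes(X, k_range = config$k_range,
                             seed = as.integer(config$seed))
    stats_out$clustering <- list(
      k = cl$k, assignments = as.list(cl$assignments),
      silhouette = cl$silhouette, removed = cl$removed,
      pca_var_explained = cl$pca$var_explained)
  }

  out_tab <- table
  names(out_tab) <- units_header(names(out_tab))
  utils::write.csv(out_tab, file.path(config$out_dir, "metrics.csv"),
                   row.names = FALSE)
  curves <- do.call(rbind, curves_rows)
  utils::write.csv(curves, file.path(config$out_dir, "curves.csv"),
                   row.names = FALSE)
  jsonlite::write_json(stats_out, file.path(config$out_dir, "stats.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  manifest <- list(package = "lastrain",
                   version = as.character(utils::packageVersion("lastrain")),
                   r_version = paste(R.version$major, R.version$minor,
                                     sep = "."),
                   seed = config$seed,
                   config = config[setdiff(names(config), "out_dir")])
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(table = table, curves = curves, stats = stats_out,
                 out_dir = config$out_dir))
}

curve_long <- function(id, curves) {
  t <- curves$frame_times
  scopes <- c("global", LA_REGIONS)
  do.call(rbind, lapply(scopes, function(sc) {
    s <- if (sc == "global") curves$global else curves$regional[, sc]
    sr <- if (sc == "global") curves$global_sr else curves$regional_sr[, sc]
    data.frame(id = id, scope = sc, `time[RR fraction]` = t,
               `strain[%]` = s, `sr[% per normalized time]` = sr,
               check.names = FALSE)
  }))
}
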