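#' Read a cohort CSV with validation
#'
#' Reads a header CSV, checks the columns against the expected variable
#' kinds, enforces complete cases (rows with any missing value are dropped
#' with a message) and validates that binary columns contain only 0/1.
#'
#' @param path CSV file path.
#' @param kinds named character vector (`"binary"`/`"continuous"`) giving
#'   the expected columns.
#' @return validated data frame with attribute `kinds`.
#' @export
read_cohort_csv <- function(path, kinds) {
  stopifnot(file.exists(path))
  df <- utils::read.csv(path, check.names = FALSE)
  unknown <- setdiff(names(df), names(kinds))
  if (length(unknown))
    stop("unknown column(s): ", paste(unknown, collapse = ", "))
  missing_cols <- setdiff(names(kinds), names(df))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  for (v in names(df)) {
    if (!is.numeric(df[[v]]))
      stop("non-numeric values in column ", v)
  }
  cc <- stats::complete.cases(df)
  if (any(!cc)) {
    message(sum(!cc), " row(s) with missing values dropped (complete-case rule)")
    df <- df[cc, , drop = FALSE]
    rownames(df) <- NULL
  }
  for (v in names(df)) {
    if (kinds[[v]] == "binary" && !all(df[[v]] %in% c(0, 1))) {
      bad <- which(!(df[[v]] %in% c(0, 1)))[1]
      stop(sprintf("binary column %s has value %s outside {0,1} at row %d",
                   v, format(df[[v]][bad]), bad))
    }
  }
  attr(df, "kinds") <- kinds[names(df)]
  df
}

#' Write a cohort CSV plus a JSON sidecar
#'
#' Writes the cohort as a header CSV and, when the table carries a
#' generating spec or planted subgroup labels, a `<path>.json` sidecar
#' with the variable kinds, the true generative parameters and the
#' subgroup labels.
#'
#' @param table cohort data frame.
#' @param path output CSV path.
#' @param sidecar write the JSON sidecar.
#' @return invisibly, the paths written.
#' @export
write_cohort_csv <- function(table, path, sidecar = TRUE) {
  if (anyNA(table)) stop("missing values are not allowed in a cohort CSV")
  utils::write.csv(table, path, row.names = FALSE)
  paths <- path
  if (sidecar) {
    spec <- attr(table, "spec")
    meta <- list(
      kinds = as.list(resolve_kinds(table, NULL)),
      subgroup = attr(table, "subgroup")
    )
    if (!is.null(spec)) {
      meta$spec <- list(variables = spec$variables,
                        interactions = spec$interactions)
    }
    jpath <- paste0(path, ".json")
    jsonlite::write_json(meta, jpath, auto_unbox = TRUE, digits = NA,
                         na = "null", matrix = "rowmajor")
    paths <- c(paths, jpath)
  }
  invisible(paths)
}

#' Export a fitted network as GraphML
#'
#' @param fit an `mgm_fit` or `weighted_network`.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_graphml <- function(fit, path) {
  net <- as_weighted_network(fit)
  signed <- net$weights * ifelse(net$signs == 0, 1, net$signs)
  g <- igraph::graph_from_adjacency_matrix(signed, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Run the full network-psychometric pipeline
#'
#' Executes the full analysis on a cohort table: standardization and MGM
#' fit, node predictability, centrality and shortest-path mediation from
#' the group node, spinglass node communities, bootstrap edge confidence
#' intervals, the group-difference table and z-profiles, and consensus
#' clustering of the minority individuals. When `out_dir` is given, all
#' artifacts are written (edge list CSV, GraphML, centrality CSV, path
#' report JSON, CI CSV, group table CSV, profile CSV, partition JSON and a
#' machine-readable run manifest).
#'
#' @param table cohort data frame (or CSV path, requiring `kinds`).
#' @param kinds optional named kind vector.
#' @param group name of the binary group column.
#' @param gamma EBIC hyperparameter (default 0.3).
#' @param B bootstrap replicates (default 1000).
#' @param consensus_iterations Louvain runs per consensus round
#'   (default 1000).
#' @param tau consensus agreement threshold.
#' @param seed integer seed driving every stochastic stage.
#' @param stratifier optional column; the network stages are rerun per
#'   stratum and returned under `strata`.
#' @param subgroups run consensus clustering of minority individuals.
#' @param out_dir optional output directory for artifacts.
#' @return list with components `fit`, `predictability`, `centrality`,
#'   `mediation`, `node_communities`, `bootstrap`, `group_table`,
#'   `profiles`, `person_partition`, `strata`, `manifest`.
#' @export
run_pipeline <- function(table, kinds = NULL, group = "MS", gamma = 0.3,
                         B = 1000, consensus_iterations = 1000, tau = 0.5,
                         seed = 1, stratifier = NULL, subgroups = TRUE,
                         out_dir = NULL) {
  if (is.character(table)) table <- read_cohort_csv(table, kinds)
  full_table <- table
  if (!is.null(stratifier)) {
    stopifnot(stratifier %in% names(table))
    # the stratifier splits reruns but is not itself a network node
    table <- table[setdiff(names(table), stratifier)]
  }
  kinds <- resolve_kinds(table, kinds[names(table)])
  config <- list(group = group, gamma = gamma, B = B,
                 consensus_iterations = consensus_iterations, tau = tau,
                 seed = seed, stratifier = stratifier,
                 subgroups = subgroups, kinds = as.list(kinds))

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  fit <- stage("fit", fit_mgm(table, kinds = kinds, gamma = gamma))
  net <- as_weighted_network(fit)
  centrality <- stage("metrics", centrality_table(net))
  mediation <- stage("metrics", mediation_report(net, group))
  node_comm <- stage("communities",
                     spinglass_communities(net, seed = seed))
  boot <- stage("bootstrap",
                bootstrap_edges(table, B = B, gamma = gamma, seed = seed + 1))
  group_table <- stage("group_stats", group_difference_table(table, group))
  profiles <- stage("group_stats", {
    ptab <- if (is.null(stratifier)) table else full_table
    z_profiles(ptab, group, variables = setdiff(names(table), group),
               stratifier = stratifier)
  })
  person_part <- NULL
  if (subgroups) {
    person_part <- stage("cluster_individuals", {
      rows <- which(table[[group]] == 1)
      sim <- person_similarity(table, rows,
                               measures = setdiff(names(table),
                                                  c(group, stratifier)))
      consensus_cluster(sim, iterations = consensus_iterations, tau = tau,
                        seed = seed + 2)
    })
  }
  strata <- NULL
  if (!is.null(stratifier)) {
    strata <- lapply(split(seq_len(nrow(full_table)),
                           full_table[[stratifier]]),
                     function(idx) {
                       sfit <- fit_mgm(table[idx, , drop = FALSE],
                                       gamma = gamma)
                       snet <- as_weighted_network(sfit)
                       list(fit = sfit,
                            centrality = centrality_table(snet),
                            mediation = mediation_report(snet, group))
                     })
  }
  manifest <- list(
    package = "cohortmgm",
    package_version = as.character(utils::packageVersion("cohortmgm")),
    r_version = R.version.string,
    n = nrow(table), p = ncol(table),
    config = config,
    config_hash = unname(config_hash(config)),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  result <- list(fit = fit, predictability = fit$predictability,
                 centrality = centrality, mediation = mediation,
                 node_communities = node_comm, bootstrap = boot,
                 group_table = group_table, profiles = profiles,
                 person_partition = person_part, strata = strata,
                 manifest = manifest)
  if (!is.null(out_dir)) write_pipeline_artifacts(result, out_dir)
  result
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA,
                       na = "null")
  tools::md5sum(tmp)
}

write_pipeline_artifacts <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(f) file.path(out_dir, f)
  utils::write.csv(edge_list(result$fit), fp("edges.csv"), row.names = FALSE)
  write_graphml(result$fit, fp("network.graphml"))
  utils::write.csv(result$centrality, fp("centrality.csv"),
                   row.names = FALSE)
  utils::write.csv(result$predictability, fp("predictability.csv"),
                   row.names = FALSE)
  jsonlite::write_json(result$mediation, fp("paths.json"),
                       auto_unbox = TRUE, digits = NA)
  boot <- result$bootstrap
  utils::write.csv(
    data.frame(edge = boot$edges, point = boot$point,
               ci_lower = boot$ci_lower, ci_upper = boot$ci_upper),
    fp("edge_cis.csv"), row.names = FALSE)
  utils::write.csv(result$group_table, fp("group_differences.csv"),
                   row.names = FALSE)
  utils::write.csv(result$profiles, fp("z_profiles.csv"), row.names = FALSE)
  partitions <- list(node_communities = list(
    labels = as.list(result$node_communities$labels),
    score = result$node_communities$score,
    n_communities = result$node_communities$n_communities))
  if (!is.null(result$person_partition)) {
    partitions$person_subgroups <- list(
      labels = unname(result$person_partition$labels),
      score = result$person_partition$score,
      n_communities = result$person_partition$n_communities)
  }
  jsonlite::write_json(partitions, fp("partitions.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(result$manifest, fp("manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(out_dir)
}
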