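#' Load a pipeline run configuration
#'
#' Flat YAML file mapping configuration keys to values; `overrides` (e.g.
#' from a caller) take precedence over file values.  See [run_pipeline()]
#' for the recognized keys.
#'
#' @param path Path to a YAML file, or `NULL` to start from defaults only.
#' @param overrides Named list of values overriding the file.
#' @return A named list (`run_config`).
#' @export
load_run_config <- function(path = NULL, overrides = list()) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    file_cfg <- yaml::read_yaml(path)
    cfg[names(file_cfg)] <- file_cfg
  }
  cfg[names(overrides)] <- overrides
  unknown <- setdiff(names(cfg), names(default_run_config()))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg
}

default_run_config <- function() {
  list(
    counts = NULL,          # path to abundance TSV (required)
    unit = "counts",        # unit of the counts table
    env = NULL,             # path to environment TSV (rda stage)
    compound = NULL,        # path to 2-column TSV: point id, concentration
    tree = NULL,            # path to Newick tree (unifrac metrics)
    groups = NULL,          # pooling map "G1=s1,s2;G2=s3,s4" or named list
    stages = c("alpha", "beta", "corr"),
    metric = "braycurtis",  # beta metric: braycurtis|jaccard|unifrac|wunifrac
    transform = "hellinger",# rda species transform
    rho = 0.5,              # grey relational resolution coefficient
    normalization = "mean", # grey relational normalization variant
    top_n = 100,            # taxa retained in the correlation network
    alpha = 0.05,           # edge filter level of the correlation network
    cor_method = "spearman",
    seed = 1,
    out_dir = "rhizolink_run")
}

#' Run the end-to-end analysis pipeline
#'
#' Executes the requested stages in dependency order
#' (`pool` -> `alpha` -> `beta` -> `rda` -> `corr` -> `gra`), writing every
#' output plus the effective configuration into `out_dir` and returning a
#' manifest of output files with their MD5 checksums.  Inputs are never
#' modified; identical configuration and inputs give identical checksums
#' for the deterministic stages.
#'
#' Stage prerequisites are validated before any work is done: `gra`
#' requires a compound table, `rda` an environment table, and the UniFrac
#' metrics a tree.
#'
#' @param config A config list from [load_run_config()], or a path to a
#'   YAML config file.
#' @return Invisibly, a data frame manifest (`stage`, `file`, `md5`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- load_run_config(config)
  cfg <- load_run_config(NULL, overrides = config)
  if (is.null(cfg$counts)) stop("config must name a 'counts' table")
  order_all <- c("pool", "alpha", "beta", "rda", "corr", "gra")
  stages <- intersect(order_all, cfg$stages)
  if (!length(stages)) stop("no recognized stages requested")

  # validate stage prerequisites up front, before any work
  if ("gra" %in% stages && is.null(cfg$compound))
    stop("stage 'gra' requires a 'compound' table")
  if ("rda" %in% stages && is.null(cfg$env))
    stop("stage 'rda' requires an 'env' table")
  if ("beta" %in% stages && cfg$metric %in% c("unifrac", "wunifrac") &&
      is.null(cfg$tree))
    stop("metric '", cfg$metric, "' requires a 'tree'")
  if ("pool" %in% stages && is.null(cfg$groups))
    stop("stage 'pool' requires a 'groups' map")
  if ("alpha" %in% stages && cfg$unit != "counts")
    stop("stage 'alpha' requires raw counts input")

  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  tab <- read_count_table(cfg$counts, unit = cfg$unit)
  manifest <- list()
  emit <- function(stage, file) {
    manifest[[length(manifest) + 1]] <<- data.frame(
      stage = stage, file = basename(file),
      md5 = unname(tools::md5sum(file)), stringsAsFactors = FALSE)
  }

  cfg_path <- file.path(cfg$out_dir, "config.yaml")
  yaml::write_yaml(cfg[!vapply(cfg, is.null, logical(1))], cfg_path)
  emit("config", cfg_path)

  work <- tab  # table consumed by downstream stages (pooled if requested)
  if ("pool" %in% stages) {
    grouping <- parse_grouping(cfg$groups)
    work <- pool_groups(tab, grouping)
    f <- file.path(cfg$out_dir, "pooled_abundance.tsv")
    write_count_table(work, f); emit("pool", f)
  }
  if ("alpha" %in% stages) {
    rep <- alpha_report(tab)
    f <- file.path(cfg$out_dir, "alpha_report.tsv")
    utils::write.table(rep, f, sep = "\t", quote = FALSE, row.names = FALSE)
    emit("alpha", f)
  }
  if ("beta" %in% stages) {
    d <- switch(cfg$metric,
      braycurtis = bray_curtis(work),
      jaccard = jaccard_distance(work),
      unifrac = unifrac(work, read_newick(cfg$tree), weighted = FALSE),
      wunifrac = unifrac(work, read_newick(cfg$tree), weighted = TRUE),
      stop("unknown beta metric: ", cfg$metric))
    f <- file.path(cfg$out_dir, paste0("distance_", cfg$metric, ".csv"))
    write_distance_csv(d, f); emit("beta", f)
    hc <- upgma(d)
    f2 <- file.path(cfg$out_dir, "upgma_dendrogram.nwk")
    ape::write.tree(ape::as.phylo(hc), f2); emit("beta", f2)
  }
  if ("rda" %in% stages) {
    env <- read_env_table(cfg$env)
    res <- rda_gated(tab, env, transform = cfg$transform)
    f <- file.path(cfg$out_dir, "rda_result.json")
    write_results(res, f); emit("rda", f)
    f2 <- file.path(cfg$out_dir, "rda_biplot_scores.tsv")
    utils::write.table(
      data.frame(factor = rownames(res$biplot_scores), res$biplot_scores),
      f2, sep = "\t", quote = FALSE, row.names = FALSE)
    emit("rda", f2)
  }
  if ("corr" %in% stages) {
    net <- correlation_network(tab, top_n = cfg$top_n,
                               method = cfg$cor_method, alpha = cfg$alpha)
    f <- file.path(cfg$out_dir, "correlation_matrix.csv")
    write_id_matrix(net$rho, f, sep = ",", id_header = "taxon_id")
    emit("corr", f)
    f2 <- file.path(cfg$out_dir, "correlation_edges.tsv")
    utils::write.table(net$edges, f2, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    emit("corr", f2)
  }
  if ("gra" %in% stages) {
    comp <- read_compound_table(cfg$compound)
    missing <- setdiff(sample_ids(work), names(comp))
    if (length(missing))
      stop("compound table lacks value(s) for: ",
           paste(missing, collapse = ", "))
    # never-observed taxa have no profile shape; mean normalization needs a
    # positive series mean
    observed <- count_table(
      unclass_table(work)[, colSums(work) > 0, drop = FALSE],
      unit = table_unit(work))
    gr <- grey_relation(comp[sample_ids(observed)], observed, rho = cfg$rho,
                        normalization = cfg$normalization)
    f <- file.path(cfg$out_dir, "gra_result.json")
    write_results(gr, f); emit("gra", f)
    f2 <- file.path(cfg$out_dir, "gra_coefficients.tsv")
    co <- gra_coefficient_report(gr)
    utils::write.table(data.frame(point = rownames(co), co, check.names = FALSE),
                       f2, sep = "\t", quote = FALSE, row.names = FALSE)
    emit("gra", f2)
    f3 <- file.path(cfg$out_dir, "gra_degrees.tsv")
    utils::write.table(gra_rank_report(gr), f3, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    emit("gra", f3)
  }
  out <- do.call(rbind, manifest)
  f <- file.path(cfg$out_dir, "manifest.tsv")
  utils::write.table(out, f, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}

# grouping argument: named list(group = c(samples)) or "G1=s1,s2;G2=s3"
parse_grouping <- function(groups) {
  if (is.character(groups) && length(groups) == 1) {
    parts <- strsplit(groups, ";", fixed = TRUE)[[1]]
    kv <- strsplit(parts, "=", fixed = TRUE)
    groups <- stats::setNames(
      lapply(kv, function(p) trimws(strsplit(p[2], ",", fixed = TRUE)[[1]])),
      trimws(vapply(kv, `[`, character(1), 1)))
  }
  if (is.list(groups)) {
    # invert group -> members into the sample -> group mapping
    return(stats::setNames(rep(names(groups), lengths(groups)),
                           unlist(groups, use.names = FALSE)))
  }
  if (!is.null(names(groups))) return(groups)  # already sample -> group
  stop("cannot interpret 'groups' specification")
}

# two-column TSV: point/group id, compound concentration
read_compound_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 2) stop("compound table needs an id and a value column")
  v <- suppressWarnings(as.numeric(df[[2]]))
  if (anyNA(v)) stop("non-numeric compound value(s) in ", path)
  stats::setNames(v, as.character(df[[1]]))
}
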