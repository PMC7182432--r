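#' Simulation configuration
#'
#' Parameterizes a synthetic UMI experiment: K clusters of stated sizes,
#' lognormal gene baseline means, lognormal per-cell depth factors,
#' negative-binomial counts with a shared dispersion, and planted
#' co-regulated gene modules whose expression is multiplied by
#' `fold_change` in a target cluster. An optional genotype split assigns a
#' fraction of cells to a second genotype whose module fold change can be
#' overridden (`fold_change_ko`), so wild-type-vs-mutant comparisons are
#' exercisable.
#'
#' Defaults are the package's reference condition for recovery
#' experiments: 3 clusters of 300 cells, 1,000 genes, one planted
#' 50-gene module at fold change 4.
#'
#' @param n_genes total number of genes.
#' @param n_cells_per_cluster integer vector, one entry per cluster.
#' @param base_mean_log_mu,base_mean_log_sigma lognormal parameters of the
#'   per-gene baseline mean (natural-log scale).
#' @param dispersion negative-binomial size parameter shared by all genes
#'   (smaller = more overdispersed).
#' @param libsize_log_sigma lognormal sigma of the per-cell depth factor
#'   (0 disables depth variation).
#' @param modules list of module specs: `name`, `n_genes`, `target_cluster`
#'   (1-based index or cluster label `"c<k>"`), `fold_change >= 1`, and
#'   optionally `fold_change_ko` for the KO genotype.
#' @param genotype_split fraction of cells assigned genotype `"KO"`
#'   (`NULL` = all `"WT"`).
#' @param stage stage label applied to all cells.
#' @param seed integer seed governing every draw.
#' @return A `SimConfig` list, validated.
#' @export
sim_config <- function(n_genes = 1000,
                       n_cells_per_cluster = c(300, 300, 300),
                       base_mean_log_mu = -1.5,
                       base_mean_log_sigma = 1,
                       dispersion = 2,
                       libsize_log_sigma = 0.3,
                       modules = list(list(name = "planted", n_genes = 50,
                                           target_cluster = 1,
                                           fold_change = 4)),
                       genotype_split = NULL,
                       stage = "E16",
                       seed = 1L) {
  modules <- lapply(modules, function(mod) {
    if (is.null(mod$name) || is.null(mod$n_genes) ||
        is.null(mod$target_cluster) || is.null(mod$fold_change))
      stop("config error: each module needs name, n_genes, target_cluster, fold_change",
           call. = FALSE)
    out <- list(name = as.character(mod$name),
                n_genes = as.integer(mod$n_genes),
                target_cluster = resolve_cluster(mod$target_cluster,
                                                 length(n_cells_per_cluster)),
                fold_change = as.numeric(mod$fold_change))
    if (is.na(out$target_cluster))
      stop("config error: module '", out$name, "' targets unknown cluster ",
           mod$target_cluster, call. = FALSE)
    if (!is.null(mod$fold_change_ko))
      out$fold_change_ko <- as.numeric(mod$fold_change_ko)
    out
  })
  cfg <- list(n_genes = as.integer(n_genes),
              n_cells_per_cluster = as.integer(n_cells_per_cluster),
              base_mean_log_mu = as.numeric(base_mean_log_mu),
              base_mean_log_sigma = as.numeric(base_mean_log_sigma),
              dispersion = as.numeric(dispersion),
              libsize_log_sigma = as.numeric(libsize_log_sigma),
              modules = modules,
              genotype_split = if (!is.null(genotype_split))
                as.numeric(genotype_split),
              stage = as.character(stage),
              seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "SimConfig"
  cfg
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (n_genes < 1) stop("config error: n_genes must be positive",
                          call. = FALSE)
    if (!length(n_cells_per_cluster) || any(n_cells_per_cluster < 1))
      stop("config error: every cluster needs at least 1 cell", call. = FALSE)
    if (!is.numeric(dispersion) || dispersion <= 0)
      stop("config error: dispersion must be > 0", call. = FALSE)
    if (libsize_log_sigma < 0)
      stop("config error: libsize_log_sigma must be >= 0", call. = FALSE)
    if (base_mean_log_sigma < 0)
      stop("config error: base_mean_log_sigma must be >= 0", call. = FALSE)
    for (mod in modules) {
      if (mod$fold_change < 1)
        stop("config error: fold_change must be >= 1 (module '", mod$name,
             "')", call. = FALSE)
      if (!is.null(mod$fold_change_ko) && mod$fold_change_ko < 1)
        stop("config error: fold_change_ko must be >= 1 (module '", mod$name,
             "')", call. = FALSE)
      tc <- resolve_cluster(mod$target_cluster, length(n_cells_per_cluster))
      if (is.na(tc))
        stop("config error: module '", mod$name,
             "' targets unknown cluster ", mod$target_cluster, call. = FALSE)
    }
    total_module_genes <- sum(vapply(modules, function(m)
      as.integer(m$n_genes), 0L))
    if (total_module_genes > n_genes)
      stop("config error: module gene counts exceed n_genes", call. = FALSE)
    if (!is.null(genotype_split) &&
        (genotype_split <= 0 || genotype_split >= 1))
      stop("config error: genotype_split must lie in (0, 1)", call. = FALSE)
  })
  invisible(cfg)
}

resolve_cluster <- function(tc, k) {
  labels <- paste0("c", seq_len(k))
  if (is.numeric(tc)) {
    if (tc >= 1 && tc <= k) return(labels[tc]) else return(NA_character_)
  }
  if (as.character(tc) %in% labels) as.character(tc) else NA_character_
}

#' Read a simulation configuration from YAML or JSON
#'
#' Fields mirror the [sim_config()] arguments; omitted fields take the
#' defaults.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return A `SimConfig`.
#' @export
read_sim_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  raw <- raw[!vapply(raw, function(v)
    is.null(v) || (is.list(v) && !length(v)), TRUE)]
  if (!is.null(raw$modules) && is.data.frame(raw$modules))
    raw$modules <- split(raw$modules, seq_len(nrow(raw$modules)))
  known <- names(formals(sim_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("config error: unknown field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(sim_config, raw)
}

#' Simulate a UMI count matrix with planted modules
#'
#' The generative model: gene baseline mean `mu_g ~ LogNormal(mu, sigma)`;
#' cell depth factor `d_c ~ LogNormal(0, libsize_log_sigma)`; the expected
#' count of gene g in cell c is `mu_g * d_c * FC(g, cluster(c),
#' genotype(c))`, where FC is the module fold change when g belongs to a
#' module targeting the cell's cluster (with the KO override when the cell
#' is KO and the module declares one) and 1 otherwise; counts are drawn
#' negative-binomial with that mean and the shared dispersion (size)
#' parameter. All randomness derives from the single config seed in a
#' fixed order (gene means, depth factors, module gene assignment,
#' genotype assignment, counts), so a config reproduces its counts
#' bit-exactly.
#'
#' @param config a `SimConfig`.
#' @return list with `counts` (an `ExpressionMatrix`, raw counts),
#'   `cells` (a `CellTable`) and `truth` (a `SimTruth`: cluster and
#'   genotype per cell, module membership, the expected per-gene
#'   per-cluster mean matrix for the wild-type genotype, and the seed).
#' @export
simulate_counts <- function(config) {
  validate_sim_config(config)
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)

  g <- config$n_genes
  k <- length(config$n_cells_per_cluster)
  n <- sum(config$n_cells_per_cluster)
  cluster_labels <- paste0("c", seq_len(k))
  cluster <- rep(cluster_labels, config$n_cells_per_cluster)

  mu_g <- stats::rlnorm(g, config$base_mean_log_mu, config$base_mean_log_sigma)
  d_c <- if (config$libsize_log_sigma > 0)
    stats::rlnorm(n, 0, config$libsize_log_sigma) else rep(1, n)

  gene_names <- sprintf("gene%04d", seq_len(g))
  pool <- sample.int(g)  # module genes drawn without replacement
  taken <- 0L
  module_genes <- list()
  for (mod in config$modules) {
    mg <- pool[(taken + 1L):(taken + mod$n_genes)]
    taken <- taken + as.integer(mod$n_genes)
    module_genes[[mod$name]] <- gene_names[sort(mg)]
  }

  genotype <- rep("WT", n)
  if (!is.null(config$genotype_split))
    genotype[stats::runif(n) < config$genotype_split] <- "KO"

  # expected mean matrix: genes x cells
  mu <- outer(mu_g, d_c)
  fc_cluster <- matrix(1, nrow = g, ncol = k,
                       dimnames = list(gene_names, cluster_labels))
  for (mod in config$modules) {
    tc <- resolve_cluster(mod$target_cluster, k)
    rows <- match(module_genes[[mod$name]], gene_names)
    fc_cluster[rows, tc] <- mod$fold_change
    in_target <- cluster == tc
    fc_cells <- rep(mod$fold_change, sum(in_target))
    if (!is.null(mod$fold_change_ko))
      fc_cells[genotype[in_target] == "KO"] <- mod$fold_change_ko
    mu[rows, in_target] <- sweep(mu[rows, in_target, drop = FALSE], 2,
                                 fc_cells, `*`)
  }

  counts <- matrix(stats::rnbinom(g * n, mu = as.vector(mu),
                                  size = config$dispersion),
                   nrow = g, ncol = n)
  barcodes <- sprintf("cell%05d", seq_len(n))
  expr <- expression_matrix(counts, gene_ids = gene_names,
                            cell_ids = barcodes, layer = "raw_counts")
  cells <- cell_table(barcodes, cluster = cluster, genotype = genotype,
                      stage = config$stage)
  # expected WT mean per gene x cluster at unit depth
  cluster_mean <- sweep(fc_cluster, 1, mu_g, `*`)
  truth <- structure(list(cluster = stats::setNames(cluster, barcodes),
                          genotype = stats::setNames(genotype, barcodes),
                          module_genes = module_genes,
                          cluster_mean = cluster_mean,
                          seed = config$seed,
                          config = config),
                     class = "SimTruth")
  list(counts = expr, cells = cells, truth = truth)
}

#' Gene sets matching the planted modules
#'
#' Turns the simulation ground truth into a [gene_set_collection()], one
#' set per planted module, suitable for scoring and for GMT round trips.
#'
#' @param truth a `SimTruth` with at least one module.
#' @return A `GeneSetCollection`.
#' @export
make_true_gene_sets <- function(truth) {
  stopifnot(inherits(truth, "SimTruth"))
  if (!length(truth$module_genes))
    stop("data error: no planted modules in truth", call. = FALSE)
  gene_set_collection(truth$module_genes,
                      rep("planted simulation module",
                          length(truth$module_genes)))
}
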