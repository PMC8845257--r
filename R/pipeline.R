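# End-to-end orchestration: load -> align -> measurement workflow -> ecospace
# clustering -> phylogenetic PLS -> eco-projection -> MANOVA -> pairwise ->
# per-trait phylogenetic signal, with every intermediate written to disk and
# a deterministic machine-readable report.

#' Build and validate a pipeline configuration
#'
#' @param traits path to the species x measurement CSV.
#' @param habitat path to the species x binary descriptor CSV.
#' @param tree path to the rooted Newick tree.
#' @param schema optional path to a JSON reduction schema; `NULL` uses the
#'   packaged default when `traits_stage = "raw"`.
#' @param traits_stage stage of the trait CSV: `"raw"` runs the full
#'   measurement workflow, `"reduced"` skips reduction, `"log"` skips the log
#'   transform too.
#' @param kmax,eps cluster-number scan limit and BIC plateau threshold.
#' @param k optional fixed cluster number, bypassing plateau selection (the
#'   BIC curve is still computed and reported).
#' @param n_perm permutations for all tests (at least 99).
#' @param seed master seed; every stochastic stage draws a sub-seed from it.
#' @param gmm_input `"pcoa"` fits the mixture on PCoA scores (default);
#'   `"distmatrix-rows"` on rows of the distance matrix.
#' @param gmm_models covariance families for the BIC scan. The pipeline
#'   default is `"spherical"` (equal-spherical) only: on embeddings of binary
#'   data, species with identical descriptor profiles produce exact duplicate
#'   points, for which the per-cluster-variance families have unbounded
#'   likelihood; their surviving local optima make the best-per-family-BIC
#'   curve non-monotone and defeat plateau detection.
#' @param eco_projection `"axes"` uses morphology rotated onto all PLS axes as
#'   the MANOVA response; `"scores"` uses the first-axis score vector only.
#' @param grafen_rho rho for Grafen branch lengths; `NULL` keeps the tree's
#'   own branch lengths (they must then exist).
#' @param out_dir output directory (created if missing).
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(traits, habitat, tree, schema = NULL,
                            traits_stage = c("raw", "reduced", "log"),
                            kmax = 9, eps = 0.05, k = NULL, n_perm = 10000,
                            seed = 20220214,
                            gmm_input = c("pcoa", "distmatrix-rows"),
                            gmm_models = "spherical",
                            eco_projection = c("axes", "scores"),
                            grafen_rho = 1, out_dir = "ecomorph_out") {
  traits_stage <- match.arg(traits_stage)
  gmm_input <- match.arg(gmm_input)
  gmm_models <- match.arg(gmm_models, c("spherical", "diagonal", "full"),
                          several.ok = TRUE)
  eco_projection <- match.arg(eco_projection)
  for (f in c(traits, habitat, tree, schema))
    if (!file.exists(f)) stop("input file not found: ", f)
  if (n_perm < 99) stop("n_perm must be at least 99")
  if (kmax < 3) stop("kmax must be at least 3")
  structure(list(traits = traits, habitat = habitat, tree = tree,
                 schema = schema, traits_stage = traits_stage, kmax = kmax,
                 eps = eps, k = if (!is.null(k)) as.integer(k),
                 n_perm = n_perm, seed = as.integer(seed),
                 gmm_input = gmm_input, gmm_models = gmm_models,
                 eco_projection = eco_projection,
                 grafen_rho = grafen_rho, out_dir = out_dir),
            class = "pipeline_config")
}

stage_try <- function(stage, log, expr) {
  log(paste0("stage ", stage, " ..."))
  t0 <- proc.time()[["elapsed"]]
  out <- tryCatch(expr, error = function(e)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE))
  log(sprintf("stage %s done (%.2f s)", stage,
              proc.time()[["elapsed"]] - t0))
  out
}

#' Run the full ecomorph-discovery pipeline
#'
#' Executes, in order: species alignment; variable reduction, log transform
#' and size correction; Jaccard distances; PCoA; BIC cluster-number scan with
#' first-plateau selection; k-means; descriptor-cluster affiliation;
#' phylogenetic two-block PLS of ecology against size-corrected morphology;
#' eco-projection of morphology; GLS MANOVA with RRPP; pairwise group tests;
#' and per-trait Blomberg's K. All intermediates are written as CSV into
#' `cfg$out_dir`, a JSON report to `report.json`, and a stage log to
#' `pipeline.log` (also echoed to stderr). Re-running with the same config
#' and inputs reproduces the report byte for byte.
#'
#' @param cfg a [pipeline_config()].
#' @param quiet suppress stderr logging.
#' @return The report, invisibly (a `pipeline_report` list).
#' @export
run_pipeline <- function(cfg, quiet = FALSE) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(cfg$out_dir, "pipeline.log")
  unlink(log_path)
  log <- function(msg) {
    line <- paste0("[ecomorphr] ", msg)
    if (!quiet) message(line)
    cat(line, "\n", file = log_path, append = TRUE)
  }
  seeds <- spawn_seeds(cfg$seed, 8)
  log(paste0("master seed ", cfg$seed))

  inputs <- stage_try("align", log, {
    traits <- read_trait_table(cfg$traits, stage = cfg$traits_stage)
    habitat <- read_microhabitat_table(cfg$habitat)
    tree <- read_newick(cfg$tree)
    if (!is.null(cfg$grafen_rho))
      tree <- grafen_branch_lengths(tree, rho = cfg$grafen_rho)
    align_species(traits = traits, habitat = habitat, tree = tree)
  })

  corrected <- stage_try("measurements", log, {
    t <- inputs$traits
    if (trait_stage(t) == "raw") {
      schema <- if (is.null(cfg$schema)) default_reduction_schema()
                else read_reduction_schema(cfg$schema)
      t <- reduce_variables(t, schema)
    }
    if (trait_stage(t) == "reduced") t <- log_transform(t)
    sc <- size_correct(t)
    write_species_csv(sc, file.path(cfg$out_dir, "traits_size_corrected.csv"))
    sc
  })

  D <- stage_try("jaccard", log, {
    d <- jaccard_distance(inputs$habitat)
    write_species_csv(d, file.path(cfg$out_dir, "distances.csv"))
    d
  })

  ord <- stage_try("pcoa", log, {
    o <- pcoa(D)
    write_species_csv(o$scores, file.path(cfg$out_dir, "pcoa_scores.csv"))
    o
  })

  bic <- stage_try("bic", log, {
    X <- if (cfg$gmm_input == "pcoa") ord$scores else unclass(D)
    b <- gmm_bic_curve(X, kmax = cfg$kmax, models = cfg$gmm_models,
                       seed = seeds[1])
    utils::write.csv(data.frame(k = b$k, bic = b$bic, model = b$model),
                     file.path(cfg$out_dir, "bic_curve.csv"),
                     row.names = FALSE)
    b
  })
  k <- if (!is.null(cfg$k)) cfg$k else select_k_plateau(bic, eps = cfg$eps)
  log(paste0("selected k = ", k,
             if (!is.null(cfg$k)) " (fixed by config)" else ""))

  clusters <- stage_try("kmeans", log, {
    cm <- kmeans_cluster(ord$scores, k, restarts = 100, seed = seeds[2])
    utils::write.csv(data.frame(species = names(cm$assignments),
                                cluster = cm$assignments),
                     file.path(cfg$out_dir, "clusters.csv"),
                     row.names = FALSE)
    cm
  })

  affiliation <- stage_try("affiliation", log, {
    TA <- trait_axis_correlation(inputs$habitat, ord)
    A <- cluster_trait_affiliation(TA, clusters)
    write_species_csv(A, file.path(cfg$out_dir, "affiliation.csv"),
                      id_name = "descriptor")
    A
  })

  C <- phylo_vcv(inputs$tree)
  pls <- stage_try("pls", log, {
    fit <- phylo_pls(ord$scores, unclass(corrected), C,
                     n_perm = cfg$n_perm, seed = seeds[3])
    load <- data.frame(variable = colnames(corrected),
                       loading = fit$y_loadings)
    utils::write.csv(load, file.path(cfg$out_dir, "pls_loadings.csv"),
                     row.names = FALSE)
    fit
  })

  eco_projected <- stage_try("eco_projection", log, {
    Yc <- sweep(unclass(corrected), 2,
                drop(phylo_gls_mean(unclass(corrected), C)))
    if (cfg$eco_projection == "axes") Yc %*% pls$y_rotation
    else matrix(Yc %*% pls$y_loadings, ncol = 1)
  })

  # singleton clusters leave the group comparison undefined; degrade to a
  # reported-but-skipped MANOVA rather than aborting the whole run
  groups_ok <- min(table(clusters$assignments)) >= 2 && k >= 2
  if (!groups_ok) {
    warning("a cluster has fewer than two members; ",
            "MANOVA and pairwise tests skipped")
    log("stage manova skipped: cluster with < 2 members")
    manova <- NULL
    pairwise <- NULL
  } else {
    manova <- stage_try("manova", log, {
      fit <- rrpp_manova(eco_projected, clusters$assignments, C,
                         n_perm = cfg$n_perm, seed = seeds[4])
      utils::write.csv(cbind(term = rownames(fit$table), fit$table),
                       file.path(cfg$out_dir, "manova_table.csv"),
                       row.names = FALSE)
      fit
    })
    pairwise <- stage_try("pairwise", log, {
      pw <- pairwise_group_tests(manova)
      utils::write.csv(pw, file.path(cfg$out_dir, "pairwise.csv"),
                       row.names = FALSE)
      pw
    })
  }

  signal <- stage_try("physignal", log, {
    ksig <- lapply(seq_len(ncol(corrected)), function(j)
      physignal(unclass(corrected)[, j], C, n_perm = cfg$n_perm,
                seed = seeds[5]))
    df <- data.frame(variable = colnames(corrected),
                     K = vapply(ksig, function(x) x$K, numeric(1)),
                     p = vapply(ksig, function(x) x$p, numeric(1)))
    utils::write.csv(df, file.path(cfg$out_dir, "physignal_per_trait.csv"),
                     row.names = FALSE)
    df
  })

  cfg_json <- file.path(cfg$out_dir, "config.json")
  jsonlite::write_json(unclass(cfg), cfg_json, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  # hash the analysis-relevant config only, so equal analyses written to
  # different directories produce byte-identical reports
  hash_json <- tempfile(fileext = ".json")
  on.exit(unlink(hash_json), add = TRUE)
  cfg_hash <- unclass(cfg)
  cfg_hash$out_dir <- NULL
  jsonlite::write_json(cfg_hash, hash_json, auto_unbox = TRUE, null = "null")
  report <- list(
    provenance = list(
      package_version = as.character(utils::packageVersion("ecomorphr")),
      seed = cfg$seed,
      config_md5 = unname(tools::md5sum(hash_json))),
    selected_k = k,
    bic = data.frame(k = bic$k, bic = bic$bic, model = bic$model),
    cluster_assignments = as.list(clusters$assignments),
    affiliation = as.data.frame(affiliation),
    pls = list(r = pls$r, z = pls$z, p = pls$p),
    manova = if (!is.null(manova))
      cbind(term = rownames(manova$table), manova$table),
    pairwise = if (!is.null(pairwise)) as.data.frame(pairwise),
    physignal = signal)
  jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE,
                       dataframe = "rows", null = "null")
  log("report written")
  class(report) <- "pipeline_report"
  invisible(report)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Ecomorph pipeline report\n")
  cat(sprintf("  selected k: %d\n", x$selected_k))
  cat(sprintf("  PLS: r = %.4f, Z = %.3f, p = %.4g\n",
              x$pls$r, x$pls$z, x$pls$p))
  if (!is.null(x$manova))
    cat(sprintf("  MANOVA: F = %.4f, Rsq = %.4f, p = %.4g\n",
                x$manova$F[1], x$manova$Rsq[1], x$manova$p[1]))
  else cat("  MANOVA: skipped (cluster with < 2 members)\n")
  invisible(x)
}

#' Write a synthetic dataset to disk in pipeline input formats
#'
#' @param scn a [synthetic_scenario()].
#' @param out_dir output directory.
#' @param seed integer seed.
#' @return Paths of the written files (traits.csv as stage `"log"`,
#'   habitat.csv, tree.nwk, truth.json), invisibly.
#' @export
write_synthetic_dataset <- function(scn, out_dir, seed = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dat <- simulate_dataset(scn, seed = seed)
  paths <- list(traits = file.path(out_dir, "traits.csv"),
                habitat = file.path(out_dir, "habitat.csv"),
                tree = file.path(out_dir, "tree.nwk"),
                truth = file.path(out_dir, "truth.json"))
  write_species_csv(dat$traits, paths$traits)
  write_species_csv(dat$habitat, paths$habitat)
  ape::write.tree(dat$tree, paths$tree)
  jsonlite::write_json(list(labels = as.list(dat$labels), seed = seed),
                       paths$truth, auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}
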