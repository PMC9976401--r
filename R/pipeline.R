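#' Configuration of a full synthetic-study run
#'
#' @param cohort A [cohort_config()].
#' @param scene A [scene_config()].
#' @param alpha Significance level for the gene screen and reported tests
#'   (default 0.05).
#' @param seed Integer seed driving the whole run (overrides the seeds
#'   embedded in `cohort` and `scene` so that one integer reproduces the
#'   study).
#' @param multiplicity Multiple-testing correction for the Braak-trend
#'   gene screen: `"none"` (default, mirroring a per-gene p < alpha
#'   screen) or `"BH"`.
#' @return A list of class `run_config`.
#' @export
run_config <- function(cohort = cohort_config(), scene = scene_config(),
                       alpha = 0.05, seed = 1L,
                       multiplicity = c("none", "BH")) {
  multiplicity <- match.arg(multiplicity)
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must lie in (0, 1)")
  cohort$seed <- as.integer(seed)
  scene$seed <- as.integer(seed) + 1L
  structure(list(cohort = cohort, scene = scene, alpha = alpha,
                 seed = as.integer(seed), multiplicity = multiplicity),
            class = "run_config")
}

braak_numeric <- c("Braak 0" = 0, "Braak II" = 2, "Braak III-IV" = 3.5,
                   "Braak V-VI" = 5.5)

#' Run the full synthetic study
#'
#' Orchestrates the complete analysis on one synthetic cohort and one
#' synthetic stained section: simulate; ddCt-quantify against the four
#' housekeepers and the Braak II reference; screen genes for Braak trend
#' (per-gene Spearman vs Braak stage and Braak II vs V--VI Mann-Whitney);
#' Z-score and hierarchically cluster the screen-positive genes; compute
#' panel gene-set scores with Kruskal-Wallis/Dunn across Braak groups;
#' classify subjects into clusters I/II on the CD163 panel; test cluster
#' enrichment against Braak group (chi-square) and dementia (Fisher
#' exact); compare chemokine/T-cell/endothelial/neuronal markers between
#' clusters (Mann-Whitney); and run the image arm (binarize, loadings,
#' vessel enrichment, per-vessel halo gradient with Friedman + Dunn).
#'
#' @param config A [run_config()].
#' @return A list of class `study_report` whose elements mirror the
#'   stages above (see Details), plus `provenance` (config and seed).
#' @details Report elements: `braak_trend_table`, `significant_genes`,
#'   `gene_cluster_tree`, `set_score_tables`, `cluster_table`
#'   (assignment + enrichment tests), `marker_assoc_table`,
#'   `loading_table`, `vessel_enrichment`, `halo`, `ground_truth`.
#' @export
run_full <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  sim <- simulate_cohort(config$cohort)
  tab <- sim$ct
  panels <- config$cohort$gene_panels
  e <- multi_housekeeper_normalize(tab)
  grp <- tab$group
  samples <- colnames(e)

  # --- Braak-trend screen: per-gene Spearman + Braak II vs V-VI MW
  stage <- braak_numeric[as.character(grp)]
  ii <- samples[grp == "Braak II"]
  vvi <- samples[grp == "Braak V-VI"]
  screen <- do.call(rbind, lapply(rownames(e), function(g) {
    sp <- spearman_corr(stage, e[g, ], mode = "asymptotic")
    mw <- mann_whitney_u(e[g, ii], e[g, vvi], mode = "asymptotic")
    data.frame(gene = g, spearman_rho = sp$statistic,
               spearman_p = sp$p_value, mw_u = mw$statistic,
               mw_p = mw$p_value, stringsAsFactors = FALSE)
  }))
  screen$mw_p_adj <- if (config$multiplicity == "BH")
    stats::p.adjust(screen$mw_p, "BH") else screen$mw_p
  sig <- screen$gene[screen$mw_p_adj < config$alpha]

  # --- cluster the screen-positive genes (gene dendrogram, as for a heatmap)
  gene_tree <- if (length(sig) >= 2)
    agglomerative_cluster(zscore_genes(e[sig, , drop = FALSE])) else NULL

  # --- panel set-scores with Kruskal-Wallis/Dunn across Braak groups
  panel_names <- setdiff(names(panels), "housekeeping")
  scores <- lapply(panel_names, function(p) gene_set_score(e, panels[[p]]))
  names(scores) <- panel_names
  set_score_tables <- lapply(panel_names, function(p) {
    s <- scores[[p]]$scores
    by_grp <- split(s, grp[samples])
    kw <- kruskal_wallis(by_grp)
    dunn <- dunn_pairwise(by_grp, parent = "kw")
    list(scores = data.frame(sample = samples, panel = p,
                             score = unname(s), group = as.character(grp),
                             stringsAsFactors = FALSE),
         kruskal_wallis = kw, dunn = dunn)
  })
  names(set_score_tables) <- panel_names

  # --- cluster-I/II classification on the CD163 panel
  cd_score <- scores[["cd163_cluster"]]
  ztab <- zscore_genes(e[panels$cd163_cluster, , drop = FALSE])
  subj_tree <- agglomerative_cluster(t(ztab))
  assign <- classify_two_clusters(subj_tree, cd_score)
  labels <- assign$labels[samples]

  demented <- factor(ifelse(grp == "Braak V-VI", "demented",
                            "non-demented"),
                     levels = c("non-demented", "demented"))
  names(demented) <- names(grp)
  braak_tab <- table(cluster = labels, braak = grp[samples])
  dem_tab <- table(cluster = labels, dementia = demented[samples])
  chi <- chi_square(braak_tab)
  # orient the 2x2 so the odds ratio is cluster-II odds of dementia
  fish <- fisher_exact(dem_tab[c("II", "I"), c("demented", "non-demented")])
  cluster_mw <- mann_whitney_u(cd_score$scores[labels == "I"],
                               cd_score$scores[labels == "II"],
                               mode = "asymptotic")

  # --- cluster-II vs cluster-I marker comparisons
  markers <- c(panels$chemokine[1], "CCR2", panels$tcell,
               panels$neuronal)
  marker_assoc <- do.call(rbind, lapply(markers, function(g) {
    mw <- mann_whitney_u(e[g, labels == "II"], e[g, labels == "I"],
                         mode = "asymptotic")
    data.frame(marker = g, mw_u = mw$statistic, p_value = mw$p_value,
               median_I = stats::median(e[g, labels == "I"]),
               median_II = stats::median(e[g, labels == "II"]),
               stringsAsFactors = FALSE)
  }))
  endo <- scores[["endothelial"]]$scores
  mw_endo <- mann_whitney_u(endo[labels == "II"], endo[labels == "I"],
                            mode = "asymptotic")
  marker_assoc <- rbind(marker_assoc, data.frame(
    marker = "endothelial_set_score", mw_u = mw_endo$statistic,
    p_value = mw_endo$p_value,
    median_I = stats::median(endo[labels == "I"]),
    median_II = stats::median(endo[labels == "II"]),
    stringsAsFactors = FALSE))

  # --- image arm
  scene <- simulate_staining_image(config$scene,
                                   channels = c("Cd163", "Iba1"))
  ppm <- config$scene$pixels_per_micron
  specs <- list(Cd163 = threshold_spec("Cd163"),
                Iba1 = threshold_spec("Iba1"))
  masks <- lapply(names(specs), function(ch)
    binarize(scene$image[[ch]], specs[[ch]]))
  names(masks) <- names(specs)
  loading_table <- do.call(rbind, lapply(names(masks), function(ch) {
    l <- compute_loading(masks[[ch]])
    data.frame(channel = ch, labeled_px = l$labeled_area,
               reference_px = l$reference_area, loading_pct = l$loading,
               stringsAsFactors = FALSE)
  }))

  field <- list(dist_um = scene$ground_truth$vessel_distance_um,
                nearest = scene$ground_truth$nearest_vessel)
  proximal <- field$dist_um <= 50 & !scene$ground_truth$vessel_mask
  reference <- !scene$ground_truth$vessel_mask
  enr <- vessel_enrichment(masks$Cd163, proximal, reference)

  halo <- halo_table(masks$Cd163, field)
  lm <- halo$loading_matrix
  complete <- stats::complete.cases(lm)
  if (sum(!complete))
    message("dropping ", sum(!complete),
            " vessel(s) with an empty ring from the Friedman test")
  lmc <- lm[complete, , drop = FALSE]
  halo_friedman <- if (nrow(lmc) >= 2) friedman(lmc) else NULL
  halo_dunn <- if (nrow(lmc) >= 2) dunn_pairwise(lmc, parent = "friedman")
               else NULL

  structure(
    list(braak_trend_table = screen,
         significant_genes = sig,
         gene_cluster_tree = gene_tree,
         set_score_tables = set_score_tables,
         cluster_table = list(
           labels = data.frame(sample = samples,
                               cluster = as.character(labels),
                               braak = as.character(grp[samples]),
                               demented = as.character(demented[samples]),
                               stringsAsFactors = FALSE),
           braak_contingency = braak_tab,
           dementia_contingency = dem_tab,
           chi_square = chi, fisher = fish,
           score_mw = cluster_mw, tree = subj_tree),
         marker_assoc_table = marker_assoc,
         loading_table = loading_table,
         vessel_enrichment = data.frame(
           region = c("vessel+", "vessel-"),
           loading_pct = c(enr$loading_vessel_plus$loading,
                           enr$loading_vessel_minus$loading)),
         halo = list(table = halo$table, loading_matrix = lm,
                     friedman = halo_friedman, dunn = halo_dunn),
         ground_truth = list(cohort = sim$ground_truth,
                             scene = scene$ground_truth),
         provenance = list(seed = config$seed, alpha = config$alpha,
                           pixels_per_micron = ppm,
                           package_version =
                             as.character(utils::packageVersion("mdcquant")))),
    class = "study_report"
  )
}

#' @export
print.study_report <- function(x, ...) {
  cat("study_report (seed", x$provenance$seed, ")\n")
  cat("  screen:", length(x$significant_genes), "significant genes\n")
  ct <- x$cluster_table
  cat("  clusters:", sum(ct$labels$cluster == "I"), "I /",
      sum(ct$labels$cluster == "II"), "II;",
      "dementia Fisher p =", format.pval(ct$fisher$p_value), "\n")
  if (!is.null(x$halo$friedman))
    cat("  halo gradient Friedman p =",
        format.pval(x$halo$friedman$p_value), "\n")
  invisible(x)
}

#' Write a study report to a directory
#'
#' Writes each report table as TSV and a JSON manifest recording the
#' provenance, test results and file list; no binary formats.
#'
#' @param report A `study_report` from [run_full()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) {
    utils::write.table(df, file.path(dir, paste0(name, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    paste0(name, ".tsv")
  }
  files <- c(
    wt(report$braak_trend_table, "braak_trend"),
    wt(do.call(rbind, lapply(report$set_score_tables, `[[`, "scores")),
       "set_scores"),
    wt(report$cluster_table$labels, "cluster_labels"),
    wt(report$marker_assoc_table, "marker_assoc"),
    wt(report$loading_table, "loadings"),
    wt(report$vessel_enrichment, "vessel_enrichment"),
    wt(report$halo$table, "halo")
  )
  tests <- list(
    cluster_chi_square = unclass(report$cluster_table$chi_square),
    cluster_fisher = unclass(report$cluster_table$fisher),
    cluster_score_mw = unclass(report$cluster_table$score_mw),
    halo_friedman = if (!is.null(report$halo$friedman))
      unclass(report$halo$friedman) else NULL,
    set_score_kw = lapply(report$set_score_tables,
                          function(t) unclass(t$kruskal_wallis))
  )
  manifest <- list(provenance = report$provenance,
                   significant_genes = report$significant_genes,
                   tests = tests, files = files)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(dir)
}
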