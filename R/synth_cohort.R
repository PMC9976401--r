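#' Default gene panels for the synthetic cohort
#'
#' Named marker panels mirroring the myeloid/microglial panels of a
#' post-mortem hippocampal expression study: homeostatic microglia (hMG),
#' activated microglia (aMG), the CD163 cluster of monocyte-derived cell
#' (MDC) markers, a wider ten-gene MDC fluidic-card panel (the five CD163
#' cluster genes plus F13A1 and four canonical monocyte markers; a
#' synthetic stand-in, since the study panel is not enumerated publicly),
#' vascular-adhesion endothelial genes, monocyte-attracting chemokines, a
#' T-cell marker, GABAergic interneuron markers used as neurodegeneration
#' proxies, classic pan-myeloid markers, and four housekeeping genes.
#'
#' @return Named list of character vectors.
#' @export
default_gene_panels <- function() {
  list(
    hMG = c("P2RY12", "CX3CR1"),
    aMG = c("SPI1", "CSF1", "PTPRC", "CD74"),
    cd163_cluster = c("CD163", "IFITM3", "CCR2", "CD68", "MSR1"),
    mdc_panel = c("CD163", "IFITM3", "CCR2", "CD68", "MSR1",
                  "F13A1", "CD14", "FCGR1A", "LYZ", "S100A8"),
    endothelial = c("SELE", "ICAM2", "PECAM1", "CDH5"),
    chemokine = c("CCL2", "CCL3", "CCL4", "CCL5"),
    tcell = "CD3E",
    neuronal = c("PVALB", "SST"),
    classic = c("AIF1", "ITGAM", "TREM2"),
    housekeeping = c("GAPDH", "ACTB", "UBE2D2", "RPL13")
  )
}

#' Configuration of the synthetic expression cohort
#'
#' Defines the statistical structure of a Braak-stratified post-mortem
#' cohort with a latent high-CD163 ("cluster II") subject subpopulation.
#' Subjects in Braak V--VI are demented by definition; demented subjects
#' carry the latent cluster-II label with probability
#' `cluster2_fraction_demented`, non-demented subjects with probability
#' `cluster2_fraction_nondemented`. Cluster-II subjects receive
#' expression-increasing Ct shifts on the CD163/MDC, endothelial,
#' chemokine and T-cell panels and a decrease on the neuronal (PV/SOM)
#' panel; the hMG panel is down-regulated in Braak V--VI regardless of
#' cluster. Housekeeping genes carry only subject-level and technical
#' noise.
#'
#' @param group_sizes Named integer vector of subjects per Braak group
#'   (default 8/26/15/44 for Braak 0/II/III-IV/V-VI).
#' @param gene_panels Named list of gene panels; must contain a
#'   `housekeeping` entry disjoint from all other panels.
#' @param effect_sizes Named numeric vector of per-panel mean Ct shifts
#'   (Ct units; the sign convention per panel is fixed by the model, see
#'   Details).
#' @param cluster2_fraction_demented,cluster2_fraction_nondemented
#'   Probabilities in `[0, 1]` of the latent cluster-II label.
#' @param ct_noise_sd Technical (per-well) Ct noise SD, Ct units (> 0).
#' @param subject_sd Subject-level random effect SD shared by all genes of
#'   a subject (input-amount variation), Ct units (> 0).
#' @param seed Integer RNG seed.
#'
#' @details Effect sizes are magnitudes; `cd163_cluster`, `mdc_panel`,
#'   `endothelial`, `chemokine` and `tcell` shifts *lower* Ct (higher
#'   expression) in cluster-II subjects, `neuronal` *raises* Ct in
#'   cluster-II subjects, and `hMG` raises Ct in all Braak V--VI
#'   subjects. Panels not named in `effect_sizes` are unshifted.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(group_sizes = c("Braak 0" = 8L, "Braak II" = 26L,
                                          "Braak III-IV" = 15L,
                                          "Braak V-VI" = 44L),
                          gene_panels = default_gene_panels(),
                          effect_sizes = c(hMG = 1.0, cd163_cluster = 2.5,
                                           mdc_panel = 2.5, endothelial = 1.5,
                                           chemokine = 1.5, tcell = 1.5,
                                           neuronal = 1.0),
                          cluster2_fraction_demented = 0.70,
                          cluster2_fraction_nondemented = 0.19,
                          ct_noise_sd = 0.5, subject_sd = 0.8,
                          seed = 1L) {
  if (any(group_sizes < 2)) stop("each Braak group needs at least 2 subjects")
  if (is.null(names(group_sizes))) stop("`group_sizes` must be named")
  if (!"housekeeping" %in% names(gene_panels))
    stop("gene_panels must include a `housekeeping` panel")
  hk <- gene_panels$housekeeping
  targets <- unique(unlist(gene_panels[names(gene_panels) != "housekeeping"]))
  if (length(intersect(hk, targets)))
    stop("housekeeping genes overlap target panels: ",
         paste(intersect(hk, targets), collapse = ", "))
  fr <- c(cluster2_fraction_demented, cluster2_fraction_nondemented)
  if (any(fr < 0 | fr > 1)) stop("cluster-II fractions must lie in [0, 1]")
  if (ct_noise_sd <= 0 || subject_sd <= 0) stop("noise SDs must be > 0")
  bad <- setdiff(names(effect_sizes), names(gene_panels))
  if (length(bad))
    stop("effect_sizes name unknown panel(s): ", paste(bad, collapse = ", "))
  structure(
    list(group_sizes = group_sizes, gene_panels = gene_panels,
         effect_sizes = effect_sizes,
         cluster2_fraction_demented = cluster2_fraction_demented,
         cluster2_fraction_nondemented = cluster2_fraction_nondemented,
         ct_noise_sd = ct_noise_sd, subject_sd = subject_sd,
         seed = as.integer(seed)),
    class = "cohort_config"
  )
}

# deterministic per-gene baseline Ct: housekeepers near 20 cycles,
# targets spread over 23-31 (independent of the RNG seed)
baseline_ct <- function(genes, housekeeping) {
  base <- 23 + (seq_along(genes) - 1) %% 9
  names(base) <- genes
  base[housekeeping] <- 19 + seq_along(housekeeping) * 0.5
  base
}

# panels whose effect lowers Ct (raises expression) in latent cluster II
.cluster2_up_panels <- c("cd163_cluster", "mdc_panel", "endothelial",
                         "chemokine", "tcell")

#' Simulate a Braak-stratified qPCR cohort with a planted CD163-high
#' subpopulation
#'
#' Draws a full sample x gene Ct table under the model described in
#' [cohort_config()], together with subject metadata (Braak group,
#' dementia status, sex, age, post-mortem delay) and the ground-truth
#' latent cluster labels.
#'
#' @param config A [cohort_config()].
#' @return A list with elements
#'   \describe{
#'     \item{ct}{a [ct_table()] (reference group = Braak II) with metadata;}
#'     \item{metadata}{the per-subject metadata data.frame;}
#'     \item{ground_truth}{list with `cluster_labels` (named factor I/II)
#'       and the per-subject random effects.}
#'   }
#' @export
simulate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  panels <- config$gene_panels
  hk <- panels$housekeeping
  genes <- unique(c(unlist(panels[names(panels) != "housekeeping"]), hk))
  groups <- rep(names(config$group_sizes), config$group_sizes)
  n <- length(groups)
  ids <- sprintf("S%03d", seq_len(n))
  demented <- groups == "Braak V-VI"

  p2 <- ifelse(demented, config$cluster2_fraction_demented,
               config$cluster2_fraction_nondemented)
  cluster <- factor(ifelse(stats::runif(n) < p2, "II", "I"),
                    levels = c("I", "II"))
  names(cluster) <- ids

  # age / post-mortem delay loosely matching a typical autopsy cohort
  age_mean <- c("Braak 0" = 49.5, "Braak II" = 77.5,
                "Braak III-IV" = 79.4, "Braak V-VI" = 78.0)
  age_sd <- c("Braak 0" = 6, "Braak II" = 8.8,
              "Braak III-IV" = 12.4, "Braak V-VI" = 12.5)
  age <- round(stats::rnorm(n, age_mean[groups], age_sd[groups]), 1)
  pmd <- round(pmax(1, stats::rnorm(n, 8, 4)), 1)
  sex <- sample(c("M", "F"), n, replace = TRUE)

  u <- stats::rnorm(n, 0, config$subject_sd)          # subject-level effect
  base <- baseline_ct(genes, hk)
  shift <- matrix(0, n, length(genes), dimnames = list(ids, genes))
  eff <- config$effect_sizes
  for (p in intersect(names(eff), .cluster2_up_panels))
    shift[cluster == "II", panels[[p]]] <-
      shift[cluster == "II", panels[[p]]] - eff[[p]]
  if ("neuronal" %in% names(eff))
    shift[cluster == "II", panels$neuronal] <-
      shift[cluster == "II", panels$neuronal] + eff[["neuronal"]]
  if ("hMG" %in% names(eff))
    shift[demented, panels$hMG] <- shift[demented, panels$hMG] + eff[["hMG"]]
  if ("aMG" %in% names(eff) && eff[["aMG"]] != 0)
    shift[demented, panels$aMG] <- shift[demented, panels$aMG] - eff[["aMG"]]

  eps <- matrix(stats::rnorm(n * length(genes), 0, config$ct_noise_sd),
                n, length(genes))
  ct <- sweep(shift + eps, 2, base, "+") + u
  dimnames(ct) <- list(ids, genes)

  metadata <- data.frame(
    sample = ids, braak_group = groups,
    demented = demented, sex = sex, age = age, pmd_h = pmd,
    stringsAsFactors = FALSE
  )
  tab <- ct_table(ct, housekeeping = hk,
                  reference_samples = ids[groups == "Braak II"],
                  group = stats::setNames(groups, ids),
                  metadata = metadata)
  list(ct = tab, metadata = metadata,
       ground_truth = list(cluster_labels = cluster, subject_effect = u))
}

#' Simulate biallelic genotypes at rs429358 and rs7412
#'
#' Alleles are drawn independently per site with the stated allele
#' frequencies (no linkage), which suffices for exercising the APOE caller
#' on realistic genotype mixes.
#'
#' @param n Number of subjects (0 allowed; returns an empty table).
#' @param allele_freqs Named numeric vector: `rs429358_C` = frequency of
#'   the C allele at rs429358, `rs7412_T` = frequency of the T allele at
#'   rs7412 (defaults 0.15 and 0.08, typical European frequencies).
#' @param seed Integer RNG seed.
#' @return data.frame with columns `sample`, `rs429358`, `rs7412`
#'   (unordered pairs encoded `"X/Y"`).
#' @export
simulate_genotypes <- function(n,
                               allele_freqs = c(rs429358_C = 0.15,
                                                rs7412_T = 0.08),
                               seed = 1L) {
  if (n < 0) stop("`n` must be non-negative")
  if (any(allele_freqs < 0 | allele_freqs > 1))
    stop("allele frequencies must lie in [0, 1]")
  set.seed(as.integer(seed))
  if (n == 0)
    return(data.frame(sample = character(), rs429358 = character(),
                      rs7412 = character(), stringsAsFactors = FALSE))
  draw_site <- function(p_alt, alt, ref) {
    a1 <- ifelse(stats::runif(n) < p_alt, alt, ref)
    a2 <- ifelse(stats::runif(n) < p_alt, alt, ref)
    vapply(seq_len(n),
           function(i) paste(sort(c(a1[i], a2[i])), collapse = "/"), "")
  }
  data.frame(
    sample = sprintf("S%03d", seq_len(n)),
    rs429358 = draw_site(allele_freqs[["rs429358_C"]], "C", "T"),
    rs7412 = draw_site(allele_freqs[["rs7412_T"]], "T", "C"),
    stringsAsFactors = FALSE
  )
}
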