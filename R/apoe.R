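#' Call an APOE epsilon diplotype from rs429358 and rs7412 genotypes
#'
#' The APOE epsilon allele is determined by the haplotype across two coding
#' SNPs: the T allele at rs429358 together with the C allele at rs7412 is
#' epsilon-3; T at both SNPs is epsilon-2; C at both positions is
#' epsilon-4. The remaining haplotype (C at rs429358 with T at rs7412) is
#' population-rare ("epsilon-1-like") and is reported with
#' `rare_haplotype = TRUE` rather than forced into the common alleles.
#'
#' Unphased biallelic genotypes determine the diplotype uniquely unless
#' both sites are heterozygous; that doubly heterozygous genotype is
#' compatible with epsilon-2/epsilon-4 and with epsilon-1/epsilon-3 and is
#' resolved to epsilon-2/epsilon-4 (the epsilon-1 haplotype being rare)
#' with `ambiguous = TRUE`.
#'
#' @param rs429358 Unordered allele pair at rs429358, e.g. `"T/C"` or
#'   `c("T", "C")`; alleles restricted to T and C.
#' @param rs7412 Unordered allele pair at rs7412, same encoding.
#' @return A list of class `apoe_call`: `alleles` (two epsilon labels,
#'   sorted), `genotype` (e.g. `"e3/e4"`), `ambiguous`, `rare_haplotype`.
#' @export
call_apoe <- function(rs429358, rs7412) {
  g1 <- parse_allele_pair(rs429358, "rs429358")
  g2 <- parse_allele_pair(rs7412, "rs7412")
  hap_call <- function(a1, a2) {
    if (a1 == "T" && a2 == "C") "e3"
    else if (a1 == "T" && a2 == "T") "e2"
    else if (a1 == "C" && a2 == "C") "e4"
    else "e1"                      # C at rs429358 with T at rs7412: rare
  }
  het1 <- g1[1] != g1[2]
  het2 <- g2[1] != g2[2]
  ambiguous <- FALSE
  if (het1 && het2) {
    # (T/C, T/C): e2+e4 or e1+e3; resolve to e2/e4, flag the phase ambiguity
    alleles <- c("e2", "e4")
    ambiguous <- TRUE
  } else if (!het1) {
    alleles <- c(hap_call(g1[1], g2[1]), hap_call(g1[1], g2[2]))
  } else {
    # rs7412 homozygous: each chromosome carries the same rs7412 allele
    alleles <- c(hap_call(g1[1], g2[1]), hap_call(g1[2], g2[1]))
  }
  alleles <- sort(alleles)
  structure(
    list(alleles = alleles,
         genotype = paste(alleles, collapse = "/"),
         ambiguous = ambiguous,
         rare_haplotype = "e1" %in% alleles),
    class = "apoe_call"
  )
}

parse_allele_pair <- function(g, site) {
  if (length(g) == 1 && is.character(g))
    g <- strsplit(g, "[/|]")[[1]]
  g <- toupper(trimws(as.character(g)))
  if (length(g) != 2 || !all(g %in% c("T", "C")))
    stop("invalid genotype at ", site,
         ": expected two alleles from {T, C}, got ",
         paste(g, collapse = "/"))
  sort(g)
}

#' @export
print.apoe_call <- function(x, ...) {
  cat("APOE", x$genotype)
  if (x$ambiguous) cat(" [phase-ambiguous]")
  if (x$rare_haplotype) cat(" [rare haplotype]")
  cat("\n")
  invisible(x)
}

#' Call APOE diplotypes for a genotype table
#'
#' @param genotypes A data.frame with columns `sample`, `rs429358`,
#'   `rs7412` (allele pairs encoded `"X/Y"`), as produced by
#'   [simulate_genotypes()] or read from CSV.
#' @return A data.frame with columns `sample`, `apoe`, `ambiguous`,
#'   `rare_haplotype`.
#' @export
call_apoe_table <- function(genotypes) {
  df <- as.data.frame(genotypes)
  need <- c("sample", "rs429358", "rs7412")
  if (!all(need %in% names(df)))
    stop("genotype table needs columns: ", paste(need, collapse = ", "))
  calls <- lapply(seq_len(nrow(df)),
                  function(i) call_apoe(df$rs429358[i], df$rs7412[i]))
  data.frame(
    sample = df$sample,
    apoe = vapply(calls, `[[`, "", "genotype"),
    ambiguous = vapply(calls, `[[`, FALSE, "ambiguous"),
    rare_haplotype = vapply(calls, `[[`, FALSE, "rare_haplotype"),
    stringsAsFactors = FALSE
  )
}
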