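#' Configuration for rare-variant candidate filtering
#'
#' Thresholds and class sets for the multistep rare-variant filter that
#' yields biallelic candidate genotypes: a genome-wide rarity threshold
#' (MAF < 0.001), a laxer threshold used for exome-sequenced probands
#' (MAF < 0.003), the consequence classes counted as protein-altering, and
#' a virtual gene panel whose genes are excluded (variants in genes already
#' known to cause the phenotype are handled by the panel analysis, not the
#' genome-wide search).
#'
#' @param maf_rare Genome-wide rarity threshold (default 0.001).
#' @param maf_rare_exome Exome rarity threshold (default 0.003).
#' @param protein_altering_classes Consequence labels treated as
#'   protein-altering.
#' @param panel_genes Gene symbols to exclude (virtual panel).
#' @param target_gene Optional list(symbol =, interval = genomic_interval).
#'
#' @return An object of class \code{filter_config}.
#' @export
filter_config <- function(maf_rare = 0.001,
                          maf_rare_exome = 0.003,
                          protein_altering_classes = c(
                            "missense", "stop_gain", "frameshift",
                            "splice_donor", "splice_acceptor",
                            "inframe_indel", "start_lost", "stop_lost"),
                          panel_genes = character(0),
                          target_gene = NULL) {
  if (!(maf_rare > 0 && maf_rare <= maf_rare_exome && maf_rare_exome < 1))
    stop("need 0 < maf_rare <= maf_rare_exome < 1")
  structure(list(maf_rare = maf_rare, maf_rare_exome = maf_rare_exome,
                 protein_altering_classes = protein_altering_classes,
                 panel_genes = panel_genes, target_gene = target_gene),
            class = "filter_config")
}

#' Filter variant sites to rare protein-altering candidates
#'
#' Retains sites whose consequence is protein-altering, whose population
#' frequency is below the rarity threshold (unknown frequency passes: an
#' allele absent from the population resource is at most as frequent as the
#' resource can resolve), and whose gene is not on the exclusion panel.
#' Order is preserved and the output is a subset of the input, so the
#' filter is idempotent.
#'
#' @param sites Site data.frame with columns \code{population_af},
#'   \code{consequence} and \code{gene} (NAs allowed).
#' @param cfg A [filter_config()].
#' @param use_exome_threshold Use \code{maf_rare_exome} instead of
#'   \code{maf_rare} (exome-sequenced probands).
#' @return The retained subset of \code{sites}, input order preserved.
#' @export
filter_rare <- function(sites, cfg = filter_config(), use_exome_threshold = FALSE) {
  stopifnot(inherits(cfg, "filter_config"))
  if (!nrow(sites)) return(sites)
  if (is.null(sites$population_af)) sites$population_af <- NA_real_
  thr <- if (use_exome_threshold) cfg$maf_rare_exome else cfg$maf_rare
  csq_ok <- !is.na(sites$consequence) &
    sites$consequence %in% cfg$protein_altering_classes
  af_ok <- is.na(sites$population_af) | sites$population_af < thr
  panel_ok <- is.na(sites$gene) | !sites$gene %in% cfg$panel_genes
  sites[csq_ok & af_ok & panel_ok, , drop = FALSE]
}

carries_any_alt <- function(calls, sample, key) {
  row <- calls[calls$sample == sample & calls$key == key, , drop = FALSE]
  if (nrow(row) != 1L) return(NA)
  if (is.na(row$a1) && is.na(row$a2)) return(NA)
  isTRUE(row$a1 == 1L) || isTRUE(row$a2 == 1L)
}

genotyped_in <- function(calls, sample) {
  !is.na(sample) && sample %in% calls$sample
}

#' Assemble biallelic candidate genotypes for one affected individual
#'
#' Combines an individual's candidate-site genotype calls with pedigree
#' segregation and deletion calls into candidate biallelic configurations:
#' \describe{
#'   \item{hom_alt}{homozygous for one candidate allele.}
#'   \item{het_plus_deletion_hemizygous}{an SNV lying inside a deletion
#'     carried by the same sample; the SNV is hemizygous on the retained
#'     chromosome regardless of its diploid GT string, because genotype
#'     callers emit diploid calls over copy-loss regions. A warning is
#'     raised when read depths contradict copy loss (substantial
#'     reference-allele depth at the site).}
#'   \item{compound_het_trans}{two heterozygous candidates placed on
#'     different parental chromosomes by segregation: both parents each
#'     carry exactly one; or a single available relative separates the two
#'     (an available parent carries exactly one of the pair, or a sibling
#'     carries exactly one — two variants a gene-length apart travel
#'     together unless on opposite chromosomes).}
#'   \item{compound_het_unresolved}{two heterozygous candidates with no
#'     informative segregation; reported with an explicit evidence grade.}
#'   \item{cis_excluded}{a pair where one parent carries both alleles —
#'     excluded as a biallelic candidate (flagged, \code{candidate = FALSE}).}
#' }
#'
#' @param individual Sample id of the affected individual.
#' @param family Family id.
#' @param calls Genotype-call data.frame (as from [read_vcf()]) restricted
#'   to candidate sites in one gene; may include relatives' calls.
#' @param deletions A \code{deletion_table} or NULL.
#' @param pedigree A \code{pedigree} or NULL.
#' @return data.frame of class \code{biallelic_genotypes}: columns
#'   \code{individual}, \code{family}, \code{configuration},
#'   \code{allele_a}, \code{allele_b}, \code{evidence}, \code{candidate}.
#' @export
assemble_biallelic <- function(individual, family, calls,
                               deletions = NULL, pedigree = NULL) {
  mine <- calls[calls$sample == individual, , drop = FALSE]
  carried <- mine[(!is.na(mine$a1) & mine$a1 == 1L) |
                  (!is.na(mine$a2) & mine$a2 == 1L), , drop = FALSE]
  dels <- sample_deletions(deletions, individual)

  out <- list()
  emit <- function(configuration, allele_a, allele_b, evidence, candidate = TRUE) {
    out[[length(out) + 1L]] <<- data.frame(
      individual = individual, family = family,
      configuration = configuration, allele_a = allele_a,
      allele_b = allele_b, evidence = evidence, candidate = candidate,
      stringsAsFactors = FALSE)
  }

  in_deletion <- function(row) {
    for (d in dels)
      if (interval_contains(d, row$chrom, row$pos)) return(d)
    NULL
  }

  het_keys <- character(0)
  for (r in seq_len(nrow(carried))) {
    row <- carried[r, ]
    d <- in_deletion(row)
    if (!is.null(d)) {
      if (!is.na(row$dp) && !is.na(row$ad_ref) && row$dp > 0 &&
          row$ad_ref / row$dp > 0.15)
        warning("sample ", individual, " site ", row$key,
                ": reference read depth (", row$ad_ref, "/", row$dp,
                ") contradicts hemizygosity over the deletion")
      emit("het_plus_deletion_hemizygous", row$key,
           sprintf("%s:%s-%sdel", d$chrom,
                   format(d$start, scientific = FALSE),
                   format(d$end, scientific = FALSE)),
           "snv_within_sample_deletion")
    } else if (isTRUE(row$a1 == 1L) && isTRUE(row$a2 == 1L)) {
      ev <- "unsegregated"
      if (!is.null(pedigree)) {
        par <- tryCatch(ped_parents(pedigree, family, individual),
                        error = function(e) list(father = NA, mother = NA))
        st <- c(father = carries_any_alt(calls, par$father, row$key),
                mother = carries_any_alt(calls, par$mother, row$key))
        ev <- paste0("father:", status_label(st["father"]),
                     ";mother:", status_label(st["mother"]))
      }
      emit("hom_alt", row$key, row$key, ev)
    } else {
      het_keys <- c(het_keys, row$key)
    }
  }

  if (length(het_keys) >= 2L) {
    par <- if (!is.null(pedigree))
      tryCatch(ped_parents(pedigree, family, individual),
               error = function(e) list(father = NA, mother = NA))
    else list(father = NA_character_, mother = NA_character_)
    sibs <- find_siblings(pedigree, family, individual)
    pairs <- utils::combn(het_keys, 2L, simplify = FALSE)
    for (p in pairs) {
      res <- classify_pair(p[1], p[2], calls, par, sibs, individual)
      emit(res$configuration, p[1], p[2], res$evidence,
           candidate = res$configuration != "cis_excluded")
    }
  }

  res <- if (length(out)) do.call(rbind, out) else data.frame(
    individual = character(), family = character(),
    configuration = character(), allele_a = character(),
    allele_b = character(), evidence = character(), candidate = logical(),
    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  class(res) <- c("biallelic_genotypes", "data.frame")
  res
}

status_label <- function(x) {
  if (is.na(x)) "unavailable" else if (x) "carrier" else "non_carrier"
}

find_siblings <- function(pedigree, family, individual) {
  if (is.null(pedigree)) return(character(0))
  me <- pedigree[pedigree$family == family & pedigree$id == individual, ]
  if (nrow(me) != 1L) return(character(0))
  if (is.na(me$father) && is.na(me$mother)) return(character(0))
  fam <- pedigree[pedigree$family == family & pedigree$id != individual, ]
  share <- (!is.na(fam$father) & !is.na(me$father) & fam$father == me$father) |
           (!is.na(fam$mother) & !is.na(me$mother) & fam$mother == me$mother)
  fam$id[share]
}

classify_pair <- function(k1, k2, calls, par, sibs, individual) {
  f1 <- carries_any_alt(calls, par$father, k1)
  f2 <- carries_any_alt(calls, par$father, k2)
  m1 <- carries_any_alt(calls, par$mother, k1)
  m2 <- carries_any_alt(calls, par$mother, k2)
  # a genotyped parent carrying both alleles: pair can sit in cis
  if (isTRUE(f1) && isTRUE(f2))
    return(list(configuration = "cis_excluded", evidence = "father_carries_both"))
  if (isTRUE(m1) && isTRUE(m2))
    return(list(configuration = "cis_excluded", evidence = "mother_carries_both"))
  if (isTRUE(f1) && isFALSE(f2) && isTRUE(m2) && isFALSE(m1))
    return(list(configuration = "compound_het_trans",
                evidence = "both_parents:paternal_a;maternal_b"))
  if (isTRUE(f2) && isFALSE(f1) && isTRUE(m1) && isFALSE(m2))
    return(list(configuration = "compound_het_trans",
                evidence = "both_parents:paternal_b;maternal_a"))
  # one informative parent: carries exactly one allele, definitively lacks
  # the other, so the other allele came from the unavailable parent
  one_parent <- function(c1, c2, who) {
    if (isTRUE(c1) && isFALSE(c2))
      list(configuration = "compound_het_trans",
           evidence = paste0("single_parent:", who, "_carries_a_only"))
    else if (isTRUE(c2) && isFALSE(c1))
      list(configuration = "compound_het_trans",
           evidence = paste0("single_parent:", who, "_carries_b_only"))
    else NULL
  }
  r <- one_parent(f1, f2, "father")
  if (!is.null(r)) return(r)
  r <- one_parent(m1, m2, "mother")
  if (!is.null(r)) return(r)
  # sibling separation: a sibling carrying exactly one of the two nearby
  # variants shows they segregate independently, hence in trans
  for (s in sibs) {
    s1 <- carries_any_alt(calls, s, k1)
    s2 <- carries_any_alt(calls, s, k2)
    if ((isTRUE(s1) && isFALSE(s2)) || (isTRUE(s2) && isFALSE(s1)))
      return(list(configuration = "compound_het_trans",
                  evidence = paste0("sibling_separation:", s)))
  }
  any_rel <- genotyped_in(calls, par$father) || genotyped_in(calls, par$mother) ||
    any(vapply(sibs, function(s) genotyped_in(calls, s), TRUE))
  list(configuration = "compound_het_unresolved",
       evidence = if (any_rel) "relatives_uninformative" else "no_segregation")
}

#' Assemble biallelic candidates for every affected individual in a cohort
#'
#' Runs [assemble_biallelic()] over all affected, genotyped individuals of
#' a pedigree and binds the results.
#'
#' @param vcf A \code{vcf_data} restricted to candidate sites.
#' @param ped A \code{pedigree}.
#' @param deletions A \code{deletion_table} or NULL.
#' @return A \code{biallelic_genotypes} data.frame.
#' @export
assemble_cohort <- function(vcf, ped, deletions = NULL) {
  out <- list()
  aff <- ped[ped$affected, , drop = FALSE]
  for (r in seq_len(nrow(aff))) {
    if (!aff$id[r] %in% vcf$calls$sample) next
    out[[r]] <- assemble_biallelic(aff$id[r], aff$family[r], vcf$calls,
                                   deletions = deletions, pedigree = ped)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("biallelic_genotypes", "data.frame")
  res
}
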