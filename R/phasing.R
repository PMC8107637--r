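#' Configuration for informative-SNV selection and phasing
#'
#' @param window_bp Window applied up- and downstream of the target gene
#'   interval, in bp (default 150000, i.e. "approximately 150 kb" fixed to
#'   an exact, reproducible value).
#' @param maf_informative Population-frequency threshold below which an SNV
#'   is informative for phasing (default 0.1): sharing a sufficiently rare
#'   allele across carrier chromosomes is evidence of common descent rather
#'   than chance.
#' @return An object of class \code{phase_config}.
#' @export
phase_config <- function(window_bp = 150000, maf_informative = 0.1) {
  stopifnot(window_bp > 0, maf_informative > 0, maf_informative < 1)
  structure(list(window_bp = window_bp, maf_informative = maf_informative),
            class = "phase_config")
}

#' Select informative SNVs around the target gene
#'
#' Restricts candidate sites to the analysis window
#' \code{[gene$start - window_bp, gene$end + window_bp]} and keeps those
#' with known population frequency below \code{maf_informative}. The index
#' variant is always included regardless of its frequency, since the local
#' haplotype is reconstructed around it.
#'
#' @param sites Site data.frame with \code{key}, \code{chrom}, \code{pos}.
#' @param freq A \code{freq_table} (or NULL: all frequencies unknown).
#' @param cfg A [phase_config()].
#' @param gene \code{genomic_interval} of the target gene.
#' @param index_key Variant key \code{chrom:pos:ref:alt} of the index
#'   variant, or NULL.
#' @return The informative subset of \code{sites}, sorted by position, with
#'   a \code{population_af} column attached.
#' @export
select_informative <- function(sites, freq, cfg, gene, index_key = NULL) {
  stopifnot(inherits(cfg, "phase_config"), inherits(gene, "genomic_interval"))
  sites <- annotate_frequency(sites, freq)
  win_lo <- gene$start - cfg$window_bp
  win_hi <- gene$end + cfg$window_bp
  in_win <- sites$chrom == gene$chrom & sites$pos >= win_lo & sites$pos <= win_hi
  informative <- in_win & !is.na(sites$population_af) &
    sites$population_af < cfg$maf_informative
  if (!is.null(index_key)) informative <- informative | sites$key == index_key
  out <- sites[informative, , drop = FALSE]
  out <- out[order(out$pos), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(index_key) && nrow(out) <= 1L)
    warning("no informative SNVs besides the index variant; ",
            "the shared core will span only the index site")
  out
}

#' Extract one sample's genotype matrix over an ordered site list
#'
#' @param calls Genotype-call data.frame (as from [read_vcf()]).
#' @param sample Sample id.
#' @param keys Ordered character vector of site keys.
#' @return Integer matrix with \code{length(keys)} rows and columns
#'   \code{a1}, \code{a2}; NA rows where the sample has no call.
#' @export
genotype_matrix <- function(calls, sample, keys) {
  rows <- calls[calls$sample == sample, , drop = FALSE]
  i <- match(keys, rows$key)
  m <- cbind(a1 = rows$a1[i], a2 = rows$a2[i])
  rownames(m) <- keys
  m
}

transmit_set <- function(g) {
  # alleles a parent can transmit; unknown genotype transmits anything
  if (is.null(g) || any(is.na(g))) c(0L, 1L) else unique(as.integer(g))
}

#' Phase a child's genotypes against parental genotypes
#'
#' For each site, assigns the child's two alleles to paternal/maternal
#' origin whenever Mendelian logic forces the assignment (the two possible
#' orderings of the child's alleles are checked against what each parent
#' can transmit; exactly one consistent ordering means the site is
#' resolved). Sites where both orderings are consistent and distinct are
#' unresolved; sites where neither is consistent are flagged as Mendelian
#' conflicts and excluded from the haplotype. Homozygous child sites are
#' always resolved (both chromosomes carry the same allele).
#'
#' @param child,father,mother Two-column genotype matrices over the same
#'   ordered site list (see [genotype_matrix()]); \code{father}/\code{mother}
#'   may be NULL when unavailable.
#' @return data.frame with one row per site: \code{paternal},
#'   \code{maternal} (0/1/NA) and \code{status} in
#'   \code{resolved}/\code{unresolved}/\code{mendel_conflict}/\code{missing}.
#' @export
phase_by_segregation <- function(child, father = NULL, mother = NULL) {
  n <- nrow(child)
  pat <- mat <- rep(NA_integer_, n)
  status <- character(n)
  for (s in seq_len(n)) {
    c1 <- child[s, 1]; c2 <- child[s, 2]
    if (is.na(c1) || is.na(c2)) { status[s] <- "missing"; next }
    Fs <- transmit_set(if (is.null(father)) NULL else father[s, ])
    Ms <- transmit_set(if (is.null(mother)) NULL else mother[s, ])
    v1 <- (c1 %in% Fs) && (c2 %in% Ms)   # (c1 paternal, c2 maternal)
    v2 <- (c2 %in% Fs) && (c1 %in% Ms)
    if (!v1 && !v2) {
      status[s] <- "mendel_conflict"
    } else if (c1 == c2) {
      pat[s] <- c1; mat[s] <- c1; status[s] <- "resolved"
    } else if (v1 && v2) {
      status[s] <- "unresolved"
    } else if (v1) {
      pat[s] <- c1; mat[s] <- c2; status[s] <- "resolved"
    } else {
      pat[s] <- c2; mat[s] <- c1; status[s] <- "resolved"
    }
  }
  data.frame(paternal = pat, maternal = mat, status = status,
             stringsAsFactors = FALSE)
}

new_phased_haplotype <- function(individual, family, sites, alleles, origin,
                                 carries_index) {
  stopifnot(nrow(sites) == length(alleles), length(alleles) == length(origin))
  if (is.unsorted(sites$pos, strictly = TRUE))
    stop("haplotype sites must be strictly increasing by position")
  structure(list(individual = individual, family = family, sites = sites,
                 alleles = as.integer(alleles), origin = origin,
                 carries_index = isTRUE(carries_index)),
            class = "phased_haplotype")
}

#' @export
print.phased_haplotype <- function(x, ...) {
  al <- ifelse(is.na(x$alleles), ".", ifelse(x$alleles == 1L, "A", "r"))
  cat(sprintf("<phased_haplotype> %s (family %s)%s\n", x$individual, x$family,
              if (x$carries_index) " [index carrier]" else ""))
  cat(sprintf("  %d sites, %d resolved: %s\n", length(x$alleles),
              sum(!is.na(x$alleles)), paste(al, collapse = "")))
  invisible(x)
}

#' Anchor a hemizygous carrier's haplotype over a deletion
#'
#' For a sample carrying the index variant in trans with a deletion that
#' removes the other copy of the gene, every variant call at a site inside
#' the deletion interval reflects the single retained chromosome — the one
#' carrying the index variant — so those alleles are assigned to the
#' index haplotype directly (origin \code{hemizygous_anchor}). Sites
#' outside the deletion are resolved only where the sample is homozygous.
#'
#' @param calls Genotype-call data.frame.
#' @param sample Sample id of the hemizygous carrier.
#' @param family Family id.
#' @param deletion \code{genomic_interval} of the deletion on the trans
#'   allele; must contain the index variant's position.
#' @param sites Informative site data.frame (ordered by position).
#' @param index_key Key of the index variant.
#' @return A \code{phased_haplotype}.
#' @export
anchor_hemizygous <- function(calls, sample, family, deletion, sites, index_key) {
  stopifnot(inherits(deletion, "genomic_interval"))
  idx <- match(index_key, sites$key)
  if (is.na(idx)) stop("index variant ", index_key, " not among the sites")
  if (!interval_contains(deletion, sites$chrom[idx], sites$pos[idx]))
    stop("anchoring refused: index variant ", index_key,
         " lies outside the deletion interval ", deletion$chrom, ":",
         format(deletion$start, scientific = FALSE), "-",
         format(deletion$end, scientific = FALSE),
         "; hemizygosity cannot place alleles on the index haplotype")
  g <- genotype_matrix(calls, sample, sites$key)
  if (!(isTRUE(g[idx, 1] == 1L) || isTRUE(g[idx, 2] == 1L)))
    stop("sample ", sample, " does not carry the index variant ", index_key)
  n <- nrow(sites)
  alleles <- rep(NA_integer_, n)
  origin <- rep("unresolved", n)
  inside <- interval_contains(deletion, sites$chrom, sites$pos)
  for (s in seq_len(n)) {
    a1 <- g[s, 1]; a2 <- g[s, 2]
    if (inside[s]) {
      if (is.na(a1) && is.na(a2)) next
      alleles[s] <- as.integer(isTRUE(a1 == 1L) || isTRUE(a2 == 1L))
      origin[s] <- "hemizygous_anchor"
    } else if (!is.na(a1) && !is.na(a2) && a1 == a2) {
      alleles[s] <- a1
      origin[s] <- "homozygous"
    }
  }
  new_phased_haplotype(sample, family, sites, alleles, origin, TRUE)
}

singleton_haplotype <- function(calls, sample, family, sites, index_key) {
  g <- genotype_matrix(calls, sample, sites$key)
  n <- nrow(sites)
  alleles <- rep(NA_integer_, n)
  origin <- rep("unresolved", n)
  hom <- !is.na(g[, 1]) & !is.na(g[, 2]) & g[, 1] == g[, 2]
  alleles[hom] <- g[hom, 1]
  origin[hom] <- "homozygous"
  idx <- match(index_key, sites$key)
  carries <- isTRUE(g[idx, 1] == 1L) || isTRUE(g[idx, 2] == 1L)
  new_phased_haplotype(sample, family, sites, alleles, origin, carries)
}

trio_haplotype <- function(calls, sample, family, father, mother, sites,
                           index_key) {
  g <- genotype_matrix(calls, sample, sites$key)
  gf <- if (genotyped_in(calls, father)) genotype_matrix(calls, father, sites$key)
  gm <- if (genotyped_in(calls, mother)) genotype_matrix(calls, mother, sites$key)
  if (is.null(gf) && is.null(gm))
    return(list(hap = singleton_haplotype(calls, sample, family, sites, index_key),
                lineage = paste0("singleton:", sample)))
  ph <- phase_by_segregation(g, gf, gm)
  idx <- match(index_key, sites$key)
  lineage <- NA_character_
  if (ph$status[idx] == "resolved") {
    if (isTRUE(ph$paternal[idx] == 1L) && isTRUE(ph$maternal[idx] == 1L))
      lineage <- "homozygous_index"
    else if (isTRUE(ph$paternal[idx] == 1L)) lineage <- "paternal"
    else if (isTRUE(ph$maternal[idx] == 1L)) lineage <- "maternal"
  }
  if (is.na(lineage))
    return(list(hap = singleton_haplotype(calls, sample, family, sites, index_key),
                lineage = paste0("singleton:", sample)))
  side <- if (lineage == "maternal") "maternal" else "paternal"
  n <- nrow(sites)
  alleles <- rep(NA_integer_, n)
  origin <- rep("unresolved", n)
  for (s in seq_len(n)) {
    if (ph$status[s] == "resolved") {
      alleles[s] <- if (side == "paternal") ph$paternal[s] else ph$maternal[s]
      origin[s] <- if (!is.na(g[s, 1]) && !is.na(g[s, 2]) && g[s, 1] == g[s, 2])
        "homozygous" else side
    } else if (ph$status[s] == "mendel_conflict") {
      origin[s] <- "mendel_conflict"
    } else if (!is.na(g[s, 1]) && !is.na(g[s, 2]) && g[s, 1] == g[s, 2]) {
      alleles[s] <- g[s, 1]
      origin[s] <- "homozygous"
    }
  }
  carries <- isTRUE(alleles[idx] == 1L)
  list(hap = new_phased_haplotype(sample, family, sites, alleles, origin, carries),
       lineage = lineage)
}

merge_haplotypes <- function(a, b) {
  # two individuals sharing one transmitted chromosome (e.g. affected sibs)
  alleles <- a$alleles
  origin <- a$origin
  conflict <- !is.na(a$alleles) & !is.na(b$alleles) & a$alleles != b$alleles
  if (any(conflict)) {
    warning("sib haplotypes disagree at ", sum(conflict),
            " site(s); those sites set to unresolved")
    alleles[conflict] <- NA_integer_
    origin[conflict] <- "unresolved"
  }
  take_b <- is.na(a$alleles) & !is.na(b$alleles) & !conflict
  alleles[take_b] <- b$alleles[take_b]
  origin[take_b] <- b$origin[take_b]
  new_phased_haplotype(paste(a$individual, b$individual, sep = "+"),
                       a$family, a$sites, alleles, origin,
                       a$carries_index || b$carries_index)
}

#' Build one phased haplotype per independent index-carrying chromosome
#'
#' For every affected index-variant carrier: samples with a deletion
#' spanning the index position are anchored hemizygously; samples with at
#' least one genotyped parent are phased by segregation, and the haplotype
#' transmitted with the index allele is extracted; samples with no usable
#' relatives resolve only homozygous sites. Affected siblings whose index
#' allele has the same parental origin share one transmitted chromosome and
#' are merged into a single haplotype, so founder-sharing statistics count
#' chromosomes, not people.
#'
#' @param vcf A \code{vcf_data} object (cohort genotypes).
#' @param ped A \code{pedigree}.
#' @param freq A \code{freq_table} or NULL.
#' @param deletions A \code{deletion_table} or NULL.
#' @param index_key Key \code{chrom:pos:ref:alt} of the index variant.
#' @param gene \code{genomic_interval} of the target gene.
#' @param cfg A [phase_config()].
#' @return An object of class \code{haplotype_set}: a list of
#'   \code{phased_haplotype} with the informative site table as attribute
#'   \code{sites}.
#' @export
build_carrier_haplotypes <- function(vcf, ped, freq = NULL, deletions = NULL,
                                     index_key, gene, cfg = phase_config()) {
  sites <- select_informative(vcf$sites, freq, cfg, gene, index_key)
  calls <- vcf$calls
  idx_row <- sites[sites$key == index_key, ]
  if (nrow(idx_row) != 1L)
    stop("index variant ", index_key, " not found among cohort sites")
  carriers <- unique(calls$sample[calls$key == index_key &
                                  ((!is.na(calls$a1) & calls$a1 == 1L) |
                                   (!is.na(calls$a2) & calls$a2 == 1L))])
  carriers <- carriers[carriers %in% ped$id[ped$affected]]
  haps <- list()
  for (fam in unique(ped$family[ped$id %in% carriers])) {
    fam_carriers <- carriers[carriers %in% ped$id[ped$family == fam]]
    by_lineage <- list()
    for (ind in fam_carriers) {
      dels <- sample_deletions(deletions, ind)
      anchor <- NULL
      for (d in dels)
        if (interval_contains(d, idx_row$chrom, idx_row$pos)) anchor <- d
      if (!is.null(anchor)) {
        hap <- anchor_hemizygous(calls, ind, fam, anchor, sites, index_key)
        lineage <- "hemizygous_anchor"
      } else {
        par <- ped_parents(ped, fam, ind)
        th <- trio_haplotype(calls, ind, fam, par$father, par$mother,
                             sites, index_key)
        hap <- th$hap
        lineage <- th$lineage
      }
      if (lineage %in% names(by_lineage))
        by_lineage[[lineage]] <- merge_haplotypes(by_lineage[[lineage]], hap)
      else by_lineage[[lineage]] <- hap
    }
    haps <- c(haps, unname(by_lineage))
  }
  for (h in haps)
    if (all(is.na(h$alleles)))
      warning("haplotype for ", h$individual, " (family ", h$family,
              ") has no resolvable sites")
  structure(haps, class = "haplotype_set", sites = sites)
}

#' Haplotype-set allele matrix
#'
#' @param haps A \code{haplotype_set} or list of \code{phased_haplotype}
#'   sharing one site list.
#' @return Integer matrix (haplotypes x sites; 0 = ref, 1 = alt,
#'   NA = unresolved wildcard) with row names \code{family:individual} and
#'   column names the site keys.
#' @export
haplotype_matrix <- function(haps) {
  stopifnot(length(haps) >= 1L)
  keys <- haps[[1]]$sites$key
  for (h in haps)
    if (!identical(h$sites$key, keys))
      stop("haplotypes have mismatched site lists")
  m <- do.call(rbind, lapply(haps, function(h) h$alleles))
  rownames(m) <- vapply(haps, function(h) paste(h$family, h$individual, sep = ":"), "")
  colnames(m) <- keys
  m
}
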