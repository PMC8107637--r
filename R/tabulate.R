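#' Packaged cohort genotype table
#'
#' The per-family candidate genotype table of the eight-family cohort: one
#' row per (family, allele), with coding HGVS (the whole-gene deletion is a
#' single allele identified by its coordinates), protein change, consequence
#' type, protein domain, population (gnomAD) allele frequency, and the
#' observed parental origin from segregation.
#'
#' @param path Optional path to a TSV in the same schema (defaults to the
#'   packaged table).
#' @return data.frame of class \code{genotype_table}.
#' @export
cohort_genotypes <- function(path = system.file("extdata", "cohort_genotypes.tsv",
                                                package = "founderhap")) {
  df <- read.delim(path, colClasses = "character")
  df$family <- as.character(df$family)
  df$n_affected <- as.integer(df$n_affected)
  df$gnomad_af <- as.numeric(df$gnomad_af)
  validate_hgvs(df$allele)
  class(df) <- c("genotype_table", "data.frame")
  df
}

validate_hgvs <- function(x) {
  ok <- grepl("^c\\.[0-9]+[ACGT]>[ACGT]$", gsub(" ", "", x)) |
    grepl("^chr[0-9XYM]+:[0-9]+-[0-9]+del$", x)
  if (any(!ok))
    stop("malformed variant label(s): ", paste(x[!ok], collapse = ", "))
  invisible(x)
}

normalize_hgvs <- function(x) gsub(" ", "", x)

#' Packaged cohort phenotype table
#'
#' Per-individual phenotype statuses transcribed feature-by-feature: each
#' feature cell is a raw status string (\code{"Yes (3)"}, \code{"No"},
#' \code{"Possible"}, \code{"ND"}; onset ages in years in brackets, stored
#' verbatim since free-text onsets like \code{"late teens"} are never
#' computed with).
#'
#' @param path Optional path to a TSV in the same schema.
#' @return Long-format data.frame of class \code{phenotype_table}: columns
#'   \code{individual}, \code{family}, \code{feature}, \code{status}
#'   (\code{yes}/\code{no}/\code{possible}/\code{no_data}), \code{onset}
#'   (verbatim bracket contents or NA), \code{raw}.
#' @export
cohort_phenotypes <- function(path = system.file("extdata", "cohort_phenotypes.tsv",
                                                 package = "founderhap")) {
  wide <- read.delim(path, colClasses = "character", check.names = FALSE)
  id_cols <- c("individual", "family", "sex", "age_presentation")
  feats <- setdiff(names(wide), id_cols)
  rows <- list()
  for (f in feats) {
    parsed <- parse_status(wide[[f]])
    rows[[f]] <- data.frame(individual = wide$individual,
                            family = wide$family, feature = f,
                            status = parsed$status, onset = parsed$onset,
                            raw = wide[[f]], stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  class(df) <- c("phenotype_table", "data.frame")
  df
}

parse_status <- function(x) {
  lx <- tolower(trimws(x))
  status <- rep("no_data", length(x))
  status[startsWith(lx, "yes")] <- "yes"
  status[lx == "no"] <- "no"
  status[startsWith(lx, "possible")] <- "possible"
  status[lx %in% c("nd", "")] <- "no_data"
  onset <- rep(NA_character_, length(x))
  m <- regmatches(x, regexec("\\(([^)]*)\\)", x))
  has <- lengths(m) == 2L
  onset[has] <- vapply(m[has], `[[`, "", 2L)
  list(status = status, onset = onset)
}

#' Summarize the cohort's distinct variants
#'
#' Counts distinct alleles by normalized coding-HGVS identity (the
#' whole-gene deletion is one allele), the missense fraction among distinct
#' alleles, the fraction of families carrying the index variant, and the
#' distribution of coding alleles (deletion excluded) across protein
#' domains. Percentages are reported to one decimal.
#'
#' @param geno A \code{genotype_table} (see [cohort_genotypes()]).
#' @param index_allele Coding HGVS of the index variant
#'   (default \code{"c.1115C>A"}).
#' @return Object of class \code{cohort_summary}: \code{n_individuals},
#'   \code{n_families}, \code{n_distinct_variants}, \code{n_missense},
#'   \code{pct_missense}, \code{n_families_with_index},
#'   \code{pct_families_with_index}, \code{n_coding},
#'   \code{domain_counts} (named integer vector over coding alleles).
#' @export
summarize_variants <- function(geno, index_allele = "c.1115C>A") {
  stopifnot(is.data.frame(geno))
  validate_hgvs(geno$allele)
  allele <- normalize_hgvs(geno$allele)
  index_allele <- normalize_hgvs(index_allele)
  fam_n <- tapply(geno$n_affected, geno$family, max)
  distinct <- !duplicated(allele)
  n_distinct <- sum(distinct)
  is_missense <- geno$type[distinct] == "missense"
  n_missense <- sum(is_missense)
  fams_with_index <- unique(geno$family[allele == index_allele])
  coding <- distinct & geno$type != "deletion"
  domain_counts <- table(geno$domain[coding])
  structure(list(
    n_individuals = sum(fam_n),
    n_families = length(unique(geno$family)),
    n_distinct_variants = n_distinct,
    n_missense = n_missense,
    pct_missense = round(100 * n_missense / n_distinct, 1),
    n_families_with_index = length(fams_with_index),
    pct_families_with_index = round(100 * length(fams_with_index) /
                                      length(unique(geno$family)), 1),
    n_coding = sum(coding),
    domain_counts = c(domain_counts),
    index_allele = index_allele), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort: %d affected individuals in %d families\n",
              x$n_individuals, x$n_families))
  cat(sprintf("  distinct candidate variants: %d\n", x$n_distinct_variants))
  cat(sprintf("  missense: %d (%.1f%%)\n", x$n_missense, x$pct_missense))
  cat(sprintf("  families carrying %s: %d/%d (%.1f%%)\n", x$index_allele,
              x$n_families_with_index, x$n_families, x$pct_families_with_index))
  cat(sprintf("  coding alleles by domain (n = %d): %s\n", x$n_coding,
              paste(names(x$domain_counts), x$domain_counts,
                    sep = ": ", collapse = "; ")))
  invisible(x)
}

#' Count individuals affected for one phenotype feature
#'
#' Counts individuals whose status for the feature is in
#' \code{affected_labels}. \code{"possible"} counts as affected by default
#' (a clinically suspected feature contributes to the feature tally);
#' individuals with status \code{no_data} stay in the denominator unless
#' \code{drop_no_data} is set.
#'
#' @param pheno A \code{phenotype_table} (see [cohort_phenotypes()]).
#' @param feature Feature name.
#' @param affected_labels Status labels counted as affected.
#' @param drop_no_data Exclude \code{no_data} individuals from the
#'   denominator.
#' @return List of class \code{feature_count}: \code{feature},
#'   \code{count}, \code{n}, \code{fraction} (NA, flagged
#'   \code{undefined}, when the denominator is zero).
#' @export
count_feature <- function(pheno, feature,
                          affected_labels = c("yes", "possible"),
                          drop_no_data = FALSE) {
  feats <- unique(pheno$feature)
  if (!feature %in% feats)
    stop("unknown feature '", feature, "'; available: ",
         paste(sort(feats), collapse = ", "))
  rows <- pheno[pheno$feature == feature, , drop = FALSE]
  status <- tolower(rows$status)
  if (drop_no_data) rows <- rows[status != "no_data", , drop = FALSE]
  status <- tolower(rows$status)
  count <- sum(status %in% tolower(affected_labels))
  n <- nrow(rows)
  structure(list(feature = feature, count = count, n = n,
                 fraction = if (n > 0) count / n else NA_real_,
                 undefined = n == 0), class = "feature_count")
}

#' @export
print.feature_count <- function(x, ...) {
  if (x$undefined)
    cat(sprintf("%s: 0 of 0 (fraction undefined)\n", x$feature))
  else
    cat(sprintf("%s: %d of %d (%.1f%%)\n", x$feature, x$count, x$n,
                100 * x$fraction))
  invisible(x)
}

#' Allele frequency from allele counts
#'
#' Exact frequency \code{allele_count / allele_number} plus a display value
#' rounded to one significant figure, matching the convention of reporting
#' e.g. 2 of 68,025 alleles as 0.00003. The exact value is always retained.
#'
#' @param allele_count Non-negative integer count of observed alleles.
#' @param allele_number Positive total number of alleles.
#' @return List of class \code{allele_frequency}: \code{af} (exact),
#'   \code{display} (string, one significant figure, plain notation),
#'   \code{allele_count}, \code{allele_number}.
#' @export
compute_af <- function(allele_count, allele_number) {
  if (allele_number <= 0) stop("allele_number must be positive")
  if (allele_count < 0 || allele_count > allele_number)
    stop("need 0 <= allele_count <= allele_number")
  af <- allele_count / allele_number
  display <- format(signif(af, 1), scientific = FALSE, trim = TRUE)
  structure(list(af = af, display = display,
                 allele_count = allele_count, allele_number = allele_number),
            class = "allele_frequency")
}

#' @export
print.allele_frequency <- function(x, ...) {
  cat(sprintf("%d of %s alleles: MAF %s (exact %s)\n", x$allele_count,
              format(x$allele_number, big.mark = ","), x$display,
              format(x$af, digits = 5)))
  invisible(x)
}

#' Reported ancestral-haplotype landmarks
#'
#' The published landmark coordinates of the shared haplotype around the
#' target gene: the two boundary SNVs of the ancestral core and the
#' reference position relative to which per-family recombinations were
#' localized.
#'
#' @param path Optional path to a TSV in the same schema.
#' @return data.frame with columns \code{landmark}, \code{chrom},
#'   \code{pos}, \code{id}.
#' @seealso [span_kb()]
#' @export
haplotype_landmarks <- function(path = system.file(
    "extdata", "reported_haplotype_landmarks.tsv", package = "founderhap")) {
  read.delim(path, colClasses = c(landmark = "character", chrom = "character",
                                  id = "character"))
}

#' Core interval between the reported boundary landmarks
#'
#' @param landmarks As from [haplotype_landmarks()].
#' @return A \code{genomic_interval} from \code{core_start} to
#'   \code{core_end}.
#' @export
reported_core_interval <- function(landmarks = haplotype_landmarks()) {
  s <- landmarks[landmarks$landmark == "core_start", ]
  e <- landmarks[landmarks$landmark == "core_end", ]
  stopifnot(nrow(s) == 1L, nrow(e) == 1L)
  genomic_interval(s$chrom, s$pos, e$pos)
}
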