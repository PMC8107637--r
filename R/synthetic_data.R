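#' Configuration for the synthetic founder-cohort generator
#'
#' Describes a multi-family cohort with the statistical structure the
#' haplotype analysis assumes: one founder haplotype shared
#' identical-by-descent by a subset of families around an index variant,
#' truncated per family by recombination, embedded among
#' frequency-stratified background SNVs; one carrier family may carry the
#' index variant hemizygously opposite a whole-gene deletion, and one may
#' be an unphaseable singleton.
#'
#' Carrier families are assigned roles in order: by default
#' \code{trio, sib_pair, trio, deletion, singleton} (extra carrier families
#' beyond five become trios), mirroring a cohort with one two-affected-sib
#' family, one hemizygous-deletion family and one singleton.
#'
#' @param window Analysis window (\code{genomic_interval}).
#' @param gene Target-gene interval inside the window.
#' @param n_sites Number of background candidate SNVs in the window.
#' @param af_range Background allele frequencies are drawn uniformly from
#'   this range (default \code{c(0.0005, 0.5)}).
#' @param n_families,n_carrier_families Total families and founder-carrier
#'   families (carriers <= families).
#' @param index_pos,index_ref,index_alt,index_af The index variant: position
#'   (strictly inside the gene), alleles, and its (tiny) population
#'   frequency.
#' @param maf_informative Frequency below which a site counts as
#'   informative; used for founder-allele ascertainment and truth
#'   bookkeeping (default 0.1, matching the phasing default).
#' @param founder_alt_prob Probability that the founder chromosome carries
#'   the alternate allele at an informative site (default 0.5). Informative
#'   sites enter such an analysis because they distinguish the founder
#'   lineage from common haplotypes, so the founder is enriched for minor
#'   alleles there relative to a random population draw.
#' @param recombination_spec List of per-family breakpoints, each
#'   \code{list(family = carrier-family-number, position =, side =
#'   "centromeric"|"telomeric")} (\code{side} names the direction in which
#'   the founder segment is lost), or the string \code{"random"} to give
#'   every carrier family a uniform random breakpoint and side. Default:
#'   carrier families 1 (centromeric) and 3 (telomeric) truncate on
#'   opposite sides and the rest transmit the full founder segment.
#' @param force_detectable Make each planted recombination observable: the
#'   first informative site beyond the breakpoint is set up so that the
#'   recombinant chromosome resolves to the non-founder allele there (and
#'   the sib-pair family resolves the founder allele). Reported
#'   recombinations are identified at observed discordant SNVs, so the
#'   validation scenario plants exactly that signal; with this off,
#'   breakpoint localization depends on chance mismatches beyond the
#'   breakpoint.
#' @param deletion_spec \code{list(family =, start =, end =)}: the carrier
#'   family (by carrier number) whose single affected individual carries
#'   the index variant hemizygously opposite this deletion, or NULL.
#' @param genotype_error_rate,missing_rate Per-allele flip rate and
#'   per-genotype missing rate in [0, 0.5].
#' @param seed Integer seed; identical seed and config give byte-identical
#'   output files.
#' @return An object of class \code{sim_config}.
#' @export
sim_config <- function(window = genomic_interval("chr17", 74712454, 75023150),
                       gene = genomic_interval("chr17", 74862454, 74873150),
                       n_sites = 120,
                       af_range = c(0.0005, 0.5),
                       n_families = 8,
                       n_carrier_families = 5,
                       index_pos = 74865062,
                       index_ref = "C", index_alt = "A",
                       index_af = 1.315e-05,
                       maf_informative = 0.1,
                       founder_alt_prob = 0.5,
                       recombination_spec = list(
                         list(family = 1, position = 74819000, side = "centromeric"),
                         list(family = 3, position = 74947400, side = "telomeric")),
                       force_detectable = TRUE,
                       deletion_spec = list(family = 4, start = 74818633,
                                            end = 74888183),
                       genotype_error_rate = 0,
                       missing_rate = 0,
                       seed = 1L) {
  if (n_carrier_families > n_families)
    stop("carrier families (", n_carrier_families,
         ") cannot exceed families (", n_families, ")")
  if (!(index_pos > gene$start && index_pos < gene$end))
    stop("index position must lie strictly inside the gene interval")
  if (!(gene$start >= window$start && gene$end <= window$end))
    stop("gene interval must lie inside the window")
  for (rate in c(genotype_error_rate, missing_rate))
    if (rate < 0 || rate > 0.5) stop("rates must lie in [0, 0.5]")
  if (is.list(recombination_spec)) {
    for (rs in recombination_spec) {
      if (rs$position < window$start || rs$position > window$end)
        stop("breakpoint ", rs$position, " lies outside the window")
      if (!rs$side %in% c("centromeric", "telomeric"))
        stop("breakpoint side must be 'centromeric' or 'telomeric'")
      if (rs$family > n_carrier_families) next  # ignored below
      if ((rs$side == "centromeric" && rs$position > index_pos) ||
          (rs$side == "telomeric" && rs$position < index_pos))
        stop("breakpoint at ", rs$position, " (", rs$side,
             ") would remove the index variant from the founder segment")
    }
  } else if (!identical(recombination_spec, "random")) {
    stop("recombination_spec must be a list of breakpoints or \"random\"")
  }
  structure(list(window = window, gene = gene, n_sites = n_sites,
                 af_range = af_range, n_families = n_families,
                 n_carrier_families = n_carrier_families,
                 index_pos = index_pos, index_ref = index_ref,
                 index_alt = index_alt, index_af = index_af,
                 maf_informative = maf_informative,
                 founder_alt_prob = founder_alt_prob,
                 recombination_spec = recombination_spec,
                 force_detectable = force_detectable,
                 deletion_spec = deletion_spec,
                 genotype_error_rate = genotype_error_rate,
                 missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

draw_background_matrix <- function(af, n_chrom) {
  # site-independent population chromosomes (rarity, not LD, carries the
  # evidential weight in this analysis)
  matrix(rbinom(n_chrom * length(af), 1L, rep(af, each = n_chrom)),
         nrow = n_chrom)
}

gt_string <- function(a1, a2) {
  s <- function(a) ifelse(is.na(a), ".", as.character(a))
  paste0(s(a1), "/", s(a2))
}

#' Simulate a founder cohort with a machine-readable truth ledger
#'
#' Draws SNV positions and frequencies, one founder haplotype, and a
#' multi-family cohort in which each carrier family transmits the founder
#' segment (possibly truncated at its planted recombination breakpoint) to
#' its affected offspring; non-carrier families are background trios. The
#' designated deletion family carries the index variant hemizygously
#' opposite the deletion (diploid-looking genotype calls are emitted over
#' the copy-loss region, as genotype callers do). Genotypes are then
#' perturbed at the configured error rate and masked at the missing rate.
#'
#' @param cfg A [sim_config()].
#' @param outdir If non-NULL, write \code{cohort.vcf}, \code{cohort.ped},
#'   \code{frequencies.tsv}, \code{deletions.tsv} and \code{truth.json}
#'   there (creating the directory). Identical seed and config give
#'   byte-identical files.
#' @return An object of class \code{sim_cohort}: list with \code{vcf}
#'   (a \code{vcf_data}), \code{ped}, \code{freq}, \code{deletions},
#'   \code{truth} (the generator's ledger: founder allele vector over
#'   informative sites, per-family transmitted segments and forced
#'   discordant sites, deletion, seed, config echo), and \code{paths} when
#'   written.
#' @export
simulate_cohort <- function(cfg = sim_config(), outdir = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  win <- cfg$window

  pool <- setdiff(seq(win$start, win$end), cfg$index_pos)
  pos <- sort(sample(pool, cfg$n_sites))
  af <- runif(cfg$n_sites, cfg$af_range[1], cfg$af_range[2])
  pos <- c(pos, cfg$index_pos)
  af <- c(af, cfg$index_af)
  o <- order(pos)
  pos <- pos[o]; af <- af[o]
  n <- length(pos)
  idx <- which(pos == cfg$index_pos)
  ref <- rep("A", n); alt <- rep("G", n)
  ref[idx] <- cfg$index_ref; alt[idx] <- cfg$index_alt
  ids <- rep(".", n); ids[idx] <- "index"
  keys <- variant_key(win$chrom, pos, ref, alt)
  informative <- af < cfg$maf_informative
  informative[idx] <- TRUE

  founder <- as.integer(runif(n) < ifelse(informative, cfg$founder_alt_prob, af))
  founder[idx] <- 1L

  # carrier roles and per-family breakpoints
  roles <- character(0)
  if (cfg$n_carrier_families > 0) {
    base <- c("trio", "sib_pair", "trio", "deletion", "singleton")
    roles <- rep("trio", cfg$n_carrier_families)
    roles[seq_len(min(5L, cfg$n_carrier_families))] <-
      base[seq_len(min(5L, cfg$n_carrier_families))]
    if (is.null(cfg$deletion_spec)) roles[roles == "deletion"] <- "trio"
  }
  brk <- vector("list", cfg$n_carrier_families)
  if (identical(cfg$recombination_spec, "random")) {
    for (k in seq_len(cfg$n_carrier_families)) {
      side <- if (runif(1) < 0.5) "centromeric" else "telomeric"
      position <- if (side == "centromeric")
        runif(1, win$start, cfg$index_pos) else runif(1, cfg$index_pos, win$end)
      brk[[k]] <- list(position = position, side = side)
    }
  } else {
    for (rs in cfg$recombination_spec)
      if (rs$family <= cfg$n_carrier_families)
        brk[[rs$family]] <- list(position = rs$position, side = rs$side)
  }

  retained_mask <- function(b) {
    if (is.null(b)) rep(TRUE, n)
    else if (b$side == "centromeric") pos >= b$position
    else pos <= b$position
  }
  first_beyond <- function(b) {
    # index (into sites) of the first informative site beyond the breakpoint
    if (b$side == "centromeric") {
      j <- which(informative & pos < b$position)
      if (length(j)) max(j) else NA_integer_
    } else {
      j <- which(informative & pos > b$position)
      if (length(j)) min(j) else NA_integer_
    }
  }

  samples <- character(0)
  gt_a1 <- list(); gt_a2 <- list()
  ped_rows <- list()
  del_rows <- list()
  truth_fam <- list()

  add_sample <- function(id, a1, a2) {
    samples[[length(samples) + 1L]] <<- id
    gt_a1[[length(gt_a1) + 1L]] <<- a1
    gt_a2[[length(gt_a2) + 1L]] <<- a2
  }
  add_ped <- function(fam, id, fa, mo, sex, pheno) {
    ped_rows[[length(ped_rows) + 1L]] <<-
      c(fam, id, fa, mo, as.character(sex), as.character(pheno))
  }

  carrier_k <- 0L
  for (f in seq_len(cfg$n_families)) {
    fam <- paste0("F", f)
    is_carrier <- f <= cfg$n_carrier_families
    if (!is_carrier) {
      bg <- draw_background_matrix(af, 6L)
      add_sample(paste0(fam, "_FA"), bg[1, ], bg[2, ])
      add_sample(paste0(fam, "_MO"), bg[3, ], bg[4, ])
      child <- rbind(bg[1L + rbinom(1, 1, 0.5), ], bg[3L + rbinom(1, 1, 0.5), ])
      add_sample(paste0(fam, "_CH"), child[1, ], child[2, ])
      add_ped(fam, paste0(fam, "_FA"), "0", "0", 1, 1)
      add_ped(fam, paste0(fam, "_MO"), "0", "0", 2, 1)
      add_ped(fam, paste0(fam, "_CH"), paste0(fam, "_FA"), paste0(fam, "_MO"), 1, 2)
      next
    }
    carrier_k <- carrier_k + 1L
    role <- roles[carrier_k]
    b <- brk[[carrier_k]]
    keep <- retained_mask(b)
    forced <- if (!is.null(b)) first_beyond(b) else NA_integer_

    if (role %in% c("trio", "sib_pair")) {
      fa_1 <- draw_background_matrix(af, 1L)[1, ]
      fa_2 <- draw_background_matrix(af, 1L)[1, ]
      mo_bg <- draw_background_matrix(af, 1L)[1, ]
      if (cfg$force_detectable && !is.na(forced)) {
        mo_bg[forced] <- 1L - founder[forced]
        fa_1[forced] <- founder[forced]
        fa_2[forced] <- founder[forced]
      }
      if (cfg$force_detectable && role == "sib_pair") {
        # resolve the founder allele at every forced site of other families
        for (bb in brk) if (!is.null(bb)) {
          j <- first_beyond(bb)
          if (!is.na(j)) { fa_1[j] <- founder[j]; fa_2[j] <- founder[j] }
        }
      }
      child_mat <- ifelse(keep, founder, mo_bg)
      add_sample(paste0(fam, "_FA"), fa_1, fa_2)
      add_sample(paste0(fam, "_MO"), founder, mo_bg)
      add_ped(fam, paste0(fam, "_FA"), "0", "0", 1, 1)
      add_ped(fam, paste0(fam, "_MO"), "0", "0", 2, 1)
      n_kids <- if (role == "sib_pair") 2L else 1L
      for (k in seq_len(n_kids)) {
        child_pat <- if (rbinom(1, 1, 0.5) == 1L) fa_1 else fa_2
        id <- if (n_kids == 1L) paste0(fam, "_CH") else paste0(fam, "_CH", k)
        add_sample(id, child_pat, child_mat)
        add_ped(fam, id, paste0(fam, "_FA"), paste0(fam, "_MO"), 1, 2)
      }
    } else if (role == "deletion") {
      ds <- cfg$deletion_spec
      id <- paste0(fam, "_CH")
      a1 <- ifelse(keep, founder, draw_background_matrix(af, 1L)[1, ])
      a2 <- draw_background_matrix(af, 1L)[1, ]  # physically deleted copy
      in_del <- pos >= ds$start & pos <= ds$end
      # diploid-looking calls over the copy-loss region reflect only the
      # retained chromosome
      a2[in_del] <- a1[in_del]
      add_sample(id, a1, a2)
      add_ped(fam, id, "0", "0", 1, 2)
      del_rows[[length(del_rows) + 1L]] <-
        c(id, win$chrom, ds$start, ds$end, 1, "simulated")
    } else { # singleton
      id <- paste0(fam, "_CH")
      a1 <- ifelse(keep, founder, draw_background_matrix(af, 1L)[1, ])
      a2 <- draw_background_matrix(af, 1L)[1, ]
      add_sample(id, a1, a2)
      add_ped(fam, id, "0", "0", 2, 2)
    }
    seg <- pos[informative & keep]
    truth_fam[[length(truth_fam) + 1L]] <- list(
      family = fam, role = role,
      segment_start = min(seg), segment_end = max(seg),
      breakpoint = if (is.null(b)) NULL else b,
      forced_site_pos = if (!is.na(forced)) pos[forced] else NULL,
      has_deletion = role == "deletion")
  }

  # genotype error and missingness perturbations
  A1 <- do.call(rbind, gt_a1)
  A2 <- do.call(rbind, gt_a2)
  if (cfg$genotype_error_rate > 0) {
    flip1 <- matrix(runif(length(A1)) < cfg$genotype_error_rate, nrow = nrow(A1))
    flip2 <- matrix(runif(length(A2)) < cfg$genotype_error_rate, nrow = nrow(A2))
    A1[flip1] <- 1L - A1[flip1]
    A2[flip2] <- 1L - A2[flip2]
  }
  if (cfg$missing_rate > 0) {
    miss <- matrix(runif(length(A1)) < cfg$missing_rate, nrow = nrow(A1))
    A1[miss] <- NA_integer_
    A2[miss] <- NA_integer_
  }
  samples <- unlist(samples)

  vcf_lines <- c(
    "##fileformat=VCFv4.2",
    "##source=founderhap-simulate",
    sprintf("##contig=<ID=%s>", win$chrom),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  for (s in seq_len(n)) {
    vcf_lines <- c(vcf_lines, paste(c(
      win$chrom, format(pos[s], scientific = FALSE), ids[s], ref[s], alt[s],
      ".", "PASS", ".", "GT", gt_string(A1[, s], A2[, s])), collapse = "\t"))
  }

  ped_lines <- vapply(ped_rows, paste, "", collapse = "\t")
  freq_lines <- c("chrom\tpos\tref\talt\taf",
                  sprintf("%s\t%s\t%s\t%s\t%s", win$chrom,
                          format(pos, scientific = FALSE), ref, alt,
                          format(af, scientific = FALSE, digits = 10)))
  del_lines <- c("sample\tchrom\tstart\tend\tcn\tevidence",
                 vapply(del_rows, paste, "", collapse = "\t"))

  truth <- list(
    seed = cfg$seed,
    index_key = keys[idx],
    index_pos = cfg$index_pos,
    informative_pos = pos[informative],
    informative_keys = keys[informative],
    founder_alleles = setNames(founder[informative], keys[informative]),
    families = truth_fam,
    site_af = setNames(af, keys),
    config = cfg[c("n_sites", "n_families", "n_carrier_families",
                   "genotype_error_rate", "missing_rate", "founder_alt_prob",
                   "maf_informative", "force_detectable")])

  paths <- NULL
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(vcf = file.path(outdir, "cohort.vcf"),
                  ped = file.path(outdir, "cohort.ped"),
                  freq = file.path(outdir, "frequencies.tsv"),
                  deletions = file.path(outdir, "deletions.tsv"),
                  truth = file.path(outdir, "truth.json"))
    writeLines(vcf_lines, paths$vcf)
    writeLines(ped_lines, paths$ped)
    writeLines(freq_lines, paths$freq)
    writeLines(del_lines, paths$deletions)
    truth_json <- truth
    truth_json$founder_alleles <- as.list(truth$founder_alleles)
    truth_json$site_af <- as.list(truth$site_af)
    truth_json$config <- truth$config
    jsonlite::write_json(truth_json, paths$truth, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }

  tmp_vcf <- tempfile(fileext = ".vcf"); writeLines(vcf_lines, tmp_vcf)
  tmp_ped <- tempfile(fileext = ".ped"); writeLines(ped_lines, tmp_ped)
  tmp_freq <- tempfile(fileext = ".tsv"); writeLines(freq_lines, tmp_freq)
  vcf <- read_vcf(tmp_vcf)
  ped <- read_ped(tmp_ped)
  freq <- read_frequency_table(tmp_freq)
  unlink(c(tmp_vcf, tmp_ped, tmp_freq))
  deletions <- NULL
  if (length(del_rows)) {
    tmp_del <- tempfile(fileext = ".tsv"); writeLines(del_lines, tmp_del)
    deletions <- read_deletions(tmp_del)
    unlink(tmp_del)
  }

  structure(list(vcf = vcf, ped = ped, freq = freq, deletions = deletions,
                 truth = truth, cfg = cfg, paths = paths),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf(
    "<sim_cohort> seed %d: %d families (%d carrier), %d sites (%d informative), %d samples\n",
    x$cfg$seed, x$cfg$n_families, x$cfg$n_carrier_families,
    nrow(x$vcf$sites), length(x$truth$informative_pos), length(x$vcf$samples)))
  invisible(x)
}

#' Draw synthetic non-carrier genotypes over a simulated cohort's sites
#'
#' Samples unrelated, founder-free individuals site-independently from the
#' cohort's configured allele frequencies — the chance-sharing null against
#' which singleton interrogation is assessed.
#'
#' @param cohort A \code{sim_cohort}.
#' @param n Number of individuals.
#' @param prefix Sample-id prefix.
#' @return A genotype-call data.frame in the [read_vcf()] calls layout.
#' @export
sim_noncarrier_calls <- function(cohort, n, prefix = "NC") {
  stopifnot(inherits(cohort, "sim_cohort"))
  af <- cohort$truth$site_af
  keys <- names(af)
  rows <- list()
  for (i in seq_len(n)) {
    g <- draw_background_matrix(unname(af), 2L)
    rows[[i]] <- data.frame(
      sample = sprintf("%s%03d", prefix, i), key = keys,
      chrom = cohort$vcf$sites$chrom[match(keys, cohort$vcf$sites$key)],
      pos = cohort$vcf$sites$pos[match(keys, cohort$vcf$sites$key)],
      a1 = g[1, ], a2 = g[2, ], phased = FALSE,
      dp = NA_integer_, ad_ref = NA_integer_, ad_alt = NA_integer_,
      raw = NA_character_, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
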