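#' @importFrom stats setNames na.omit rbinom runif
#' @importFrom utils read.delim write.table
NULL

variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, format(pos, scientific = FALSE, trim = TRUE), ref, alt, sep = ":")
}

parse_gt_string <- function(gt) {
  # "0/1", "1|0", "./.", "0/.": returns list(a1, a2, phased); alleles NA when "."
  phased <- grepl("|", gt, fixed = TRUE)
  parts <- strsplit(gt, "[/|]")
  a <- vapply(parts, function(p) {
    if (length(p) != 2L) c(NA_integer_, NA_integer_)
    else suppressWarnings(as.integer(ifelse(p == ".", NA, p)))
  }, integer(2))
  list(a1 = a[1, ], a2 = a[2, ], phased = phased,
       bad = lengths(parts) != 2L)
}

#' Read a VCF file into sites and genotype calls
#'
#' Parses the VCF v4.x subset used by this package: the eight fixed columns
#' plus FORMAT and sample columns, with \code{GT} and optionally \code{DP}
#' and \code{AD}. Multiallelic records are rejected by default because the
#' downstream analysis concerns biallelic SNVs; with
#' \code{split_multiallelic = TRUE} each ALT allele becomes its own site
#' (genotype codes pointing at another ALT of the same record are mapped to
#' missing rather than silently to reference).
#'
#' @param path Path to an uncompressed VCF text file.
#' @param split_multiallelic Split multiallelic records instead of erroring.
#'
#' @return An object of class \code{vcf_data}: a list with
#'   \describe{
#'     \item{sites}{data.frame, one row per (position, alt): \code{chrom},
#'       \code{pos}, \code{id}, \code{ref}, \code{alt}, \code{qual},
#'       \code{filter}, \code{info}, \code{format}, \code{key}, plus
#'       \code{gene}/\code{consequence}/\code{domain} columns parsed from
#'       INFO keys \code{GENE}/\code{CSQ}/\code{DOMAIN} when present.}
#'     \item{calls}{data.frame, one row per sample per site: \code{sample},
#'       \code{key}, \code{chrom}, \code{pos}, \code{a1}, \code{a2}
#'       (0 = ref, 1 = alt, NA = missing), \code{phased}, \code{dp},
#'       \code{ad_ref}, \code{ad_alt}, \code{raw} (verbatim sample field).}
#'     \item{header}{the \code{##} header lines, verbatim.}
#'     \item{samples}{sample names in column order.}
#'   }
#'   When phased, the allele order is (paternal-derived, maternal-derived).
#' @export
read_vcf <- function(path, split_multiallelic = FALSE) {
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1], "##fileformat=VCF"))
    stop("not a VCF file (missing ##fileformat header): ", path)
  hdr <- lines[startsWith(lines, "##")]
  chrom_i <- which(startsWith(lines, "#CHROM"))
  if (length(chrom_i) != 1L)
    stop("malformed VCF: expected exactly one #CHROM line in ", path)
  cols <- strsplit(lines[chrom_i], "\t", fixed = TRUE)[[1]]
  if (length(cols) < 8L)
    stop("malformed #CHROM line at line ", chrom_i, ": fewer than 8 columns")
  samples <- if (length(cols) > 9L) cols[-(1:9)] else character(0)
  rec_i <- setdiff(seq_along(lines), c(which(startsWith(lines, "#"))))
  rec_i <- rec_i[nzchar(lines[rec_i])]

  site_rows <- list()
  call_rows <- list()
  for (i in rec_i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 8L)
      stop("malformed VCF record at line ", i, ": fewer than 8 fields")
    if (length(samples) && length(f) != 9L + length(samples))
      stop("malformed VCF record at line ", i, ": expected ",
           9L + length(samples), " fields, got ", length(f))
    pos <- suppressWarnings(as.numeric(f[2]))
    if (is.na(pos)) stop("malformed POS at line ", i, ": ", f[2])
    alts <- strsplit(f[5], ",", fixed = TRUE)[[1]]
    if (length(alts) > 1L && !split_multiallelic)
      stop("multiallelic record at line ", i,
           " (ALT = ", f[5], "); re-run with split_multiallelic = TRUE ",
           "or normalize the input first")
    fmt <- if (length(f) >= 9L) f[9] else NA_character_
    fmt_keys <- if (!is.na(fmt)) strsplit(fmt, ":", fixed = TRUE)[[1]] else character(0)
    if (length(samples) && !"GT" %in% fmt_keys)
      stop("VCF record at line ", i, " lacks GT in FORMAT")
    sample_fields <- if (length(samples)) f[-(1:9)] else character(0)

    for (ai in seq_along(alts)) {
      alt <- alts[ai]
      if (alt == f[4]) stop("REF equals ALT at line ", i)
      key <- variant_key(f[1], pos, f[4], alt)
      site_rows[[length(site_rows) + 1L]] <- data.frame(
        chrom = f[1], pos = pos, id = f[3], ref = f[4], alt = alt,
        qual = f[6], filter = f[7], info = f[8], format = fmt,
        key = key, stringsAsFactors = FALSE)
      if (!length(samples)) next
      gts <- character(length(samples))
      dps <- rep(NA_integer_, length(samples))
      adr <- rep(NA_integer_, length(samples))
      ada <- rep(NA_integer_, length(samples))
      for (si in seq_along(samples)) {
        sv <- strsplit(sample_fields[si], ":", fixed = TRUE)[[1]]
        gts[si] <- sv[match("GT", fmt_keys)]
        di <- match("DP", fmt_keys)
        if (!is.na(di) && di <= length(sv))
          dps[si] <- suppressWarnings(as.integer(sv[di]))
        adi <- match("AD", fmt_keys)
        if (!is.na(adi) && adi <= length(sv)) {
          ad <- suppressWarnings(as.integer(strsplit(sv[adi], ",")[[1]]))
          if (length(ad) >= 1L + ai) { adr[si] <- ad[1]; ada[si] <- ad[1L + ai] }
        }
      }
      pg <- parse_gt_string(gts)
      if (any(pg$bad))
        stop("malformed GT at line ", i, " for sample ",
             samples[which(pg$bad)[1]], ": '", gts[which(pg$bad)[1]],
             "' (diploid GT required)")
      # map allele codes to this alt: code ai -> 1, 0 -> 0, other alt -> NA
      remap <- function(a) ifelse(is.na(a), NA_integer_,
                                  ifelse(a == 0L, 0L, ifelse(a == ai, 1L, NA_integer_)))
      call_rows[[length(call_rows) + 1L]] <- data.frame(
        sample = samples, key = key, chrom = f[1], pos = pos,
        a1 = remap(pg$a1), a2 = remap(pg$a2), phased = pg$phased,
        dp = dps, ad_ref = adr, ad_alt = ada, raw = sample_fields,
        stringsAsFactors = FALSE)
    }
  }
  sites <- if (length(site_rows)) do.call(rbind, site_rows) else
    data.frame(chrom = character(), pos = numeric(), id = character(),
               ref = character(), alt = character(), qual = character(),
               filter = character(), info = character(), format = character(),
               key = character(), stringsAsFactors = FALSE)
  rownames(sites) <- NULL
  # pull simple annotation keys out of INFO
  info_field <- function(info, k) {
    m <- regmatches(info, regexec(paste0("(?:^|;)", k, "=([^;]*)"), info))
    vapply(m, function(x) if (length(x) == 2L) x[2] else NA_character_, "")
  }
  sites$gene <- info_field(sites$info, "GENE")
  sites$consequence <- info_field(sites$info, "CSQ")
  sites$domain <- info_field(sites$info, "DOMAIN")
  calls <- if (length(call_rows)) do.call(rbind, call_rows) else
    data.frame(sample = character(), key = character(), chrom = character(),
               pos = numeric(), a1 = integer(), a2 = integer(),
               phased = logical(), dp = integer(), ad_ref = integer(),
               ad_alt = integer(), raw = character(), stringsAsFactors = FALSE)
  rownames(calls) <- NULL
  structure(list(sites = sites, calls = calls, header = hdr, samples = samples),
            class = "vcf_data")
}

#' @export
print.vcf_data <- function(x, ...) {
  cat(sprintf("<vcf_data> %d site(s), %d sample(s), %d genotype call(s)\n",
              nrow(x$sites), length(x$samples), nrow(x$calls)))
  invisible(x)
}

#' Write a vcf_data object back to a VCF file
#'
#' Inverse of [read_vcf()] for records that were not multiallelic-split:
#' header lines, site order, genotype strings and phase separators are
#' preserved byte-for-byte.
#'
#' @param x A \code{vcf_data} object.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_vcf <- function(x, path) {
  stopifnot(inherits(x, "vcf_data"))
  chrom_line <- paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                        "FILTER", "INFO",
                        if (length(x$samples)) c("FORMAT", x$samples)),
                      collapse = "\t")
  recs <- character(nrow(x$sites))
  for (r in seq_len(nrow(x$sites))) {
    s <- x$sites[r, ]
    fixed <- c(s$chrom, format(s$pos, scientific = FALSE, trim = TRUE),
               s$id, s$ref, s$alt, s$qual, s$filter, s$info)
    if (length(x$samples)) {
      cc <- x$calls[x$calls$key == s$key, ]
      raw <- cc$raw[match(x$samples, cc$sample)]
      fixed <- c(fixed, s$format, raw)
    }
    recs[r] <- paste(fixed, collapse = "\t")
  }
  writeLines(c(x$header, chrom_line, recs), path)
  invisible(path)
}

#' Read a 6-column PED pedigree file
#'
#' Whitespace-delimited columns: family id, individual id, father id,
#' mother id, sex (1 = male, 2 = female, 0 = unknown), phenotype
#' (2 = affected). A parent id of \code{"0"} means the parent is
#' unavailable; any other parent id must resolve to an individual in the
#' same family.
#'
#' @param path Path to the PED file.
#' @return A data.frame of class \code{pedigree} with columns \code{family},
#'   \code{id}, \code{father}, \code{mother} (NA when unavailable),
#'   \code{sex}, \code{affected} (logical).
#' @export
read_ped <- function(path) {
  raw <- read.delim(path, header = FALSE, sep = "", comment.char = "#",
                    colClasses = "character", blank.lines.skip = TRUE)
  if (ncol(raw) != 6L)
    stop("PED file must have exactly 6 columns, found ", ncol(raw), ": ", path)
  names(raw) <- c("family", "id", "father", "mother", "sex", "phenotype")
  ped <- data.frame(
    family = raw$family, id = raw$id,
    father = ifelse(raw$father == "0", NA_character_, raw$father),
    mother = ifelse(raw$mother == "0", NA_character_, raw$mother),
    sex = suppressWarnings(as.integer(raw$sex)),
    affected = raw$phenotype == "2",
    stringsAsFactors = FALSE)
  validate_pedigree(ped)
  class(ped) <- c("pedigree", "data.frame")
  ped
}

validate_pedigree <- function(ped) {
  if (anyDuplicated(paste(ped$family, ped$id)))
    stop("duplicate individual id within a family")
  for (r in seq_len(nrow(ped))) {
    fam <- ped$family[r]
    for (p in c(ped$father[r], ped$mother[r])) {
      if (!is.na(p) && !p %in% ped$id[ped$family == fam])
        stop("dangling parent id '", p, "' for individual '", ped$id[r],
             "' in family '", fam, "': parents must be listed or marked 0")
    }
  }
  # no individual is its own ancestor
  anc <- function(fam, id, seen = character(0)) {
    if (id %in% seen) stop("pedigree cycle: individual '", id,
                           "' in family '", fam, "' is its own ancestor")
    row <- ped[ped$family == fam & ped$id == id, ]
    for (p in c(row$father, row$mother))
      if (!is.na(p)) anc(fam, p, c(seen, id))
  }
  for (r in seq_len(nrow(ped))) anc(ped$family[r], ped$id[r])
  invisible(ped)
}

#' Parents of an individual in a pedigree
#'
#' @param ped A \code{pedigree}.
#' @param family,id Family and individual id.
#' @return List with \code{father} and \code{mother} ids (NA if unavailable).
#' @export
ped_parents <- function(ped, family, id) {
  row <- ped[ped$family == family & ped$id == id, ]
  if (nrow(row) != 1L) stop("individual '", id, "' not found in family '", family, "'")
  list(father = row$father, mother = row$mother)
}

#' Read a population allele-frequency table
#'
#' Tab-separated with header columns \code{chrom}, \code{pos}, \code{ref},
#' \code{alt}, \code{af} — a file-based stand-in for a population frequency
#' resource such as gnomAD. Sites absent from the table are treated
#' downstream as frequency-unknown.
#'
#' @param path Path to the TSV file.
#' @return A data.frame of class \code{freq_table} keyed by
#'   \code{chrom:pos:ref:alt}.
#' @export
read_frequency_table <- function(path) {
  df <- read.delim(path, colClasses = c(chrom = "character", ref = "character",
                                        alt = "character"))
  need <- c("chrom", "pos", "ref", "alt", "af")
  if (!all(need %in% names(df)))
    stop("frequency table must have columns ", paste(need, collapse = ", "))
  if (any(is.na(df$af)) || any(df$af < 0 | df$af > 1))
    stop("allele frequencies must lie in [0, 1]")
  df$key <- variant_key(df$chrom, df$pos, df$ref, df$alt)
  dup <- df$key[duplicated(df$key)]
  for (k in unique(dup)) {
    if (length(unique(df$af[df$key == k])) > 1L)
      stop("conflicting allele frequencies for ", k)
  }
  df <- df[!duplicated(df$key), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("freq_table", "data.frame")
  df
}

#' Look up allele frequencies for variant sites
#'
#' @param freq A \code{freq_table} (or NULL: all unknown).
#' @param key Character vector of \code{chrom:pos:ref:alt} keys.
#' @return Numeric vector of frequencies; NA where unknown.
#' @export
lookup_af <- function(freq, key) {
  if (is.null(freq)) return(rep(NA_real_, length(key)))
  freq$af[match(key, freq$key)]
}

#' Attach population frequencies to a site table
#'
#' @param sites Site data.frame with a \code{key} column (as from [read_vcf()]).
#' @param freq A \code{freq_table}.
#' @return \code{sites} with a \code{population_af} column (NA = unknown).
#' @export
annotate_frequency <- function(sites, freq) {
  sites$population_af <- lookup_af(freq, sites$key)
  sites
}

#' Read a deletion/CNV call table
#'
#' Tab-separated with header columns \code{sample}, \code{chrom},
#' \code{start}, \code{end}, \code{cn} (copy number: 1 = heterozygous
#' deletion, 0 = homozygous loss), optional \code{evidence}. Deletions are
#' consumed as upstream calls; this package does not discover them from
#' reads.
#'
#' @param path Path to the TSV file.
#' @return A data.frame of class \code{deletion_table}.
#' @export
read_deletions <- function(path) {
  df <- read.delim(path, colClasses = c(sample = "character", chrom = "character"))
  need <- c("sample", "chrom", "start", "end", "cn")
  if (!all(need %in% names(df)))
    stop("deletion table must have columns ", paste(need, collapse = ", "))
  if (!all(df$cn %in% c(0L, 1L)))
    stop("deletion copy number must be 0 or 1")
  if (any(df$end < df$start)) stop("deletion end before start")
  if (!"evidence" %in% names(df)) df$evidence <- NA_character_
  class(df) <- c("deletion_table", "data.frame")
  df
}

#' Deletions carried by one sample
#'
#' @param deletions A \code{deletion_table} (or NULL).
#' @param sample Sample id.
#' @return List of \code{genomic_interval}s (possibly empty) with copy
#'   number attached as attribute \code{cn}.
#' @export
sample_deletions <- function(deletions, sample) {
  if (is.null(deletions)) return(list())
  rows <- deletions[deletions$sample == sample, , drop = FALSE]
  lapply(seq_len(nrow(rows)), function(r) {
    iv <- genomic_interval(rows$chrom[r], rows$start[r], rows$end[r])
    attr(iv, "cn") <- rows$cn[r]
    iv
  })
}
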