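# Independent brute-force oracles and fixture builders used across the suite.

# Exhaustive trio-phase oracle: enumerates both orderings of the child's
# alleles at each site and keeps those consistent with what each parent can
# transmit (enumeration, not set logic, so it is an independent check).
oracle_phase_trio <- function(child, father = NULL, mother = NULL) {
  n <- nrow(child)
  res <- data.frame(paternal = rep(NA_integer_, n),
                    maternal = rep(NA_integer_, n),
                    status = rep("", n), stringsAsFactors = FALSE)
  transmittable <- function(parent, s) {
    if (is.null(parent)) return(c(0L, 1L))
    g <- parent[s, ]
    if (any(is.na(g))) return(c(0L, 1L))
    sort(unique(as.integer(g)))
  }
  for (s in seq_len(n)) {
    c1 <- child[s, 1]; c2 <- child[s, 2]
    if (is.na(c1) || is.na(c2)) { res$status[s] <- "missing"; next }
    Fs <- transmittable(father, s)
    Ms <- transmittable(mother, s)
    keep <- list()
    for (ord in list(c(c1, c2), c(c2, c1))) {
      ok <- FALSE
      for (fa in Fs) for (ma in Ms)
        if (fa == ord[1] && ma == ord[2]) ok <- TRUE
      if (ok) keep[[paste(ord, collapse = ",")]] <- ord
    }
    if (length(keep) == 0L) {
      res$status[s] <- "mendel_conflict"
    } else if (length(keep) == 1L) {
      a <- keep[[1]]
      res$paternal[s] <- a[1]; res$maternal[s] <- a[2]
      res$status[s] <- "resolved"
    } else {
      res$status[s] <- "unresolved"
    }
  }
  res
}

# Exhaustive shared-core oracle: enumerates every contiguous site run
# containing the index and returns the longest one free of resolved
# discordance, then reports boundaries at the outermost concordant sites.
oracle_core <- function(m, pos, index_idx) {
  n <- ncol(m)
  col_discordant <- function(j) {
    vals <- m[, j][!is.na(m[, j])]
    length(unique(vals)) > 1L
  }
  col_concordant <- function(j) {
    vals <- m[, j][!is.na(m[, j])]
    length(vals) >= 1L && length(unique(vals)) == 1L
  }
  best <- NULL
  for (i in seq_len(index_idx)) {
    for (j in index_idx:n) {
      ok <- TRUE
      for (k in i:j) if (col_discordant(k)) { ok <- FALSE; break }
      if (ok && (is.null(best) || (j - i) > (best[2] - best[1])))
        best <- c(i, j)
    }
  }
  stopifnot(!is.null(best))
  run <- best[1]:best[2]
  conc <- run[vapply(run, col_concordant, TRUE)]
  if (!length(conc)) conc <- index_idx
  list(run = run, b_lo = min(conc), b_hi = max(conc),
       start = pos[min(conc)], end = pos[max(conc)])
}

# Breakpoint-side oracle: per family, first out-of-core site (scanning
# outward) whose resolved allele differs from the explicitly counted modal
# allele of that column.
oracle_breakpoints <- function(m, pos, fams, b_lo, b_hi) {
  n <- ncol(m)
  modal <- function(j) {
    counts <- c(`0` = 0L, `1` = 0L)
    for (v in m[, j]) if (!is.na(v)) counts[as.character(v)] <- counts[as.character(v)] + 1L
    if (counts[1] == counts[2]) return(NA_integer_)
    if (counts["1"] > counts["0"]) 1L else 0L
  }
  out <- list()
  for (f in unique(fams)) {
    rows <- which(fams == f)
    cent <- NA_real_; tel <- NA_real_
    if (b_lo > 1L) for (j in (b_lo - 1L):1L) {
      mo <- modal(j)
      if (!is.na(mo) && any(!is.na(m[rows, j]) & m[rows, j] != mo)) {
        cent <- pos[j]; break
      }
    }
    if (b_hi < n) for (j in (b_hi + 1L):n) {
      mo <- modal(j)
      if (!is.na(mo) && any(!is.na(m[rows, j]) & m[rows, j] != mo)) {
        tel <- pos[j]; break
      }
    }
    side <- if (!is.na(cent) && !is.na(tel)) "both"
    else if (!is.na(cent)) "centromeric"
    else if (!is.na(tel)) "telomeric" else "none"
    out[[f]] <- list(side = side, centromeric_pos = cent, telomeric_pos = tel)
  }
  out
}

# Build a list of phased_haplotype objects from an allele matrix.
make_haps <- function(m, pos, chrom = "chr17", fams = NULL) {
  if (is.null(fams)) fams <- paste0("fam", seq_len(nrow(m)))
  sites <- data.frame(chrom = chrom, pos = pos, id = ".",
                      ref = "A", alt = "G",
                      key = paste(chrom, pos, "A", "G", sep = ":"),
                      stringsAsFactors = FALSE)
  lapply(seq_len(nrow(m)), function(i) {
    al <- m[i, ]
    founderhap:::new_phased_haplotype(
      paste0("ind", i), fams[i], sites, al,
      ifelse(is.na(al), "unresolved", "resolved_test"), TRUE)
  })
}

# Write a small VCF from record lines; returns the path.
write_test_vcf <- function(records, samples = c("S1", "S2"),
                           format = "GT", header_extra = character(0)) {
  path <- tempfile(fileext = ".vcf")
  hdr <- c("##fileformat=VCFv4.2", header_extra,
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(hdr, records), path)
  path
}

fixture_path <- function(name) {
  system.file("extdata", name, package = "founderhap")
}

# Random error-free trio over n sites: parents drawn uniformly, child
# alleles transmitted one from each parent, then shuffled within genotype.
random_trio <- function(n) {
  father <- matrix(sample(0:1, 2 * n, replace = TRUE), ncol = 2)
  mother <- matrix(sample(0:1, 2 * n, replace = TRUE), ncol = 2)
  pat <- father[cbind(seq_len(n), sample(1:2, n, replace = TRUE))]
  mat <- mother[cbind(seq_len(n), sample(1:2, n, replace = TRUE))]
  child <- matrix(NA_integer_, nrow = n, ncol = 2)
  for (s in seq_len(n)) {
    if (sample(c(TRUE, FALSE), 1)) child[s, ] <- c(pat[s], mat[s])
    else child[s, ] <- c(mat[s], pat[s])
  }
  list(child = child, father = father, mother = mother,
       truth_pat = pat, truth_mat = mat)
}
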