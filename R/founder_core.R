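column_state <- function(col) {
  # classify one site across haplotypes: resolved values all equal ->
  # concordant; none resolved -> wildcard; otherwise discordant
  r <- col[!is.na(col)]
  if (!length(r)) list(state = "wildcard", consensus = NA_integer_)
  else if (length(unique(r)) == 1L) list(state = "concordant", consensus = r[1])
  else list(state = "discordant", consensus = NA_integer_)
}

column_mode <- function(col) {
  # modal resolved allele; NA on tie or no data (used for breakpoint
  # attribution beyond the core)
  r <- col[!is.na(col)]
  if (!length(r)) return(NA_integer_)
  tab <- table(r)
  if (sum(tab == max(tab)) > 1L) return(NA_integer_)
  as.integer(names(tab)[which.max(tab)])
}

#' Maximal shared core across carrier haplotypes
#'
#' Finds the maximal contiguous run of informative sites containing the
#' index variant at which all carrier haplotypes carry the same resolved
#' allele or a wildcard (unresolved site). A site where every haplotype is
#' unresolved contributes no evidence and cannot break the core; extension
#' stops at the first site with any resolved discordance. The core interval
#' is reported from the first to the last \emph{concordant} site of the run
#' (wildcard-only sites at the run edges are listed as unresolved support,
#' not used as boundaries), matching the convention of reporting a shared
#' haplotype from outermost observed concordant SNV to outermost observed
#' concordant SNV.
#'
#' For each family whose haplotype is discordant beyond the core, the side
#' of its recombination is reported: \code{centromeric} (first discordant
#' site below the core, in the lower-coordinate direction) or
#' \code{telomeric} (above the core); a family discordant on both sides is
#' labelled \code{both}. Discordance of a haplotype at an out-of-core site
#' is measured against the modal resolved allele there (the allele still
#' shared by the families whose founder segment extends further); where the
#' resolved alleles tie, the recombinant family cannot be identified and no
#' family is attributed at that site.
#'
#' @param haps A \code{haplotype_set} (or list of \code{phased_haplotype}
#'   over one site list) with at least one haplotype.
#' @param index_pos Genomic position of the index variant; must be one of
#'   the haplotype sites.
#' @param tolerance Number of resolved mismatches tolerated before
#'   extension stops (default 0: any resolved mismatch ends the core).
#' @return An object of class \code{core_result}: list with \code{core}
#'   (\code{genomic_interval} between the two boundary sites),
#'   \code{boundary_sites} (ids/keys of the flanking concordant sites),
#'   \code{core_keys}, \code{consensus} (named allele vector over core
#'   sites), \code{unresolved_support} (wildcard-only site keys inside the
#'   run), \code{per_family_breakpoints} (data.frame: family, side,
#'   centromeric_pos, telomeric_pos), \code{discordant_sites} (positions),
#'   \code{n_haplotypes}, \code{span_bp}.
#' @export
shared_core <- function(haps, index_pos, tolerance = 0) {
  if (!length(haps)) stop("shared_core requires at least one haplotype")
  m <- haplotype_matrix(haps)
  sites <- haps[[1]]$sites
  n <- nrow(sites)
  idx <- which(sites$pos == index_pos)
  if (length(idx) != 1L)
    stop("index position ", index_pos, " is not a haplotype site")
  st <- lapply(seq_len(n), function(j) column_state(m[, j, drop = TRUE]))
  state <- vapply(st, `[[`, "", "state")
  consensus <- vapply(st, function(x) as.integer(x$consensus), 1L)

  # extend from the index site, stopping after `tolerance` discordant sites
  lo <- idx
  bad <- 0L
  while (lo > 1L) {
    if (state[lo - 1L] == "discordant") {
      bad <- bad + 1L
      if (bad > tolerance) break
    }
    lo <- lo - 1L
  }
  hi <- idx
  bad <- 0L
  while (hi < n) {
    if (state[hi + 1L] == "discordant") {
      bad <- bad + 1L
      if (bad > tolerance) break
    }
    hi <- hi + 1L
  }
  run <- lo:hi
  conc <- run[state[run] == "concordant"]
  if (!length(conc)) conc <- idx  # degenerate: lone index site
  b_lo <- min(conc); b_hi <- max(conc)
  core <- genomic_interval(sites$chrom[b_lo], sites$pos[b_lo], sites$pos[b_hi])
  core_run <- b_lo:b_hi

  fams <- vapply(haps, function(h) h$family, "")
  mode_allele <- vapply(seq_len(n), function(j) column_mode(m[, j, drop = TRUE]), 1L)
  bp <- data.frame(family = unique(fams), side = "none",
                   centromeric_pos = NA_real_, telomeric_pos = NA_real_,
                   stringsAsFactors = FALSE)
  for (fi in seq_len(nrow(bp))) {
    rows <- which(fams == bp$family[fi])
    disc_at <- function(j) {
      # attribution needs a defined modal allele; at a tie the recombinant
      # family cannot be identified and nobody is attributed
      any(!is.na(m[rows, j]) & !is.na(mode_allele[j]) &
            m[rows, j] != mode_allele[j])
    }
    left <- if (b_lo > 1L) rev(seq_len(b_lo - 1L)) else integer(0)
    for (j in left) if (disc_at(j)) { bp$centromeric_pos[fi] <- sites$pos[j]; break }
    right <- if (b_hi < n) (b_hi + 1L):n else integer(0)
    for (j in right) if (disc_at(j)) { bp$telomeric_pos[fi] <- sites$pos[j]; break }
    bp$side[fi] <- if (!is.na(bp$centromeric_pos[fi]) && !is.na(bp$telomeric_pos[fi]))
      "both"
    else if (!is.na(bp$centromeric_pos[fi])) "centromeric"
    else if (!is.na(bp$telomeric_pos[fi])) "telomeric"
    else "none"
  }

  cons <- consensus[core_run]
  names(cons) <- sites$key[core_run]
  structure(list(
    core = core,
    boundary_sites = c(site_label(sites, b_lo), site_label(sites, b_hi)),
    core_keys = sites$key[core_run],
    consensus = cons,
    unresolved_support = sites$key[core_run][state[core_run] == "wildcard"],
    per_family_breakpoints = bp,
    discordant_sites = sites$pos[state == "discordant"],
    n_haplotypes = length(haps),
    span_bp = core$end - core$start,
    sites = sites,
    index_pos = index_pos,
    matrix = m), class = "core_result")
}

site_label <- function(sites, i) {
  id <- sites$id[i]
  if (!is.null(id) && !is.na(id) && nzchar(id) && id != ".") id else sites$key[i]
}

#' @export
print.core_result <- function(x, ...) {
  cat("Shared ancestral haplotype core\n")
  cat(sprintf("  %d carrier haplotype(s) over %d informative sites\n",
              x$n_haplotypes, nrow(x$sites)))
  cat(sprintf("  core: %s:%s-%s  (%s bp, %d kb), %d site(s), boundaries %s .. %s\n",
              x$core$chrom,
              format(x$core$start, scientific = FALSE),
              format(x$core$end, scientific = FALSE),
              format(x$span_bp, scientific = FALSE), span_kb(x$core),
              length(x$core_keys), x$boundary_sites[1], x$boundary_sites[2]))
  bp <- x$per_family_breakpoints
  for (r in seq_len(nrow(bp))) {
    if (bp$side[r] == "none") next
    pos <- stats::na.omit(c(bp$centromeric_pos[r], bp$telomeric_pos[r]))
    cat(sprintf("  family %s: recombination %s (first discordant site %s)\n",
                bp$family[r], bp$side[r],
                paste(format(pos, scientific = FALSE, trim = TRUE),
                      collapse = ", ")))
  }
  invisible(x)
}

#' @export
summary.core_result <- function(object, ...) {
  cat(sprintf(
    "Core spans %d kb (%s bp) across %d haplotypes; %d concordant-run sites (%d unresolved support), %d discordant sites outside.\n",
    span_kb(object$core), format(object$span_bp, scientific = FALSE),
    object$n_haplotypes, length(object$core_keys),
    length(object$unresolved_support), length(object$discordant_sites)))
  invisible(object)
}

#' Plot a core_result haplotype matrix
#'
#' Draws the haplotype-by-site allele matrix (ref, alt, unresolved) with
#' the shared core shaded and the index variant marked.
#'
#' @param x A \code{core_result}.
#' @param ... Passed to \code{graphics::image}.
#' @export
plot.core_result <- function(x, ...) {
  m <- x$matrix
  z <- t(m)[, rev(seq_len(nrow(m))), drop = FALSE]
  graphics::image(x = x$sites$pos, y = seq_len(nrow(m)), z = z,
                  col = c("grey85", "firebrick"), xlab = "position",
                  ylab = "", yaxt = "n", ...)
  graphics::axis(2, at = seq_len(nrow(m)), labels = rev(rownames(m)),
                 las = 2, cex.axis = 0.7)
  graphics::rect(x$core$start, 0.5, x$core$end, nrow(m) + 0.5,
                 border = "navy", lwd = 2)
  graphics::abline(v = x$index_pos, lty = 2)
  invisible(x)
}

#' Span of a core interval in whole kilobases
#'
#' The span between the two boundary point coordinates,
#' \code{floor((end - start) / 1000)}; e.g. boundaries 74819055 and
#' 74947323 give 128268 bp, reported as 128 kb. The exact bp difference is
#' attached as attribute \code{bp}.
#'
#' @param core A \code{genomic_interval} (or a \code{core_result}).
#' @return Integer kb span with attribute \code{bp}.
#' @export
span_kb <- function(core) {
  if (inherits(core, "core_result")) core <- core$core
  stopifnot(inherits(core, "genomic_interval"))
  bp <- core$end - core$start
  structure(as.integer(floor(bp / 1000)), bp = bp)
}

#' Interrogate an unphased singleton genotype against a core consensus
#'
#' A singleton cannot be phased, but every allele of an established core
#' haplotype can be looked for directly in its genotype: the verdict is
#' \code{consistent} if the consensus allele is present (het or hom) at
#' every resolved core site, \code{inconsistent} if absent at any, and
#' \code{indeterminate} if no core site is testable (all genotypes
#' missing). Presence, not phase, is assessed.
#'
#' @param calls Genotype-call data.frame containing the singleton's calls.
#' @param sample Singleton sample id.
#' @param core A \code{core_result} (supplies core sites and consensus
#'   alleles), or a named integer vector of consensus alleles keyed by
#'   site key.
#' @return List of class \code{interrogation}: \code{verdict},
#'   \code{per_site} data.frame (key, consensus, present),
#'   \code{n_untestable}, \code{missing_sites}.
#' @export
interrogate_singleton <- function(calls, sample, core) {
  cons <- if (inherits(core, "core_result")) core$consensus else core
  cons <- cons[!is.na(cons)]
  keys <- names(cons)
  g <- genotype_matrix(calls, sample, keys)
  present <- rep(NA, length(keys))
  for (i in seq_along(keys)) {
    a <- g[i, ]
    if (all(is.na(a))) next
    present[i] <- cons[i] %in% a[!is.na(a)]
  }
  verdict <- if (all(is.na(present))) "indeterminate"
  else if (any(!present, na.rm = TRUE)) "inconsistent"
  else "consistent"
  structure(list(
    verdict = verdict,
    per_site = data.frame(key = keys, consensus = as.integer(cons),
                          present = present, stringsAsFactors = FALSE),
    n_untestable = sum(is.na(present)),
    missing_sites = keys[is.na(present)]), class = "interrogation")
}

#' @export
print.interrogation <- function(x, ...) {
  cat(sprintf("<interrogation> verdict: %s (%d/%d sites testable",
              x$verdict, sum(!is.na(x$per_site$present)), nrow(x$per_site)))
  bad <- x$per_site$key[!is.na(x$per_site$present) & !x$per_site$present]
  if (length(bad)) cat("; absent at ", paste(bad, collapse = ", "), sep = "")
  cat(")\n")
  invisible(x)
}
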